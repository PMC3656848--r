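#' MCMC configuration
#'
#' Settings for the reversible-jump Mk mapping chain. `ratedev` is the
#' half-width of the uniform sliding-window proposal on each rate
#' (reflected at zero), the knob that is tuned until the rate-proposal
#' acceptance rate falls in `target_accept` (20-40\% by default). Under
#' the `"hyper_exp"` prior each rate has an exponential prior whose mean
#' is itself uniform on `hyper` and is resampled by its own Metropolis
#' move; `"uniform"` gives a flat prior on `[0, uniform_max]`.
#'
#' @param iterations Total chain length.
#' @param burnin Iterations discarded before summarization
#'   (default 25\%).
#' @param ratedev Positive proposal half-width.
#' @param hyper Interval `[a, b]` for the exponential prior's mean.
#' @param seed Integer RNG seed; the chain is fully reproducible.
#' @param rj Logical: enable reversible-jump moves between the equal-rates
#'   and distinct-rates models.
#' @param thin Keep every `thin`-th post-burn-in iteration for summaries.
#' @param target_accept Length-2 acceptance window for [tune_ratedev()].
#' @param prior `"hyper_exp"` or `"uniform"`.
#' @param uniform_max Upper bound of the flat rate prior.
#' @return An object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(iterations = 100000L,
                        burnin = floor(iterations * 0.25),
                        ratedev = 1, hyper = c(0, 20), seed = 1L,
                        rj = TRUE, thin = 100L,
                        target_accept = c(0.20, 0.40),
                        prior = c("hyper_exp", "uniform"),
                        uniform_max = 100) {
  prior <- match.arg(prior)
  stopifnot(iterations >= 1, burnin >= 0, burnin < iterations,
            ratedev > 0, length(hyper) == 2L, hyper[1] <= hyper[2],
            hyper[1] >= 0, thin >= 1, uniform_max > 0)
  structure(list(iterations = as.integer(iterations),
                 burnin = as.integer(burnin), ratedev = ratedev,
                 hyper = as.numeric(hyper), seed = as.integer(seed),
                 rj = isTRUE(rj), thin = as.integer(thin),
                 target_accept = target_accept, prior = prior,
                 uniform_max = uniform_max),
            class = "mcmc_config")
}

#' @keywords internal
#' log prior density of a rate vector
.rate_logprior <- function(r, cfg, m) {
  if (cfg$prior == "uniform") {
    if (any(r > cfg$uniform_max)) return(-Inf)
    return(0)
  }
  if (m <= 0) m <- 1e-12
  sum(stats::dexp(r, rate = 1 / m, log = TRUE))
}

#' @keywords internal
#' reflect a proposal at 0 (and optionally at an upper bound)
.reflect <- function(x, lower = 0) {
  bad <- x < lower
  x[bad] <- 2 * lower - x[bad]
  x
}

#' @keywords internal
#' Marginal node-state posteriors by the up-down algorithm.
#' Returns an (ntip+nnode) x k matrix of per-node marginals.
.mk_node_marginals <- function(prep, Q, prior, constraint = NULL) {
  k <- prep$k
  nn <- prep$ntip + prep$nnode
  edge <- prep$edge
  ne <- nrow(edge)
  D <- matrix(1, nn, k)
  D[seq_len(prep$ntip), ] <- prep$tipp
  if (!is.null(constraint)) {
    for (v in which(!is.na(constraint))) {
      keep <- constraint[v]
      D[v, -keep] <- 0
    }
  }
  P <- vector("list", ne)
  msg <- matrix(0, ne, k)
  for (e in seq_len(ne)) {
    P[[e]] <- expQt(Q, prep$el[e])
    v <- as.vector(P[[e]] %*% D[edge[e, 2L], ])
    m <- max(v)
    if (m <= 0) return(NULL)  # data impossible under constraint
    msg[e, ] <- v / m
    D[edge[e, 1L], ] <- D[edge[e, 1L], ] * msg[e, ]
    if (!is.null(constraint) && !is.na(constraint[edge[e, 1L]])) {
      D[edge[e, 1L], -constraint[edge[e, 1L]]] <- 0
    }
  }
  U <- matrix(0, nn, k)
  U[prep$root, ] <- prior
  children <- split(seq_len(ne), edge[, 1L])
  for (e in rev(seq_len(ne))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    rest <- U[par, ]
    for (e2 in children[[as.character(par)]]) {
      if (e2 != e) rest <- rest * msg[e2, ]
    }
    u <- as.vector(rest %*% P[[e]])
    if (!is.null(constraint) && !is.na(constraint[ch])) u[-constraint[ch]] <- 0
    m <- max(u)
    U[ch, ] <- if (m > 0) u / m else u
  }
  post <- U * D
  s <- rowSums(post)
  s[s <= 0] <- 1
  post / s
}

#' @keywords internal
#' Resolve named tip sets to ape node ids on one tree; NA when the tip
#' set is not a monophyletic clade there.
.resolve_nodes <- function(tree, tip_sets) {
  ntip <- length(tree$tip.label)
  vapply(tip_sets, function(tips) {
    idx <- match(tips, tree$tip.label)
    if (anyNA(idx)) return(NA_integer_)
    if (length(idx) == 1L) return(idx)
    mrca <- ape::getMRCA(tree, idx)
    desc <- ape::extract.clade(tree, mrca)$tip.label
    if (setequal(desc, tips)) mrca else NA_integer_
  }, integer(1))
}

#' Reversible-jump MCMC ancestral state mapping
#'
#' Metropolis-Hastings chain over transition rates, an optional rate-model
#' indicator (equal versus distinct rates, the reversible-jump move for a
#' binary character), the hyperprior mean, and the current tree of a
#' posterior sample. Trees are proposed uniformly at random from the
#' sample and accepted through the usual likelihood ratio, so
#' phylogenetic uncertainty is integrated over. At every retained
#' iteration the marginal node-state posteriors are computed on the
#' current tree and averaged; nodes are addressed as MRCAs of tip sets so
#' they remain identifiable across topologies, and iterations whose tree
#' lacks a node's tip set as a clade are skipped for that node's summary.
#'
#' @param sample A [tree_sample()] (or single `"phylo"`).
#' @param char A [character_matrix()].
#' @param model A [rate_model()] template; its design defines the
#'   "distinct rates" model, and the reversible jump collapses all free
#'   classes into one for the "equal rates" model.
#' @param config An [mcmc_config()].
#' @param node_constraints Optional named list `tip-set name -> state`
#'   fossilizing nodes at fixed states (for Bayes-factor node tests).
#' @param nodes Named list of tip-label vectors addressing the nodes to
#'   summarize; defaults to every internal clade of the first tree, named
#'   `n<ape node id>`. Supply `list()` to skip node summaries.
#' @return An object of class `"mk_posterior"`: mean per-node, per-state
#'   posterior probabilities (`node_pp`), rate-proposal acceptance rate,
#'   visited model frequencies (`model_freq`), the harmonic-mean log
#'   marginal likelihood (`log_hm`, with jackknife standard error as an
#'   attribute), retained log-likelihoods and rates, and bookkeeping.
#' @export
run_mcmc <- function(sample, char, model, config = mcmc_config(),
                     node_constraints = NULL, nodes = NULL) {
  if (inherits(sample, "phylo")) sample <- tree_sample(sample)
  stopifnot(inherits(sample, "tree_sample"), inherits(config, "mcmc_config"))
  set.seed(config$seed)
  ntree <- length(sample$trees)
  preps <- lapply(sample$trees, .mk_prep, char = char, model = model)
  prior <- root_prior_vector(model)
  k <- model$k
  p <- model$n_free
  if (p < 1L) stop("model template has no free rates")

  # default node addressing: internal clades of the first tree
  if (is.null(nodes)) {
    tr1 <- preps[[1]]$tree
    ids <- preps[[1]]$ntip + seq_len(tr1$Nnode)
    nodes <- lapply(ids, function(i) ape::extract.clade(tr1, i)$tip.label)
    names(nodes) <- paste0("n", ids)
  }
  node_ids <- lapply(preps, function(pr) .resolve_nodes(pr$tree, nodes))

  # fossilized-node constraints, resolved per tree
  cons_states <- NULL
  if (!is.null(node_constraints) && length(node_constraints)) {
    cn <- names(node_constraints)
    if (!all(cn %in% names(nodes))) {
      stop("constraint on unaddressed node(s): ",
           paste(setdiff(cn, names(nodes)), collapse = ", "))
    }
    cons_states <- vapply(node_constraints, function(s) {
      i <- match(s, model$states)
      if (is.na(i)) stop("unknown constraint state '", s, "'")
      i
    }, integer(1))
    present <- vapply(seq_len(ntree), function(ti) {
      all(!is.na(node_ids[[ti]][cn]))
    }, logical(1))
    if (mean(present) < 0.5) {
      stop("constrained node is not a clade in more than half of the trees")
    }
  }
  constraint_for <- function(ti) {
    if (is.null(cons_states)) return(NULL)
    cv <- rep(NA_integer_, preps[[ti]]$ntip + preps[[ti]]$nnode)
    ids <- node_ids[[ti]][names(cons_states)]
    if (anyNA(ids)) return(NA)  # constraint unplaceable on this tree
    cv[ids] <- cons_states
    cv
  }

  # two candidate rate designs: all-equal and the template
  eq_design <- model$design
  eq_design[eq_design > 0L] <- 1L
  designs <- list(equal = rate_model(model$states, eq_design,
                                     rates = 1, root_prior = model$root_prior),
                  distinct = model)
  n_models <- if (config$rj && p > 1L) 2L else 1L
  cur_model <- if (n_models == 2L) 2L else 2L  # start in the template model

  loglik_at <- function(ti, mdl, r) {
    cv <- constraint_for(ti)
    if (length(cv) == 1L && is.na(cv[1])) return(-Inf)
    .mk_loglik_prep(preps[[ti]], rate_matrix(designs[[mdl]], r), prior, cv)
  }

  a <- config$hyper[1]; b <- config$hyper[2]
  m_cur <- if (config$prior == "hyper_exp") {
    if (b > a) stats::runif(1, a, b) else a
  } else NA_real_
  if (!is.na(m_cur) && m_cur <= 0) m_cur <- (a + b) / 2 + 1e-6
  np_cur <- if (cur_model == 1L) 1L else p
  r_cur <- rep(1, np_cur)
  ti_cur <- 1L
  ll_cur <- loglik_at(ti_cur, cur_model, r_cur)

  n_prop <- 0L; n_acc <- 0L
  model_visits <- c(equal = 0L, distinct = 0L)
  ret_ll <- numeric(0); ret_model <- integer(0); ret_rates <- list()
  pp_sum <- matrix(0, length(nodes), k,
                   dimnames = list(names(nodes), model$states))
  pp_n <- stats::setNames(rep(0L, length(nodes)), names(nodes))
  n_skip <- 0L

  for (it in seq_len(config$iterations)) {
    # (1) tree swap
    if (ntree > 1L) {
      tj <- sample.int(ntree, 1L)
      if (tj != ti_cur) {
        ll_new <- loglik_at(tj, cur_model, r_cur)
        if (log(stats::runif(1)) < ll_new - ll_cur) {
          ti_cur <- tj; ll_cur <- ll_new
        }
      }
    }
    # (2) rate sliding-window move
    r_new <- .reflect(r_cur + stats::runif(length(r_cur), -config$ratedev,
                                           config$ratedev))
    lp_old <- .rate_logprior(r_cur, config, m_cur)
    lp_new <- .rate_logprior(r_new, config, m_cur)
    n_prop <- n_prop + 1L
    if (is.finite(lp_new)) {
      ll_new <- loglik_at(ti_cur, cur_model, r_new)
      if (log(stats::runif(1)) < (ll_new + lp_new) - (ll_cur + lp_old)) {
        r_cur <- r_new; ll_cur <- ll_new
        n_acc <- n_acc + 1L
      }
    }
    # (3) hyperprior-mean move (prior-only Metropolis step)
    if (config$prior == "hyper_exp" && b > a) {
      m_new <- .reflect(m_cur + stats::runif(1, -(b - a) / 10, (b - a) / 10),
                        lower = a)
      if (m_new > b) m_new <- 2 * b - m_new
      if (m_new > 0 && m_new >= a && m_new <= b) {
        if (log(stats::runif(1)) <
            .rate_logprior(r_cur, config, m_new) -
            .rate_logprior(r_cur, config, m_cur)) {
          m_cur <- m_new
        }
      }
    }
    # (4) reversible jump between equal- and distinct-rates models;
    # new rates are drawn from the prior so the acceptance ratio reduces
    # to the likelihood ratio
    if (n_models == 2L) {
      mdl_new <- 3L - cur_model
      np_new <- if (mdl_new == 1L) 1L else p
      r_new <- if (config$prior == "hyper_exp") {
        stats::rexp(np_new, rate = 1 / max(m_cur, 1e-12))
      } else {
        stats::runif(np_new, 0, config$uniform_max)
      }
      ll_new <- loglik_at(ti_cur, mdl_new, r_new)
      if (log(stats::runif(1)) < ll_new - ll_cur) {
        cur_model <- mdl_new; r_cur <- r_new; ll_cur <- ll_new
      }
    }
    # retained-iteration summaries
    if (it > config$burnin && (it - config$burnin) %% config$thin == 0L) {
      ret_ll <- c(ret_ll, ll_cur)
      ret_model <- c(ret_model, cur_model)
      ret_rates[[length(ret_rates) + 1L]] <- r_cur
      model_visits[cur_model] <- model_visits[cur_model] + 1L
      if (length(nodes)) {
        cv <- constraint_for(ti_cur)
        if (!(length(cv) == 1L && is.na(cv[1]))) {
          marg <- .mk_node_marginals(preps[[ti_cur]],
                                     rate_matrix(designs[[cur_model]], r_cur),
                                     prior, cv)
          if (!is.null(marg)) {
            ids <- node_ids[[ti_cur]]
            ok <- which(!is.na(ids))
            if (length(ok) < length(ids)) n_skip <- n_skip + 1L
            pp_sum[ok, ] <- pp_sum[ok, , drop = FALSE] +
              marg[ids[ok], , drop = FALSE]
            pp_n[ok] <- pp_n[ok] + 1L
          }
        }
      }
    }
  }

  accept <- if (n_prop) n_acc / n_prop else NA_real_
  if (is.finite(accept) && (accept < 0.05 || accept > 0.95)) {
    warning("rate-proposal acceptance rate ", round(accept, 3),
            " outside [0.05, 0.95]; retune ratedev")
  }
  node_pp <- pp_sum / pmax(pp_n, 1L)
  node_pp[pp_n == 0L, ] <- NA_real_
  log_hm <- if (length(ret_ll)) harmonic_mean_log_marginal(ret_ll) else NA_real_
  structure(list(node_pp = node_pp, node_n = pp_n,
                 accept_rate = accept,
                 model_freq = model_visits / max(1L, sum(model_visits)),
                 log_hm = log_hm,
                 retained_loglik = ret_ll,
                 retained_model = c("equal", "distinct")[ret_model],
                 retained_rates = ret_rates,
                 n_retained = length(ret_ll),
                 nodes = nodes, states = model$states,
                 skipped_iterations = n_skip, config = config),
            class = "mk_posterior")
}

#' @export
print.mk_posterior <- function(x, digits = 3, ...) {
  cat("Mk MCMC posterior summary\n")
  cat("  retained samples:", x$n_retained,
      " rate acceptance:", round(x$accept_rate, 3), "\n")
  if (x$config$rj) {
    cat("  model frequencies:",
        paste(names(x$model_freq), round(x$model_freq, 3), collapse = "  "), "\n")
  }
  cat("  harmonic-mean log marginal likelihood:",
      format(x$log_hm, digits = 6), "\n")
  if (nrow(x$node_pp)) {
    cat("  mean node posteriors (first rows):\n")
    print(round(utils::head(x$node_pp), digits))
  }
  invisible(x)
}

#' @export
summary.mk_posterior <- function(object, ...) {
  w <- max(lengths(object$retained_rates), 1L)
  rates <- do.call(rbind, lapply(object$retained_rates,
                                 function(r) rep(r, length.out = w)))
  list(node_pp = object$node_pp,
       rate_mean = if (is.null(rates)) numeric(0) else colMeans(rates),
       model_freq = object$model_freq,
       log_hm = object$log_hm,
       accept_rate = object$accept_rate)
}

#' Tune the rate-proposal half-width to the target acceptance window
#'
#' Runs short pilot chains, doubling `ratedev` while acceptance is above
#' the window (steps too timid) and halving it while below, until the
#' pilot acceptance rate falls inside `config$target_accept`.
#'
#' @inheritParams run_mcmc
#' @param pilot_iterations Length of each pilot chain.
#' @param max_steps Maximum doublings/halvings before giving up.
#' @return The tuned `ratedev` (positive scalar).
#' @export
tune_ratedev <- function(sample, char, model, config = mcmc_config(),
                         pilot_iterations = 10000L, max_steps = 20L) {
  rd <- config$ratedev
  for (step in seq_len(max_steps)) {
    cfg <- config
    cfg$ratedev <- rd
    cfg$iterations <- as.integer(pilot_iterations)
    cfg$burnin <- as.integer(pilot_iterations %/% 5)
    cfg$seed <- config$seed + step
    pil <- suppressWarnings(run_mcmc(sample, char, model, cfg, nodes = list()))
    acc <- pil$accept_rate
    if (acc >= config$target_accept[1] && acc <= config$target_accept[2]) {
      return(rd)
    }
    rd <- if (acc > config$target_accept[2]) rd * 2 else rd / 2
  }
  stop("could not reach the target acceptance window within ",
       max_steps, " adjustments")
}

#' Harmonic-mean log marginal likelihood
#'
#' The harmonic-mean estimator of the marginal likelihood from retained
#' posterior log-likelihood samples, `ln(n) - logsumexp(-lnL_i)`, computed
#' stably in log space. The estimator is known to have high (sometimes
#' infinite) variance; a jackknife standard error is attached as the
#' `"jackknife_se"` attribute so its stability can be inspected, but the
#' headline value is the plain harmonic mean.
#'
#' @param retained_loglik Non-empty numeric vector of log-likelihoods
#'   (nats).
#' @return Log marginal-likelihood estimate (nats).
#' @examples
#' harmonic_mean_log_marginal(log(c(2, 4)))  # log(8/3)
#' @export
harmonic_mean_log_marginal <- function(retained_loglik) {
  lnl <- as.numeric(retained_loglik)
  if (length(lnl) == 0L) stop("empty log-likelihood list")
  n <- length(lnl)
  lse <- function(x) {
    m <- max(x)
    if (!is.finite(m)) return(m)
    m + log(sum(exp(x - m)))
  }
  est <- log(n) - lse(-lnl)
  se <- NA_real_
  if (n > 2L) {
    jack <- vapply(seq_len(n), function(i) {
      log(n - 1L) - lse(-lnl[-i])
    }, numeric(1))
    se <- sqrt((n - 1L) / n * sum((jack - mean(jack))^2))
  }
  structure(est, jackknife_se = se)
}

#' Twice the log Bayes factor and its verdict
#'
#' `2 ln(BF) = 2 (ln HM1 - ln HM2)` with the conventional support
#' thresholds: above 2 positive, above 6 strong, above 10 very strong;
#' below 2 the first model is not significantly better.
#'
#' @param ln_hm1,ln_hm2 Log marginal likelihoods of the two models.
#' @return List with `statistic` and `verdict`
#'   (`none`/`positive`/`strong`/`very_strong`).
#' @export
bayes_factor_2ln <- function(ln_hm1, ln_hm2) {
  stat <- 2 * (as.numeric(ln_hm1) - as.numeric(ln_hm2))
  verdict <- if (stat > 10) "very_strong" else if (stat > 6) "strong" else
    if (stat > 2) "positive" else "none"
  list(statistic = stat, verdict = verdict)
}

#' Bayes-factor test of a fixed (fossilized) node state
#'
#' Runs two constrained chains with the node fossilized in each candidate
#' state, estimates each marginal likelihood by the harmonic mean, and
#' compares them with `2 ln(BF)`. The favored state is the one with the
#' higher harmonic-mean marginal likelihood.
#'
#' @inheritParams run_mcmc
#' @param node Tip-label character vector addressing the node as an MRCA,
#'   or the name of an entry of `nodes`.
#' @param states Length-2 character vector of candidate states (defaults
#'   to the model's first two states).
#' @return List with `statistic` (`2 ln BF` of state 1 over state 2),
#'   `verdict`, `favored_state`, and the two log harmonic means.
#' @export
fixed_state_node_test <- function(sample, char, model, config = mcmc_config(),
                                  node, states = NULL) {
  if (is.null(states)) states <- model$states[1:2]
  stopifnot(length(states) == 2L, all(states %in% model$states))
  nodes <- list(target = node)
  lnhm <- vapply(states, function(s) {
    res <- run_mcmc(sample, char, model, config,
                    node_constraints = list(target = s), nodes = nodes)
    as.numeric(res$log_hm)
  }, numeric(1))
  bf <- bayes_factor_2ln(lnhm[1], lnhm[2])
  list(statistic = bf$statistic, verdict = bf$verdict,
       favored_state = states[which.max(lnhm)],
       log_hm = stats::setNames(lnhm, states))
}
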