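#' @keywords internal
#' Precompute pruning structures for one tree and character.
.mk_prep <- function(tree, char, model) {
  stopifnot(inherits(char, "character_matrix"), inherits(model, "rate_model"))
  if (!all(char$levels %in% model$states)) {
    stop("character states (", paste(char$levels, collapse = ","),
         ") do not match model states (", paste(model$states, collapse = ","), ")")
  }
  tree <- validate_tree(tree)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  absent <- setdiff(tree$tip.label, names(char$states))
  if (length(absent)) stop("tip(s) absent from character matrix: ",
                           paste(absent, collapse = ", "))
  k <- model$k
  st <- match(char$states[tree$tip.label], model$states)
  tipp <- matrix(1, ntip, k)
  obs <- which(!is.na(st))
  if (length(obs)) {
    tipp[obs, ] <- 0
    tipp[cbind(obs, st[obs])] <- 1
  }
  list(tree = tree, edge = tree$edge, el = tree$edge.length,
       ntip = ntip, nnode = tree$Nnode, root = ntip + 1L, k = k, tipp = tipp)
}

#' @keywords internal
#' Pruning log-likelihood on a prepared structure. `constraint` is an
#' optional integer vector over node numbers (NA = free, otherwise the
#' 1-based index of the state the node is fossilized in).
.mk_loglik_prep <- function(prep, Q, prior, constraint = NULL) {
  k <- prep$k
  nn <- prep$ntip + prep$nnode
  L <- matrix(1, nn, k)
  L[seq_len(prep$ntip), ] <- prep$tipp
  edge <- prep$edge
  el <- prep$el
  logscale <- 0
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    lch <- L[ch, ]
    if (!is.null(constraint) && ch <= nn && !is.na(constraint[ch])) {
      keep <- constraint[ch]
      lch[-keep] <- 0
    }
    v <- as.vector(expQt(Q, el[e]) %*% lch)
    w <- L[par, ] * v
    m <- max(w)
    if (m <= 0) return(-Inf)
    L[par, ] <- w / m
    logscale <- logscale + log(m)
  }
  lroot <- L[prep$root, ]
  if (!is.null(constraint) && !is.na(constraint[prep$root])) {
    lroot[-constraint[prep$root]] <- 0
  }
  s <- sum(prior * lroot)
  if (s <= 0) return(-Inf)
  log(s) + logscale
}

#' Pruning log-likelihood of a discrete character on a rooted tree
#'
#' Felsenstein's post-order pruning recursion: per-state conditional
#' likelihoods are propagated from the tips to the root and combined there
#' with the model's root prior. Missing tips contribute all-ones partials
#' (full marginalization).
#'
#' @param tree A `"phylo"` object; every tip must appear in `char`.
#' @param char A [character_matrix()].
#' @param model A [rate_model()] whose state set covers the character's.
#' @param rates Optional rate vector overriding `model$rates`.
#' @return Log-likelihood in nats (<= 0 for a single character).
#' @examples
#' tr <- read_newick("(A:1,B:1);")
#' ch <- character_matrix(c(A = "0", B = "1"))
#' m <- rate_model(c("0", "1"), design = matrix(c(0, 1, 1, 0), 2), rates = 1)
#' pruning_loglik(tr, ch, m)  # log(0.25 * (1 - exp(-4)))
#' @export
pruning_loglik <- function(tree, char, model, rates = NULL) {
  if (!is.null(rates)) model <- set_rates(model, rates)
  prep <- .mk_prep(tree, char, model)
  .mk_loglik_prep(prep, rate_matrix(model), root_prior_vector(model))
}

#' Maximum-likelihood Mk fit of transition rates
#'
#' Maximizes the pruning likelihood over the free rate classes of a
#' constrained [rate_model()], with bounded multi-start local optimization:
#' rates are bounded to `[1e-8, 100]` events per unit branch length and the
#' optimizer is started from a deterministic log-spaced grid, so fits are
#' reproducible without stochastic search. One-way (irreversible) models
#' are expressed through zero-fixed design cells and optimized on the
#' boundary directly.
#'
#' @param tree A `"phylo"` object.
#' @param char A [character_matrix()]; at least one non-missing tip.
#' @param model A [rate_model()] template giving the constraint structure
#'   and root prior.
#' @param bounds Length-2 rate bounds.
#' @param n_starts Number of deterministic log-spaced starting points.
#' @return An object of class `"mk_fit"` with components `rates`
#'   (ML estimates per equality class), `logLik`, `converged`, `evals`,
#'   `model` (template with fitted rates) and `tree`.
#' @seealso [irreversibility_test()], [mean_loglik_sample()]
#' @export
fit_mk <- function(tree, char, model, bounds = c(1e-8, 100), n_starts = 5L) {
  prep <- .mk_prep(tree, char, model)
  if (all(is.na(char$states[tree$tip.label]))) {
    stop("all tips missing: nothing to fit")
  }
  prior <- root_prior_vector(model)
  p <- model$n_free
  nll <- function(r) {
    ll <- .mk_loglik_prep(prep, rate_matrix(model, r), prior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  evals <- 0L
  nll_count <- function(r) { evals <<- evals + 1L; nll(r) }
  if (p == 0L) {
    ll <- -nll(numeric(0))
    return(structure(list(rates = numeric(0), logLik = ll, converged = TRUE,
                          evals = 1L, model = model, tree = prep$tree,
                          call = match.call()), class = "mk_fit"))
  }
  starts <- 10^seq(log10(0.01), log10(10), length.out = n_starts)
  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(
      stats::optim(rep(s, p), nll_count, method = "L-BFGS-B",
                   lower = bounds[1], upper = bounds[2],
                   control = list(factr = 1e7, maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (fit$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(rates = rep(NA_real_, p), logLik = NA_real_,
                          converged = FALSE, evals = evals, model = model,
                          tree = prep$tree, call = match.call()),
                     class = "mk_fit"))
  }
  rates <- stats::setNames(best$par, paste0("q", seq_len(p)))
  structure(list(rates = rates, logLik = -best$value,
                 converged = any_conv, evals = evals,
                 model = set_rates(model, best$par), tree = prep$tree,
                 call = match.call()),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, digits = 4, ...) {
  cat("Mk maximum-likelihood fit\n")
  cat("  states:", paste(x$model$states, collapse = ", "), "\n")
  cat("  log-likelihood:", format(x$logLik, digits = digits),
      if (!x$converged) " (NOT converged)" else "", "\n", sep = "")
  if (length(x$rates)) {
    cat("  rates:\n")
    print(round(x$rates, digits))
  }
  invisible(x)
}

#' @export
summary.mk_fit <- function(object, ...) {
  Q <- rate_matrix(object$model)
  dimnames(Q) <- list(object$model$states, object$model$states)
  out <- list(rates = object$rates, Q = Q, logLik = object$logLik,
              converged = object$converged, evals = object$evals,
              df = object$model$n_free)
  class(out) <- "summary.mk_fit"
  out
}

#' @export
print.summary.mk_fit <- function(x, digits = 4, ...) {
  cat("Mk fit:", x$df, "free rate(s), lnL =", format(x$logLik, digits = digits),
      "(", x$evals, "likelihood evaluations )\n")
  cat("Fitted generator matrix:\n")
  print(round(x$Q, digits))
  invisible(x)
}

#' @export
coef.mk_fit <- function(object, ...) object$rates

#' @export
logLik.mk_fit <- function(object, ...) {
  structure(object$logLik, df = object$model$n_free, class = "logLik")
}

#' @export
simulate.mk_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    simulate_mk_character(object$tree, object$model)$char
  })
}

#' Mean maximized log-likelihood over a posterior tree sample
#'
#' Fits the rate model independently on every tree of the sample and
#' returns the arithmetic mean of the maximized log-likelihoods, the
#' tree-file averaging used by the irreversibility test.
#'
#' @param sample A [tree_sample()].
#' @inheritParams fit_mk
#' @param max_fail_frac Error if more than this fraction of per-tree fits
#'   fail to converge (default 0.1).
#' @return The mean log-likelihood (numeric scalar) with attribute
#'   `"per_tree"` holding the per-tree values.
#' @export
mean_loglik_sample <- function(sample, char, model, max_fail_frac = 0.1, ...) {
  stopifnot(inherits(sample, "tree_sample"), length(sample$trees) > 0L)
  fits <- lapply(sample$trees, fit_mk, char = char, model = model, ...)
  lnl <- vapply(fits, `[[`, numeric(1), "logLik")
  conv <- vapply(fits, `[[`, logical(1), "converged")
  n_bad <- sum(!conv | !is.finite(lnl))
  if (n_bad > 0L) {
    warning(n_bad, " of ", length(fits), " per-tree fits did not converge")
  }
  if (n_bad > max_fail_frac * length(fits)) {
    stop("too many per-tree fit failures (", n_bad, "/", length(fits), ")")
  }
  ok <- is.finite(lnl)
  structure(mean(lnl[ok]), per_tree = lnl)
}
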