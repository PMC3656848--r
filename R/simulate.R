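#' Simulate a pure-birth (Yule) tree
#'
#' Starts from the root with two lineages; with `k` extant lineages the
#' wait to the next speciation is exponential with rate `k * birth_rate`,
#' and a uniformly chosen lineage splits, until `n_tips` are reached.
#' Tips are contemporaneous (the tree is ultrametric) and the expected
#' root-to-tip depth is `sum(1/(k * birth_rate))` for `k = 2..n_tips`.
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate per lineage.
#' @param seed Optional integer seed for exact reproducibility.
#' @return A `"phylo"` tree with tips `t1..tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be positive")
  if (!is.null(seed)) set.seed(seed)
  n_tips <- as.integer(n_tips)
  # grow pendant lineages; node ids: tips 1..n, internals n+1, n+2, ...
  max_node <- 2L * n_tips - 1L
  parent <- integer(max_node)
  birth <- numeric(max_node)     # time each node was created
  root <- n_tips + 1L
  next_int <- n_tips + 2L
  next_tip <- 1L
  t_now <- 0
  birth[root] <- 0
  open <- c(root, root)          # parents of the currently open lineages
  # each open slot becomes either a tip or an internal node when resolved
  k <- 2L
  repeat {
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    if (k == n_tips) break
    i <- sample.int(k, 1L)
    nd <- next_int; next_int <- next_int + 1L
    parent[nd] <- open[i]
    birth[nd] <- t_now
    open[i] <- nd
    open <- c(open, nd)
    k <- k + 1L
  }
  # close all open lineages as tips at time t_now
  for (i in seq_len(k)) {
    parent[next_tip] <- open[i]
    birth[next_tip] <- t_now
    next_tip <- next_tip + 1L
  }
  child <- setdiff(seq_len(max_node), root)
  edge <- cbind(parent[child], child)
  tr <- list(edge = edge,
             edge.length = birth[child] - birth[parent[child]],
             tip.label = paste0("t", seq_len(n_tips)),
             Nnode = n_tips - 1L)
  class(tr) <- "phylo"
  tr <- stats::reorder(ape::collapse.singles(tr), "cladewise")
  validate_tree(tr)
}

#' Emulate a posterior tree sample by branch-length jitter
#'
#' Produces `n_trees` copies of a base tree with every branch length
#' multiplied by an independent lognormal factor (`meanlog = 0`,
#' `sdlog = length_jitter_sd`), a stand-in for the branch-length
#' variation of a Bayesian posterior sample; the topology is fixed.
#'
#' @param base A `"phylo"` tree.
#' @param n_trees Number of trees to emit.
#' @param length_jitter_sd Lognormal sd of the per-branch factors
#'   (0 gives identical copies).
#' @param seed Optional integer seed.
#' @return A [tree_sample()].
#' @export
emulate_tree_sample <- function(base, n_trees, length_jitter_sd = 0.1,
                                seed = NULL) {
  base <- validate_tree(base)
  stopifnot(n_trees >= 1, length_jitter_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(i) {
    tr <- base
    if (length_jitter_sd > 0) {
      tr$edge.length <- tr$edge.length *
        stats::rlnorm(length(tr$edge.length), 0, length_jitter_sd)
    }
    tr
  })
  tree_sample(trees, run_id = 1L)
}

#' Simulate a discrete character under an Mk model, with full truth
#'
#' Exact event-by-event continuous-time simulation: the root state is
#' drawn from the model's root prior, and along each branch the state
#' waits exponential times (rate = the current state's exit rate) between
#' transitions, so every change has a recorded branch and time. Returned
#' truth includes every node's true state and the event list, which is
#' what switch-recovery and parameter-recovery tests compare against.
#'
#' @param tree A `"phylo"` tree.
#' @param model A [rate_model()] with the generating rates.
#' @param seed Optional integer seed.
#' @return List with `char` (a [character_matrix()] over the tips),
#'   `node_states` (true state label per ape node number) and `events`
#'   (data frame `parent`, `child`, `time`, `from`, `to`).
#' @export
simulate_mk_character <- function(tree, model, seed = NULL) {
  tree <- validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  Q <- rate_matrix(model)
  k <- model$k
  prior <- root_prior_vector(model)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  tree_cw <- stats::reorder(tree, "cladewise")  # parents before children
  state <- integer(nn)
  root <- ntip + 1L
  state[root] <- sample.int(k, 1L, prob = prior)
  ev <- list()
  for (e in seq_len(nrow(tree_cw$edge))) {
    par <- tree_cw$edge[e, 1L]; ch <- tree_cw$edge[e, 2L]
    s <- state[par]
    t_left <- tree_cw$edge.length[e]
    t_at <- 0
    repeat {
      exit <- -Q[s, s]
      if (exit <= 0) break
      w <- stats::rexp(1, rate = exit)
      if (w >= t_left) break
      t_left <- t_left - w
      t_at <- t_at + w
      probs <- Q[s, ]; probs[s] <- 0
      s_new <- sample.int(k, 1L, prob = probs)
      ev[[length(ev) + 1L]] <- data.frame(parent = par, child = ch,
                                          time = t_at,
                                          from = model$states[s],
                                          to = model$states[s_new])
      s <- s_new
    }
    state[ch] <- s
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(parent = integer(0), child = integer(0), time = numeric(0),
               from = character(0), to = character(0))
  char <- character_matrix(
    stats::setNames(model$states[state[seq_len(ntip)]], tree_cw$tip.label),
    levels = model$states)
  list(char = char,
       node_states = stats::setNames(model$states[state], seq_len(nn)),
       events = events)
}

#' Simulate a host-association table with planted switches
#'
#' Evolves the presence/absence of each host lineage independently along
#' the tree (mirroring the one-analysis-per-host design of the mapping
#' pipeline), then assembles a [host_table()] from the realized tip
#' presences. Specificity annotations are derived from the realized host
#' counts: `n_genera` counts the distinct host genera present,
#' `sporadic_extra` is never planted, and `eco_similar` is set for
#' single-genus species. Planted gains (0 -> 1 events) are the true host
#' switches that recovery tests compare against.
#'
#' @param tree A `"phylo"` tree whose tips are the species.
#' @param per_host_models Named list of binary [rate_model()]s (states
#'   `"0"`, `"1"`), one per host lineage; defaults to gain rate 0.3 and
#'   loss rate 0.3 with a root mostly absent, for all eight lineages.
#' @param seed Optional integer seed.
#' @return List with `table` (a [host_table()]), `node_sets` (true host
#'   set per node), `events` (all transition events, with a `host`
#'   column) and `gains` (the planted switches: 0 -> 1 events only).
#' @export
simulate_host_table <- function(tree, per_host_models = NULL, seed = NULL) {
  tree <- validate_tree(tree)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(per_host_models)) {
    base <- rate_model(c("0", "1"), rates = c(0.3, 0.3),
                       root_prior = c(0.85, 0.15))
    per_host_models <- stats::setNames(rep(list(base), length(HOST_LINEAGES)),
                                       HOST_LINEAGES)
  }
  hosts <- names(per_host_models)
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  pres <- matrix(0L, nn, length(hosts), dimnames = list(NULL, hosts))
  ev <- list()
  for (h in hosts) {
    sim <- simulate_mk_character(tree, per_host_models[[h]])
    pres[, h] <- as.integer(sim$node_states == "1")
    if (nrow(sim$events)) {
      sim$events$host <- h
      ev[[length(ev) + 1L]] <- sim$events
    }
  }
  events <- if (length(ev)) do.call(rbind, ev) else
    data.frame(parent = integer(0), child = integer(0), time = numeric(0),
               from = character(0), to = character(0), host = character(0))
  gains <- events[events$from == "0" & events$to == "1", , drop = FALSE]
  node_sets <- lapply(seq_len(nn), function(v) hosts[pres[v, ] == 1L])
  names(node_sets) <- as.character(seq_len(nn))

  tab <- data.frame(species = tree$tip.label, stringsAsFactors = FALSE)
  for (h in HOST_LINEAGES) {
    tab[[h]] <- if (h %in% hosts) pres[seq_len(ntip), h] else 0L
  }
  genera <- apply(tab[HOST_LINEAGES], 1, function(fl) {
    length(unique(HOST_GENUS[HOST_LINEAGES[fl == 1L]]))
  })
  tab$n_genera <- as.integer(genera)
  tab$sporadic_extra <- FALSE
  tab$eco_similar <- genera == 1L
  list(table = host_table(tab), node_sets = node_sets,
       events = events, gains = gains)
}
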