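# Independent oracles used across the suite: exhaustive enumeration for
# likelihood and parsimony, and a Taylor-series matrix exponential.

# exp(Qt) by scaled Taylor series, independent of the package's expQt
taylor_expm <- function(Q, t, order = 30L) {
  A <- Q * t
  s <- max(0L, ceiling(log2(max(1, max(abs(A))))))
  B <- A / 2^s
  P <- diag(nrow(A)); term <- diag(nrow(A))
  for (i in seq_len(order)) {
    term <- term %*% B / i
    P <- P + term
  }
  for (i in seq_len(s)) P <- P %*% P
  P
}

# full-enumeration Mk likelihood: sum over every assignment of states to
# internal nodes AND missing tips of prior(root) * prod(edge transitions)
brute_force_loglik <- function(tree, char, model) {
  tree <- reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  k <- model$k
  st <- match(char$states[tree$tip.label], model$states)
  prior <- if (is.numeric(model$root_prior)) model$root_prior else
    switch(model$root_prior,
           uniform = rep(1 / k, k),
           stationary = stationary_distribution(model))
  Ps <- lapply(seq_len(nrow(tree$edge)),
               function(e) taylor_expm(rate_matrix(model), tree$edge.length[e]))
  choices <- c(lapply(seq_len(ntip), function(i) if (is.na(st[i])) 1:k else st[i]),
               rep(list(1:k), nn - ntip))
  grid <- as.matrix(expand.grid(choices))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    a <- grid[g, ]
    p <- prior[a[ntip + 1L]]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Ps[[e]][a[tree$edge[e, 1L]], a[tree$edge[e, 2L]]]
    }
    total <- total + p
  }
  log(total)
}

# exhaustive parsimony: minimum changes, per-node MPR sets (union over all
# optimal assignments, missing tips marginalized), and the set of edges
# that carry a change in at least one optimal assignment
brute_force_parsimony <- function(tree, char) {
  tree <- reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  k <- char$k
  st <- match(char$states[tree$tip.label], char$levels)
  choices <- c(lapply(seq_len(ntip), function(i) if (is.na(st[i])) 1:k else st[i]),
               rep(list(1:k), nn - ntip))
  grid <- as.matrix(expand.grid(choices))
  cost <- apply(grid, 1, function(a) {
    sum(a[tree$edge[, 1L]] != a[tree$edge[, 2L]])
  })
  score <- min(cost)
  opt <- grid[cost == score, , drop = FALSE]
  sets <- lapply(seq_len(nn), function(v) sort(unique(char$levels[opt[, v]])))
  change_edges <- which(vapply(seq_len(nrow(tree$edge)), function(e) {
    any(opt[, tree$edge[e, 1L]] != opt[, tree$edge[e, 2L]])
  }, logical(1)))
  list(score = score, sets = sets, change_edges = change_edges, tree = tree)
}

# random rooted tree with positive branch lengths, reproducible
random_test_tree <- function(n_tips, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_tips, rooted = TRUE)
  tr$edge.length <- tr$edge.length + 0.05
  tr
}

random_character <- function(tree, k, seed, p_missing = 0) {
  set.seed(seed)
  levels <- as.character(seq_len(k) - 1L)
  st <- sample(levels, length(tree$tip.label), replace = TRUE)
  if (p_missing > 0) {
    st[runif(length(st)) < p_missing] <- NA_character_
  }
  character_matrix(setNames(st, tree$tip.label), levels = levels)
}

# binary G/S character helper
gs_character <- function(states) {
  character_matrix(states, levels = c("G", "S"))
}
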