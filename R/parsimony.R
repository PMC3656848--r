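INF_COST <- 1e9  # finite stand-in for impossible assignments

#' @keywords internal
#' Unit-cost (Fitch/unordered) parsimony dynamic program.
#' Returns down-pass and up-pass cost tables over all nodes.
.parsimony_dp <- function(tree, char) {
  stopifnot(inherits(char, "character_matrix"))
  tree <- validate_tree(tree)
  tree <- stats::reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  k <- char$k
  absent <- setdiff(tree$tip.label, names(char$states))
  if (length(absent)) stop("tip(s) absent from character matrix: ",
                           paste(absent, collapse = ", "))
  st <- match(char$states[tree$tip.label], char$levels)

  down <- matrix(0, nn, k)
  obs <- which(!is.na(st))
  if (length(obs)) {
    down[obs, ] <- INF_COST
    down[cbind(obs, st[obs])] <- 0
  }
  edge <- tree$edge
  # msg[e, s] = min_t( (s != t) + down(child_e, t) ), the edge message
  msg <- matrix(0, nrow(edge), k)
  for (e in seq_len(nrow(edge))) {
    ch <- edge[e, 2L]
    dch <- down[ch, ]
    best <- min(dch)
    msg[e, ] <- pmin(dch, best + 1)
    down[edge[e, 1L], ] <- down[edge[e, 1L], ] + msg[e, ]
  }
  root <- ntip + 1L
  score <- min(down[root, ])

  # up-pass: up[v, s] = min cost of the tree outside v's subtree, v = s
  up <- matrix(0, nn, k)
  children <- split(seq_len(nrow(edge)), edge[, 1L])
  for (e in rev(seq_len(nrow(edge)))) {   # reverse postorder = preorder
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    sib <- setdiff(children[[as.character(par)]], e)
    rest <- up[par, ]
    for (e2 in sib) rest <- rest + msg[e2, ]
    best <- min(rest)
    up[ch, ] <- pmin(rest, best + 1)
  }
  list(tree = tree, ntip = ntip, nn = nn, k = k, levels = char$levels,
       tip_state = st, down = down, up = up, msg = msg, score = score)
}

#' Fitch (unordered) parsimony score
#'
#' Minimum number of state changes needed to explain the character on the
#' tree under unordered parsimony; computed by a unit-cost Sankoff dynamic
#' program, which handles hard polytomies and missing tips exactly.
#'
#' @param tree A `"phylo"` object (polytomies allowed).
#' @param char A [character_matrix()].
#' @return Integer parsimony score (0 with a warning if every tip is
#'   missing).
#' @export
fitch_score <- function(tree, char) {
  if (all(is.na(char$states[tree$tip.label]))) {
    warning("all tips missing; parsimony score is 0")
    return(0L)
  }
  as.integer(round(.parsimony_dp(tree, char)$score))
}

#' Most-parsimonious-reconstruction state sets
#'
#' For every node, the set of states attainable in at least one
#' most-parsimonious reconstruction (the MPR set): the union over all
#' optimal assignments, so nodes where several states tie are reported as
#' ambiguous rather than resolved arbitrarily. Missing tips carry the full
#' state set.
#'
#' @inheritParams fitch_score
#' @return An object of class `"parsimony_recon"`: the tree, the score,
#'   and per-node MPR sets (list of character vectors indexed by ape node
#'   number).
#' @export
fitch_state_sets <- function(tree, char) {
  dp <- .parsimony_dp(tree, char)
  total <- dp$down + dp$up
  sets <- vector("list", dp$nn)
  for (v in seq_len(dp$nn)) {
    sets[[v]] <- dp$levels[total[v, ] <= dp$score + 1e-9]
  }
  # missing tips: no information, full state set by convention
  miss <- which(is.na(dp$tip_state))
  for (v in miss) sets[[v]] <- dp$levels
  structure(list(tree = dp$tree, score = as.integer(round(dp$score)),
                 sets = sets, ntip = dp$ntip, levels = dp$levels,
                 dp = dp),
            class = "parsimony_recon")
}

#' @export
print.parsimony_recon <- function(x, ...) {
  amb <- sum(vapply(x$sets, length, integer(1))[-seq_len(x$ntip)] > 1L)
  cat("Parsimony reconstruction: score", x$score, "(",
      amb, "ambiguous internal node(s) of", x$tree$Nnode, ")\n")
  invisible(x)
}

#' @export
plot.parsimony_recon <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  lab <- vapply(x$sets[-seq_len(x$ntip)], paste, character(1), collapse = "/")
  ape::nodelabels(lab, frame = "rect", cex = 0.7)
  invisible(x)
}

#' Count unambiguous and ambiguous parsimony changes on branches
#'
#' A branch is an unambiguous change when the parent and child MPR sets are
#' disjoint (every optimal reconstruction changes state there), and
#' ambiguous when the sets intersect but at least one optimal
#' reconstruction still places a change on that branch.
#'
#' @param recon A [fitch_state_sets()] result.
#' @return A list with integer components `unambiguous` and `ambiguous`,
#'   plus a `branches` data frame flagging each edge.
#' @export
count_parsimony_changes <- function(recon) {
  stopifnot(inherits(recon, "parsimony_recon"))
  dp <- recon$dp
  edge <- dp$tree$edge
  unamb <- 0L; amb <- 0L
  flag <- character(nrow(edge))
  for (e in seq_len(nrow(edge))) {
    par <- edge[e, 1L]; ch <- edge[e, 2L]
    sp <- recon$sets[[par]]; sv <- recon$sets[[ch]]
    if (length(intersect(sp, sv)) == 0L) {
      unamb <- unamb + 1L
      flag[e] <- "unambiguous"
      next
    }
    # does some MPR place a change on this edge?
    # cost with parent = s_p, child = s_v:
    #   up(par,s_p) + [down(par,s_p) - msg_e(s_p)] + 1 + down(ch,s_v)
    rest <- dp$up[par, ] + dp$down[par, ] - dp$msg[e, ]
    dch <- dp$down[ch, ]
    changed <- FALSE
    for (a in seq_len(dp$k)) {
      for (b in seq_len(dp$k)) {
        if (a == b) next
        if (rest[a] + 1 + dch[b] <= dp$score + 1e-9) { changed <- TRUE; break }
      }
      if (changed) break
    }
    if (changed) { amb <- amb + 1L; flag[e] <- "ambiguous" } else flag[e] <- "none"
  }
  list(unambiguous = unamb, ambiguous = amb,
       branches = data.frame(parent = edge[, 1L], child = edge[, 2L],
                             change = flag))
}
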