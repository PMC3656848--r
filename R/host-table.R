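HOST_LINEAGES <- c("LS", "LO", "H", "S", "A", "C", "P", "M")

# the eight mapped host lineages collapse to six host genera:
# Lasioglossum (LS + LO), Halictus (H + S), Andrena, Colletes, Perdita,
# Melitturga
HOST_GENUS <- c(LS = "Lasioglossum", LO = "Lasioglossum",
                H = "Halictus", S = "Halictus",
                A = "Andrena", C = "Colletes", P = "Perdita", M = "Melitturga")

#' Host-association table
#'
#' Per-species host records for a set of cuckoo-bee species: presence
#' flags for the eight mapped host lineages (`LS` *Lasioglossum* s. str.,
#' `LO` other *Lasioglossum*, `H` *Halictus* s. str., `S` *Halictus*
#' (*Seladonia*), `A` *Andrena*, `C` *Colletes*, `P` *Perdita*, `M`
#' *Melitturga*), together with the annotations the specificity rules
#' need: the number of distinct host genera recorded, whether the extra
#' genera beyond the main one are used only sporadically, and whether the
#' hosts are ecologically similar. Species with no recorded hosts have all
#' flags unset and unknown specificity.
#'
#' @param df Data frame with columns `species`, the eight lineage flags
#'   (0/1), `n_genera`, `sporadic_extra`, `eco_similar` (logical or 0/1).
#'   Optional columns `spec_I`, `spec_II`, `spec_III` carry published
#'   calls and are preserved but not used by the classifier.
#' @return An object of class `"host_table"` (a validated data frame).
#' @export
host_table <- function(df) {
  need <- c("species", HOST_LINEAGES, "n_genera", "sporadic_extra", "eco_similar")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("host table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$species)) stop("duplicate species row")
  for (h in HOST_LINEAGES) df[[h]] <- as.integer(df[[h]])
  df$sporadic_extra <- as.logical(df$sporadic_extra)
  df$eco_similar <- as.logical(df$eco_similar)
  df$n_genera <- as.integer(df$n_genera)
  any_host <- rowSums(df[HOST_LINEAGES]) > 0L
  if (any(any_host & df$n_genera < 1L)) {
    stop("species with host flags must record n_genera >= 1")
  }
  if (any(!any_host & df$n_genera != 0L)) {
    stop("species without host flags must have n_genera = 0")
  }
  if (any(df$sporadic_extra & df$n_genera < 2L)) {
    stop("sporadic_extra requires at least two recorded genera")
  }
  structure(df, class = c("host_table", "data.frame"))
}

#' @export
print.host_table <- function(x, ...) {
  known <- sum(rowSums(x[HOST_LINEAGES]) > 0L)
  cat("Host table:", nrow(x), "species (", known, "with known hosts )\n")
  NextMethod()
}

#' Read a host table from CSV
#'
#' @param path CSV path with the [host_table()] schema.
#' @return A [host_table()].
#' @export
read_host_table <- function(path) {
  host_table(utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE))
}

#' The packaged Sphecodes host-association table
#'
#' The 37-species host/specificity table shipped with the package:
#' presence of the eight host lineages, sporadic-use and
#' ecological-similarity annotations, and the published specialization
#' calls under the three rule sets. Seven species have no recorded hosts,
#' leaving 30 species with known host records.
#'
#' @return A [host_table()].
#' @export
sphecodes_hosts <- function() {
  read_host_table(system.file("extdata", "sphecodes_hosts.csv",
                              package = "hostarrow", mustWork = TRUE))
}

#' Classify one species as specialist or generalist
#'
#' Applies one of the three graded rule sets to a species' host
#' annotations:
#' * Distribution I (least restrictive): specialist if the regularly used
#'   hosts represent a single genus, extra genera being tolerated when
#'   they are only sporadically used;
#' * Distribution II (main analysis): as I, with the additional
#'   requirement that the hosts (including any sporadic extras) are
#'   ecologically similar;
#' * Distribution III (most restrictive): specialist only for ecologically
#'   similar hosts of a single genus.
#' A species with no recorded hosts is `unknown` under every rule set.
#'
#' @param record A one-row [host_table()] slice (or list) with
#'   `n_genera`, `sporadic_extra`, `eco_similar` and the lineage flags.
#' @param distribution `"I"`, `"II"` or `"III"`.
#' @return `"S"`, `"G"` or `"unknown"`.
#' @export
classify_specificity <- function(record, distribution = c("II", "I", "III")) {
  distribution <- match.arg(distribution)
  flags <- unlist(record[HOST_LINEAGES])
  if (sum(as.integer(flags)) == 0L) return("unknown")
  n <- as.integer(record$n_genera)
  sporadic <- isTRUE(as.logical(record$sporadic_extra))
  eco <- isTRUE(as.logical(record$eco_similar))
  if (sporadic && n < 2L) stop("contradictory annotations: sporadic_extra with a single genus")
  single_or_sporadic <- n == 1L || sporadic
  s <- switch(distribution,
              I = single_or_sporadic,
              II = single_or_sporadic && eco,
              III = n == 1L && eco)
  if (s) "S" else "G"
}

#' Tally specialists and generalists under one rule set
#'
#' @param table A [host_table()].
#' @param distribution `"I"`, `"II"` or `"III"`.
#' @return Named integer vector `c(specialist, generalist, unknown)`.
#' @examples
#' \dontrun{count_specificity(sphecodes_hosts(), "II")}
#' @export
count_specificity <- function(table, distribution = c("II", "I", "III")) {
  distribution <- match.arg(distribution)
  stopifnot(inherits(table, "host_table"))
  calls <- vapply(seq_len(nrow(table)), function(i) {
    classify_specificity(table[i, ], distribution)
  }, character(1))
  c(specialist = sum(calls == "S"),
    generalist = sum(calls == "G"),
    unknown = sum(calls == "unknown"))
}

#' Build per-host binary presence/absence characters
#'
#' One binary character per host lineage, states `"0"`/`"1"`; species with
#' no recorded hosts are missing in all eight characters (their absence
#' flags carry no information).
#'
#' @param table A [host_table()].
#' @return Named list of eight [character_matrix()] objects.
#' @export
build_host_datasets <- function(table) {
  stopifnot(inherits(table, "host_table"))
  known <- rowSums(table[HOST_LINEAGES]) > 0L
  out <- lapply(HOST_LINEAGES, function(h) {
    st <- as.character(table[[h]])
    st[!known] <- NA_character_
    character_matrix(stats::setNames(st, table$species), levels = c("0", "1"))
  })
  stats::setNames(out, HOST_LINEAGES)
}

#' Threshold node posteriors into ancestral host calls
#'
#' A host lineage is called at a node when its mean posterior probability
#' of presence strictly exceeds the threshold (default 0.7; a posterior of
#' exactly 0.7 is excluded).
#'
#' @param posteriors Named list (by host lineage) of [run_mcmc()]
#'   summaries, or of named numeric vectors of per-node PP(presence).
#' @param threshold Strict cutoff on the mean posterior probability.
#' @return An object of class `"ancestral_host_calls"`: a named list (by
#'   node) of host-lineage character vectors, with the threshold as an
#'   attribute.
#' @export
call_ancestral_hosts <- function(posteriors, threshold = 0.7) {
  pp <- lapply(posteriors, function(x) {
    if (inherits(x, "mk_posterior")) {
      if (!"1" %in% colnames(x$node_pp)) stop("posterior lacks a presence state '1'")
      stats::setNames(x$node_pp[, "1"], rownames(x$node_pp))
    } else as.numeric(x) |> stats::setNames(names(x))
  })
  nodes <- names(pp[[1]])
  for (x in pp) {
    if (!identical(names(x), nodes)) stop("posterior summaries disagree on node sets")
  }
  calls <- lapply(nodes, function(nd) {
    names(pp)[vapply(pp, function(x) x[[nd]] > threshold, logical(1))]
  })
  structure(stats::setNames(calls, nodes), threshold = threshold,
            class = "ancestral_host_calls")
}

#' Enumerate host switches along a tree
#'
#' A host switch is the gain of a host lineage relative to the
#' reconstructed parent: a lineage present in a child's host set but
#' absent from its (non-empty) parent set. Multiple gains on one branch
#' count separately; branches whose parent set is empty carry no
#' information and are skipped (recorded in the `skipped` component).
#' Losses are not counted.
#'
#' @param tree A `"phylo"` object.
#' @param node_sets Named list of host sets: one entry per node, named by
#'   ape node number (tips `1..ntip`, root `ntip+1`, ...). Tip entries may
#'   instead be supplied via `tip_hosts`.
#' @param tip_hosts Optional named list of host sets by tip label.
#' @return A list with `switches` (data frame `parent`, `child`, `host`),
#'   `total` count, and `skipped` branches.
#' @export
detect_host_switches <- function(tree, node_sets, tip_hosts = NULL) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  sets <- node_sets
  if (!is.null(tip_hosts)) {
    for (i in seq_len(ntip)) {
      sets[[as.character(i)]] <- tip_hosts[[tree$tip.label[i]]]
    }
  }
  edge <- tree$edge
  rows <- list(); skipped <- integer(0)
  for (e in seq_len(nrow(edge))) {
    par <- as.character(edge[e, 1L]); ch <- as.character(edge[e, 2L])
    ps <- sets[[par]]; cs <- sets[[ch]]
    if (is.null(ps) || length(ps) == 0L) { skipped <- c(skipped, e); next }
    if (is.null(cs)) next
    gained <- setdiff(cs, ps)
    for (h in gained) {
      rows[[length(rows) + 1L]] <- data.frame(parent = edge[e, 1L],
                                              child = edge[e, 2L], host = h)
    }
  }
  switches <- if (length(rows)) do.call(rbind, rows) else
    data.frame(parent = integer(0), child = integer(0), host = character(0))
  list(switches = switches, total = nrow(switches), skipped = skipped)
}
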