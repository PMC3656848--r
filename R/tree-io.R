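#' Parse a Newick string into a rooted tree
#'
#' Thin validating wrapper around [ape::read.tree()]. The tree must be a
#' single rooted Newick statement terminated by `;`. Tip labels must be
#' unique; edges without a branch length are set to 0 with a warning (a
#' zero-length edge contributes an identity transition matrix).
#'
#' @param text A single Newick string.
#' @return An object of class `"phylo"` (see \pkg{ape}), always carrying an
#'   `edge.length` vector.
#' @examples
#' tr <- read_newick("(A:1.0,B:1.0);")
#' tr$tip.label
#' @export
read_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (!grepl(";", text)) stop("Newick statement must be terminated by ';'")
  bal <- cumsum((strsplit(text, "")[[1]] == "(") - (strsplit(text, "")[[1]] == ")"))
  if (any(bal < 0) || bal[length(bal)] != 0L) {
    pos <- if (any(bal < 0)) which(bal < 0)[1] else length(bal)
    stop("unbalanced parentheses in Newick string at position ", pos)
  }
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) stop("Newick parse error: ", conditionMessage(e)))
  if (is.null(tr)) stop("Newick parse error: no tree found")
  validate_tree(tr)
}

#' @keywords internal
validate_tree <- function(tr) {
  if (anyDuplicated(tr$tip.label)) {
    dup <- tr$tip.label[duplicated(tr$tip.label)][1]
    stop("duplicate tip label '", dup, "'")
  }
  if (is.null(tr$edge.length)) {
    warning("tree has no branch lengths; all set to 0")
    tr$edge.length <- rep(0, nrow(tr$edge))
  }
  if (anyNA(tr$edge.length)) {
    warning("missing branch lengths set to 0")
    tr$edge.length[is.na(tr$edge.length)] <- 0
  }
  if (any(tr$edge.length < 0)) stop("negative branch length")
  tr
}

#' Serialize a tree to Newick
#'
#' @param tree A `"phylo"` object.
#' @return A Newick string terminated by `;`.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree, digits = 12)
}

#' Construct a tree sample (posterior "tree file")
#'
#' A tree sample is an ordered list of rooted trees sharing one tip set,
#' each tagged with the id of the independent MCMC run it came from.
#'
#' @param trees A list of `"phylo"` objects (or a `"multiPhylo"`).
#' @param run_id Integer vector, recycled to the number of trees.
#' @return An object of class `"tree_sample"`: a list with elements
#'   `trees` and `run_id`.
#' @export
tree_sample <- function(trees, run_id = 1L) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  # index through `[[` so compressed multiPhylo tip labels are restored
  trees <- lapply(seq_along(trees), function(i) validate_tree(trees[[i]]))
  if (length(trees) == 0L) stop("empty tree sample")
  tips <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    if (!identical(sort(trees[[i]]$tip.label), tips)) {
      stop("tree ", i, " does not share the tip set of tree 1")
    }
  }
  run_id <- as.integer(rep_len(run_id, length(trees)))
  structure(list(trees = trees, run_id = run_id), class = "tree_sample")
}

#' @export
length.tree_sample <- function(x) length(x$trees)

#' @export
print.tree_sample <- function(x, ...) {
  cat("Tree sample:", length(x$trees), "trees,",
      length(unique(x$run_id)), "run(s),",
      length(x$trees[[1]]$tip.label), "tips\n")
  invisible(x)
}

#' Parse the TREES block of a NEXUS file into a tree sample
#'
#' Reads every tree of a NEXUS TREES block (translate table honoured) in
#' file order via [ape::read.nexus()].
#'
#' @param text NEXUS content as a single string, or a file path.
#' @param run_id Integer id attached to every tree (one file = one run).
#' @return A [tree_sample()].
#' @export
read_nexus_trees <- function(text, run_id = 1L) {
  stopifnot(is.character(text), length(text) == 1L)
  path <- text
  if (grepl("\n", text) || !file.exists(text)) {
    if (!grepl("#NEXUS", toupper(text), fixed = TRUE)) {
      stop("not a NEXUS file or string: ", substr(text, 1, 40))
    }
    path <- tempfile(fileext = ".nex")
    on.exit(unlink(path))
    writeLines(text, path)
  }
  if (!any(grepl("begin trees", readLines(path, warn = FALSE), ignore.case = TRUE))) {
    stop("no TREES block found")
  }
  trees <- tryCatch(ape::read.nexus(path),
                    error = function(e) stop("NEXUS parse error: ", conditionMessage(e)))
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (length(trees) == 0L) stop("TREES block contains no trees")
  tree_sample(trees, run_id = run_id)
}

#' Burn-in and thin a set of posterior tree runs
#'
#' Per run, the first `floor(burnin_fraction * n)` trees are discarded and
#' every `step`-th of the remainder is kept, counting from the `step`-th
#' (so a run of 10,000 saved trees with 25\% burn-in thinned by 10 keeps
#' exactly 750 trees; two such runs give the canonical 1,500-tree file).
#' Runs are concatenated in input order.
#'
#' @param runs A `tree_sample`, or a list of `tree_sample` objects (one per
#'   independent run).
#' @param burnin_fraction Fraction in `[0, 1)` discarded per run.
#' @param step Positive integer thinning interval.
#' @return A [tree_sample()] of the retained trees.
#' @export
thin_tree_sample <- function(runs, burnin_fraction = 0.25, step = 10L) {
  if (inherits(runs, "tree_sample")) {
    runs <- split_runs(runs)
  }
  stopifnot(is.list(runs), length(runs) > 0L)
  if (!is.numeric(step) || step < 1 || step != floor(step)) {
    stop("step must be a positive integer")
  }
  if (burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("burnin_fraction must lie in [0, 1)")
  }
  kept <- list(); kept_id <- integer(0)
  for (r in seq_along(runs)) {
    run <- runs[[r]]
    if (!inherits(run, "tree_sample")) run <- tree_sample(run, run_id = r)
    n <- length(run$trees)
    if (n == 0L) stop("run ", r, " is empty")
    drop <- floor(burnin_fraction * n)
    idx <- seq_len(n)[-seq_len(drop)]
    if (drop == 0L) idx <- seq_len(n)
    keep <- idx[seq_along(idx) %% step == 0L]
    kept <- c(kept, run$trees[keep])
    kept_id <- c(kept_id, rep(unique(run$run_id)[1], length(keep)))
  }
  if (length(kept) == 0L) {
    stop("thinning left no trees; use a smaller step or burn-in")
  }
  tree_sample(kept, run_id = kept_id)
}

#' @keywords internal
split_runs <- function(sample) {
  ids <- unique(sample$run_id)
  lapply(ids, function(id) {
    sel <- sample$run_id == id
    tree_sample(sample$trees[sel], run_id = id)
  })
}
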