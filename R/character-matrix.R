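#' Discrete character matrix (single character)
#'
#' Maps taxa to discrete states with an explicit missing marker. State
#' labels are interned as strings and sorted lexicographically; a state's
#' index is its 0-based position in that sorted list (so for a
#' specialist/generalist character, G = 0 and S = 1). The convention is
#' fixed for reproducibility across runs.
#'
#' @param states Character vector of states, named by taxon; `NA` marks
#'   missing data.
#' @param levels Optional complete state set (some states may be absent
#'   from the data); defaults to the sorted unique observed states.
#' @return An object of class `"character_matrix"`: a list with `states`
#'   (named character, `NA` = missing), `levels` (sorted) and `k`.
#' @export
character_matrix <- function(states, levels = NULL) {
  stopifnot(is.character(states) | all(is.na(states)), !is.null(names(states)))
  if (anyDuplicated(names(states))) {
    stop("duplicate taxon '", names(states)[duplicated(names(states))][1], "'")
  }
  nm <- names(states)
  states <- stats::setNames(as.character(states), nm)
  obs <- sort(unique(states[!is.na(states)]))
  if (is.null(levels)) levels <- obs
  levels <- sort(unique(as.character(levels)))
  if (!all(obs %in% levels)) {
    stop("state(s) outside levels: ", paste(setdiff(obs, levels), collapse = ", "))
  }
  if (length(levels) < 1L) stop("character has no states")
  structure(list(states = states, levels = levels,
                 k = length(levels)),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  cat("Character matrix:", length(x$states), "taxa,", x$k, "states (",
      paste(x$levels, collapse = ", "), "),",
      sum(is.na(x$states)), "missing\n")
  invisible(x)
}

#' State indices of a character matrix
#'
#' @param x A [character_matrix()].
#' @return Named integer vector of 0-based state indices (`NA` = missing).
#' @export
state_index <- function(x) {
  stopifnot(inherits(x, "character_matrix"))
  idx <- match(x$states, x$levels) - 1L
  stats::setNames(idx, names(x$states))
}

#' Read a character matrix from CSV or a NEXUS DATA block
#'
#' CSV input must have a header row with columns `taxon,state`; NEXUS
#' input (detected by a leading `#NEXUS`) is parsed with
#' [ape::read.nexus.data()].
#'
#' @param path File path.
#' @param missing_token Token mapped to the missing marker (default `"?"`).
#' @param levels Optional complete state set, see [character_matrix()].
#' @return A [character_matrix()].
#' @export
read_character_matrix <- function(path, missing_token = "?", levels = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  head1 <- readLines(path, n = 1L, warn = FALSE)
  if (length(head1) == 0L) stop("empty character file: ", path)
  if (grepl("^\\s*#NEXUS", head1, ignore.case = TRUE)) {
    dat <- ape::read.nexus.data(path)
    states <- vapply(dat, function(s) paste(s, collapse = ""), character(1))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
    if (!all(c("taxon", "state") %in% names(df))) {
      stop("CSV must have columns 'taxon' and 'state'")
    }
    if (nrow(df) == 0L) stop("empty character file: ", path)
    if (anyDuplicated(df$taxon)) {
      stop("duplicate taxon row '", df$taxon[duplicated(df$taxon)][1], "'")
    }
    states <- stats::setNames(as.character(df$state), df$taxon)
  }
  states[states == missing_token] <- NA_character_
  character_matrix(states, levels = levels)
}
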