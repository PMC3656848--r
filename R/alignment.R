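#' DNA alignment container
#'
#' A minimal aligned-matrix container: a character matrix of single
#' upper-case symbols over `A C G T - N ?` with unique taxon rownames.
#'
#' @param seqs Named character vector of equal-length sequences, or a
#'   character matrix (taxa x sites).
#' @return An object of class `"dna_alignment"`.
#' @export
dna_alignment <- function(seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    stopifnot(is.character(seqs))
    if (is.null(names(seqs))) stop("sequences must be named by taxon")
    w <- unique(nchar(seqs))
    if (length(w) > 1L) stop("sequences differ in length: ", paste(w, collapse = ", "))
    m <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m))) stop("alignment taxa must be named")
  if (anyDuplicated(rownames(m))) stop("duplicate taxon label in alignment")
  bad <- setdiff(unique(as.vector(m)), c("A", "C", "G", "T", "-", "N", "?"))
  if (length(bad)) stop("invalid alignment symbol(s): ", paste(bad, collapse = " "))
  structure(m, class = c("dna_alignment", "matrix"))
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat("DNA alignment:", nrow(x), "taxa x", ncol(x), "sites\n")
  invisible(x)
}

#' Read a FASTA alignment
#'
#' @param path Path to an (uncompressed) aligned FASTA file.
#' @return A [dna_alignment()].
#' @export
read_fasta_alignment <- function(path) {
  x <- ape::read.FASTA(path)
  if (length(x) == 0L) stop("empty FASTA file: ", path)
  m <- toupper(as.character(as.matrix(x)))
  dna_alignment(m)
}

#' Concatenate gene alignments into a supermatrix
#'
#' Columns are appended in input order. Taxa form the union over parts, in
#' order of first appearance; positions of taxa absent from a part are
#' filled with `?`. Per-part column ranges are recorded in the
#' `"partitions"` attribute for provenance.
#'
#' @param parts A list of [dna_alignment()] objects.
#' @return A [dna_alignment()] of width `sum(ncol(part))`.
#' @examples
#' a <- dna_alignment(c(x = "ACGT", y = "AC-T"))
#' b <- dna_alignment(c(y = "GG", z = "TT"))
#' ncol(concatenate_alignments(list(a, b)))  # 6
#' @export
concatenate_alignments <- function(parts) {
  if (length(parts) == 0L) stop("no alignments to concatenate")
  parts <- lapply(parts, function(p) if (inherits(p, "dna_alignment")) p else dna_alignment(p))
  taxa <- unique(unlist(lapply(parts, rownames)))
  widths <- vapply(parts, ncol, integer(1))
  out <- matrix("?", nrow = length(taxa), ncol = sum(widths),
                dimnames = list(taxa, NULL))
  at <- 0L
  ranges <- matrix(NA_integer_, nrow = length(parts), ncol = 2,
                   dimnames = list(names(parts), c("from", "to")))
  for (i in seq_along(parts)) {
    cols <- at + seq_len(widths[i])
    out[rownames(parts[[i]]), cols] <- unclass(parts[[i]])
    ranges[i, ] <- c(at + 1L, at + widths[i])
    at <- at + widths[i]
  }
  res <- dna_alignment(out)
  attr(res, "partitions") <- ranges
  res
}
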