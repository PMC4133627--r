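#' Construct a MetaAlignment from gapped rows
#'
#' @param seqs character vector of gapped rows (equal length, over
#'   \code{A,C,G,T,U,-,.}, any case); names are used as ids when `ids` is
#'   missing.
#' @param ids optional character vector of record ids.
#' @param usesU optional logical vector; defaults to whether each input row
#'   contained \code{U}/\code{u}.
#' @return a [MetaAlignment-class].
#' @examples
#' MetaAlignment(c(seq1 = "AC-G", seq2 = "A-TG"))
#' @export
MetaAlignment <- function(seqs, ids = names(seqs), usesU = NULL) {
  force(ids)
  seqs <- as.character(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (is.null(usesU)) usesU <- grepl("u", seqs, ignore.case = TRUE)
  norm <- normalizeRows(seqs)
  new("MetaAlignment", ids = as.character(ids), seqs = norm,
      usesU = as.logical(usesU))
}

## Upper-case, '.' -> '-', 'U' -> 'T'; reject anything else loudly.
normalizeRows <- function(seqs) {
  norm <- chartr(".U", "-T", toupper(seqs))
  bad <- grepl("[^ACGT-]", norm)
  if (any(bad)) {
    ch <- regmatches(norm[bad][1L], regexpr("[^ACGT-]", norm[bad][1L]))
    stop("unsupported ambiguous or non-nucleotide character '", ch,
         "' in record ", which(bad)[1L], call. = FALSE)
  }
  norm
}

#' @rdname MetaAlignment-class
#' @export
setMethod("seqIds", "MetaAlignment", function(x) x@ids)

#' @rdname MetaAlignment-class
#' @export
setMethod("gappedRows", "MetaAlignment",
          function(x) stats::setNames(x@seqs, x@ids))

#' @rdname MetaAlignment-class
#' @export
setMethod("alignmentWidth", "MetaAlignment",
          function(x) nchar(x@seqs[1L]))

#' @rdname MetaAlignment-class
#' @export
setMethod("nSequences", "MetaAlignment", function(x) length(x@seqs))

setMethod("show", "MetaAlignment", function(object) {
  cat(sprintf("MetaAlignment: %d sequences, %d columns\n",
              nSequences(object), alignmentWidth(object)))
  n <- min(6L, nSequences(object))
  w <- alignmentWidth(object)
  for (k in seq_len(n)) {
    row <- object@seqs[k]
    if (w > 60L) row <- paste0(substr(row, 1L, 57L), "...")
    cat(sprintf("  %-12s %s\n", substr(object@ids[k], 1L, 12L), row))
  }
  if (nSequences(object) > n) cat("  ...\n")
})

#' Equality of two alignments (ids, row order and gapped strings)
#'
#' @param a,b [MetaAlignment-class] objects.
#' @return logical; TRUE when ids and gapped rows are identical in order.
#' @export
sameAlignment <- function(a, b) {
  identical(a@ids, b@ids) && identical(a@seqs, b@seqs)
}

## Alignment rows as a character matrix (rows = sequences, cols = columns).
rowMatrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln@seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = nSequences(aln), byrow = TRUE)
  rownames(m) <- aln@ids
  m
}

matrixToAlignment <- function(m, aln) {
  new("MetaAlignment", ids = aln@ids,
      seqs = apply(m, 1L, paste, collapse = ""), usesU = aln@usesU)
}

#' Read an aligned FASTA file
#'
#' Reads a gapped FASTA alignment. Both \code{-} and \code{.} are accepted
#' as gap characters (and normalized to \code{-}); \code{U}/\code{u} is
#' stored as \code{T} and restored on output; case is normalized to upper.
#' Ambiguity codes (N, R, Y, ...) are rejected: the aligner supports
#' unambiguous nucleotides only.
#'
#' @param source path to an aligned FASTA file (or connection understood by
#'   [Biostrings::readBStringSet]).
#' @return a [MetaAlignment-class]; record order is preserved.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "AC-G", ">b", "A-TG"), f)
#' readAlignedFasta(f)
#' @export
readAlignedFasta <- function(source) {
  recs <- Biostrings::readBStringSet(source, format = "fasta")
  if (length(recs) < 2L)
    stop("need at least two sequences", call. = FALSE)
  raw <- as.character(recs)
  ids <- names(recs)
  if (is.null(ids)) ids <- rep("", length(raw))
  if (length(unique(nchar(raw))) > 1L)
    stop("unequal alignment row lengths", call. = FALSE)
  MetaAlignment(raw, ids = ids)
}

#' Write an aligned FASTA file
#'
#' Rows are wrapped at 60 columns; \code{T} is written back as \code{U} for
#' records whose input used RNA. Reading the file back reproduces the
#' alignment exactly.
#'
#' @param aln a [MetaAlignment-class].
#' @param sink output file path.
#' @return invisibly, `sink`.
#' @export
writeAlignedFasta <- function(aln, sink) {
  out <- aln@seqs
  out[aln@usesU] <- chartr("T", "U", out[aln@usesU])
  xs <- Biostrings::BStringSet(stats::setNames(out, aln@ids))
  Biostrings::writeXStringSet(xs, filepath = sink, width = 60L)
  invisible(sink)
}

#' @describeIn degap Degap a MetaAlignment; errors on an all-gap row.
#' @export
setMethod("degap", "MetaAlignment", function(x) {
  out <- gsub("-", "", x@seqs, fixed = TRUE)
  if (any(!nzchar(out)))
    stop("empty sequence after degapping (row ",
         which(!nzchar(out))[1L], ")", call. = FALSE)
  stats::setNames(out, x@ids)
})

#' Remove void (all-gap) columns from an alignment
#'
#' Merging independently derived sequence-profile alignments can leave
#' profile positions that no sequence uses; the corresponding all-gap
#' columns are uninformative and dropped before an alignment is reported.
#'
#' @param aln a [MetaAlignment-class].
#' @return the alignment without all-gap columns; column order and degapped
#'   content are unchanged.
#' @export
removeVoidColumns <- function(aln) {
  m <- rowMatrix(aln)
  keep <- colSums(m != GAP_CHAR) > 0L
  if (all(keep)) return(aln)
  if (!any(keep)) stop("alignment has only void columns", call. = FALSE)
  matrixToAlignment(m[, keep, drop = FALSE], aln)
}
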