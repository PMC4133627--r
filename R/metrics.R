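#' Aligned residue pairs of an alignment
#'
#' The set of homology statements an alignment makes: for every column and
#' every unordered pair of rows that both hold a residue in that column,
#' one pair identifier combining (row id, ungapped residue index) of the
#' two rows. Rows are identified by id, so the set is invariant to row
#' order and to void columns.
#'
#' @param aln a [MetaAlignment-class].
#' @return character vector of canonical pair keys (a set: no duplicates).
#' @export
residuePairs <- function(aln) {
  m <- rowMatrix(aln)
  res <- m != GAP_CHAR
  uidx <- t(apply(res, 1L, cumsum))          # ungapped index where res
  ids <- aln@ids
  ## column scan: for each column, all unordered pairs of residue rows,
  ## keyed in canonical id order so row order never matters
  keys <- vector("list", ncol(m))
  for (col in seq_len(ncol(m))) {
    rows <- which(res[, col])
    if (length(rows) < 2L) next
    rows <- rows[order(ids[rows])]
    pr <- utils::combn(rows, 2L)
    keys[[col]] <- paste0(ids[pr[1L, ]], ":", uidx[cbind(pr[1L, ], col)], "|",
                          ids[pr[2L, ]], ":", uidx[cbind(pr[2L, ], col)])
  }
  unique(unlist(keys, use.names = FALSE))
}

## per-column signatures: the multiset of (id, ungapped-index) residue
## placements, order-canonicalized; used by the TC score.
columnSignatures <- function(aln) {
  m <- rowMatrix(aln)
  res <- m != GAP_CHAR
  uidx <- t(apply(res, 1L, cumsum))
  ids <- aln@ids
  vapply(seq_len(ncol(m)), function(col) {
    rows <- which(res[, col])
    if (!length(rows)) return("")
    parts <- paste0(ids[rows], ":", uidx[cbind(rows, col)])
    paste(sort(parts), collapse = "|")
  }, character(1))
}

#' Score a test alignment against a reference (SP, modeler, TC)
#'
#' Three standard accuracy measures of a reconstructed alignment relative
#' to a trusted reference over the same sequences:
#' \describe{
#'   \item{sp (developer score, f_D)}{correctly aligned residue pairs over
#'     the reference's residue pairs -- sensitivity to true homologies.}
#'   \item{modeler (f_M)}{correctly aligned residue pairs over the test
#'     alignment's residue pairs -- precision of the stated homologies.}
#'   \item{tc}{reference columns whose full residue content is reproduced
#'     as a column of the test alignment, over all reference columns.}
#' }
#' All three lie in \[0, 1\] and equal 1 when the alignments are identical.
#' Column identity for TC compares residue placements, so shifting a
#' column's position does not matter but its content does. When a
#' denominator is empty the score is 1 if both alignments state no pairs
#' and 0 otherwise (with a message).
#'
#' @param test,ref [MetaAlignment-class] objects with identical id sets
#'   degapping to identical sequences.
#' @return named list with numeric elements `sp`, `modeler`, `tc`.
#' @examples
#' a <- MetaAlignment(c(x = "AC-G", y = "ACTG"))
#' scoreAlignment(a, a)   # all 1
#' @export
scoreAlignment <- function(test, ref) {
  dt <- degap(test); dr <- degap(ref)
  if (!setequal(names(dt), names(dr)) ||
      !identical(dt[sort(names(dt))], dr[sort(names(dr))]))
    stop("alignments not comparable: ids or degapped sequences differ",
         call. = FALSE)
  pt <- residuePairs(test)
  pr <- residuePairs(ref)
  ninter <- length(intersect(pt, pr))
  emptyScore <- function(other) {
    message("empty residue-pair denominator; score set by convention")
    if (length(other) == 0L) 1 else 0
  }
  sp <- if (length(pr)) ninter / length(pr) else emptyScore(pt)
  modeler <- if (length(pt)) ninter / length(pt) else emptyScore(pr)
  sigT <- columnSignatures(test)
  sigR <- columnSignatures(ref)
  tc <- sum(sigR %in% sigT) / length(sigR)
  list(sp = sp, modeler = modeler, tc = tc)
}
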