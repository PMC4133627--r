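#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib ProfileRealign, .registration = TRUE
NULL

## Canonical nucleotide alphabet. 'U' is folded into 'T' at parse time and
## restored (per record) on output, so one engine serves DNA and RNA input.
NUC_ALPHABET <- c("A", "C", "G", "T")
GAP_CHAR <- "-"

#' MetaAlignment: an ordered set of equal-length gapped nucleotide rows
#'
#' The central container of the package: the multiple sequence alignment
#' being reformed. Rows are stored as upper-case gapped strings over
#' \code{A,C,G,T,-}; whether a record originally used RNA (\code{U}) is
#' remembered per row so that output can be written back in the input
#' alphabet.
#'
#' @slot ids character vector of unique record identifiers, in input order.
#' @slot seqs character vector of gapped rows, all of identical width.
#' @slot usesU logical vector, one flag per row; \code{TRUE} when the input
#'   record was RNA and \code{T} should be rendered as \code{U} on output.
#'
#' @seealso [readAlignedFasta()], [reformAlignment()], [degap()]
#' @exportClass MetaAlignment
setClass("MetaAlignment",
  representation(ids = "character", seqs = "character", usesU = "logical"))

setValidity("MetaAlignment", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (length(object@seqs) != n)
    msg <- c(msg, "ids and seqs must have equal length")
  if (length(object@usesU) != n)
    msg <- c(msg, "usesU must have one flag per row")
  if (n >= 1L) {
    w <- nchar(object@seqs)
    if (length(unique(w)) > 1L)
      msg <- c(msg, "unequal alignment row lengths")
    else if (w[1L] < 1L)
      msg <- c(msg, "alignment width must be at least 1")
    if (anyDuplicated(object@ids))
      msg <- c(msg, "duplicate sequence ids")
    bad <- grepl(sprintf("[^%s%s]", paste(NUC_ALPHABET, collapse = ""), GAP_CHAR),
                 object@seqs)
    if (any(bad))
      msg <- c(msg, "unsupported ambiguous or non-nucleotide character")
  }
  if (length(msg)) msg else TRUE
})

#' ResidueProfile: a count-weighted summary of alignment columns
#'
#' One position per (non-void) alignment column; each position holds the raw
#' residue counts of that column (the \eqn{\langle}Residue,
#' Weight\eqn{\rangle} pairs). Gaps contribute nothing, so every column sum
#' equals the number of residues observed in the source column.
#'
#' @slot counts integer matrix, 4 rows named \code{A,C,G,T}, one column per
#'   profile position; all entries non-negative, every column sum positive.
#'
#' @seealso [buildProfile()], [conservationRate()], [applyInsertions()]
#' @exportClass ResidueProfile
setClass("ResidueProfile", representation(counts = "matrix"))

setValidity("ResidueProfile", function(object) {
  m <- object@counts
  if (!is.numeric(m)) return("counts must be a numeric matrix")
  if (nrow(m) != 4L || !identical(rownames(m), NUC_ALPHABET))
    return("counts must have rows A,C,G,T")
  if (ncol(m) < 1L) return("profile must have at least one position")
  if (any(m < 0) || any(m != floor(m))) return("counts must be non-negative integers")
  if (any(colSums(m) < 1)) return("void profile position (all-zero column)")
  TRUE
})

#' ScoringParams: adjusted substitution matrix and the four gap penalties
#'
#' Holds the scoring system of the sequence-profile aligner: the adjusted
#' (strictly positive) substitution matrix and the four interior gap
#' penalties -- opening/extending a gap in the profile (HGOP/HGEP, charged
#' when a sequence residue is inserted between profile positions) and
#' opening/extending a gap in the sequence (VGOP/VGEP, charged when a
#' profile position is skipped). Terminal gaps are always free. All
#' penalties are stored as numbers \eqn{\le 0} and added to the score under
#' maximization; "a harder penalty" means larger magnitude.
#'
#' @slot submat 4x4 numeric matrix over \code{A,C,G,T}, symmetric, strictly
#'   positive (already bonus/coefficient-adjusted).
#' @slot hgop,hgep,vgop,vgep gap penalties, each \eqn{\le 0}, with
#'   \eqn{|open| \ge |extend|} in both orientations and
#'   \eqn{|HGOP| \ge |VGOP|} (opening a gap in the profile is dearer).
#' @slot bonus,coeff the matrix-adjustment parameters that produced
#'   \code{submat} (kept for reporting).
#' @slot apsi the percent average pairwise sequence identity the parameters
#'   were derived from, or \code{NA} for user-supplied parameters.
#' @slot terminalGapsFree always \code{TRUE}; terminal gaps are never
#'   penalized.
#'
#' @seealso [paramsFromAPSI()], [scaleGapPenalties()], [alignToProfile()]
#' @exportClass ScoringParams
setClass("ScoringParams",
  representation(submat = "matrix", hgop = "numeric", hgep = "numeric",
                 vgop = "numeric", vgep = "numeric", bonus = "numeric",
                 coeff = "numeric", apsi = "numeric",
                 terminalGapsFree = "logical"))

setValidity("ScoringParams", function(object) {
  msg <- character()
  m <- object@submat
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)) ||
      !identical(rownames(m), NUC_ALPHABET) || !identical(colnames(m), NUC_ALPHABET))
    return("submat must be a 4x4 numeric matrix with A,C,G,T dimnames")
  if (!isTRUE(all.equal(m, t(m)))) msg <- c(msg, "submat must be symmetric")
  if (any(m <= 0)) msg <- c(msg, "all substitution scores must be strictly positive")
  for (s in c("hgop", "hgep", "vgop", "vgep")) {
    v <- slot(object, s)
    if (length(v) != 1L || is.na(v) || v > 0)
      msg <- c(msg, sprintf("%s must be a single number <= 0", s))
  }
  if (!length(msg)) {
    if (abs(object@hgop) < abs(object@hgep))
      msg <- c(msg, "|HGOP| must be >= |HGEP|")
    if (abs(object@vgop) < abs(object@vgep))
      msg <- c(msg, "|VGOP| must be >= |VGEP|")
    if (abs(object@hgop) < abs(object@vgop))
      msg <- c(msg, "|HGOP| must be >= |VGOP|")
  }
  if (!isTRUE(object@terminalGapsFree))
    msg <- c(msg, "terminal gaps are always free in this model")
  if (length(msg)) msg else TRUE
})

#' PairwiseTrace: one sequence's alignment against the profile
#'
#' An ordered list of steps recording how a sequence was aligned against the
#' profile: \code{M} (match: profile position i against sequence position j),
#' \code{S} (sequence gap: profile position i consumed against a gap) or
#' \code{P} (profile gap: sequence residue j inserted at junction i, i.e.
#' between profile positions i and i+1). Profile positions and sequence
#' positions are each consumed exactly once, in increasing order.
#'
#' @slot seqId identifier of the traced sequence.
#' @slot ops character vector over \code{M,S,P}, one entry per step.
#' @slot ppos integer: for \code{M}/\code{S} the 1-based profile position
#'   consumed; for \code{P} the 0-based junction (number of profile positions
#'   consumed before the insertion).
#' @slot spos integer: for \code{M}/\code{P} the 1-based sequence position
#'   consumed; \code{NA} for \code{S}.
#' @slot score the optimal free-end-gap alignment score attained.
#'
#' @seealso [alignToProfile()], [extractInsertions()], [mergeTraces()]
#' @exportClass PairwiseTrace
setClass("PairwiseTrace",
  representation(seqId = "character", ops = "character", ppos = "integer",
                 spos = "integer", score = "numeric"))

setValidity("PairwiseTrace", function(object) {
  n <- length(object@ops)
  if (length(object@ppos) != n || length(object@spos) != n)
    return("ops, ppos and spos must be parallel vectors")
  if (!all(object@ops %in% c("M", "S", "P")))
    return("ops must be over {M, S, P}")
  sp <- object@spos[object@ops != "S"]
  if (any(is.na(sp)) || is.unsorted(sp, strictly = TRUE))
    return("sequence positions must be consumed once each, in order")
  pp <- object@ppos[object@ops != "P"]
  if (is.unsorted(pp, strictly = TRUE))
    return("profile positions must be consumed once each, in order")
  j <- object@ppos[object@ops == "P"]
  if (is.unsorted(j))
    return("profile-gap junctions must be non-decreasing")
  TRUE
})
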