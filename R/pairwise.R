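#' Align one sequence against a profile (Gotoh, free terminal gaps)
#'
#' Global alignment of an ungapped sequence against a count-weighted
#' profile, using the three-state affine-gap recursion under maximization.
#' Cell scores come from [additiveScore()]; interior gap openings are
#' charged the position-specific penalty of [positionGOP()] (HGOP for
#' residues inserted between profile positions, VGOP for skipped profile
#' positions), extensions the flat HGEP/VGEP; terminal gaps are free on
#' both sides. Traceback ties are broken deterministically with priority
#' MATCH > SEQGAP > PROFGAP, which biases against profile growth.
#'
#' @param seq an ungapped sequence string over \code{A,C,G,T} (a single
#'   element of [degap()] output works directly; its name is used as the
#'   id when `id` is missing).
#' @param prof a [ResidueProfile-class].
#' @param params a [ScoringParams-class], already length-scaled for this
#'   sequence (see [scaleGapPenalties()]).
#' @param id sequence identifier recorded in the trace.
#' @return a [PairwiseTrace-class] attaining the optimal score.
#' @examples
#' prof <- buildProfile(MetaAlignment(c(a = "ACGT", b = "ACGT")))
#' alignToProfile("ACGT", prof, paramsFromAPSI(100), id = "q")
#' @export
alignToProfile <- function(seq, prof, params, id = names(seq)) {
  if (is.null(id) || !nzchar(id)) id <- "seq"
  seq <- as.character(seq)
  stopifnot(length(seq) == 1L, nchar(seq) >= 1L)
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]], NUC_ALPHABET)
  if (anyNA(codes))
    stop("sequence contains a character outside A,C,G,T", call. = FALSE)
  res <- .gotoh_align(prof@counts + 0, codes, params@submat,
                      params@hgop, params@hgep, params@vgop, params@vgep)
  ops <- c("M", "S", "P")[res$ops + 1L]
  i <- 0L; j <- 0L
  ppos <- integer(length(ops)); spos <- integer(length(ops))
  for (k in seq_along(ops)) {
    if (ops[k] == "M") { i <- i + 1L; j <- j + 1L; ppos[k] <- i; spos[k] <- j }
    else if (ops[k] == "S") { i <- i + 1L; ppos[k] <- i; spos[k] <- NA_integer_ }
    else { j <- j + 1L; ppos[k] <- i; spos[k] <- j }
  }
  new("PairwiseTrace", seqId = id, ops = ops, ppos = ppos, spos = spos,
      score = res$score)
}

setMethod("show", "PairwiseTrace", function(object) {
  cat(sprintf("PairwiseTrace '%s': %d steps (%d match, %d seq-gap, %d insert), score %.6g\n",
              object@seqId, length(object@ops), sum(object@ops == "M"),
              sum(object@ops == "S"), sum(object@ops == "P"), object@score))
})

#' Extract profile insertions from a trace
#'
#' One record per maximal run of PROFGAP steps: the junction (0-based,
#' between profile positions `junction` and `junction + 1`; 0 and
#' `profileLength` denote terminal overhangs), the inserted residues in
#' order, and the sequence id. An empty list means the trace fits the
#' profile and no fine-tuning is needed.
#'
#' @param trace a [PairwiseTrace-class].
#' @param seq the ungapped sequence the trace belongs to.
#' @return list of insertion records (`junction`, `residues`, `sourceId`).
#' @export
extractInsertions <- function(trace, seq) {
  seq <- as.character(seq)
  isP <- trace@ops == "P"
  if (!any(isP)) return(list())
  runs <- rle(isP)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (r in which(runs$values)) {
    idx <- seq.int(starts[r], ends[r])
    out[[length(out) + 1L]] <- list(
      junction = trace@ppos[idx[1L]],
      residues = substr(seq, trace@spos[idx[1L]], trace@spos[idx[length(idx)]]),
      sourceId = trace@seqId)
  }
  out
}
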