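#' One sequence-alignment pass with profile fine-tuning
#'
#' Aligns every sequence independently against the profile (each with its
#' length-scaled penalties). If any alignment inserts residues the profile
#' cannot host, all insertions from the whole pass are collected and
#' applied to the profile in one deterministic batch (sorted by junction,
#' same-junction insertions merged left-anchored), and the pass restarts
#' against the enlarged profile. The pass ends when a full round produces
#' zero insertions; the result is therefore independent of the order in
#' which sequences are processed.
#'
#' @param seqs named character vector of ungapped sequences.
#' @param prof the starting [ResidueProfile-class].
#' @param params a [ScoringParams-class] (unscaled; scaling per sequence is
#'   done internally).
#' @param maxFinetuneRounds safeguard on the number of profile-enlargement
#'   rounds; exhausting it signals a parameterization whose gap penalties
#'   rival the substitution scores, which the model forbids.
#' @return list with elements `profile` (the final, possibly enlarged
#'   profile) and `traces` (insertion-free [PairwiseTrace-class] objects,
#'   one per sequence, in input order).
#' @export
sequenceAlignmentPass <- function(seqs, prof, params, maxFinetuneRounds = 20L) {
  stopifnot(length(seqs) >= 1L)
  M <- max(nchar(seqs))
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  for (round in seq_len(maxFinetuneRounds)) {
    traces <- vector("list", length(seqs))
    insertions <- list()
    offenders <- character()
    for (k in seq_along(seqs)) {
      sp <- scaleGapPenalties(params, nchar(seqs[[k]]), M)
      tr <- alignToProfile(seqs[[k]], prof, sp, id = ids[k])
      traces[[k]] <- tr
      ins <- extractInsertions(tr, seqs[[k]])
      if (length(ins)) {
        insertions <- c(insertions, ins)
        offenders <- c(offenders, ids[k])
      }
    }
    if (!length(insertions))
      return(list(profile = prof, traces = traces))
    ord <- order(vapply(insertions, `[[`, integer(1), "junction"))
    prof <- applyInsertions(prof, insertions[ord])
  }
  stop("profile fine-tuning did not settle after ", maxFinetuneRounds,
       " rounds (offending sequences: ", paste(unique(offenders), collapse = ", "),
       "); gap penalties are too large relative to the substitution scores",
       call. = FALSE)
}

#' Merge insertion-free traces into a unified alignment
#'
#' The reformed alignment is inferred indirectly: every trace covers all
#' profile positions (by MATCH or SEQGAP), so the traces are stacked into a
#' matrix with one column per profile position -- a sequence's residue where
#' it matches the position, a gap where it skips it.
#'
#' @param prof the [ResidueProfile-class] the traces were computed against.
#' @param traces list of insertion-free [PairwiseTrace-class] objects.
#' @param seqs named character vector of the ungapped sequences, parallel
#'   to `traces`.
#' @param usesU optional logical vector carried through to the result.
#' @return a [MetaAlignment-class] with `profileLength(prof)` columns that
#'   degaps to `seqs` row-for-row (possibly containing void columns; strip
#'   with [removeVoidColumns()]).
#' @export
mergeTraces <- function(prof, traces, seqs, usesU = NULL) {
  p <- profileLength(prof)
  rows <- vapply(seq_along(traces), function(k) {
    tr <- traces[[k]]
    if (any(tr@ops == "P"))
      stop("trace for '", tr@seqId, "' contains profile insertions; ",
           "fine-tuning must run first", call. = FALSE)
    chars <- rep(GAP_CHAR, p)
    isM <- tr@ops == "M"
    chars[tr@ppos[isM]] <- strsplit(as.character(seqs[[k]]), "",
                                    fixed = TRUE)[[1L]][tr@spos[isM]]
    paste(chars, collapse = "")
  }, character(1))
  ids <- vapply(traces, function(tr) tr@seqId, character(1))
  if (is.null(usesU)) usesU <- rep(FALSE, length(rows))
  new("MetaAlignment", ids = ids, seqs = rows, usesU = usesU)
}

#' Reform an existing multiple sequence alignment
#'
#' The meta-alignment driver. Per outer iteration: void columns are
#' stripped, the APSI of the current alignment is computed and the default
#' scoring parameters derived from it (unless `params` overrides them), the
#' alignment is summarized into a count-weighted profile, every sequence is
#' independently realigned against the profile (with fine-tuning of the
#' profile on insertions), the individual alignments are merged and void
#' columns stripped again. Iteration stops when two successive alignments
#' are identical or after `maxIterations` iterations.
#'
#' The result always degaps to exactly the input sequences, in input order;
#' only the gap structure is reformed.
#'
#' @param initial the starting [MetaAlignment-class] (from any aligner).
#' @param maxIterations maximum number of outer refinement iterations
#'   (default 5).
#' @param maxFinetuneRounds safeguard for [sequenceAlignmentPass()].
#' @param params optional [ScoringParams-class] overriding the APSI-driven
#'   defaults.
#' @param verbose log per-iteration APSI, parameters, profile length and
#'   convergence to stderr.
#' @return the reformed [MetaAlignment-class], free of void columns.
#' @examples
#' aln <- MetaAlignment(c(a = "ACGT-A", b = "ACG-TA", c = "ACGT-A"))
#' reformAlignment(aln)
#' @export
reformAlignment <- function(initial, maxIterations = 5L,
                            maxFinetuneRounds = 20L, params = NULL,
                            verbose = FALSE) {
  stopifnot(maxIterations >= 1L)
  cur <- removeVoidColumns(initial)
  if (nSequences(cur) < 2L) return(cur)
  seqs <- degap(cur)
  for (iter in seq_len(maxIterations)) {
    if (is.null(params)) {
      apsi <- computeAPSI(cur)
      sp <- paramsFromAPSI(apsi)
    } else {
      apsi <- NA_real_
      sp <- params
    }
    prof <- buildProfile(cur)
    pass <- sequenceAlignmentPass(seqs, prof, sp, maxFinetuneRounds)
    nins <- profileLength(pass$profile) - profileLength(prof)
    nxt <- removeVoidColumns(
      mergeTraces(pass$profile, pass$traces, seqs, usesU = cur@usesU))
    if (verbose)
      message(sprintf(
        "iteration %d: APSI %.2f, profile %d positions (+%d inserted), width %d -> %d",
        iter, apsi, profileLength(pass$profile), nins,
        alignmentWidth(cur), alignmentWidth(nxt)))
    if (sameAlignment(nxt, cur)) {
      if (verbose) message("converged after ", iter, " iteration(s)")
      return(nxt)
    }
    cur <- nxt
  }
  if (verbose) message("stopped at the iteration limit (", maxIterations, ")")
  cur
}
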