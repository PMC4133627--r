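#' Build the count-weighted summarization profile of an alignment
#'
#' Each alignment column becomes one profile position holding the raw counts
#' of the residues observed in that column; gaps contribute nothing. Using
#' observed counts rather than averaged frequencies lets the aligner
#' distinguish a column supported by many identical residues from one
#' supported by a single residue.
#'
#' @param aln a [MetaAlignment-class] with no all-gap column (strip with
#'   [removeVoidColumns()] first).
#' @return a [ResidueProfile-class] with exactly `alignmentWidth(aln)`
#'   positions; its total weight equals the total residue count of `aln`.
#' @examples
#' buildProfile(MetaAlignment(c(a = "AC-", b = "A-G")))
#' @export
buildProfile <- function(aln) {
  m <- rowMatrix(aln)
  counts <- vapply(NUC_ALPHABET,
                   function(b) colSums(m == b),
                   numeric(ncol(m)))
  counts <- matrix(as.integer(t(counts)), nrow = 4L,
                   dimnames = list(NUC_ALPHABET, NULL))
  if (any(colSums(counts) == 0L))
    stop("void column in input alignment (column ",
         which(colSums(counts) == 0L)[1L], ")", call. = FALSE)
  new("ResidueProfile", counts = counts)
}

#' @rdname ResidueProfile-class
#' @export
setMethod("profileCounts", "ResidueProfile", function(x) x@counts)

#' @rdname ResidueProfile-class
#' @export
setMethod("profileLength", "ResidueProfile", function(x) ncol(x@counts))

setMethod("show", "ResidueProfile", function(object) {
  p <- profileLength(object)
  cat(sprintf("ResidueProfile: %d positions, total weight %d\n",
              p, sum(object@counts)))
  shown <- min(p, 10L)
  print(object@counts[, seq_len(shown), drop = FALSE])
  if (p > shown) cat("  ... (", p - shown, " more positions)\n", sep = "")
})

#' @describeIn conservationRate max weight over total weight, per position.
#' @export
setMethod("conservationRate", "ResidueProfile", function(x) {
  apply(x@counts, 2L, max) / colSums(x@counts)
})

#' Percent average pairwise sequence identity (APSI) of an alignment
#'
#' Mean, over all unordered row pairs, of the percent identity of the pair:
#' identical-residue columns divided by the number of columns where both
#' rows hold a residue (dual-gap and single-gap columns are excluded from
#' the denominator). A pair with no co-ungapped column contributes 0 and a
#' warning is issued. APSI drives the default scoring parameters.
#'
#' @param aln a [MetaAlignment-class] with at least 2 rows.
#' @return percent in \[0, 100\].
#' @examples
#' computeAPSI(MetaAlignment(c(a = "ACGT", b = "ACGA")))  # 75
#' @export
computeAPSI <- function(aln) {
  n <- nSequences(aln)
  if (n < 2L) stop("APSI needs at least two rows", call. = FALSE)
  m <- rowMatrix(aln)
  res <- m != GAP_CHAR
  total <- 0
  npair <- 0L
  for (a in seq_len(n - 1L)) {
    for (b in seq.int(a + 1L, n)) {
      both <- res[a, ] & res[b, ]
      npair <- npair + 1L
      if (!any(both)) {
        warning("row pair (", aln@ids[a], ", ", aln@ids[b],
                ") shares no co-ungapped column; counted as 0 identity")
        next
      }
      total <- total + 100 * sum(m[a, both] == m[b, both]) / sum(both)
    }
  }
  total / npair
}

#' Enlarge a profile to accommodate new insertions (fine-tuning mode)
#'
#' When an optimal sequence-profile alignment inserts residues the profile
#' cannot host, the profile is grown: each insertion at junction j (between
#' positions j and j+1, 0-based junctions) contributes new positions, one
#' per inserted residue, weighted 1 by the inserting sequence. Insertions
#' from several sequences at the same junction are merged left-anchored,
#' per offset: the junction gains `max(insertion lengths)` new positions and
#' each sequence's residues add weight 1 at their offset. Pre-existing
#' positions and weights are untouched.
#'
#' @param prof a [ResidueProfile-class].
#' @param insertions a list of insertion records, each a list with elements
#'   `junction` (integer in \[0, profileLength\]), `residues` (non-empty
#'   string over ACGT) and `sourceId`.
#' @return the enlarged [ResidueProfile-class] (unchanged when `insertions`
#'   is empty).
#' @export
applyInsertions <- function(prof, insertions) {
  if (!length(insertions)) return(prof)
  p <- profileLength(prof)
  junc <- vapply(insertions, function(x) as.integer(x$junction), integer(1))
  if (any(junc < 0L | junc > p))
    stop("insertion junction out of range [0, ", p, "]", call. = FALSE)
  ## per-junction left-anchored merge of the inserted residue strings
  blocks <- lapply(split(insertions, junc), function(recs) {
    strs <- vapply(recs, function(x) x$residues, character(1))
    width <- max(nchar(strs))
    blk <- matrix(0L, nrow = 4L, ncol = width,
                  dimnames = list(NUC_ALPHABET, NULL))
    for (s in strs) {
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      for (k in seq_along(ch)) blk[ch[k], k] <- blk[ch[k], k] + 1L
    }
    blk
  })
  pieces <- list()
  prev <- 0L
  for (jname in names(blocks)) {
    j <- as.integer(jname)
    if (j > prev)
      pieces <- c(pieces, list(prof@counts[, seq.int(prev + 1L, j), drop = FALSE]))
    pieces <- c(pieces, list(blocks[[jname]]))
    prev <- j
  }
  if (prev < p)
    pieces <- c(pieces, list(prof@counts[, seq.int(prev + 1L, p), drop = FALSE]))
  new("ResidueProfile", counts = do.call(cbind, pieces))
}

#' Dump a profile as a TSV table (debug aid)
#'
#' One row per profile position with the A/C/G/T counts and the position's
#' conservation rate.
#'
#' @param prof a [ResidueProfile-class].
#' @param sink output file path.
#' @return invisibly, `sink`.
#' @export
profileToTSV <- function(prof, sink) {
  d <- data.frame(position = seq_len(profileLength(prof)),
                  t(prof@counts),
                  PCR = conservationRate(prof))
  utils::write.table(d, sink, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sink)
}
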