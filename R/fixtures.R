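#' Simulate a sequence family with a known true alignment
#'
#' Star-topology generator: a random ancestor of `ancestorLength` sites is
#' evolved independently into `nSequences` leaves. Per leaf, each ancestor
#' site is deleted with probability `indelRate / 2` and otherwise
#' substituted with probability `substitutionRate` (uniformly to one of the
#' other three residues); after each junction between ancestor sites
#' (including both ends) an insertion arises with probability
#' `indelRate / 2`, with geometric length of mean `meanIndelLength` and
#' uniform random residues. The true alignment records homology exactly:
#' ancestor sites are shared columns; each leaf's insertions occupy private
#' columns (gaps in every other row), so independent insertions are never
#' asserted homologous. Void columns (sites deleted in every leaf) are
#' stripped. Deterministic given `seed`.
#'
#' @param nSequences number of leaves (\eqn{\ge 2}).
#' @param ancestorLength number of ancestor sites (\eqn{\ge 1}).
#' @param substitutionRate per-site substitution probability in \[0, 1).
#' @param indelRate per-site indel probability in \[0, 1), split evenly
#'   between deletions and insertions.
#' @param meanIndelLength mean of the geometric insertion-length
#'   distribution (\eqn{\ge 1}).
#' @param seed integer seed; the generator is self-contained and restores
#'   the caller's RNG state.
#' @return list with `truth` (the true [MetaAlignment-class]) and `seqs`
#'   (named character vector of the ungapped leaf sequences).
#' @examples
#' fam <- simulateFamily(5, 60, substitutionRate = 0.2, seed = 1)
#' computeAPSI(fam$truth)
#' @export
simulateFamily <- function(nSequences, ancestorLength,
                           substitutionRate = 0.2, indelRate = 0.05,
                           meanIndelLength = 2, seed = 1L) {
  stopifnot(nSequences >= 2L, ancestorLength >= 1L,
            substitutionRate >= 0, substitutionRate < 1,
            indelRate >= 0, indelRate < 1, meanIndelLength >= 1)
  withSeed(seed, {
    anc <- sample(NUC_ALPHABET, ancestorLength, replace = TRUE)
    ## per leaf: residue kept at each site (or NA = deleted), plus an
    ## insertion string after each junction 0..L
    site <- matrix(NA_character_, nrow = nSequences, ncol = ancestorLength)
    ins <- matrix("", nrow = nSequences, ncol = ancestorLength + 1L)
    for (k in seq_len(nSequences)) {
      keep <- stats::runif(ancestorLength) >= indelRate / 2
      res <- anc
      mut <- stats::runif(ancestorLength) < substitutionRate
      for (s in which(mut))
        res[s] <- sample(setdiff(NUC_ALPHABET, anc[s]), 1L)
      res[!keep] <- NA_character_
      if (all(is.na(res))) res[1L] <- anc[1L]   # never let a leaf vanish
      site[k, ] <- res
      where <- stats::runif(ancestorLength + 1L) < indelRate / 2
      for (j in which(where)) {
        len <- stats::rgeom(1L, 1 / meanIndelLength) + 1L
        ins[k, j] <- paste(sample(NUC_ALPHABET, len, replace = TRUE),
                           collapse = "")
      }
    }
    ## assemble truth columns: [junction-0 insertions][site 1][junction-1
    ## insertions][site 2]...; insertions are leaf-private columns
    cols <- list()
    addInsertionCols <- function(j) {
      for (k in seq_len(nSequences)) {
        s <- ins[k, j]
        if (!nzchar(s)) next
        for (ch in strsplit(s, "", fixed = TRUE)[[1L]]) {
          col <- rep(GAP_CHAR, nSequences)
          col[k] <- ch
          cols[[length(cols) + 1L]] <<- col
        }
      }
    }
    addInsertionCols(1L)
    for (s in seq_len(ancestorLength)) {
      col <- site[, s]
      col[is.na(col)] <- GAP_CHAR
      if (any(col != GAP_CHAR)) cols[[length(cols) + 1L]] <- col
      addInsertionCols(s + 1L)
    }
    m <- do.call(cbind, cols)
    ids <- sprintf("seq%02d", seq_len(nSequences))
    truth <- new("MetaAlignment", ids = ids,
                 seqs = apply(m, 1L, paste, collapse = ""),
                 usesU = rep(FALSE, nSequences))
    list(truth = truth, seqs = degap(truth))
  })
}

#' Corrupt an alignment by random gap-block displacement
#'
#' Emulates the frozen-subalignment errors of progressive aligners: `nMoves`
#' times, a random maximal gap run of a random row is excised and
#' re-inserted at a random other point of the same row. Row lengths and
#' degapped content are unchanged; only the gap structure (and hence the
#' asserted homologies) is damaged. Deterministic given `seed`.
#'
#' @param aln a [MetaAlignment-class].
#' @param nMoves number of displacement moves (0 returns the input).
#' @param seed integer seed (caller's RNG state is restored).
#' @return the corrupted [MetaAlignment-class].
#' @export
corruptAlignment <- function(aln, nMoves, seed = 1L) {
  stopifnot(nMoves >= 0L)
  if (nMoves == 0L) return(aln)
  pick1 <- function(x) x[sample.int(length(x), 1L)]   # no scalar pitfall
  withSeed(seed, {
    rows <- aln@seqs
    for (mv in seq_len(nMoves)) {
      hasGap <- grepl("-", rows, fixed = TRUE) &
        grepl("[ACGT]", rows)
      if (!any(hasGap)) break
      k <- pick1(which(hasGap))
      ch <- strsplit(rows[k], "", fixed = TRUE)[[1L]]
      runs <- rle(ch == GAP_CHAR)
      gapRun <- which(runs$values)
      r <- pick1(gapRun)
      ends <- cumsum(runs$lengths)
      from <- ends[r] - runs$lengths[r] + 1L
      body <- ch[-seq.int(from, ends[r])]
      at <- sample.int(length(body) + 1L, 1L) - 1L   # insert after 'at'
      rows[k] <- paste(c(body[seq_len(at)],
                         rep(GAP_CHAR, runs$lengths[r]),
                         body[seq.int(at + 1L, length.out = length(body) - at)]),
                       collapse = "")
    }
    new("MetaAlignment", ids = aln@ids, seqs = rows, usesU = aln@usesU)
  })
}

## run expr under a local, fully seeded RNG and restore the caller's state
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
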