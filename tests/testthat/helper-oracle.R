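# Independent oracles and random-instance generators shared by the tests.
# The alignment oracle enumerates every monotone sequence-profile alignment
# and scores each path from first principles; it shares no search code with
# the DP engine.

## all monotone op sequences from (0,0) to (P,N): M consumes both,
## S consumes one profile position, P consumes one sequence residue
enumAllPaths <- function(P, N) {
  rec <- function(i, j) {
    if (i == P && j == N) return(list(character()))
    out <- list()
    if (i < P && j < N)
      out <- c(out, lapply(rec(i + 1L, j + 1L), function(p) c("M", p)))
    if (i < P)
      out <- c(out, lapply(rec(i + 1L, j), function(p) c("S", p)))
    if (j < N)
      out <- c(out, lapply(rec(i, j + 1L), function(p) c("P", p)))
    out
  }
  rec(0L, 0L)
}

## score one path under the model: additive cell scores, affine interior
## penalties with conservation-modulated openings, free terminal gaps
scorePath <- function(ops, counts, seqCodes, submat,
                      hgop, hgep, vgop, vgep) {
  P <- ncol(counts); N <- length(seqCodes)
  pcr <- apply(counts, 2, max) / colSums(counts)
  ss <- function(i, j) sum(counts[, i] * submat[, seqCodes[j]])
  i <- 0L; j <- 0L; total <- 0; prev <- ""
  for (op in ops) {
    if (op == "M") {
      i <- i + 1L; j <- j + 1L
      total <- total + ss(i, j)
    } else if (op == "S") {
      i <- i + 1L
      if (!(j == 0L || j == N))
        total <- total + if (prev == "S") vgep else vgop - pcr[i] * ss(i, j)
    } else {
      j <- j + 1L
      if (!(i == 0L || i == ncol(counts)))
        total <- total + if (prev == "P") hgep else hgop - pcr[i] * ss(i, j)
    }
    prev <- op
  }
  total
}

oracleBestScore <- function(counts, seqCodes, submat,
                            hgop, hgep, vgop, vgep) {
  paths <- enumAllPaths(ncol(counts), length(seqCodes))
  max(vapply(paths, scorePath, numeric(1), counts = counts,
             seqCodes = seqCodes, submat = submat,
             hgop = hgop, hgep = hgep, vgop = vgop, vgep = vgep))
}

randomCountsMatrix <- function(p, maxWeight = 4L) {
  m <- matrix(0L, nrow = 4L, ncol = p,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (col in seq_len(p)) {
    k <- sample.int(4L, 1L)
    rows <- sample.int(4L, k)
    m[rows, col] <- sample.int(maxWeight, k, replace = TRUE)
  }
  m
}

## a random ScoringParams honouring the constraint system
randomParams <- function() {
  raw <- matrix(runif(16, 1, 120), 4, 4)
  sm <- (raw + t(raw)) / 2
  dimnames(sm) <- list(c("A", "C", "G", "T"), c("A", "C", "G", "T"))
  hgop <- -runif(1, 0, 400)
  hgep <- -runif(1, 0, abs(hgop))
  vgop <- -runif(1, 0, abs(hgop))
  vgep <- -runif(1, 0, abs(vgop))
  new("ScoringParams", submat = sm, hgop = hgop, hgep = hgep,
      vgop = vgop, vgep = vgep,
      bonus = 1, coeff = 1, apsi = NA_real_, terminalGapsFree = TRUE)
}

randomSeqString <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## random valid alignment: random ungapped rows padded with random gaps,
## no void columns guaranteed only if checked by caller
randomAlignment <- function(nrow = 3L, width = 10L, gapProb = 0.25) {
  repeat {
    rows <- vapply(seq_len(nrow), function(k) {
      ch <- sample(c("A", "C", "G", "T"), width, replace = TRUE)
      gap <- runif(width) < gapProb
      if (all(gap)) gap[sample.int(width, 1L)] <- FALSE
      ch[gap] <- "-"
      paste(ch, collapse = "")
    }, character(1))
    aln <- MetaAlignment(rows, ids = sprintf("r%02d", seq_len(nrow)))
    m <- do.call(rbind, strsplit(rows, ""))
    if (all(colSums(m != "-") > 0)) return(aln)
  }
}
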