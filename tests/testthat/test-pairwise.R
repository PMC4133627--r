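test_that("self-alignment against an exactly matching profile is all matches", {
  prof <- buildProfile(MetaAlignment(c(a = "ACGT", b = "ACGT")))
  p <- paramsFromAPSI(100)
  tr <- alignToProfile("ACGT", prof, p, id = "q")
  expect_equal(tr@ops, rep("M", 4))
  expect_equal(tr@ppos, 1:4)
  expect_equal(tr@spos, 1:4)
  adj <- p@submat
  expect_equal(tr@score,
               sum(sapply(1:4, function(i)
                 additiveScore(profileCounts(prof)[, i][profileCounts(prof)[, i] > 0],
                               substr("ACGT", i, i), adj))))
})

test_that("terminal sequence gaps are free: a short exact subsequence nests", {
  prof <- buildProfile(MetaAlignment(c(a = "ACGT", b = "ACGT")))
  tr <- alignToProfile("CG", prof, paramsFromAPSI(100), id = "q")
  expect_equal(tr@ops, c("S", "M", "M", "S"))
  expect_equal(tr@ppos[tr@ops == "M"], 2:3)
})

test_that("the DP optimum equals exhaustive enumeration on random instances", {
  set.seed(41)
  for (rep in 1:200) {
    p <- sample.int(5L, 1L)
    n <- sample.int(5L, 1L)
    counts <- randomCountsMatrix(p)
    seqStr <- randomSeqString(n)
    codes <- match(strsplit(seqStr, "")[[1]], c("A", "C", "G", "T"))
    params <- randomParams()
    prof <- new("ResidueProfile", counts = counts)
    tr <- alignToProfile(seqStr, prof, params, id = "q")
    best <- oracleBestScore(counts, codes, params@submat,
                            params@hgop, params@hgep,
                            params@vgop, params@vgep)
    expect_equal(tr@score, best, tolerance = 1e-9)
    # and the returned trace attains the reported score
    expect_equal(scorePath(tr@ops, counts, codes, params@submat,
                           params@hgop, params@hgep,
                           params@vgop, params@vgep),
                 tr@score, tolerance = 1e-9)
    expect_true(validObject(tr))
  }
})

test_that("free end gaps: padding the profile never hurts the score", {
  set.seed(42)
  for (rep in 1:20) {
    counts <- randomCountsMatrix(4L)
    seqStr <- randomSeqString(4L)
    params <- randomParams()
    inner <- alignToProfile(seqStr, new("ResidueProfile", counts = counts),
                            params, id = "q")
    pad <- randomCountsMatrix(2L)
    padded <- new("ResidueProfile", counts = cbind(pad[, 1, drop = FALSE],
                                                   counts,
                                                   pad[, 2, drop = FALSE]))
    outer <- alignToProfile(seqStr, padded, params, id = "q")
    # extra flanking positions can be consumed by free terminal gaps,
    # so the optimum cannot decrease
    expect_gte(outer@score, inner@score - 1e-9)
  }
})

test_that("a sequence scores at least its own row path through its profile", {
  set.seed(43)
  for (rep in 1:20) {
    aln <- randomAlignment(nrow = 4L, width = 12L)
    prof <- buildProfile(aln)
    params <- paramsFromAPSI(60)
    row <- unname(gappedRows(aln))[1]
    seqStr <- gsub("-", "", row, fixed = TRUE)
    ops <- ifelse(strsplit(row, "")[[1]] == "-", "S", "M")
    codes <- match(strsplit(seqStr, "")[[1]], c("A", "C", "G", "T"))
    own <- scorePath(ops, profileCounts(prof) + 0, codes, params@submat,
                     params@hgop, params@hgep, params@vgop, params@vgep)
    tr <- alignToProfile(seqStr, prof, params, id = "q")
    expect_gte(tr@score, own - 1e-9)
  }
})

test_that("insertions are read off the trace as maximal PROFGAP runs", {
  mk <- function(ops, ppos, spos, id = "s1")
    new("PairwiseTrace", seqId = id, ops = ops, ppos = as.integer(ppos),
        spos = as.integer(spos), score = 0)

  expect_equal(extractInsertions(mk(rep("M", 3), 1:3, 1:3), "ACG"), list())

  # insertion of "CT" after profile position 3
  tr <- mk(c("M", "M", "M", "P", "P", "M"),
           c(1, 2, 3, 3, 3, 4), c(1, 2, 3, 4, 5, 6))
  ins <- extractInsertions(tr, "ACGCTA")
  expect_length(ins, 1)
  expect_equal(ins[[1]]$junction, 3L)
  expect_equal(ins[[1]]$residues, "CT")
  expect_equal(ins[[1]]$sourceId, "s1")

  # two separate runs, reported in junction order, terminal overhang at 0
  tr2 <- mk(c("P", "M", "M", "P", "M"),
            c(0, 1, 2, 2, 3), c(1, 2, 3, 4, 5))
  ins2 <- extractInsertions(tr2, "GACTA")
  expect_length(ins2, 2)
  expect_equal(sapply(ins2, `[[`, "junction"), c(0L, 2L))
  expect_equal(sapply(ins2, `[[`, "residues"), c("G", "T"))
})

test_that("degenerate inputs are rejected", {
  prof <- buildProfile(MetaAlignment(c(a = "AC", b = "AC")))
  expect_error(alignToProfile("ACN", prof, paramsFromAPSI(50)), "outside")
  expect_error(alignToProfile("", prof, paramsFromAPSI(50)))
})
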