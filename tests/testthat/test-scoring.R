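# Reference copy of the published HOXD70 table (Chiaromonte, Yap & Miller
# 2002), transcribed independently of R/scoring.R for cross-checking.
HOXD70_REF <- matrix(c(
    91, -114,  -31, -123,
  -114,  100, -125,  -31,
   -31, -125,  100, -114,
  -123,  -31, -114,   91), nrow = 4, byrow = TRUE,
  dimnames = list(c("A", "C", "G", "T"), c("A", "C", "G", "T")))

test_that("the base matrix is HOXD70: symmetric and strand-symmetric", {
  m <- baseHOXD()
  expect_equal(m, HOXD70_REF)
  expect_equal(m, t(m))
  expect_equal(m["A", "A"], m["T", "T"])
  expect_equal(m["C", "C"], m["G", "G"])
})

test_that("matrix adjustment is coeff * base + bonus with positivity", {
  base <- baseHOXD()
  # identity coefficient: adjusted = base + bonus elementwise
  expect_equal(adjustMatrix(base, bonus = 200, coeff = 1), base + 200)
  adj <- adjustMatrix(base, bonus = 300, coeff = 1.5)
  expect_equal(adj, 1.5 * base + 300)
  expect_true(all(adj > 0))
  # matches stay strictly above mismatches for the same residue
  for (b in c("A", "C", "G", "T"))
    expect_true(adj[b, b] > max(adj[setdiff(colnames(adj), b), b]))
  expect_error(adjustMatrix(base, bonus = 10, coeff = 1),
               "bonus too small")
})

test_that("APSI-derived parameters honour the constraint system over [0,100]", {
  for (apsi in seq(0, 100, by = 1)) {
    p <- paramsFromAPSI(apsi)
    expect_true(all(p@submat > 0))
    expect_true(all(c(p@hgop, p@hgep, p@vgop, p@vgep) <= 0))
    expect_gte(abs(p@hgop), abs(p@hgep))
    expect_gte(abs(p@vgop), abs(p@vgep))
    # opening a gap in the profile is dearer than in the sequence
    expect_gte(abs(p@hgop), abs(p@vgop))
  }
  # frozen spot value at APSI 60, from direct hand evaluation of the
  # calibration: bonus = 200 + 2*60, coeff = 1 + 60/100, linear penalties
  p60 <- paramsFromAPSI(60)
  expect_equal(p60@bonus, 320)
  expect_equal(p60@coeff, 1.6)
  expect_equal(p60@hgop, -420)
  expect_equal(p60@hgep, -80)
  expect_equal(p60@vgop, -210)
  expect_equal(p60@vgep, -40)
  expect_equal(p60@submat["A", "A"], 1.6 * 91 + 320)
  expect_error(paramsFromAPSI(101))
})

test_that("length scaling is the identity at N = M and stiffens short sequences", {
  p <- paramsFromAPSI(50)
  same <- scaleGapPenalties(p, 80, 80)
  expect_equal(c(same@hgop, same@hgep, same@vgop, same@vgep),
               c(p@hgop, p@hgep, p@vgop, p@vgep))
  half <- scaleGapPenalties(p, 50, 100)
  for (s in c("hgop", "hgep", "vgop", "vgep"))
    expect_gte(abs(slot(half, s)), abs(slot(p, s)))
  # frozen spot value: factor 1 + ln(100/30) at (N=30, M=100)
  sc <- scaleGapPenalties(p, 30, 100)
  expect_equal(sc@hgop, p@hgop * (1 + log(100 / 30)))
  expect_equal(sc@vgep, p@vgep * (1 + log(100 / 30)))
  # monotone in N for fixed M
  mags <- sapply(10:100, function(n) abs(scaleGapPenalties(p, n, 100)@hgop))
  expect_true(all(diff(mags) <= 0))
  expect_error(scaleGapPenalties(p, 101, 100), "N > M")
})

test_that("the additive score is the count-weighted sum over the alphabet", {
  adj <- adjustMatrix(baseHOXD(), 300)
  # k identical residues score k times a singleton
  expect_equal(additiveScore(c(C = 5), "C", adj), 5 * adj["C", "C"])
  expect_gt(additiveScore(c(C = 5), "C", adj),
            additiveScore(c(C = 1), "C", adj))
  expect_equal(additiveScore(c(A = 1, G = 1), "C", adj),
               adj["A", "C"] + adj["G", "C"])
  # brute-force loop-over-alphabet oracle on random positions
  set.seed(31)
  for (rep in 1:50) {
    counts <- randomCountsMatrix(1L)[, 1]
    pos <- counts[counts > 0]
    b <- sample(c("A", "C", "G", "T"), 1L)
    brute <- 0
    for (a in names(pos)) brute <- brute + pos[[a]] * adj[a, b]
    expect_equal(additiveScore(pos, b, adj), brute)
  }
  # linearity in the counts under count-wise merge
  p1 <- c(A = 2, C = 1); p2 <- c(A = 1, T = 3)
  merged <- c(A = 3, C = 1, T = 3)
  expect_equal(additiveScore(merged, "G", adj),
               additiveScore(p1, "G", adj) + additiveScore(p2, "G", adj))
})

test_that("position-specific opening penalty is linear in the conservation rate", {
  expect_equal(positionGOP(-10, 0.75, 20), -10 - 0.75 * 20)
  # vanishing modulation as pcr -> 0
  expect_equal(positionGOP(-10, 1e-9, 20), -10, tolerance = 1e-6)
  # doubling pcr doubles the modulation term
  base <- -50; ss <- 40
  expect_equal(positionGOP(base, 0.8, ss) - base,
               2 * (positionGOP(base, 0.4, ss) - base))
  # magnitude non-decreasing in pcr and in ss
  expect_gte(abs(positionGOP(-10, 0.9, 20)), abs(positionGOP(-10, 0.5, 20)))
  expect_gte(abs(positionGOP(-10, 0.5, 50)), abs(positionGOP(-10, 0.5, 20)))
})

test_that("user overrides are validated against the constraint system", {
  p <- makeScoringParams(-100, -10, -50, -5)
  expect_s4_class(p, "ScoringParams")
  expect_true(is.na(p@apsi))
  # positive penalty, |extend| > |open|, |VGOP| > |HGOP| all rejected
  expect_error(makeScoringParams(-100, -10, 3, -5))
  expect_error(makeScoringParams(-100, -150, -50, -5))
  expect_error(makeScoringParams(-40, -10, -50, -5))
})
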