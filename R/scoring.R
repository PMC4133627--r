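#' The HOXD70 nucleotide substitution matrix
#'
#' The empirically derived HOXD70 scoring matrix of Chiaromonte, Yap &
#' Miller (2002), the standard nucleotide matrix behind BLASTZ/LASTZ. It is
#' symmetric and strand-symmetric (A:A = T:T, C:C = G:G). The aligner never
#' uses it raw: see [adjustMatrix()].
#'
#' @return 4x4 numeric matrix with \code{A,C,G,T} dimnames.
#' @export
baseHOXD <- function() {
  m <- matrix(c(
      91, -114,  -31, -123,
    -114,  100, -125,  -31,
     -31, -125,  100, -114,
    -123,  -31, -114,   91),
    nrow = 4L, byrow = TRUE, dimnames = list(NUC_ALPHABET, NUC_ALPHABET))
  m
}

#' Adjust a substitution matrix with a bonus and a re-adjustment coefficient
#'
#' The profile aligner needs every substitution score strictly positive and
#' substantially higher than the gap penalties, otherwise sequences open
#' gaps instead of tolerating mismatches and the profile balloons with
#' poorly supported positions. A flat positive `bonus` achieves that, but
#' lifting all scores equally understates the margin between matches and
#' mismatches; the multiplicative re-adjustment coefficient `coeff`
#' (\eqn{\ge 1}) restores it by stretching the raw scores before the bonus
#' is added:
#' \deqn{Sub'(a,b) = coeff \cdot Sub(a,b) + bonus.}
#' `coeff = 1` is the identity element: the adjustment reduces to
#' `base + bonus`.
#'
#' @param base symmetric 4x4 substitution matrix (e.g. [baseHOXD()]).
#' @param bonus positive additive lift.
#' @param coeff multiplicative stretch, \eqn{\ge 1}.
#' @return the adjusted matrix; errors if any entry is non-positive.
#' @export
adjustMatrix <- function(base, bonus, coeff = 1) {
  stopifnot(bonus > 0, coeff >= 1)
  adj <- coeff * base + bonus
  if (any(adj <= 0))
    stop("bonus too small for matrix", call. = FALSE)
  adj
}

#' Default scoring parameters from the APSI of the starting alignment
#'
#' The matrix bonus, re-adjustment coefficient and the four gap penalties
#' are derived from the percent average pairwise sequence identity of the
#' starting alignment. The calibration is linear in APSI and honours the
#' model's constraint system at every APSI in \[0, 100\]:
#' all adjusted substitution scores are strictly positive and substantially
#' larger than the gap penalties; all penalties are \eqn{\le 0};
#' \eqn{|open| \ge |extend|} in both orientations; and opening a gap in the
#' profile is dearer than opening one in the sequence
#' (\eqn{|HGOP| \ge |VGOP|}), because the profile by construction already
#' offers a position for every residue while skipping a low-scoring profile
#' position should stay inexpensive. Gap costs stiffen with APSI: the more
#' similar the sequences, the less the reformer should perturb the gap
#' structure.
#'
#' @param apsi_p percent APSI in \[0, 100\].
#' @return a [ScoringParams-class] (matrix already adjusted).
#' @examples
#' paramsFromAPSI(60)
#' @export
paramsFromAPSI <- function(apsi_p) {
  stopifnot(is.numeric(apsi_p), length(apsi_p) == 1L,
            apsi_p >= 0, apsi_p <= 100)
  bonus <- 200 + 2 * apsi_p
  coeff <- 1 + apsi_p / 100
  new("ScoringParams",
      submat = adjustMatrix(baseHOXD(), bonus, coeff),
      hgop = -(300 + 2 * apsi_p),
      hgep = -(50 + apsi_p / 2),
      vgop = -(150 + apsi_p),
      vgep = -(25 + apsi_p / 4),
      bonus = bonus, coeff = coeff, apsi = apsi_p,
      terminalGapsFree = TRUE)
}

#' Assemble user-supplied scoring parameters
#'
#' Bypasses the APSI-driven defaults entirely, for users who bring their own
#' penalties and/or matrix. The constraint system of
#' [ScoringParams-class] is still enforced.
#'
#' @param hgop,hgep,vgop,vgep gap penalties, each \eqn{\le 0}.
#' @param base base substitution matrix (default [baseHOXD()]).
#' @param bonus,coeff matrix adjustment, as in [adjustMatrix()].
#' @return a [ScoringParams-class].
#' @export
makeScoringParams <- function(hgop, hgep, vgop, vgep,
                              base = baseHOXD(), bonus = 300, coeff = 1) {
  new("ScoringParams",
      submat = adjustMatrix(base, bonus, coeff),
      hgop = hgop, hgep = hgep, vgop = vgop, vgep = vgep,
      bonus = bonus, coeff = coeff, apsi = NA_real_,
      terminalGapsFree = TRUE)
}

#' Scale gap penalties by the sequence/longest-sequence length ratio
#'
#' Before each sequence is aligned against the profile, all four gap
#' penalties are stiffened for sequences shorter than the longest in the
#' set, so that short sequences do not scatter cheap gaps:
#' \deqn{GP'(N) = GP \cdot (1 + \ln(M/N))}
#' where N is the length of the sequence to be aligned and M the length of
#' the largest sequence. The scaling is the identity at N = M and the
#' penalty magnitude is non-increasing in N.
#'
#' @param params a [ScoringParams-class].
#' @param N length of the sequence to be aligned, \eqn{1 \le N \le M}.
#' @param M length of the largest sequence in the set.
#' @return a [ScoringParams-class] with scaled penalties.
#' @export
scaleGapPenalties <- function(params, N, M) {
  stopifnot(N >= 1, M >= 1)
  if (N > M) stop("sequence longer than the stated maximum (N > M)",
                  call. = FALSE)
  f <- 1 + log(M / N)
  new("ScoringParams",
      submat = params@submat,
      hgop = params@hgop * f, hgep = params@hgep * f,
      vgop = params@vgop * f, vgep = params@vgep * f,
      bonus = params@bonus, coeff = params@coeff, apsi = params@apsi,
      terminalGapsFree = TRUE)
}

#' Additive count-weighted column score
#'
#' Score of aligning residue `b` of a sequence against one profile
#' position: the counts of the position's residues, not their frequencies,
#' weight the substitution scores,
#' \deqn{SS = \sum_{a \in A} C_a \, Sub(a, b),}
#' so a column of k identical residues scores k times a singleton column --
#' the discrimination that motivates the additive model.
#'
#' @param pos one profile position: a named numeric vector of counts over
#'   (a subset of) \code{A,C,G,T}, or a single column of
#'   [profileCounts()].
#' @param b a residue in \code{A,C,G,T}.
#' @param matrix adjusted substitution matrix.
#' @return the additive score (a number).
#' @examples
#' additiveScore(c(A = 1, G = 1), "C", adjustMatrix(baseHOXD(), 300))
#' @export
additiveScore <- function(pos, b, matrix) {
  stopifnot(b %in% NUC_ALPHABET)
  sum(pos * matrix[names(pos), b])
}

#' Position-specific gap-opening penalty
#'
#' Opening a gap against a well-conserved profile position must cost more
#' than opening one against a weakly supported position: the conservation
#' rate of the position, multiplied by the substitution score of the
#' adjacent cell, is added to the base opening penalty's magnitude,
#' \deqn{GOP_{ij} = GOP - PCR_i \cdot SS_{ij}.}
#' The modulation is linear in the conservation rate and applies to the
#' opening penalties (HGOP, VGOP) only -- never to extensions.
#'
#' @param base_gop base opening penalty (\eqn{\le 0}).
#' @param pcr_i conservation rate of the profile position, in (0, 1].
#' @param ss_ij additive substitution score of the (profile position,
#'   sequence residue) cell adjacent to the candidate opening.
#' @return the effective (more negative) opening penalty.
#' @export
positionGOP <- function(base_gop, pcr_i, ss_ij) {
  stopifnot(pcr_i > 0, pcr_i <= 1)
  base_gop - pcr_i * ss_ij
}
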