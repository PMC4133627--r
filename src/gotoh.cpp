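#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Sequence-to-profile global alignment, Gotoh three-state affine recursion
// under maximization with free terminal gaps.
//
// States: M  = profile position i aligned to sequence residue j,
//         Ix = profile position i consumed against a gap in the sequence
//              (SEQGAP, penalties VGOP/VGEP),
//         Iy = sequence residue j inserted between profile positions
//              (PROFGAP, penalties HGOP/HGEP).
// Cell score is the additive count-weighted column score
// SS(i,j) = sum_a C_a(i) * Sub(a, seq_j). Interior gap openings are
// modulated by the profile conservation rate of the adjacent profile
// position: GOP_ij = GOP - PCR_i * SS(i,j). Terminal gaps (j in {0,N} for
// Ix, i in {0,P} for Iy) cost nothing. Tie-breaking is deterministic with
// priority M > Ix > Iy throughout.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(NumericMatrix counts, IntegerVector seq,
                 NumericMatrix submat,
                 double hgop, double hgep, double vgop, double vgep) {
  const int P = counts.ncol();
  const int N = seq.size();
  if (P < 1) stop("empty profile");
  if (N < 1) stop("empty sequence");

  // additive scores SS(i,j), 1-based logical indices stored 0-based
  std::vector<double> SS((size_t)P * N);
  std::vector<double> pcr(P);
  for (int i = 0; i < P; ++i) {
    double tot = 0.0, mx = 0.0;
    for (int a = 0; a < 4; ++a) {
      tot += counts(a, i);
      if (counts(a, i) > mx) mx = counts(a, i);
    }
    pcr[i] = mx / tot;
    for (int j = 0; j < N; ++j) {
      const int b = seq[j] - 1;
      double s = 0.0;
      for (int a = 0; a < 4; ++a) s += counts(a, i) * submat(a, b);
      SS[(size_t)i * N + j] = s;
    }
  }

  const size_t W = (size_t)N + 1;
  std::vector<double> Mm((P + 1) * W, NEG_INF), Ix((P + 1) * W, NEG_INF),
      Iy((P + 1) * W, NEG_INF);
  // predecessor state per cell: 0 = M, 1 = Ix, 2 = Iy
  std::vector<unsigned char> pM((P + 1) * W), pX((P + 1) * W), pY((P + 1) * W);

  Mm[0] = 0.0;
  for (int i = 1; i <= P; ++i) {        // free leading gaps in the sequence
    Ix[i * W] = 0.0;
    pX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= N; ++j) {        // free leading profile gaps
    Iy[j] = 0.0;
    pY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 0; i <= P; ++i) {
    for (int j = 0; j <= N; ++j) {
      if (i == 0 && j == 0) continue;
      const size_t c = i * W + j;
      if (i >= 1 && j >= 1) {
        const size_t d = (i - 1) * W + (j - 1);
        double cand[3] = {Mm[d], Ix[d], Iy[d]};
        int best = 0;
        for (int k = 1; k < 3; ++k) if (cand[k] > cand[best]) best = k;
        if (cand[best] > NEG_INF / 2) {
          Mm[c] = cand[best] + SS[(size_t)(i - 1) * N + (j - 1)];
          pM[c] = (unsigned char)best;
        }
      }
      if (i >= 1 && j >= 1) {           // Ix for j==0 was initialized above
        const bool term = (j == N);
        const double ss = SS[(size_t)(i - 1) * N + (j - 1)];
        const double open = term ? 0.0 : vgop - pcr[i - 1] * ss;
        const double ext = term ? 0.0 : vgep;
        const size_t u = (i - 1) * W + j;
        double cand[3] = {Mm[u] + open, Ix[u] + ext, Iy[u] + open};
        int best = 0;
        for (int k = 1; k < 3; ++k) if (cand[k] > cand[best]) best = k;
        Ix[c] = cand[best];
        pX[c] = (unsigned char)best;
      }
      if (j >= 1 && i >= 1 && i <= P) { // Iy for i==0 was initialized above
        const bool term = (i == P);
        const double ss = SS[(size_t)(i - 1) * N + (j - 1)];
        const double open = term ? 0.0 : hgop - pcr[i - 1] * ss;
        const double ext = term ? 0.0 : hgep;
        const size_t l = i * W + (j - 1);
        double cand[3] = {Mm[l] + open, Ix[l] + open, Iy[l] + ext};
        int best = 0;
        for (int k = 1; k < 3; ++k) if (cand[k] > cand[best]) best = k;
        Iy[c] = cand[best];
        pY[c] = (unsigned char)best;
      }
    }
  }

  const size_t fin = (size_t)P * W + N;
  double cand[3] = {Mm[fin], Ix[fin], Iy[fin]};
  int state = 0;
  for (int k = 1; k < 3; ++k) if (cand[k] > cand[state]) state = k;
  const double score = cand[state];

  // traceback: ops 0 = MATCH, 1 = SEQGAP, 2 = PROFGAP
  std::vector<int> rops;
  rops.reserve(P + N);
  int i = P, j = N;
  while (i > 0 || j > 0) {
    const size_t c = (size_t)i * W + j;
    if (state == 0) {
      rops.push_back(0);
      state = pM[c];
      --i; --j;
    } else if (state == 1) {
      rops.push_back(1);
      state = pX[c];
      --i;
    } else {
      rops.push_back(2);
      state = pY[c];
      --j;
    }
  }
  IntegerVector ops(rops.size());
  for (size_t k = 0; k < rops.size(); ++k)
    ops[k] = rops[rops.size() - 1 - k];
  return List::create(_["score"] = score, _["ops"] = ops);
}
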