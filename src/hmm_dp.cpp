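#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Local (Smith-Waterman-style entry/exit) profile-HMM dynamic programming in
// log2-odds space. States per match column k: M_k (emitting, scored against
// background), I_k (emitting from background, log-odds 0) and D_k (silent).
// An alignment enters at any M_k with weight 1/K and may exit after any M_k
// with weight 1; unaligned flanking residues score 0. `lo` is the K x 21
// match log2-odds matrix (column 21 = X, all zeros); `ltr` is the K x 7
// log2-transition matrix with columns MM, MI, MD, IM, II, DM, DD, where row k
// holds the transitions leaving column k.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp2((a > b ? b : a) - m)) / M_LN2;
}

// columns of ltr
enum { MM = 0, MI = 1, MD = 2, IM = 3, II = 4, DM = 5, DD = 6 };

static void check_obs(const IntegerVector& obs) {
  for (int i = 0; i < obs.size(); ++i)
    if (obs[i] < 1 || obs[i] > 21) stop("sequence symbol outside alphabet");
}

// Viterbi score (log2 space; comparisons only, no log-sum-exp needed)
static double viterbi_bits(const NumericMatrix& lo, const NumericMatrix& ltr,
                           const IntegerVector& obs) {
  const int K = lo.nrow(), L = obs.size();
  const double entry = -std::log2((double)K);
  std::vector<double> Mprev(K + 1, NEG_INF), Iprev(K + 1, NEG_INF),
      Dprev(K + 1, NEG_INF), Mcur(K + 1), Icur(K + 1), Dcur(K + 1);
  double best = NEG_INF;
  for (int i = 1; i <= L; ++i) {
    const int a = obs[i - 1] - 1;
    Mcur[0] = Icur[0] = Dcur[0] = NEG_INF;
    for (int k = 1; k <= K; ++k) {
      double cand = entry;
      if (k > 1) {
        double fm = Mprev[k - 1] + ltr(k - 2, MM);
        double fi = Iprev[k - 1] + ltr(k - 2, IM);
        double fd = Dprev[k - 1] + ltr(k - 2, DM);
        if (fm > cand) cand = fm;
        if (fi > cand) cand = fi;
        if (fd > cand) cand = fd;
      }
      Mcur[k] = lo(k - 1, a) + cand;
      double gm = Mprev[k] + ltr(k - 1, MI);
      double gi = Iprev[k] + ltr(k - 1, II);
      Icur[k] = gm > gi ? gm : gi;
    }
    Dcur[1] = NEG_INF;
    for (int k = 2; k <= K; ++k) {
      double hm = Mcur[k - 1] + ltr(k - 2, MD);
      double hd = Dcur[k - 1] + ltr(k - 2, DD);
      Dcur[k] = hm > hd ? hm : hd;
    }
    for (int k = 1; k <= K; ++k)
      if (Mcur[k] > best) best = Mcur[k];
    std::swap(Mprev, Mcur); std::swap(Iprev, Icur); std::swap(Dprev, Dcur);
  }
  return best;
}

// Forward score: scaled linear-space odds with a per-row log2 accumulator
// (numerically equivalent to log-space summation at double precision, an
// order of magnitude faster).
static double forward_bits(const NumericMatrix& lo, const NumericMatrix& ltr,
                           const IntegerVector& obs) {
  const int K = lo.nrow(), L = obs.size();
  const double entry0 = 1.0 / (double)K;
  // odds-space emissions and transitions
  std::vector<double> em(K * 21), tr(K * 7);
  for (int k = 0; k < K; ++k) {
    for (int a = 0; a < 21; ++a) em[k * 21 + a] = std::exp2(lo(k, a));
    for (int c = 0; c < 7; ++c) tr[k * 7 + c] = std::exp2(ltr(k, c));
  }
  std::vector<double> Mprev(K + 1, 0.0), Iprev(K + 1, 0.0), Dprev(K + 1, 0.0),
      Mcur(K + 1), Icur(K + 1), Dcur(K + 1);
  double scale = 0.0;          // cumulative log2 scale of the current row
  double total = NEG_INF;      // log2 of the summed exit mass
  for (int i = 1; i <= L; ++i) {
    const int a = obs[i - 1] - 1;
    // entry mass, expressed on the current row's scale
    const double entry = entry0 * std::exp2(-scale);
    Mcur[0] = Icur[0] = Dcur[0] = 0.0;
    double rowmax = 0.0;
    for (int k = 1; k <= K; ++k) {
      double cand = entry;
      if (k > 1) {
        const double* t = &tr[(k - 2) * 7];
        cand += Mprev[k - 1] * t[MM] + Iprev[k - 1] * t[IM] +
                Dprev[k - 1] * t[DM];
      }
      Mcur[k] = em[(k - 1) * 21 + a] * cand;
      const double* tk = &tr[(k - 1) * 7];
      Icur[k] = Mprev[k] * tk[MI] + Iprev[k] * tk[II];
    }
    Dcur[1] = 0.0;
    for (int k = 2; k <= K; ++k) {
      const double* t = &tr[(k - 2) * 7];
      Dcur[k] = Mcur[k - 1] * t[MD] + Dcur[k - 1] * t[DD];
    }
    double row_exit = 0.0;
    for (int k = 1; k <= K; ++k) {
      row_exit += Mcur[k];
      double m = Mcur[k] > Icur[k] ? Mcur[k] : Icur[k];
      if (Dcur[k] > m) m = Dcur[k];
      if (m > rowmax) rowmax = m;
    }
    if (row_exit > 0.0)
      total = lse2(total, std::log2(row_exit) + scale);
    // rescale so the largest cell is 1
    if (rowmax > 0.0 && (rowmax > 1e100 || rowmax < 1e-100)) {
      const double f = 1.0 / rowmax;
      for (int k = 1; k <= K; ++k) { Mcur[k] *= f; Icur[k] *= f; Dcur[k] *= f; }
      scale += std::log2(rowmax);
    }
    std::swap(Mprev, Mcur); std::swap(Iprev, Icur); std::swap(Dprev, Dcur);
  }
  return total;
}

// [[Rcpp::export(name = ".hmm_dp_bits")]]
double hmm_dp_bits(NumericMatrix lo, NumericMatrix ltr, IntegerVector obs,
                   bool forward) {
  check_obs(obs);
  if (obs.size() == 0) return NEG_INF;
  return forward ? forward_bits(lo, ltr, obs) : viterbi_bits(lo, ltr, obs);
}

// Viterbi with traceback. Returns the optimal score and, for each residue,
// the match column it aligns to (0 = unaligned flank or insert state).
// [[Rcpp::export(name = ".hmm_viterbi_path")]]
List hmm_viterbi_path(NumericMatrix lo, NumericMatrix ltr, IntegerVector obs) {
  const int K = lo.nrow(), L = obs.size();
  check_obs(obs);
  const double entry = -std::log2((double)K);
  // state codes for pointers: 0 entry, 1 M, 2 I, 3 D
  NumericMatrix Mv(L + 1, K + 1), Iv(L + 1, K + 1), Dv(L + 1, K + 1);
  IntegerMatrix Mp(L + 1, K + 1), Ip(L + 1, K + 1), Dp(L + 1, K + 1);
  std::fill(Mv.begin(), Mv.end(), NEG_INF);
  std::fill(Iv.begin(), Iv.end(), NEG_INF);
  std::fill(Dv.begin(), Dv.end(), NEG_INF);

  double best = NEG_INF; int bi = -1, bk = -1;
  for (int i = 1; i <= L; ++i) {
    const int a = obs[i - 1] - 1;
    for (int k = 1; k <= K; ++k) {
      double cand = entry; int ptr = 0;
      if (k > 1) {
        double fm = Mv(i - 1, k - 1) + ltr(k - 2, MM);
        double fi = Iv(i - 1, k - 1) + ltr(k - 2, IM);
        double fd = Dv(i - 1, k - 1) + ltr(k - 2, DM);
        if (fm > cand) { cand = fm; ptr = 1; }
        if (fi > cand) { cand = fi; ptr = 2; }
        if (fd > cand) { cand = fd; ptr = 3; }
      }
      Mv(i, k) = lo(k - 1, a) + cand; Mp(i, k) = ptr;
      double gm = Mv(i - 1, k) + ltr(k - 1, MI);
      double gi = Iv(i - 1, k) + ltr(k - 1, II);
      if (gm >= gi) { Iv(i, k) = gm; Ip(i, k) = 1; }
      else          { Iv(i, k) = gi; Ip(i, k) = 2; }
    }
    for (int k = 2; k <= K; ++k) {
      double hm = Mv(i, k - 1) + ltr(k - 2, MD);
      double hd = Dv(i, k - 1) + ltr(k - 2, DD);
      if (hm >= hd) { Dv(i, k) = hm; Dp(i, k) = 1; }
      else          { Dv(i, k) = hd; Dp(i, k) = 3; }
    }
    for (int k = 1; k <= K; ++k)
      if (Mv(i, k) > best) { best = Mv(i, k); bi = i; bk = k; }
  }

  IntegerVector cols(L, 0);
  if (bi > 0 && best > NEG_INF) {
    int i = bi, k = bk, st = 1; // start at best-ending M cell
    while (true) {
      if (st == 1) {            // M: residue i aligned to column k
        cols[i - 1] = k;
        int p = Mp(i, k);
        if (p == 0) break;      // entry
        st = p; --i; --k;
      } else if (st == 2) {     // I: residue i unaligned insert
        int p = Ip(i, k);
        st = p; --i;
      } else {                  // D: silent
        int p = Dp(i, k);
        st = p; --k;
      }
    }
  }
  return List::create(_["bits"] = best, _["cols"] = cols);
}
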