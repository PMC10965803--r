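#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment score with affine gaps.
// A gap of length L costs gap_open + L * gap_extend, matching the
// convention of Biostrings::pairwiseAlignment(type = "global").
// Sequences are 0-based integer codes into the 20-letter alphabet.
// CDR3 loops are short, so the hot path uses fixed-size DP tables up
// to FASTLEN residues; longer sequences take a heap-allocated path.
#define FASTLEN 63
#define MAXLEN 4000

static int nw_affine_slow(const int* a, int la, const int* b, int lb,
                          const int* S, int go, int ge) {
  const int NEG = -100000000;
  std::vector<int> M((la + 1) * (lb + 1)), X((la + 1) * (lb + 1)),
      Y((la + 1) * (lb + 1));
  int w = lb + 1;
  M[0] = 0; X[0] = NEG; Y[0] = NEG;
  for (int i = 1; i <= la; ++i) {
    M[i * w] = NEG; X[i * w] = -(go + ge * i); Y[i * w] = NEG;
  }
  for (int j = 1; j <= lb; ++j) {
    M[j] = NEG; Y[j] = -(go + ge * j); X[j] = NEG;
  }
  for (int i = 1; i <= la; ++i) {
    const int* Sa = S + 20 * a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      int d = i * w + j;
      int m = M[d - w - 1], x = X[d - w - 1], y = Y[d - w - 1];
      int best = m > x ? m : x; if (y > best) best = y;
      M[d] = best + Sa[b[j - 1]];
      int m1 = M[d - w] - (go + ge), x1 = X[d - w] - ge;
      X[d] = m1 > x1 ? m1 : x1;
      int m2 = M[d - 1] - (go + ge), y2 = Y[d - 1] - ge;
      Y[d] = m2 > y2 ? m2 : y2;
    }
  }
  int last = la * w + lb;
  int r = M[last];
  if (X[last] > r) r = X[last];
  if (Y[last] > r) r = Y[last];
  return r;
}

static inline int nw_affine(const int* a, int la, const int* b, int lb,
                            const int* S, int go, int ge) {
  if (la > FASTLEN || lb > FASTLEN)
    return nw_affine_slow(a, la, b, lb, S, go, ge);
  const int NEG = -100000000;
  static int M[FASTLEN + 1][FASTLEN + 1], X[FASTLEN + 1][FASTLEN + 1],
      Y[FASTLEN + 1][FASTLEN + 1];
  M[0][0] = 0; X[0][0] = NEG; Y[0][0] = NEG;
  for (int i = 1; i <= la; ++i) {
    M[i][0] = NEG; X[i][0] = -(go + ge * i); Y[i][0] = NEG;
  }
  for (int j = 1; j <= lb; ++j) {
    M[0][j] = NEG; Y[0][j] = -(go + ge * j); X[0][j] = NEG;
  }
  for (int i = 1; i <= la; ++i) {
    const int* Sa = S + 20 * a[i - 1];
    for (int j = 1; j <= lb; ++j) {
      int m = M[i - 1][j - 1], x = X[i - 1][j - 1], y = Y[i - 1][j - 1];
      int best = m > x ? m : x; if (y > best) best = y;
      M[i][j] = best + Sa[b[j - 1]];
      int m1 = M[i - 1][j] - (go + ge), x1 = X[i - 1][j] - ge;
      X[i][j] = m1 > x1 ? m1 : x1;
      int m2 = M[i][j - 1] - (go + ge), y2 = Y[i][j - 1] - ge;
      Y[i][j] = m2 > y2 ? m2 : y2;
    }
  }
  int r = M[la][lb];
  if (X[la][lb] > r) r = X[la][lb];
  if (Y[la][lb] > r) r = Y[la][lb];
  return r;
}

struct EncRep {
  std::vector<std::vector<int> > seqs;
  std::vector<double> w;
  std::vector<double> self;  // raw self-alignment scores
};

static void decode_reps(const List& reps, std::vector<EncRep>& out) {
  int n = reps.size();
  out.resize(n);
  for (int i = 0; i < n; ++i) {
    List r = reps[i];
    List sq = r["seqs"];
    NumericVector w = r["w"];
    NumericVector self = r["self"];
    EncRep& e = out[i];
    int m = sq.size();
    e.seqs.resize(m);
    e.w.assign(w.begin(), w.end());
    e.self.assign(self.begin(), self.end());
    for (int j = 0; j < m; ++j) {
      IntegerVector s = sq[j];
      if (s.size() > MAXLEN) stop("sequence longer than supported maximum");
      e.seqs[j].assign(s.begin(), s.end());
    }
  }
}

static inline double clamp1(double x) {
  if (x > 1.0) return 1.0;
  if (x < -1.0) return -1.0;
  return x;
}

// Abundance-weighted best-match homology between two encoded repertoires.
static double pair_homology(const EncRep& A, const EncRep& B,
                            const int* S, int go, int ge, bool normalize) {
  int ma = (int)A.seqs.size(), mb = (int)B.seqs.size();
  std::vector<double> bestA(ma, -1e300), bestB(mb, -1e300);
  for (int j = 0; j < ma; ++j) {
    const std::vector<int>& a = A.seqs[j];
    for (int jp = 0; jp < mb; ++jp) {
      const std::vector<int>& b = B.seqs[jp];
      double s = (double)nw_affine(a.data(), (int)a.size(),
                                   b.data(), (int)b.size(), S, go, ge);
      if (normalize) s = clamp1(s / std::sqrt(A.self[j] * B.self[jp]));
      if (s > bestA[j]) bestA[j] = s;
      if (s > bestB[jp]) bestB[jp] = s;
    }
  }
  double num = 0.0, den = 0.0;
  for (int j = 0; j < ma; ++j) { num += A.w[j] * bestA[j]; den += A.w[j]; }
  for (int jp = 0; jp < mb; ++jp) { num += B.w[jp] * bestB[jp]; den += B.w[jp]; }
  return num / den;
}

static std::vector<int> flatten_sub(const IntegerMatrix& S) {
  std::vector<int> Sf(400);
  for (int i = 0; i < 20; ++i)
    for (int j = 0; j < 20; ++j) Sf[20 * i + j] = S(i, j);
  return Sf;
}

// [[Rcpp::export]]
int cpp_nw_score(IntegerVector a, IntegerVector b, IntegerMatrix S,
                 int gap_open, int gap_extend) {
  if (a.size() == 0 || b.size() == 0) stop("empty sequence");
  std::vector<int> Sf = flatten_sub(S);
  return nw_affine(INTEGER(a), a.size(), INTEGER(b), b.size(),
                   Sf.data(), gap_open, gap_extend);
}

// [[Rcpp::export]]
NumericMatrix cpp_kernel(List reps, IntegerMatrix S, int gap_open,
                         int gap_extend, bool normalize) {
  std::vector<EncRep> E;
  decode_reps(reps, E);
  std::vector<int> Sf = flatten_sub(S);
  int n = (int)E.size();
  NumericMatrix K(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      double v = pair_homology(E[i], E[j], Sf.data(), gap_open, gap_extend,
                               normalize);
      K(i, j) = v;
      K(j, i) = v;
    }
    Rcpp::checkUserInterrupt();
  }
  return K;
}

// [[Rcpp::export]]
NumericMatrix cpp_cross_kernel(List reps_a, List reps_b, IntegerMatrix S,
                               int gap_open, int gap_extend, bool normalize) {
  std::vector<EncRep> A, B;
  decode_reps(reps_a, A);
  decode_reps(reps_b, B);
  std::vector<int> Sf = flatten_sub(S);
  NumericMatrix K((int)A.size(), (int)B.size());
  for (int i = 0; i < (int)A.size(); ++i) {
    for (int j = 0; j < (int)B.size(); ++j)
      K(i, j) = pair_homology(A[i], B[j], Sf.data(), gap_open, gap_extend,
                              normalize);
    Rcpp::checkUserInterrupt();
  }
  return K;
}

// Homology for an explicit list of (i, j) index pairs (1-based), used to
// fill only the missing entries of a cached pool-level kernel.
// [[Rcpp::export]]
NumericVector cpp_kernel_pairs(List reps, IntegerVector ii, IntegerVector jj,
                               IntegerMatrix S, int gap_open, int gap_extend,
                               bool normalize) {
  std::vector<EncRep> E;
  decode_reps(reps, E);
  std::vector<int> Sf = flatten_sub(S);
  int m = ii.size();
  NumericVector out(m);
  for (int t = 0; t < m; ++t) {
    out[t] = pair_homology(E[ii[t] - 1], E[jj[t] - 1], Sf.data(), gap_open,
                           gap_extend, normalize);
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
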