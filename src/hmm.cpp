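#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Forward / Viterbi log-odds (nats) of a sequence against a local-alignment-
// wrapped profile HMM. Entry: uniform 1/M into any match state at any
// position; exit: factor 1/M from any match state; flanking residues and
// insert emissions score as background (odds 1).
//
// lo: M x 21 matrix of log emission odds per match state; column 21 (index
//     20) is the wildcard (log-odds 0 enforced by caller).
// seq: integer vector, 0-based residue indices (20 = wildcard).
// tMM,tMI,tMD,tIM,tII,tDM,tDD: length M-1 log transition probabilities from
//     source node j (1-based j = 1..M-1).
// viterbi: if true, replace sums with maxima.
// [[Rcpp::export]]
double hmm_score_cpp(NumericMatrix lo, IntegerVector seq,
                     NumericVector tMM, NumericVector tMI, NumericVector tMD,
                     NumericVector tIM, NumericVector tII,
                     NumericVector tDM, NumericVector tDD,
                     bool viterbi) {
  int M = lo.nrow();
  int L = seq.size();
  double log_entry = -std::log((double)M);
  double log_exit = -std::log((double)M);

  std::vector<double> Mprev(M, NEG_INF), Iprev(M, NEG_INF), Dprev(M, NEG_INF);
  std::vector<double> Mcur(M), Icur(M), Dcur(M);
  double total = NEG_INF;

  for (int i = 0; i < L; ++i) {
    int a = seq[i];
    for (int j = 0; j < M; ++j) {
      double acc = log_entry;
      if (j > 0) {
        double t1 = Mprev[j - 1] + tMM[j - 1];
        double t2 = Iprev[j - 1] + tIM[j - 1];
        double t3 = Dprev[j - 1] + tDM[j - 1];
        if (viterbi) {
          if (t1 > acc) acc = t1;
          if (t2 > acc) acc = t2;
          if (t3 > acc) acc = t3;
        } else {
          acc = lse2(lse2(acc, t1), lse2(t2, t3));
        }
      }
      Mcur[j] = lo(j, a) + acc;
    }
    for (int j = 0; j < M - 1; ++j) {
      double t1 = Mprev[j] + tMI[j];
      double t2 = Iprev[j] + tII[j];
      Icur[j] = viterbi ? (t1 > t2 ? t1 : t2) : lse2(t1, t2);
    }
    if (M > 0) Icur[M - 1] = NEG_INF;
    Dcur[0] = NEG_INF;
    for (int j = 1; j < M; ++j) {
      double t1 = Mcur[j - 1] + tMD[j - 1];
      double t2 = Dcur[j - 1] + tDD[j - 1];
      Dcur[j] = viterbi ? (t1 > t2 ? t1 : t2) : lse2(t1, t2);
    }
    for (int j = 0; j < M; ++j) {
      double e = Mcur[j] + log_exit;
      if (viterbi) {
        if (e > total) total = e;
      } else {
        total = lse2(total, e);
      }
    }
    Mprev = Mcur; Iprev = Icur; Dprev = Dcur;
  }
  return total;
}
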