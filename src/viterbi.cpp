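// Glocal (global-in-model, local-in-sequence) Viterbi for a profile HMM with
// plan7-style topology: states M_j / I_j / D_j, no D<->I transitions, free
// (zero-cost) flanks before the first and after the last emitting state.
// All scores are log2 (bits); insert emissions score 0 (background log-odds).
//
// Tie-breaking on exact score equality: smaller envelope start (leftmost),
// then fewer insertions, then a fixed predecessor order (M < I < D).

#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

struct Cell {
  double s;   // score in bits
  int start;  // first emitted residue position (INT_MAX if none yet)
  int nins;   // insertions so far
};

static inline bool better(const Cell &a, const Cell &b) {
  if (a.s != b.s) return a.s > b.s;
  if (a.start != b.start) return a.start < b.start;
  return a.nins < b.nins;
}

// [[Rcpp::export]]
List viterbi_glocal_cpp(NumericMatrix ebits, double tBM, double tBD,
                        NumericVector tMM, NumericVector tMI, NumericVector tMD,
                        NumericVector tIM, NumericVector tII,
                        NumericVector tDM, NumericVector tDD,
                        IntegerVector seq) {
  const int L = ebits.nrow();
  const int n = seq.size();
  const double NEG = R_NegInf;
  const Cell BAD = {NEG, INT_MAX, 0};

  // full matrices, (n+1) x (L+1); index idx(i,j) = i*(L+1)+j
  std::vector<Cell> VM((n + 1) * (L + 1), BAD), VI((n + 1) * (L + 1), BAD),
      VD((n + 1) * (L + 1), BAD);
  std::vector<signed char> PM((n + 1) * (L + 1), -1), PI((n + 1) * (L + 1), -1),
      PD((n + 1) * (L + 1), -1);
  // pointer codes: 0 = entry (B), 1 = from M, 2 = from I, 3 = from D

  auto idx = [L](int i, int j) { return i * (L + 1) + j; };

  for (int i = 0; i <= n; ++i) {
    // delete entry at any offset i (flank residues 1..i skipped for free)
    VD[idx(i, 1)] = {tBD, INT_MAX, 0};
    PD[idx(i, 1)] = 0;
    for (int j = 1; j <= L; ++j) {
      if (i >= 1) {
        const int r = seq[i - 1];  // 0 = unknown residue, emits 0 bits
        const double e = (r == 0) ? 0.0 : ebits(j - 1, r - 1);
        // match state
        Cell bm = BAD;
        signed char pm = -1;
        if (j == 1) {
          bm = {tBM, INT_MAX, 0};
          pm = 0;
        } else {
          const Cell &m = VM[idx(i - 1, j - 1)];
          const Cell &iv = VI[idx(i - 1, j - 1)];
          const Cell &d = VD[idx(i - 1, j - 1)];
          Cell c;
          if (m.s > NEG) {
            c = {m.s + tMM[j - 2], m.start, m.nins};
            if (better(c, bm)) { bm = c; pm = 1; }
          }
          if (iv.s > NEG) {
            c = {iv.s + tIM[j - 2], iv.start, iv.nins};
            if (better(c, bm)) { bm = c; pm = 2; }
          }
          if (d.s > NEG) {
            c = {d.s + tDM[j - 2], d.start, d.nins};
            if (better(c, bm)) { bm = c; pm = 3; }
          }
        }
        if (pm >= 0) {
          bm.s += e;
          if (bm.start == INT_MAX) bm.start = i;
          VM[idx(i, j)] = bm;
          PM[idx(i, j)] = pm;
        }
        // insert state I_j exists for j = 1..L-1
        if (j <= L - 1) {
          Cell bi = BAD;
          signed char pi = -1;
          const Cell &m = VM[idx(i - 1, j)];
          const Cell &iv = VI[idx(i - 1, j)];
          Cell c;
          if (m.s > NEG) {
            c = {m.s + tMI[j - 1], m.start, m.nins + 1};
            if (better(c, bi)) { bi = c; pi = 1; }
          }
          if (iv.s > NEG) {
            c = {iv.s + tII[j - 1], iv.start, iv.nins + 1};
            if (better(c, bi)) { bi = c; pi = 2; }
          }
          if (pi >= 0) {
            if (bi.start == INT_MAX) bi.start = i;  // cannot happen in practice
            VI[idx(i, j)] = bi;
            PI[idx(i, j)] = pi;
          }
        }
      }
      // delete state (same row i), j >= 2
      if (j >= 2) {
        Cell bd = BAD;
        signed char pd = -1;
        const Cell &m = VM[idx(i, j - 1)];
        const Cell &d = VD[idx(i, j - 1)];
        Cell c;
        if (m.s > NEG) {
          c = {m.s + tMD[j - 2], m.start, m.nins};
          if (better(c, bd)) { bd = c; pd = 1; }
        }
        if (d.s > NEG) {
          c = {d.s + tDD[j - 2], d.start, d.nins};
          if (better(c, bd)) { bd = c; pd = 3; }
        }
        if (pd >= 0) {
          VD[idx(i, j)] = bd;
          PD[idx(i, j)] = pd;
        }
      }
    }
  }

  // best end: M_L or D_L at any i (trailing flank free), E transitions cost 0
  Cell best = BAD;
  int bi = -1;
  signed char bstate = -1;  // 1 = M, 3 = D
  for (int i = 0; i <= n; ++i) {
    const Cell &m = VM[idx(i, L)];
    if (m.s > NEG && better(m, best)) { best = m; bi = i; bstate = 1; }
    const Cell &d = VD[idx(i, L)];
    if (d.s > NEG && better(d, best)) { best = d; bi = i; bstate = 3; }
  }
  if (bi < 0) {
    return List::create(_["score"] = NEG, _["states"] = IntegerVector(L),
                        _["mpos"] = IntegerVector(L),
                        _["ins"] = IntegerVector(L), _["env"] = IntegerVector::create(0, 0));
  }

  // traceback
  IntegerVector states(L), mpos(L), ins(L);
  int i = bi, j = L;
  signed char st = bstate;
  int env_start = 0, env_end = 0;
  while (j >= 1) {
    if (st == 1) {  // match
      states[j - 1] = 1;
      mpos[j - 1] = i;
      if (env_end == 0) env_end = i;
      env_start = i;
      signed char p = PM[idx(i, j)];
      if (p == 0) break;
      st = p;
      --i;
      --j;
    } else if (st == 2) {  // insert at I_j
      ins[j - 1] += 1;
      if (env_end == 0) env_end = i;
      env_start = i;
      signed char p = PI[idx(i, j)];
      st = p;
      --i;  // stay at node j
    } else {  // delete
      states[j - 1] = 3;
      signed char p = PD[idx(i, j)];
      if (p == 0) break;
      st = p;
      --j;  // same row i
    }
  }

  return List::create(_["score"] = best.s, _["states"] = states,
                      _["mpos"] = mpos, _["ins"] = ins,
                      _["env"] = IntegerVector::create(env_start, env_end));
}

// Score-only variant: identical recurrences and score, no traceback state.
// Used wherever only the bit score is needed (seed rescoring, search
// gating); roughly an order of magnitude faster than the traceback kernel.
// [[Rcpp::export]]
double viterbi_score_cpp(NumericMatrix ebits, double tBM, double tBD,
                         NumericVector tMM, NumericVector tMI, NumericVector tMD,
                         NumericVector tIM, NumericVector tII,
                         NumericVector tDM, NumericVector tDD,
                         IntegerVector seq) {
  const int L = ebits.nrow();
  const int n = seq.size();
  const double NEG = -1e300;  // effective -Inf that stays finite-arithmetic
  const double *EB = REAL(ebits);
  const double *MM = REAL(tMM), *MI = REAL(tMI), *MD = REAL(tMD);
  const double *IM = REAL(tIM), *II = REAL(tII);
  const double *DM = REAL(tDM), *DD = REAL(tDD);
  const int *S = INTEGER(seq);
  std::vector<double> Mp(L + 1, NEG), Ip(L + 1, NEG), Dc(L + 1, NEG),
      Mc(L + 1, NEG), Ic(L + 1, NEG), zero(L, 0.0);
  auto clamp = [NEG](double x) { return (x < NEG || !std::isfinite(x)) ? NEG : x; };
  double best = NEG;
  // i = 0 row: delete-only entry
  Dc[1] = clamp(tBD);
  for (int j = 2; j <= L; ++j) Dc[j] = clamp(Dc[j - 1] + DD[j - 2]);
  if (Dc[L] > best) best = Dc[L];
  std::vector<double> Dp = Dc;
  const double bm0 = clamp(tBM), bd0 = clamp(tBD);
  for (int i = 1; i <= n; ++i) {
    const int r = S[i - 1];
    const double *e = (r == 0) ? zero.data() : EB + (size_t)(r - 1) * L;
    Mc[1] = bm0 + e[0];
    Dc[1] = bd0;
    for (int j = 2; j <= L; ++j) {
      double m = Mp[j - 1] + MM[j - 2];
      const double vi = Ip[j - 1] + IM[j - 2];
      if (vi > m) m = vi;
      const double vd = Dp[j - 1] + DM[j - 2];
      if (vd > m) m = vd;
      Mc[j] = m + e[j - 1];
      double d = Mc[j - 1] + MD[j - 2];
      const double dd = Dc[j - 1] + DD[j - 2];
      if (dd > d) d = dd;
      Dc[j] = d;
      // insert state for the previous node (I_1 .. I_{L-1})
      double v = Mp[j - 1] + MI[j - 2];
      const double vv = Ip[j - 1] + II[j - 2];
      if (vv > v) v = vv;
      Ic[j - 1] = v;
    }
    if (Mc[L] > best) best = Mc[L];
    if (Dc[L] > best) best = Dc[L];
    std::swap(Mp, Mc);
    std::swap(Ip, Ic);
    std::swap(Dp, Dc);
  }
  return best <= NEG ? R_NegInf : best;
}
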