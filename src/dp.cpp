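#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// All scores are log2-odds ("bits"). The local profile-HMM architecture:
// uniform begin over (match state i, sequence position j), i.e. 1/(n*T);
// uniform exit over the remaining match states, p_end(i) = 1/(n - i + 1).
// Transition log-odds passed in are already damped by log2(1 - p_end(i)).
// Insert states emit background (log-odds 0). Unaligned flanks emit
// background in both numerator and denominator and contribute nothing.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// trans columns: 0 tMM, 1 tMI, 2 tMD, 3 tIM, 4 tII, 5 tDM, 6 tDD
// (log2, damped). logend[i] = log2 p_end(i+1). seq: 0-based residue indices,
// -1 = ambiguous (background emission, log-odds 0).

// Scaled-probability forward: values are odds relative to the background,
// rescaled once per sequence position so no cell needs a transcendental.
// oem: 2^lem (odds emissions); otrans: linear damped transition
// probabilities (same column layout); pend: linear exit probabilities.
// [[Rcpp::export]]
double cpp_forward(const NumericMatrix& oem, const IntegerVector& seq,
                   const NumericMatrix& otrans, const NumericVector& pend) {
  const int n = oem.nrow(), T = seq.size();
  if (T == 0) return NEG_INF;
  const double begin_true = 1.0 / ((double)n * (double)T);
  std::vector<double> Mprev(n, 0.0), Iprev(n, 0.0), Dprev(n, 0.0),
      Mcur(n), Icur(n), Dcur(n);
  const double* tMM = &otrans(0, 0);
  const double* tMI = &otrans(0, 1);
  const double* tMD = &otrans(0, 2);
  const double* tIM = &otrans(0, 3);
  const double* tII = &otrans(0, 4);
  const double* tDM = &otrans(0, 5);
  const double* tDD = &otrans(0, 6);
  double C = 0.0;        // cumulative log2 scale
  double acc = 0.0;      // ended-path mass, scaled by 2^C
  double bscaled = begin_true;
  for (int j = 0; j < T; ++j) {
    const int a = seq[j];
    const double* em = (a >= 0) ? &oem(0, a) : nullptr;
    double ended = 0.0, vmax = 0.0;
    {
      const double e0 = em ? em[0] : 1.0;
      Mcur[0] = e0 * bscaled;
      Dcur[0] = 0.0;
      Icur[0] = (j > 0) ? (Mprev[0] * tMI[0] + Iprev[0] * tII[0]) : 0.0;
      ended = Mcur[0] * pend[0];
      vmax = Mcur[0] > Icur[0] ? Mcur[0] : Icur[0];
    }
    for (int i = 1; i < n; ++i) {
      const double e = em ? em[i] : 1.0;
      double s = bscaled;
      if (j > 0) {
        s += Mprev[i - 1] * tMM[i - 1] + Iprev[i - 1] * tIM[i - 1] +
             Dprev[i - 1] * tDM[i - 1];
      }
      const double m = e * s;
      const double d = Mcur[i - 1] * tMD[i - 1] + Dcur[i - 1] * tDD[i - 1];
      const double ins = (j > 0) ? (Mprev[i] * tMI[i] + Iprev[i] * tII[i])
                                 : 0.0;
      Mcur[i] = m; Dcur[i] = d; Icur[i] = ins;
      ended += m * pend[i];
      double v = m > ins ? m : ins;
      if (d > v) v = d;
      if (v > vmax) vmax = v;
    }
    acc += ended;
    // rescale lazily: magnitudes drift slowly, so most positions skip this
    double big = vmax > acc ? vmax : acc;
    if (big > 1e100 || (big > 0 && big < 1e-100)) {
      const double inv = 1.0 / big;
      for (int i = 0; i < n; ++i) {
        Mcur[i] *= inv; Icur[i] *= inv; Dcur[i] *= inv;
      }
      acc *= inv;
      C += std::log2(big);
      bscaled = std::exp2(std::log2(begin_true) - C);
      if (!std::isfinite(bscaled)) bscaled = 0.0;
    }
    Mprev.swap(Mcur);
    Iprev.swap(Icur);
    Dprev.swap(Dcur);
  }
  if (acc <= 0) return NEG_INF;
  return std::log2(acc) + C;
}

// Batched forward over a list of pre-encoded sequences.
// [[Rcpp::export]]
NumericVector cpp_forward_batch(const NumericMatrix& oem, const List& seqs,
                                const NumericMatrix& otrans,
                                const NumericVector& pend) {
  const int m = seqs.size();
  NumericVector out(m);
  for (int k = 0; k < m; ++k) {
    out[k] = cpp_forward(oem, seqs[k], otrans, pend);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_viterbi(const NumericMatrix& lem, const IntegerVector& seq,
                 const NumericMatrix& trans, const NumericVector& logend) {
  const int n = lem.nrow(), T = seq.size();
  if (T == 0)
    return List::create(_["score"] = NEG_INF,
                        _["qstart"] = 0, _["qend"] = 0,
                        _["tstart"] = 0, _["tend"] = 0,
                        _["trace"] = IntegerMatrix(0, 2));
  const double logbegin = -std::log2((double)n) - std::log2((double)T);
  // DP matrices with backpointers: 0 begin, 1 from M, 2 from I, 3 from D
  NumericMatrix M(n, T), I(n, T), D(n, T);
  IntegerMatrix bM(n, T), bI(n, T), bD(n, T);
  double best = NEG_INF;
  int bi = -1, bj = -1;
  for (int j = 0; j < T; ++j) {
    const int a = seq[j];
    for (int i = 0; i < n; ++i) {
      const double em = (a >= 0) ? lem(i, a) : 0.0;
      double s = logbegin;
      int bp = 0;
      if (i > 0 && j > 0) {
        double vm = M(i - 1, j - 1) + trans(i - 1, 0);
        double vi = I(i - 1, j - 1) + trans(i - 1, 3);
        double vd = D(i - 1, j - 1) + trans(i - 1, 5);
        if (vm > s) { s = vm; bp = 1; }
        if (vi > s) { s = vi; bp = 2; }
        if (vd > s) { s = vd; bp = 3; }
      }
      M(i, j) = em + s;
      bM(i, j) = bp;
      if (i > 0) {
        double vm = M(i - 1, j) + trans(i - 1, 2);
        double vd = D(i - 1, j) + trans(i - 1, 6);
        if (vm >= vd) { D(i, j) = vm; bD(i, j) = 1; }
        else          { D(i, j) = vd; bD(i, j) = 3; }
      } else {
        D(i, j) = NEG_INF; bD(i, j) = 0;
      }
      if (j > 0) {
        double vm = M(i, j - 1) + trans(i, 1);
        double vi = I(i, j - 1) + trans(i, 4);
        if (vm >= vi) { I(i, j) = vm; bI(i, j) = 1; }
        else          { I(i, j) = vi; bI(i, j) = 2; }
      } else {
        I(i, j) = NEG_INF; bI(i, j) = 0;
      }
      double endscore = M(i, j) + logend[i];
      if (endscore > best) { best = endscore; bi = i; bj = j; }
    }
  }
  // traceback from (bi, bj) in M
  std::vector<int> qs, ts;
  int state = 1, i = bi, j = bj;
  int qstart = bi, tstart = bj;
  while (true) {
    if (state == 1) {            // in M(i, j)
      qs.push_back(i + 1);
      ts.push_back(j + 1);
      qstart = i; tstart = j;
      int bp = bM(i, j);
      if (bp == 0) break;
      state = bp; --i; --j;
    } else if (state == 2) {     // in I(i, j)
      state = bI(i, j); --j;
    } else {                     // in D(i, j)
      state = bD(i, j); --i;
    }
  }
  const int npair = qs.size();
  IntegerMatrix trace(npair, 2);
  for (int k = 0; k < npair; ++k) {
    trace(k, 0) = qs[npair - 1 - k];
    trace(k, 1) = ts[npair - 1 - k];
  }
  return List::create(_["score"] = best,
                      _["qstart"] = qstart + 1, _["qend"] = bi + 1,
                      _["tstart"] = tstart + 1, _["tend"] = bj + 1,
                      _["trace"] = trace);
}

// Local profile-profile alignment over match-column pairs with affine gaps.
// S(i, j) = co-emission column score in bits; gap costs in bits (positive).
// [[Rcpp::export]]
List cpp_pp_align(const NumericMatrix& S, double gap_open, double gap_extend) {
  const int nq = S.nrow(), nt = S.ncol();
  NumericMatrix M(nq + 1, nt + 1), X(nq + 1, nt + 1), Y(nq + 1, nt + 1);
  IntegerMatrix bM(nq + 1, nt + 1);
  for (int i = 0; i <= nq; ++i) {
    M(i, 0) = 0; X(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
  }
  for (int j = 0; j <= nt; ++j) {
    M(0, j) = 0; X(0, j) = NEG_INF; Y(0, j) = NEG_INF;
  }
  double best = 0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= nq; ++i) {
    for (int j = 1; j <= nt; ++j) {
      // X: gap in target (consume query column), Y: gap in query
      double xo = M(i - 1, j) - gap_open, xe = X(i - 1, j) - gap_extend;
      X(i, j) = xo > xe ? xo : xe;
      double yo = M(i, j - 1) - gap_open, ye = Y(i, j - 1) - gap_extend;
      Y(i, j) = yo > ye ? yo : ye;
      double vm = M(i - 1, j - 1), vx = X(i - 1, j - 1), vy = Y(i - 1, j - 1);
      double pre = 0; int bp = 0;                   // 0 = local restart
      if (vm > pre) { pre = vm; bp = 1; }
      if (vx > pre) { pre = vx; bp = 2; }
      if (vy > pre) { pre = vy; bp = 3; }
      M(i, j) = pre + S(i - 1, j - 1);
      bM(i, j) = bp;
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }
  // traceback of paired columns (match-match steps only)
  std::vector<int> qcols, tcols;
  int i = bi, j = bj, state = 1;
  while (i > 0 && j > 0 && state != 0) {
    if (state == 1) {
      qcols.push_back(i);
      tcols.push_back(j);
      int bp = bM(i, j);
      --i; --j;
      if (bp == 0) break;
      state = bp;
    } else if (state == 2) {
      // inside X at (i, j): came from M or X at (i-1, j)
      double xo = M(i - 1, j) - gap_open, xe = X(i - 1, j) - gap_extend;
      state = (xo >= xe) ? 1 : 2;
      --i;
    } else {
      double yo = M(i, j - 1) - gap_open, ye = Y(i, j - 1) - gap_extend;
      state = (yo >= ye) ? 1 : 3;
      --j;
    }
  }
  const int npair = qcols.size();
  IntegerMatrix pairs(npair, 2);
  for (int k = 0; k < npair; ++k) {
    pairs(k, 0) = qcols[npair - 1 - k];
    pairs(k, 1) = tcols[npair - 1 - k];
  }
  return List::create(_["score"] = best,
                      _["qstart"] = npair ? pairs(0, 0) : 0,
                      _["qend"] = bi, _["tstart"] = npair ? pairs(0, 1) : 0,
                      _["tend"] = bj, _["pairs"] = pairs);
}
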