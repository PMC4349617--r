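// Compiled inner loop for the selection fitness: binary C-SVC with RBF
// kernel solved by SMO (maximal-violating-pair working set, libsvm-style
// stopping rule), leave-one-out cross-validation, the 16x16 gamma/C code
// grid, and the Kaplan-Meier area-between-curves statistic. The GA
// evaluates this fitness tens of thousands of times per run, which rules
// out per-fold round trips through R.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double TAU = 1e-12;
static const double SMO_EPS = 1e-3;
static const int MAX_ITER = 100000;

// RBF kernel matrix between rows of A and rows of B.
static void rbf_kernel(const NumericMatrix &A, const NumericMatrix &B,
                       double gamma, std::vector<double> &K) {
  int na = A.nrow(), nb = B.nrow(), d = A.ncol();
  K.assign((size_t)na * nb, 0.0);
  for (int i = 0; i < na; ++i) {
    for (int j = 0; j < nb; ++j) {
      double s = 0.0;
      for (int k = 0; k < d; ++k) {
        double diff = A(i, k) - B(j, k);
        s += diff * diff;
      }
      K[(size_t)i * nb + j] = std::exp(-gamma * s);
    }
  }
}

// SMO for min 1/2 a'Qa - e'a, 0 <= a <= C, y'a = 0 with Q_ij = y_i y_j K_ij.
// K is the full kernel over `all` samples; `idx` lists the active training
// rows. Second-order working-set selection (the libsvm rule: maximal
// violator paired with the largest gain partner). `alpha` may carry a
// feasible warm start (same length as idx); it is used as the starting
// point when `warm` is true. Returns alpha (aligned with idx) and rho.
static void smo_solve(const std::vector<double> &K, int ldk,
                      const std::vector<int> &idx,
                      const std::vector<int> &y, /* +1/-1, full length */
                      double C, std::vector<double> &alpha, double &rho,
                      bool warm = false) {
  int n = (int)idx.size();
  if (!warm) alpha.assign(n, 0.0);
  std::vector<int> ys(n);
  for (int i = 0; i < n; ++i) ys[i] = y[idx[i]];
  std::vector<double> QD(n);
  for (int i = 0; i < n; ++i) QD[i] = K[(size_t)idx[i] * ldk + idx[i]];

  auto Kij = [&](int i, int j) -> double {
    return K[(size_t)idx[i] * ldk + idx[j]];
  };

  std::vector<double> G(n, -1.0);
  if (warm) {
    for (int t = 0; t < n; ++t) {
      double s = 0.0;
      for (int u = 0; u < n; ++u)
        if (alpha[u] > 0) s += alpha[u] * ys[u] * Kij(u, t);
      G[t] = ys[t] * s - 1.0;
    }
  }

  for (int iter = 0; iter < MAX_ITER; ++iter) {
    // i: maximal violator among I_up
    double gmax = -HUGE_VAL, gmin = HUGE_VAL;
    int i = -1;
    for (int t = 0; t < n; ++t) {
      double v = -ys[t] * G[t];
      bool in_up = (ys[t] == 1 && alpha[t] < C) || (ys[t] == -1 && alpha[t] > 0);
      bool in_low = (ys[t] == 1 && alpha[t] > 0) || (ys[t] == -1 && alpha[t] < C);
      if (in_up && v > gmax) { gmax = v; i = t; }
      if (in_low && v < gmin) gmin = v;
    }
    if (i < 0 || gmax - gmin < SMO_EPS) break;
    // j: best second-order gain among violating I_low partners
    int j = -1;
    double best_gain = -HUGE_VAL;
    for (int t = 0; t < n; ++t) {
      bool in_low = (ys[t] == 1 && alpha[t] > 0) || (ys[t] == -1 && alpha[t] < C);
      if (!in_low) continue;
      double b = gmax + ys[t] * G[t];
      if (b <= 0) continue;
      double a = QD[i] + QD[t] - 2.0 * Kij(i, t);
      if (a <= 0) a = TAU;
      double gain = b * b / a;
      if (gain > best_gain) { best_gain = gain; j = t; }
    }
    if (j < 0) break;

    double Kii = QD[i], Kjj = QD[j], Kij_ = Kij(i, j);
    double old_ai = alpha[i], old_aj = alpha[j];
    // in plain-kernel terms the two-variable quadratic coefficient is
    // K_ii + K_jj - 2 K_ij for either sign pattern
    if (ys[i] != ys[j]) {
      double quad = Kii + Kjj - 2.0 * Kij_;
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = alpha[i] - alpha[j];
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij_;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = alpha[i] + alpha[j];
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }

    double dai = alpha[i] - old_ai, daj = alpha[j] - old_aj;
    if (dai == 0.0 && daj == 0.0) break;
    for (int t = 0; t < n; ++t) {
      G[t] += ys[t] * ys[i] * Kij(i, t) * dai + ys[t] * ys[j] * Kij(j, t) * daj;
    }
  }

  // rho per the KKT conditions (free SVs average, else interval midpoint)
  double ub = HUGE_VAL, lb = -HUGE_VAL, sum_free = 0.0;
  int nr_free = 0;
  for (int t = 0; t < n; ++t) {
    double yG = ys[t] * G[t];
    if (alpha[t] >= C) {
      if (ys[t] == -1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else if (alpha[t] <= 0) {
      if (ys[t] == 1) ub = std::min(ub, yG); else lb = std::max(lb, yG);
    } else { ++nr_free; sum_free += yG; }
  }
  rho = nr_free > 0 ? sum_free / nr_free : (ub + lb) / 2.0;
}

// decision value for sample `t` (row index into K's second dimension)
static double decide(const std::vector<double> &K, int ldk,
                     const std::vector<int> &idx, const std::vector<int> &y,
                     const std::vector<double> &alpha, double rho, int t) {
  double f = 0.0;
  for (size_t s = 0; s < idx.size(); ++s)
    if (alpha[s] > 0)
      f += alpha[s] * y[idx[s]] * K[(size_t)idx[s] * ldk + t];
  return f - rho;
}

static int majority(const std::vector<int> &y, const std::vector<int> &idx) {
  int pos = 0;
  for (int t : idx) if (y[t] == 1) ++pos;
  int neg = (int)idx.size() - pos;
  return pos >= neg ? 1 : 0; // tie toward class 1
}

// LOOCV predictions. One solve on the full data seeds every fold: a
// held-out sample with alpha = 0 leaves the remaining KKT system optimal,
// so its fold needs no refit; support-vector folds warm-start from the
// full solution with the equality constraint repaired on same-class
// variables.
static void loocv_core(const std::vector<double> &K, int n,
                       const std::vector<int> &y, double C,
                       std::vector<int> &pred) {
  pred.assign(n, 0);
  bool pos = false, neg = false;
  for (int t = 0; t < n; ++t) { if (y[t] == 1) pos = true; else neg = true; }
  std::vector<int> all(n);
  for (int t = 0; t < n; ++t) all[t] = t;
  std::vector<double> alpha_full;
  double rho_full;
  if (pos && neg) smo_solve(K, n, all, y, C, alpha_full, rho_full);

  std::vector<int> idx(n - 1);
  std::vector<double> alpha(n - 1);
  double rho;
  for (int held = 0; held < n; ++held) {
    int p = 0;
    bool fpos = false, fneg = false;
    for (int t = 0; t < n; ++t) {
      if (t == held) continue;
      idx[p++] = t;
      if (y[t] == 1) fpos = true; else fneg = true;
    }
    if (!fpos || !fneg) { // one-class fold: majority (= only) class
      pred[held] = majority(y, idx);
      continue;
    }
    if (alpha_full[held] <= 0) {
      // not a support vector: the full model restricted to the fold is
      // already the fold's optimum
      pred[held] = decide(K, n, all, y, alpha_full, rho_full, held) >= 0
                     ? 1 : 0;
      continue;
    }
    // warm start: drop the held-out alpha and restore y'alpha = 0 by
    // raising same-class variables toward C
    double deficit = alpha_full[held];
    for (int t = 0; t < n - 1; ++t) alpha[t] = alpha_full[idx[t]];
    for (int t = 0; t < n - 1 && deficit > 0; ++t) {
      if (y[idx[t]] != y[held]) continue;
      double room = C - alpha[t];
      double add = room < deficit ? room : deficit;
      alpha[t] += add;
      deficit -= add;
    }
    if (deficit > 1e-12) { // same-class capacity exhausted: cold start
      std::fill(alpha.begin(), alpha.end(), 0.0);
    }
    smo_solve(K, n, idx, y, C, alpha, rho, true);
    pred[held] = decide(K, n, idx, y, alpha, rho, held) >= 0 ? 1 : 0;
  }
}

static std::vector<int> to_pm1(const IntegerVector &y01) {
  std::vector<int> y(y01.size());
  for (int i = 0; i < y01.size(); ++i) y[i] = y01[i] == 1 ? 1 : -1;
  return y;
}

// [[Rcpp::export(name = ".svc_loocv_cpp")]]
IntegerVector svc_loocv_cpp(NumericMatrix X, IntegerVector y01,
                            double gamma, double C) {
  int n = X.nrow();
  std::vector<int> y = to_pm1(y01);
  std::vector<double> K;
  rbf_kernel(X, X, gamma, K);
  std::vector<int> pred;
  loocv_core(K, n, y, C, pred);
  return IntegerVector(pred.begin(), pred.end());
}

// [[Rcpp::export(name = ".svc_train_predict_cpp")]]
IntegerVector svc_train_predict_cpp(NumericMatrix Xtr, IntegerVector y01,
                                    double gamma, double C,
                                    NumericMatrix Xte) {
  int n = Xtr.nrow(), m = Xte.nrow();
  std::vector<int> y = to_pm1(y01);
  bool pos = false, neg = false;
  for (int v : y) { if (v == 1) pos = true; else neg = true; }
  IntegerVector out(m);
  if (!pos || !neg) {
    int lab = pos ? 1 : 0;
    std::fill(out.begin(), out.end(), lab);
    return out;
  }
  std::vector<double> Ktr, Kte;
  rbf_kernel(Xtr, Xtr, gamma, Ktr);
  rbf_kernel(Xtr, Xte, gamma, Kte); // ld = m
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> alpha;
  double rho;
  smo_solve(Ktr, n, idx, y, C, alpha, rho);
  for (int j = 0; j < m; ++j) {
    double f = 0.0;
    for (int i = 0; i < n; ++i)
      if (alpha[i] > 0) f += alpha[i] * y[i] * Kte[(size_t)i * m + j];
    out[j] = (f - rho) >= 0 ? 1 : 0;
  }
  return out;
}

// Kaplan-Meier product-limit survival at the event times of one group,
// then exact step-function integral of S_a - S_b over [0, tmax] / tmax.
// group: 1 = curve a, 2 = curve b; events: 1 event, 0 censored.
struct StepCurve { std::vector<double> t, s; }; // S(0)=1 implicit

static StepCurve km_fit(const std::vector<double> &times,
                        const std::vector<int> &events) {
  int n = (int)times.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    return times[a] < times[b];
  });
  StepCurve c;
  double surv = 1.0;
  int at_risk = n, i = 0;
  while (i < n) {
    double t = times[ord[i]];
    int d = 0, nties = 0;
    while (i < n && times[ord[i]] == t) {
      if (events[ord[i]] == 1) ++d;
      ++nties; ++i;
    }
    if (d > 0) { // events before censorings at ties: both leave at t
      surv *= 1.0 - (double)d / at_risk;
      c.t.push_back(t);
      c.s.push_back(surv);
    }
    at_risk -= nties;
  }
  return c;
}

static double curve_at(const StepCurve &c, double t) {
  // right-continuous: S(t) = value after the last breakpoint <= t
  double s = 1.0;
  for (size_t i = 0; i < c.t.size() && c.t[i] <= t; ++i) s = c.s[i];
  return s;
}

static double area_between(const StepCurve &a, const StepCurve &b,
                           double tmax) {
  std::vector<double> brk;
  brk.push_back(0.0);
  for (double t : a.t) if (t < tmax) brk.push_back(t);
  for (double t : b.t) if (t < tmax) brk.push_back(t);
  brk.push_back(tmax);
  std::sort(brk.begin(), brk.end());
  brk.erase(std::unique(brk.begin(), brk.end()), brk.end());
  double area = 0.0;
  for (size_t i = 0; i + 1 < brk.size(); ++i) {
    double w = brk[i + 1] - brk[i];
    area += w * (curve_at(a, brk[i]) - curve_at(b, brk[i]));
  }
  return area / tmax;
}

// [[Rcpp::export(name = ".asurv_cpp")]]
double asurv_cpp(NumericVector times, IntegerVector events,
                 IntegerVector group, double tmax) {
  std::vector<double> ta, tb;
  std::vector<int> ea, eb;
  for (int i = 0; i < times.size(); ++i) {
    if (group[i] == 1) { ta.push_back(times[i]); ea.push_back(events[i]); }
    else if (group[i] == 2) { tb.push_back(times[i]); eb.push_back(events[i]); }
  }
  if (ta.empty() || tb.empty()) return 0.0;
  StepCurve a = km_fit(ta, ea), b = km_fit(tb, eb);
  return area_between(a, b, tmax);
}

// Fitness over the full 16x16 (gamma_code, c_code) grid: LOOCV accuracy,
// signed Asurv of the predicted groups (predicted class 0 = curve a), and
// f = w*acc + (1-w)*max(asurv, 0). Rows are gamma-major (kernel reuse);
// the caller applies the smallest-c-then-smallest-gamma tie-break.
// [[Rcpp::export(name = ".svc_grid_cpp")]]
NumericMatrix svc_grid_cpp(NumericMatrix X, IntegerVector y01,
                           NumericVector times, IntegerVector events,
                           double w, double tmax) {
  int n = X.nrow();
  std::vector<int> y = to_pm1(y01);
  NumericMatrix out(256, 5);
  colnames(out) = CharacterVector::create("gamma_code", "c_code", "acc",
                                          "asurv", "f");
  std::vector<double> K;
  std::vector<int> pred;
  std::vector<int> grp(n);
  int row = 0;
  for (int gcode = 0; gcode < 16; ++gcode) {
    double gamma = std::pow(2.0, gcode - 7);
    rbf_kernel(X, X, gamma, K);
    for (int ccode = 0; ccode < 16; ++ccode) {
      double C = std::pow(2.0, ccode - 7);
      loocv_core(K, n, y, C, pred);
      int correct = 0;
      for (int i = 0; i < n; ++i) {
        if (pred[i] == y01[i]) ++correct;
        grp[i] = pred[i] == 0 ? 1 : 2; // predicted non-distant = curve a
      }
      double acc = (double)correct / n;
      IntegerVector g(grp.begin(), grp.end());
      double as = asurv_cpp(times, events, g, tmax);
      double f = w * acc + (1.0 - w) * std::max(as, 0.0);
      out(row, 0) = gcode; out(row, 1) = ccode;
      out(row, 2) = acc; out(row, 3) = as; out(row, 4) = f;
      ++row;
    }
  }
  return out;
}
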