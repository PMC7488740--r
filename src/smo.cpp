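#include <Rcpp.h>
using namespace Rcpp;

// Sequential minimal optimization for the C-SVC dual on a precomputed
// kernel matrix. Working-pair selection is maximal-violating-pair with a
// second-order choice of the partner index; stopping rule and pair update
// follow the standard KKT-violation formulation.
//
// Dual: min 1/2 a' Q a - e' a,  0 <= a <= C,  y' a = 0,  Q_ij = y_i y_j K_ij.
// G_i = (Q a)_i - 1 is maintained incrementally.
// [[Rcpp::export]]
List smo_solve(NumericMatrix K, IntegerVector y, double C,
               double eps = 1e-3, int max_iter = 200000) {
  const int n = K.nrow();
  if (K.ncol() != n || y.size() != n) stop("kernel/label size mismatch");
  const double TAU = 1e-12;
  std::vector<double> alpha(n, 0.0), G(n, -1.0);

  int iter = 0;
  double m_up = 0.0, M_low = 0.0;
  for (iter = 0; iter < max_iter; ++iter) {
    // i: most violating index in I_up
    int i = -1;
    m_up = -std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool in_up = (y[t] == 1 && alpha[t] < C) || (y[t] == -1 && alpha[t] > 0);
      if (!in_up) continue;
      double v = -y[t] * G[t];
      if (v > m_up) { m_up = v; i = t; }
    }
    // M over I_low, and second-order choice of j
    M_low = std::numeric_limits<double>::infinity();
    int j = -1;
    double obj_min = std::numeric_limits<double>::infinity();
    for (int t = 0; t < n; ++t) {
      bool in_low = (y[t] == 1 && alpha[t] > 0) || (y[t] == -1 && alpha[t] < C);
      if (!in_low) continue;
      double v = -y[t] * G[t];
      if (v < M_low) M_low = v;
      if (i >= 0 && v < m_up) {
        double b = m_up - v;                       // violation of the pair
        double a = K(i, i) + K(t, t) - 2.0 * K(i, t);
        if (a <= 0) a = TAU;
        double obj = -(b * b) / a;
        if (obj < obj_min) { obj_min = obj; j = t; }
      }
    }
    if (i < 0 || j < 0 || m_up - M_low < eps) break;

    double Kii = K(i, i), Kjj = K(j, j), Kij = K(i, j);
    double ai_old = alpha[i], aj_old = alpha[j];
    if (y[i] != y[j]) {
      double quad = Kii + Kjj - 2.0 * Kij;  // Q_ii + Q_jj + 2 Q_ij, y_i y_j = -1
      if (quad <= 0) quad = TAU;
      double delta = (-G[i] - G[j]) / quad;
      double diff = ai_old - aj_old;
      alpha[i] += delta; alpha[j] += delta;
      if (diff > 0) { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = diff; } }
      else          { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = -diff; } }
      if (diff > 0) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = C - diff; } }
      else          { if (alpha[j] > C) { alpha[j] = C; alpha[i] = C + diff; } }
    } else {
      double quad = Kii + Kjj - 2.0 * Kij;
      if (quad <= 0) quad = TAU;
      double delta = (G[i] - G[j]) / quad;
      double sum = ai_old + aj_old;
      alpha[i] -= delta; alpha[j] += delta;
      if (sum > C) { if (alpha[i] > C) { alpha[i] = C; alpha[j] = sum - C; } }
      else         { if (alpha[j] < 0) { alpha[j] = 0; alpha[i] = sum; } }
      if (sum > C) { if (alpha[j] > C) { alpha[j] = C; alpha[i] = sum - C; } }
      else         { if (alpha[i] < 0) { alpha[i] = 0; alpha[j] = sum; } }
    }
    double dai = alpha[i] - ai_old, daj = alpha[j] - aj_old;
    if (dai == 0.0 && daj == 0.0) break;  // numerically stuck pair
    for (int t = 0; t < n; ++t)
      G[t] += y[t] * (y[i] * K(t, i) * dai + y[j] * K(t, j) * daj);
  }

  // bias: average over free support vectors, else midpoint of the KKT band
  double b_sum = 0.0; int b_n = 0;
  for (int t = 0; t < n; ++t)
    if (alpha[t] > 0 && alpha[t] < C) { b_sum += -y[t] * G[t]; ++b_n; }
  double b = b_n > 0 ? b_sum / b_n : 0.5 * (m_up + M_low);

  NumericVector coef(n);
  for (int t = 0; t < n; ++t) coef[t] = alpha[t] * y[t];
  return List::create(_["coef"] = coef, _["b"] = b, _["iterations"] = iter,
                      _["converged"] = (iter < max_iter));
}
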