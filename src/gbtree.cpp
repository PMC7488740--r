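#include <Rcpp.h>
using namespace Rcpp;

// Histogram-based gradient-boosted trees for binary logistic loss,
// deterministic (no row/column subsampling, single thread, fixed
// first-feature/first-bin tie-breaking). Used to derive per-dimension
// importance: "weight" (number of splits on the feature), "gain"
// (summed split gain) and "cover" (summed hessian of split nodes).

struct SplitInfo {
  double gain = 0.0;
  int feature = -1;
  int bin = -1;        // go left if code <= bin
};

static void grow_node(const std::vector<int> &idx,
                      const std::vector<std::vector<int>> &code,
                      const std::vector<double> &grad,
                      const std::vector<double> &hess,
                      int depth, int max_depth, int nbins,
                      double lambda, double min_child_weight, double eta,
                      std::vector<double> &margin,
                      std::vector<double> &imp_weight,
                      std::vector<double> &imp_gain,
                      std::vector<double> &imp_cover) {
  const int p = (int)code.size();
  double Gt = 0.0, Ht = 0.0;
  for (int r : idx) { Gt += grad[r]; Ht += hess[r]; }

  SplitInfo best;
  if (depth < max_depth && (int)idx.size() >= 2) {
    double parent_score = (Gt * Gt) / (Ht + lambda);
    std::vector<double> hg(nbins), hh(nbins);
    for (int f = 0; f < p; ++f) {
      std::fill(hg.begin(), hg.end(), 0.0);
      std::fill(hh.begin(), hh.end(), 0.0);
      const std::vector<int> &cf = code[f];
      for (int r : idx) { hg[cf[r]] += grad[r]; hh[cf[r]] += hess[r]; }
      double GL = 0.0, HL = 0.0;
      for (int b = 0; b < nbins - 1; ++b) {
        GL += hg[b]; HL += hh[b];
        double HR = Ht - HL;
        if (HL < min_child_weight || HR < min_child_weight) continue;
        double GR = Gt - GL;
        double gain = 0.5 * ((GL * GL) / (HL + lambda) +
                             (GR * GR) / (HR + lambda) - parent_score);
        if (gain > best.gain + 1e-12) { best.gain = gain; best.feature = f; best.bin = b; }
      }
    }
  }

  if (best.feature < 0) {  // leaf
    double w = -Gt / (Ht + lambda);
    for (int r : idx) margin[r] += eta * w;
    return;
  }

  imp_weight[best.feature] += 1.0;
  imp_gain[best.feature] += best.gain;
  imp_cover[best.feature] += Ht;

  std::vector<int> left, right;
  const std::vector<int> &cf = code[best.feature];
  for (int r : idx) (cf[r] <= best.bin ? left : right).push_back(r);
  grow_node(left, code, grad, hess, depth + 1, max_depth, nbins, lambda,
            min_child_weight, eta, margin, imp_weight, imp_gain, imp_cover);
  grow_node(right, code, grad, hess, depth + 1, max_depth, nbins, lambda,
            min_child_weight, eta, margin, imp_weight, imp_gain, imp_cover);
}

// [[Rcpp::export]]
List gbtree_train(NumericMatrix X, NumericVector y, int nrounds = 100,
                  int max_depth = 6, double eta = 0.3, double lambda = 1.0,
                  double min_child_weight = 1.0, int nbins = 256) {
  const int n = X.nrow(), p = X.ncol();
  if (y.size() != n) stop("label length mismatch");

  // quantile pre-binning, per feature; deterministic given the data
  std::vector<std::vector<int>> code(p, std::vector<int>(n));
  for (int f = 0; f < p; ++f) {
    std::vector<double> v(n);
    for (int r = 0; r < n; ++r) v[r] = X(r, f);
    std::vector<double> s(v);
    std::sort(s.begin(), s.end());
    s.erase(std::unique(s.begin(), s.end()), s.end());
    std::vector<double> cuts;  // inclusive upper edges; code = #edges < value
    int nu = (int)s.size();
    if (nu > nbins) {
      for (int b = 1; b < nbins; ++b)
        cuts.push_back(s[(size_t)((double)b * nu / nbins) - 1]);
      cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
    } else if (nu > 1) {
      cuts.assign(s.begin(), s.end() - 1);
    }
    for (int r = 0; r < n; ++r)
      code[f][r] = (int)(std::lower_bound(cuts.begin(), cuts.end(), v[r]) -
                         cuts.begin());
  }

  std::vector<double> margin(n, 0.0), grad(n), hess(n);
  std::vector<double> imp_weight(p, 0.0), imp_gain(p, 0.0), imp_cover(p, 0.0);
  std::vector<int> all(n);
  for (int r = 0; r < n; ++r) all[r] = r;

  for (int round = 0; round < nrounds; ++round) {
    for (int r = 0; r < n; ++r) {
      double pr = 1.0 / (1.0 + std::exp(-margin[r]));
      grad[r] = pr - y[r];
      hess[r] = std::max(pr * (1.0 - pr), 1e-16);
    }
    grow_node(all, code, grad, hess, 0, max_depth, nbins, lambda,
              min_child_weight, eta, margin, imp_weight, imp_gain, imp_cover);
  }

  NumericVector fitted(n);
  for (int r = 0; r < n; ++r) fitted[r] = 1.0 / (1.0 + std::exp(-margin[r]));
  return List::create(_["weight"] = NumericVector(imp_weight.begin(), imp_weight.end()),
                      _["gain"] = NumericVector(imp_gain.begin(), imp_gain.end()),
                      _["cover"] = NumericVector(imp_cover.begin(), imp_cover.end()),
                      _["fitted"] = fitted);
}
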