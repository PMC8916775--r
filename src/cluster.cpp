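#include <Rcpp.h>
using namespace Rcpp;

// 4-connected components of supra-threshold pixels (|stat| > thresh) on a
// matrix lattice; mass = sum of |stat| over a cluster. Iterative flood fill.

static void flood(const NumericMatrix &stat, double thresh,
                  IntegerMatrix &labels, int r0, int c0, int lab,
                  double &mass, std::vector<int> &stack) {
  int nr = stat.nrow(), nc = stat.ncol();
  stack.clear();
  stack.push_back(r0 + c0 * nr);
  labels(r0, c0) = lab;
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int r = idx % nr, c = idx / nr;
    mass += std::abs(stat(r, c));
    const int dr[4] = {-1, 1, 0, 0};
    const int dc[4] = {0, 0, -1, 1};
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (labels(rr, cc) == 0 && std::abs(stat(rr, cc)) > thresh) {
        labels(rr, cc) = lab;
        stack.push_back(rr + cc * nr);
      }
    }
  }
}

// [[Rcpp::export]]
List cluster_components_cpp(NumericMatrix stat, double thresh) {
  int nr = stat.nrow(), nc = stat.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<double> masses;
  std::vector<int> stack;
  int lab = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (labels(r, c) == 0 && std::abs(stat(r, c)) > thresh) {
        double mass = 0.0;
        flood(stat, thresh, labels, r, c, ++lab, mass, stack);
        masses.push_back(mass);
      }
    }
  }
  return List::create(_["labels"] = labels,
                      _["masses"] = NumericVector(masses.begin(), masses.end()));
}

// Max cluster mass for each row of `stats` (one permutation per row),
// where each row is a flattened nr x nc map (column-major).
// [[Rcpp::export]]
NumericVector max_cluster_mass_batch_cpp(NumericMatrix stats, int nr, int nc,
                                         double thresh) {
  int nperm = stats.nrow();
  if (stats.ncol() != nr * nc) stop("map size mismatch");
  NumericVector out(nperm);
  NumericMatrix map(nr, nc);
  for (int p = 0; p < nperm; ++p) {
    for (int j = 0; j < nr * nc; ++j) map[j] = stats(p, j);
    List comp = cluster_components_cpp(map, thresh);
    NumericVector masses = comp["masses"];
    double mx = 0.0;
    for (int k = 0; k < masses.size(); ++k)
      if (masses[k] > mx) mx = masses[k];
    out[p] = mx;
  }
  return out;
}
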