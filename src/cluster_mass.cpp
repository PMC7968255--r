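#include <Rcpp.h>
using namespace Rcpp;

// Maximum absolute sign-consistent cluster mass of a thresholded statistic
// map. Cells with |t| > thr are clustered within each sign via the neighbor
// lists (1-based indices); the returned value is max over clusters of
// |sum(t)|. This is the inner kernel of the permutation null loop.
// [[Rcpp::export(name = ".max_cluster_mass_cpp")]]
double max_cluster_mass_cpp(NumericVector tmap, double thr, List neighbors) {
  int n = tmap.size();
  std::vector<char> visited(n, 0);
  std::vector<int> stack;
  stack.reserve(256);
  double mx = 0.0;
  for (int start = 0; start < n; ++start) {
    double tv = tmap[start];
    if (visited[start] || (tv <= thr && tv >= -thr)) continue;
    bool pos = tv > 0;
    double mass = 0.0;
    stack.clear();
    stack.push_back(start);
    visited[start] = 1;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      mass += tmap[c];
      IntegerVector nb = neighbors[c];
      for (int j = 0; j < nb.size(); ++j) {
        int v = nb[j] - 1;
        if (visited[v]) continue;
        double tw = tmap[v];
        if (pos ? (tw > thr) : (tw < -thr)) {
          visited[v] = 1;
          stack.push_back(v);
        }
      }
    }
    if (std::fabs(mass) > mx) mx = std::fabs(mass);
  }
  return mx;
}
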