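#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

//' 6-neighbour connected-component labelling of a 3D logical mask
//'
//' @param mask logical vector of length nx*ny*nz in column-major order.
//' @param nx,ny,nz grid dimensions.
//' @return integer labels (0 = background), same layout as the mask.
//' @export
// [[Rcpp::export]]
IntegerVector label_clusters6(LogicalVector mask, int nx, int ny, int nz) {
  const int n = nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match grid dimensions");
  IntegerVector labels(n, 0);
  int next_label = 0;
  std::vector<int> queue;
  queue.reserve(256);
  for (int start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    labels[start] = next_label;
    queue.clear();
    queue.push_back(start);
    while (!queue.empty()) {
      int v = queue.back();
      queue.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      const int dx[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dz[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
          continue;
        int w = xx + nx * (yy + ny * zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = next_label;
          queue.push_back(w);
        }
      }
    }
  }
  return labels;
}

//' Maximum cluster statistic of a thresholded statistic map
//'
//' Extent (voxel count) or mass (summed statistic) of the largest
//' above-threshold 6-connected cluster; the quantity tracked per
//' permutation in the FWE max-statistic scheme.
//'
//' @param stat statistic map, length nx*ny*nz, column-major.
//' @param threshold cluster-forming threshold (strictly above).
//' @param nx,ny,nz grid dimensions.
//' @param mass use cluster mass instead of extent.
//' @return the maximum cluster statistic (0 when nothing survives).
//' @export
// [[Rcpp::export]]
double max_cluster_stat(NumericVector stat, double threshold,
                        int nx, int ny, int nz, bool mass) {
  const int n = nx * ny * nz;
  if (stat.size() != n) stop("map length does not match grid dimensions");
  LogicalVector mask(n);
  for (int i = 0; i < n; ++i) mask[i] = stat[i] > threshold;
  IntegerVector labels = label_clusters6(mask, nx, ny, nz);
  int n_lab = 0;
  for (int i = 0; i < n; ++i) if (labels[i] > n_lab) n_lab = labels[i];
  if (n_lab == 0) return 0.0;
  std::vector<double> acc(n_lab, 0.0);
  for (int i = 0; i < n; ++i) {
    if (labels[i] > 0) acc[labels[i] - 1] += mass ? stat[i] : 1.0;
  }
  double best = 0.0;
  for (int k = 0; k < n_lab; ++k) if (acc[k] > best) best = acc[k];
  return best;
}
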