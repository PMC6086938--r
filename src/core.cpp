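#include <Rcpp.h>
#include <queue>
#include <map>
#include <vector>
using namespace Rcpp;

// Voxel grids arrive as flat vectors in R array order (x fastest), dims = (nx, ny, nz).

struct QItem {
  double value;
  long long order; // insertion counter: earlier pushes flood first on ties
  int idx;
  int label;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.value != b.value) return a.value > b.value; // min-heap on value
    return a.order > b.order;
  }
};

static inline void neighbors6(int idx, int nx, int ny, int nz, int* out, int* nn) {
  int x = idx % nx, y = (idx / nx) % ny, z = idx / (nx * ny);
  *nn = 0;
  if (x > 0)      out[(*nn)++] = idx - 1;
  if (x < nx - 1) out[(*nn)++] = idx + 1;
  if (y > 0)      out[(*nn)++] = idx - nx;
  if (y < ny - 1) out[(*nn)++] = idx + nx;
  if (z > 0)      out[(*nn)++] = idx - nx * ny;
  if (z < nz - 1) out[(*nn)++] = idx + nx * ny;
}

// Seeded watershed by priority flooding on `relief` (ascending), restricted to
// `foreground`. Seeds are nonzero labels in `seeds`. Ties broken by insertion
// order, which is itself deterministic (seeds scanned in x,y,z-ascending order).
// [[Rcpp::export]]
IntegerVector cx_watershed(NumericVector relief, IntegerVector seeds,
                           LogicalVector foreground, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = relief.size();
  if (seeds.size() != n || foreground.size() != n)
    stop("relief, seeds and foreground must have identical length");
  IntegerVector labels(n, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long counter = 0;
  int nb[6]; int nn;
  for (int i = 0; i < n; ++i) labels[i] = seeds[i];
  for (int i = 0; i < n; ++i) {
    if (seeds[i] > 0) {
      neighbors6(i, nx, ny, nz, nb, &nn);
      for (int k = 0; k < nn; ++k) {
        int j = nb[k];
        if (labels[j] == 0 && foreground[j])
          pq.push(QItem{relief[j], counter++, j, seeds[i]});
      }
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    if (labels[it.idx] != 0) continue;
    labels[it.idx] = it.label;
    neighbors6(it.idx, nx, ny, nz, nb, &nn);
    for (int k = 0; k < nn; ++k) {
      int j = nb[k];
      if (labels[j] == 0 && foreground[j])
        pq.push(QItem{relief[j], counter++, j, it.label});
    }
  }
  labels.attr("dim") = dims;
  return labels;
}

// Voxel-face adjacency census of a labeled volume (6-connectivity).
// Returns shared-face counts b_ij for every touching label pair and, per label,
// the total boundary face count B_j (faces to background, to other labels and
// to the volume edge all count as boundary).
// [[Rcpp::export]]
List cx_contact_faces(IntegerVector labels, IntegerVector dims, int n_labels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::map<std::pair<int,int>, double> shared;
  std::vector<double> B(n_labels + 1, 0.0);
  const int strides[3] = {1, nx, nx * ny};
  const int lim[3] = {nx, ny, nz};
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    int idx = x + nx * (y + (long long)ny * z);
    int li = labels[idx];
    int pos[3] = {x, y, z};
    for (int ax = 0; ax < 3; ++ax) {
      // +axis face
      if (pos[ax] == lim[ax] - 1) { if (li > 0) B[li] += 1; }
      else {
        int lj = labels[idx + strides[ax]];
        if (li != lj) {
          if (li > 0) B[li] += 1;
          if (lj > 0) B[lj] += 1;
          if (li > 0 && lj > 0) {
            std::pair<int,int> key(std::min(li, lj), std::max(li, lj));
            shared[key] += 1;
          }
        }
      }
      // -axis face on the volume edge (interior -axis faces are the +axis
      // faces of the previous voxel and already counted)
      if (pos[ax] == 0 && li > 0) B[li] += 1;
    }
  }
  int m = shared.size();
  IntegerVector ii(m), jj(m); NumericVector bb(m);
  int k = 0;
  for (auto& kv : shared) { ii[k] = kv.first.first; jj[k] = kv.first.second; bb[k] = kv.second; ++k; }
  NumericVector Bout(n_labels);
  for (int l = 1; l <= n_labels; ++l) Bout[l - 1] = B[l];
  return List::create(_["i"] = ii, _["j"] = jj, _["faces"] = bb, _["boundary"] = Bout);
}

// Local maxima under 26-connectivity: voxel value >= every neighbor and above
// threshold. Plateau voxels all qualify; the caller thins them by distance.
// [[Rcpp::export]]
LogicalVector cx_local_maxima(NumericVector img, IntegerVector dims, double threshold) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(img.size(), false);
  for (int z = 0; z < nz; ++z) for (int y = 0; y < ny; ++y) for (int x = 0; x < nx; ++x) {
    long long idx = x + nx * (y + (long long)ny * z);
    double v = img[idx];
    if (v <= threshold) continue;
    bool ismax = true;
    for (int dz = -1; dz <= 1 && ismax; ++dz) for (int dy = -1; dy <= 1 && ismax; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int X = x + dx, Y = y + dy, Z = z + dz;
        if (X < 0 || X >= nx || Y < 0 || Y >= ny || Z < 0 || Z >= nz) continue;
        if (img[X + nx * (Y + (long long)ny * Z)] > v) { ismax = false; break; }
      }
    if (ismax) out[idx] = true;
  }
  out.attr("dim") = dims;
  return out;
}
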