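// Geometry kernels for the canopy-counting pipeline: exact k-nearest-neighbour
// search (static kd-tree), PCA surface normals with curvature, curvature-seeded
// region growing, and 8-connected component labelling for the raster detector.
#include <RcppArmadillo.h>
#include <queue>
#include <algorithm>
#include <functional>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// ---- static 3-d kd-tree ---------------------------------------------------

struct KDNode {
  int point;      // index into the coordinate matrix
  int axis;       // split dimension 0..2
  int left, right;
};

class KDTree {
public:
  KDTree(const NumericMatrix& X) : X_(X) {
    int n = X.nrow();
    nodes_.reserve(n);
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    root_ = build(idx.begin(), idx.end(), 0);
  }

  // k nearest neighbours of the query point (excluding `self` if >= 0)
  void knn(const double* q, int k, int self,
           std::vector<int>& out_idx, std::vector<double>& out_d2) const {
    heap_ = std::priority_queue<std::pair<double, int> >();
    k_ = k; self_ = self;
    search(root_, q);
    int m = (int)heap_.size();
    out_idx.resize(m); out_d2.resize(m);
    for (int i = m - 1; i >= 0; --i) {
      out_d2[i]  = heap_.top().first;
      out_idx[i] = heap_.top().second;
      heap_.pop();
    }
  }

private:
  const NumericMatrix& X_;
  std::vector<KDNode> nodes_;
  int root_;
  mutable std::priority_queue<std::pair<double, int> > heap_;
  mutable int k_, self_;

  int build(std::vector<int>::iterator lo, std::vector<int>::iterator hi,
            int depth) {
    if (lo >= hi) return -1;
    int axis = depth % 3;
    std::vector<int>::iterator mid = lo + (hi - lo) / 2;
    const NumericMatrix& X = X_;
    std::nth_element(lo, mid, hi, [&X, axis](int a, int b) {
      return X(a, axis) < X(b, axis);
    });
    KDNode nd;
    nd.point = *mid;
    nd.axis = axis;
    int me = (int)nodes_.size();
    nodes_.push_back(nd);
    nodes_[me].left  = build(lo, mid, depth + 1);
    nodes_[me].right = build(mid + 1, hi, depth + 1);
    return me;
  }

  void consider(int p, const double* q) const {
    if (p == self_) return;
    double d2 = 0.0;
    for (int a = 0; a < 3; ++a) {
      double d = X_(p, a) - q[a];
      d2 += d * d;
    }
    if ((int)heap_.size() < k_) {
      heap_.push(std::make_pair(d2, p));
    } else if (d2 < heap_.top().first) {
      heap_.pop();
      heap_.push(std::make_pair(d2, p));
    }
  }

  void search(int node, const double* q) const {
    if (node < 0) return;
    const KDNode& nd = nodes_[node];
    consider(nd.point, q);
    double diff = q[nd.axis] - X_(nd.point, nd.axis);
    int near = diff <= 0 ? nd.left : nd.right;
    int far  = diff <= 0 ? nd.right : nd.left;
    search(near, q);
    if ((int)heap_.size() < k_ || diff * diff < heap_.top().first)
      search(far, q);
  }
};

} // namespace

// k nearest neighbours for every point of X (self excluded).
// Returns 1-based index matrix (n x k) and Euclidean distances (n x k).
// [[Rcpp::export(name = ".cc_knn")]]
List cc_knn(NumericMatrix X, int k) {
  int n = X.nrow();
  if (k < 1) stop("k must be >= 1");
  if (k > n - 1) stop("k (%d) exceeds the number of other points (%d)", k, n - 1);
  KDTree tree(X);
  IntegerMatrix idx(n, k);
  NumericMatrix dist(n, k);
  std::vector<int> nb; std::vector<double> d2;
  double q[3];
  for (int i = 0; i < n; ++i) {
    q[0] = X(i, 0); q[1] = X(i, 1); q[2] = X(i, 2);
    tree.knn(q, k, i, nb, d2);
    for (int j = 0; j < k; ++j) {
      idx(i, j)  = nb[j] + 1;
      dist(i, j) = std::sqrt(d2[j]);
    }
  }
  return List::create(_["idx"] = idx, _["dist"] = dist);
}

// PCA normal + surface variation per point from its k-NN neighbourhood
// (point itself included in the covariance). Normal = eigenvector of the
// smallest eigenvalue, flipped so nz >= 0; for exactly vertical surfaces
// (nz == 0) the sign is fixed by ny > 0, then nx > 0.
// curvature = lambda_0 / (lambda_0 + lambda_1 + lambda_2), lambda_0 smallest.
// [[Rcpp::export(name = ".cc_normals")]]
NumericMatrix cc_normals(NumericMatrix X, IntegerMatrix idx) {
  int n = X.nrow(), k = idx.ncol();
  NumericMatrix out(n, 4);
  arma::mat C(3, 3), vec;
  arma::vec mu(3), val;
  for (int i = 0; i < n; ++i) {
    mu.zeros();
    for (int a = 0; a < 3; ++a) mu(a) = X(i, a);
    for (int j = 0; j < k; ++j) {
      int p = idx(i, j) - 1;
      for (int a = 0; a < 3; ++a) mu(a) += X(p, a);
    }
    mu /= (k + 1);
    C.zeros();
    double d[3];
    for (int j = -1; j < k; ++j) {
      int p = j < 0 ? i : idx(i, j) - 1;
      for (int a = 0; a < 3; ++a) d[a] = X(p, a) - mu(a);
      for (int a = 0; a < 3; ++a)
        for (int b = a; b < 3; ++b)
          C(a, b) += d[a] * d[b];
    }
    C(1, 0) = C(0, 1); C(2, 0) = C(0, 2); C(2, 1) = C(1, 2);
    arma::eig_sym(val, vec, C);          // ascending eigenvalues
    double nx = vec(0, 0), ny = vec(1, 0), nz = vec(2, 0);
    // sign convention: nz >= 0; exactly-vertical surfaces (|nz| ~ 0 up to
    // round-off) are oriented by +y, then +x
    const double eps = 1e-9;
    bool flip;
    if (std::fabs(nz) > eps) flip = nz < 0;
    else if (std::fabs(ny) > eps) flip = ny < 0;
    else flip = nx < 0;
    if (flip) { nx = -nx; ny = -ny; nz = -nz; }
    out(i, 0) = nx; out(i, 1) = ny; out(i, 2) = nz;
    double tot = val(0) + val(1) + val(2);
    out(i, 3) = tot > 0 ? val(0) / tot : 0.0;
  }
  return out;
}

// Curvature-seeded region growing over precomputed k-NN neighbourhoods.
// Candidate seeds are visited in order of ascending curvature; a neighbour
// joins a region when the (unsigned) angle between its normal and the normal
// of the point currently being expanded is below the threshold, and itself
// becomes an expansion front point when its curvature is below curv_thresh.
// Regions smaller than min_cluster are reported as unclustered (0).
// Returns per-point labels: 1..m for clusters, 0 for unclustered.
// [[Rcpp::export(name = ".cc_region_growing")]]
IntegerVector cc_region_growing(IntegerMatrix nbr, NumericMatrix normals,
                                NumericVector curvature, double cos_thresh,
                                double curv_thresh, int min_cluster) {
  int n = nbr.nrow(), k = nbr.ncol();
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(), [&curvature](int a, int b) {
    return curvature[a] < curvature[b];
  });
  IntegerVector labels(n, 0);
  std::vector<char> visited(n, 0);
  std::vector<int> front, members;
  int next_label = 0;
  for (int oi = 0; oi < n; ++oi) {
    int s0 = order[oi];
    if (visited[s0]) continue;
    ++next_label;
    front.clear(); members.clear();
    visited[s0] = 1;
    front.push_back(s0);
    members.push_back(s0);
    for (size_t f = 0; f < front.size(); ++f) {
      int s = front[f];
      double sx = normals(s, 0), sy = normals(s, 1), sz = normals(s, 2);
      for (int j = 0; j < k; ++j) {
        int p = nbr(s, j) - 1;
        if (visited[p]) continue;
        double dot = std::fabs(sx * normals(p, 0) + sy * normals(p, 1) +
                               sz * normals(p, 2));
        if (dot < cos_thresh) continue;
        visited[p] = 1;
        members.push_back(p);
        if (curvature[p] < curv_thresh) front.push_back(p);
      }
    }
    int lab = ((int)members.size() >= min_cluster) ? next_label : 0;
    if (lab == 0) --next_label;
    for (size_t m = 0; m < members.size(); ++m) labels[members[m]] = lab;
  }
  return labels;
}

// 8-connected component labelling of a logical matrix (union-find).
// Components are numbered 1..m in raster order of their first pixel.
// [[Rcpp::export(name = ".cc_label_components")]]
IntegerMatrix cc_label_components(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> parent(1, 0);            // parent[0] unused
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  IntegerMatrix lab(nr, nc);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) { lab(r, c) = 0; continue; }
      // neighbours already labelled in column-major scan:
      // same column r-1; previous column r-1, r, r+1
      int best = 0;
      int cand[4][2] = {{r - 1, c}, {r - 1, c - 1}, {r, c - 1}, {r + 1, c - 1}};
      for (int t = 0; t < 4; ++t) {
        int rr = cand[t][0], cc = cand[t][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l == 0) continue;
        if (best == 0) best = find(l);
        else {
          int l2 = find(l);
          if (l2 != best) parent[std::max(l2, best)] = std::min(l2, best),
                          best = std::min(l2, best);
        }
      }
      if (best == 0) {
        ++next;
        parent.push_back(next);
        best = next;
      }
      lab(r, c) = best;
    }
  }
  // flatten and renumber in raster order of first appearance
  std::vector<int> newid(next + 1, 0);
  int m = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (lab(r, c)) {
        int root = find(lab(r, c));
        if (!newid[root]) newid[root] = ++m;
        lab(r, c) = newid[root];
      }
  return lab;
}
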