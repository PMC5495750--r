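// Compiled kernels for the searchlight / cluster machinery: per-sphere
// RDM vectorization, 3D connected components, bootstrap null cluster
// sizes, and row quantiles.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Per-center neural RDM vectors.
// beta: C x V matrix (conditions x mask voxels), starts: V+1 CSR offsets,
// members: 0-based mask-voxel indices.  Returns V x C(C-1)/2 matrix of
// correlation distances (1 - Pearson r across member voxels), row-major
// pair order (0,1),(0,2),...  Rows with fewer than min_voxels members or a
// constant condition pattern are NA.
// [[Rcpp::export]]
NumericMatrix cpp_rdm_vectors(NumericMatrix beta, IntegerVector starts,
                              IntegerVector members, int min_voxels) {
  const int C = beta.nrow();
  const int V = starts.size() - 1;
  const int P = C * (C - 1) / 2;
  NumericMatrix out(V, P);
  std::vector<double> sub((size_t)C * 256), mean(C), nrm(C);
  for (int v = 0; v < V; ++v) {
    const int a = starts[v], b = starts[v + 1];
    const int m = b - a;
    if (m < min_voxels || m < 3) {
      for (int p = 0; p < P; ++p) out(v, p) = NA_REAL;
      continue;
    }
    if ((size_t)C * m > sub.size()) sub.resize((size_t)C * m);
    // gather and center
    for (int c = 0; c < C; ++c) mean[c] = 0.0;
    for (int t = 0; t < m; ++t) {
      const int col = members[a + t];
      const double *src = &beta(0, col);
      double *dst = &sub[(size_t)t * C];
      for (int c = 0; c < C; ++c) { dst[c] = src[c]; mean[c] += src[c]; }
    }
    for (int c = 0; c < C; ++c) mean[c] /= m;
    for (int c = 0; c < C; ++c) nrm[c] = 0.0;
    for (int t = 0; t < m; ++t) {
      double *dst = &sub[(size_t)t * C];
      for (int c = 0; c < C; ++c) {
        dst[c] -= mean[c];
        nrm[c] += dst[c] * dst[c];
      }
    }
    bool degenerate = false;
    for (int c = 0; c < C; ++c) {
      if (nrm[c] <= 0.0) { degenerate = true; break; }
      nrm[c] = std::sqrt(nrm[c]);
    }
    if (degenerate) {
      for (int p = 0; p < P; ++p) out(v, p) = NA_REAL;
      continue;
    }
    int p = 0;
    for (int i = 0; i < C - 1; ++i) {
      for (int j = i + 1; j < C; ++j, ++p) {
        double dot = 0.0;
        const double *si = &sub[i], *sj = &sub[j];
        for (int t = 0; t < m; ++t)
          dot += si[(size_t)t * C] * sj[(size_t)t * C];
        double r = dot / (nrm[i] * nrm[j]);
        if (r > 1.0) r = 1.0; else if (r < -1.0) r = -1.0;
        out(v, p) = 1.0 - r;
      }
    }
  }
  return out;
}

static void neighbor_offsets(const IntegerVector &dim, int connectivity,
                             std::vector<int> &di, std::vector<int> &dj,
                             std::vector<int> &dk) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int nz = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && nz > 1) continue;
        if (connectivity == 18 && nz > 2) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
}

// Label connected components of a logical 3D array (column-major, dims in
// `dim`) under 6/18/26 connectivity.  Returns integer labels (0 =
// background), components numbered from 1 in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_clusters(LogicalVector supra, IntegerVector dim,
                                 int connectivity) {
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int n = n1 * n2 * n3;
  IntegerVector labels(n, 0);
  std::vector<int> di, dj, dk;
  neighbor_offsets(dim, connectivity, di, dj, dk);
  std::vector<int> stack;
  int next = 0;
  for (int idx = 0; idx < n; ++idx) {
    if (!supra[idx] || labels[idx] != 0) continue;
    ++next;
    labels[idx] = next;
    stack.clear();
    stack.push_back(idx);
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      int i = cur % n1, j = (cur / n1) % n2, k = cur / (n1 * n2);
      for (size_t o = 0; o < di.size(); ++o) {
        int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        int nb = ii + jj * n1 + kk * n1 * n2;
        if (supra[nb] && labels[nb] == 0) {
          labels[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return labels;
}

// Null cluster sizes from bootstrap maps.
// null_maps: V x B matrix (mask voxels x bootstrap samples), thr: per-voxel
// thresholds (length V), vox_lin: 0-based linear grid index per mask voxel.
// Returns a list with `max_sizes` (largest supra-threshold cluster per
// map) and, if pooled, `all_sizes` (every null cluster size, all maps).
// [[Rcpp::export]]
List cpp_null_cluster_sizes(NumericMatrix null_maps, NumericVector thr,
                            IntegerVector vox_lin, IntegerVector dim,
                            int connectivity, bool pooled) {
  const int V = null_maps.nrow(), B = null_maps.ncol();
  const int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const int n = n1 * n2 * n3;
  std::vector<int> di, dj, dk;
  neighbor_offsets(dim, connectivity, di, dj, dk);
  // grid -> mask voxel index (-1 off mask)
  std::vector<int> gidx(n, -1);
  for (int v = 0; v < V; ++v) gidx[vox_lin[v]] = v;
  // precompute adjacency between mask voxels
  std::vector<int> adj_start(V + 1, 0);
  std::vector<int> adj;
  adj.reserve((size_t)V * di.size() / 2);
  for (int v = 0; v < V; ++v) {
    int cur = vox_lin[v];
    int i = cur % n1, j = (cur / n1) % n2, k = cur / (n1 * n2);
    for (size_t o = 0; o < di.size(); ++o) {
      int ii = i + di[o], jj = j + dj[o], kk = k + dk[o];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      int g = gidx[ii + jj * n1 + kk * n1 * n2];
      if (g >= 0) adj.push_back(g);
    }
    adj_start[v + 1] = (int)adj.size();
  }
  NumericVector max_sizes(B);
  std::vector<double> all;
  std::vector<char> supra(V);
  std::vector<int> comp(V), stack;
  for (int b = 0; b < B; ++b) {
    for (int v = 0; v < V; ++v) {
      double z = null_maps(v, b);
      supra[v] = (!ISNAN(z) && !ISNAN(thr[v]) && z > thr[v]) ? 1 : 0;
      comp[v] = 0;
    }
    int best = 0;
    for (int v = 0; v < V; ++v) {
      if (!supra[v] || comp[v]) continue;
      int size = 0;
      comp[v] = 1;
      stack.clear(); stack.push_back(v);
      while (!stack.empty()) {
        int cur = stack.back(); stack.pop_back();
        ++size;
        for (int e = adj_start[cur]; e < adj_start[cur + 1]; ++e) {
          int w = adj[e];
          if (supra[w] && !comp[w]) { comp[w] = 1; stack.push_back(w); }
        }
      }
      if (size > best) best = size;
      if (pooled) all.push_back((double)size);
    }
    max_sizes[b] = best;
  }
  List out = List::create(Named("max_sizes") = max_sizes);
  if (pooled) out["all_sizes"] = NumericVector(all.begin(), all.end());
  return out;
}

// Type-7 quantile of each row of X at probability p (NA rows stay NA).
// [[Rcpp::export]]
NumericVector cpp_row_quantile(NumericMatrix X, double p) {
  const int V = X.nrow(), B = X.ncol();
  NumericVector out(V);
  std::vector<double> buf(B);
  for (int v = 0; v < V; ++v) {
    bool bad = false;
    for (int b = 0; b < B; ++b) {
      buf[b] = X(v, b);
      if (ISNAN(buf[b])) { bad = true; break; }
    }
    if (bad) { out[v] = NA_REAL; continue; }
    double h = (B - 1) * p;
    int lo = (int)std::floor(h);
    double frac = h - lo;
    std::nth_element(buf.begin(), buf.begin() + lo, buf.end());
    double qlo = buf[lo];
    double qhi = qlo;
    if (frac > 0.0 && lo + 1 < B) {
      qhi = *std::min_element(buf.begin() + lo + 1, buf.end());
    }
    out[v] = qlo + frac * (qhi - qlo);
  }
  return out;
}
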