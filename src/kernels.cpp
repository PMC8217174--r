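// O(n^2) statistical kernels: distance correlation and k-nearest-neighbor
// conditional mutual information (Chebyshev metric), plus the neighbor-based
// local permutation scheme used to calibrate the CMI test.
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Double-center a distance matrix in place: A_ij - rowmean_i - colmean_j + grand.
static void double_center(arma::mat& D) {
  const arma::uword n = D.n_rows;
  arma::vec rm = arma::mean(D, 1);
  double gm = arma::mean(rm);
  for (arma::uword i = 0; i < n; ++i)
    for (arma::uword j = 0; j < n; ++j)
      D(i, j) += gm - rm(i) - rm(j);
}

static arma::mat centered_dist(const arma::vec& x) {
  const arma::uword n = x.n_elem;
  arma::mat D(n, n);
  for (arma::uword i = 0; i < n; ++i) {
    D(i, i) = 0.0;
    for (arma::uword j = i + 1; j < n; ++j) {
      double d = std::abs(x(i) - x(j));
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  double_center(D);
  return D;
}

static double dcor_from_centered(const arma::mat& A, const arma::mat& B) {
  const double n2 = static_cast<double>(A.n_rows) * static_cast<double>(A.n_rows);
  double dcov2 = arma::accu(A % B) / n2;
  double dvarx = arma::accu(A % A) / n2;
  double dvary = arma::accu(B % B) / n2;
  double denom = std::sqrt(dvarx * dvary);
  if (denom <= 0.0 || dcov2 <= 0.0) return 0.0;
  return std::sqrt(dcov2 / denom);
}

// [[Rcpp::export]]
double cpp_dcor(const arma::vec& x, const arma::vec& y) {
  arma::mat A = centered_dist(x);
  arma::mat B = centered_dist(y);
  return dcor_from_centered(A, B);
}

// Distance correlation of (x[perm], y) for each permutation column (1-based
// indices). Simultaneous row/column permutation of a double-centered matrix
// stays double-centered, so each permuted statistic costs one O(n^2) pass.
// [[Rcpp::export]]
NumericVector cpp_dcor_perm(const arma::vec& x, const arma::vec& y,
                            const IntegerMatrix& perms) {
  arma::mat A = centered_dist(x);
  arma::mat B = centered_dist(y);
  const arma::uword n = x.n_elem;
  const double n2 = static_cast<double>(n) * static_cast<double>(n);
  double dvarx = arma::accu(A % A) / n2;
  double dvary = arma::accu(B % B) / n2;
  double denom = std::sqrt(dvarx * dvary);
  const int np = perms.ncol();
  NumericVector out(np);
  std::vector<arma::uword> pi(n);
  for (int p = 0; p < np; ++p) {
    for (arma::uword i = 0; i < n; ++i) pi[i] = perms(i, p) - 1;
    double acc = 0.0;
    for (arma::uword j = 0; j < n; ++j) {
      const double* Acol = A.colptr(pi[j]);
      const double* Bcol = B.colptr(j);
      for (arma::uword i = 0; i < n; ++i) acc += Acol[pi[i]] * Bcol[i];
    }
    double dcov2 = acc / n2;
    out[p] = (denom <= 0.0 || dcov2 <= 0.0) ? 0.0 : std::sqrt(dcov2 / denom);
  }
  return out;
}

// Block-permutation index matrix (1-based). Contiguous blocks of block_len
// are shuffled within each segment delimited by the 0-based boundary starts,
// so no permuted chunk crosses a segment junction. Uses R's RNG.
// [[Rcpp::export]]
IntegerMatrix cpp_block_perms(const int n, const int block_len,
                              const int n_perm,
                              const IntegerVector& boundaries) {
  std::vector<int> seg_start(boundaries.begin(), boundaries.end());
  std::vector<int> seg_end;
  for (size_t s = 1; s < seg_start.size(); ++s) seg_end.push_back(seg_start[s]);
  seg_end.push_back(n);
  // per-segment block starts and lengths (0-based starts)
  std::vector<std::vector<int>> bstarts(seg_start.size());
  std::vector<std::vector<int>> blens(seg_start.size());
  for (size_t s = 0; s < seg_start.size(); ++s) {
    for (int b = seg_start[s]; b < seg_end[s]; b += block_len) {
      bstarts[s].push_back(b);
      blens[s].push_back(std::min(block_len, seg_end[s] - b));
    }
  }
  IntegerMatrix out(n, n_perm);
  for (int p = 0; p < n_perm; ++p) {
    int pos = 0;
    for (size_t s = 0; s < seg_start.size(); ++s) {
      const int nb = static_cast<int>(bstarts[s].size());
      std::vector<int> ord(nb);
      for (int b = 0; b < nb; ++b) ord[b] = b;
      for (int b = nb - 1; b > 0; --b) {
        int j = static_cast<int>(unif_rand() * (b + 1));
        std::swap(ord[b], ord[j]);
      }
      for (int b = 0; b < nb; ++b) {
        const int st = bstarts[s][ord[b]];
        for (int m = 0; m < blens[s][ord[b]]; ++m) out(pos++, p) = st + m + 1;
      }
    }
  }
  return out;
}

static inline double cheb(const arma::mat& M, arma::uword i, arma::uword j) {
  double m = 0.0;
  for (arma::uword c = 0; c < M.n_cols; ++c) {
    double d = std::abs(M(i, c) - M(j, c));
    if (d > m) m = d;
  }
  return m;
}

// KSG-style conditional mutual information I(x; y | z) in nats, Chebyshev
// metric, k nearest neighbors in the joint space, strict-inequality subspace
// counts (Frenzel-Pompe). With zero-column z this reduces to the KSG mutual
// information estimator. Columns are expected standardized by the caller.
// [[Rcpp::export]]
double cpp_cmi_knn(const arma::mat& x, const arma::mat& y, const arma::mat& z,
                   const int k) {
  const arma::uword n = x.n_rows;
  const bool has_z = z.n_cols > 0;
  std::vector<double> djoint(n);
  double acc = 0.0;
  std::vector<double> row(n);
  for (arma::uword i = 0; i < n; ++i) {
    // k-th nearest joint-space neighbor distance (self excluded)
    for (arma::uword j = 0; j < n; ++j) {
      double d = cheb(x, i, j);
      double dy = cheb(y, i, j);
      if (dy > d) d = dy;
      if (has_z) {
        double dz = cheb(z, i, j);
        if (dz > d) d = dz;
      }
      row[j] = d;
    }
    row[i] = std::numeric_limits<double>::infinity();
    std::nth_element(row.begin(), row.begin() + (k - 1), row.end());
    djoint[i] = row[k - 1];
  }
  for (arma::uword i = 0; i < n; ++i) {
    const double di = djoint[i];
    int nxz = 0, nyz = 0, nz = 0;
    for (arma::uword j = 0; j < n; ++j) {
      if (j == i) continue;
      double dz = has_z ? cheb(z, i, j) : 0.0;
      if (dz >= di) continue;
      ++nz;
      double dx = cheb(x, i, j);
      if (std::max(dx, dz) < di) ++nxz;
      double dy = cheb(y, i, j);
      if (std::max(dy, dz) < di) ++nyz;
    }
    if (has_z) {
      acc += R::digamma(nz + 1.0) - R::digamma(nxz + 1.0) - R::digamma(nyz + 1.0);
    } else {
      acc += -R::digamma(nxz + 1.0) - R::digamma(nyz + 1.0);
    }
  }
  double cmi = R::digamma(static_cast<double>(k)) + acc / static_cast<double>(n);
  if (!has_z) cmi += R::digamma(static_cast<double>(n));
  return cmi;
}

// CMI of (x[perm], y | z) for each permutation column, reusing precomputed
// pairwise Chebyshev distances (permuting x only permutes the index set of
// its distance matrix). Memory is 2-3 n^2 doubles.
// [[Rcpp::export]]
NumericVector cpp_cmi_knn_perm(const arma::mat& x, const arma::mat& y,
                               const arma::mat& z, const int k,
                               const IntegerMatrix& perms) {
  const arma::uword n = x.n_rows;
  const bool has_z = z.n_cols > 0;
  arma::mat Dx(n, n), Dy(n, n), Dz;
  if (has_z) Dz.set_size(n, n);
  for (arma::uword i = 0; i < n; ++i) {
    Dx(i, i) = 0.0; Dy(i, i) = 0.0; if (has_z) Dz(i, i) = 0.0;
    for (arma::uword j = i + 1; j < n; ++j) {
      double d = cheb(x, i, j); Dx(i, j) = d; Dx(j, i) = d;
      d = cheb(y, i, j); Dy(i, j) = d; Dy(j, i) = d;
      if (has_z) { d = cheb(z, i, j); Dz(i, j) = d; Dz(j, i) = d; }
    }
  }
  const int np = perms.ncol();
  NumericVector out(np);
  std::vector<arma::uword> px(n);
  std::vector<double> heap(k);  // max-heap of the k smallest joint distances
  for (int p = 0; p < np; ++p) {
    for (arma::uword i = 0; i < n; ++i) px[i] = perms(i, p) - 1;
    double acc = 0.0;
    for (arma::uword i = 0; i < n; ++i) {
      const double* dxrow = Dx.colptr(px[i]);
      const double* dyrow = Dy.colptr(i);
      const double* dzrow = has_z ? Dz.colptr(i) : nullptr;
      int hs = 0;
      for (arma::uword j = 0; j < n; ++j) {
        if (j == i) continue;
        double v = std::max(dxrow[px[j]], dyrow[j]);
        if (has_z) v = std::max(v, dzrow[j]);
        if (hs < k) {
          heap[hs++] = v;
          if (hs == k) std::make_heap(heap.begin(), heap.end());
        } else if (v < heap[0]) {
          std::pop_heap(heap.begin(), heap.end());
          heap[k - 1] = v;
          std::push_heap(heap.begin(), heap.end());
        }
      }
      const double di = heap[0];
      int nxz = 0, nyz = 0, nz = 0;
      for (arma::uword j = 0; j < n; ++j) {
        if (j == i) continue;
        const double dzv = has_z ? dzrow[j] : 0.0;
        if (dzv < di) {
          ++nz;
          if (std::max(dxrow[px[j]], dzv) < di) ++nxz;
          if (std::max(dyrow[j], dzv) < di) ++nyz;
        }
      }
      if (has_z) {
        acc += R::digamma(nz + 1.0) - R::digamma(nxz + 1.0) -
          R::digamma(nyz + 1.0);
      } else {
        acc += -R::digamma(nxz + 1.0) - R::digamma(nyz + 1.0);
      }
    }
    double cmi = R::digamma(static_cast<double>(k)) +
      acc / static_cast<double>(n);
    if (!has_z) cmi += R::digamma(static_cast<double>(n));
    out[p] = cmi;
  }
  return out;
}

// Indices (1-based) of the k nearest neighbors of each row of z, Chebyshev
// metric, self excluded. Used by the local permutation scheme.
// [[Rcpp::export]]
IntegerMatrix cpp_knn_indices(const arma::mat& z, const int k) {
  const arma::uword n = z.n_rows;
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, arma::uword>> row(n);
  for (arma::uword i = 0; i < n; ++i) {
    for (arma::uword j = 0; j < n; ++j)
      row[j] = std::make_pair(j == i ? std::numeric_limits<double>::infinity()
                                     : cheb(z, i, j), j);
    std::partial_sort(row.begin(), row.begin() + k, row.end());
    for (int m = 0; m < k; ++m) out(i, m) = static_cast<int>(row[m].second) + 1;
  }
  return out;
}

// Neighbor-respecting local permutations: each sample's x value is swapped
// with one drawn from its nearest neighbors in the conditioning space,
// preferring indices not yet used so the map stays close to a bijection.
// Uses R's RNG (seed-reproducible from set.seed()).
// [[Rcpp::export]]
IntegerMatrix cpp_local_perm(const IntegerMatrix& nbrs, const int n_perm) {
  const int n = nbrs.nrow();
  const int k = nbrs.ncol();
  IntegerMatrix out(n, n_perm);
  std::vector<int> order(n);
  std::vector<int> cand(k);
  std::vector<bool> used(n);
  for (int p = 0; p < n_perm; ++p) {
    for (int i = 0; i < n; ++i) order[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      std::swap(order[i], order[j]);
    }
    std::fill(used.begin(), used.end(), false);
    for (int m = 0; m < n; ++m) {
      const int i = order[m];
      for (int c = 0; c < k; ++c) cand[c] = nbrs(i, c);
      for (int c = k - 1; c > 0; --c) {
        int j = static_cast<int>(unif_rand() * (c + 1));
        std::swap(cand[c], cand[j]);
      }
      int pick = cand[0];
      for (int c = 0; c < k; ++c) {
        if (!used[cand[c] - 1]) { pick = cand[c]; break; }
      }
      used[pick - 1] = true;
      out(i, p) = pick;
    }
  }
  return out;
}
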