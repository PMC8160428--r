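// Incremental (beneath-beyond) convex hull in d dimensions.
//
// Supports the functional-richness (FRic) computation: returns the hull
// volume and the indices of the hull vertices for a point cloud in
// d >= 2 dimensions.  Points are assumed to be continuous measurements
// (ties / exact degeneracies have measure zero); a point set whose affine
// rank is below d is reported as degenerate (NA volume) rather than
// assigned a zero-thickness volume.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <map>
#include <vector>

using namespace arma;

namespace {

struct Facet {
  std::vector<unsigned int> verts; // sorted point indices, length d
  vec normal;                      // outward unit normal
  double offset;                   // normal . x == offset on the plane
};

// Unit normal of the hyperplane through the rows of V (d points in d dims):
// the right singular vector of the (d-1) x d difference matrix belonging to
// its smallest singular value.
vec facet_normal(const mat &X, const std::vector<unsigned int> &verts) {
  const unsigned int d = X.n_cols;
  mat M(d - 1, d);
  for (unsigned int i = 1; i < d; ++i)
    M.row(i - 1) = X.row(verts[i]) - X.row(verts[0]);
  mat Q, R;
  qr(Q, R, M.t()); // full QR of d x (d-1): last column of Q spans null(M)
  return Q.col(d - 1);
}

Facet make_facet(const mat &X, std::vector<unsigned int> verts,
                 const rowvec &interior) {
  std::sort(verts.begin(), verts.end());
  Facet f;
  f.normal = facet_normal(X, verts);
  f.offset = dot(f.normal, X.row(verts[0]).t());
  const double side = dot(f.normal, interior.t()) - f.offset;
  if (side > 0) { // orient outward: interior strictly beneath
    f.normal = -f.normal;
    f.offset = -f.offset;
  }
  f.verts = std::move(verts);
  return f;
}

// Greedy affinely independent subset of size d+1; empty if rank-deficient.
std::vector<unsigned int> initial_simplex(const mat &X, double tol) {
  const unsigned int n = X.n_rows, d = X.n_cols;
  std::vector<unsigned int> chosen;
  chosen.push_back(0);
  mat B(d, 0); // orthonormal basis of directions from X[chosen[0]]
  for (unsigned int k = 0; k < d; ++k) {
    double best = tol;
    int best_i = -1;
    vec best_r;
    for (unsigned int i = 0; i < n; ++i) {
      vec v = (X.row(i) - X.row(chosen[0])).t();
      if (B.n_cols > 0) v -= B * (B.t() * v);
      const double r = norm(v);
      if (r > best) {
        best = r;
        best_i = (int)i;
        best_r = v / r;
      }
    }
    if (best_i < 0) return std::vector<unsigned int>();
    chosen.push_back((unsigned int)best_i);
    B = join_rows(B, best_r);
  }
  return chosen;
}

} // namespace

// [[Rcpp::export]]
Rcpp::List convhull_cpp(const arma::mat &X) {
  const unsigned int n = X.n_rows, d = X.n_cols;
  if (d < 2) Rcpp::stop("convhull_cpp requires at least 2 dimensions");
  const double scale = std::max(1.0, X.is_empty() ? 1.0 : abs(X).max());
  const double tol = 1e-9 * scale;

  if (n < d + 1)
    return Rcpp::List::create(Rcpp::Named("volume") = NA_REAL,
                              Rcpp::Named("vertices") = Rcpp::IntegerVector());

  std::vector<unsigned int> simp = initial_simplex(X, tol);
  if (simp.empty())
    return Rcpp::List::create(Rcpp::Named("volume") = NA_REAL,
                              Rcpp::Named("vertices") = Rcpp::IntegerVector());

  rowvec interior(d, fill::zeros);
  for (unsigned int i = 0; i <= d; ++i) interior += X.row(simp[i]);
  interior /= (double)(d + 1);

  std::vector<Facet> facets;
  for (unsigned int drop = 0; drop <= d; ++drop) {
    std::vector<unsigned int> verts;
    for (unsigned int i = 0; i <= d; ++i)
      if (i != drop) verts.push_back(simp[i]);
    facets.push_back(make_facet(X, verts, interior));
  }

  std::vector<bool> in_simplex(n, false);
  for (unsigned int i = 0; i <= d; ++i) in_simplex[simp[i]] = true;

  // Insert far points first: the hull grows quickly and most later points
  // are rejected by the (cheap) visibility scan without building facets.
  std::vector<unsigned int> order;
  for (unsigned int i = 0; i < n; ++i)
    if (!in_simplex[i]) order.push_back(i);
  {
    vec d2(n, fill::zeros);
    for (unsigned int i = 0; i < n; ++i)
      d2(i) = accu(square(X.row(i) - interior));
    std::sort(order.begin(), order.end(),
              [&](unsigned int a, unsigned int b) { return d2(a) > d2(b); });
  }

  for (unsigned int p : order) {
    const vec pt = X.row(p).t();
    std::vector<size_t> visible;
    for (size_t f = 0; f < facets.size(); ++f)
      if (dot(facets[f].normal, pt) - facets[f].offset > tol)
        visible.push_back(f);
    if (visible.empty()) continue; // beneath every facet: interior point

    // Horizon ridges: (d-1)-subsets occurring in exactly one visible facet.
    std::map<std::vector<unsigned int>, int> ridge_count;
    for (size_t vi : visible) {
      const std::vector<unsigned int> &fv = facets[vi].verts;
      for (unsigned int drop = 0; drop < d; ++drop) {
        std::vector<unsigned int> ridge;
        for (unsigned int i = 0; i < d; ++i)
          if (i != drop) ridge.push_back(fv[i]);
        ++ridge_count[ridge];
      }
    }

    std::vector<Facet> kept;
    kept.reserve(facets.size());
    std::vector<bool> is_visible(facets.size(), false);
    for (size_t vi : visible) is_visible[vi] = true;
    for (size_t f = 0; f < facets.size(); ++f)
      if (!is_visible[f]) kept.push_back(std::move(facets[f]));

    for (auto &rc : ridge_count) {
      if (rc.second != 1) continue;
      std::vector<unsigned int> verts = rc.first;
      verts.push_back(p);
      kept.push_back(make_facet(X, verts, interior));
    }
    facets = std::move(kept);
  }

  // Volume: cone decomposition from the interior point over outward facets.
  double logfact = 0.0;
  for (unsigned int i = 2; i <= d; ++i) logfact += std::log((double)i);
  double vol = 0.0;
  std::vector<bool> is_vertex(n, false);
  mat S(d, d);
  for (const Facet &f : facets) {
    for (unsigned int i = 0; i < d; ++i) {
      S.col(i) = (X.row(f.verts[i]) - interior).t();
      is_vertex[f.verts[i]] = true;
    }
    vol += std::abs(det(S));
  }
  vol /= std::exp(logfact);

  Rcpp::IntegerVector vertices;
  for (unsigned int i = 0; i < n; ++i)
    if (is_vertex[i]) vertices.push_back((int)i + 1);

  return Rcpp::List::create(Rcpp::Named("volume") = vol,
                            Rcpp::Named("vertices") = vertices);
}
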