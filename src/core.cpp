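// Compiled kernels: dense SIFT extraction, Lloyd k-means, nearest-codeword
// assignment, and the ADMM solver for locality-constrained sparse coding.
// All RNG-dependent choices (k-means++ seeding, sampling) happen in R so that
// set.seed() alone fixes every result; these routines are deterministic.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double TWO_PI = 6.283185307179586476925286766559;

// ---------------------------------------------------------------------------
// Dense upright SIFT
// ---------------------------------------------------------------------------

// Gradients by central differences with edge replication; 4x4 spatial cells x
// 8 orientation bins, Gaussian-weighted (sigma = patch/2, centred), trilinear
// (bilinear spatial + linear orientation) interpolation; L2 normalise, clip at
// 0.2, renormalise. Zero-gradient patches yield zero vectors.
// [[Rcpp::export]]
List dense_sift_cpp(const arma::mat& img, int patch, int spacing) {
  const int H = img.n_rows, W = img.n_cols;
  if (patch > H || patch > W) stop("patch larger than frame");
  if (spacing < 1) stop("spacing must be >= 1");

  arma::mat gx(H, W), gy(H, W), mag(H, W), ori(H, W);
  for (int c = 0; c < W; ++c) {
    const int cl = (c == 0) ? 0 : c - 1, cr = (c == W - 1) ? W - 1 : c + 1;
    for (int r = 0; r < H; ++r) {
      const int rl = (r == 0) ? 0 : r - 1, rr = (r == H - 1) ? H - 1 : r + 1;
      const double dx = (img(r, cr) - img(r, cl)) / 2.0;
      const double dy = (img(rr, c) - img(rl, c)) / 2.0;
      gx(r, c) = dx; gy(r, c) = dy;
      mag(r, c) = std::sqrt(dx * dx + dy * dy);
      double a = std::atan2(dy, dx);
      if (a < 0) a += TWO_PI;
      ori(r, c) = a;
    }
  }

  const int nr = (H - patch) / spacing + 1;
  const int nc = (W - patch) / spacing + 1;
  const int n = nr * nc, d = 128;
  const double cell = patch / 4.0;
  const double ctr = (patch - 1) / 2.0;
  const double gsig = patch / 2.0;

  // per-offset tables: Gaussian weight, lower cell index, interpolation frac
  std::vector<double> gw(patch), frac(patch);
  std::vector<int> lo(patch);
  for (int p = 0; p < patch; ++p) {
    gw[p] = std::exp(-((p - ctr) * (p - ctr)) / (2.0 * gsig * gsig));
    const double u = (p + 0.5) / cell - 0.5;
    lo[p] = (int)std::floor(u);
    frac[p] = u - lo[p];
  }

  // per-pixel orientation bins and fractions, computed once for the frame
  arma::Mat<int> obin(H, W);
  arma::mat ofrac(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double o = ori(r, c) / (TWO_PI / 8.0);
      if (o >= 8.0) o = 0.0;
      const int io = (int)std::floor(o);
      obin(r, c) = io;
      ofrac(r, c) = o - io;
    }

  arma::mat D(n, d, arma::fill::zeros);
  arma::mat centers(n, 2);
  std::vector<double> acc(d);

  for (int gi = 0; gi < nr; ++gi) {
    for (int gj = 0; gj < nc; ++gj) {
      const int row = gi * nc + gj;
      const int r0 = gi * spacing, c0 = gj * spacing;
      centers(row, 0) = r0 + (patch - 1) / 2.0;
      centers(row, 1) = c0 + (patch - 1) / 2.0;
      std::fill(acc.begin(), acc.end(), 0.0);
      for (int pc = 0; pc < patch; ++pc) {
        const int iv = lo[pc];
        const double fv = frac[pc];
        const double wgc = gw[pc];
        const double* magc = mag.colptr(c0 + pc) + r0;
        const int* obc = obin.colptr(c0 + pc) + r0;
        const double* ofc = ofrac.colptr(c0 + pc) + r0;
        for (int pr = 0; pr < patch; ++pr) {
          const double m = magc[pr];
          if (m == 0.0) continue;
          const int iu = lo[pr];
          const double fu = frac[pr];
          const double w = gw[pr] * wgc * m;
          const int io = obc[pr];
          const double fo = ofc[pr];
          const int ob0 = io, ob1 = (io + 1) & 7;
          const double w0 = w * (1.0 - fo), w1 = w * fo;
          for (int du = 0; du <= 1; ++du) {
            const int cu = iu + du;
            if (cu < 0 || cu > 3) continue;
            const double wu = du ? fu : 1.0 - fu;
            for (int dv = 0; dv <= 1; ++dv) {
              const int cv = iv + dv;
              if (cv < 0 || cv > 3) continue;
              const double wv = wu * (dv ? fv : 1.0 - fv);
              const int base = (cu * 4 + cv) * 8;
              acc[base + ob0] += w0 * wv;
              acc[base + ob1] += w1 * wv;
            }
          }
        }
      }
      double nrm2 = 0.0;
      for (int k = 0; k < d; ++k) nrm2 += acc[k] * acc[k];
      if (nrm2 > 1e-24) {
        const double inv = 1.0 / std::sqrt(nrm2);
        double nrm2b = 0.0;
        for (int k = 0; k < d; ++k) {
          double v = acc[k] * inv;
          if (v > 0.2) v = 0.2;
          acc[k] = v;
          nrm2b += v * v;
        }
        if (nrm2b > 1e-24) {
          const double invb = 1.0 / std::sqrt(nrm2b);
          for (int k = 0; k < d; ++k) D(row, k) = acc[k] * invb;
        }
      }
    }
  }
  return List::create(_["descriptors"] = D, _["centers"] = centers);
}

// ---------------------------------------------------------------------------
// Nearest-codeword assignment (exhaustive), ties to the lowest index
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List nn_assign_cpp(const arma::mat& B, const arma::mat& X) {
  if (B.n_rows != X.n_rows) stop("dimension mismatch between descriptors and codebook");
  const arma::uword m = B.n_cols, n = X.n_cols;
  arma::rowvec bn = arma::sum(arma::square(B), 0);
  arma::uvec idx(n);
  arma::vec dist2(n);
  const arma::uword chunk = 8192;
  for (arma::uword s = 0; s < n; s += chunk) {
    const arma::uword e = std::min(s + chunk, n) - 1;
    arma::mat G = B.t() * X.cols(s, e);            // m x nb
    arma::rowvec xn = arma::sum(arma::square(X.cols(s, e)), 0);
    for (arma::uword j = 0; j < G.n_cols; ++j) {
      double best = bn(0) - 2.0 * G(0, j);
      arma::uword bi = 0;
      for (arma::uword i = 1; i < m; ++i) {
        const double v = bn(i) - 2.0 * G(i, j);
        if (v < best) { best = v; bi = i; }
      }
      idx(s + j) = bi + 1;
      double d2 = best + xn(j);
      dist2(s + j) = d2 > 0 ? d2 : 0.0;
    }
  }
  return List::create(_["index"] = idx, _["dist2"] = dist2);
}

// K nearest codewords per column of X, ascending distance, ties to lowest index.
// [[Rcpp::export]]
arma::umat knn_cpp(const arma::mat& B, const arma::mat& X, int K) {
  if (B.n_rows != X.n_rows) stop("dimension mismatch between descriptors and codebook");
  const arma::uword m = B.n_cols, n = X.n_cols;
  if (K < 1 || (arma::uword)K > m) stop("K out of range");
  arma::rowvec bn = arma::sum(arma::square(B), 0);
  arma::umat out(K, n);
  const arma::uword chunk = 8192;
  std::vector<std::pair<double, arma::uword> > buf(m);
  for (arma::uword s = 0; s < n; s += chunk) {
    const arma::uword e = std::min(s + chunk, n) - 1;
    arma::mat G = B.t() * X.cols(s, e);
    for (arma::uword j = 0; j < G.n_cols; ++j) {
      for (arma::uword i = 0; i < m; ++i)
        buf[i] = std::make_pair(bn(i) - 2.0 * G(i, j), i);
      std::partial_sort(buf.begin(), buf.begin() + K, buf.end());
      for (int k = 0; k < K; ++k) out(k, s + j) = buf[k].second + 1;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Lloyd k-means (assignment + update), empty clusters re-seeded from the
// farthest point, objective tracked per iteration
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List lloyd_cpp(const arma::mat& X, arma::mat C, int max_iter, double tol) {
  const arma::uword n = X.n_cols, m = C.n_cols;
  arma::rowvec xn = arma::sum(arma::square(X), 0);
  arma::uvec assign(n, arma::fill::zeros);
  std::vector<double> objs;
  double prev = arma::datum::inf;
  int it = 0;
  for (it = 0; it < max_iter; ++it) {
    arma::rowvec cn = arma::sum(arma::square(C), 0);
    arma::vec mind(n);
    const arma::uword chunk = 16384;
    for (arma::uword s = 0; s < n; s += chunk) {
      const arma::uword e = std::min(s + chunk, n) - 1;
      arma::mat G = C.t() * X.cols(s, e);
      for (arma::uword j = 0; j < G.n_cols; ++j) {
        double best = cn(0) - 2.0 * G(0, j);
        arma::uword bi = 0;
        for (arma::uword i = 1; i < m; ++i) {
          const double v = cn(i) - 2.0 * G(i, j);
          if (v < best) { best = v; bi = i; }
        }
        assign(s + j) = bi;
        double d2 = best + xn(s + j);
        mind(s + j) = d2 > 0 ? d2 : 0.0;
      }
    }
    const double obj = arma::accu(mind);
    objs.push_back(obj);
    // centroid update
    arma::mat Cn(C.n_rows, m, arma::fill::zeros);
    arma::vec cnt(m, arma::fill::zeros);
    for (arma::uword j = 0; j < n; ++j) {
      Cn.col(assign(j)) += X.col(j);
      cnt(assign(j)) += 1.0;
    }
    // re-seed empties from successively farthest points (deterministic)
    arma::uvec used(n, arma::fill::zeros);
    for (arma::uword i = 0; i < m; ++i) {
      if (cnt(i) > 0) { Cn.col(i) /= cnt(i); continue; }
      double best = -1.0; arma::uword bj = 0;
      for (arma::uword j = 0; j < n; ++j)
        if (!used(j) && mind(j) > best) { best = mind(j); bj = j; }
      used(bj) = 1;
      Cn.col(i) = X.col(bj);
    }
    const double rel = (prev == arma::datum::inf)
      ? arma::datum::inf
      : std::fabs(prev - obj) / std::max(prev, 1e-12);
    C = Cn;
    prev = obj;
    if (rel <= tol) { ++it; break; }
  }
  return List::create(_["centers"] = C, _["cluster"] = assign + 1,
                      _["objective"] = objs, _["iterations"] = it);
}

// ---------------------------------------------------------------------------
// ADMM for locality-constrained sparse coding
//   min ||x - Bc||^2 + lambda * sum_j d_j |c_j|   s.t.  1'c = 1
// Splitting c = y: the smooth term and the sum-to-one constraint live on y
// (equality enforced exactly via a KKT multiplier), the weighted l1 on c
// (elementwise soft-thresholding), scaled dual u.
// ---------------------------------------------------------------------------

// One LSC solve. Mbase is the bordered KKT matrix without the penalty block
// (2B'B with the sum-to-one border); Minv0 its inverse at the initial
// penalty mu0, shared across descriptors. The penalty is adapted by the
// standard residual-balancing rule (x2 / x0.5 when primal and dual residuals
// diverge by more than a decade), re-inverting the small KKT system locally
// when it changes; adaptation is deterministic.
static void admm_solve_one(const arma::mat& Mbase, const arma::mat& Minv0,
                           const arma::mat& B, const arma::vec& x,
                           const arma::vec& d, double lambda, double mu0,
                           double tol, int max_iter, arma::vec& c_out,
                           double& obj_out, int& iters_out, bool& conv_out,
                           double& resid_out) {
  const arma::uword m = B.n_cols;
  double mu = mu0;
  arma::vec Btx2 = 2.0 * (B.t() * x);
  // deterministic warm point: indicator at the nearest basis (each solve is
  // still independent across descriptors)
  arma::vec c(m, arma::fill::zeros), u(m, arma::fill::zeros), y(m);
  {
    arma::uword bi = 0;
    double best = arma::datum::inf;
    for (arma::uword i = 0; i < m; ++i) {
      const double d2 = arma::dot(B.col(i) - x, B.col(i) - x);
      if (d2 < best) { best = d2; bi = i; }
    }
    c(bi) = 1.0;
  }
  arma::vec y_prev(m, arma::fill::zeros);
  arma::vec thr = (lambda / (2.0 * mu)) * d;
  arma::vec rhs(m + 1);
  rhs(m) = 1.0;
  arma::mat Minv_local;                 // materialised only if mu changes
  const arma::mat* Minv = &Minv0;
  bool conv = false;
  int it = 0, last_adapt = 0;
  double resid = arma::datum::inf;
  const double alpha = 1.7;  // over-relaxation; does not change the optimum
  for (it = 0; it < max_iter; ++it) {
    rhs.head(m) = Btx2 + 2.0 * mu * (c + u);
    y = Minv->head_rows(m) * rhs;          // first m rows of the KKT solution
    const arma::vec yhat = alpha * y + (1.0 - alpha) * c;
    arma::vec z = yhat - u;
    for (arma::uword j = 0; j < m; ++j) {
      const double v = z(j), t = thr(j);
      c(j) = (v > t) ? v - t : ((v < -t) ? v + t : 0.0);
    }
    u += c - yhat;
    const double r1 = arma::abs(c - y).max();          // primal residual
    const double r2 = std::fabs(arma::accu(c) - 1.0);  // feasibility of c
    const double r3 = (it == 0) ? arma::datum::inf
      : 2.0 * mu * arma::abs(y - y_prev).max();        // dual residual
    y_prev = y;
    resid = std::max(r1, std::max(r2, r3));
    if (resid <= tol) { conv = true; ++it; break; }
    if (it >= 1 && it - last_adapt >= 5 && std::isfinite(r3)) {
      double fac = 0.0;
      if (r1 > 10.0 * r3 && mu < mu0 * 1024) fac = 2.0;
      else if (r3 > 10.0 * r1 && mu > mu0 / 1024) fac = 0.5;
      if (fac != 0.0) {
        mu *= fac;
        u /= fac;                         // keep the unscaled dual unchanged
        thr = (lambda / (2.0 * mu)) * d;
        arma::mat M = Mbase;
        M.submat(0, 0, m - 1, m - 1).diag() += 2.0 * mu;
        Minv_local = arma::inv(M);
        Minv = &Minv_local;
        last_adapt = it;
      }
    }
  }
  const arma::vec rvec = x - B * c;
  obj_out = arma::dot(rvec, rvec) + lambda * arma::accu(d % arma::abs(c));
  c_out = c;
  iters_out = it;
  conv_out = conv;
  resid_out = resid;
}

// Full-codebook LSC for all columns of X. D: m x n locality weights; if D has
// zero size it is computed as exp(dist(x, b_j)/sigma).
// [[Rcpp::export]]
List lsc_admm_cpp(const arma::mat& B, const arma::mat& X, double lambda,
                  double sigma, double mu, double tol, int max_iter,
                  const arma::mat& D) {
  if (B.n_rows != X.n_rows) stop("dimension mismatch between descriptors and codebook");
  const arma::uword m = B.n_cols, n = X.n_cols;
  const bool haveD = (D.n_elem > 0);
  if (haveD && (D.n_rows != m || D.n_cols != n)) stop("bad locality weight matrix");

  arma::mat Mbase(m + 1, m + 1, arma::fill::zeros);
  Mbase.submat(0, 0, m - 1, m - 1) = 2.0 * (B.t() * B);
  Mbase.submat(0, m, m - 1, m).ones();
  Mbase.submat(m, 0, m, m - 1).ones();
  arma::mat M0 = Mbase;
  M0.submat(0, 0, m - 1, m - 1).diag() += 2.0 * mu;
  arma::mat Minv0 = arma::inv(M0);

  arma::mat C(m, n);
  arma::vec obj(n), resid(n);
  arma::ivec iters(n), conv(n);
  for (arma::uword j = 0; j < n; ++j) {
    arma::vec x = X.col(j), d;
    if (haveD) d = D.col(j);
    else {
      d.set_size(m);
      for (arma::uword i = 0; i < m; ++i)
        d(i) = std::exp(arma::norm(x - B.col(i), 2) / sigma);
    }
    arma::vec c; double o; int itn; bool cv; double rs;
    admm_solve_one(Mbase, Minv0, B, x, d, lambda, mu, tol, max_iter,
                   c, o, itn, cv, rs);
    C.col(j) = c; obj(j) = o; iters(j) = itn; conv(j) = cv ? 1 : 0; resid(j) = rs;
  }
  return List::create(_["codes"] = C, _["objective"] = obj,
                      _["iterations"] = iters, _["converged"] = conv,
                      _["residual"] = resid);
}

// K-NN restricted LSC: solve in the span of each descriptor's K nearest
// codewords (indices precomputed, 1-based, K x n), scatter back to length m.
// [[Rcpp::export]]
List lsc_admm_knn_cpp(const arma::mat& B, const arma::mat& X,
                      const arma::umat& knn_idx, double lambda, double sigma,
                      double mu, double tol, int max_iter) {
  if (B.n_rows != X.n_rows) stop("dimension mismatch between descriptors and codebook");
  const arma::uword m = B.n_cols, n = X.n_cols, K = knn_idx.n_rows;
  if (knn_idx.n_cols != n) stop("bad knn index matrix");

  arma::mat C(m, n, arma::fill::zeros);
  arma::vec obj(n), resid(n);
  arma::ivec iters(n), conv(n);
  arma::mat Mi(K + 1, K + 1);
  for (arma::uword j = 0; j < n; ++j) {
    arma::vec x = X.col(j);
    arma::uvec sel = knn_idx.col(j) - 1;
    arma::mat Bi = B.cols(sel);
    arma::vec d(K);
    for (arma::uword k = 0; k < K; ++k)
      d(k) = std::exp(arma::norm(x - Bi.col(k), 2) / sigma);
    Mi.zeros();
    Mi.submat(0, 0, K - 1, K - 1) = 2.0 * (Bi.t() * Bi);
    Mi.submat(0, K, K - 1, K).ones();
    Mi.submat(K, 0, K, K - 1).ones();
    arma::mat M0 = Mi;
    M0.submat(0, 0, K - 1, K - 1).diag() += 2.0 * mu;
    arma::mat Minv0 = arma::inv(M0);
    arma::vec c; double o; int itn; bool cv; double rs;
    admm_solve_one(Mi, Minv0, Bi, x, d, lambda, mu, tol, max_iter,
                   c, o, itn, cv, rs);
    for (arma::uword k = 0; k < K; ++k) C(sel(k), j) = c(k);
    obj(j) = o; iters(j) = itn; conv(j) = cv ? 1 : 0; resid(j) = rs;
  }
  return List::create(_["codes"] = C, _["objective"] = obj,
                      _["iterations"] = iters, _["converged"] = conv,
                      _["residual"] = resid);
}

// ---------------------------------------------------------------------------
// Greedy vocabulary-tree descent over a flattened tree. Internal node j has
// its `branch` child centroids in columns [j*branch, (j+1)*branch) of
// `centers`; children(k, j) > 0 is the 1-based id of an internal child,
// children(k, j) < 0 encodes leaf index -children(k, j).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::ivec tree_quantize_cpp(const arma::mat& centers,
                             const arma::imat& children,
                             const arma::mat& X) {
  const arma::uword branch = children.n_rows, n = X.n_cols;
  if (centers.n_rows != X.n_rows) stop("dimension mismatch between descriptors and codebook");
  const arma::uword dim = X.n_rows;
  arma::ivec out(n);
  for (arma::uword j = 0; j < n; ++j) {
    const double* xp = X.colptr(j);
    long node = 1;                       // 1-based internal id, root first
    long leaf = -1;
    while (leaf < 0) {
      const arma::uword base = (node - 1) * branch;
      arma::uword bk = 0;
      double best = arma::datum::inf;
      for (arma::uword k = 0; k < branch; ++k) {
        const double* cp = centers.colptr(base + k);
        double d2 = 0.0;
        for (arma::uword t = 0; t < dim; ++t) {
          const double df = cp[t] - xp[t];
          d2 += df * df;
        }
        if (d2 < best) { best = d2; bk = k; }
      }
      const long nxt = children(bk, node - 1);
      if (nxt < 0) leaf = -nxt; else node = nxt;
    }
    out(j) = leaf;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Blob rasteriser for the synthetic endomicroscopy textures: anti-aliased
// discs with a Gaussian-falloff rim, combined by per-pixel maximum over a
// uniform background (stained nuclei do not sum).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::mat draw_blobs_cpp(int H, int W, const arma::vec& row, const arma::vec& col,
                         const arma::vec& radius, const arma::vec& amp,
                         double background, double edge_sigma) {
  arma::mat img(H, W, arma::fill::value(background));
  const arma::uword nb = row.n_elem;
  for (arma::uword b = 0; b < nb; ++b) {
    const double r = radius(b), a = amp(b), cr = row(b), cc = col(b);
    const double reach = r + 3.0 * edge_sigma;
    const int r0 = std::max(0, (int)std::floor(cr - reach));
    const int r1 = std::min(H - 1, (int)std::ceil(cr + reach));
    const int c0 = std::max(0, (int)std::floor(cc - reach));
    const int c1 = std::min(W - 1, (int)std::ceil(cc + reach));
    for (int i = r0; i <= r1; ++i) {
      for (int j = c0; j <= c1; ++j) {
        const double dist = std::sqrt((i - cr) * (i - cr) + (j - cc) * (j - cc));
        double v;
        if (dist <= r) v = a;
        else {
          const double t = dist - r;
          v = a * std::exp(-(t * t) / (2.0 * edge_sigma * edge_sigma));
        }
        if (v > img(i, j)) img(i, j) = v;
      }
    }
  }
  return img;
}
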