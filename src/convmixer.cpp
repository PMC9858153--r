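// ConvMixer forward/backward engine.
//
// Activations for a whole batch live in one matrix A of shape
// (npos * n_images) x hidden_dim: column ch is channel ch for every patch
// position of every image, with image i occupying the contiguous row slab
// [i*npos, (i+1)*npos). Each slab is a column-major gh x gw grid. This
// layout turns the patch embedding and pointwise convolutions into single
// large GEMMs, makes batch-norm statistics contiguous column reductions,
// and gives the depthwise convolution a contiguous grid per
// (image, channel) for tight scalar loops.
//
// GELU uses the tanh approximation 0.5 z (1 + tanh(c (z + 0.044715 z^3)));
// the tanh factors are cached in training so the backward pass is purely
// polynomial. Batch normalization uses batch statistics (biased variance)
// in training and running statistics at inference.
//
// All large intermediates live in a persistent workspace that is reused
// across calls: a training iteration touches ~1.5 GB of activation and
// cache buffers, and freeing them each call would spend as much time in
// kernel page handling as in arithmetic. Matrix assignment in Armadillo
// reuses an existing allocation when the shape is unchanged, and swap()
// moves buffers without copying. cm_release_workspace() frees everything.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct CMConfig {
  int in_h, in_w, in_c, patch, hdim, depth, k, n_classes;
  bool pre_act;
  double bn_eps;
  int gh, gw, npos;
};

static CMConfig parse_cfg(const List& cfg) {
  CMConfig c;
  c.in_h = as<int>(cfg["in_h"]);
  c.in_w = as<int>(cfg["in_w"]);
  c.in_c = as<int>(cfg["in_c"]);
  c.patch = as<int>(cfg["patch"]);
  c.hdim = as<int>(cfg["hdim"]);
  c.depth = as<int>(cfg["depth"]);
  c.k = as<int>(cfg["k"]);
  c.n_classes = as<int>(cfg["n_classes"]);
  c.pre_act = as<bool>(cfg["pre_act"]);
  c.bn_eps = as<double>(cfg["bn_eps"]);
  if (c.k % 2 == 0) stop("Depthwise kernel size must be odd.");
  c.gh = (c.in_h - c.patch) / c.patch + 1;
  c.gw = (c.in_w - c.patch) / c.patch + 1;
  if (c.gh < 1 || c.gw < 1) stop("Input smaller than one patch.");
  c.npos = c.gh * c.gw;
  return c;
}

// ---- persistent workspace ------------------------------------------------

struct CMWorkspace {
  mat P, Z0, T0, A, U, G, B, Tmp, Apre, dA, dR, dRes;
  std::vector<mat> Xin, Uc, Rc, Wc, Tu, Tw;
};
static CMWorkspace ws;

// [[Rcpp::export]]
void cm_release_workspace() {
  ws = CMWorkspace();
}

// ---- GELU (tanh approximation) -------------------------------------------

static const double GELU_C = 0.79788456080286535588;  // sqrt(2/pi)
static const double GELU_A = 0.044715;

// training: act = gelu(Z), T = cached tanh factor
static void gelu_fwd(const mat& Z, mat& act, mat& T) {
  act.set_size(Z.n_rows, Z.n_cols);
  T.set_size(Z.n_rows, Z.n_cols);
  const double* z = Z.memptr();
  double* a = act.memptr();
  double* t = T.memptr();
  const size_t n = Z.n_elem;
  for (size_t j = 0; j < n; ++j) {
    const double zz = z[j];
    const double tt = std::tanh(GELU_C * (zz + GELU_A * zz * zz * zz));
    t[j] = tt;
    a[j] = 0.5 * zz * (1.0 + tt);
  }
}

// inference: Z <- gelu(Z)
static void gelu_inplace(mat& Z) {
  double* z = Z.memptr();
  const size_t n = Z.n_elem;
  for (size_t j = 0; j < n; ++j) {
    const double zz = z[j];
    z[j] = 0.5 * zz * (1.0 + std::tanh(GELU_C * (zz + GELU_A * zz * zz * zz)));
  }
}

// recompute act = 0.5 z (1 + T) from caches, into out
static void gelu_from_T_into(const mat& Z, const mat& T, mat& out) {
  out.set_size(Z.n_rows, Z.n_cols);
  const double* z = Z.memptr();
  const double* t = T.memptr();
  double* o = out.memptr();
  const size_t n = Z.n_elem;
  for (size_t j = 0; j < n; ++j) o[j] = 0.5 * z[j] * (1.0 + t[j]);
}

// dY <- dY * gelu'(Z), with T cached (polynomial only: tanh' = 1 - T^2)
static void dgelu_mult_inplace(mat& dY, const mat& Z, const mat& T) {
  double* d = dY.memptr();
  const double* z = Z.memptr();
  const double* t = T.memptr();
  const size_t n = dY.n_elem;
  for (size_t j = 0; j < n; ++j) {
    const double zz = z[j], tt = t[j];
    const double inner = GELU_C * (1.0 + 3.0 * GELU_A * zz * zz);
    d[j] *= 0.5 * (1.0 + tt) + 0.5 * zz * (1.0 - tt * tt) * inner;
  }
}

// ---- patch extraction ----------------------------------------------------

// patch-feature matrix: (patch*patch*in_c) x (npos * n)
static void build_patches(const double* X, int n, const CMConfig& c, mat& P) {
  const int pp = c.patch * c.patch;
  const size_t img_len = (size_t)c.in_h * c.in_w * c.in_c;
  P.set_size(pp * c.in_c, (size_t)c.npos * n);
  for (int i = 0; i < n; ++i) {
    const double* img = X + (size_t)i * img_len;
    for (int gx = 0; gx < c.gw; ++gx) {
      for (int gy = 0; gy < c.gh; ++gy) {
        double* col = P.colptr((size_t)i * c.npos + gx * c.gh + gy);
        for (int ch = 0; ch < c.in_c; ++ch) {
          const double* plane = img + (size_t)ch * c.in_h * c.in_w;
          for (int dx = 0; dx < c.patch; ++dx) {
            const double* src = plane + (size_t)(gx * c.patch + dx) * c.in_h +
                                gy * c.patch;
            std::copy(src, src + c.patch, col + ch * pp + dx * c.patch);
          }
        }
      }
    }
  }
}

// ---- depthwise convolution ----------------------------------------------

// same-padded correlation on one contiguous gh x gw grid
static void dw_slab(const double* G, double* O, const double* K, int gh,
                    int gw, int k) {
  const int r = k / 2;
  for (int x = 0; x < gw; ++x) {
    const int dx0 = std::max(-r, -x), dx1 = std::min(r, gw - 1 - x);
    for (int y = 0; y < gh; ++y) {
      const int dy0 = std::max(-r, -y), dy1 = std::min(r, gh - 1 - y);
      double s = 0.0;
      for (int dx = dx0; dx <= dx1; ++dx) {
        const double* gcol = G + (size_t)(x + dx) * gh + y;
        const double* krow = K + (dx + r) * k + r;
        for (int dy = dy0; dy <= dy1; ++dy) s += krow[dy] * gcol[dy];
      }
      O[y + (size_t)gh * x] = s;
    }
  }
}

// backward through one grid: accumulate dK and dG (dG must be zeroed)
static void dw_slab_bwd(const double* G, const double* dO, const double* K,
                        double* dK, double* dG, int gh, int gw, int k) {
  const int r = k / 2;
  for (int x = 0; x < gw; ++x) {
    const int dx0 = std::max(-r, -x), dx1 = std::min(r, gw - 1 - x);
    for (int y = 0; y < gh; ++y) {
      const int dy0 = std::max(-r, -y), dy1 = std::min(r, gh - 1 - y);
      const double d = dO[y + (size_t)gh * x];
      if (d == 0.0) continue;
      for (int dx = dx0; dx <= dx1; ++dx) {
        const double* gcol = G + (size_t)(x + dx) * gh + y;
        double* dgcol = dG + (size_t)(x + dx) * gh + y;
        const double* krow = K + (dx + r) * k + r;
        double* dkrow = dK + (dx + r) * k + r;
        for (int dy = dy0; dy <= dy1; ++dy) {
          dkrow[dy] += d * gcol[dy];
          dgcol[dy] += d * krow[dy];
        }
      }
    }
  }
}

// depthwise conv of the whole batch matrix A ((npos*n) x h), into out
static void dwconv_all(const mat& A, const mat& K, const vec& b, int n,
                       const CMConfig& c, mat& out) {
  out.set_size(A.n_rows, A.n_cols);
  for (int ch = 0; ch < c.hdim; ++ch) {
    std::vector<double> kk(c.k * c.k);
    for (int j = 0; j < c.k * c.k; ++j) kk[j] = K(ch, j);
    const double* src = A.colptr(ch);
    double* dst = out.colptr(ch);
    const double bias = b(ch);
    for (int i = 0; i < n; ++i) {
      dw_slab(src + (size_t)i * c.npos, dst + (size_t)i * c.npos, kk.data(),
              c.gh, c.gw, c.k);
    }
    for (size_t j = 0; j < (size_t)c.npos * n; ++j) dst[j] += bias;
  }
}

static void dwconv_all_bwd(const mat& A, const mat& dOut, const mat& K,
                           mat& dK, vec& db, int n, const CMConfig& c,
                           mat& dA) {
  dA.set_size(A.n_rows, A.n_cols);
  dA.zeros();
  for (int ch = 0; ch < c.hdim; ++ch) {
    std::vector<double> kk(c.k * c.k), dkk(c.k * c.k, 0.0);
    for (int j = 0; j < c.k * c.k; ++j) kk[j] = K(ch, j);
    const double* src = A.colptr(ch);
    const double* dsrc = dOut.colptr(ch);
    double* ddst = dA.colptr(ch);
    double bsum = 0.0;
    for (int i = 0; i < n; ++i) {
      const size_t off = (size_t)i * c.npos;
      dw_slab_bwd(src + off, dsrc + off, kk.data(), dkk.data(), ddst + off,
                  c.gh, c.gw, c.k);
    }
    for (size_t j = 0; j < (size_t)c.npos * n; ++j) bsum += dsrc[j];
    for (int j = 0; j < c.k * c.k; ++j) dK(ch, j) += dkk[j];
    db(ch) += bsum;
  }
}

// ---- batch normalization (fused single-pass column loops) ----------------

struct BNStats { vec mu, invstd, var; };

static BNStats bn_stats(const mat& A, double eps) {
  const int h = A.n_cols;
  const size_t N = A.n_rows;
  BNStats st;
  st.mu.set_size(h); st.var.set_size(h); st.invstd.set_size(h);
  for (int ch = 0; ch < h; ++ch) {
    const double* p = A.colptr(ch);
    double s = 0.0, s2 = 0.0;
    for (size_t j = 0; j < N; ++j) { s += p[j]; s2 += p[j] * p[j]; }
    const double mu = s / N;
    double v = s2 / N - mu * mu;
    if (v < 0) v = 0;
    st.mu(ch) = mu; st.var(ch) = v;
    st.invstd(ch) = 1.0 / std::sqrt(v + eps);
  }
  return st;
}

static void bn_inplace(mat& A, const BNStats& st, const vec& gamma,
                       const vec& beta) {
  const size_t N = A.n_rows;
  for (int ch = 0; ch < (int)A.n_cols; ++ch) {
    const double g = st.invstd(ch) * gamma(ch);
    const double b = beta(ch) - st.mu(ch) * g;
    double* p = A.colptr(ch);
    for (size_t j = 0; j < N; ++j) p[j] = p[j] * g + b;
  }
}

static void bn_running_inplace(mat& A, const vec& rmu, const vec& rvar,
                               const vec& gamma, const vec& beta, double eps) {
  const size_t N = A.n_rows;
  for (int ch = 0; ch < (int)A.n_cols; ++ch) {
    const double g = gamma(ch) / std::sqrt(rvar(ch) + eps);
    const double b = beta(ch) - rmu(ch) * g;
    double* p = A.colptr(ch);
    for (size_t j = 0; j < N; ++j) p[j] = p[j] * g + b;
  }
}

// ---- pooling -------------------------------------------------------------

// global average pool: (npos*n) x h -> n x h
static mat pool_all(const mat& A, int n, const CMConfig& c) {
  mat F(n, c.hdim);
  const double inv = 1.0 / c.npos;
  for (int ch = 0; ch < c.hdim; ++ch) {
    const double* src = A.colptr(ch);
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      const double* p = src + (size_t)i * c.npos;
      for (int j = 0; j < c.npos; ++j) s += p[j];
      F(i, ch) = s * inv;
    }
  }
  return F;
}

// broadcast pooled gradient back over positions: n x h -> (npos*n) x h
static void unpool_all(const mat& dF, int n, const CMConfig& c, mat& dA) {
  dA.set_size((size_t)c.npos * n, c.hdim);
  const double inv = 1.0 / c.npos;
  for (int ch = 0; ch < c.hdim; ++ch) {
    double* dst = dA.colptr(ch);
    for (int i = 0; i < n; ++i) {
      const double v = dF(i, ch) * inv;
      double* p = dst + (size_t)i * c.npos;
      for (int j = 0; j < c.npos; ++j) p[j] = v;
    }
  }
}

// row-wise softmax of an n x classes matrix, in place
static void softmax_rows(mat& L) {
  vec m = max(L, 1);
  L.each_col() -= m;
  L = exp(L);
  vec s = sum(L, 1);
  L.each_col() /= s;
}

// ---- main entry ----------------------------------------------------------

// [[Rcpp::export]]
List cm_run(NumericVector X4d, IntegerVector y, List params, List cfg_list,
            NumericMatrix run_mean, NumericMatrix run_var, bool training,
            bool want_grad) {
  CMConfig c = parse_cfg(cfg_list);
  IntegerVector dims = X4d.attr("dim");
  int n;
  if (dims.size() == 4) n = dims[3];
  else if (dims.size() == 3) n = 1;
  else stop("Image input must be a 3- or 4-dimensional array.");
  if (dims[0] != c.in_h || dims[1] != c.in_w || dims[2] != c.in_c)
    stop("Image dimensions do not match the model configuration.");
  if (n < 1) stop("Empty batch.");
  const bool have_y = y.size() > 0;
  if (want_grad && (!training || !have_y))
    stop("Gradients require training mode and labels.");
  if (have_y && y.size() != n) stop("Label length must match batch size.");

  const mat We = as<mat>(params["We"]);        // h x (pp*c)
  const vec be = as<vec>(params["be"]);
  const mat bn_gamma = as<mat>(params["bn_gamma"]);  // h x (2*depth+1)
  const mat bn_beta = as<mat>(params["bn_beta"]);
  cube dwW = as<cube>(params["dwW"]);          // h x k*k x depth
  const mat dwb = as<mat>(params["dwb"]);
  cube pwW = as<cube>(params["pwW"]);          // h x h x depth  [out, in]
  const mat pwb = as<mat>(params["pwb"]);
  const mat fcW = as<mat>(params["fcW"]);      // classes x h
  const vec fcb = as<vec>(params["fcb"]);
  const int n_bn = 2 * c.depth + 1;

  std::vector<BNStats> st(n_bn);
  const mat rmu(run_mean.begin(), run_mean.nrow(), run_mean.ncol());
  const mat rvar(run_var.begin(), run_var.nrow(), run_var.ncol());
  if (!training &&
      ((int)rmu.n_cols != n_bn || (int)rmu.n_rows != c.hdim))
    stop("Running BN statistics have the wrong shape.");

  build_patches(REAL(X4d), n, c, ws.P);        // (pp*c) x (npos*n)

  if (training) {
    if ((int)ws.Xin.size() != c.depth) {
      ws.Xin.assign(c.depth, mat());
      ws.Uc.assign(c.depth, mat());
      ws.Rc.assign(c.depth, mat());
      ws.Wc.assign(c.depth, mat());
      ws.Tu.assign(c.depth, mat());
      ws.Tw.assign(c.depth, mat());
    }
    ws.Z0 = ws.P.t() * We.t();                 // (npos*n) x h
    ws.Z0.each_row() += be.t();
    gelu_fwd(ws.Z0, ws.A, ws.T0);
    st[0] = bn_stats(ws.A, c.bn_eps);
    bn_inplace(ws.A, st[0], bn_gamma.col(0), bn_beta.col(0));

    for (int d = 0; d < c.depth; ++d) {
      const int b1 = 2 * d + 1, b2 = 2 * d + 2;
      ws.Xin[d] = ws.A;
      dwconv_all(ws.A, dwW.slice(d), dwb.col(d), n, c, ws.U);
      if (c.pre_act) ws.U += ws.A;
      gelu_fwd(ws.U, ws.G, ws.Tmp);
      ws.Tu[d].swap(ws.Tmp);
      ws.Uc[d].swap(ws.U);
      st[b1] = bn_stats(ws.G, c.bn_eps);
      bn_inplace(ws.G, st[b1], bn_gamma.col(b1), bn_beta.col(b1));
      if (!c.pre_act) ws.G += ws.A;            // residual: R = Xin + V
      ws.Rc[d].swap(ws.G);                     // Rc[d] = pointwise input R
      ws.B = ws.Rc[d] * pwW.slice(d).t();
      ws.B.each_row() += pwb.col(d).t();
      gelu_fwd(ws.B, ws.G, ws.Tmp);
      ws.Tw[d].swap(ws.Tmp);
      ws.Wc[d].swap(ws.B);
      st[b2] = bn_stats(ws.G, c.bn_eps);
      bn_inplace(ws.G, st[b2], bn_gamma.col(b2), bn_beta.col(b2));
      ws.A.swap(ws.G);
    }
  } else {
    ws.A = ws.P.t() * We.t();
    ws.A.each_row() += be.t();
    gelu_inplace(ws.A);
    bn_running_inplace(ws.A, rmu.col(0), rvar.col(0), bn_gamma.col(0),
                       bn_beta.col(0), c.bn_eps);
    for (int d = 0; d < c.depth; ++d) {
      const int b1 = 2 * d + 1, b2 = 2 * d + 2;
      dwconv_all(ws.A, dwW.slice(d), dwb.col(d), n, c, ws.U);
      if (c.pre_act) ws.U += ws.A;
      gelu_inplace(ws.U);
      bn_running_inplace(ws.U, rmu.col(b1), rvar.col(b1), bn_gamma.col(b1),
                         bn_beta.col(b1), c.bn_eps);
      if (!c.pre_act) ws.U += ws.A;            // residual: R = Xin + V
      ws.B = ws.U * pwW.slice(d).t();
      ws.B.each_row() += pwb.col(d).t();
      gelu_inplace(ws.B);
      bn_running_inplace(ws.B, rmu.col(b2), rvar.col(b2), bn_gamma.col(b2),
                         bn_beta.col(b2), c.bn_eps);
      ws.A.swap(ws.B);
    }
  }

  mat F = pool_all(ws.A, n, c);                // n x h
  mat logits = F * fcW.t();
  logits.each_row() += fcb.t();
  mat probs = logits;
  softmax_rows(probs);

  double loss = NA_REAL;
  if (have_y) {
    loss = 0.0;
    for (int i = 0; i < n; ++i)
      loss += -std::log(std::max(probs(i, y[i]), 1e-300));
    loss /= n;
  }

  List out = List::create(Named("probs") = probs);
  if (have_y) out["loss"] = loss;
  if (training) {
    mat batch_mu(c.hdim, n_bn), batch_var(c.hdim, n_bn);
    for (int b = 0; b < n_bn; ++b) {
      batch_mu.col(b) = st[b].mu;
      batch_var.col(b) = st[b].var;
    }
    out["bn_mean"] = batch_mu;
    out["bn_var"] = batch_var;
  }
  if (!want_grad) return out;

  // ---------------- backward ----------------
  mat dbn_gamma(c.hdim, n_bn, fill::zeros), dbn_beta(c.hdim, n_bn, fill::zeros);
  cube ddwW(size(dwW), fill::zeros);
  mat ddwb(c.hdim, c.depth, fill::zeros);
  cube dpwW(size(pwW), fill::zeros);
  mat dpwb(c.hdim, c.depth, fill::zeros);

  mat dlogits = probs;  // n x classes
  for (int i = 0; i < n; ++i) dlogits(i, y[i]) -= 1.0;
  dlogits /= (double)n;
  mat dfcW = dlogits.t() * F;
  vec dfcb = sum(dlogits, 0).t();
  mat dF = dlogits * fcW;  // n x h
  unpool_all(dF, n, c, ws.dA);

  // backward through BN layer b; Apre holds the cached pre-BN activations
  // (left intact); dY is replaced by the input gradient. Fused per-column
  // loops: two passes, no temporaries.
  auto bn_backward = [&](int b, const mat& Apre, mat& dY) {
    const double N = (double)Apre.n_rows;
    const size_t NN = Apre.n_rows;
    for (int ch = 0; ch < c.hdim; ++ch) {
      const double mu = st[b].mu(ch), invstd = st[b].invstd(ch);
      const double* a = Apre.colptr(ch);
      double* dy = dY.colptr(ch);
      double s_dy = 0.0, s_dyx = 0.0;
      for (size_t j = 0; j < NN; ++j) {
        s_dy += dy[j];
        s_dyx += dy[j] * (a[j] - mu) * invstd;
      }
      dbn_beta(ch, b) += s_dy;
      dbn_gamma(ch, b) += s_dyx;
      const double g_inv = bn_gamma(ch, b) * invstd / N;
      for (size_t j = 0; j < NN; ++j) {
        const double xhat = (a[j] - mu) * invstd;
        dy[j] = g_inv * (N * dy[j] - s_dy - xhat * s_dyx);
      }
    }
  };

  for (int d = c.depth - 1; d >= 0; --d) {
    const int b1 = 2 * d + 1, b2 = 2 * d + 2;
    gelu_from_T_into(ws.Wc[d], ws.Tw[d], ws.Apre);
    bn_backward(b2, ws.Apre, ws.dA);               // dA = grad wrt gelu(W)
    dgelu_mult_inplace(ws.dA, ws.Wc[d], ws.Tw[d]); // grad wrt W
    dpwW.slice(d) += ws.dA.t() * ws.Rc[d];
    dpwb.col(d) += sum(ws.dA, 0).t();
    ws.dR = ws.dA * pwW.slice(d);
    if (!c.pre_act) ws.dRes = ws.dR;               // residual branch into Xin
    gelu_from_T_into(ws.Uc[d], ws.Tu[d], ws.Apre);
    bn_backward(b1, ws.Apre, ws.dR);               // dR = grad wrt gelu(U)
    dgelu_mult_inplace(ws.dR, ws.Uc[d], ws.Tu[d]); // grad wrt U
    vec dbtmp(c.hdim, fill::zeros);
    dwconv_all_bwd(ws.Xin[d], ws.dR, dwW.slice(d), ddwW.slice(d), dbtmp, n, c,
                   ws.dA);
    ddwb.col(d) += dbtmp;
    if (c.pre_act) ws.dA += ws.dR; else ws.dA += ws.dRes;
  }
  gelu_from_T_into(ws.Z0, ws.T0, ws.Apre);
  bn_backward(0, ws.Apre, ws.dA);
  dgelu_mult_inplace(ws.dA, ws.Z0, ws.T0);
  mat dWe = ws.dA.t() * ws.P.t();  // h x (pp*c)
  vec dbe = sum(ws.dA, 0).t();

  out["grads"] = List::create(
      Named("We") = dWe, Named("be") = dbe,
      Named("bn_gamma") = dbn_gamma, Named("bn_beta") = dbn_beta,
      Named("dwW") = ddwW, Named("dwb") = ddwb,
      Named("pwW") = dpwW, Named("pwb") = dpwb,
      Named("fcW") = dfcW, Named("fcb") = dfcb);
  return out;
}

// ---- allocator tuning ----------------------------------------------------
// Large freed blocks default to mmap/munmap round trips; raising the
// thresholds keeps transient buffers in the process heap for reuse.
#ifdef __GLIBC__
#include <malloc.h>
#endif

// [[Rcpp::export]]
void cm_tune_allocator() {
#ifdef __GLIBC__
  // glibc caps M_MMAP_THRESHOLD at 32 MiB on 64-bit systems
  mallopt(M_MMAP_THRESHOLD, 32 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 128 * 1024 * 1024);
#endif
}
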