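// Minimal CNN primitives for the per-class binary UNet: 3x3 'same' convolution
// via im2col + GEMM, 2x2 max pooling, and their backward passes. Doubles
// throughout; single-threaded determinism is inherited from BLAS.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// im2col for a 3x3 kernel with zero padding 1: rows index pixels
// (column-major, matching R array layout), cols index (channel, kj, ki).
static arma::mat im2col3(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat cols(H * (long long)W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = c * 9 + (dj + 1) * 3 + (di + 1);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          const double* src = &x(i0 + di, j + dj, c);
          double* dst = cols.colptr(k) + (long long)j * H + i0;
          std::copy(src, src + (i1 - i0), dst);
        }
      }
    }
  }
  return cols;
}

// scatter-add of column gradients back onto the padded input
static arma::cube col2im3(const arma::mat& dcols, int H, int W, int C) {
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        const int k = c * 9 + (dj + 1) * 3 + (di + 1);
        const int j0 = std::max(0, -dj), j1 = std::min(W, W - dj);
        const int i0 = std::max(0, -di), i1 = std::min(H, H - di);
        for (int j = j0; j < j1; ++j) {
          const double* src = dcols.colptr(k) + (long long)j * H + i0;
          double* dst = &dx(i0 + di, j + dj, c);
          for (int i = 0; i < i1 - i0; ++i) dst[i] += src[i];
        }
      }
    }
  }
  return dx;
}

// [[Rcpp::export]]
List cpp_conv3_fwd(const arma::cube& x, const arma::mat& w, const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat out = im2col3(x) * w;
  out.each_row() += b.t();
  arma::cube y(out.memptr(), H, W, Cout);
  return List::create(_["out"] = y);
}

// Forward keeping the im2col matrix for the backward pass.
// [[Rcpp::export]]
List cpp_conv3_fwd_cache(const arma::cube& x, const arma::mat& w, const arma::vec& b) {
  const int H = x.n_rows, W = x.n_cols;
  const int Cout = w.n_cols;
  arma::mat cols = im2col3(x);
  arma::mat out = cols * w;
  out.each_row() += b.t();
  arma::cube y(out.memptr(), H, W, Cout);
  return List::create(_["out"] = y, _["cols"] = cols);
}

// [[Rcpp::export]]
List cpp_conv3_bwd(const arma::cube& gout, const arma::mat& cols,
                   const arma::mat& w, int cin) {
  const int H = gout.n_rows, W = gout.n_cols, Cout = gout.n_slices;
  arma::mat g(const_cast<double*>(gout.memptr()), (long long)H * W, Cout,
              false, true);
  arma::mat dw = cols.t() * g;
  arma::vec db = arma::sum(g, 0).t();
  arma::mat dcols = g * w.t();
  arma::cube dx = col2im3(dcols, H, W, cin);
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}

// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube idx(Ho, Wo, C); // linear index into the input slice
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < Wo; ++j) {
      for (int i = 0; i < Ho; ++i) {
        const int ii = 2 * i, jj = 2 * j;
        double best = x(ii, jj, c);
        long long bi = (long long)jj * H + ii;
        const int di[3] = {1, 0, 1}, dj[3] = {0, 1, 1};
        for (int k = 0; k < 3; ++k) {
          double v = x(ii + di[k], jj + dj[k], c);
          if (v > best) { best = v; bi = (long long)(jj + dj[k]) * H + ii + di[k]; }
        }
        y(i, j, c) = best;
        idx(i, j, c) = bi;
      }
    }
  }
  return List::create(_["out"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& gout, const arma::ucube& idx,
                            int H, int W) {
  const int Ho = gout.n_rows, Wo = gout.n_cols, C = gout.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* slice = dx.slice_memptr(c);
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i)
        slice[idx(i, j, c)] += gout(i, j, c);
  }
  return dx;
}

// ---------------------------------------------------------------------------
// Whole-network forward/backward for one tile, kept in C++ so the training
// loop does not shuttle per-layer caches through R. The parameter list uses
// the same names as the R side: enc{d}_1/2, bott_1/2, dec{d}_1/2, out.

struct ConvCache {
  arma::mat cols; // im2col of the layer input
  arma::cube z;   // pre-activation
  int cin;
};

static arma::cube conv_relu_fwd(const arma::cube& x, const arma::mat& w,
                                const arma::vec& b, ConvCache& cc,
                                bool keep_cache) {
  const int H = x.n_rows, W = x.n_cols;
  arma::mat cols = im2col3(x);
  arma::mat out = cols * w;
  out.each_row() += b.t();
  arma::cube z(out.memptr(), H, W, w.n_cols);
  if (keep_cache) {
    cc.cols = std::move(cols);
    cc.z = z;
    cc.cin = x.n_slices;
  }
  z.transform([](double v) { return v > 0 ? v : 0.0; });
  return z;
}

static arma::cube conv_relu_bwd(const arma::cube& gout, const ConvCache& cc,
                                const arma::mat& w, arma::mat& dw, arma::vec& db) {
  const int H = gout.n_rows, W = gout.n_cols, Cout = gout.n_slices;
  arma::mat g((long long)H * W, Cout);
  const double* zp = cc.z.memptr();
  const double* gp = gout.memptr();
  double* gm = g.memptr();
  const long long n = (long long)H * W * Cout;
  for (long long k = 0; k < n; ++k) gm[k] = zp[k] > 0 ? gp[k] : 0.0;
  dw = cc.cols.t() * g;
  db = arma::sum(g, 0).t();
  arma::mat dcols = g * w.t();
  return col2im3(dcols, H, W, cc.cin);
}

static arma::cube upsample2_cpp(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v; y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

static arma::cube downsum2_cpp(const arma::cube& g) {
  const int H = g.n_rows / 2, W = g.n_cols / 2, C = g.n_slices;
  arma::cube y(H, W, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i)
        y(i, j, c) = g(2 * i, 2 * j, c) + g(2 * i + 1, 2 * j, c) +
                     g(2 * i, 2 * j + 1, c) + g(2 * i + 1, 2 * j + 1, c);
  return y;
}

static void get_wb(const List& params, const std::string& nm, arma::mat& w,
                   arma::vec& b) {
  List p = params[nm];
  w = as<arma::mat>(p["w"]);
  b = as<arma::vec>(p["b"]);
}

struct UnetState {
  std::vector<ConvCache> enc1, enc2; // per depth
  std::vector<arma::cube> skips;
  std::vector<arma::ucube> pool_idx;
  std::vector<arma::uword> pool_h, pool_w;
  ConvCache bott1, bott2;
  std::vector<ConvCache> dec1, dec2;
  arma::cube head_in;
  arma::mat prob;
};

static void unet_fwd_cpp(const arma::cube& x, const List& params, int depth,
                         bool keep, UnetState& st) {
  arma::mat w; arma::vec b;
  arma::cube cur = x;
  st.enc1.resize(depth); st.enc2.resize(depth);
  st.skips.resize(depth); st.pool_idx.resize(depth);
  st.pool_h.resize(depth); st.pool_w.resize(depth);
  st.dec1.resize(depth); st.dec2.resize(depth);
  for (int d = 0; d < depth; ++d) {
    std::string pre = "enc" + std::to_string(d + 1);
    get_wb(params, pre + "_1", w, b);
    cur = conv_relu_fwd(cur, w, b, st.enc1[d], keep);
    get_wb(params, pre + "_2", w, b);
    cur = conv_relu_fwd(cur, w, b, st.enc2[d], keep);
    st.skips[d] = cur;
    st.pool_h[d] = cur.n_rows; st.pool_w[d] = cur.n_cols;
    // 2x2 max pool with argmax bookkeeping
    const int Ho = cur.n_rows / 2, Wo = cur.n_cols / 2, C = cur.n_slices;
    arma::cube pooled(Ho, Wo, C);
    arma::ucube idx(Ho, Wo, C);
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          const int ii = 2 * i, jj = 2 * j;
          double best = cur(ii, jj, c);
          arma::uword bi = (arma::uword)jj * cur.n_rows + ii;
          const int di[3] = {1, 0, 1}, dj[3] = {0, 1, 1};
          for (int k = 0; k < 3; ++k) {
            double vv = cur(ii + di[k], jj + dj[k], c);
            if (vv > best) { best = vv; bi = (arma::uword)(jj + dj[k]) * cur.n_rows + ii + di[k]; }
          }
          pooled(i, j, c) = best;
          idx(i, j, c) = bi;
        }
    if (keep) st.pool_idx[d] = idx;
    cur = pooled;
  }
  get_wb(params, "bott_1", w, b);
  cur = conv_relu_fwd(cur, w, b, st.bott1, keep);
  get_wb(params, "bott_2", w, b);
  cur = conv_relu_fwd(cur, w, b, st.bott2, keep);
  for (int d = depth - 1; d >= 0; --d) {
    arma::cube up = upsample2_cpp(cur);
    arma::cube cat = arma::join_slices(up, st.skips[d]);
    std::string pre = "dec" + std::to_string(d + 1);
    get_wb(params, pre + "_1", w, b);
    cur = conv_relu_fwd(cat, w, b, st.dec1[d], keep);
    get_wb(params, pre + "_2", w, b);
    cur = conv_relu_fwd(cur, w, b, st.dec2[d], keep);
  }
  st.head_in = cur;
  get_wb(params, "out", w, b);
  const long long n = (long long)cur.n_rows * cur.n_cols;
  arma::mat flat(const_cast<double*>(cur.memptr()), n, cur.n_slices, false, true);
  arma::vec z = flat * w + b(0);
  st.prob = arma::mat(cur.n_rows, cur.n_cols);
  for (long long k = 0; k < n; ++k) st.prob(k) = 1.0 / (1.0 + std::exp(-z(k)));
}

// [[Rcpp::export]]
arma::mat cpp_unet_predict(const arma::cube& x, const List& params, int depth) {
  UnetState st;
  unet_fwd_cpp(x, params, depth, false, st);
  return st.prob;
}

// One tile's loss and parameter gradients (BCE, eps = 1e-7 clamp).
// [[Rcpp::export]]
List cpp_unet_grad(const arma::cube& x, const arma::mat& y, const List& params,
                   int depth) {
  UnetState st;
  unet_fwd_cpp(x, params, depth, true, st);
  const double eps = 1e-7;
  const long long n = (long long)y.n_elem;
  double loss = 0;
  arma::mat dz(y.n_rows, y.n_cols);
  for (long long k = 0; k < n; ++k) {
    double p = std::min(1.0 - eps, std::max(eps, st.prob(k)));
    loss += -(y(k) * std::log(p) + (1 - y(k)) * std::log(1 - p));
    dz(k) = (st.prob(k) - y(k)) / n;
  }
  loss /= n;

  List grads;
  arma::mat w; arma::vec b;
  // head
  get_wb(params, "out", w, b);
  const int hc = st.head_in.n_slices;
  arma::mat flat(st.head_in.memptr(), n, hc, false, true);
  arma::vec gz(dz.memptr(), n, false, true);
  arma::mat dw_out = flat.t() * gz;
  grads["out"] = List::create(_["w"] = dw_out,
                              _["b"] = arma::vec{arma::accu(gz)});
  arma::mat gflat = gz * w.t();
  arma::cube gcur(gflat.memptr(), st.head_in.n_rows, st.head_in.n_cols, hc);
  // decoder (shallowest first)
  for (int d = 0; d < depth; ++d) {
    std::string pre = "dec" + std::to_string(d + 1);
    arma::mat dw1, dw2; arma::vec db1, db2;
    get_wb(params, pre + "_2", w, b);
    arma::cube g1 = conv_relu_bwd(gcur, st.dec2[d], w, dw2, db2);
    get_wb(params, pre + "_1", w, b);
    arma::cube gcat = conv_relu_bwd(g1, st.dec1[d], w, dw1, db1);
    grads[pre + "_1"] = List::create(_["w"] = dw1, _["b"] = db1);
    grads[pre + "_2"] = List::create(_["w"] = dw2, _["b"] = db2);
    const int cskip = st.skips[d].n_slices;
    const int cup = gcat.n_slices - cskip;
    arma::cube dup = gcat.slices(0, cup - 1);
    st.skips[d] = gcat.slices(cup, gcat.n_slices - 1); // reuse as skip grad
    gcur = downsum2_cpp(dup);
  }
  // bottleneck
  {
    arma::mat dw1, dw2; arma::vec db1, db2;
    get_wb(params, "bott_2", w, b);
    arma::cube g1 = conv_relu_bwd(gcur, st.bott2, w, dw2, db2);
    get_wb(params, "bott_1", w, b);
    gcur = conv_relu_bwd(g1, st.bott1, w, dw1, db1);
    grads["bott_1"] = List::create(_["w"] = dw1, _["b"] = db1);
    grads["bott_2"] = List::create(_["w"] = dw2, _["b"] = db2);
  }
  // encoder (deepest first)
  for (int d = depth - 1; d >= 0; --d) {
    const int H = st.pool_h[d], W = st.pool_w[d];
    const int Ho = gcur.n_rows, Wo = gcur.n_cols, C = gcur.n_slices;
    arma::cube gpool(H, W, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c) {
      double* slice = gpool.slice_memptr(c);
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i)
          slice[st.pool_idx[d](i, j, c)] += gcur(i, j, c);
    }
    gpool += st.skips[d]; // skip-connection gradient
    std::string pre = "enc" + std::to_string(d + 1);
    arma::mat dw1, dw2; arma::vec db1, db2;
    get_wb(params, pre + "_2", w, b);
    arma::cube g1 = conv_relu_bwd(gpool, st.enc2[d], w, dw2, db2);
    get_wb(params, pre + "_1", w, b);
    gcur = conv_relu_bwd(g1, st.enc1[d], w, dw1, db1);
    grads[pre + "_1"] = List::create(_["w"] = dw1, _["b"] = db1);
    grads[pre + "_2"] = List::create(_["w"] = dw2, _["b"] = db2);
  }
  return List::create(_["loss"] = loss, _["grads"] = grads,
                      _["prob"] = st.prob);
}
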