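// Minimal seeded CNN engine: conv2d, transposed conv2d, fully-connected and
// residual layers with ReLU/sigmoid activations, trained by Adam on
// cross-entropy, MSE or logit-BCE losses. Batches are matrices with one
// flattened (H-fastest, then W, then channel) sample per column, matching the
// column-major layout of an R array dim c(H, W, C, N).
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;
using Rcpp::List;
using Rcpp::as;

struct ConvDims {
  int in_c, out_c, k, stride, pad;
  int in_h, in_w, out_h, out_w;
};

// x: flattened (in_h, in_w, in_c); returns (in_c*k*k) x (out_h*out_w),
// row r = c*k*k + ky*k + kx, column j = ox*out_h + oy. Out-of-frame taps are 0.
static void im2col_into(const double* x, const ConvDims& d, mat& col, int col0) {
  for (int c = 0; c < d.in_c; ++c) {
    const double* xc = x + (size_t)c * d.in_h * d.in_w;
    for (int ky = 0; ky < d.k; ++ky) {
      for (int kx = 0; kx < d.k; ++kx) {
        int r = c * d.k * d.k + ky * d.k + kx;
        for (int ox = 0; ox < d.out_w; ++ox) {
          int ix = ox * d.stride - d.pad + kx;
          double* dst = col.colptr(col0 + ox * d.out_h) + r;
          if (ix < 0 || ix >= d.in_w) {
            for (int oy = 0; oy < d.out_h; ++oy, dst += col.n_rows) *dst = 0.0;
          } else {
            const double* src = xc + (size_t)ix * d.in_h;
            for (int oy = 0; oy < d.out_h; ++oy, dst += col.n_rows) {
              int iy = oy * d.stride - d.pad + ky;
              *dst = (iy < 0 || iy >= d.in_h) ? 0.0 : src[iy];
            }
          }
        }
      }
    }
  }
}

// Accumulate columns back into a flattened image (inverse of im2col).
static void col2im_acc(const mat& col, int col0, const ConvDims& d, double* x) {
  for (int c = 0; c < d.in_c; ++c) {
    double* xc = x + (size_t)c * d.in_h * d.in_w;
    for (int ky = 0; ky < d.k; ++ky) {
      for (int kx = 0; kx < d.k; ++kx) {
        int r = c * d.k * d.k + ky * d.k + kx;
        for (int ox = 0; ox < d.out_w; ++ox) {
          int ix = ox * d.stride - d.pad + kx;
          if (ix < 0 || ix >= d.in_w) continue;
          const double* src = col.colptr(col0 + ox * d.out_h) + r;
          double* dst = xc + (size_t)ix * d.in_h;
          for (int oy = 0; oy < d.out_h; ++oy, src += col.n_rows) {
            int iy = oy * d.stride - d.pad + ky;
            if (iy >= 0 && iy < d.in_h) dst[iy] += *src;
          }
        }
      }
    }
  }
}

// conv forward for a batch: X (in_feat x B) -> Y (out_feat x B); caches col.
static mat conv_forward(const mat& X, const mat& W, const vec& b,
                        const ConvDims& d, mat& col_cache) {
  int B = X.n_cols, npos = d.out_h * d.out_w;
  col_cache.set_size(d.in_c * d.k * d.k, (size_t)B * npos);
  for (int s = 0; s < B; ++s) im2col_into(X.colptr(s), d, col_cache, s * npos);
  mat Y = W * col_cache;            // out_c x (B*npos)
  Y.each_col() += b;
  mat out(npos * d.out_c, B);
  for (int s = 0; s < B; ++s) {
    mat Ys = Y.cols((size_t)s * npos, (size_t)(s + 1) * npos - 1); // out_c x npos
    out.col(s) = vectorise(Ys.t());
  }
  return out;
}

// conv backward: grad wrt input, filter, bias.
static mat conv_backward(const mat& dOut, const mat& X, const mat& W,
                         const ConvDims& d, const mat& col_cache,
                         mat& dW, vec& db) {
  int B = X.n_cols, npos = d.out_h * d.out_w;
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(W.n_rows);
  mat dX(X.n_rows, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    mat dYs(dOut.colptr(s), npos, d.out_c);     // copy; npos x out_c
    mat dY = dYs.t();                           // out_c x npos
    dW += dY * col_cache.cols((size_t)s * npos, (size_t)(s + 1) * npos - 1).t();
    db += sum(dY, 1);
    mat dcol = W.t() * dY;                      // (in_c*k*k) x npos
    col2im_acc(dcol, 0, d, dX.colptr(s));       // dcol treated with col0=0
  }
  return dX;
}

// Transposed conv. `d` describes the EQUIVALENT forward conv mapping the
// tconv OUTPUT (d.in_*) to the tconv INPUT (d.out_*); W is that conv's weight
// (d.out_c x d.in_c*k*k). Bias is per tconv-output channel (length d.in_c).
static mat tconv_forward(const mat& X, const mat& W, const vec& b,
                         const ConvDims& d) {
  int B = X.n_cols, npos = d.out_h * d.out_w;
  size_t out_feat = (size_t)d.in_h * d.in_w * d.in_c;
  mat out(out_feat, B, fill::zeros);
  for (int s = 0; s < B; ++s) {
    mat Xs(X.colptr(s), npos, d.out_c);         // npos x out_c
    mat dcol = W.t() * Xs.t();                  // (in_c*k*k) x npos
    col2im_acc(dcol, 0, d, out.colptr(s));
    for (int c = 0; c < d.in_c; ++c)
      out.col(s).subvec((size_t)c * d.in_h * d.in_w,
                        (size_t)(c + 1) * d.in_h * d.in_w - 1) += b(c);
  }
  return out;
}

static mat tconv_backward(const mat& dOut, const mat& X, const mat& W,
                          const ConvDims& d, mat& dW, vec& db) {
  int B = X.n_cols, npos = d.out_h * d.out_w;
  dW.zeros(W.n_rows, W.n_cols);
  db.zeros(d.in_c);
  mat dX(X.n_rows, B, fill::zeros);
  mat col(d.in_c * d.k * d.k, npos);
  for (int s = 0; s < B; ++s) {
    im2col_into(dOut.colptr(s), d, col, 0);
    mat Xs(X.colptr(s), npos, d.out_c);         // the conv's "dY" is our input
    dW += Xs.t() * col.t();
    mat dXs = W * col;                          // out_c x npos
    dX.col(s) = vectorise(dXs.t());
    for (int c = 0; c < d.in_c; ++c)
      db(c) += accu(dOut.col(s).subvec((size_t)c * d.in_h * d.in_w,
                                       (size_t)(c + 1) * d.in_h * d.in_w - 1));
  }
  return dX;
}

enum Act { ACT_NONE = 0, ACT_RELU = 1, ACT_SIGMOID = 2, ACT_LOG = 3, ACT_ABS = 4 };

static void act_forward(mat& Y, int act) {
  if (act == ACT_RELU) Y.transform([](double v) { return v > 0 ? v : 0.0; });
  else if (act == ACT_SIGMOID)
    Y.transform([](double v) { return 1.0 / (1.0 + std::exp(-v)); });
  else if (act == ACT_ABS) Y.transform([](double v) { return std::fabs(v); });
  else if (act == ACT_LOG)
    Y.transform([](double v) { return std::log(v + 1e-6); });
}
static void act_backward(mat& g, const mat& out, int act) {
  if (act == ACT_RELU) g %= conv_to<mat>::from(out > 0);
  else if (act == ACT_SIGMOID) g %= out % (1.0 - out);
  else if (act == ACT_ABS) {
    // out = |x|; sign recovered from cached input is unavailable, so abs is
    // only attached to layers whose raw output is cached via xsign
  } else if (act == ACT_LOG) g %= exp(-out);
}

struct Layer {
  std::string type;
  int act = ACT_NONE;
  ConvDims d{}, d2{}, dp{};
  bool has_proj = false;
  mat W, W2, Wp;
  vec b, b2, bp;
  // batchnorm parameters and state
  vec gam, bet, rmean, rvar, cmu, cvar, ggam, gbet;
  vec mgam, vgam, mbet, vbet;
  mat xhat, xsign;
  double drop = 0.0;
  mat dmask;
  // caches
  mat in, out, col, col2, colp, h1, z2pre;
  // adam state
  mat mW, vW, mW2, vW2, mWp, vWp;
  vec mb, vb, mb2, vb2, mbp, vbp;
  // grads
  mat gW, gW2, gWp;
  vec gb, gb2, gbp;
};

static ConvDims dims_from(const List& l, const char* prefix) {
  ConvDims d;
  std::string p(prefix);
  d.in_c = as<int>(l[p + "in_c"]);  d.out_c = as<int>(l[p + "out_c"]);
  d.k = as<int>(l[p + "k"]);        d.stride = as<int>(l[p + "stride"]);
  d.pad = as<int>(l[p + "pad"]);
  d.in_h = as<int>(l[p + "in_h"]);  d.in_w = as<int>(l[p + "in_w"]);
  d.out_h = as<int>(l[p + "out_h"]); d.out_w = as<int>(l[p + "out_w"]);
  return d;
}

static std::vector<Layer> parse_layers(const List& layers_r) {
  std::vector<Layer> L;
  for (int i = 0; i < layers_r.size(); ++i) {
    List lr = layers_r[i];
    Layer l;
    l.type = as<std::string>(lr["type"]);
    std::string a = as<std::string>(lr["act"]);
    l.act = a == "relu" ? ACT_RELU
          : a == "sigmoid" ? ACT_SIGMOID
          : a == "log" ? ACT_LOG
          : a == "abs" ? ACT_ABS : ACT_NONE;
    if (lr.containsElementNamed("drop")) l.drop = as<double>(lr["drop"]);
    if (l.type == "gap") {
      l.d.in_h = as<int>(lr["in_h"]); l.d.in_w = as<int>(lr["in_w"]);
      l.d.in_c = as<int>(lr["in_c"]);
      L.push_back(std::move(l));
      continue;
    }
    if (l.type == "bnorm") {
      l.d.in_h = as<int>(lr["in_h"]); l.d.in_w = as<int>(lr["in_w"]);
      l.d.in_c = as<int>(lr["in_c"]);
      l.gam = as<vec>(lr["gamma"]); l.bet = as<vec>(lr["beta"]);
      l.rmean = as<vec>(lr["rmean"]); l.rvar = as<vec>(lr["rvar"]);
      L.push_back(std::move(l));
      continue;
    }
    l.W = as<mat>(lr["W"]);
    l.b = as<vec>(lr["b"]);
    if (l.type == "conv" || l.type == "tconv") {
      l.d = dims_from(lr, "");
    } else if (l.type == "resblock") {
      l.d = dims_from(lr, "");
      l.d2 = dims_from(lr, "c2_");
      l.W2 = as<mat>(lr["W2"]); l.b2 = as<vec>(lr["b2"]);
      l.has_proj = as<bool>(lr["has_proj"]);
      if (l.has_proj) {
        l.dp = dims_from(lr, "p_");
        l.Wp = as<mat>(lr["Wp"]); l.bp = as<vec>(lr["bp"]);
      }
    }
    L.push_back(std::move(l));
  }
  return L;
}

static List export_layers(const List& layers_r, std::vector<Layer>& L) {
  List out = Rcpp::clone(layers_r);
  for (size_t i = 0; i < L.size(); ++i) {
    if (L[i].type == "gap") continue;
    List lr = out[i];
    if (L[i].type == "bnorm") {
      lr["gamma"] = L[i].gam; lr["beta"] = L[i].bet;
      lr["rmean"] = L[i].rmean; lr["rvar"] = L[i].rvar;
      out[i] = lr;
      continue;
    }
    lr["W"] = L[i].W; lr["b"] = L[i].b;
    if (L[i].type == "resblock") {
      lr["W2"] = L[i].W2; lr["b2"] = L[i].b2;
      if (L[i].has_proj) { lr["Wp"] = L[i].Wp; lr["bp"] = L[i].bp; }
    }
    out[i] = lr;
  }
  return out;
}

static mat layer_forward(Layer& l, const mat& X, bool cache, bool train,
                         std::mt19937* gen = nullptr) {
  mat Y;
  if (l.type == "conv") {
    Y = conv_forward(X, l.W, l.b, l.d, l.col);
  } else if (l.type == "tconv") {
    Y = tconv_forward(X, l.W, l.b, l.d);
  } else if (l.type == "fc") {
    Y = l.W * X;
    Y.each_col() += l.b;
  } else if (l.type == "gap") { // global average pool per channel
    int npos = l.d.in_h * l.d.in_w;
    Y.set_size(l.d.in_c, X.n_cols);
    for (uword s = 0; s < X.n_cols; ++s) {
      mat Xs(const_cast<double*>(X.colptr(s)), npos, l.d.in_c, false);
      Y.col(s) = mean(Xs, 0).t();
    }
  } else if (l.type == "bnorm") {
    // per-channel normalization over batch x spatial positions
    int npos = l.d.in_h * l.d.in_w;
    int C = l.d.in_c;
    double m = (double)npos * X.n_cols;
    vec mu(C), va(C);
    if (train) {
      for (int c = 0; c < C; ++c) {
        double s1 = 0, s2 = 0;
        for (uword sc = 0; sc < X.n_cols; ++sc) {
          const double* p = X.colptr(sc) + (size_t)c * npos;
          for (int j = 0; j < npos; ++j) { s1 += p[j]; s2 += p[j] * p[j]; }
        }
        mu(c) = s1 / m;
        va(c) = std::max(s2 / m - mu(c) * mu(c), 0.0);
      }
      if (cache) {
        l.rmean = 0.9 * l.rmean + 0.1 * mu;
        l.rvar = 0.9 * l.rvar + 0.1 * va;
      }
    } else { mu = l.rmean; va = l.rvar; }
    Y.set_size(X.n_rows, X.n_cols);
    for (int c = 0; c < C; ++c) {
      double inv = 1.0 / std::sqrt(va(c) + 1e-5);
      for (uword sc = 0; sc < X.n_cols; ++sc) {
        const double* p = X.colptr(sc) + (size_t)c * npos;
        double* q = Y.colptr(sc) + (size_t)c * npos;
        for (int j = 0; j < npos; ++j)
          q[j] = l.gam(c) * ((p[j] - mu(c)) * inv) + l.bet(c);
      }
    }
    if (cache) {
      l.cmu = mu; l.cvar = va;
      l.xhat.set_size(X.n_rows, X.n_cols);
      for (int c = 0; c < C; ++c) {
        double inv = 1.0 / std::sqrt(va(c) + 1e-5);
        for (uword sc = 0; sc < X.n_cols; ++sc) {
          const double* p = X.colptr(sc) + (size_t)c * npos;
          double* q = l.xhat.colptr(sc) + (size_t)c * npos;
          for (int j = 0; j < npos; ++j) q[j] = (p[j] - mu(c)) * inv;
        }
      }
    }
  } else { // resblock: conv1 -> relu -> conv2, + shortcut, -> relu
    mat h = conv_forward(X, l.W, l.b, l.d, l.col);
    act_forward(h, ACT_RELU);
    if (cache) l.h1 = h;
    mat z = conv_forward(h, l.W2, l.b2, l.d2, l.col2);
    mat s = l.has_proj ? conv_forward(X, l.Wp, l.bp, l.dp, l.colp) : X;
    Y = z + s;
  }
  if (l.act == ACT_ABS && cache) l.xsign = sign(Y);
  act_forward(Y, l.act);
  if (l.drop > 0 && train && gen != nullptr) { // inverted dropout
    std::uniform_real_distribution<double> U(0.0, 1.0);
    l.dmask.set_size(Y.n_rows, Y.n_cols);
    double keep = 1.0 - l.drop;
    for (uword j = 0; j < Y.n_elem; ++j)
      l.dmask(j) = U(*gen) < keep ? 1.0 / keep : 0.0;
    Y %= l.dmask;
  } else l.dmask.reset();
  if (cache) { l.in = X; l.out = Y; }
  return Y;
}

static mat layer_backward(Layer& l, mat g) {
  if (l.dmask.n_elem > 0) g %= l.dmask;
  if (l.act == ACT_ABS) g %= l.xsign;
  else act_backward(g, l.out, l.act);
  if (l.type == "conv") {
    return conv_backward(g, l.in, l.W, l.d, l.col, l.gW, l.gb);
  } else if (l.type == "tconv") {
    return tconv_backward(g, l.in, l.W, l.d, l.gW, l.gb);
  } else if (l.type == "fc") {
    l.gW = g * l.in.t();
    l.gb = sum(g, 1);
    return l.W.t() * g;
  } else if (l.type == "gap") {
    int npos = l.d.in_h * l.d.in_w;
    mat dX(l.in.n_rows, l.in.n_cols);
    for (uword s = 0; s < g.n_cols; ++s)
      for (int c = 0; c < l.d.in_c; ++c)
        dX.col(s).subvec((size_t)c * npos, (size_t)(c + 1) * npos - 1)
          .fill(g(c, s) / (double)npos);
    return dX;
  } else if (l.type == "bnorm") {
    int npos = l.d.in_h * l.d.in_w;
    int C = l.d.in_c;
    double m = (double)npos * g.n_cols;
    l.ggam.zeros(C); l.gbet.zeros(C);
    mat dX(g.n_rows, g.n_cols);
    for (int c = 0; c < C; ++c) {
      double sdy = 0, sdyx = 0;
      for (uword sc = 0; sc < g.n_cols; ++sc) {
        const double* dg = g.colptr(sc) + (size_t)c * npos;
        const double* xh = l.xhat.colptr(sc) + (size_t)c * npos;
        for (int j = 0; j < npos; ++j) { sdy += dg[j]; sdyx += dg[j] * xh[j]; }
      }
      l.ggam(c) = sdyx; l.gbet(c) = sdy;
      double inv = l.gam(c) / std::sqrt(l.cvar(c) + 1e-5);
      double mdy = sdy / m, mdyx = sdyx / m;
      for (uword sc = 0; sc < g.n_cols; ++sc) {
        const double* dg = g.colptr(sc) + (size_t)c * npos;
        const double* xh = l.xhat.colptr(sc) + (size_t)c * npos;
        double* q = dX.colptr(sc) + (size_t)c * npos;
        for (int j = 0; j < npos; ++j)
          q[j] = inv * (dg[j] - mdy - xh[j] * mdyx);
      }
    }
    return dX;
  } else {
    mat dh = conv_backward(g, l.h1, l.W2, l.d2, l.col2, l.gW2, l.gb2);
    act_backward(dh, l.h1, ACT_RELU);
    mat dx1 = conv_backward(dh, l.in, l.W, l.d, l.col, l.gW, l.gb);
    if (l.has_proj) {
      mat dx2 = conv_backward(g, l.in, l.Wp, l.dp, l.colp, l.gWp, l.gbp);
      return dx1 + dx2;
    }
    return dx1 + g;
  }
}

// loss value and gradient at the network output
static double loss_and_grad(const mat& O, const mat& Y, const std::string& loss,
                            mat& g) {
  if (loss == "mse") {
    g = 2.0 * (O - Y) / (double)O.n_elem;
    return accu(square(O - Y)) / (double)O.n_elem;
  } else if (loss == "cross_entropy") {
    mat P = O;
    P.each_row() -= max(P, 0);
    P = exp(P);
    P.each_row() /= sum(P, 0);
    g = (P - Y) / (double)O.n_cols;
    double ll = 0;
    for (uword j = 0; j < O.n_cols; ++j)
      for (uword i = 0; i < O.n_rows; ++i)
        if (Y(i, j) > 0) ll -= Y(i, j) * std::log(std::max(P(i, j), 1e-12));
    return ll / (double)O.n_cols;
  } else { // bce on logits
    mat P = O;
    act_forward(P, ACT_SIGMOID);
    g = (P - Y) / (double)O.n_elem;
    mat l = -Y % log(clamp(P, 1e-12, 1.0)) -
            (1.0 - Y) % log(clamp(1.0 - P, 1e-12, 1.0));
    return accu(l) / (double)O.n_elem;
  }
}

static void adam_tensor(mat& W, const mat& g, mat& m, mat& v, double lr,
                        double b1, double b2, double eps, double bc1, double bc2) {
  if (m.n_elem == 0) { m.zeros(W.n_rows, W.n_cols); v.zeros(W.n_rows, W.n_cols); }
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  W -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
}
static void adam_vec(vec& W, const vec& g, vec& m, vec& v, double lr,
                     double b1, double b2, double eps, double bc1, double bc2) {
  if (m.n_elem == 0) { m.zeros(W.n_elem); v.zeros(W.n_elem); }
  m = b1 * m + (1 - b1) * g;
  v = b2 * v + (1 - b2) * square(g);
  W -= lr * (m / bc1) / (sqrt(v / bc2) + eps);
}

// [[Rcpp::export]]
arma::mat cpp_nn_forward(List layers_r, const arma::mat& X, int batch = 64) {
  std::vector<Layer> L = parse_layers(layers_r);
  mat out;
  for (uword s0 = 0; s0 < X.n_cols; s0 += batch) {
    uword s1 = std::min<uword>(s0 + batch, X.n_cols) - 1;
    mat h = X.cols(s0, s1);
    for (auto& l : L) h = layer_forward(l, h, false, false);
    if (out.n_elem == 0) out.set_size(h.n_rows, X.n_cols);
    out.cols(s0, s1) = h;
  }
  return out;
}

// [[Rcpp::export]]
List cpp_nn_train(List layers_r, const arma::mat& X, const arma::mat& Y,
                  std::string loss, int epochs, int batch,
                  const arma::vec& lr_by_epoch,
                  const arma::imat& perm, double beta1 = 0.9,
                  double beta2 = 0.999, double eps = 1e-8,
                  double weight_decay = 0.0, int rng_seed = 1) {
  std::vector<Layer> L = parse_layers(layers_r);
  int N = X.n_cols;
  std::mt19937 gen((unsigned)rng_seed);
  vec history(epochs, fill::zeros);
  long step = 0;
  for (int e = 0; e < epochs; ++e) {
    double lr = lr_by_epoch(std::min<uword>(e, lr_by_epoch.n_elem - 1));
    double esum = 0; long ecnt = 0;
    for (int s0 = 0; s0 < N; s0 += batch) {
      int s1 = std::min(s0 + batch, N) - 1;
      int B = s1 - s0 + 1;
      uvec idx(B);
      for (int j = 0; j < B; ++j) idx(j) = (uword)perm(s0 + j, e);
      mat h = X.cols(idx);
      mat Yb = Y.cols(idx);
      for (auto& l : L) h = layer_forward(l, h, true, true, &gen);
      mat g;
      double lv = loss_and_grad(h, Yb, loss, g);
      esum += lv * B; ecnt += B;
      for (int li = (int)L.size() - 1; li >= 0; --li) g = layer_backward(L[li], g);
      ++step;
      double bc1 = 1 - std::pow(beta1, (double)step);
      double bc2 = 1 - std::pow(beta2, (double)step);
      for (auto& l : L) {
        if (l.type == "gap") continue;
        if (l.type == "bnorm") {
          adam_vec(l.gam, l.ggam, l.mgam, l.vgam, lr, beta1, beta2, eps, bc1, bc2);
          adam_vec(l.bet, l.gbet, l.mbet, l.vbet, lr, beta1, beta2, eps, bc1, bc2);
          continue;
        }
        if (weight_decay > 0) {
          l.W *= (1 - lr * weight_decay);
          if (l.type == "resblock") {
            l.W2 *= (1 - lr * weight_decay);
            if (l.has_proj) l.Wp *= (1 - lr * weight_decay);
          }
        }
        adam_tensor(l.W, l.gW, l.mW, l.vW, lr, beta1, beta2, eps, bc1, bc2);
        adam_vec(l.b, l.gb, l.mb, l.vb, lr, beta1, beta2, eps, bc1, bc2);
        if (l.type == "resblock") {
          adam_tensor(l.W2, l.gW2, l.mW2, l.vW2, lr, beta1, beta2, eps, bc1, bc2);
          adam_vec(l.b2, l.gb2, l.mb2, l.vb2, lr, beta1, beta2, eps, bc1, bc2);
          if (l.has_proj) {
            adam_tensor(l.Wp, l.gWp, l.mWp, l.vWp, lr, beta1, beta2, eps, bc1, bc2);
            adam_vec(l.bp, l.gbp, l.mbp, l.vbp, lr, beta1, beta2, eps, bc1, bc2);
          }
        }
      }
      Rcpp::checkUserInterrupt();
    }
    history(e) = esum / ecnt;
  }
  return List::create(Rcpp::Named("layers") = export_layers(layers_r, L),
                      Rcpp::Named("history") = history);
}

// [[Rcpp::export]]
double cpp_nn_loss(List layers_r, const arma::mat& X, const arma::mat& Y,
                   std::string loss) {
  std::vector<Layer> L = parse_layers(layers_r);
  mat h = X;
  for (auto& l : L) h = layer_forward(l, h, false, true);
  mat g;
  return loss_and_grad(h, Y, loss, g);
}

// Analytic gradients for one full batch (finite-difference verification hook).
// [[Rcpp::export]]
List cpp_nn_grad(List layers_r, const arma::mat& X, const arma::mat& Y,
                 std::string loss) {
  std::vector<Layer> L = parse_layers(layers_r);
  mat h = X;
  for (auto& l : L) h = layer_forward(l, h, true, true);
  mat g;
  loss_and_grad(h, Y, loss, g);
  for (int li = (int)L.size() - 1; li >= 0; --li) g = layer_backward(L[li], g);
  List out(L.size());
  for (size_t i = 0; i < L.size(); ++i) {
    Layer& l = L[i];
    if (l.type == "gap") {
      out[i] = List::create(Rcpp::Named("W") = mat(), Rcpp::Named("b") = vec());
    } else if (l.type == "bnorm") {
      out[i] = List::create(Rcpp::Named("W") = l.ggam, Rcpp::Named("b") = l.gbet);
    } else if (l.type == "resblock") {
      out[i] = List::create(
          Rcpp::Named("W") = l.gW, Rcpp::Named("b") = l.gb,
          Rcpp::Named("W2") = l.gW2, Rcpp::Named("b2") = l.gb2,
          Rcpp::Named("Wp") = l.has_proj ? l.gWp : mat(),
          Rcpp::Named("bp") = l.has_proj ? l.gbp : vec());
    } else {
      out[i] = List::create(Rcpp::Named("W") = l.gW, Rcpp::Named("b") = l.gb);
    }
  }
  return out;
}
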