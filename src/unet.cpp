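// Compact 2D U-Net-style encoder-decoder for binary slice segmentation.
//
// Feature maps are stored as (channels x H*W) single-precision matrices with
// pixel index p = i + j*H (column-major, matching R). Convolutions are 3x3,
// stride 1, zero padding 1, realised as im2col + GEMM. The network is:
//   depth encoder levels (two conv+ReLU, then 2x2 max pool),
//   a two-conv bottleneck,
//   depth decoder levels (nearest x2 upsample, skip concatenation, two
//   conv+ReLU), and a final 1x1 conv + sigmoid.
// Loss is batch-global soft Dice; optimisation is Adam. All randomness comes
// from a mt19937 stream seeded at construction (Box-Muller, raw uniforms, so
// initialisation is identical across standard library implementations).
//
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <random>

using namespace arma;

struct Conv {
  int cin, cout, k;          // k = 3 or 1
  fmat W;                    // cout x cin*k*k
  fvec b;
  fmat gW; fvec gb;          // gradient accumulators
  fmat mW, vW; fvec mb, vb;  // Adam state
};

struct Cache {
  std::vector<fmat> conv_in;   // input feature map per conv layer
  std::vector<fmat> conv_out;  // post-activation output per conv layer
  std::vector<int>  Hs, Ws;    // spatial size at each conv layer input
  std::vector<umat> pool_arg;  // per encoder level: argmax source pixel
};

static void im2col3(const fmat& X, int H, int W, fmat& col) {
  const int cin = X.n_rows;
  col.zeros(cin * 9, H * W);
  for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di) {
      const int r0 = (dj + 1) * 3 + (di + 1);
      for (int j = 0; j < W; ++j) {
        const int js = j + dj;
        if (js < 0 || js >= W) continue;
        for (int i = 0; i < H; ++i) {
          const int is = i + di;
          if (is < 0 || is >= H) continue;
          const int p = i + j * H, ps = is + js * H;
          for (int c = 0; c < cin; ++c) col(c * 9 + r0, p) = X(c, ps);
        }
      }
    }
}

static void col2im3(const fmat& dcol, int H, int W, fmat& dX) {
  const int cin = dX.n_rows;
  for (int dj = -1; dj <= 1; ++dj)
    for (int di = -1; di <= 1; ++di) {
      const int r0 = (dj + 1) * 3 + (di + 1);
      for (int j = 0; j < W; ++j) {
        const int js = j + dj;
        if (js < 0 || js >= W) continue;
        for (int i = 0; i < H; ++i) {
          const int is = i + di;
          if (is < 0 || is >= H) continue;
          const int p = i + j * H, ps = is + js * H;
          for (int c = 0; c < cin; ++c) dX(c, ps) += dcol(c * 9 + r0, p);
        }
      }
    }
}

struct UNet {
  int depth, base;
  std::vector<Conv> layers;  // enc(0,0..1) .. enc(D-1,*), bott0, bott1,
                             // dec(D-1,*) .. dec(0,*), final 1x1
  std::mt19937 rng;
  long adam_t = 0;

  int n_layers() const { return 4 * depth + 3; }
  int enc_idx(int d, int j) const { return 2 * d + j; }
  int bott_idx(int j) const { return 2 * depth + j; }
  int dec_idx(int d, int j) const { return 2 * depth + 2 + 2 * (depth - 1 - d) + j; }
  int fin_idx() const { return 4 * depth + 2; }
  int chan(int d) const { return base << d; }  // encoder level width

  float gaussf() {
    double u1 = (rng() + 0.5) * (1.0 / 4294967296.0);
    double u2 = (rng() + 0.5) * (1.0 / 4294967296.0);
    return (float)(std::sqrt(-2.0 * std::log(u1)) * std::cos(2.0 * M_PI * u2));
  }

  void add_layer(int cin, int cout, int k) {
    Conv c;
    c.cin = cin; c.cout = cout; c.k = k;
    c.W.set_size(cout, cin * k * k);
    const float sd = std::sqrt(2.0f / (cin * k * k));
    for (uword e = 0; e < c.W.n_elem; ++e) c.W(e) = sd * gaussf();
    c.b.zeros(cout);
    c.gW.zeros(arma::size(c.W)); c.gb.zeros(cout);
    c.mW.zeros(arma::size(c.W)); c.vW.zeros(arma::size(c.W));
    c.mb.zeros(cout); c.vb.zeros(cout);
    layers.push_back(c);
  }

  UNet(int depth_, int base_, int seed) : depth(depth_), base(base_), rng(seed) {
    for (int d = 0; d < depth; ++d) {
      int cin = (d == 0) ? 1 : chan(d - 1);
      add_layer(cin, chan(d), 3);
      add_layer(chan(d), chan(d), 3);
    }
    add_layer(chan(depth - 1), chan(depth), 3);
    add_layer(chan(depth), chan(depth), 3);
    for (int d = depth - 1; d >= 0; --d) {
      int cup = (d == depth - 1) ? chan(depth) : chan(d + 1);
      add_layer(cup + chan(d), chan(d), 3);
      add_layer(chan(d), chan(d), 3);
    }
    add_layer(chan(0), 1, 1);
  }

  fmat conv_relu(int idx, const fmat& X, int H, int W, Cache* cc) {
    Conv& L = layers[idx];
    fmat col;
    im2col3(X, H, W, col);
    fmat Y = L.W * col;
    Y.each_col() += L.b;
    Y.transform([](float v) { return v > 0.0f ? v : 0.0f; });
    if (cc) {
      cc->conv_in[idx] = X;
      cc->conv_out[idx] = Y;
      cc->Hs[idx] = H; cc->Ws[idx] = W;
    }
    return Y;
  }

  fmat conv_relu_back(int idx, fmat dY, const Cache& cc) {
    Conv& L = layers[idx];
    const int H = cc.Hs[idx], W = cc.Ws[idx];
    dY %= conv_to<fmat>::from(cc.conv_out[idx] > 0.0f);
    fmat col;
    im2col3(cc.conv_in[idx], H, W, col);
    L.gW += dY * col.t();
    L.gb += sum(dY, 1);
    fmat dcol = L.W.t() * dY;
    fmat dX(L.cin, H * W, fill::zeros);
    col2im3(dcol, H, W, dX);
    return dX;
  }

  static fmat maxpool(const fmat& X, int H, int W, umat* arg) {
    const int C = X.n_rows, H2 = H / 2, W2 = W / 2;
    fmat out(C, H2 * W2);
    if (arg) arg->set_size(C, H2 * W2);
    for (int j = 0; j < W2; ++j)
      for (int i = 0; i < H2; ++i) {
        const int p = i + j * H2;
        const int s00 = 2 * i + 2 * j * H, s10 = s00 + 1;
        const int s01 = s00 + H, s11 = s01 + 1;
        for (int c = 0; c < C; ++c) {
          int sbest = s00; float vbest = X(c, s00);
          if (X(c, s10) > vbest) { vbest = X(c, s10); sbest = s10; }
          if (X(c, s01) > vbest) { vbest = X(c, s01); sbest = s01; }
          if (X(c, s11) > vbest) { vbest = X(c, s11); sbest = s11; }
          out(c, p) = vbest;
          if (arg) (*arg)(c, p) = sbest;
        }
      }
    return out;
  }

  static fmat maxpool_back(const fmat& dOut, const umat& arg, int C, int H, int W) {
    fmat dX(C, H * W, fill::zeros);
    for (uword p = 0; p < dOut.n_cols; ++p)
      for (int c = 0; c < C; ++c) dX(c, arg(c, p)) += dOut(c, p);
    return dX;
  }

  static fmat upsample2(const fmat& X, int H, int W) {
    const int C = X.n_rows, H2 = H * 2, W2 = W * 2;
    fmat out(C, H2 * W2);
    for (int j = 0; j < W2; ++j) {
      const int js = j / 2;
      for (int i = 0; i < H2; ++i) {
        const int p = i + j * H2, ps = (i / 2) + js * H;
        for (int c = 0; c < C; ++c) out(c, p) = X(c, ps);
      }
    }
    return out;
  }

  static fmat upsample2_back(const fmat& dOut, int H, int W) {
    // H, W are the *source* (coarse) dimensions
    const int C = dOut.n_rows, H2 = H * 2;
    fmat dX(C, H * W, fill::zeros);
    for (int j = 0; j < W * 2; ++j) {
      const int js = j / 2;
      for (int i = 0; i < H2; ++i) {
        const int p = i + j * H2, ps = (i / 2) + js * H;
        for (int c = 0; c < C; ++c) dX(c, ps) += dOut(c, p);
      }
    }
    return dX;
  }

  // Forward pass; returns probabilities (1 x H*W). cc may be null.
  fmat forward(const fmat& x0, int H, int W, Cache* cc) {
    if (cc) {
      cc->conv_in.resize(n_layers());
      cc->conv_out.resize(n_layers());
      cc->Hs.assign(n_layers(), 0);
      cc->Ws.assign(n_layers(), 0);
      cc->pool_arg.resize(depth);
    }
    fmat cur = x0;
    int h = H, w = W;
    std::vector<fmat> skips(depth);
    std::vector<int> sh(depth), sw(depth);
    for (int d = 0; d < depth; ++d) {
      cur = conv_relu(enc_idx(d, 0), cur, h, w, cc);
      cur = conv_relu(enc_idx(d, 1), cur, h, w, cc);
      skips[d] = cur; sh[d] = h; sw[d] = w;
      umat arg;
      cur = maxpool(cur, h, w, cc ? &arg : nullptr);
      if (cc) cc->pool_arg[d] = std::move(arg);
      h /= 2; w /= 2;
    }
    cur = conv_relu(bott_idx(0), cur, h, w, cc);
    cur = conv_relu(bott_idx(1), cur, h, w, cc);
    for (int d = depth - 1; d >= 0; --d) {
      cur = upsample2(cur, h, w);
      h = sh[d]; w = sw[d];
      cur = join_cols(cur, skips[d]);
      cur = conv_relu(dec_idx(d, 0), cur, h, w, cc);
      cur = conv_relu(dec_idx(d, 1), cur, h, w, cc);
    }
    Conv& F = layers[fin_idx()];
    if (cc) {
      cc->conv_in[fin_idx()] = cur;
      cc->Hs[fin_idx()] = h; cc->Ws[fin_idx()] = w;
    }
    fmat z = F.W * cur;
    z.each_col() += F.b;
    fmat p = 1.0f / (1.0f + exp(-z));
    if (cc) cc->conv_out[fin_idx()] = p;
    return p;
  }

  // Backward from dL/dprob (1 x H*W) using a forward cache.
  void backward(const fmat& dp, const Cache& cc) {
    Conv& F = layers[fin_idx()];
    const fmat& p = cc.conv_out[fin_idx()];
    fmat dz = dp % p % (1.0f - p);
    F.gW += dz * cc.conv_in[fin_idx()].t();
    F.gb += sum(dz, 1);
    fmat dcur = F.W.t() * dz;
    std::vector<fmat> dskip(depth);
    for (int d = 0; d <= depth - 1; ++d) {
      dcur = conv_relu_back(dec_idx(d, 1), dcur, cc);
      dcur = conv_relu_back(dec_idx(d, 0), dcur, cc);
      const int cup = layers[dec_idx(d, 0)].cin - chan(d);
      dskip[d] = dcur.rows(cup, dcur.n_rows - 1);
      fmat dup = dcur.rows(0, cup - 1);
      const int h = cc.Hs[dec_idx(d, 0)] / 2, w = cc.Ws[dec_idx(d, 0)] / 2;
      dcur = upsample2_back(dup, h, w);
    }
    dcur = conv_relu_back(bott_idx(1), dcur, cc);
    dcur = conv_relu_back(bott_idx(0), dcur, cc);
    for (int d = depth - 1; d >= 0; --d) {
      const int h = cc.Hs[enc_idx(d, 0)], w = cc.Ws[enc_idx(d, 0)];
      fmat dpooled = maxpool_back(dcur, cc.pool_arg[d], chan(d), h, w);
      dpooled += dskip[d];
      dpooled = conv_relu_back(enc_idx(d, 1), dpooled, cc);
      dcur = conv_relu_back(enc_idx(d, 0), dpooled, cc);
    }
  }

  void zero_grads() {
    for (auto& L : layers) { L.gW.zeros(); L.gb.zeros(); }
  }

  void adam_step(double lr) {
    ++adam_t;
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    const float c1 = 1.0f - std::pow(b1, (float)adam_t);
    const float c2 = 1.0f - std::pow(b2, (float)adam_t);
    for (auto& L : layers) {
      L.mW = b1 * L.mW + (1 - b1) * L.gW;
      L.vW = b2 * L.vW + (1 - b2) * square(L.gW);
      L.W -= (float)lr * (L.mW / c1) / (sqrt(L.vW / c2) + eps);
      L.mb = b1 * L.mb + (1 - b1) * L.gb;
      L.vb = b2 * L.vb + (1 - b2) * square(L.gb);
      L.b -= (float)lr * (L.mb / c1) / (sqrt(L.vb / c2) + eps);
    }
  }
};

// [[Rcpp::export]]
SEXP unet_create(int depth, int base, int seed) {
  if (depth < 1 || base < 1) Rcpp::stop("depth and base width must be >= 1");
  Rcpp::XPtr<UNet> ptr(new UNet(depth, base, seed), true);
  return ptr;
}

static void check_dims(const UNet& net, int H, int W) {
  const int f = 1 << net.depth;
  if (H % f != 0 || W % f != 0)
    Rcpp::stop("slice dimensions (%d x %d) must be divisible by 2^depth = %d",
               H, W, f);
}

// X, Y: (H, W, N) arrays; one global soft-Dice loss over the batch.
// [[Rcpp::export]]
double unet_train_batch(SEXP ptr_, const arma::cube& X, const arma::cube& Y,
                        double lr) {
  Rcpp::XPtr<UNet> net(ptr_);
  const int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  check_dims(*net, H, W);
  const float eps = 1.0f;  // Dice smoothing
  std::vector<Cache> caches(N);
  std::vector<fmat> probs(N), ys(N);
  double I = 0.0, U = 0.0;
  for (int s = 0; s < N; ++s) {
    fmat x = conv_to<fmat>::from(vectorise(X.slice(s)).t());
    ys[s] = conv_to<fmat>::from(vectorise(Y.slice(s)).t());
    probs[s] = net->forward(x, H, W, &caches[s]);
    I += accu(probs[s] % ys[s]);
    U += accu(probs[s]) + accu(ys[s]);
  }
  const double dice = (2.0 * I + eps) / (U + eps);
  net->zero_grads();
  const double denom = (U + eps) * (U + eps);
  const float a = (float)((2.0 * I + eps) / denom);
  const float bcoef = (float)(2.0 * (U + eps) / denom);
  for (int s = 0; s < N; ++s) {
    fmat dp = a - bcoef * ys[s];
    net->backward(dp, caches[s]);
  }
  net->adam_step(lr);
  return 1.0 - dice;
}

// [[Rcpp::export]]
arma::cube unet_predict_batch(SEXP ptr_, const arma::cube& X) {
  Rcpp::XPtr<UNet> net(ptr_);
  const int H = X.n_rows, W = X.n_cols, N = X.n_slices;
  check_dims(*net, H, W);
  arma::cube out(H, W, N);
  for (int s = 0; s < N; ++s) {
    fmat x = conv_to<fmat>::from(vectorise(X.slice(s)).t());
    fmat p = net->forward(x, H, W, nullptr);
    out.slice(s) = reshape(conv_to<mat>::from(p), H, W);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List unet_get_weights(SEXP ptr_) {
  Rcpp::XPtr<UNet> net(ptr_);
  Rcpp::List out(net->layers.size());
  for (size_t i = 0; i < net->layers.size(); ++i) {
    const Conv& L = net->layers[i];
    out[i] = Rcpp::List::create(
        Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(L.W)),
        Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(L.b)));
  }
  return out;
}

// [[Rcpp::export]]
void unet_set_weights(SEXP ptr_, Rcpp::List w) {
  Rcpp::XPtr<UNet> net(ptr_);
  if ((size_t)w.size() != net->layers.size())
    Rcpp::stop("weight list has %d entries, network has %d layers",
               (int)w.size(), (int)net->layers.size());
  for (size_t i = 0; i < net->layers.size(); ++i) {
    Rcpp::List li = w[i];
    mat W = Rcpp::as<mat>(li["W"]);
    vec b = Rcpp::as<vec>(li["b"]);
    Conv& L = net->layers[i];
    if (W.n_rows != L.W.n_rows || W.n_cols != L.W.n_cols)
      Rcpp::stop("layer %d weight shape mismatch", (int)i + 1);
    L.W = conv_to<fmat>::from(W);
    L.b = conv_to<fvec>::from(b);
  }
}

// [[Rcpp::export]]
Rcpp::IntegerVector unet_shape(SEXP ptr_) {
  Rcpp::XPtr<UNet> net(ptr_);
  return Rcpp::IntegerVector::create(net->depth, net->base,
                                     (int)net->layers.size());
}
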