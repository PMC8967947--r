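// Small convolutional network for spectral/time-domain EEG inputs.
//
// Layer stack (fixed): conv(3x3,32) -> BN -> LeakyReLU ->
// conv(3x3,64) -> BN -> LeakyReLU -> FC(2048) -> BN -> LeakyReLU ->
// FC(K) -> BN -> LeakyReLU -> softmax, cross-entropy loss, Adam updates.
// The separable variant factorises each 3x3 convolution into a 3x1
// convolution followed by a 1x3 depthwise convolution.
//
// Data layout: a batch of n single-channel H x W inputs is an n x (H*W)
// matrix, each row flattened row-major (p = r*W + c).  Internally feature
// maps live in (n*P) x C matrices (P = H*W), row index s*P + p, so
// convolutions become im2col + GEMM (BLAS sgemm via Armadillo).
// All computation is single precision and deterministic given the inputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::frowvec;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::IntegerMatrix;
using Rcpp::IntegerVector;

typedef std::vector<std::pair<int,int> > OffsetList;

static OffsetList offsets3x3() {
  OffsetList off;
  for (int dr = -1; dr <= 1; ++dr)
    for (int dc = -1; dc <= 1; ++dc)
      off.push_back(std::make_pair(dr, dc));
  return off;
}

static OffsetList offsets3x1() {              // vertical taps
  OffsetList off;
  for (int dr = -1; dr <= 1; ++dr) off.push_back(std::make_pair(dr, 0));
  return off;
}

// Gather neighbourhoods: (n*P) x (T*C), zero outside the H x W grid
// ("same" padding).  Column t*C + ci holds channel ci at offset t.
static fmat im2col(const fmat& F, int n, int H, int W, const OffsetList& off) {
  const int C = F.n_cols, P = H * W, T = (int)off.size();
  fmat col(n * P, T * C, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    const int dr = off[t].first, dc = off[t].second;
    for (int ci = 0; ci < C; ++ci) {
      const float* src = F.colptr(ci);
      float* dst = col.colptr(t * C + ci);
      for (int s = 0; s < n; ++s) {
        const int base = s * P;
        for (int r = 0; r < H; ++r) {
          const int rr = r + dr;
          if (rr < 0 || rr >= H) continue;
          const int rowoff = base + r * W, srcoff = base + rr * W;
          for (int c = 0; c < W; ++c) {
            const int cc = c + dc;
            if (cc < 0 || cc >= W) continue;
            dst[rowoff + c] = src[srcoff + cc];
          }
        }
      }
    }
  }
  return col;
}

// Scatter-add transpose of im2col.
static fmat col2im(const fmat& dcol, int n, int H, int W, int C,
                   const OffsetList& off) {
  const int P = H * W, T = (int)off.size();
  fmat dF(n * P, C, arma::fill::zeros);
  for (int t = 0; t < T; ++t) {
    const int dr = off[t].first, dc = off[t].second;
    for (int ci = 0; ci < C; ++ci) {
      const float* src = dcol.colptr(t * C + ci);
      float* dst = dF.colptr(ci);
      for (int s = 0; s < n; ++s) {
        const int base = s * P;
        for (int r = 0; r < H; ++r) {
          const int rr = r + dr;
          if (rr < 0 || rr >= H) continue;
          const int rowoff = base + r * W, dstoff = base + rr * W;
          for (int c = 0; c < W; ++c) {
            const int cc = c + dc;
            if (cc < 0 || cc >= W) continue;
            dst[dstoff + cc] += src[rowoff + c];
          }
        }
      }
    }
  }
  return dF;
}

// Depthwise 1x3 (horizontal) convolution, "same" padding.
static fmat depthwise1x3(const fmat& F, int n, int H, int W, const fmat& wb) {
  const int C = F.n_cols, P = H * W;
  fmat out(n * P, C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    const float* src = F.colptr(ci);
    float* dst = out.colptr(ci);
    const float w0 = wb(0, ci), w1 = wb(1, ci), w2 = wb(2, ci);
    for (int s = 0; s < n; ++s) {
      const int base = s * P;
      for (int r = 0; r < H; ++r) {
        const int ro = base + r * W;
        for (int c = 0; c < W; ++c) {
          float acc = w1 * src[ro + c];
          if (c > 0)     acc += w0 * src[ro + c - 1];
          if (c < W - 1) acc += w2 * src[ro + c + 1];
          dst[ro + c] = acc;
        }
      }
    }
  }
  return out;
}

static void depthwise1x3_bwd(const fmat& F, const fmat& dOut, int n, int H,
                             int W, const fmat& wb, fmat& dF, fmat& dwb) {
  const int C = F.n_cols, P = H * W;
  dF.zeros(n * P, C);
  dwb.zeros(3, C);
  for (int ci = 0; ci < C; ++ci) {
    const float* src = F.colptr(ci);
    const float* gd = dOut.colptr(ci);
    float* dsrc = dF.colptr(ci);
    const float w0 = wb(0, ci), w1 = wb(1, ci), w2 = wb(2, ci);
    double g0 = 0, g1 = 0, g2 = 0;
    for (int s = 0; s < n; ++s) {
      const int base = s * P;
      for (int r = 0; r < H; ++r) {
        const int ro = base + r * W;
        for (int c = 0; c < W; ++c) {
          const float g = gd[ro + c];
          g1 += (double)g * src[ro + c];
          dsrc[ro + c] += w1 * g;
          if (c > 0)     { g0 += (double)g * src[ro + c - 1]; dsrc[ro + c - 1] += w0 * g; }
          if (c < W - 1) { g2 += (double)g * src[ro + c + 1]; dsrc[ro + c + 1] += w2 * g; }
        }
      }
    }
    dwb(0, ci) = (float)g0; dwb(1, ci) = (float)g1; dwb(2, ci) = (float)g2;
  }
}

struct BNCache { frowvec invstd; fmat xhat; };

// Batch normalisation over columns (one statistic per channel/feature).
static fmat bn_forward_train(const fmat& A, const frowvec& g, const frowvec& b,
                             frowvec& rm, frowvec& rv, float eps, float mom,
                             BNCache& cache) {
  const int N = A.n_rows;
  frowvec mu = arma::mean(A, 0);
  fmat centered = A.each_row() - mu;
  frowvec var = arma::mean(arma::square(centered), 0);
  cache.invstd = 1.0f / arma::sqrt(var + eps);
  cache.xhat = centered.each_row() % cache.invstd;
  rm = (1.0f - mom) * rm + mom * mu;
  rv = (1.0f - mom) * rv + mom * var;
  fmat out = cache.xhat.each_row() % g;
  out.each_row() += b;
  (void)N;
  return out;
}

static fmat bn_forward_eval(const fmat& A, const frowvec& g, const frowvec& b,
                            const frowvec& rm, const frowvec& rv, float eps) {
  frowvec invstd = 1.0f / arma::sqrt(rv + eps);
  fmat out = (A.each_row() - rm).each_row() % (invstd % g);
  out.each_row() += b;
  return out;
}

static fmat bn_backward(const fmat& dOut, const frowvec& g,
                        const BNCache& cache, frowvec& dg, frowvec& db) {
  const float N = (float)dOut.n_rows;
  dg = arma::sum(dOut % cache.xhat, 0);
  db = arma::sum(dOut, 0);
  fmat dxhat = dOut.each_row() % g;
  frowvec sum_dxhat = arma::sum(dxhat, 0);
  frowvec sum_dxhat_xhat = arma::sum(dxhat % cache.xhat, 0);
  fmat dA = N * dxhat;
  dA.each_row() -= sum_dxhat;
  dA -= cache.xhat.each_row() % sum_dxhat_xhat;
  dA.each_row() %= (cache.invstd / N);
  return dA;
}

static fmat leaky(const fmat& A, float slope, fmat& mask) {
  mask = arma::conv_to<fmat>::from(A >= 0.0f);
  mask.transform([slope](float v) { return v > 0.0f ? 1.0f : slope; });
  return A % mask;
}

struct Config {
  int H, W, C1, C2, fc, K;
  bool separable;
  float slope, bn_eps, bn_mom;
};

static Config read_config(const List& cfg) {
  Config c;
  c.H = Rcpp::as<int>(cfg["input_rows"]);
  c.W = Rcpp::as<int>(cfg["input_cols"]);
  c.C1 = Rcpp::as<int>(cfg["conv1"]);
  c.C2 = Rcpp::as<int>(cfg["conv2"]);
  c.fc = Rcpp::as<int>(cfg["fc_width"]);
  c.K = Rcpp::as<int>(cfg["n_classes"]);
  c.separable = Rcpp::as<bool>(cfg["separable"]);
  c.slope = Rcpp::as<double>(cfg["leaky_slope"]);
  c.bn_eps = 1e-5f;
  c.bn_mom = 0.1f;
  return c;
}

static fmat as_f(SEXP m) {
  return arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(m));
}
static frowvec as_fr(SEXP v) {
  return arma::conv_to<frowvec>::from(Rcpp::as<arma::rowvec>(v));
}

struct Params {
  // convolution weights (standard: K1, K2; separable adds depthwise Wb)
  fmat K1, K1b, K2, K2b, W1, W2;
  frowvec g1, b1, g2, b2, g3, b3, g4, b4;
  frowvec rm1, rv1, rm2, rv2, rm3, rv3, rm4, rv4;
};

static Params read_params(const List& w, const List& run, bool separable) {
  Params p;
  p.K1 = as_f(w["K1"]);
  p.K2 = as_f(w["K2"]);
  if (separable) { p.K1b = as_f(w["K1b"]); p.K2b = as_f(w["K2b"]); }
  p.W1 = as_f(w["W1"]); p.W2 = as_f(w["W2"]);
  p.g1 = as_fr(w["g1"]); p.b1 = as_fr(w["b1"]);
  p.g2 = as_fr(w["g2"]); p.b2 = as_fr(w["b2"]);
  p.g3 = as_fr(w["g3"]); p.b3 = as_fr(w["b3"]);
  p.g4 = as_fr(w["g4"]); p.b4 = as_fr(w["b4"]);
  p.rm1 = as_fr(run["rm1"]); p.rv1 = as_fr(run["rv1"]);
  p.rm2 = as_fr(run["rm2"]); p.rv2 = as_fr(run["rv2"]);
  p.rm3 = as_fr(run["rm3"]); p.rv3 = as_fr(run["rv3"]);
  p.rm4 = as_fr(run["rm4"]); p.rv4 = as_fr(run["rv4"]);
  return p;
}

static List write_params(const Params& p, bool separable) {
  List w = List::create(
    Rcpp::Named("K1") = arma::conv_to<arma::mat>::from(p.K1),
    Rcpp::Named("K2") = arma::conv_to<arma::mat>::from(p.K2),
    Rcpp::Named("W1") = arma::conv_to<arma::mat>::from(p.W1),
    Rcpp::Named("W2") = arma::conv_to<arma::mat>::from(p.W2),
    Rcpp::Named("g1") = arma::conv_to<arma::rowvec>::from(p.g1),
    Rcpp::Named("b1") = arma::conv_to<arma::rowvec>::from(p.b1),
    Rcpp::Named("g2") = arma::conv_to<arma::rowvec>::from(p.g2),
    Rcpp::Named("b2") = arma::conv_to<arma::rowvec>::from(p.b2),
    Rcpp::Named("g3") = arma::conv_to<arma::rowvec>::from(p.g3),
    Rcpp::Named("b3") = arma::conv_to<arma::rowvec>::from(p.b3),
    Rcpp::Named("g4") = arma::conv_to<arma::rowvec>::from(p.g4),
    Rcpp::Named("b4") = arma::conv_to<arma::rowvec>::from(p.b4));
  if (separable) {
    w["K1b"] = arma::conv_to<arma::mat>::from(p.K1b);
    w["K2b"] = arma::conv_to<arma::mat>::from(p.K2b);
  }
  return w;
}

static List write_running(const Params& p) {
  return List::create(
    Rcpp::Named("rm1") = arma::conv_to<arma::rowvec>::from(p.rm1),
    Rcpp::Named("rv1") = arma::conv_to<arma::rowvec>::from(p.rv1),
    Rcpp::Named("rm2") = arma::conv_to<arma::rowvec>::from(p.rm2),
    Rcpp::Named("rv2") = arma::conv_to<arma::rowvec>::from(p.rv2),
    Rcpp::Named("rm3") = arma::conv_to<arma::rowvec>::from(p.rm3),
    Rcpp::Named("rv3") = arma::conv_to<arma::rowvec>::from(p.rv3),
    Rcpp::Named("rm4") = arma::conv_to<arma::rowvec>::from(p.rm4),
    Rcpp::Named("rv4") = arma::conv_to<arma::rowvec>::from(p.rv4));
}

// Reshape batch rows into the internal (n*P) x 1 feature-map layout.
static fmat input_map(const fmat& X) {
  const int n = X.n_rows, P = X.n_cols;
  fmat F(n * P, 1);
  float* dst = F.colptr(0);
  for (int s = 0; s < n; ++s)
    for (int p = 0; p < P; ++p)
      dst[s * P + p] = X(s, p);
  return F;
}

static fmat flatten_map(const fmat& F, int n, int P) {
  const int C = F.n_cols;
  fmat out(n, P * C);
  for (int ci = 0; ci < C; ++ci) {
    const float* src = F.colptr(ci);
    for (int s = 0; s < n; ++s) {
      const float* sp = src + s * P;
      for (int p = 0; p < P; ++p) out(s, ci * P + p) = sp[p];
    }
  }
  return out;
}

static fmat unflatten_map(const fmat& Xf, int n, int P, int C) {
  fmat F(n * P, C);
  for (int ci = 0; ci < C; ++ci) {
    float* dst = F.colptr(ci);
    for (int s = 0; s < n; ++s)
      for (int p = 0; p < P; ++p)
        dst[s * P + p] = Xf(s, ci * P + p);
  }
  return F;
}

struct ForwardCache {
  fmat F0, col1, col1b_in, a1, m1;           // conv1 stage
  fmat col2, col2b_in, a2, m2;               // conv2 stage
  fmat flat, fc1, a3, m3, fc2, a4, m4, prob; // dense stages
  BNCache bn1, bn2, bn3, bn4;
};

// Full forward pass; train mode uses batch statistics and fills caches.
static fmat forward(const fmat& X, Params& p, const Config& c, bool train,
                    ForwardCache& cc) {
  const int n = X.n_rows, P = c.H * c.W;
  static const OffsetList off9 = offsets3x3();
  static const OffsetList off3 = offsets3x1();

  cc.F0 = input_map(X);
  fmat z1;
  if (!c.separable) {
    cc.col1 = im2col(cc.F0, n, c.H, c.W, off9);
    z1 = cc.col1 * p.K1;
  } else {
    cc.col1 = im2col(cc.F0, n, c.H, c.W, off3);
    cc.col1b_in = cc.col1 * p.K1;            // 3x1 conv output
    z1 = depthwise1x3(cc.col1b_in, n, c.H, c.W, p.K1b);
  }
  fmat h1 = train
    ? bn_forward_train(z1, p.g1, p.b1, p.rm1, p.rv1, c.bn_eps, c.bn_mom, cc.bn1)
    : bn_forward_eval(z1, p.g1, p.b1, p.rm1, p.rv1, c.bn_eps);
  cc.a1 = leaky(h1, c.slope, cc.m1);

  fmat z2;
  if (!c.separable) {
    cc.col2 = im2col(cc.a1, n, c.H, c.W, off9);
    z2 = cc.col2 * p.K2;
  } else {
    cc.col2 = im2col(cc.a1, n, c.H, c.W, off3);
    cc.col2b_in = cc.col2 * p.K2;
    z2 = depthwise1x3(cc.col2b_in, n, c.H, c.W, p.K2b);
  }
  fmat h2 = train
    ? bn_forward_train(z2, p.g2, p.b2, p.rm2, p.rv2, c.bn_eps, c.bn_mom, cc.bn2)
    : bn_forward_eval(z2, p.g2, p.b2, p.rm2, p.rv2, c.bn_eps);
  cc.a2 = leaky(h2, c.slope, cc.m2);

  cc.flat = flatten_map(cc.a2, n, P);
  cc.fc1 = cc.flat * p.W1;
  fmat h3 = train
    ? bn_forward_train(cc.fc1, p.g3, p.b3, p.rm3, p.rv3, c.bn_eps, c.bn_mom, cc.bn3)
    : bn_forward_eval(cc.fc1, p.g3, p.b3, p.rm3, p.rv3, c.bn_eps);
  cc.a3 = leaky(h3, c.slope, cc.m3);

  cc.fc2 = cc.a3 * p.W2;
  fmat h4 = train
    ? bn_forward_train(cc.fc2, p.g4, p.b4, p.rm4, p.rv4, c.bn_eps, c.bn_mom, cc.bn4)
    : bn_forward_eval(cc.fc2, p.g4, p.b4, p.rm4, p.rv4, c.bn_eps);
  cc.a4 = leaky(h4, c.slope, cc.m4);

  fmat logits = cc.a4;
  logits.each_col() -= arma::max(logits, 1);
  fmat e = arma::exp(logits);
  cc.prob = e.each_col() / arma::sum(e, 1);
  return cc.prob;
}

struct Grads {
  fmat K1, K1b, K2, K2b, W1, W2;
  frowvec g1, b1, g2, b2, g3, b3, g4, b4;
};

// Backward pass from softmax cross-entropy; y is 0-based labels.
static double backward(const arma::ivec& y, Params& p, const Config& c,
                       ForwardCache& cc, Grads& gr) {
  const int n = cc.prob.n_rows, P = c.H * c.W;
  static const OffsetList off9 = offsets3x3();
  static const OffsetList off3 = offsets3x1();

  double loss = 0.0;
  fmat dlog = cc.prob;
  for (int s = 0; s < n; ++s) {
    loss -= std::log(std::max(cc.prob(s, y[s]), 1e-30f));
    dlog(s, y[s]) -= 1.0f;
  }
  loss /= n;
  dlog /= (float)n;

  fmat d_a4 = dlog % cc.m4;
  fmat d_fc2 = bn_backward(d_a4, p.g4, cc.bn4, gr.g4, gr.b4);
  gr.W2 = cc.a3.t() * d_fc2;
  fmat d_a3 = (d_fc2 * p.W2.t()) % cc.m3;
  fmat d_fc1 = bn_backward(d_a3, p.g3, cc.bn3, gr.g3, gr.b3);
  gr.W1 = cc.flat.t() * d_fc1;
  fmat d_flat = d_fc1 * p.W1.t();
  fmat d_a2 = unflatten_map(d_flat, n, P, c.C2) % cc.m2;
  fmat d_z2 = bn_backward(d_a2, p.g2, cc.bn2, gr.g2, gr.b2);

  fmat d_a1;
  if (!c.separable) {
    gr.K2 = cc.col2.t() * d_z2;
    d_a1 = col2im(d_z2 * p.K2.t(), n, c.H, c.W, c.C1, off9);
  } else {
    fmat d_mid;
    depthwise1x3_bwd(cc.col2b_in, d_z2, n, c.H, c.W, p.K2b, d_mid, gr.K2b);
    gr.K2 = cc.col2.t() * d_mid;
    d_a1 = col2im(d_mid * p.K2.t(), n, c.H, c.W, c.C1, off3);
  }
  d_a1 %= cc.m1;
  fmat d_z1 = bn_backward(d_a1, p.g1, cc.bn1, gr.g1, gr.b1);
  if (!c.separable) {
    gr.K1 = cc.col1.t() * d_z1;
  } else {
    fmat d_mid;
    depthwise1x3_bwd(cc.col1b_in, d_z1, n, c.H, c.W, p.K1b, d_mid, gr.K1b);
    gr.K1 = cc.col1.t() * d_mid;
  }
  return loss;
}

struct Adam {
  std::vector<fmat> m, v;
  long t;
  float lr, b1, b2, eps;
  void init(const std::vector<fmat*>& ws) {
    t = 0;
    m.clear(); v.clear();
    for (size_t i = 0; i < ws.size(); ++i) {
      m.push_back(fmat(ws[i]->n_rows, ws[i]->n_cols, arma::fill::zeros));
      v.push_back(fmat(ws[i]->n_rows, ws[i]->n_cols, arma::fill::zeros));
    }
  }
  void step(std::vector<fmat*>& ws, std::vector<fmat*>& gs) {
    ++t;
    const float c1 = 1.0f - std::pow(b1, (float)t);
    const float c2 = 1.0f - std::pow(b2, (float)t);
    for (size_t i = 0; i < ws.size(); ++i) {
      float* __restrict w = ws[i]->memptr();
      const float* __restrict g = gs[i]->memptr();
      float* __restrict mi = m[i].memptr();
      float* __restrict vi = v[i].memptr();
      const size_t n = ws[i]->n_elem;
      const float a1 = 1.0f - b1, a2 = 1.0f - b2;
      const float scale = lr / c1, inv_c2 = 1.0f / c2;
      for (size_t j = 0; j < n; ++j) {       // moment update (SIMD-friendly)
        mi[j] = b1 * mi[j] + a1 * g[j];
        vi[j] = b2 * vi[j] + a2 * g[j] * g[j];
      }
      for (size_t j = 0; j < n; ++j)
        w[j] -= scale * mi[j] / (std::sqrt(vi[j] * inv_c2) + eps);
    }
  }
};

static void collect(Params& p, Grads& g, bool separable,
                    std::vector<fmat*>& ws, std::vector<fmat*>& gs,
                    std::vector<fmat>& rowholder) {
  // gamma/beta rowvecs are wrapped as 1 x C fmats referencing copies;
  // simpler: treat them via temporary fmat views held in rowholder.
  ws.push_back(&p.K1); gs.push_back(&g.K1);
  ws.push_back(&p.K2); gs.push_back(&g.K2);
  if (separable) {
    ws.push_back(&p.K1b); gs.push_back(&g.K1b);
    ws.push_back(&p.K2b); gs.push_back(&g.K2b);
  }
  ws.push_back(&p.W1); gs.push_back(&g.W1);
  ws.push_back(&p.W2); gs.push_back(&g.W2);
  (void)rowholder;
}

// [[Rcpp::export(name = ".cnn_train_cpp")]]
List cnn_train_cpp(NumericMatrix X_, IntegerVector y_, List weights,
                   List running, List cfg, IntegerMatrix perm, List tcfg) {
  Config c = read_config(cfg);
  Params p = read_params(weights, running, c.separable);
  fmat X = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(X_));
  arma::ivec y = Rcpp::as<arma::ivec>(y_) - 1;   // to 0-based
  const int n = X.n_rows;
  const int epochs = Rcpp::as<int>(tcfg["epochs"]);
  int batch = std::min(n, Rcpp::as<int>(tcfg["batch_size"]));

  Adam opt;
  opt.lr = Rcpp::as<double>(tcfg["learning_rate"]);
  opt.b1 = 0.9f; opt.b2 = 0.999f; opt.eps = 1e-8f;

  // Matrix parameters get Adam via pointers; BN gamma/beta are rowvecs and
  // get their own scalar-state Adam below.
  Grads gr;
  gr.K1.zeros(p.K1.n_rows, p.K1.n_cols);
  gr.K2.zeros(p.K2.n_rows, p.K2.n_cols);
  if (c.separable) {
    gr.K1b.zeros(p.K1b.n_rows, p.K1b.n_cols);
    gr.K2b.zeros(p.K2b.n_rows, p.K2b.n_cols);
  }
  gr.W1.zeros(p.W1.n_rows, p.W1.n_cols);
  gr.W2.zeros(p.W2.n_rows, p.W2.n_cols);
  std::vector<fmat*> ws, gs; std::vector<fmat> hold;
  collect(p, gr, c.separable, ws, gs, hold);
  opt.init(ws);

  frowvec* bnw[8] = { &p.g1, &p.b1, &p.g2, &p.b2, &p.g3, &p.b3, &p.g4, &p.b4 };
  frowvec* bng[8] = { &gr.g1, &gr.b1, &gr.g2, &gr.b2, &gr.g3, &gr.b3,
                      &gr.g4, &gr.b4 };
  std::vector<frowvec> bnm(8), bnv(8);
  for (int i = 0; i < 8; ++i) {
    bnm[i] = arma::zeros<frowvec>(bnw[i]->n_elem);
    bnv[i] = arma::zeros<frowvec>(bnw[i]->n_elem);
  }

  Rcpp::NumericVector trace(epochs);
  ForwardCache cc;
  for (int e = 0; e < epochs; ++e) {
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (int start = 0; start < n; start += batch) {
      const int stop = std::min(start + batch, n) - 1;
      arma::uvec idx(stop - start + 1);
      arma::ivec yb(stop - start + 1);
      for (int i = start; i <= stop; ++i) {
        const int s = perm(e, i) - 1;
        idx[i - start] = s;
        yb[i - start] = y[s];
      }
      fmat Xb = X.rows(idx);
      forward(Xb, p, c, true, cc);
      double loss = backward(yb, p, c, cc, gr);
      epoch_loss += loss;
      ++n_batches;
      opt.step(ws, gs);
      const float c1 = 1.0f - std::pow(opt.b1, (float)opt.t);
      const float c2 = 1.0f - std::pow(opt.b2, (float)opt.t);
      for (int i = 0; i < 8; ++i) {
        bnm[i] = opt.b1 * bnm[i] + (1.0f - opt.b1) * (*bng[i]);
        bnv[i] = opt.b2 * bnv[i] + (1.0f - opt.b2) * arma::square(*bng[i]);
        *bnw[i] -= opt.lr * (bnm[i] / c1) / (arma::sqrt(bnv[i] / c2) + opt.eps);
      }
    }
    trace[e] = epoch_loss / n_batches;
  }
  return List::create(Rcpp::Named("weights") = write_params(p, c.separable),
                      Rcpp::Named("running") = write_running(p),
                      Rcpp::Named("loss_trace") = trace);
}

// [[Rcpp::export(name = ".cnn_predict_cpp")]]
NumericMatrix cnn_predict_cpp(NumericMatrix X_, List weights, List running,
                              List cfg) {
  Config c = read_config(cfg);
  Params p = read_params(weights, running, c.separable);
  fmat X = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(X_));
  ForwardCache cc;
  fmat prob = forward(X, p, c, false, cc);
  arma::mat out = arma::conv_to<arma::mat>::from(prob);
  return Rcpp::wrap(out);
}

// Train-mode loss and analytic gradients for one batch, without updating
// anything: used to verify backpropagation against finite differences.
// [[Rcpp::export(name = ".cnn_lossgrad_cpp")]]
List cnn_lossgrad_cpp(NumericMatrix X_, IntegerVector y_, List weights,
                      List running, List cfg) {
  Config c = read_config(cfg);
  Params p = read_params(weights, running, c.separable);
  fmat X = arma::conv_to<fmat>::from(Rcpp::as<arma::mat>(X_));
  arma::ivec y = Rcpp::as<arma::ivec>(y_) - 1;
  ForwardCache cc;
  // keep running stats untouched by working on copies
  frowvec rm1 = p.rm1, rv1 = p.rv1, rm2 = p.rm2, rv2 = p.rv2,
          rm3 = p.rm3, rv3 = p.rv3, rm4 = p.rm4, rv4 = p.rv4;
  forward(X, p, c, true, cc);
  p.rm1 = rm1; p.rv1 = rv1; p.rm2 = rm2; p.rv2 = rv2;
  p.rm3 = rm3; p.rv3 = rv3; p.rm4 = rm4; p.rv4 = rv4;
  Grads gr;
  double loss = backward(y, p, c, cc, gr);
  List g = List::create(
    Rcpp::Named("K1") = arma::conv_to<arma::mat>::from(gr.K1),
    Rcpp::Named("K2") = arma::conv_to<arma::mat>::from(gr.K2),
    Rcpp::Named("W1") = arma::conv_to<arma::mat>::from(gr.W1),
    Rcpp::Named("W2") = arma::conv_to<arma::mat>::from(gr.W2),
    Rcpp::Named("g1") = arma::conv_to<arma::rowvec>::from(gr.g1),
    Rcpp::Named("b1") = arma::conv_to<arma::rowvec>::from(gr.b1),
    Rcpp::Named("g2") = arma::conv_to<arma::rowvec>::from(gr.g2),
    Rcpp::Named("b2") = arma::conv_to<arma::rowvec>::from(gr.b2),
    Rcpp::Named("g3") = arma::conv_to<arma::rowvec>::from(gr.g3),
    Rcpp::Named("b3") = arma::conv_to<arma::rowvec>::from(gr.b3),
    Rcpp::Named("g4") = arma::conv_to<arma::rowvec>::from(gr.g4),
    Rcpp::Named("b4") = arma::conv_to<arma::rowvec>::from(gr.b4));
  if (c.separable) {
    g["K1b"] = arma::conv_to<arma::mat>::from(gr.K1b);
    g["K2b"] = arma::conv_to<arma::mat>::from(gr.K2b);
  }
  return List::create(Rcpp::Named("loss") = loss, Rcpp::Named("grads") = g);
}
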