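// Nested-UNet (UNet++) engine: 3x3 convolutions with batch normalization and
// ReLU, 2x2 max pooling, 2x2 stride-2 transposed-convolution upsampling,
// dense in-level skip concatenations and a sigmoid 1x1 head. Training uses
// the hybrid Dice/focal/cross-entropy loss and the RAdam optimizer, all in
// single precision. Feature maps are stored as (H*W*batch x channels)
// matrices, pixels column-major within each sample, so that every
// gather/scatter runs over contiguous column segments.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <vector>
#include <cstring>
using namespace arma;

struct Param {
  fmat w, g, m, v;
  void init(int r, int c, float sd) {
    if (sd > 0) {
      Rcpp::NumericVector rn = Rcpp::rnorm(r * c, 0.0, sd);
      w.set_size(r, c);
      for (int i = 0; i < r * c; ++i) w[i] = (float)rn[i];
    } else {
      w.zeros(r, c);
    }
    g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
  void init_const(int r, int c, float val) {
    w.set_size(r, c); w.fill(val);
    g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};

struct ConvLayer {            // k x k convolution, stride 1, pad (k-1)/2
  int cin = 0, cout = 0, k = 3;
  Param W, b;                 // W: (k*k*cin, cout), b: (cout, 1)
  void build(int ci, int co, int kk) {
    cin = ci; cout = co; k = kk;
    W.init(kk * kk * ci, co, std::sqrt(2.0f / (kk * kk * ci)));
    b.init(co, 1, 0.0f);
  }
  long n_par() const { return (long)W.w.n_elem + b.w.n_elem; }
};

struct BNLayer {
  int c = 0;
  Param gamma, beta;
  fvec rm, rv;                // running mean / variance for eval mode
  void build(int cc) {
    c = cc;
    gamma.init_const(cc, 1, 1.0f);
    beta.init(cc, 1, 0.0f);
    rm.zeros(cc); rv.ones(cc);
  }
  long n_par() const { return 2L * c; }
};

struct DeconvLayer {          // 2x2 stride-2 transposed convolution
  int cin = 0, cout = 0;
  Param W, b;                 // W: (4*cin, cout), one 2x2 tap per row block
  void build(int ci, int co) {
    cin = ci; cout = co;
    W.init(4 * ci, co, std::sqrt(2.0f / (4.0f * ci)));
    b.init(co, 1, 0.0f);
  }
  long n_par() const { return (long)W.w.n_elem + b.w.n_elem; }
};

struct Block {                // conv-BN-ReLU twice
  ConvLayer c1, c2;
  BNLayer n1, n2;
  void build(int cin, int cout) {
    c1.build(cin, cout, 3); n1.build(cout);
    c2.build(cout, cout, 3); n2.build(cout);
  }
  long n_par() const {
    return c1.n_par() + c2.n_par() + n1.n_par() + n2.n_par();
  }
};

// ---- primitive ops ----

extern "C" void sgemm_(const char* transa, const char* transb,
                       const int* m, const int* n, const int* k,
                       const float* alpha, const float* a, const int* lda,
                       const float* b, const int* ldb, const float* beta,
                       float* c, const int* ldc);

static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* a, int lda, const float* b, int ldb,
                  float beta, float* c, int ldc) {
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, a, &lda, b, &ldb, &beta, c, &ldc);
}

// scratch buffers for the tiled im2col (single-threaded use)
static std::vector<float> g_colbuf, g_dcolbuf;

// image-column tile size keeping the col buffer (~tile*H*9C floats) in L2
static inline int conv_tile(int H, int C) {
  int cb = (int)(65536 / ((size_t)H * 9 * C));
  return std::max(1, std::min(cb, 64));
}

// tile of one sample: X block (cols [c0,c1), stride ldx per channel) ->
// col ((c1-c0)*H x 9C)
static void im2col_tile(const float* X, size_t ldx, int C, int H, int W,
                        int c0, int c1, float* col) {
  size_t HT = (size_t)(c1 - c0) * H;
  std::memset(col, 0, HT * 9 * C * sizeof(float));
  for (int t = 0; t < 9; ++t) {
    int dr = t % 3 - 1, dc = t / 3 - 1;
    int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
    int len = r1 - r0;
    if (len <= 0) continue;
    for (int ch = 0; ch < C; ++ch) {
      const float* src = X + (size_t)ch * ldx;
      float* dst = col + ((size_t)t * C + ch) * HT - (size_t)c0 * H;
      for (int c = c0; c < c1; ++c) {
        int sc = c + dc;
        if (sc < 0 || sc >= W) continue;
        std::memcpy(dst + (size_t)c * H + r0,
                    src + (size_t)sc * H + r0 + dr, len * sizeof(float));
      }
    }
  }
}

// scatter-add transpose of im2col_tile into dX (whole sample block)
static void col2im_tile(const float* dcol, size_t ldx, int C, int H, int W,
                        int c0, int c1, float* dX) {
  size_t HT = (size_t)(c1 - c0) * H;
  for (int t = 0; t < 9; ++t) {
    int dr = t % 3 - 1, dc = t / 3 - 1;
    int r0 = std::max(0, -dr), r1 = std::min(H, H - dr);
    int len = r1 - r0;
    if (len <= 0) continue;
    for (int ch = 0; ch < C; ++ch) {
      const float* src = dcol + ((size_t)t * C + ch) * HT -
        (size_t)c0 * H;
      float* dst = dX + (size_t)ch * ldx;
      for (int c = c0; c < c1; ++c) {
        int sc = c + dc;
        if (sc < 0 || sc >= W) continue;
        float* d = dst + (size_t)sc * H + r0 + dr;
        const float* s = src + (size_t)c * H + r0;
        for (int i = 0; i < len; ++i) d[i] += s[i];
      }
    }
  }
}

static void add_bias(fmat& A, const fmat& b) {
  for (size_t ch = 0; ch < A.n_cols; ++ch) A.col(ch) += b(ch, 0);
}

static fmat conv_fwd(const ConvLayer& L, const fmat& X, int H, int W, int B) {
  if (L.k == 1) {
    fmat out = X * L.W.w;
    add_bias(out, L.b.w);
    return out;
  }
  size_t HW = (size_t)H * W, P = HW * B;
  fmat out(P, L.cout);
  int CB = conv_tile(H, L.cin);
  size_t need = (size_t)CB * H * 9 * L.cin;
  if (g_colbuf.size() < need) g_colbuf.resize(need);
  for (int b = 0; b < B; ++b) {
    const float* Xb = X.memptr() + (size_t)b * HW;
    for (int c0 = 0; c0 < W; c0 += CB) {
      int c1 = std::min(W, c0 + CB);
      int m = (c1 - c0) * H;
      im2col_tile(Xb, P, L.cin, H, W, c0, c1, g_colbuf.data());
      sgemm('N', 'N', m, L.cout, 9 * L.cin, 1.0f, g_colbuf.data(), m,
            L.W.w.memptr(), 9 * L.cin, 0.0f,
            out.memptr() + (size_t)b * HW + (size_t)c0 * H, (int)P);
    }
  }
  add_bias(out, L.b.w);
  return out;
}

static fmat conv_bwd(ConvLayer& L, const fmat& X, const fmat& dY,
                     int H, int W, int B) {
  L.b.g += sum(dY, 0).t();
  if (L.k == 1) {
    L.W.g += X.t() * dY;
    return dY * L.W.w.t();
  }
  size_t HW = (size_t)H * W, P = HW * B;
  fmat dX(P, L.cin, fill::zeros);
  int CB = conv_tile(H, L.cin);
  size_t need = (size_t)CB * H * 9 * L.cin;
  if (g_colbuf.size() < need) g_colbuf.resize(need);
  if (g_dcolbuf.size() < need) g_dcolbuf.resize(need);
  for (int b = 0; b < B; ++b) {
    const float* Xb = X.memptr() + (size_t)b * HW;
    float* dXb = dX.memptr() + (size_t)b * HW;
    for (int c0 = 0; c0 < W; c0 += CB) {
      int c1 = std::min(W, c0 + CB);
      int m = (c1 - c0) * H;
      const float* dYt = dY.memptr() + (size_t)b * HW + (size_t)c0 * H;
      im2col_tile(Xb, P, L.cin, H, W, c0, c1, g_colbuf.data());
      // dW += col^T dY_tile
      sgemm('T', 'N', 9 * L.cin, L.cout, m, 1.0f, g_colbuf.data(), m,
            dYt, (int)P, 1.0f, L.W.g.memptr(), 9 * L.cin);
      // dcol = dY_tile W^T
      sgemm('N', 'T', m, 9 * L.cin, L.cout, 1.0f, dYt, (int)P,
            L.W.w.memptr(), 9 * L.cin, 0.0f, g_dcolbuf.data(), m);
      col2im_tile(g_dcolbuf.data(), P, L.cin, H, W, c0, c1, dXb);
    }
  }
  return dX;
}

struct BNCache { fvec mu, istd; };

static fmat bn_fwd(BNLayer& L, const fmat& Z, bool training, BNCache& cache) {
  const float eps = 1e-5f, mom = 0.1f;
  int C = L.c;
  float N = (float)Z.n_rows;
  cache.mu.set_size(C); cache.istd.set_size(C);
  fmat out(Z.n_rows, C);
  for (int ch = 0; ch < C; ++ch) {
    float mu, var;
    if (training) {
      mu = accu(Z.col(ch)) / N;
      var = accu(square(Z.col(ch) - mu)) / N;
      L.rm[ch] = (1 - mom) * L.rm[ch] + mom * mu;
      L.rv[ch] = (1 - mom) * L.rv[ch] + mom * var;
    } else {
      mu = L.rm[ch]; var = L.rv[ch];
    }
    float istd = 1.0f / std::sqrt(var + eps);
    cache.mu[ch] = mu; cache.istd[ch] = istd;
    out.col(ch) = (Z.col(ch) - mu) * (istd * L.gamma.w(ch, 0)) +
      L.beta.w(ch, 0);
  }
  return out;
}

static fmat bn_bwd(BNLayer& L, const fmat& dY, const fmat& Z,
                   const BNCache& cache) {
  float N = (float)Z.n_rows;
  fmat dZ(Z.n_rows, Z.n_cols);
  for (int ch = 0; ch < L.c; ++ch) {
    fvec xhat = (Z.col(ch) - cache.mu[ch]) * cache.istd[ch];
    fvec dy = dY.col(ch);
    float dg = accu(dy % xhat), db = accu(dy);
    L.gamma.g(ch, 0) += dg;
    L.beta.g(ch, 0) += db;
    float gam = L.gamma.w(ch, 0);
    dZ.col(ch) = (gam * cache.istd[ch] / N) *
      (N * dy - db - xhat * dg);
  }
  return dZ;
}

static inline void relu_inplace(fmat& A) {
  float* p = A.memptr();
  for (size_t i = 0; i < A.n_elem; ++i) if (p[i] < 0) p[i] = 0;
}

static inline void relu_bwd_inplace(fmat& d, const fmat& out) {
  float* dp = d.memptr();
  const float* op = out.memptr();
  for (size_t i = 0; i < d.n_elem; ++i) if (op[i] <= 0) dp[i] = 0;
}

static fmat pool_fwd(const fmat& X, int C, int H, int W, int B,
                     Mat<unsigned int>& arg) {
  int Ho = H / 2, Wo = W / 2;
  size_t HWo = (size_t)Ho * Wo, HW = (size_t)H * W;
  fmat out(HWo * B, C);
  arg.set_size(HWo * B, C);
  for (int ch = 0; ch < C; ++ch) {
    const float* x = X.colptr(ch);
    float* o = out.colptr(ch);
    unsigned int* a = arg.colptr(ch);
    for (int b = 0; b < B; ++b) {
      size_t offi = (size_t)b * HW, offo = (size_t)b * HWo;
      for (int c = 0; c < Wo; ++c) {
        const float* base = x + offi + (size_t)(2 * c) * H;
        size_t ibase = offi + (size_t)(2 * c) * H;
        for (int r = 0; r < Ho; ++r) {
          size_t i0 = 2 * r, i1 = i0 + 1, i2 = i0 + H, i3 = i2 + 1;
          float best = base[i0]; size_t bi = ibase + i0;
          if (base[i1] > best) { best = base[i1]; bi = ibase + i1; }
          if (base[i2] > best) { best = base[i2]; bi = ibase + i2; }
          if (base[i3] > best) { best = base[i3]; bi = ibase + i3; }
          o[offo + (size_t)c * Ho + r] = best;
          a[offo + (size_t)c * Ho + r] = (unsigned int)bi;
        }
      }
    }
  }
  return out;
}

static fmat pool_bwd(const fmat& dY, const Mat<unsigned int>& arg, int C,
                     size_t nrows_in) {
  fmat dX(nrows_in, C, fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const float* dy = dY.colptr(ch);
    const unsigned int* a = arg.colptr(ch);
    float* dx = dX.colptr(ch);
    for (size_t p = 0; p < dY.n_rows; ++p) dx[a[p]] += dy[p];
  }
  return dX;
}

// input (Hs*Ws*B, Cin) at the coarse scale -> output (2Hs*2Ws*B, Cout);
// stride = kernel = 2, so each output pixel receives exactly one tap.
static fmat deconv_fwd(const DeconvLayer& L, const fmat& X, int Hs, int Ws,
                       int B) {
  int H = 2 * Hs;
  size_t HWs = (size_t)Hs * Ws, HW = (size_t)H * 2 * Ws;
  fmat out(HW * B, L.cout);
  for (int t = 0; t < 4; ++t) {
    int dr = t % 2, dc = t / 2;
    fmat Yt = X * L.W.w.rows(t * L.cin, (t + 1) * L.cin - 1);
    add_bias(Yt, L.b.w);
    for (int ch = 0; ch < L.cout; ++ch) {
      const float* y = Yt.colptr(ch);
      float* o = out.colptr(ch);
      for (int b = 0; b < B; ++b) {
        size_t offs = (size_t)b * HWs, offo = (size_t)b * HW;
        for (int c = 0; c < Ws; ++c) {
          const float* ys = y + offs + (size_t)c * Hs;
          float* od = o + offo + (size_t)(2 * c + dc) * H + dr;
          for (int r = 0; r < Hs; ++r) od[2 * r] = ys[r];
        }
      }
    }
  }
  return out;
}

static fmat deconv_bwd(DeconvLayer& L, const fmat& X, const fmat& dY,
                       int Hs, int Ws, int B) {
  int H = 2 * Hs;
  size_t HWs = (size_t)Hs * Ws, HW = (size_t)H * 2 * Ws;
  fmat dX(X.n_rows, L.cin, fill::zeros);
  fmat dYt(X.n_rows, L.cout);
  for (int t = 0; t < 4; ++t) {
    int dr = t % 2, dc = t / 2;
    for (int ch = 0; ch < L.cout; ++ch) {
      float* d = dYt.colptr(ch);
      const float* dy = dY.colptr(ch);
      for (int b = 0; b < B; ++b) {
        size_t offs = (size_t)b * HWs, offo = (size_t)b * HW;
        for (int c = 0; c < Ws; ++c) {
          float* dd = d + offs + (size_t)c * Hs;
          const float* ds = dy + offo + (size_t)(2 * c + dc) * H + dr;
          for (int r = 0; r < Hs; ++r) dd[r] = ds[2 * r];
        }
      }
    }
    L.W.g.rows(t * L.cin, (t + 1) * L.cin - 1) += X.t() * dYt;
    L.b.g += sum(dYt, 0).t();
    dX += dYt * L.W.w.rows(t * L.cin, (t + 1) * L.cin - 1).t();
  }
  return dX;
}

// ---- network ----

struct Net {
  int L = 5, Cin = 1;
  std::vector<int> w;
  std::vector<std::vector<Block>> blocks;    // [i][j], j <= L-1-i
  std::vector<std::vector<DeconvLayer>> ups; // [i][j-1] for j >= 1
  ConvLayer head;
  long step = 0;
  std::vector<Param*> params;

  void build(const std::vector<int>& widths, int cin) {
    w = widths; L = (int)widths.size(); Cin = cin;
    blocks.assign(L, {});
    ups.assign(L, {});
    for (int i = 0; i < L; ++i) {
      int nj = L - i;
      blocks[i].resize(nj);
      for (int j = 0; j < nj; ++j) {
        int in_ch = (j == 0) ? (i == 0 ? Cin : w[i - 1]) : (j + 1) * w[i];
        blocks[i][j].build(in_ch, w[i]);
      }
      if (i < L - 1) {
        ups[i].resize(nj - 1);
        for (int j = 1; j < nj; ++j) ups[i][j - 1].build(w[i + 1], w[i]);
      }
    }
    head.build(w[0], 1, 1);
    collect();
  }

  void collect() {
    params.clear();
    auto add = [&](Param& p) { params.push_back(&p); };
    for (int i = 0; i < L; ++i) {
      for (auto& blk : blocks[i]) {
        add(blk.c1.W); add(blk.c1.b); add(blk.n1.gamma); add(blk.n1.beta);
        add(blk.c2.W); add(blk.c2.b); add(blk.n2.gamma); add(blk.n2.beta);
      }
      for (auto& u : ups[i]) { add(u.W); add(u.b); }
    }
    add(head.W); add(head.b);
  }

  long n_par() const {
    long n = head.n_par();
    for (int i = 0; i < L; ++i) {
      for (auto& blk : blocks[i]) n += blk.n_par();
      for (auto& u : ups[i]) n += u.n_par();
    }
    return n;
  }

  void zero_grad() { for (auto* p : params) p->g.zeros(); }

  void radam_step(float lr) {
    const float b1 = 0.9f, b2 = 0.999f, eps = 1e-8f;
    ++step;
    float t = (float)step;
    float b1t = std::pow(b1, t), b2t = std::pow(b2, t);
    float rho_inf = 2.0f / (1.0f - b2) - 1.0f;
    float rho_t = rho_inf - 2.0f * t * b2t / (1.0f - b2t);
    bool rect = rho_t > 4.0f;
    float r = 1.0f;
    if (rect)
      r = std::sqrt(((rho_t - 4) * (rho_t - 2) * rho_inf) /
                    ((rho_inf - 4) * (rho_inf - 2) * rho_t));
    for (auto* p : params) {
      p->m = b1 * p->m + (1 - b1) * p->g;
      p->v = b2 * p->v + (1 - b2) * square(p->g);
      fmat mhat = p->m / (1 - b1t);
      if (rect) {
        fmat vhat = sqrt(p->v / (1 - b2t)) + eps;
        p->w -= lr * r * mhat / vhat;
      } else {
        p->w -= lr * mhat;
      }
    }
  }
};

struct NodeCache {
  fmat in, z1, h1, z2, out;
  BNCache bc1, bc2;
  Mat<unsigned int> pool_arg;   // only for (i > 0, j = 0)
};

struct FwdCtx {
  int H, W, B;
  std::vector<std::vector<NodeCache>> node;  // [i][j]
  fmat logits, prob;
};

static void block_fwd(Block& blk, NodeCache& nc, int H, int W, int B,
                      bool training) {
  nc.z1 = conv_fwd(blk.c1, nc.in, H, W, B);
  nc.h1 = bn_fwd(blk.n1, nc.z1, training, nc.bc1);
  relu_inplace(nc.h1);
  nc.z2 = conv_fwd(blk.c2, nc.h1, H, W, B);
  nc.out = bn_fwd(blk.n2, nc.z2, training, nc.bc2);
  relu_inplace(nc.out);
}

static fmat block_bwd(Block& blk, NodeCache& nc, fmat dOut,
                      int H, int W, int B) {
  relu_bwd_inplace(dOut, nc.out);
  fmat d = bn_bwd(blk.n2, dOut, nc.z2, nc.bc2);
  d = conv_bwd(blk.c2, nc.h1, d, H, W, B);
  relu_bwd_inplace(d, nc.h1);
  d = bn_bwd(blk.n1, d, nc.z1, nc.bc1);
  return conv_bwd(blk.c1, nc.in, d, H, W, B);
}

static void net_forward(Net& net, const fmat& X, int H, int W, int B,
                        bool training, FwdCtx& ctx) {
  int L = net.L;
  ctx.H = H; ctx.W = W; ctx.B = B;
  ctx.node.assign(L, {});
  for (int i = 0; i < L; ++i) ctx.node[i].resize(L - i);
  for (int i = 0; i < L; ++i) {              // backbone column j = 0
    int Hi = H >> i, Wi = W >> i;
    NodeCache& nc = ctx.node[i][0];
    if (i == 0) nc.in = X;
    else
      nc.in = pool_fwd(ctx.node[i - 1][0].out, net.w[i - 1],
                       H >> (i - 1), W >> (i - 1), B, nc.pool_arg);
    block_fwd(net.blocks[i][0], nc, Hi, Wi, B, training);
  }
  for (int j = 1; j < L; ++j) {              // dense columns
    for (int i = 0; i <= L - 1 - j; ++i) {
      int Hi = H >> i, Wi = W >> i;
      NodeCache& nc = ctx.node[i][j];
      fmat up = deconv_fwd(net.ups[i][j - 1], ctx.node[i + 1][j - 1].out,
                           Hi / 2, Wi / 2, B);
      nc.in.set_size(up.n_rows, (size_t)(j + 1) * net.w[i]);
      for (int q = 0; q < j; ++q)
        nc.in.cols(q * net.w[i], (q + 1) * net.w[i] - 1) =
          ctx.node[i][q].out;
      nc.in.cols(j * net.w[i], (j + 1) * net.w[i] - 1) = up;
      block_fwd(net.blocks[i][j], nc, Hi, Wi, B, training);
    }
  }
  ctx.logits = conv_fwd(net.head, ctx.node[0][L - 1].out, H, W, B);
  ctx.prob = 1.0f / (1.0f + exp(-ctx.logits));
}

static void net_backward(Net& net, FwdCtx& ctx, const fmat& dlogits) {
  int L = net.L, H = ctx.H, W = ctx.W, B = ctx.B;
  std::vector<std::vector<fmat>> dout(L);    // gradient at each node output
  for (int i = 0; i < L; ++i) {
    dout[i].resize(L - i);
    for (int j = 0; j < L - i; ++j)
      dout[i][j].zeros(ctx.node[i][j].out.n_rows, net.w[i]);
  }
  dout[0][L - 1] += conv_bwd(net.head, ctx.node[0][L - 1].out, dlogits,
                             H, W, B);
  for (int j = L - 1; j >= 1; --j) {
    for (int i = L - 1 - j; i >= 0; --i) {
      int Hi = H >> i, Wi = W >> i;
      NodeCache& nc = ctx.node[i][j];
      fmat dIn = block_bwd(net.blocks[i][j], nc, dout[i][j], Hi, Wi, B);
      for (int q = 0; q < j; ++q)
        dout[i][q] += dIn.cols(q * net.w[i], (q + 1) * net.w[i] - 1);
      fmat dUp = dIn.cols(j * net.w[i], (j + 1) * net.w[i] - 1);
      dout[i + 1][j - 1] += deconv_bwd(net.ups[i][j - 1],
                                       ctx.node[i + 1][j - 1].out, dUp,
                                       Hi / 2, Wi / 2, B);
    }
  }
  for (int i = L - 1; i >= 0; --i) {
    NodeCache& nc = ctx.node[i][0];
    fmat dIn = block_bwd(net.blocks[i][0], nc, dout[i][0],
                         H >> i, W >> i, B);
    if (i > 0)
      dout[i - 1][0] += pool_bwd(dIn, nc.pool_arg, net.w[i - 1],
                                 ctx.node[i - 1][0].out.n_rows);
  }
}

// hybrid loss on probabilities, plus gradient wrt logits
static double hybrid_loss_grad(const fmat& P, const fmat& G, int B,
                               double alpha, double beta, double gamma_w,
                               double at, double gf, fmat& dlogit) {
  const double eps = 1e-6, clip = 1e-7;
  size_t N = P.n_elem, per = N / B;
  fmat Pc = clamp(P, (float)clip, (float)(1.0 - clip));
  // Dice: per-sample soft Dice, averaged over the batch
  double dice = 0.0;
  fmat ddice(P.n_rows, 1);
  for (int b = 0; b < B; ++b) {
    size_t r0 = (size_t)b * per, r1 = r0 + per - 1;
    double inter = 0, sp = 0, sg = 0;
    const float* pp = P.memptr(); const float* gg = G.memptr();
    for (size_t i = r0; i <= r1; ++i) {
      inter += (double)pp[i] * gg[i]; sp += pp[i]; sg += gg[i];
    }
    double den = sp + sg + eps;
    dice += 1.0 - (2.0 * inter + eps) / den;
    // d/dP of (1 - (2I+eps)/den) = (-2*den*G + (2I+eps)) / den^2
    float a1 = (float)(-2.0 / den / B);
    float a0 = (float)((2.0 * inter + eps) / (den * den) / B);
    float* dd = ddice.memptr();
    for (size_t i = r0; i <= r1; ++i) dd[i] = a1 * gg[i] + a0;
  }
  dice /= B;
  // Focal and CE (means over all pixels), gradient wrt logits
  double focal = 0, ce = 0;
  dlogit.set_size(P.n_rows, 1);
  const float* pp = P.memptr(); const float* pc = Pc.memptr();
  const float* gg = G.memptr();
  const float* dd = ddice.memptr();
  float* dl = dlogit.memptr();
  for (size_t i = 0; i < N; ++i) {
    double p = pc[i], g = gg[i];
    double pt = g > 0.5 ? p : 1.0 - p;
    double om = 1.0 - pt, lpt = std::log(pt);
    double powg = std::pow(om, gf);
    focal += -at * powg * lpt;
    ce += -(g * std::log(p) + (1 - g) * std::log(1 - p));
    double dfdpt = at * (gf * std::pow(om, gf - 1.0) * lpt - powg / pt);
    double dfocal = dfdpt * (2.0 * g - 1.0) / (double)N;
    double dpdz = (double)pp[i] * (1.0 - pp[i]);
    dl[i] = (float)(alpha * dd[i] * dpdz + beta * dfocal * dpdz +
                    gamma_w * (pp[i] - g) / (double)N);
  }
  focal /= N; ce /= N;
  return alpha * dice + beta * focal + gamma_w * ce;
}

// ---- R interface ----

typedef Rcpp::XPtr<Net> NetPtr;

static fmat r_to_fmat(const Rcpp::NumericVector& x, int H, int W, int C,
                      int B) {
  size_t HW = (size_t)H * W;
  fmat out(HW * B, C);
  const double* src = x.begin();
  for (int b = 0; b < B; ++b)
    for (int ch = 0; ch < C; ++ch) {
      const double* s = src + ((size_t)b * C + ch) * HW;
      float* d = out.colptr(ch) + (size_t)b * HW;
      for (size_t p = 0; p < HW; ++p) d[p] = (float)s[p];
    }
  return out;
}

// [[Rcpp::export(name = ".unetpp_create")]]
SEXP unetpp_create(Rcpp::IntegerVector widths, int in_channels) {
  Net* net = new Net();
  net->build(std::vector<int>(widths.begin(), widths.end()), in_channels);
  return NetPtr(net, true);
}

// [[Rcpp::export(name = ".unetpp_param_count")]]
double unetpp_param_count(SEXP ptr) {
  return (double)NetPtr(ptr)->n_par();
}

// [[Rcpp::export(name = ".unetpp_forward")]]
Rcpp::NumericVector unetpp_forward(SEXP ptr, Rcpp::NumericVector x,
                                   bool training = false) {
  NetPtr net(ptr);
  Rcpp::IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], B = d[3];
  fmat X = r_to_fmat(x, H, W, C, B);
  FwdCtx ctx;
  net_forward(*net, X, H, W, B, training, ctx);
  Rcpp::NumericVector out((size_t)H * W * B);
  const float* p = ctx.prob.memptr();
  for (size_t i = 0; i < (size_t)H * W * B; ++i) out[i] = p[i];
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, B);
  return out;
}

// [[Rcpp::export(name = ".unetpp_train_batch")]]
double unetpp_train_batch(SEXP ptr, Rcpp::NumericVector x,
                          Rcpp::NumericVector g, double lr,
                          double alpha, double beta, double gamma_w,
                          double focal_alpha_t, double focal_gamma_f) {
  NetPtr net(ptr);
  Rcpp::IntegerVector d = x.attr("dim");
  int H = d[0], W = d[1], C = d[2], B = d[3];
  fmat X = r_to_fmat(x, H, W, C, B);
  fmat G = r_to_fmat(g, H, W, 1, B);
  FwdCtx ctx;
  net_forward(*net, X, H, W, B, true, ctx);
  fmat dlogit;
  double loss = hybrid_loss_grad(ctx.prob, G, B, alpha, beta, gamma_w,
                                 focal_alpha_t, focal_gamma_f, dlogit);
  net->zero_grad();
  net_backward(*net, ctx, dlogit);
  net->radam_step((float)lr);
  return loss;
}

// gradients accumulated by the last training step (debug/verification)
// [[Rcpp::export(name = ".unetpp_get_grads")]]
Rcpp::List unetpp_get_grads(SEXP ptr) {
  NetPtr net(ptr);
  Rcpp::List out((int)net->params.size());
  Rcpp::CharacterVector names((int)net->params.size());
  int k = 0;
  for (auto* p : net->params) {
    names[k] = "p" + std::to_string(k);
    out[k] = Rcpp::NumericVector(p->g.begin(), p->g.end());
    ++k;
  }
  out.names() = names;
  return out;
}

// [[Rcpp::export(name = ".unetpp_get_state")]]
Rcpp::List unetpp_get_state(SEXP ptr) {
  NetPtr net(ptr);
  int n = (int)net->params.size(), r = 0;
  for (int i = 0; i < net->L; ++i) r += 2 * (int)net->blocks[i].size();
  Rcpp::List out(n + 2 * r);
  Rcpp::CharacterVector names(n + 2 * r);
  int k = 0;
  for (auto* p : net->params) {
    Rcpp::NumericVector v(p->w.begin(), p->w.end());
    names[k] = "p" + std::to_string(k);
    out[k++] = v;
  }
  int ri = 0;
  auto push_rs = [&](BNLayer& bn) {
    names[k] = "rm" + std::to_string(ri);
    out[k++] = Rcpp::NumericVector(bn.rm.begin(), bn.rm.end());
    names[k] = "rv" + std::to_string(ri);
    out[k++] = Rcpp::NumericVector(bn.rv.begin(), bn.rv.end());
    ++ri;
  };
  for (int i = 0; i < net->L; ++i)
    for (auto& blk : net->blocks[i]) { push_rs(blk.n1); push_rs(blk.n2); }
  out.names() = names;
  return out;
}

// [[Rcpp::export(name = ".unetpp_set_state")]]
void unetpp_set_state(SEXP ptr, Rcpp::List state) {
  NetPtr net(ptr);
  int k = 0;
  for (auto* p : net->params) {
    Rcpp::NumericVector v = state["p" + std::to_string(k)];
    ++k;
    if ((size_t)v.size() != p->w.n_elem)
      Rcpp::stop("state size mismatch for parameter %d", k - 1);
    for (size_t i = 0; i < p->w.n_elem; ++i) p->w[i] = (float)v[i];
  }
  int ri = 0;
  auto pull_rs = [&](BNLayer& bn) {
    Rcpp::NumericVector m = state["rm" + std::to_string(ri)];
    Rcpp::NumericVector v = state["rv" + std::to_string(ri)];
    for (int i = 0; i < bn.c; ++i) {
      bn.rm[i] = (float)m[i];
      bn.rv[i] = (float)v[i];
    }
    ++ri;
  };
  for (int i = 0; i < net->L; ++i)
    for (auto& blk : net->blocks[i]) { pull_rs(blk.n1); pull_rs(blk.n2); }
}
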