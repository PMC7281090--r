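// Fused single-precision training and inference path for the U-Net-like
// segmenter. The R-level double-precision implementation remains the
// reference; this path computes identical quantities in float32 with the
// whole per-batch forward/backward loop in C++, which is what makes
// CPU-scale training practical. Layout conventions match unet_kernels.cpp:
// tensors are (H, W, C), flattened pixel index i + j*H, im2col column order
// k = (dy+1)*3 + (dx+1) within each channel block.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const float LRELU_SLOPE = 0.1f;

static fmat im2col3f(const fcube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fmat M(H * W, 9 * C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const fmat& xc = x.slice(c);
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const uword k = 9 * c + (uword)((dy + 1) * 3 + (dx + 1));
        for (uword j = 0; j < W; ++j) {
          const int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          const int i0 = std::max(0, -dy);
          const int i1 = std::min((int)H, (int)H - dy);
          const float* src = xc.colptr((uword)js);
          float* dst = M.colptr(k) + j * H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + dy];
        }
      }
  }
  return M;
}

static fcube col2im3f(const fmat& M, uword H, uword W, uword C) {
  fcube dx(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    fmat& xc = dx.slice(c);
    for (int dy = -1; dy <= 1; ++dy)
      for (int ddx = -1; ddx <= 1; ++ddx) {
        const uword k = 9 * c + (uword)((dy + 1) * 3 + (ddx + 1));
        for (uword j = 0; j < W; ++j) {
          const int js = (int)j + ddx;
          if (js < 0 || js >= (int)W) continue;
          const int i0 = std::max(0, -dy);
          const int i1 = std::min((int)H, (int)H - dy);
          const float* src = M.colptr(k) + j * H;
          float* dst = xc.colptr((uword)js);
          for (int i = i0; i < i1; ++i) dst[i + dy] += src[i];
        }
      }
  }
  return dx;
}

struct LayerW { fmat W; fvec b; };

static LayerW readLayer(const List& l) {
  LayerW out;
  out.W = conv_to<fmat>::from(as<mat>(l["W"]));
  out.b = conv_to<fvec>::from(as<vec>(l["b"]));
  return out;
}

struct Weights {
  std::vector<LayerW> enc, dec;
  LayerW bot;
  fvec headW;
  float headb;
  int levels;
};

static Weights readWeights(const List& wts, int levels) {
  Weights w; w.levels = levels;
  List enc = wts["enc"], dec = wts["dec"];
  for (int l = 0; l < levels; ++l) {
    w.enc.push_back(readLayer(enc[l]));
    w.dec.push_back(readLayer(dec[l]));
  }
  w.bot = readLayer(wts["bot"]);
  List head = wts["head"];
  w.headW = conv_to<fvec>::from(vectorise(as<mat>(head["W"])));
  w.headb = (float)as<double>(head["b"]);
  return w;
}

static void lrelu(fcube& x) {
  x.transform([](float v) { return v > 0 ? v : LRELU_SLOPE * v; });
}

static fcube conv_fw(const fcube& x, const LayerW& w, fmat* Mout) {
  fmat M = im2col3f(x);
  fmat Y = M * w.W;
  Y.each_row() += w.b.t();
  if (Mout) *Mout = std::move(M);
  return fcube(Y.memptr(), x.n_rows, x.n_cols, w.W.n_cols);
}

static void pool_fw(const fcube& x, fcube& y, ucube& idx) {
  const uword H2 = x.n_rows / 2, W2 = x.n_cols / 2, C = x.n_slices;
  y.set_size(H2, W2, C); idx.set_size(H2, W2, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W2; ++j)
      for (uword i = 0; i < H2; ++i) {
        float best = x(2 * i, 2 * j, c); uword bk = 0;
        for (uword dj = 0; dj < 2; ++dj)
          for (uword di = 0; di < 2; ++di) {
            const float v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bk = di + 2 * dj; }
          }
        y(i, j, c) = best; idx(i, j, c) = bk;
      }
}

static fcube pool_bw(const fcube& dy, const ucube& idx) {
  const uword H2 = dy.n_rows, W2 = dy.n_cols, C = dy.n_slices;
  fcube dx(2 * H2, 2 * W2, C, fill::zeros);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W2; ++j)
      for (uword i = 0; i < H2; ++i) {
        const uword k = idx(i, j, c);
        dx(2 * i + (k % 2), 2 * j + (k / 2), c) = dy(i, j, c);
      }
  return dx;
}

static fcube up_fw(const fcube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  fcube y(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        const float v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;     y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

static fcube up_bw(const fcube& dy) {
  const uword H2 = dy.n_rows / 2, W2 = dy.n_cols / 2, C = dy.n_slices;
  fcube dx(H2, W2, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W2; ++j)
      for (uword i = 0; i < H2; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

static fcube concat_c(const fcube& a, const fcube& b) {
  fcube out(a.n_rows, a.n_cols, a.n_slices + b.n_slices);
  out.slices(0, a.n_slices - 1) = a;
  out.slices(a.n_slices, out.n_slices - 1) = b;
  return out;
}

struct FwdCache {
  std::vector<fmat> encM, decM;
  fmat botM;
  std::vector<fcube> enc_a, dec_a;
  std::vector<ucube> pool_idx;
  fcube bot_a, last_a;
};

// forward over a normalized input; emits per-pixel probabilities. When
// cache != nullptr the intermediates needed for the backward pass are kept.
static fmat forward(const fcube& x, const Weights& w, FwdCache* cache) {
  const int L = w.levels;
  fcube cur = x;
  std::vector<fcube> enc_a_local;
  for (int l = 0; l < L; ++l) {
    fmat M;
    fcube a = conv_fw(cur, w.enc[l], cache ? &M : nullptr);
    lrelu(a);
    fcube pooled; ucube idx;
    pool_fw(a, pooled, idx);
    if (cache) {
      cache->encM.push_back(std::move(M));
      cache->enc_a.push_back(a);
      cache->pool_idx.push_back(std::move(idx));
    } else {
      enc_a_local.push_back(std::move(a));
    }
    cur = std::move(pooled);
  }
  {
    fmat M;
    cur = conv_fw(cur, w.bot, cache ? &M : nullptr);
    lrelu(cur);
    if (cache) { cache->botM = std::move(M); cache->bot_a = cur; }
  }
  if (cache) cache->decM.resize(L);
  if (cache) cache->dec_a.resize(L);
  for (int l = L - 1; l >= 0; --l) {
    fcube up = up_fw(cur);
    const fcube& skip = cache ? cache->enc_a[l] : enc_a_local[l];
    fcube cat = concat_c(up, skip);
    fmat M;
    cur = conv_fw(cat, w.dec[l], cache ? &M : nullptr);
    lrelu(cur);
    if (cache) { cache->decM[l] = std::move(M); cache->dec_a[l] = cur; }
  }
  fcube last = concat_c(cur, x);             // input-level skip into the head
  const uword N = last.n_rows * last.n_cols;
  fmat lastm(const_cast<float*>(last.memptr()), N, last.n_slices, false,
             true);
  fvec logits = lastm * w.headW;
  logits += w.headb;
  fmat p(last.n_rows, last.n_cols);
  for (uword i = 0; i < N; ++i) p(i) = 1.0f / (1.0f + std::exp(-logits(i)));
  if (cache) cache->last_a = last;
  return p;
}

struct Grads {
  std::vector<fmat> encW, decW;
  std::vector<fvec> encB, decB;
  fmat botW; fvec botB;
  fvec headW; float headB = 0;
  bool init = false;
};

static void lrelu_bw(fcube& d, const fcube& a) {
  const uword n = d.n_elem;
  for (uword i = 0; i < n; ++i)
    if (a(i) <= 0) d(i) *= LRELU_SLOPE;
}

static void backward(const fmat& dlogit, const Weights& w, FwdCache& cache,
                     Grads& g) {
  const int L = w.levels;
  const uword N = dlogit.n_elem;
  if (!g.init) {
    g.encW.resize(L); g.encB.resize(L); g.decW.resize(L); g.decB.resize(L);
    for (int l = 0; l < L; ++l) {
      g.encW[l].zeros(w.enc[l].W.n_rows, w.enc[l].W.n_cols);
      g.encB[l].zeros(w.enc[l].b.n_elem);
      g.decW[l].zeros(w.dec[l].W.n_rows, w.dec[l].W.n_cols);
      g.decB[l].zeros(w.dec[l].b.n_elem);
    }
    g.botW.zeros(w.bot.W.n_rows, w.bot.W.n_cols);
    g.botB.zeros(w.bot.b.n_elem);
    g.headW.zeros(w.headW.n_elem);
    g.headB = 0;
    g.init = true;
  }
  const fmat lastm(const_cast<float*>(cache.last_a.memptr()), N,
                   cache.last_a.n_slices, false, true);
  const fvec dl(const_cast<float*>(dlogit.memptr()), N, false, true);
  g.headW += lastm.t() * dl;
  g.headB += accu(dl);
  // only decoder features backpropagate; the input-skip gradient is dropped
  const uword C1 = cache.dec_a[0].n_slices;
  fcube dcur(cache.last_a.n_rows, cache.last_a.n_cols, C1);
  for (uword c = 0; c < C1; ++c)
    dcur.slice(c) = reshape(dl * w.headW(c), dcur.n_rows, dcur.n_cols);
  std::vector<fcube> dskip(L);
  for (int l = 0; l < L; ++l) {
    lrelu_bw(dcur, cache.dec_a[l]);
    const fmat dYm(const_cast<float*>(dcur.memptr()),
                   dcur.n_rows * dcur.n_cols, dcur.n_slices, false, true);
    g.decW[l] += cache.decM[l].t() * dYm;
    g.decB[l] += sum(dYm, 0).t();
    const uword Cin = w.dec[l].W.n_rows / 9;
    fcube dcat = col2im3f(dYm * w.dec[l].W.t(), dcur.n_rows, dcur.n_cols,
                          Cin);
    const uword skipC = cache.enc_a[l].n_slices;
    const uword above = Cin - skipC;
    dskip[l] = dcat.slices(above, Cin - 1);
    dcur = up_bw(dcat.slices(0, above - 1));
  }
  lrelu_bw(dcur, cache.bot_a);
  {
    const fmat dYm(const_cast<float*>(dcur.memptr()),
                   dcur.n_rows * dcur.n_cols, dcur.n_slices, false, true);
    g.botW += cache.botM.t() * dYm;
    g.botB += sum(dYm, 0).t();
    const uword Cin = w.bot.W.n_rows / 9;
    dcur = col2im3f(dYm * w.bot.W.t(), dcur.n_rows, dcur.n_cols, Cin);
  }
  for (int l = L - 1; l >= 0; --l) {
    fcube da = pool_bw(dcur, cache.pool_idx[l]);
    da += dskip[l];
    lrelu_bw(da, cache.enc_a[l]);
    const fmat dYm(const_cast<float*>(da.memptr()),
                   da.n_rows * da.n_cols, da.n_slices, false, true);
    g.encW[l] += cache.encM[l].t() * dYm;
    g.encB[l] += sum(dYm, 0).t();
    const uword Cin = w.enc[l].W.n_rows / 9;
    dcur = col2im3f(dYm * w.enc[l].W.t(), da.n_rows, da.n_cols, Cin);
  }
}

static fcube asFcube(SEXP s) {
  NumericVector v(s);
  IntegerVector d = v.attr("dim");
  cube c(v.begin(), d[0], d[1], d[2], false, true);
  return conv_to<fcube>::from(c);
}

// Mean BCE loss and accumulated gradients over one mini-batch of
// normalized inputs xs and 0/1 label matrices ys.
// [[Rcpp::export]]
List cpp_unet_batch_grad(List xs, List ys, List wts, int levels) {
  Weights w = readWeights(wts, levels);
  const int B = xs.size();
  Grads g;
  double totLoss = 0;
  for (int s = 0; s < B; ++s) {
    fcube x = asFcube(xs[s]);
    fmat y = conv_to<fmat>::from(as<mat>(ys[s]));
    FwdCache cache;
    fmat p = forward(x, w, &cache);
    const uword N = p.n_elem;
    double loss = 0;
    for (uword i = 0; i < N; ++i) {
      const double pi = std::min(std::max((double)p(i), 1e-7), 1 - 1e-7);
      loss -= y(i) * std::log(pi) + (1 - y(i)) * std::log(1 - pi);
    }
    totLoss += loss / N;
    fmat dlogit = (p - y) / ((float)N * (float)B);
    backward(dlogit, w, cache, g);
  }
  const int L = levels;
  List enc(L), dec(L);
  for (int l = 0; l < L; ++l) {
    enc[l] = List::create(Named("W") = conv_to<mat>::from(g.encW[l]),
                          Named("b") = conv_to<vec>::from(g.encB[l]));
    dec[l] = List::create(Named("W") = conv_to<mat>::from(g.decW[l]),
                          Named("b") = conv_to<vec>::from(g.decB[l]));
  }
  return List::create(
      Named("loss") = totLoss / B,
      Named("grads") = List::create(
          Named("enc") = enc, Named("dec") = dec,
          Named("bot") = List::create(
              Named("W") = conv_to<mat>::from(g.botW),
              Named("b") = conv_to<vec>::from(g.botB)),
          Named("head") = List::create(
              Named("W") = mat(conv_to<vec>::from(g.headW)),
              Named("b") = (double)g.headB)));
}

// Inference: per-pixel probabilities for one normalized input.
// [[Rcpp::export]]
NumericMatrix cpp_unet_infer(SEXP x, List wts, int levels) {
  Weights w = readWeights(wts, levels);
  fcube xc = asFcube(x);
  fmat p = forward(xc, w, nullptr);
  return wrap(conv_to<mat>::from(p));
}
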