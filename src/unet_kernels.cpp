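// Numerical kernels for the U-Net-like segmenter and for connected-component
// labeling. Tensors are arma::cube with layout (H, W, C), matching R arrays
// indexed [row, col, channel]; 3x3 convolutions use zero padding of 1 so
// spatial dims are preserved. Flattened pixel index is i + j*H (column-major),
// identical to R's as.vector() on an H x W matrix.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

// im2col for a 3x3 window, zero pad 1: (H*W) x (9*C).
// Column block for channel c holds offsets (dy, dx) in order
// (-1,-1),(-1,0),(-1,1),(0,-1),...,(1,1) indexed k = (dy+1)*3 + (dx+1).
static mat im2col3(const cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  mat M(H * W, 9 * C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    const mat& xc = x.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int dx = -1; dx <= 1; ++dx) {
        const uword k = 9 * c + (uword)((dy + 1) * 3 + (dx + 1));
        for (uword j = 0; j < W; ++j) {
          const int js = (int)j + dx;
          if (js < 0 || js >= (int)W) continue;
          const int i0 = std::max(0, -dy);
          const int i1 = std::min((int)H, (int)H - dy);
          const double* src = xc.colptr((uword)js);
          double* dst = M.colptr(k) + j * H;
          for (int i = i0; i < i1; ++i) dst[i] = src[i + dy];
        }
      }
    }
  }
  return M;
}

// adjoint of im2col3: scatter-add (H*W) x (9*C) back to (H, W, C)
static cube col2im3(const mat& M, uword H, uword W, uword C) {
  cube dx(H, W, C, fill::zeros);
  for (uword c = 0; c < C; ++c) {
    mat& xc = dx.slice(c);
    for (int dy = -1; dy <= 1; ++dy) {
      for (int ddx = -1; ddx <= 1; ++ddx) {
        const uword k = 9 * c + (uword)((dy + 1) * 3 + (ddx + 1));
        for (uword j = 0; j < W; ++j) {
          const int js = (int)j + ddx;
          if (js < 0 || js >= (int)W) continue;
          const int i0 = std::max(0, -dy);
          const int i1 = std::min((int)H, (int)H - dy);
          const double* src = M.colptr(k) + j * H;
          double* dst = xc.colptr((uword)js);
          for (int i = i0; i < i1; ++i) dst[i + dy] += src[i];
        }
      }
    }
  }
  return dx;
}

// 3x3 convolution, zero pad 1. Wmat is (9*Cin) x Cout with rows ordered as
// im2col3 columns; b has length Cout.
// [[Rcpp::export]]
arma::cube cpp_conv3_fw(const arma::cube& x, const arma::mat& Wmat,
                        const arma::vec& b) {
  const uword H = x.n_rows, W = x.n_cols;
  mat Y = im2col3(x) * Wmat;
  Y.each_row() += b.t();
  return cube(Y.memptr(), H, W, Wmat.n_cols);
}

// forward that also returns the im2col matrix for reuse in the backward
// pass (saves recomputing it)
// [[Rcpp::export]]
Rcpp::List cpp_conv3_fw_cache(const arma::cube& x, const arma::mat& Wmat,
                              const arma::vec& b) {
  const uword H = x.n_rows, W = x.n_cols;
  mat M = im2col3(x);
  mat Y = M * Wmat;
  Y.each_row() += b.t();
  return Rcpp::List::create(
      Rcpp::Named("y") = cube(Y.memptr(), H, W, Wmat.n_cols),
      Rcpp::Named("M") = M);
}

// gradients of the 3x3 convolution wrt input, weights, bias; M is the
// cached im2col matrix of the layer input
// [[Rcpp::export]]
Rcpp::List cpp_conv3_bw(const arma::mat& M, const arma::mat& Wmat,
                        const arma::cube& dy, int Cin) {
  const uword H = dy.n_rows, W = dy.n_cols, Cout = dy.n_slices;
  const mat dYm(const_cast<double*>(dy.memptr()), H * W, Cout, false, true);
  mat dW = M.t() * dYm;
  vec db = sum(dYm, 0).t();
  mat dM = dYm * Wmat.t();
  return Rcpp::List::create(
      Rcpp::Named("dx") = col2im3(dM, H, W, (uword)Cin),
      Rcpp::Named("dW") = dW,
      Rcpp::Named("db") = db);
}

// 2x2 max pooling, stride 2; H and W must be even. Returns pooled values
// and the argmax offset (di + 2*dj, in 0..3) for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_maxpool_fw(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  if (H % 2 || W % 2) stop("maxpool requires even spatial dims");
  const uword H2 = H / 2, W2 = W / 2;
  cube y(H2, W2, C), idx(H2, W2, C);
  for (uword c = 0; c < C; ++c) {
    for (uword j = 0; j < W2; ++j) {
      for (uword i = 0; i < H2; ++i) {
        double best = x(2 * i, 2 * j, c); uword bk = 0;
        for (uword dj = 0; dj < 2; ++dj)
          for (uword di = 0; di < 2; ++di) {
            const double v = x(2 * i + di, 2 * j + dj, c);
            if (v > best) { best = v; bk = di + 2 * dj; }
          }
        y(i, j, c) = best; idx(i, j, c) = (double)bk;
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("y") = y, Rcpp::Named("idx") = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bw(const arma::cube& dy, const arma::cube& idx) {
  const uword H2 = dy.n_rows, W2 = dy.n_cols, C = dy.n_slices;
  cube dx(2 * H2, 2 * W2, C, fill::zeros);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W2; ++j)
      for (uword i = 0; i < H2; ++i) {
        const uword k = (uword)idx(i, j, c);
        dx(2 * i + (k % 2), 2 * j + (k / 2), c) = dy(i, j, c);
      }
  return dx;
}

// nearest-neighbour 2x upsampling
// [[Rcpp::export]]
arma::cube cpp_upsample_fw(const arma::cube& x) {
  const uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube y(2 * H, 2 * W, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W; ++j)
      for (uword i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        y(2 * i, 2 * j, c) = v;     y(2 * i + 1, 2 * j, c) = v;
        y(2 * i, 2 * j + 1, c) = v; y(2 * i + 1, 2 * j + 1, c) = v;
      }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample_bw(const arma::cube& dy) {
  const uword H2 = dy.n_rows / 2, W2 = dy.n_cols / 2, C = dy.n_slices;
  cube dx(H2, W2, C);
  for (uword c = 0; c < C; ++c)
    for (uword j = 0; j < W2; ++j)
      for (uword i = 0; i < H2; ++i)
        dx(i, j, c) = dy(2 * i, 2 * j, c) + dy(2 * i + 1, 2 * j, c) +
                      dy(2 * i, 2 * j + 1, c) + dy(2 * i + 1, 2 * j + 1, c);
  return dx;
}

// ---------------------------------------------------------------------------
// connected-component labeling, two-pass union-find, 4- or 8-connectivity.
// Labels are assigned in raster-scan first-encounter order starting at 1;
// callers impose any further deterministic ordering.

static int uf_find(std::vector<int>& parent, int a) {
  while (parent[a] != a) { parent[a] = parent[parent[a]]; a = parent[a]; }
  return a;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  a = uf_find(parent, a); b = uf_find(parent, b);
  if (a != b) parent[std::max(a, b)] = std::min(a, b);
}

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask,
                                   int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> parent(1, 0);
  int next = 1;
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int lbl = 0;
      // neighbours already scanned in column-major order
      const int nb[4][2] = {{i - 1, j}, {i, j - 1},
                            {i - 1, j - 1}, {i + 1, j - 1}};
      const int nn = (connectivity == 8) ? 4 : 2;
      for (int t = 0; t < nn; ++t) {
        const int ni = nb[t][0], nj = nb[t][1];
        if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
        const int nl = lab(ni, nj);
        if (nl == 0) continue;
        if (lbl == 0) lbl = nl;
        else uf_union(parent, lbl, nl);
      }
      if (lbl == 0) { lbl = next++; parent.push_back(lbl); }
      lab(i, j) = lbl;
    }
  }
  // second pass: flatten and renumber in first-encounter order
  std::vector<int> remap(next, 0);
  int out = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (!lab(i, j)) continue;
      const int root = uf_find(parent, lab(i, j));
      if (!remap[root]) remap[root] = ++out;
      lab(i, j) = remap[root];
    }
  return lab;
}
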