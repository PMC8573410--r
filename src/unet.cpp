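// 3D U-Net: native forward/backward with soft-Dice loss.
//
// Feature maps are stored as arma::fmat of size (nvox x channels), one
// channel per column, voxel index = x + nx*y + nx*ny*z (column-major,
// matching R's array layout for dim c(nx, ny, nz, C)).
//
// 3x3x3 convolutions run as chunked im2col + sgemm. Weight arrays come from
// R with dim c(3,3,3,Cin,Cout); flattened row index kx + 3*ky + 9*kz + 27*ci
// therefore matches the im2col column order with no reshuffling.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <cfloat>
#include <cstring>

using namespace Rcpp;

namespace {

struct Dim3 {
  int nx, ny, nz;
  long n() const { return (long)nx * ny * nz; }
};

const float NORM_EPS = 1e-5f;

arma::fmat as_fmat(const NumericVector& v, int nrow, int ncol) {
  if ((long)v.size() != (long)nrow * ncol)
    stop("parameter has length %d, expected %d", (int)v.size(), nrow * ncol);
  arma::fmat M(nrow, ncol);
  for (long i = 0; i < (long)v.size(); ++i) M(i) = (float)v[i];
  return M;
}

arma::fvec as_fvec(const NumericVector& v) {
  arma::fvec x(v.size());
  for (int i = 0; i < v.size(); ++i) x[i] = (float)v[i];
  return x;
}

NumericVector to_numeric(const arma::fmat& M) {
  NumericVector out(M.n_elem);
  for (arma::uword i = 0; i < M.n_elem; ++i) out[i] = M(i);
  return out;
}

NumericVector to_numeric(const arma::fvec& v) {
  NumericVector out(v.n_elem);
  for (arma::uword i = 0; i < v.n_elem; ++i) out[i] = v[i];
  return out;
}

// ---- im2col / col2im ------------------------------------------------------

// Fill A (cols x 27*Cin) for output z-slab [z0, z0+zc); zero padding.
void im2col_chunk(const arma::fmat& F, const Dim3& d, int z0, int zc,
                  arma::fmat& A) {
  const int nx = d.nx, ny = d.ny, nz = d.nz;
  const long cols = (long)nx * ny * zc;
  A.zeros(cols, 27 * F.n_cols);
  for (arma::uword ci = 0; ci < F.n_cols; ++ci) {
    const float* src = F.colptr(ci);
    for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
        for (int kx = 0; kx < 3; ++kx) {
          const int r = kx + 3 * ky + 9 * kz + 27 * (int)ci;
          float* dst = A.colptr(r);
          const int dx = kx - 1, dy = ky - 1, dz = kz - 1;
          const int x_lo = std::max(0, -dx);
          const int x_hi = std::min(nx - 1, nx - 1 - dx);
          if (x_hi < x_lo) continue;
          const int len = x_hi - x_lo + 1;
          for (int z = z0; z < z0 + zc; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int ys = y + dy;
              if (ys < 0 || ys >= ny) continue;
              const long di = (long)x_lo + (long)nx * y + (long)nx * ny * (z - z0);
              const long si = (long)(x_lo + dx) + (long)nx * ys + (long)nx * ny * zs;
              std::memcpy(dst + di, src + si, sizeof(float) * len);
            }
          }
        }
  }
}

// Scatter-add transpose of im2col_chunk.
void col2im_add_chunk(const arma::fmat& dA, const Dim3& d, int z0, int zc,
                      arma::fmat& dF) {
  const int nx = d.nx, ny = d.ny, nz = d.nz;
  for (arma::uword ci = 0; ci < dF.n_cols; ++ci) {
    float* dst = dF.colptr(ci);
    for (int kz = 0; kz < 3; ++kz)
      for (int ky = 0; ky < 3; ++ky)
        for (int kx = 0; kx < 3; ++kx) {
          const int r = kx + 3 * ky + 9 * kz + 27 * (int)ci;
          const float* src = dA.colptr(r);
          const int dx = kx - 1, dy = ky - 1, dz = kz - 1;
          const int x_lo = std::max(0, -dx);
          const int x_hi = std::min(nx - 1, nx - 1 - dx);
          if (x_hi < x_lo) continue;
          const int len = x_hi - x_lo + 1;
          for (int z = z0; z < z0 + zc; ++z) {
            const int zs = z + dz;
            if (zs < 0 || zs >= nz) continue;
            for (int y = 0; y < ny; ++y) {
              const int ys = y + dy;
              if (ys < 0 || ys >= ny) continue;
              const long di = (long)x_lo + (long)nx * y + (long)nx * ny * (z - z0);
              const long si = (long)(x_lo + dx) + (long)nx * ys + (long)nx * ny * zs;
              for (int i = 0; i < len; ++i) dst[si + i] += src[di + i];
            }
          }
        }
  }
}

int conv_chunk_slices(const Dim3& d, int cin) {
  // keep the im2col buffer cache-sized
  long maxcols = 1500000L / (27L * cin);
  long zc = maxcols / ((long)d.nx * d.ny);
  if (zc < 1) zc = 1;
  if (zc > d.nz) zc = d.nz;
  return (int)zc;
}

arma::fmat conv3_fwd(const arma::fmat& F, const arma::fmat& W, const Dim3& d) {
  const int cout = W.n_cols;
  arma::fmat out(d.n(), cout);
  const int zc_max = conv_chunk_slices(d, F.n_cols);
  arma::fmat A;
  for (int z0 = 0; z0 < d.nz; z0 += zc_max) {
    const int zc = std::min(zc_max, d.nz - z0);
    im2col_chunk(F, d, z0, zc, A);
    const long r0 = (long)d.nx * d.ny * z0;
    out.rows(r0, r0 + (long)d.nx * d.ny * zc - 1) = A * W;
  }
  return out;
}

void conv3_bwd(const arma::fmat& F, const arma::fmat& W, const arma::fmat& dOut,
               const Dim3& d, arma::fmat& dF, arma::fmat& dW) {
  dF.zeros(F.n_rows, F.n_cols);
  dW.zeros(W.n_rows, W.n_cols);
  const int zc_max = conv_chunk_slices(d, F.n_cols);
  arma::fmat A, dA;
  for (int z0 = 0; z0 < d.nz; z0 += zc_max) {
    const int zc = std::min(zc_max, d.nz - z0);
    im2col_chunk(F, d, z0, zc, A);
    const long r0 = (long)d.nx * d.ny * z0;
    const arma::fmat dOc = dOut.rows(r0, r0 + (long)d.nx * d.ny * zc - 1);
    dW += A.t() * dOc;
    dA = dOc * W.t();
    col2im_add_chunk(dA, d, z0, zc, dF);
  }
}

// ---- per-channel (instance) normalization --------------------------------

struct NormCache {
  arma::fmat xhat;
  arma::fvec invstd;
};

arma::fmat norm_fwd(const arma::fmat& X, const arma::fvec& g, const arma::fvec& b,
                    NormCache& c) {
  const int C = X.n_cols;
  const long N = X.n_rows;
  c.xhat.set_size(N, C);
  c.invstd.set_size(C);
  arma::fmat Y(N, C);
  for (int j = 0; j < C; ++j) {
    const float mu = arma::mean(X.col(j));
    const float var = arma::mean(arma::square(X.col(j) - mu));
    const float is = 1.0f / std::sqrt(var + NORM_EPS);
    c.invstd[j] = is;
    c.xhat.col(j) = (X.col(j) - mu) * is;
    Y.col(j) = c.xhat.col(j) * g[j] + b[j];
  }
  return Y;
}

arma::fmat norm_bwd(const arma::fmat& dY, const arma::fvec& g, const NormCache& c,
                    arma::fvec& dg, arma::fvec& db) {
  const int C = dY.n_cols;
  const long N = dY.n_rows;
  arma::fmat dX(N, C);
  dg.set_size(C);
  db.set_size(C);
  for (int j = 0; j < C; ++j) {
    const arma::fvec dxh = dY.col(j) * g[j];
    const float s1 = arma::accu(dxh);
    const float s2 = arma::accu(dxh % c.xhat.col(j));
    dX.col(j) = (c.invstd[j] / (float)N) *
                ((float)N * dxh - s1 - c.xhat.col(j) * s2);
    dg[j] = arma::accu(dY.col(j) % c.xhat.col(j));
    db[j] = arma::accu(dY.col(j));
  }
  return dX;
}

void relu_inplace(arma::fmat& X) {
  X.transform([](float v) { return v > 0.0f ? v : 0.0f; });
}

// dY masked by activation output (> 0 iff pre-activation > 0)
void relu_bwd_inplace(arma::fmat& dY, const arma::fmat& act) {
  for (arma::uword i = 0; i < dY.n_elem; ++i)
    if (act(i) <= 0.0f) dY(i) = 0.0f;
}

// ---- pooling --------------------------------------------------------------

arma::fmat pool_fwd(const arma::fmat& X, const Dim3& d, arma::umat& argm,
                    Dim3& dout) {
  dout.nx = d.nx / 2; dout.ny = d.ny / 2; dout.nz = d.nz / 2;
  const int C = X.n_cols;
  const long M = dout.n();
  arma::fmat Y(M, C);
  argm.set_size(M, C);
  for (int c = 0; c < C; ++c) {
    const float* s = X.colptr(c);
    for (int z = 0; z < dout.nz; ++z)
      for (int y = 0; y < dout.ny; ++y)
        for (int x = 0; x < dout.nx; ++x) {
          const long o = (long)x + (long)dout.nx * y + (long)dout.nx * dout.ny * z;
          float best = -FLT_MAX;
          long bi = 0;
          for (int dz = 0; dz < 2; ++dz)
            for (int dy = 0; dy < 2; ++dy)
              for (int dx = 0; dx < 2; ++dx) {
                const long i = (long)(2 * x + dx) + (long)d.nx * (2 * y + dy) +
                               (long)d.nx * d.ny * (2 * z + dz);
                if (s[i] > best) { best = s[i]; bi = i; }
              }
          Y(o, c) = best;
          argm(o, c) = (arma::uword)bi;
        }
  }
  return Y;
}

arma::fmat pool_bwd(const arma::fmat& dY, const arma::umat& argm, const Dim3& din) {
  arma::fmat dX(din.n(), dY.n_cols, arma::fill::zeros);
  for (arma::uword c = 0; c < dY.n_cols; ++c)
    for (arma::uword o = 0; o < dY.n_rows; ++o)
      dX(argm(o, c), c) += dY(o, c);
  return dX;
}

// ---- 2x2x2 stride-2 up-convolution ---------------------------------------

// Wu comes in as (8*Cin x Cout), row index dx + 2*dy + 4*dz + 8*ci.
arma::fmat upconv_sub(const arma::fmat& Wu, int cin, int off) {
  arma::fmat Wd(cin, Wu.n_cols);
  for (int ci = 0; ci < cin; ++ci) Wd.row(ci) = Wu.row(off + 8 * ci);
  return Wd;
}

arma::fmat upconv_fwd(const arma::fmat& X, const Dim3& d, const arma::fmat& Wu,
                      const arma::fvec& b, Dim3& dout) {
  dout.nx = 2 * d.nx; dout.ny = 2 * d.ny; dout.nz = 2 * d.nz;
  const int cin = X.n_cols, cout = Wu.n_cols;
  arma::fmat Y(dout.n(), cout);
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        const int off = dx + 2 * dy + 4 * dz;
        arma::fmat Od = X * upconv_sub(Wu, cin, off);
        Od.each_row() += b.t();
        for (int c = 0; c < cout; ++c) {
          const float* s = Od.colptr(c);
          float* t = Y.colptr(c);
          for (int z = 0; z < d.nz; ++z)
            for (int y = 0; y < d.ny; ++y) {
              const long si = (long)d.nx * y + (long)d.nx * d.ny * z;
              const long ti = (long)dx + (long)dout.nx * (2 * y + dy) +
                              (long)dout.nx * dout.ny * (2 * z + dz);
              for (int x = 0; x < d.nx; ++x) t[ti + 2 * x] = s[si + x];
            }
        }
      }
  return Y;
}

arma::fmat upconv_bwd(const arma::fmat& X, const Dim3& d, const arma::fmat& Wu,
                      const arma::fmat& dY, const Dim3& dout,
                      arma::fmat& dWu, arma::fvec& db) {
  const int cin = X.n_cols, cout = Wu.n_cols;
  arma::fmat dX(X.n_rows, cin, arma::fill::zeros);
  dWu.zeros(Wu.n_rows, Wu.n_cols);
  db.zeros(cout);
  arma::fmat dOd(d.n(), cout);
  for (int dz = 0; dz < 2; ++dz)
    for (int dy = 0; dy < 2; ++dy)
      for (int dx = 0; dx < 2; ++dx) {
        const int off = dx + 2 * dy + 4 * dz;
        for (int c = 0; c < cout; ++c) {
          float* s = dOd.colptr(c);
          const float* t = dY.colptr(c);
          for (int z = 0; z < d.nz; ++z)
            for (int y = 0; y < d.ny; ++y) {
              const long si = (long)d.nx * y + (long)d.nx * d.ny * z;
              const long ti = (long)dx + (long)dout.nx * (2 * y + dy) +
                              (long)dout.nx * dout.ny * (2 * z + dz);
              for (int x = 0; x < d.nx; ++x) s[si + x] = t[ti + 2 * x];
            }
        }
        dX += dOd * upconv_sub(Wu, cin, off).t();
        const arma::fmat dWd = X.t() * dOd;
        for (int ci = 0; ci < cin; ++ci) dWu.row(off + 8 * ci) = dWd.row(ci);
        db += arma::sum(dOd, 0).t();
      }
  return dX;
}

// ---- blocks ---------------------------------------------------------------

struct Block {
  arma::fmat W1; arma::fvec g1, b1;
  arma::fmat W2; arma::fvec g2, b2;
};

struct BlockCache {
  arma::fmat in;
  NormCache n1, n2;
  arma::fmat a1, a2;
};

struct BlockGrads {
  arma::fmat dW1; arma::fvec dg1, db1;
  arma::fmat dW2; arma::fvec dg2, db2;
};

arma::fmat block_fwd(const Block& B, const arma::fmat& X, const Dim3& d,
                     BlockCache* c) {
  NormCache n1, n2;
  arma::fmat z = conv3_fwd(X, B.W1, d);
  z = norm_fwd(z, B.g1, B.b1, n1);
  relu_inplace(z);
  arma::fmat z2 = conv3_fwd(z, B.W2, d);
  z2 = norm_fwd(z2, B.g2, B.b2, n2);
  relu_inplace(z2);
  if (c) {
    c->in = X;
    c->n1 = std::move(n1);
    c->n2 = std::move(n2);
    c->a1 = std::move(z);
    c->a2 = z2;
  }
  return z2;
}

arma::fmat block_bwd(const Block& B, const BlockCache& c, const Dim3& d,
                     arma::fmat dY, BlockGrads& G) {
  relu_bwd_inplace(dY, c.a2);
  const arma::fmat dz2 = norm_bwd(dY, B.g2, c.n2, G.dg2, G.db2);
  arma::fmat da1;
  conv3_bwd(c.a1, B.W2, dz2, d, da1, G.dW2);
  relu_bwd_inplace(da1, c.a1);
  const arma::fmat dz1 = norm_bwd(da1, B.g1, c.n1, G.dg1, G.db1);
  arma::fmat din;
  conv3_bwd(c.in, B.W1, dz1, d, din, G.dW1);
  return din;
}

// ---- whole network --------------------------------------------------------

struct Net {
  int levels, base;
  std::vector<int> ch;
  std::vector<Block> enc;              // levels entries, last = bottleneck
  struct DecLevel { arma::fmat Wu; arma::fvec bu; Block blk; };
  std::vector<DecLevel> dec;           // levels-1 entries, deepest first
  arma::fmat Wh; arma::fvec bh;
};

Block load_block(const List& p, int& k, int cin, int cout) {
  Block B;
  B.W1 = as_fmat(p[k++], 27 * cin, cout);
  B.g1 = as_fvec(p[k++]);
  B.b1 = as_fvec(p[k++]);
  B.W2 = as_fmat(p[k++], 27 * cout, cout);
  B.g2 = as_fvec(p[k++]);
  B.b2 = as_fvec(p[k++]);
  return B;
}

Net load_net(const List& params, int levels, int base) {
  Net net;
  net.levels = levels;
  net.base = base;
  net.ch.resize(levels);
  for (int l = 0; l < levels; ++l) net.ch[l] = base << l;
  int k = 0;
  for (int l = 0; l < levels; ++l) {
    const int cin = (l == 0) ? 1 : net.ch[l - 1];
    net.enc.push_back(load_block(params, k, cin, net.ch[l]));
  }
  for (int l = levels - 2; l >= 0; --l) {
    Net::DecLevel D;
    D.Wu = as_fmat(params[k++], 8 * net.ch[l + 1], net.ch[l]);
    D.bu = as_fvec(params[k++]);
    D.blk = load_block(params, k, 2 * net.ch[l], net.ch[l]);
    net.dec.push_back(std::move(D));
  }
  net.Wh = as_fmat(params[k++], net.ch[0], 2);
  net.bh = as_fvec(params[k++]);
  if (k != params.size()) stop("parameter list has %d entries, expected %d",
                               (int)params.size(), k);
  return net;
}

void check_dims(const Dim3& d, int levels) {
  const int m = 1 << (levels - 1);
  if (d.nx % m || d.ny % m || d.nz % m)
    stop("input sides must be multiples of %d (got %dx%dx%d)", m, d.nx, d.ny, d.nz);
}

}  // namespace

// Forward pass; returns two-channel softmax probabilities.
// [[Rcpp::export(name = ".unet_forward_cpp")]]
List unet_forward_cpp(List params, NumericVector x, IntegerVector dim,
                      int levels, int base) {
  Dim3 d{dim[0], dim[1], dim[2]};
  check_dims(d, levels);
  Net net = load_net(params, levels, base);

  arma::fmat cur(d.n(), 1);
  for (long i = 0; i < d.n(); ++i) cur(i, 0) = (float)x[i];

  std::vector<arma::fmat> skips;
  std::vector<Dim3> dims;
  Dim3 dl = d;
  for (int l = 0; l < levels - 1; ++l) {
    cur = block_fwd(net.enc[l], cur, dl, nullptr);
    skips.push_back(cur);
    dims.push_back(dl);
    arma::umat argm;
    Dim3 dnext;
    cur = pool_fwd(cur, dl, argm, dnext);
    dl = dnext;
  }
  cur = block_fwd(net.enc[levels - 1], cur, dl, nullptr);

  for (int i = 0; i < levels - 1; ++i) {
    const int l = levels - 2 - i;
    Dim3 dup;
    arma::fmat up = upconv_fwd(cur, dl, net.dec[i].Wu, net.dec[i].bu, dup);
    cur.reset();
    arma::fmat cat = arma::join_rows(up, skips[l]);
    up.reset();
    skips[l].reset();
    dl = dims[l];
    cur = block_fwd(net.dec[i].blk, cat, dl, nullptr);
  }

  arma::fmat logits = cur * net.Wh;
  logits.each_row() += net.bh.t();
  NumericVector fg(d.n()), bg(d.n());
  for (long i = 0; i < d.n(); ++i) {
    const float m = std::max(logits(i, 0), logits(i, 1));
    const float e0 = std::exp(logits(i, 0) - m);
    const float e1 = std::exp(logits(i, 1) - m);
    fg[i] = e1 / (e0 + e1);
    bg[i] = e0 / (e0 + e1);
  }
  return List::create(_["fg"] = fg, _["bg"] = bg);
}

// Forward + backward on one sample; returns soft-Dice loss and gradients
// in the same order/shapes as the parameter list.
// [[Rcpp::export(name = ".unet_grad_cpp")]]
List unet_grad_cpp(List params, NumericVector x, NumericVector target,
                   IntegerVector dim, int levels, int base, double smooth) {
  Dim3 d{dim[0], dim[1], dim[2]};
  check_dims(d, levels);
  if ((long)target.size() != d.n()) stop("target size mismatch");
  Net net = load_net(params, levels, base);

  arma::fmat cur(d.n(), 1);
  for (long i = 0; i < d.n(); ++i) cur(i, 0) = (float)x[i];

  std::vector<BlockCache> ecache(levels);
  std::vector<arma::umat> argms(levels - 1);
  std::vector<Dim3> dims(levels);
  Dim3 dl = d;
  for (int l = 0; l < levels - 1; ++l) {
    dims[l] = dl;
    cur = block_fwd(net.enc[l], cur, dl, &ecache[l]);
    Dim3 dnext;
    cur = pool_fwd(cur, dl, argms[l], dnext);
    dl = dnext;
  }
  dims[levels - 1] = dl;
  cur = block_fwd(net.enc[levels - 1], cur, dl, &ecache[levels - 1]);

  std::vector<BlockCache> dcache(levels - 1);
  std::vector<arma::fmat> upcat_in(levels - 1);  // input to each upconv
  std::vector<Dim3> updin(levels - 1);
  for (int i = 0; i < levels - 1; ++i) {
    const int l = levels - 2 - i;
    upcat_in[i] = cur;
    updin[i] = dl;
    Dim3 dup;
    arma::fmat up = upconv_fwd(cur, dl, net.dec[i].Wu, net.dec[i].bu, dup);
    arma::fmat cat = arma::join_rows(up, ecache[l].a2);
    dl = dims[l];
    cur = block_fwd(net.dec[i].blk, cat, dl, &dcache[i]);
  }

  arma::fmat logits = cur * net.Wh;
  logits.each_row() += net.bh.t();
  const long N = d.n();
  arma::fvec p1(N);
  for (long i = 0; i < N; ++i) {
    const float m = std::max(logits(i, 0), logits(i, 1));
    const float e0 = std::exp(logits(i, 0) - m);
    const float e1 = std::exp(logits(i, 1) - m);
    p1[i] = e1 / (e0 + e1);
  }
  arma::fvec g(N);
  for (long i = 0; i < N; ++i) g[i] = (float)target[i];

  const double s = smooth;
  const double num = 2.0 * arma::dot(p1, g) + s;
  const double den = arma::accu(p1) + arma::accu(g) + s;
  const double loss = 1.0 - num / den;

  // dL/dp1 = (num - 2*den*g) / den^2
  arma::fvec dLdp1 = (arma::fvec)((num / (den * den)) - (2.0 / den) * g);
  arma::fmat dZ(N, 2);
  for (long i = 0; i < N; ++i) {
    const float dp = p1[i] * (1.0f - p1[i]) * dLdp1[i];
    dZ(i, 1) = dp;
    dZ(i, 0) = -dp;
  }

  arma::fmat dWh = cur.t() * dZ;
  arma::fvec dbh = arma::sum(dZ, 0).t();
  arma::fmat dcur = dZ * net.Wh.t();
  dZ.reset();

  std::vector<BlockGrads> dgrads(levels - 1);
  std::vector<arma::fmat> dWu(levels - 1);
  std::vector<arma::fvec> dbu(levels - 1);
  std::vector<arma::fmat> dskip(levels - 1);  // gradient into encoder skip, by level

  for (int i = levels - 2; i >= 0; --i) {
    const int l = levels - 2 - i;
    dl = dims[l];
    arma::fmat dcat = block_bwd(net.dec[i].blk, dcache[i], dl, dcur, dgrads[i]);
    const int cl = net.ch[l];
    arma::fmat dup = dcat.cols(0, cl - 1);
    dskip[l] = dcat.cols(cl, 2 * cl - 1);
    dcat.reset();
    Dim3 dupdim{2 * updin[i].nx, 2 * updin[i].ny, 2 * updin[i].nz};
    dcur = upconv_bwd(upcat_in[i], updin[i], net.dec[i].Wu, dup, dupdim,
                      dWu[i], dbu[i]);
  }

  std::vector<BlockGrads> egrads(levels);
  // bottleneck
  dl = dims[levels - 1];
  dcur = block_bwd(net.enc[levels - 1], ecache[levels - 1], dl, dcur,
                   egrads[levels - 1]);
  for (int l = levels - 2; l >= 0; --l) {
    arma::fmat dpost = pool_bwd(dcur, argms[l], dims[l]);
    dpost += dskip[l];
    dcur = block_bwd(net.enc[l], ecache[l], dims[l], dpost, egrads[l]);
  }

  List grads(params.size());
  int k = 0;
  for (int l = 0; l < levels; ++l) {
    grads[k++] = to_numeric(egrads[l].dW1);
    grads[k++] = to_numeric(egrads[l].dg1);
    grads[k++] = to_numeric(egrads[l].db1);
    grads[k++] = to_numeric(egrads[l].dW2);
    grads[k++] = to_numeric(egrads[l].dg2);
    grads[k++] = to_numeric(egrads[l].db2);
  }
  for (int i = 0; i < levels - 1; ++i) {
    grads[k++] = to_numeric(dWu[i]);
    grads[k++] = to_numeric(dbu[i]);
    grads[k++] = to_numeric(dgrads[i].dW1);
    grads[k++] = to_numeric(dgrads[i].dg1);
    grads[k++] = to_numeric(dgrads[i].db1);
    grads[k++] = to_numeric(dgrads[i].dW2);
    grads[k++] = to_numeric(dgrads[i].dg2);
    grads[k++] = to_numeric(dgrads[i].db2);
  }
  grads[k++] = to_numeric(dWh);
  grads[k++] = to_numeric(dbh);

  CharacterVector nm = params.names();
  grads.names() = nm;
  return List::create(_["loss"] = loss, _["grads"] = grads);
}
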