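// Depthwise-separable convolutional patch classifier (MobileNet-v1 style).
//
// Single-precision training engine. Activation layout: arma::fmat with
// n_rows = H*W*N (row index = n*H*W + p, p = col*H + row, column-major
// spatial) and n_cols = channels. Pointwise convolutions and the classifier
// head are then single GEMMs, batch-norm statistics are contiguous column
// reductions, and each (sample, channel) spatial map is a contiguous block
// of a column for the depthwise loops.

#include <RcppArmadillo.h>
#include <deque>
#include <malloc.h>
#include <random>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#define GN_SET_FTZ()                                  \
  do {                                                \
    _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON);       \
    _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON); \
  } while (0)
#else
#define GN_SET_FTZ() do {} while (0)
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::uword;

namespace {

constexpr int N_BLOCKS = 13;
const int BASE_OUT[N_BLOCKS] = {64, 128, 128, 256, 256, 512, 512,
                                512, 512, 512, 512, 1024, 1024};
const int DW_STRIDE[N_BLOCKS] = {1, 2, 1, 2, 1, 2, 1, 1, 1, 1, 1, 2, 1};

struct Rng {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed) {}
  double unif() { return ((eng() >> 11) + 0.5) / 9007199254740992.0; }
  double norm() {  // Box-Muller (avoids implementation-defined stdlib dists)
    if (has_spare) { has_spare = false; return spare; }
    double u = unif(), v = unif();
    double r = std::sqrt(-2.0 * std::log(u));
    double a = 6.283185307179586 * v;
    spare = r * std::sin(a);
    has_spare = true;
    return r * std::cos(a);
  }
};

struct BN {
  fvec gamma, beta, rmean, rvar;
  float eps = 1e-3f, decay = 0.9f;
  void init(int c) {
    gamma.ones(c); beta.zeros(c); rmean.zeros(c); rvar.ones(c);
  }
};

struct SamePad {
  int out, pad;  // pad = leading pad (TF convention: extra pad trails)
};
SamePad same_pad(int in, int k, int s) {
  int out = (in + s - 1) / s;
  int total = std::max((out - 1) * s + k - in, 0);
  return SamePad{out, total / 2};
}

struct Net {
  double alpha;
  int input_size, n_classes;
  double dropout;
  std::vector<int> ch;       // ch[0] = first conv out, ch[1..13] = block outs
  fmat W0;                   // 27 x ch0   (3x3x3 conv, stride 2)
  BN bn0;
  std::vector<fmat> Wdw;     // 9 x c_in   (per-channel 3x3)
  std::vector<BN> bnd;
  std::vector<fmat> Wpw;     // c_in x c_out
  std::vector<BN> bnp;
  fmat Wfc;                  // c_last x n_classes
  fvec bfc;
  fvec input_mean;           // length 3, subtracted after [0,1] scaling
  Rng rng;

  int opt_mode = 0;          // 0 = adam, 1 = sgd + nesterov
  float lr = 1e-3f, momentum = 0.9f, beta1 = 0.9f, beta2 = 0.999f,
        opt_eps = 1e-8f;
  long t = 0;
  std::vector<fmat> m_state, v_state;

  Net(double alpha_, int input_size_, int n_classes_, double dropout_,
      uint64_t seed)
      : alpha(alpha_), input_size(input_size_), n_classes(n_classes_),
        dropout(dropout_), rng(seed) {
    ch.resize(N_BLOCKS + 1);
    ch[0] = (int)std::ceil(alpha * 32.0);
    for (int b = 0; b < N_BLOCKS; ++b)
      ch[b + 1] = (int)std::ceil(alpha * BASE_OUT[b]);
    auto he = [&](fmat& w, int fan_in) {
      double sd = std::sqrt(2.0 / fan_in);
      for (uword i = 0; i < w.n_elem; ++i) w(i) = (float)(sd * rng.norm());
    };
    W0.set_size(27, ch[0]); he(W0, 27);
    bn0.init(ch[0]);
    Wdw.resize(N_BLOCKS); bnd.resize(N_BLOCKS);
    Wpw.resize(N_BLOCKS); bnp.resize(N_BLOCKS);
    for (int b = 0; b < N_BLOCKS; ++b) {
      Wdw[b].set_size(9, ch[b]); he(Wdw[b], 9);
      bnd[b].init(ch[b]);
      Wpw[b].set_size(ch[b], ch[b + 1]); he(Wpw[b], ch[b]);
      bnp[b].init(ch[b + 1]);
    }
    Wfc.set_size(ch[N_BLOCKS], n_classes);
    double sd = std::sqrt(1.0 / ch[N_BLOCKS]);
    for (uword i = 0; i < Wfc.n_elem; ++i) Wfc(i) = (float)(sd * rng.norm());
    bfc.zeros(n_classes);
    input_mean.zeros(3);
  }

  std::vector<fmat*> trainables() {
    std::vector<fmat*> p;
    bn_mats.clear();
    p.push_back(&W0);
    push_bn(p, bn0);
    for (int b = 0; b < N_BLOCKS; ++b) {
      p.push_back(&Wdw[b]); push_bn(p, bnd[b]);
      p.push_back(&Wpw[b]); push_bn(p, bnp[b]);
    }
    p.push_back(&Wfc);
    bn_mats.emplace_back(bfc.memptr(), bfc.n_elem, 1, false, true);
    p.push_back(&bn_mats.back());
    return p;
  }

 private:
  // gamma/beta/bias vectors exposed as aliasing single-column matrices so the
  // optimizer treats every parameter uniformly
  std::deque<fmat> bn_mats;
  void push_bn(std::vector<fmat*>& p, BN& bn) {
    bn_mats.emplace_back(bn.gamma.memptr(), bn.gamma.n_elem, 1, false, true);
    p.push_back(&bn_mats.back());
    bn_mats.emplace_back(bn.beta.memptr(), bn.beta.n_elem, 1, false, true);
    p.push_back(&bn_mats.back());
  }
};

// ---- layer kernels ---------------------------------------------------------

// im2col for the initial 3x3 conv over 3 input channels, TF same padding.
fmat im2col3(const fmat& X, int H, int W, int N, int stride, int& oH,
             int& oW) {
  SamePad pr = same_pad(H, 3, stride), pc = same_pad(W, 3, stride);
  oH = pr.out; oW = pc.out;
  const int HW = H * W, OHW = oH * oW;
  fmat col(OHW * (uword)N, 27, arma::fill::zeros);
  for (int c = 0; c < 3; ++c) {
    const float* xc = X.colptr(c);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        float* dst = col.colptr(c * 9 + kj * 3 + ki);
        for (int n = 0; n < N; ++n) {
          const float* xs = xc + (size_t)n * HW;
          float* ds = dst + (size_t)n * OHW;
          for (int oc = 0; oc < oW; ++oc) {
            int ic = oc * stride - pc.pad + kj;
            if (ic < 0 || ic >= W) continue;
            for (int orr = 0; orr < oH; ++orr) {
              int ir = orr * stride - pr.pad + ki;
              if (ir < 0 || ir >= H) continue;
              ds[oc * oH + orr] = xs[ic * H + ir];
            }
          }
        }
      }
    }
  }
  return col;
}

// depthwise 3x3 conv, TF same padding; X (HW*N x C) -> (oHW*N x C)
fmat dwconv_fwd(const fmat& X, const fmat& Wd, int H, int W, int N, int stride,
                int& oH, int& oW) {
  SamePad pr = same_pad(H, 3, stride), pc = same_pad(W, 3, stride);
  oH = pr.out; oW = pc.out;
  const int C = X.n_cols, HW = H * W, OHW = oH * oW;
  // interior output range whose 3x3 window is fully in bounds
  const int r_lo = (pr.pad + stride - 1) / stride;
  const int r_hi = std::min(oH, (H - 3 + pr.pad) / stride + 1);
  const int c_lo = (pc.pad + stride - 1) / stride;
  const int c_hi = std::min(oW, (W - 3 + pc.pad) / stride + 1);
  fmat Y(OHW * (uword)N, C);
  for (int c = 0; c < C; ++c) {
    const float* w = Wd.colptr(c);
    const float w0 = w[0], w1 = w[1], w2 = w[2], w3 = w[3], w4 = w[4],
                w5 = w[5], w6 = w[6], w7 = w[7], w8 = w[8];
    const float* xc = X.colptr(c);
    float* yc = Y.colptr(c);
    for (int n = 0; n < N; ++n) {
      const float* xs = xc + (size_t)n * HW;
      float* ys = yc + (size_t)n * OHW;
      for (int oc = 0; oc < oW; ++oc) {
        int ic0 = oc * stride - pc.pad;
        bool cin = (oc >= c_lo && oc < c_hi);
        if (cin) {
          const float* x0 = xs + (size_t)(ic0) * H;
          const float* x1 = x0 + H;
          const float* x2 = x1 + H;
          float* yp = ys + (size_t)oc * oH;
          for (int orr = r_lo; orr < r_hi; ++orr) {
            int ir0 = orr * stride - pr.pad;
            yp[orr] = w0 * x0[ir0] + w1 * x0[ir0 + 1] + w2 * x0[ir0 + 2] +
                      w3 * x1[ir0] + w4 * x1[ir0 + 1] + w5 * x1[ir0 + 2] +
                      w6 * x2[ir0] + w7 * x2[ir0 + 1] + w8 * x2[ir0 + 2];
          }
        }
        for (int orr = 0; orr < oH; ++orr) {
          if (cin && orr >= r_lo && orr < r_hi) continue;
          int ir0 = orr * stride - pr.pad;
          float acc = 0.0f;
          for (int kj = 0; kj < 3; ++kj) {
            int ic = ic0 + kj;
            if (ic < 0 || ic >= W) continue;
            const float* xcol = xs + (size_t)ic * H;
            for (int ki = 0; ki < 3; ++ki) {
              int ir = ir0 + ki;
              if (ir < 0 || ir >= H) continue;
              acc += w[kj * 3 + ki] * xcol[ir];
            }
          }
          ys[oc * oH + orr] = acc;
        }
      }
    }
  }
  return Y;
}

// backward of dwconv: given dY (oHW*N x C), X, returns dX and fills dW
fmat dwconv_bwd(const fmat& dY, const fmat& X, const fmat& Wd, int H, int W,
                int N, int stride, fmat& dW) {
  SamePad pr = same_pad(H, 3, stride), pc = same_pad(W, 3, stride);
  const int oH = pr.out, oW = pc.out;
  const int C = X.n_cols, HW = H * W, OHW = oH * oW;
  fmat dX(X.n_rows, C, arma::fill::zeros);
  dW.zeros(9, C);
  // loop per kernel offset so the innermost loops are contiguous in both the
  // output gradient and the input column (vectorizable)
  for (int c = 0; c < C; ++c) {
    const float* w = Wd.colptr(c);
    const float* xc = X.colptr(c);
    const float* gc = dY.colptr(c);
    float* dxc = dX.colptr(c);
    float* dwp = dW.colptr(c);
    double dwacc[9] = {0};
    for (int n = 0; n < N; ++n) {
      const float* xs = xc + (size_t)n * HW;
      const float* gs = gc + (size_t)n * OHW;
      float* dxs = dxc + (size_t)n * HW;
      for (int kj = 0; kj < 3; ++kj) {
        for (int oc = 0; oc < oW; ++oc) {
          int ic = oc * stride - pc.pad + kj;
          if (ic < 0 || ic >= W) continue;
          const float* gcol = gs + (size_t)oc * oH;
          const float* xcol = xs + (size_t)ic * H;
          float* dxcol = dxs + (size_t)ic * H;
          for (int ki = 0; ki < 3; ++ki) {
            int off = ki - pr.pad;
            // valid orr range: 0 <= orr*stride + off < H
            int lo = off < 0 ? (-off + stride - 1) / stride : 0;
            int hi = std::min(oH, (H - 1 - off) / stride + 1);
            const float wk = w[kj * 3 + ki];
            float acc = 0;
            if (stride == 1) {
              const float* xo = xcol + off;
              float* dxo = dxcol + off;
              for (int orr = lo; orr < hi; ++orr)
                dxo[orr] += wk * gcol[orr];
              for (int orr = lo; orr < hi; ++orr)
                acc += gcol[orr] * xo[orr];
            } else {
              for (int orr = lo; orr < hi; ++orr) {
                float g = gcol[orr];
                int ir = orr * stride + off;
                acc += g * xcol[ir];
                dxcol[ir] += wk * g;
              }
            }
            dwacc[kj * 3 + ki] += acc;
          }
        }
      }
    }
    for (int k = 0; k < 9; ++k) dwp[k] = (float)dwacc[k];
  }
  return dX;
}

struct BNCache { fmat xhat; fvec invstd; };

// batch norm, optionally fused with relu on the output
fmat bn_fwd(const fmat& X, BN& bn, bool training, BNCache* cache, bool relu) {
  const int C = X.n_cols;
  const size_t M = X.n_rows;
  fmat Y(M, C);
  fvec mean(C), var(C);
  if (training) {
    for (int c = 0; c < C; ++c) {
      const float* x = X.colptr(c);
      double s = 0, s2 = 0;
      for (size_t i = 0; i < M; ++i) { s += x[i]; s2 += (double)x[i] * x[i]; }
      double mu = s / M;
      double v = s2 / M - mu * mu;
      mean(c) = (float)mu;
      var(c) = (float)(v > 0 ? v : 0);
    }
    bn.rmean = bn.decay * bn.rmean + (1.0f - bn.decay) * mean;
    bn.rvar = bn.decay * bn.rvar + (1.0f - bn.decay) * var;
  } else {
    mean = bn.rmean; var = bn.rvar;
  }
  fvec invstd = 1.0f / arma::sqrt(var + bn.eps);
  if (cache) { cache->xhat.set_size(M, C); cache->invstd = invstd; }
  for (int c = 0; c < C; ++c) {
    const float* x = X.colptr(c);
    float* y = Y.colptr(c);
    float mu = mean(c), is = invstd(c), g = bn.gamma(c), be = bn.beta(c);
    if (cache) {
      float* xh = cache->xhat.colptr(c);
      for (size_t i = 0; i < M; ++i) {
        xh[i] = (x[i] - mu) * is;
        float v = g * xh[i] + be;
        y[i] = (relu && v < 0) ? 0.0f : v;
      }
    } else {
      for (size_t i = 0; i < M; ++i) {
        float v = g * (x[i] - mu) * is + be;
        y[i] = (relu && v < 0) ? 0.0f : v;
      }
    }
  }
  return Y;
}

// returns dX; fills dgamma, dbeta
fmat bn_bwd(const fmat& dY, const BN& bn, const BNCache& cache, fvec& dgamma,
            fvec& dbeta) {
  const int C = dY.n_cols;
  const size_t M = dY.n_rows;
  const double Md = (double)M;
  fmat dX(M, C);
  dgamma.set_size(C); dbeta.set_size(C);
  for (int c = 0; c < C; ++c) {
    const float* dy = dY.colptr(c);
    const float* xh = cache.xhat.colptr(c);
    float* dx = dX.colptr(c);
    double sdy = 0, sdyx = 0;
    for (size_t i = 0; i < M; ++i) {
      sdy += dy[i];
      sdyx += (double)dy[i] * xh[i];
    }
    dgamma(c) = (float)sdyx;
    dbeta(c) = (float)sdy;
    float k = (float)((double)bn.gamma(c) * cache.invstd(c) / Md);
    float fsdy = (float)sdy, fsdyx = (float)sdyx;
    for (size_t i = 0; i < M; ++i)
      dx[i] = k * ((float)Md * dy[i] - fsdy - xh[i] * fsdyx);
  }
  return dX;
}

// zero gradient entries where the relu output `ref` was inactive
inline void relu_mask_(fmat& g, const fmat& ref) {
  float* gp = g.memptr();
  const float* rp = ref.memptr();
  for (size_t i = 0, n = g.n_elem; i < n; ++i)
    if (rp[i] <= 0) gp[i] = 0;
}

struct Workspace {
  fmat col0;                      // im2col of input
  BNCache bc0;
  std::vector<fmat> dw_in, pw_in; // per block; dw_in[0] is the conv0 relu out
  std::vector<BNCache> bcd, bcp;
  std::vector<int> Hs, Ws;        // spatial dims entering each block
  int fH = 0, fW = 0;
  fmat feats;                     // block-13 relu output
  fmat pooled;                    // N x C
  fmat drop_mask;                 // N x C (empty if no dropout)
  fmat probs;                     // N x K
};

// full convolutional stack; X (HW*N x 3) already centered.
// ws == nullptr -> inference mode with running BN stats, no caches.
fmat conv_stack(Net& net, const fmat& X, int H, int W, int N, bool training,
                Workspace* ws, int& fH, int& fW) {
  int oH, oW;
  fmat col = im2col3(X, H, W, N, 2, oH, oW);
  fmat a = col * net.W0;
  if (ws) ws->col0 = std::move(col);
  a = bn_fwd(a, net.bn0, training, ws ? &ws->bc0 : nullptr, true);
  if (ws) { ws->Hs.assign(N_BLOCKS, 0); ws->Ws.assign(N_BLOCKS, 0);
            ws->dw_in.resize(N_BLOCKS); ws->pw_in.resize(N_BLOCKS);
            ws->bcd.resize(N_BLOCKS); ws->bcp.resize(N_BLOCKS); }
  int h = oH, w = oW;
  for (int b = 0; b < N_BLOCKS; ++b) {
    const fmat* ain = &a;
    if (ws) { ws->Hs[b] = h; ws->Ws[b] = w;
              ws->dw_in[b] = std::move(a); ain = &ws->dw_in[b]; }
    int nh, nw;
    fmat z = dwconv_fwd(*ain, net.Wdw[b], h, w, N, DW_STRIDE[b], nh, nw);
    z = bn_fwd(z, net.bnd[b], training, ws ? &ws->bcd[b] : nullptr, true);
    const fmat* zin = &z;
    if (ws) { ws->pw_in[b] = std::move(z); zin = &ws->pw_in[b]; }
    fmat y = *zin * net.Wpw[b];
    y = bn_fwd(y, net.bnp[b], training, ws ? &ws->bcp[b] : nullptr, true);
    a = std::move(y);
    h = nh; w = nw;
  }
  fH = h; fW = w;
  return a;
}

fmat softmax_rows(fmat logits) {
  for (uword i = 0; i < logits.n_rows; ++i) {
    arma::frowvec r = logits.row(i);
    r -= r.max();
    r = arma::exp(r);
    logits.row(i) = r / arma::accu(r);
  }
  return logits;
}

fmat head_fwd(Net& net, const fmat& feats, int fH, int fW, int N,
              bool training, Workspace* ws) {
  const int C = feats.n_cols, FHW = fH * fW;
  fmat pooled(N, C);
  for (int c = 0; c < C; ++c) {
    const float* fc = feats.colptr(c);
    for (int n = 0; n < N; ++n) {
      double s = 0;
      const float* fs = fc + (size_t)n * FHW;
      for (int p = 0; p < FHW; ++p) s += fs[p];
      pooled(n, c) = (float)(s / FHW);
    }
  }
  fmat drop_mask;
  if (training && net.dropout > 0) {
    drop_mask.set_size(N, C);
    float keep = 1.0f - (float)net.dropout;
    for (uword i = 0; i < drop_mask.n_elem; ++i)
      drop_mask(i) = net.rng.unif() < keep ? 1.0f / keep : 0.0f;
    pooled %= drop_mask;
  }
  if (ws) { ws->pooled = pooled; ws->drop_mask = drop_mask; }
  fmat logits = pooled * net.Wfc;
  logits.each_row() += net.bfc.t();
  return softmax_rows(std::move(logits));
}

fmat ingest(const NumericVector& x, int& H, int& W, int& N, const fvec& cm) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() == 3) { H = dims[0]; W = dims[1]; N = 1;
    if (dims[2] != 3) stop("expected 3 channels");
  } else if (dims.size() == 4) { H = dims[0]; W = dims[1]; N = dims[3];
    if (dims[2] != 3) stop("expected 3 channels");
  } else stop("input must be an (H, W, 3[, N]) array");
  const int HW = H * W;
  fmat X(HW * (uword)N, 3);
  const double* src = x.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < 3; ++c) {
      const double* s = src + (size_t)n * HW * 3 + (size_t)c * HW;
      float* d = X.colptr(c) + (size_t)n * HW;
      float mc = cm(c);
      for (int p = 0; p < HW; ++p) d[p] = (float)s[p] - mc;
    }
  return X;
}

double xent_and_dlogits(const fmat& probs, const IntegerVector& y,
                        fmat& dlogit) {
  const int N = probs.n_rows;
  double loss = 0;
  dlogit = probs;
  for (int n = 0; n < N; ++n) {
    int k = y[n] - 1;
    if (k < 0 || k >= (int)probs.n_cols) stop("label out of range");
    loss -= std::log((double)probs(n, k) + 1e-12);
    dlogit(n, k) -= 1.0f;
  }
  dlogit /= (float)N;
  return loss / N;
}

// backward through the whole net; returns gradients in trainables() order
std::vector<fmat> backward(Net& net, Workspace& ws, const fmat& dlogits,
                           int N) {
  const int C = ws.pooled.n_cols, FHW = ws.fH * ws.fW;
  fmat dWfc = ws.pooled.t() * dlogits;
  fvec dbfc = arma::sum(dlogits, 0).t();
  fmat dpool = dlogits * net.Wfc.t();
  if (!ws.drop_mask.is_empty()) dpool %= ws.drop_mask;

  fmat da(ws.feats.n_rows, C);
  for (int c = 0; c < C; ++c) {
    float* dc = da.colptr(c);
    for (int n = 0; n < N; ++n) {
      float v = dpool(n, c) / FHW;
      float* ds = dc + (size_t)n * FHW;
      for (int p = 0; p < FHW; ++p) ds[p] = v;
    }
  }
  relu_mask_(da, ws.feats);

  std::vector<fmat> gWdw(N_BLOCKS), gWpw(N_BLOCKS);
  std::vector<fvec> gd_gamma(N_BLOCKS), gd_beta(N_BLOCKS),
      gp_gamma(N_BLOCKS), gp_beta(N_BLOCKS);
  for (int b = N_BLOCKS - 1; b >= 0; --b) {
    fvec dg, db;
    fmat dz = bn_bwd(da, net.bnp[b], ws.bcp[b], dg, db);
    gp_gamma[b] = dg; gp_beta[b] = db;
    gWpw[b] = ws.pw_in[b].t() * dz;
    fmat ddw_relu = dz * net.Wpw[b].t();
    relu_mask_(ddw_relu, ws.pw_in[b]);
    fmat ddw = bn_bwd(ddw_relu, net.bnd[b], ws.bcd[b], dg, db);
    gd_gamma[b] = dg; gd_beta[b] = db;
    fmat dWd;
    fmat dprev = dwconv_bwd(ddw, ws.dw_in[b], net.Wdw[b], ws.Hs[b], ws.Ws[b],
                            N, DW_STRIDE[b], dWd);
    gWdw[b] = dWd;
    relu_mask_(dprev, ws.dw_in[b]);  // dw_in is the previous relu output
    da = std::move(dprev);
  }
  fvec dg0, db0;
  fmat dz0 = bn_bwd(da, net.bn0, ws.bc0, dg0, db0);
  fmat dW0 = ws.col0.t() * dz0;

  std::vector<fmat> g;
  g.push_back(dW0);
  g.push_back(fmat(dg0));
  g.push_back(fmat(db0));
  for (int b = 0; b < N_BLOCKS; ++b) {
    g.push_back(gWdw[b]);
    g.push_back(fmat(gd_gamma[b]));
    g.push_back(fmat(gd_beta[b]));
    g.push_back(gWpw[b]);
    g.push_back(fmat(gp_gamma[b]));
    g.push_back(fmat(gp_beta[b]));
  }
  g.push_back(dWfc);
  g.push_back(fmat(dbfc));
  return g;
}

void apply_update(Net& net, const std::vector<fmat>& grads) {
  std::vector<fmat*> params = net.trainables();
  if (net.m_state.empty()) {
    for (auto* p : params)
      net.m_state.emplace_back(arma::size(*p), arma::fill::zeros);
    if (net.opt_mode == 0)
      for (auto* p : params)
        net.v_state.emplace_back(arma::size(*p), arma::fill::zeros);
  }
  net.t += 1;
  if (net.opt_mode == 0) {
    float b1 = net.beta1, b2 = net.beta2;
    float corr1 = 1.0f - std::pow(b1, (float)net.t);
    float corr2 = 1.0f - std::pow(b2, (float)net.t);
    for (size_t i = 0; i < params.size(); ++i) {
      net.m_state[i] = b1 * net.m_state[i] + (1 - b1) * grads[i];
      net.v_state[i] = b2 * net.v_state[i] + (1 - b2) * arma::square(grads[i]);
      *params[i] -= net.lr * (net.m_state[i] / corr1) /
                    (arma::sqrt(net.v_state[i] / corr2) + net.opt_eps);
    }
  } else {
    for (size_t i = 0; i < params.size(); ++i) {
      net.m_state[i] = net.momentum * net.m_state[i] - net.lr * grads[i];
      *params[i] += net.momentum * net.m_state[i] - net.lr * grads[i];
    }
  }
}

Net* get(SEXP ptr) {
  Rcpp::XPtr<Net> p(ptr);
  return p.get();
}

}  // namespace

// [[Rcpp::export]]
SEXP gn_create(double alpha, int input_size, int n_classes, double dropout,
               double seed) {
  if (alpha <= 0) stop("alpha must be positive");
#ifdef __GLIBC__
  // keep large activation buffers on the heap so they are reused across
  // iterations instead of being mmap'd and faulted in every call
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
#endif
  if (input_size % 32 != 0) stop("input_size must be a multiple of 32");
  Net* net = new Net(alpha, input_size, n_classes, dropout, (uint64_t)seed);
  return Rcpp::XPtr<Net>(net, true);
}

// [[Rcpp::export]]
List gn_config(SEXP ptr) {
  Net* net = get(ptr);
  double npar = (double)net->W0.n_elem + net->Wfc.n_elem + net->bfc.n_elem +
                2.0 * net->ch[0];
  for (int b = 0; b < N_BLOCKS; ++b)
    npar += net->Wdw[b].n_elem + net->Wpw[b].n_elem + 2.0 * net->ch[b] +
            2.0 * net->ch[b + 1];
  IntegerVector strides(N_BLOCKS);
  for (int b = 0; b < N_BLOCKS; ++b) strides[b] = DW_STRIDE[b];
  return List::create(
      _["alpha"] = net->alpha, _["input_size"] = net->input_size,
      _["n_classes"] = net->n_classes, _["dropout"] = net->dropout,
      _["channels"] = IntegerVector(net->ch.begin(), net->ch.end()),
      _["block_strides"] = strides,
      _["n_params"] = npar,
      _["feature_hw"] = net->input_size / 32);
}

// [[Rcpp::export]]
void gn_set_optimizer(SEXP ptr, std::string mode, double lr, double momentum) {
  Net* net = get(ptr);
  if (mode == "adam") net->opt_mode = 0;
  else if (mode == "sgdn") net->opt_mode = 1;
  else stop("unknown optimizer mode");
  net->lr = (float)lr;
  net->momentum = (float)momentum;
  net->m_state.clear();
  net->v_state.clear();
  net->t = 0;
}

// [[Rcpp::export]]
void gn_set_input_mean(SEXP ptr, NumericVector m) {
  Net* net = get(ptr);
  if (m.size() != 3) stop("input mean must have length 3");
  for (int i = 0; i < 3; ++i) net->input_mean(i) = (float)m[i];
}

// [[Rcpp::export]]
double gn_train_step(SEXP ptr, NumericVector x, IntegerVector y) {
  GN_SET_FTZ();  // subnormal activations/gradients cripple x86 throughput
  Net* net = get(ptr);
  int H, W, N;
  fmat X = ingest(x, H, W, N, net->input_mean);
  if (H != net->input_size || W != net->input_size)
    stop("training batch must match the network input size");
  if ((int)y.size() != N) stop("labels do not match batch size");
  Workspace ws;
  ws.feats = conv_stack(*net, X, H, W, N, true, &ws, ws.fH, ws.fW);
  ws.probs = head_fwd(*net, ws.feats, ws.fH, ws.fW, N, true, &ws);
  fmat dlogits;
  double loss = xent_and_dlogits(ws.probs, y, dlogits);
  if (!std::isfinite(loss))
    stop("training diverged: non-finite loss at iteration %ld",
         (long)(net->t + 1));
  std::vector<fmat> grads = backward(*net, ws, dlogits, N);
  apply_update(*net, grads);
  return loss;
}

// [[Rcpp::export]]
List gn_loss_grads(SEXP ptr, NumericVector x, IntegerVector y) {
  // training-mode forward/backward without an optimizer update (dropout is
  // bypassed so the loss is deterministic; used for gradient verification)
  GN_SET_FTZ();
  Net* net = get(ptr);
  double saved_dropout = net->dropout;
  net->dropout = 0.0;
  int H, W, N;
  fmat X = ingest(x, H, W, N, net->input_mean);
  Workspace ws;
  ws.feats = conv_stack(*net, X, H, W, N, true, &ws, ws.fH, ws.fW);
  ws.probs = head_fwd(*net, ws.feats, ws.fH, ws.fW, N, true, &ws);
  fmat dlogits;
  double loss = xent_and_dlogits(ws.probs, y, dlogits);
  std::vector<fmat> grads = backward(*net, ws, dlogits, N);
  net->dropout = saved_dropout;
  List out(grads.size());
  for (size_t i = 0; i < grads.size(); ++i)
    out[i] = wrap(arma::conv_to<arma::mat>::from(grads[i]));
  return List::create(_["loss"] = loss, _["grads"] = out);
}

// [[Rcpp::export]]
NumericMatrix gn_predict(SEXP ptr, NumericVector x) {
  GN_SET_FTZ();
  Net* net = get(ptr);
  int H, W, N;
  fmat X = ingest(x, H, W, N, net->input_mean);
  int fH, fW;
  fmat feats = conv_stack(*net, X, H, W, N, false, nullptr, fH, fW);
  fmat probs = head_fwd(*net, feats, fH, fW, N, false, nullptr);
  return wrap(arma::conv_to<arma::mat>::from(probs));
}

// [[Rcpp::export]]
NumericVector gn_features(SEXP ptr, NumericVector x) {
  // inference-mode feature maps after the last depthwise-separable block,
  // for arbitrary input sizes; returns an (fH, fW, C, N) array
  GN_SET_FTZ();
  Net* net = get(ptr);
  int H, W, N;
  fmat X = ingest(x, H, W, N, net->input_mean);
  int fH, fW;
  fmat feats = conv_stack(*net, X, H, W, N, false, nullptr, fH, fW);
  const int C = feats.n_cols, FHW = fH * fW;
  NumericVector out((size_t)FHW * C * N);
  out.attr("dim") = IntegerVector::create(fH, fW, C, N);
  double* dst = out.begin();
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const float* s = feats.colptr(c) + (size_t)n * FHW;
      double* d = dst + (size_t)n * FHW * C + (size_t)c * FHW;
      for (int p = 0; p < FHW; ++p) d[p] = s[p];
    }
  return out;
}

// [[Rcpp::export]]
List gn_get_weights(SEXP ptr) {
  Net* net = get(ptr);
  List out;
  auto putm = [&](std::string name, const fmat& m) {
    out[name] = wrap(arma::conv_to<arma::mat>::from(m));
  };
  auto putv = [&](std::string name, const fvec& v) {
    out[name] = wrap(arma::conv_to<arma::vec>::from(v));
  };
  putm("W0", net->W0);
  auto bn_out = [&](const BN& bn, std::string name) {
    putv(name + ".gamma", bn.gamma);
    putv(name + ".beta", bn.beta);
    putv(name + ".rmean", bn.rmean);
    putv(name + ".rvar", bn.rvar);
  };
  bn_out(net->bn0, "bn0");
  for (int b = 0; b < N_BLOCKS; ++b) {
    std::string i = std::to_string(b + 1);
    putm("Wdw" + i, net->Wdw[b]);
    bn_out(net->bnd[b], "bnd" + i);
    putm("Wpw" + i, net->Wpw[b]);
    bn_out(net->bnp[b], "bnp" + i);
  }
  putm("Wfc", net->Wfc);
  putv("bfc", net->bfc);
  putv("input_mean", net->input_mean);
  return out;
}

// [[Rcpp::export]]
void gn_set_weights(SEXP ptr, List w) {
  Net* net = get(ptr);
  auto getm = [&](std::string name) -> fmat {
    if (!w.containsElementNamed(name.c_str()))
      stop("missing weight tensor '%s'", name.c_str());
    return arma::conv_to<fmat>::from(as<arma::mat>(w[name]));
  };
  auto getv = [&](std::string name) -> fvec {
    if (!w.containsElementNamed(name.c_str()))
      stop("missing weight tensor '%s'", name.c_str());
    return arma::conv_to<fvec>::from(as<arma::vec>(w[name]));
  };
  auto bn_in = [&](BN& bn, std::string name) {
    bn.gamma = getv(name + ".gamma"); bn.beta = getv(name + ".beta");
    bn.rmean = getv(name + ".rmean"); bn.rvar = getv(name + ".rvar");
  };
  net->W0 = getm("W0");
  bn_in(net->bn0, "bn0");
  for (int b = 0; b < N_BLOCKS; ++b) {
    std::string i = std::to_string(b + 1);
    net->Wdw[b] = getm("Wdw" + i);
    bn_in(net->bnd[b], "bnd" + i);
    net->Wpw[b] = getm("Wpw" + i);
    bn_in(net->bnp[b], "bnp" + i);
  }
  net->Wfc = getm("Wfc");
  net->bfc = getv("bfc");
  if (w.containsElementNamed("input_mean"))
    net->input_mean = getv("input_mean");
  net->m_state.clear();
  net->v_state.clear();
}

// [[Rcpp::export]]
NumericVector gn_assemble_batch(List pixels, int rs, int cs,
                                NumericMatrix params) {
  // params columns: r0, c0 (1-based crop offsets), swap, rev_r, rev_c,
  // 3x3 colour matrix (row-major), offset. Gathers the augmented crops of
  // uint8-encoded (raw) or numeric patches into an (cs, cs, 3, N) array.
  const int N = pixels.size();
  if (params.nrow() != N || params.ncol() != 15)
    stop("params must be N x 15");
  NumericVector out((size_t)cs * cs * 3 * N);
  out.attr("dim") = IntegerVector::create(cs, cs, 3, N);
  double* dst = out.begin();
  for (int n = 0; n < N; ++n) {
    const int r0 = (int)params(n, 0) - 1, c0 = (int)params(n, 1) - 1;
    const bool swap = params(n, 2) != 0, rev_r = params(n, 3) != 0,
               rev_c = params(n, 4) != 0;
    double m[9], off = params(n, 14);
    for (int k = 0; k < 9; ++k) m[k] = params(n, 5 + k);
    RObject px = pixels[n];
    const Rbyte* praw = nullptr;
    const double* pdbl = nullptr;
    if (TYPEOF(px) == RAWSXP) praw = RAW(px);
    else pdbl = REAL(px);
    const size_t plane = (size_t)rs * rs;
    double* o0 = dst + (size_t)n * cs * cs * 3;
    for (int oc = 0; oc < cs; ++oc) {
      for (int orr = 0; orr < cs; ++orr) {
        // crop indices before the dihedral remap
        int cr = rev_r ? cs - 1 - orr : orr;
        int cc = rev_c ? cs - 1 - oc : oc;
        if (swap) std::swap(cr, cc);
        size_t src = (size_t)(c0 + cc) * rs + (r0 + cr);
        double rgb[3];
        for (int ch = 0; ch < 3; ++ch)
          rgb[ch] = praw ? praw[src + ch * plane] / 255.0
                         : pdbl[src + ch * plane];
        for (int ch = 0; ch < 3; ++ch) {
          double v = m[ch * 3] * rgb[0] + m[ch * 3 + 1] * rgb[1] +
                     m[ch * 3 + 2] * rgb[2] + off;
          o0[(size_t)ch * cs * cs + (size_t)oc * cs + orr] =
              v < 0 ? 0 : (v > 1 ? 1 : v);
        }
      }
    }
  }
  return out;
}
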