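// Native depth-configurable multi-head U-Net (float32) with manual
// backpropagation, AdamW and global gradient-norm clipping.
//
// Layout conventions:
//   feature maps  : arma::fcube (H rows, W cols, C slices)
//   conv weights  : arma::fmat (Cout, k*k*Cin), col index = (c*k + ky)*k + kx
//   im2col matrix : (H*W, k*k*Cin); pixel linear index p = j*H + i (col-major)
//
// The network follows the classic U-Net shape: encoder blocks of two 3x3
// convolutions each followed by BatchNorm and ReLU, 2x2 max-pooling between
// levels, and up-blocks made of a 1x1 channel-reduction convolution followed
// by bilinear x2 interpolation, skip concatenation, and a decoder conv block.
// A final 1x1 convolution emits one logit map per output channel.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <memory>
#ifdef __GLIBC__
#include <malloc.h>
#endif

using arma::fcube;
using arma::fmat;
using arma::fvec;

static const float BN_EPS = 1e-5f;
static const float BN_MOMENTUM = 0.1f;

// ---------------------------------------------------------------------------
// im2col / col2im for 3x3 same-padding convolutions

static void im2col3(const fcube& x, fmat& col) {
  const arma::uword H = x.n_rows, W = x.n_cols, C = x.n_slices;
  col.set_size(H * W, 9 * C);
  fmat pad(H + 2, W + 2, arma::fill::zeros);
  for (arma::uword c = 0; c < C; ++c) {
    pad.submat(1, 1, H, W) = x.slice(c);
    for (arma::uword ky = 0; ky < 3; ++ky)
      for (arma::uword kx = 0; kx < 3; ++kx) {
        arma::uword idx = (c * 3 + ky) * 3 + kx;
        col.col(idx) = arma::vectorise(pad.submat(ky, kx, ky + H - 1, kx + W - 1));
      }
  }
}

static void col2im3(const fmat& dcol, arma::uword H, arma::uword W, arma::uword C,
                    fcube& dx) {
  dx.set_size(H, W, C);
  fmat pad(H + 2, W + 2);
  for (arma::uword c = 0; c < C; ++c) {
    pad.zeros();
    for (arma::uword ky = 0; ky < 3; ++ky)
      for (arma::uword kx = 0; kx < 3; ++kx) {
        arma::uword idx = (c * 3 + ky) * 3 + kx;
        pad.submat(ky, kx, ky + H - 1, kx + W - 1) +=
          arma::reshape(dcol.col(idx), H, W);
      }
    dx.slice(c) = pad.submat(1, 1, H, W);
  }
}

// ---------------------------------------------------------------------------
// Layers

struct Param {
  fmat w, g, m, v;           // value, gradient, Adam moments
  Param() {}
  void init(arma::uword r, arma::uword c) {
    w.set_size(r, c);
    g.zeros(r, c); m.zeros(r, c); v.zeros(r, c);
  }
};

struct Conv {
  arma::uword k, cin, cout;
  Param W, b;                // b is 1 x cout
  fmat cache_col;            // im2col of last training input
  fcube cache_in;            // needed only for k==1 backward (uses reshape)
  arma::uword inH = 0, inW = 0;

  void init(arma::uword k_, arma::uword cin_, arma::uword cout_, std::mt19937& rng) {
    k = k_; cin = cin_; cout = cout_;
    W.init(cout, k * k * cin);
    b.init(1, cout);
    b.w.zeros();
    std::normal_distribution<float> nd(0.0f, std::sqrt(2.0f / (float)(k * k * cin)));
    for (arma::uword i = 0; i < W.w.n_elem; ++i) W.w(i) = nd(rng);
  }

  fcube forward(const fcube& x, bool train) {
    inH = x.n_rows; inW = x.n_cols;
    const arma::uword HW = inH * inW;
    fcube out(inH, inW, cout);
    if (k == 1) {
      fmat xm(const_cast<float*>(x.memptr()), HW, cin, false, true);
      fmat om = xm * W.w.t();
      om.each_row() += b.w;
      std::memcpy(out.memptr(), om.memptr(), sizeof(float) * om.n_elem);
      if (train) cache_in = x;
    } else {
      if (train) {
        im2col3(x, cache_col);
        fmat om = cache_col * W.w.t();
        om.each_row() += b.w;
        std::memcpy(out.memptr(), om.memptr(), sizeof(float) * om.n_elem);
      } else {
        // eval: chunk over pixel rows to bound im2col memory on large scans
        fmat pad(inH + 2, inW + 2, arma::fill::zeros);
        const arma::uword chunk_cols = std::max<arma::uword>(1, 65536 / inH);
        fmat col;
        for (arma::uword j0 = 0; j0 < inW; j0 += chunk_cols) {
          arma::uword j1 = std::min(inW, j0 + chunk_cols);
          arma::uword nc = j1 - j0;
          col.set_size(inH * nc, 9 * cin);
          for (arma::uword c = 0; c < cin; ++c) {
            pad.submat(1, 1, inH, inW) = x.slice(c);
            for (arma::uword ky = 0; ky < 3; ++ky)
              for (arma::uword kx = 0; kx < 3; ++kx) {
                arma::uword idx = (c * 3 + ky) * 3 + kx;
                col.col(idx) = arma::vectorise(
                  pad.submat(ky, kx + j0, ky + inH - 1, kx + j1 - 1));
              }
          }
          fmat om = col * W.w.t();
          om.each_row() += b.w;
          for (arma::uword c = 0; c < cout; ++c)
            out.slice(c).cols(j0, j1 - 1) =
              arma::reshape(om.col(c), inH, nc);
        }
      }
    }
    return out;
  }

  fcube backward(const fcube& dout) {
    const arma::uword HW = inH * inW;
    fmat dm(const_cast<float*>(dout.memptr()), HW, cout, false, true);
    b.g += arma::sum(dm, 0);
    fcube dx;
    if (k == 1) {
      fmat xm(const_cast<float*>(cache_in.memptr()), HW, cin, false, true);
      W.g += dm.t() * xm;
      fmat dxm = dm * W.w;
      dx.set_size(inH, inW, cin);
      std::memcpy(dx.memptr(), dxm.memptr(), sizeof(float) * dxm.n_elem);

    } else {
      W.g += dm.t() * cache_col;
      fmat dcol = dm * W.w;
      col2im3(dcol, inH, inW, cin, dx);

    }
    return dx;
  }
};

struct BatchNorm {
  arma::uword C;
  Param gamma, beta;         // 1 x C
  fvec run_mean, run_var;
  // caches
  fcube cache_xhat;
  fvec cache_invstd;

  void init(arma::uword C_) {
    C = C_;
    gamma.init(1, C); beta.init(1, C);
    gamma.w.ones(); beta.w.zeros();
    run_mean.zeros(C); run_var.ones(C);
  }

  fcube forward(const fcube& x, bool train) {
    fcube out(x.n_rows, x.n_cols, C);
    if (train) {
      cache_xhat.set_size(x.n_rows, x.n_cols, C);
      cache_invstd.set_size(C);
      const float n = (float)(x.n_rows * x.n_cols);
      for (arma::uword c = 0; c < C; ++c) {
        float mu = arma::accu(x.slice(c)) / n;
        fmat xc = x.slice(c) - mu;
        float var = arma::accu(arma::square(xc)) / n;
        float invstd = 1.0f / std::sqrt(var + BN_EPS);
        cache_invstd(c) = invstd;
        cache_xhat.slice(c) = xc * invstd;
        out.slice(c) = cache_xhat.slice(c) * gamma.w(0, c) + beta.w(0, c);
        run_mean(c) = (1.0f - BN_MOMENTUM) * run_mean(c) + BN_MOMENTUM * mu;
        run_var(c)  = (1.0f - BN_MOMENTUM) * run_var(c)  + BN_MOMENTUM * var;
      }
    } else {
      for (arma::uword c = 0; c < C; ++c) {
        float invstd = 1.0f / std::sqrt(run_var(c) + BN_EPS);
        out.slice(c) = (x.slice(c) - run_mean(c)) * invstd * gamma.w(0, c) +
          beta.w(0, c);
      }
    }
    return out;
  }

  fcube backward(const fcube& dout) {
    fcube dx(dout.n_rows, dout.n_cols, C);
    const float n = (float)(dout.n_rows * dout.n_cols);
    for (arma::uword c = 0; c < C; ++c) {
      const fmat& dy = dout.slice(c);
      const fmat& xh = cache_xhat.slice(c);
      float sum_dy = arma::accu(dy);
      float sum_dy_xh = arma::accu(dy % xh);
      gamma.g(0, c) += sum_dy_xh;
      beta.g(0, c)  += sum_dy;
      dx.slice(c) = (gamma.w(0, c) * cache_invstd(c) / n) *
        (n * dy - sum_dy - xh * sum_dy_xh);
    }

    return dx;
  }
};

struct ReLU {
  fcube mask;
  fcube forward(const fcube& x, bool train) {
    fcube out(x.n_rows, x.n_cols, x.n_slices);
    const float* xp = x.memptr();
    float* op = out.memptr();
    if (train) {
      mask.set_size(x.n_rows, x.n_cols, x.n_slices);
      float* mp = mask.memptr();
      for (arma::uword i = 0; i < x.n_elem; ++i) {
        bool pos = xp[i] > 0.0f;
        op[i] = pos ? xp[i] : 0.0f;
        mp[i] = pos ? 1.0f : 0.0f;
      }
    } else {
      for (arma::uword i = 0; i < x.n_elem; ++i)
        op[i] = xp[i] > 0.0f ? xp[i] : 0.0f;
    }
    return out;
  }
  fcube backward(const fcube& dout) {
    return dout % mask;
  }
};

struct ConvBlock {
  Conv c1, c2;
  BatchNorm b1, b2;
  ReLU r1, r2;
  void init(arma::uword cin, arma::uword cout, std::mt19937& rng) {
    c1.init(3, cin, cout, rng);  b1.init(cout);
    c2.init(3, cout, cout, rng); b2.init(cout);
  }
  fcube forward(const fcube& x, bool train) {
    fcube h = r1.forward(b1.forward(c1.forward(x, train), train), train);
    return r2.forward(b2.forward(c2.forward(h, train), train), train);
  }
  fcube backward(const fcube& dout) {
    fcube d = c2.backward(b2.backward(r2.backward(dout)));
    return c1.backward(b1.backward(r1.backward(d)));
  }
  void collect(std::vector<Param*>& ps) {
    ps.push_back(&c1.W); ps.push_back(&c1.b);
    ps.push_back(&b1.gamma); ps.push_back(&b1.beta);
    ps.push_back(&c2.W); ps.push_back(&c2.b);
    ps.push_back(&b2.gamma); ps.push_back(&b2.beta);
  }
};

struct MaxPool {
  arma::ucube argmax;        // linear index into input slice
  arma::uword inH = 0, inW = 0;
  fcube forward(const fcube& x, bool train) {
    inH = x.n_rows; inW = x.n_cols;
    const arma::uword H2 = inH / 2, W2 = inW / 2, C = x.n_slices;
    fcube out(H2, W2, C);
    if (train) argmax.set_size(H2, W2, C);
    for (arma::uword c = 0; c < C; ++c) {
      const fmat& s = x.slice(c);
      for (arma::uword j = 0; j < W2; ++j)
        for (arma::uword i = 0; i < H2; ++i) {
          arma::uword i0 = 2 * i, j0 = 2 * j;
          float v00 = s(i0, j0), v10 = s(i0 + 1, j0);
          float v01 = s(i0, j0 + 1), v11 = s(i0 + 1, j0 + 1);
          float best = v00; arma::uword bi = i0, bj = j0;
          if (v10 > best) { best = v10; bi = i0 + 1; bj = j0; }
          if (v01 > best) { best = v01; bi = i0; bj = j0 + 1; }
          if (v11 > best) { best = v11; bi = i0 + 1; bj = j0 + 1; }
          out(i, j, c) = best;
          if (train) argmax(i, j, c) = bj * inH + bi;
        }
    }
    return out;
  }
  fcube backward(const fcube& dout) {
    const arma::uword C = dout.n_slices;
    fcube dx(inH, inW, C, arma::fill::zeros);
    for (arma::uword c = 0; c < C; ++c) {
      float* dst = dx.slice(c).memptr();
      for (arma::uword j = 0; j < dout.n_cols; ++j)
        for (arma::uword i = 0; i < dout.n_rows; ++i)
          dst[argmax(i, j, c)] += dout(i, j, c);
    }

    return dx;
  }
};

// Bilinear x2 upsampling (half-pixel centres, i.e. align_corners = false).
struct Upsample2 {
  arma::uword inH = 0, inW = 0;
  static void weights(arma::uword n_in, arma::uword n_out,
                      arma::uvec& i0, arma::uvec& i1, fvec& w1) {
    i0.set_size(n_out); i1.set_size(n_out); w1.set_size(n_out);
    for (arma::uword o = 0; o < n_out; ++o) {
      double src = (o + 0.5) * (double)n_in / (double)n_out - 0.5;
      if (src < 0) src = 0;
      double fl = std::floor(src);
      arma::uword a = (arma::uword)fl;
      if (a >= n_in - 1) { a = n_in - 1; i0(o) = a; i1(o) = a; w1(o) = 0.0f; }
      else { i0(o) = a; i1(o) = a + 1; w1(o) = (float)(src - fl); }
    }
  }
  fcube forward(const fcube& x, bool) {
    inH = x.n_rows; inW = x.n_cols;
    const arma::uword H2 = inH * 2, W2 = inW * 2, C = x.n_slices;
    arma::uvec ri0, ri1, ci0, ci1; fvec rw, cw;
    weights(inH, H2, ri0, ri1, rw);
    weights(inW, W2, ci0, ci1, cw);
    fcube out(H2, W2, C);
    fmat tmp(H2, inW);
    for (arma::uword c = 0; c < C; ++c) {
      const fmat& s = x.slice(c);
      for (arma::uword i = 0; i < H2; ++i)
        tmp.row(i) = s.row(ri0(i)) * (1.0f - rw(i)) + s.row(ri1(i)) * rw(i);
      fmat& o = out.slice(c);
      for (arma::uword j = 0; j < W2; ++j)
        o.col(j) = tmp.col(ci0(j)) * (1.0f - cw(j)) + tmp.col(ci1(j)) * cw(j);
    }
    return out;
  }
  fcube backward(const fcube& dout) {
    const arma::uword H2 = dout.n_rows, W2 = dout.n_cols, C = dout.n_slices;
    arma::uvec ri0, ri1, ci0, ci1; fvec rw, cw;
    weights(inH, H2, ri0, ri1, rw);
    weights(inW, W2, ci0, ci1, cw);
    fcube dx(inH, inW, C, arma::fill::zeros);
    fmat tmp(H2, inW);
    for (arma::uword c = 0; c < C; ++c) {
      tmp.zeros();
      const fmat& d = dout.slice(c);
      for (arma::uword j = 0; j < W2; ++j) {
        tmp.col(ci0(j)) += d.col(j) * (1.0f - cw(j));
        tmp.col(ci1(j)) += d.col(j) * cw(j);
      }
      fmat& g = dx.slice(c);
      for (arma::uword i = 0; i < H2; ++i) {
        g.row(ri0(i)) += tmp.row(i) * (1.0f - rw(i));
        g.row(ri1(i)) += tmp.row(i) * rw(i);
      }
    }
    return dx;
  }
};

// ---------------------------------------------------------------------------
// Network

struct UNet {
  arma::uword depth, in_ch, out_ch;
  std::vector<arma::uword> enc_ch;
  std::vector<ConvBlock> enc, dec;
  std::vector<MaxPool> pools;
  std::vector<Conv> ups;           // 1x1 channel-reduction convs
  std::vector<Upsample2> lerps;
  Conv head;
  std::vector<Param*> params;
  long step_count = 0;
  double accum_n = 0;              // samples accumulated since last update

  // caches for backward
  std::vector<fcube> enc_out;
  std::vector<arma::uword> skip_ch;

  UNet(const std::vector<arma::uword>& channels, arma::uword in_ch_,
       arma::uword out_ch_, unsigned int seed)
    : depth(channels.size()), in_ch(in_ch_), out_ch(out_ch_), enc_ch(channels) {
    std::mt19937 rng(seed);
    enc.resize(depth); dec.resize(depth - 1);
    pools.resize(depth - 1); ups.resize(depth - 1); lerps.resize(depth - 1);
    arma::uword cin = in_ch;
    for (arma::uword l = 0; l < depth; ++l) {
      enc[l].init(cin, enc_ch[l], rng);
      cin = enc_ch[l];
    }
    const arma::uword dch = enc_ch.back();   // decoder runs at constant width
    for (arma::uword l = 0; l < depth - 1; ++l) {
      ups[l].init(1, dch, dch, rng);
      // decoder level l receives dch (upsampled) + enc_ch[depth-2-l] (skip)
      dec[l].init(dch + enc_ch[depth - 2 - l], dch, rng);
    }
    head.init(1, dch, out_ch, rng);
    for (auto& b : enc) b.collect(params);
    for (auto& u : ups) { params.push_back(&u.W); params.push_back(&u.b); }
    for (auto& b : dec) b.collect(params);
    params.push_back(&head.W); params.push_back(&head.b);
  }

  fcube forward(const fcube& x, bool train) {
    enc_out.assign(depth, fcube());
    fcube h = x;
    for (arma::uword l = 0; l < depth; ++l) {
      h = enc[l].forward(h, train);
      if (l < depth - 1) {
        enc_out[l] = h;          // skip connection
        h = pools[l].forward(h, train);
      }
    }
    for (arma::uword l = 0; l < depth - 1; ++l) {
      fcube u = lerps[l].forward(ups[l].forward(h, train), train);
      const fcube& skip = enc_out[depth - 2 - l];
      fcube cat = arma::join_slices(u, skip);
      if (!train) enc_out[depth - 2 - l].reset();
      h = dec[l].forward(cat, train);
    }
    fcube logits = head.forward(h, train);
    if (!train) enc_out.clear();
    return logits;
  }

  void backward(const fcube& dlogits) {
    fcube d = head.backward(dlogits);
    for (arma::uword l = depth - 1; l-- > 0;) {   // decoder depth-2 .. 0
      fcube dcat = dec[l].backward(d);
      const arma::uword dch = enc_ch.back();
      fcube du = dcat.slices(0, dch - 1);
      fcube dskip = dcat.slices(dch, dcat.n_slices - 1);
      d = ups[l].backward(lerps[l].backward(du));
      skip_grads[depth - 2 - l] = std::move(dskip);
    }
    // walk encoder backwards
    for (arma::uword l = depth; l-- > 0;) {
      if (l < depth - 1) {
        fcube dp = pools[l].backward(d);
        dp += skip_grads[l];
        skip_grads[l].reset();
        d = enc[l].backward(dp);
      } else {
        d = enc[l].backward(d);
      }
    }
    enc_out.clear();
  }

  std::vector<fcube> skip_grads = std::vector<fcube>(16);

  // returns loss; accumulates gradients
  double accumulate(const fcube& x, const fcube& y) {
    fcube logits = forward(x, true);
    const double n = (double)logits.n_elem;
    // stable BCE-with-logits and its gradient
    double loss = 0.0;
    fcube dlog(logits.n_rows, logits.n_cols, logits.n_slices);
    const float* zp = logits.memptr();
    const float* yp = y.memptr();
    float* dp = dlog.memptr();
    for (arma::uword i = 0; i < logits.n_elem; ++i) {
      double z = zp[i], t = yp[i];
      double m = z > 0 ? z : 0.0;
      loss += m - z * t + std::log1p(std::exp(-std::fabs(z)));
      double s = 1.0 / (1.0 + std::exp(-z));
      dp[i] = (float)((s - t) / n);
    }
    loss /= n;
    backward(dlog);
    accum_n += 1.0;
    return loss;
  }

  // AdamW update with global-norm clipping; returns pre/post-clip grad norms
  std::pair<double, double> apply_update(double lr, double wd, double clip) {
    if (accum_n <= 0) return {0.0, 0.0};
    double sq = 0.0;
    for (auto* p : params) {
      p->g /= (float)accum_n;
      sq += arma::accu(arma::conv_to<arma::mat>::from(p->g % p->g));
    }
    double norm = std::sqrt(sq), used = norm;
    if (clip > 0 && norm > clip) {
      float sc = (float)(clip / norm);
      for (auto* p : params) p->g *= sc;
      used = clip;
    }
    ++step_count;
    const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
    const float bc1 = (float)(1.0 - std::pow(b1, (double)step_count));
    const float bc2 = (float)(1.0 - std::pow(b2, (double)step_count));
    for (auto* p : params) {
      p->m = 0.9f * p->m + 0.1f * p->g;
      p->v = 0.999f * p->v + 0.001f * (p->g % p->g);
      fmat mhat = p->m / bc1;
      fmat vhat = p->v / bc2;
      p->w -= (float)lr * (mhat / (arma::sqrt(vhat) + (float)eps) +
                           (float)wd * p->w);
      p->g.zeros();
    }
    accum_n = 0;
    return {norm, used};
  }
};

// ---------------------------------------------------------------------------
// R interface

static fcube rmat_to_cube(const Rcpp::NumericMatrix& img) {
  fcube x(img.nrow(), img.ncol(), 1);
  std::copy(img.begin(), img.end(), x.slice(0).memptr());
  return x;
}

static fcube rarray_to_cube(const Rcpp::NumericVector& arr) {
  Rcpp::IntegerVector dim = arr.attr("dim");
  fcube x(dim[0], dim[1], dim[2]);
  std::copy(arr.begin(), arr.end(), x.memptr());
  return x;
}

static Rcpp::NumericVector cube_to_rarray(const fcube& x) {
  Rcpp::NumericVector out(x.n_elem);
  std::copy(x.memptr(), x.memptr() + x.n_elem, out.begin());
  out.attr("dim") = Rcpp::IntegerVector::create(x.n_rows, x.n_cols, x.n_slices);
  return out;
}

// [[Rcpp::export]]
SEXP unet_create(Rcpp::IntegerVector enc_channels, int in_channels,
                 int out_channels, int seed) {
  std::vector<arma::uword> ch(enc_channels.begin(), enc_channels.end());
#ifdef __GLIBC__
  // keep large transient buffers on the heap so repeated training steps
  // reuse pages instead of faulting fresh mmap regions every step
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
#endif
  Rcpp::XPtr<UNet> ptr(new UNet(ch, in_channels, out_channels,
                                (unsigned int)seed), true);
  return ptr;
}

// [[Rcpp::export]]
double unet_num_params(SEXP xp) {
  Rcpp::XPtr<UNet> net(xp);
  double n = 0;
  for (auto* p : net->params) n += (double)p->w.n_elem;
  return n;
}

// [[Rcpp::export]]
Rcpp::NumericVector unet_forward_logits(SEXP xp, Rcpp::NumericMatrix img) {
  Rcpp::XPtr<UNet> net(xp);
  fcube x = rmat_to_cube(img);
  fcube logits = net->forward(x, false);
  return cube_to_rarray(logits);
}

// [[Rcpp::export]]
double unet_accumulate(SEXP xp, Rcpp::NumericMatrix img,
                       Rcpp::NumericVector target) {
  Rcpp::XPtr<UNet> net(xp);
  fcube x = rmat_to_cube(img);
  fcube y = rarray_to_cube(target);
  return net->accumulate(x, y);
}

// [[Rcpp::export]]
Rcpp::List unet_apply_update(SEXP xp, double lr, double wd, double clip) {
  Rcpp::XPtr<UNet> net(xp);
  auto ns = net->apply_update(lr, wd, clip);
  return Rcpp::List::create(Rcpp::Named("grad_norm") = ns.first,
                            Rcpp::Named("grad_norm_clipped") = ns.second);
}

// [[Rcpp::export]]
Rcpp::List unet_get_grads(SEXP xp) {
  Rcpp::XPtr<UNet> net(xp);
  Rcpp::List ps(net->params.size());
  for (size_t i = 0; i < net->params.size(); ++i) {
    const fmat& g = net->params[i]->g;
    Rcpp::NumericMatrix m(g.n_rows, g.n_cols);
    std::copy(g.memptr(), g.memptr() + g.n_elem, m.begin());
    ps[i] = m;
  }
  return ps;
}

// [[Rcpp::export]]
Rcpp::List unet_get_state(SEXP xp) {
  Rcpp::XPtr<UNet> net(xp);
  Rcpp::List ps(net->params.size());
  for (size_t i = 0; i < net->params.size(); ++i) {
    const fmat& w = net->params[i]->w;
    Rcpp::NumericMatrix m(w.n_rows, w.n_cols);
    std::copy(w.memptr(), w.memptr() + w.n_elem, m.begin());
    ps[i] = m;
  }
  // BatchNorm running statistics, encoder blocks then decoder blocks
  std::vector<BatchNorm*> bns;
  for (auto& b : net->enc) { bns.push_back(&b.b1); bns.push_back(&b.b2); }
  for (auto& b : net->dec) { bns.push_back(&b.b1); bns.push_back(&b.b2); }
  Rcpp::List rs(bns.size());
  for (size_t i = 0; i < bns.size(); ++i) {
    Rcpp::NumericMatrix m(bns[i]->C, 2);
    for (arma::uword c = 0; c < bns[i]->C; ++c) {
      m(c, 0) = bns[i]->run_mean(c);
      m(c, 1) = bns[i]->run_var(c);
    }
    rs[i] = m;
  }
  return Rcpp::List::create(Rcpp::Named("params") = ps,
                            Rcpp::Named("bn_running") = rs,
                            Rcpp::Named("step_count") = (double)net->step_count);
}

// [[Rcpp::export]]
void unet_set_state(SEXP xp, Rcpp::List state) {
  Rcpp::XPtr<UNet> net(xp);
  Rcpp::List ps = state["params"];
  if ((size_t)ps.size() != net->params.size())
    Rcpp::stop("parameter list does not match this architecture");
  for (size_t i = 0; i < net->params.size(); ++i) {
    Rcpp::NumericMatrix m = ps[i];
    fmat& w = net->params[i]->w;
    if ((arma::uword)m.nrow() != w.n_rows || (arma::uword)m.ncol() != w.n_cols)
      Rcpp::stop("parameter %d has wrong shape", (int)i);
    std::copy(m.begin(), m.end(), w.memptr());
  }
  Rcpp::List rs = state["bn_running"];
  std::vector<BatchNorm*> bns;
  for (auto& b : net->enc) { bns.push_back(&b.b1); bns.push_back(&b.b2); }
  for (auto& b : net->dec) { bns.push_back(&b.b1); bns.push_back(&b.b2); }
  for (size_t i = 0; i < bns.size(); ++i) {
    Rcpp::NumericMatrix m = rs[i];
    for (arma::uword c = 0; c < bns[i]->C; ++c) {
      bns[i]->run_mean(c) = (float)m(c, 0);
      bns[i]->run_var(c) = (float)m(c, 1);
    }
  }
  net->step_count = (long)Rcpp::as<double>(state["step_count"]);
}
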