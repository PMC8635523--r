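// Minimal convolutional-network training backend.
//
// Layers: conv (valid/same, arbitrary stride, ReLU), max-pool, flatten,
// dense (ReLU on hidden, softmax handled at the loss). Activations are kept
// as single-precision (channels x batch*pixels) matrices; convolution is
// batched im2col + one BLAS GEMM per layer per mini-batch, which keeps the
// arithmetic in large matrix products. Optimizer: mini-batch SGD with
// classical momentum on the multi-class cross-entropy. Single-threaded and
// deterministic for a fixed seed.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

enum LayerKind { CONV = 0, POOL = 1, FLATTEN = 2, DENSE = 3 };

struct LayerDef {
  int kind = 0;
  int filters = 0, kh = 0, kw = 0, sh = 1, sw = 1;
  bool same = false;   // padding
  int units = 0;
  bool relu = true;    // false on the final (softmax) dense layer
};

struct Shape { int h = 1, w = 1, c = 1; int pix() const { return h * w; } };

static std::vector<LayerDef> parse_layers(const Rcpp::List& layers) {
  std::vector<LayerDef> defs;
  for (int i = 0; i < layers.size(); ++i) {
    Rcpp::List L(layers[i]);
    std::string kind = Rcpp::as<std::string>(L["kind"]);
    LayerDef d;
    if (kind == "conv" || kind == "maxpool") {
      Rcpp::IntegerVector k(L["kernel"]), s(L["stride"]);
      d.kh = k[0]; d.kw = k[1]; d.sh = s[0]; d.sw = s[1];
      if (d.kh < 1 || d.kw < 1 || d.sh < 1 || d.sw < 1)
        Rcpp::stop("layer %d: kernel and stride must be positive", i + 1);
      d.same = Rcpp::as<std::string>(L["padding"]) == "same";
      if (kind == "conv") {
        d.kind = CONV;
        d.filters = Rcpp::as<int>(L["filters"]);
        if (d.filters < 1) Rcpp::stop("layer %d: filters must be positive", i + 1);
      } else {
        d.kind = POOL;
      }
    } else if (kind == "flatten") {
      d.kind = FLATTEN;
    } else if (kind == "dense") {
      d.kind = DENSE;
      d.units = Rcpp::as<int>(L["units"]);
      if (d.units < 1) Rcpp::stop("layer %d: units must be positive", i + 1);
      d.relu = Rcpp::as<std::string>(L["activation"]) != "softmax";
    } else {
      Rcpp::stop("unknown layer kind '%s'", kind.c_str());
    }
    defs.push_back(d);
  }
  return defs;
}

// output spatial size and padding of a conv/pool layer
static void conv_geom(const LayerDef& d, int h, int w,
                      int& oh, int& ow, int& pt, int& pl) {
  if (d.same) {
    oh = (h + d.sh - 1) / d.sh;
    ow = (w + d.sw - 1) / d.sw;
    int ph = std::max((oh - 1) * d.sh + d.kh - h, 0);
    int pw = std::max((ow - 1) * d.sw + d.kw - w, 0);
    pt = ph / 2; pl = pw / 2;
  } else {
    oh = (h - d.kh) / d.sh + 1;
    ow = (w - d.kw) / d.sw + 1;
    pt = 0; pl = 0;
  }
}

static std::vector<Shape> infer_shapes(const std::vector<LayerDef>& defs,
                                       int h0, int w0, int c0) {
  std::vector<Shape> io(defs.size() + 1);
  io[0] = {h0, w0, c0};
  for (size_t l = 0; l < defs.size(); ++l) {
    const LayerDef& d = defs[l];
    Shape in = io[l], out;
    if (d.kind == CONV || d.kind == POOL) {
      int oh, ow, pt, pl;
      if (!d.same && (in.h < d.kh || in.w < d.kw))
        Rcpp::stop("layer %d: kernel (%dx%d) exceeds its input (%dx%d)",
                   (int)l + 1, d.kh, d.kw, in.h, in.w);
      conv_geom(d, in.h, in.w, oh, ow, pt, pl);
      if (oh < 1 || ow < 1)
        Rcpp::stop("layer %d produces a non-positive spatial dimension", (int)l + 1);
      out = {oh, ow, d.kind == CONV ? d.filters : in.c};
    } else if (d.kind == FLATTEN) {
      out = {1, 1, in.h * in.w * in.c};
    } else {  // DENSE
      if (in.h != 1 || in.w != 1)
        Rcpp::stop("layer %d: dense layer requires flattened input", (int)l + 1);
      out = {1, 1, d.units};
    }
    io[l + 1] = out;
  }
  return io;
}

// valid output-row range [lo, hi) for which ii = oi*sh - pt + ki is in [0, h)
static inline void oi_range(int sh, int pt, int ki, int h, int oh,
                            int& lo, int& hi) {
  lo = 0;
  if (pt > ki) lo = (pt - ki + sh - 1) / sh;
  hi = oh;
  int max_num = h - 1 + pt - ki;          // oi*sh <= max_num
  if (max_num < 0) { hi = lo; return; }
  hi = std::min(oh, max_num / sh + 1);
}

// im2col for one image into columns [q0, q0 + oh*ow) of col.
// a: (c x h*w) image; col has c*kh*kw rows, row r = ch + c*(ki + kh*kj).
static void im2col_into(const float* a, const Shape& in, const LayerDef& d,
                        int oh, int ow, int pt, int pl, fmat& col,
                        uword q0) {
  const int c = in.c, h = in.h, w = in.w;
  const uword crows = col.n_rows;
  for (int kj = 0; kj < d.kw; ++kj) {
    for (int ki = 0; ki < d.kh; ++ki) {
      const int rbase = c * (ki + d.kh * kj);
      int lo, hi;
      oi_range(d.sh, pt, ki, h, oh, lo, hi);
      for (int oj = 0; oj < ow; ++oj) {
        const int jj = oj * d.sw - pl + kj;
        if (jj < 0 || jj >= w) continue;
        const int ii0 = lo * d.sh - pt + ki;
        const float* src = a + (size_t)c * (ii0 + (size_t)h * jj);
        float* dst = col.memptr() + (size_t)crows * (q0 + lo + (size_t)oh * oj)
                     + rbase;
        if (c <= 64) {  // scalar copy beats memcpy call overhead for small c
          for (int oi = lo; oi < hi; ++oi) {
            for (int ch = 0; ch < c; ++ch) dst[ch] = src[ch];
            src += (size_t)c * d.sh;
            dst += crows;
          }
        } else {
          for (int oi = lo; oi < hi; ++oi) {
            std::memcpy(dst, src, c * sizeof(float));
            src += (size_t)c * d.sh;
            dst += crows;
          }
        }
      }
    }
  }
}

// scatter-add the column gradient of one image back onto the input gradient
static void col2im_add(const fmat& dcol, uword q0, const Shape& in,
                       const LayerDef& d, int oh, int ow, int pt, int pl,
                       float* da) {
  const int c = in.c, h = in.h, w = in.w;
  const uword crows = dcol.n_rows;
  for (int kj = 0; kj < d.kw; ++kj) {
    for (int ki = 0; ki < d.kh; ++ki) {
      const int rbase = c * (ki + d.kh * kj);
      int lo, hi;
      oi_range(d.sh, pt, ki, h, oh, lo, hi);
      for (int oj = 0; oj < ow; ++oj) {
        const int jj = oj * d.sw - pl + kj;
        if (jj < 0 || jj >= w) continue;
        const int ii0 = lo * d.sh - pt + ki;
        float* dst = da + (size_t)c * (ii0 + (size_t)h * jj);
        const float* src = dcol.memptr()
                           + (size_t)crows * (q0 + lo + (size_t)oh * oj) + rbase;
        for (int oi = lo; oi < hi; ++oi) {
          for (int ch = 0; ch < c; ++ch) dst[ch] += src[ch];
          dst += (size_t)c * d.sh;
          src += crows;
        }
      }
    }
  }
}

struct Cache {
  std::vector<fmat> act;            // act[l] = batched input of layer l
  std::vector<fmat> col;            // per conv layer (batched)
  std::vector<Mat<uword>> arg;      // per pool layer: argmax source column
};

struct Net {
  std::vector<LayerDef> defs;
  std::vector<Shape> io;
  std::vector<fmat> W;
  std::vector<fvec> b;

  void init(std::mt19937& gen) {
    W.assign(defs.size(), fmat());
    b.assign(defs.size(), fvec());
    std::normal_distribution<double> nd(0.0, 1.0);
    for (size_t l = 0; l < defs.size(); ++l) {
      const LayerDef& d = defs[l];
      int fan_in = d.kind == CONV ? io[l].c * d.kh * d.kw
                 : d.kind == DENSE ? io[l].c : 0;
      if (!fan_in) continue;
      int rows = d.kind == CONV ? d.filters : d.units;
      W[l].set_size(rows, fan_in);
      double sd = std::sqrt(2.0 / fan_in);
      for (uword i = 0; i < W[l].n_elem; ++i) W[l](i) = (float)(sd * nd(gen));
      b[l].zeros(rows);
    }
  }

  // batched forward of bn images; a0 is (c0 x bn*pix0), image-major blocks.
  // Returns logits (n_classes x bn).
  fmat forward(fmat a0, int bn, Cache* cache) const {
    fmat a = std::move(a0);
    if (cache) {
      cache->act.assign(defs.size() + 1, fmat());
      cache->col.assign(defs.size(), fmat());
      cache->arg.assign(defs.size(), Mat<uword>());
      cache->act[0] = a;
    }
    for (size_t l = 0; l < defs.size(); ++l) {
      const LayerDef& d = defs[l];
      const Shape& in = io[l];
      if (d.kind == CONV) {
        int oh, ow, pt, pl;
        conv_geom(d, in.h, in.w, oh, ow, pt, pl);
        const uword opix = (uword)oh * ow;
        fmat col(W[l].n_cols, opix * bn, fill::zeros);
        for (int bimg = 0; bimg < bn; ++bimg) {
          im2col_into(a.memptr() + (size_t)in.c * in.pix() * bimg, in, d,
                      oh, ow, pt, pl, col, opix * bimg);
        }
        fmat z = W[l] * col;
        z.each_col() += b[l];
        if (d.relu) z.transform([](float v) { return v > 0.f ? v : 0.f; });
        if (cache) cache->col[l] = std::move(col);
        a = std::move(z);
      } else if (d.kind == POOL) {
        int oh, ow, pt, pl;
        conv_geom(d, in.h, in.w, oh, ow, pt, pl);
        const uword opix = (uword)oh * ow;
        fmat out(in.c, opix * bn);
        Mat<uword> arg(in.c, opix * bn);
        for (int bimg = 0; bimg < bn; ++bimg) {
          const uword in_off = (uword)in.pix() * bimg;
          for (int oj = 0; oj < ow; ++oj) {
            for (int oi = 0; oi < oh; ++oi) {
              const uword q = opix * bimg + oi + (uword)oh * oj;
              for (int ch = 0; ch < in.c; ++ch) {
                float best = -std::numeric_limits<float>::infinity();
                uword bidx = 0;
                for (int kj = 0; kj < d.kw; ++kj) {
                  const int jj = oj * d.sw - pl + kj;
                  if (jj < 0 || jj >= in.w) continue;
                  for (int ki = 0; ki < d.kh; ++ki) {
                    const int ii = oi * d.sh - pt + ki;
                    if (ii < 0 || ii >= in.h) continue;
                    const uword src = in_off + ii + (uword)in.h * jj;
                    float v = a(ch, src);
                    if (v > best) { best = v; bidx = src; }
                  }
                }
                out(ch, q) = best;
                arg(ch, q) = bidx;
              }
            }
          }
        }
        if (cache) cache->arg[l] = std::move(arg);
        a = std::move(out);
      } else if (d.kind == FLATTEN) {
        a.reshape(a.n_elem / bn, bn);   // image blocks are contiguous
      } else {  // DENSE
        fmat z = W[l] * a;
        z.each_col() += b[l];
        if (d.relu) z.transform([](float v) { return v > 0.f ? v : 0.f; });
        a = std::move(z);
      }
      if (cache) cache->act[l + 1] = a;
    }
    return a;
  }

  // batched backward from the softmax gradient; accumulates into gW/gb
  void backward(const Cache& cache, fmat d, int bn,
                std::vector<fmat>& gW, std::vector<fvec>& gb) const {
    for (int l = (int)defs.size() - 1; l >= 0; --l) {
      const LayerDef& def = defs[l];
      const Shape& in = io[l];
      if (def.kind == CONV || def.kind == DENSE) {
        if (def.relu) {
          const fmat& out = cache.act[l + 1];
          for (uword i = 0; i < d.n_elem; ++i) if (out(i) <= 0.f) d(i) = 0.f;
        }
        if (def.kind == DENSE) {
          gW[l] = d * cache.act[l].t();
          gb[l] = sum(d, 1);
          if (l > 0) d = W[l].t() * d;  // no input gradient needed at layer 0
        } else {
          int oh, ow, pt, pl;
          conv_geom(def, in.h, in.w, oh, ow, pt, pl);
          const uword opix = (uword)oh * ow;
          gW[l] = d * cache.col[l].t();
          gb[l] = sum(d, 1);
          if (l > 0) {
            fmat dcol = W[l].t() * d;
            fmat da(in.c, (uword)in.pix() * bn, fill::zeros);
            for (int bimg = 0; bimg < bn; ++bimg) {
              col2im_add(dcol, opix * bimg, in, def, oh, ow, pt, pl,
                         da.memptr() + (size_t)in.c * in.pix() * bimg);
            }
            d = std::move(da);
          }
        }
      } else if (def.kind == POOL) {
        const Mat<uword>& arg = cache.arg[l];
        fmat da(in.c, (uword)in.pix() * bn, fill::zeros);
        for (uword q = 0; q < d.n_cols; ++q)
          for (int ch = 0; ch < in.c; ++ch)
            da(ch, arg(ch, q)) += d(ch, q);
        d = std::move(da);
      } else {  // FLATTEN
        d.reshape(in.c, (uword)in.pix() * bn);
      }
    }
  }
};

// convert an R (h, w, c, N) array into a single-precision (c x N*h*w)
// matrix with contiguous image-major blocks
static fmat to_float_images(const Rcpp::NumericVector& X, int h, int w,
                            int c, int N) {
  fmat a(c, (uword)N * h * w);
  for (int n = 0; n < N; ++n) {
    const double* p = X.begin() + (size_t)n * h * w * c;
    float* base = a.memptr() + (size_t)c * h * w * n;
    for (int k = 0; k < c; ++k)
      for (int j = 0; j < w; ++j)
        for (int i = 0; i < h; ++i)
          base[(size_t)c * (i + (size_t)h * j) + k] =
            (float)p[i + (size_t)h * (j + (size_t)w * k)];
  }
  return a;
}

// gather image blocks [idx] of a pre-converted store into one batch matrix
static fmat gather_batch(const fmat& store, int pix,
                         const std::vector<int>& idx) {
  const int bn = (int)idx.size();
  const int c = store.n_rows;
  fmat a(c, (uword)bn * pix);
  for (int bimg = 0; bimg < bn; ++bimg) {
    std::memcpy(a.memptr() + (size_t)c * pix * bimg,
                store.memptr() + (size_t)c * pix * idx[bimg],
                (size_t)c * pix * sizeof(float));
  }
  return a;
}

static void softmax_cols(fmat& z) {
  for (uword q = 0; q < z.n_cols; ++q) {
    fvec col = z.col(q);
    col -= col.max();
    col = exp(col);
    z.col(q) = col / accu(col);
  }
}

// [[Rcpp::export]]
Rcpp::IntegerMatrix cnn_shapes_cpp(Rcpp::List layers, int h, int w, int c) {
  Net net;
  net.defs = parse_layers(layers);
  net.io = infer_shapes(net.defs, h, w, c);
  std::mt19937 gen(1u);
  net.init(gen);
  // run a real forward pass and verify the declared element counts against
  // the activations the backend actually produced
  Cache cache;
  net.forward(fmat(c, (uword)h * w, fill::ones), 1, &cache);
  Rcpp::IntegerMatrix out(net.defs.size() + 1, 3);
  for (size_t l = 0; l < net.defs.size() + 1; ++l) {
    if ((uword)(net.io[l].c * net.io[l].pix()) != cache.act[l].n_elem)
      Rcpp::stop("shape audit failed at layer %d", (int)l);
    out(l, 0) = net.io[l].h; out(l, 1) = net.io[l].w; out(l, 2) = net.io[l].c;
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cnn_train_cpp(Rcpp::List layers, Rcpp::NumericVector X,
                         Rcpp::IntegerVector y, Rcpp::NumericVector Xval,
                         Rcpp::IntegerVector yval, int n_classes, int epochs,
                         double lr, double momentum, int batch_size,
                         int seed) {
  Rcpp::IntegerVector dim = X.attr("dim");
  const int h = dim[0], w = dim[1], c = dim[2], N = dim[3];
  Rcpp::IntegerVector dimv = Xval.attr("dim");
  const int Nv = dimv[3];

  Net net;
  net.defs = parse_layers(layers);
  net.io = infer_shapes(net.defs, h, w, c);
  if (net.io.back().c != n_classes)
    Rcpp::stop("final layer has %d units but there are %d classes",
               net.io.back().c, n_classes);
  std::mt19937 gen((unsigned)seed);
  net.init(gen);

  std::vector<fmat> vW(net.defs.size());
  std::vector<fvec> vb(net.defs.size());
  std::vector<fmat> gW(net.defs.size());
  std::vector<fvec> gb(net.defs.size());
  for (size_t l = 0; l < net.defs.size(); ++l) {
    if (net.W[l].n_elem) {
      vW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
      vb[l].zeros(net.b[l].n_elem);
      gW[l].zeros(net.W[l].n_rows, net.W[l].n_cols);
      gb[l].zeros(net.b[l].n_elem);
    }
  }

  const fmat Xs = to_float_images(X, h, w, c, N);
  const fmat Xvs = to_float_images(Xval, h, w, c, Nv);
  const int pix = h * w;

  Rcpp::NumericVector tr_acc(epochs), tr_loss(epochs), va_acc(epochs),
      va_loss(epochs);
  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  for (int ep = 0; ep < epochs; ++ep) {
    std::shuffle(order.begin(), order.end(), gen);
    double loss_sum = 0; int correct = 0;
    for (int start = 0; start < N; start += batch_size) {
      const int bn = std::min(batch_size, N - start);
      std::vector<int> idx(order.begin() + start, order.begin() + start + bn);
      Cache cache;
      fmat logits = net.forward(gather_batch(Xs, pix, idx), bn, &cache);
      fmat p = logits;
      softmax_cols(p);
      for (int bimg = 0; bimg < bn; ++bimg) {
        const int truth = y[idx[bimg]];
        loss_sum += -std::log((double)p(truth, bimg) + 1e-12);
        if ((int)index_max(p.col(bimg)) == truth) ++correct;
        p(truth, bimg) -= 1.f;              // softmax cross-entropy gradient
      }
      net.backward(cache, std::move(p), bn, gW, gb);
      // fused classical-momentum step: v <- mu v - (lr/bn) g; w <- w + v
      const float mu = (float)momentum, lrb = (float)(lr / bn);
      for (size_t l = 0; l < net.defs.size(); ++l) {
        if (!net.W[l].n_elem) continue;
        float* v = vW[l].memptr(); float* g = gW[l].memptr();
        float* wp = net.W[l].memptr();
        const uword nw = net.W[l].n_elem;
        for (uword i = 0; i < nw; ++i) {
          v[i] = mu * v[i] - lrb * g[i];
          wp[i] += v[i];
        }
        float* bv = vb[l].memptr(); float* bg = gb[l].memptr();
        float* bp = net.b[l].memptr();
        for (uword i = 0; i < net.b[l].n_elem; ++i) {
          bv[i] = mu * bv[i] - lrb * bg[i];
          bp[i] += bv[i];
        }
      }
    }
    tr_loss[ep] = loss_sum / N;
    tr_acc[ep] = (double)correct / N;
    double vloss = 0; int vcorrect = 0;
    for (int start = 0; start < Nv; start += batch_size) {
      const int bn = std::min(batch_size, Nv - start);
      std::vector<int> idx(bn);
      for (int i = 0; i < bn; ++i) idx[i] = start + i;
      fmat p = net.forward(gather_batch(Xvs, pix, idx), bn, nullptr);
      softmax_cols(p);
      for (int bimg = 0; bimg < bn; ++bimg) {
        vloss += -std::log((double)p(yval[start + bimg], bimg) + 1e-12);
        if ((int)index_max(p.col(bimg)) == yval[start + bimg]) ++vcorrect;
      }
    }
    va_loss[ep] = Nv ? vloss / Nv : NA_REAL;
    va_acc[ep] = Nv ? (double)vcorrect / Nv : NA_REAL;
    if (!std::isfinite(tr_loss[ep]))
      Rcpp::stop("non-finite training loss at epoch %d", ep + 1);
    Rcpp::checkUserInterrupt();
  }

  Rcpp::List weights(net.defs.size());
  for (size_t l = 0; l < net.defs.size(); ++l) {
    if (net.W[l].n_elem) {
      weights[l] = Rcpp::List::create(
          Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(net.W[l])),
          Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(net.b[l])));
    } else {
      weights[l] = R_NilValue;
    }
  }
  return Rcpp::List::create(
      Rcpp::Named("weights") = weights,
      Rcpp::Named("train_accuracy") = tr_acc,
      Rcpp::Named("train_loss") = tr_loss,
      Rcpp::Named("val_accuracy") = va_acc,
      Rcpp::Named("val_loss") = va_loss);
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cnn_predict_cpp(Rcpp::List layers, Rcpp::List weights,
                                    Rcpp::NumericVector X) {
  Rcpp::IntegerVector dim = X.attr("dim");
  const int h = dim[0], w = dim[1], c = dim[2], N = dim[3];
  Net net;
  net.defs = parse_layers(layers);
  net.io = infer_shapes(net.defs, h, w, c);
  net.W.assign(net.defs.size(), fmat());
  net.b.assign(net.defs.size(), fvec());
  for (size_t l = 0; l < net.defs.size(); ++l) {
    if (!Rf_isNull(weights[l])) {
      Rcpp::List wl(weights[l]);
      net.W[l] = conv_to<fmat>::from(Rcpp::as<mat>(wl["W"]));
      net.b[l] = conv_to<fvec>::from(Rcpp::as<vec>(wl["b"]));
    }
  }
  const int K = net.io.back().c;
  const fmat Xs = to_float_images(X, h, w, c, N);
  Rcpp::NumericMatrix out(N, K);
  const int bs = 16;
  for (int start = 0; start < N; start += bs) {
    const int bn = std::min(bs, N - start);
    std::vector<int> idx(bn);
    for (int i = 0; i < bn; ++i) idx[i] = start + i;
    fmat p = net.forward(gather_batch(Xs, h * w, idx), bn, nullptr);
    softmax_cols(p);
    for (int bimg = 0; bimg < bn; ++bimg)
      for (int k = 0; k < K; ++k) out(start + bimg, k) = p(k, bimg);
  }
  return out;
}
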