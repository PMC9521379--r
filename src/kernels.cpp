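// Low-level numeric kernels for the 2D U-Net and for connected-component
// labelling. Arrays are column-major with spatial layout H x W x C, matching
// the R side. Convolutions use im2col + BLAS gemm (via Armadillo); stride is
// always 1 and padding keeps the spatial size ("same" convolution).
//
// The exported primitive kernels (.conv2dForward, ...) operate in double
// precision and exist mainly as building blocks for tests and reference
// computations. The fused network engine (UNetRun below) runs in single
// precision, the standard working precision for CNN training; losses are
// accumulated in double.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Build the im2col matrix: rows index output pixels (h + H*w), columns index
// (kh, kw, ci) as kh + k*kw + k*k*ci. Zero padding of width `pad`.
template <typename eT>
static arma::Mat<eT> im2colT(const arma::Cube<eT>& x, const int k,
                             const int pad) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::Mat<eT> cols(static_cast<size_t>(H) * W,
                     static_cast<size_t>(k) * k * C, arma::fill::zeros);
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const size_t col = kh + k * kw + static_cast<size_t>(k) * k * ci;
        // output pixel (h, w) reads x[h + kh - pad, w + kw - pad, ci]
        const int h0 = std::max(0, pad - kh);      // first valid output row
        const int h1 = std::min(H, H + pad - kh);  // one past the last
        const int w0 = std::max(0, pad - kw);
        const int w1 = std::min(W, W + pad - kw);
        if (h0 >= h1 || w0 >= w1) continue;
        for (int w = w0; w < w1; ++w) {
          const eT* src = x.slice_colptr(ci, w + kw - pad) + (h0 + kh - pad);
          eT* dst = cols.colptr(col) + (static_cast<size_t>(w) * H + h0);
          std::copy(src, src + (h1 - h0), dst);
        }
      }
    }
  }
  return cols;
}

// Scatter-add transpose of im2col.
template <typename eT>
static void col2imT(const arma::Mat<eT>& cols, arma::Cube<eT>& gx, const int k,
                    const int pad) {
  const int H = gx.n_rows, W = gx.n_cols, C = gx.n_slices;
  for (int ci = 0; ci < C; ++ci) {
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const size_t col = kh + k * kw + static_cast<size_t>(k) * k * ci;
        const int h0 = std::max(0, pad - kh);
        const int h1 = std::min(H, H + pad - kh);
        const int w0 = std::max(0, pad - kw);
        const int w1 = std::min(W, W + pad - kw);
        if (h0 >= h1 || w0 >= w1) continue;
        for (int w = w0; w < w1; ++w) {
          const eT* src = cols.colptr(col) + (static_cast<size_t>(w) * H + h0);
          eT* dst = gx.slice_colptr(ci, w + kw - pad) + (h0 + kh - pad);
          for (int h = 0; h < h1 - h0; ++h) dst[h] += src[h];
        }
      }
    }
  }
}

// Transposed convolution, kernel 2x2, stride 2 (spatial size doubles; the
// 2x2 output blocks do not overlap). Weight rows index (a, b, ci) as
// a + 2*b + 4*ci with (a, b) the offset inside the 2x2 output block.
template <typename eT>
static arma::Cube<eT> upconvFwdT(const arma::Cube<eT>& x,
                                 const arma::Mat<eT>& w,
                                 const arma::Col<eT>& b) {
  const int H = x.n_rows, W = x.n_cols, Ci = x.n_slices;
  const int Co = w.n_cols;
  const arma::Mat<eT> xMat(const_cast<eT*>(x.memptr()),
                           static_cast<size_t>(H) * W, Ci, false, true);
  arma::Cube<eT> y(2 * H, 2 * W, Co);
  arma::Mat<eT> wab(Ci, Co);
  for (int bo = 0; bo < 2; ++bo) {
    for (int ao = 0; ao < 2; ++ao) {
      for (int ci = 0; ci < Ci; ++ci) wab.row(ci) = w.row(ao + 2 * bo + 4 * ci);
      arma::Mat<eT> yab = xMat * wab;  // H*W x Co
      yab.each_row() += b.t();
      for (int co = 0; co < Co; ++co) {
        const eT* src = yab.colptr(co);
        for (int ww = 0; ww < W; ++ww) {
          eT* dst = y.slice_colptr(co, 2 * ww + bo);
          for (int hh = 0; hh < H; ++hh)
            dst[2 * hh + ao] = src[static_cast<size_t>(ww) * H + hh];
        }
      }
    }
  }
  return y;
}

template <typename eT>
static arma::Cube<eT> upconvBwdT(const arma::Cube<eT>& x,
                                 const arma::Mat<eT>& w,
                                 const arma::Cube<eT>& gy, arma::Mat<eT>& gw,
                                 arma::Col<eT>& gb) {
  const int H = x.n_rows, W = x.n_cols, Ci = x.n_slices;
  const int Co = w.n_cols;
  const arma::Mat<eT> xMat(const_cast<eT*>(x.memptr()),
                           static_cast<size_t>(H) * W, Ci, false, true);
  arma::Mat<eT> gxMat(static_cast<size_t>(H) * W, Ci, arma::fill::zeros);
  gw.zeros(4 * Ci, Co);
  gb.zeros(Co);
  arma::Mat<eT> gyab(static_cast<size_t>(H) * W, Co);
  arma::Mat<eT> wab(Ci, Co);
  for (int bo = 0; bo < 2; ++bo) {
    for (int ao = 0; ao < 2; ++ao) {
      for (int co = 0; co < Co; ++co) {
        eT* dst = gyab.colptr(co);
        for (int ww = 0; ww < W; ++ww) {
          const eT* src = gy.slice_colptr(co, 2 * ww + bo);
          for (int hh = 0; hh < H; ++hh)
            dst[static_cast<size_t>(ww) * H + hh] = src[2 * hh + ao];
        }
      }
      for (int ci = 0; ci < Ci; ++ci) wab.row(ci) = w.row(ao + 2 * bo + 4 * ci);
      gxMat += gyab * wab.t();
      arma::Mat<eT> gwab = xMat.t() * gyab;  // Ci x Co
      for (int ci = 0; ci < Ci; ++ci) gw.row(ao + 2 * bo + 4 * ci) += gwab.row(ci);
      gb += arma::sum(gyab, 0).t();
    }
  }
  return arma::Cube<eT>(gxMat.memptr(), H, W, Ci);
}

// ---- exported double-precision primitives (test oracles / reference) ------

// [[Rcpp::export(name = ".conv2dForward")]]
arma::cube conv2dForward(const arma::cube& x, const arma::mat& w,
                         const arma::vec& b, const int k, const int pad) {
  arma::mat y = im2colT(x, k, pad) * w;
  y.each_row() += b.t();
  return arma::cube(y.memptr(), x.n_rows, x.n_cols, w.n_cols);
}

// [[Rcpp::export(name = ".conv2dBackward")]]
List conv2dBackward(const arma::cube& x, const arma::mat& w,
                    const arma::cube& gy, const int k, const int pad) {
  const int H = x.n_rows, W = x.n_cols, Ci = x.n_slices;
  const arma::mat gyMat(const_cast<double*>(gy.memptr()),
                        static_cast<size_t>(H) * W, gy.n_slices, false, true);
  arma::mat cols = im2colT(x, k, pad);
  arma::mat gw = cols.t() * gyMat;
  arma::vec gb = arma::sum(gyMat, 0).t();
  arma::mat gxCols = gyMat * w.t();
  arma::cube gx(H, W, Ci, arma::fill::zeros);
  col2imT(gxCols, gx, k, pad);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling, stride 2. Returns the pooled cube and the linear
// (1-based) index of each maximum into the input, for the backward pass.
// [[Rcpp::export(name = ".maxPool2Forward")]]
List maxPool2Forward(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  arma::cube y(Ho, Wo, C);
  IntegerVector idx(static_cast<size_t>(Ho) * Wo * C);
  size_t p = 0;
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h, ++p) {
        double best = -std::numeric_limits<double>::infinity();
        size_t bi = 0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {  // ties resolve to the first element
            const double v = x(2 * h + a, 2 * w + b, c);
            if (v > best) {
              best = v;
              bi = (2 * h + a) + static_cast<size_t>(H) * (2 * w + b) +
                   static_cast<size_t>(H) * W * c;
            }
          }
        y(h, w, c) = best;
        idx[p] = static_cast<int>(bi) + 1;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxPool2Backward")]]
arma::cube maxPool2Backward(const IntegerVector& idx, const arma::cube& gy,
                            const int H, const int W) {
  arma::cube gx(H, W, gy.n_slices, arma::fill::zeros);
  const double* g = gy.memptr();
  double* out = gx.memptr();
  const size_t n = idx.size();
  for (size_t p = 0; p < n; ++p) out[idx[p] - 1] += g[p];
  return gx;
}

// [[Rcpp::export(name = ".upconv2Forward")]]
arma::cube upconv2Forward(const arma::cube& x, const arma::mat& w,
                          const arma::vec& b) {
  return upconvFwdT(x, w, b);
}

// [[Rcpp::export(name = ".upconv2Backward")]]
List upconv2Backward(const arma::cube& x, const arma::mat& w,
                     const arma::cube& gy) {
  arma::mat gw;
  arma::vec gb;
  arma::cube gx = upconvBwdT(x, w, gy, gw, gb);
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// ---------------------------------------------------------------------------
// Fused U-Net engine: the full forward pass, and the full forward+backward
// of the mask-gated cross-entropy training step, run in a single call so no
// intermediate crosses the R/C++ boundary. Layer naming matches the R weight
// list: enc{i}.c1/.c2, bot.c1/.c2, dec{i}.up/.c1/.c2, out. Dropout draws use
// R's RNG (unif_rand), so R-level seeding controls them.

typedef arma::fmat FMat;
typedef arma::fcube FCube;
typedef arma::fvec FVec;

class UNetRun {
 public:
  UNetRun(const List& weights, int depth, double theta, bool drop)
      : depth_(depth), theta_(static_cast<float>(theta)), drop_(drop) {
    CharacterVector nms = weights.names();
    for (int i = 0; i < nms.size(); ++i) {
      const std::string n = as<std::string>(nms[i]);
      if (n.size() > 2 && n.compare(n.size() - 2, 2, ".w") == 0)
        W_[n] = arma::conv_to<FMat>::from(as<arma::mat>(weights[n]));
      else
        B_[n] = arma::conv_to<FVec>::from(as<arma::vec>(weights[n]));
    }
  }

  FCube forward(const FCube& x, bool keepCache) {
    FCube cur = x;
    std::vector<FCube> skips(depth_ - 1);
    for (int i = 1; i <= depth_ - 1; ++i) {
      const std::string nm = "enc" + std::to_string(i);
      cur = conv(nm + ".c1", cur, 3, 1, true, keepCache);
      cur = conv(nm + ".c2", cur, 3, 1, true, keepCache);
      cur = dropout(nm, cur, keepCache);
      skips[i - 1] = cur;
      cur = pool(nm, cur, keepCache);
    }
    cur = conv("bot.c1", cur, 3, 1, true, keepCache);
    cur = conv("bot.c2", cur, 3, 1, true, keepCache);
    for (int i = depth_ - 1; i >= 1; --i) {
      const std::string nm = "dec" + std::to_string(i);
      if (keepCache) ins_[nm + ".up"] = cur;
      FCube up = upconvFwdT(cur, W_[nm + ".up.w"], B_[nm + ".up.b"]);
      up = dropout(nm, up, keepCache);
      const FCube& sk = skips[i - 1];
      FCube cat(up.n_rows, up.n_cols, up.n_slices + sk.n_slices);
      cat.slices(0, up.n_slices - 1) = up;
      cat.slices(up.n_slices, cat.n_slices - 1) = sk;
      cur = conv(nm + ".c1", cat, 3, 1, true, keepCache);
      cur = conv(nm + ".c2", cur, 3, 1, true, keepCache);
    }
    FCube logits = conv("out", cur, 1, 0, false, keepCache);
    return softmax(logits);
  }

  // Backward from the loss gradient w.r.t. the pre-softmax scores;
  // accumulates into gW_/gB_ (so a batch sums its gradients).
  void backward(const FCube& gLogits) {
    FCube g = convBwd("out", gLogits, 1, 0, false);
    std::vector<FCube> skipG(depth_ - 1);
    for (int i = 1; i <= depth_ - 1; ++i) {
      const std::string nm = "dec" + std::to_string(i);
      g = convBwd(nm + ".c2", g, 3, 1, true);
      g = convBwd(nm + ".c1", g, 3, 1, true);
      const size_t cu = W_[nm + ".up.w"].n_cols;  // up-conv output channels
      FCube gUp = g.slices(0, cu - 1);
      skipG[i - 1] = g.slices(cu, g.n_slices - 1);
      gUp = dropoutBwd(nm, gUp);
      FMat gw;
      FVec gb;
      g = upconvBwdT(ins_[nm + ".up"], W_[nm + ".up.w"], gUp, gw, gb);
      accumulate(nm + ".up", gw, gb);
    }
    g = convBwd("bot.c2", g, 3, 1, true);
    g = convBwd("bot.c1", g, 3, 1, true);
    for (int i = depth_ - 1; i >= 1; --i) {
      const std::string nm = "enc" + std::to_string(i);
      g = poolBwd(nm, g);
      g += skipG[i - 1];
      g = dropoutBwd(nm, g);
      g = convBwd(nm + ".c2", g, 3, 1, true);
      g = convBwd(nm + ".c1", g, 3, 1, true, i > 1);
    }
  }

  List gradients() const {
    List out;
    for (std::map<std::string, FMat>::const_iterator it = gW_.begin();
         it != gW_.end(); ++it)
      out[it->first + ".w"] = arma::conv_to<arma::mat>::from(it->second);
    for (std::map<std::string, FVec>::const_iterator it = gB_.begin();
         it != gB_.end(); ++it) {
      arma::vec v = arma::conv_to<arma::vec>::from(it->second);
      out[it->first + ".b"] = NumericVector(v.begin(), v.end());
    }
    return out;
  }

 private:
  static FCube softmax(const FCube& z) {
    FCube p = z;
    const size_t n = z.n_rows * z.n_cols, C = z.n_slices;
    for (size_t px = 0; px < n; ++px) {
      float m = -std::numeric_limits<float>::infinity();
      for (size_t c = 0; c < C; ++c) m = std::max(m, z[px + c * n]);
      float s = 0;
      for (size_t c = 0; c < C; ++c)
        s += (p[px + c * n] = std::exp(z[px + c * n] - m));
      for (size_t c = 0; c < C; ++c) p[px + c * n] /= s;
    }
    return p;
  }

  FCube conv(const std::string& nm, const FCube& x, int k, int pad, bool relu,
             bool keepCache) {
    FMat c = im2colT(x, k, pad);
    FMat y = c * W_[nm + ".w"];
    y.each_row() += B_[nm + ".b"].t();
    FCube out(y.memptr(), x.n_rows, x.n_cols, y.n_cols);
    if (relu) out.transform([](float v) { return v > 0 ? v : 0.0f; });
    if (keepCache) {
      cols_[nm] = std::move(c);
      if (relu) act_[nm] = out;
    }
    return out;
  }

  FCube convBwd(const std::string& nm, FCube gy, int k, int pad, bool relu,
                bool needGx = true) {
    if (relu) {
      const FCube& a = act_[nm];
      for (size_t i = 0; i < gy.n_elem; ++i)
        if (a[i] <= 0) gy[i] = 0;
    }
    const FMat& w = W_[nm + ".w"];
    const FMat gyMat(gy.memptr(), gy.n_rows * gy.n_cols, gy.n_slices, false,
                     true);
    accumulate(nm, cols_[nm].t() * gyMat, arma::sum(gyMat, 0).t());
    if (!needGx) return FCube();  // input layer: no gradient needed upstream
    FMat gxCols = gyMat * w.t();
    const int ci = w.n_rows / (k * k);
    FCube gx(gy.n_rows, gy.n_cols, ci, arma::fill::zeros);
    col2imT(gxCols, gx, k, pad);
    return gx;
  }

  FCube dropout(const std::string& nm, const FCube& x, bool keepCache) {
    if (!drop_ || theta_ <= 0) return x;
    FCube keep(x.n_rows, x.n_cols, x.n_slices);
    for (size_t i = 0; i < keep.n_elem; ++i)
      keep[i] = (unif_rand() >= theta_) ? 1.0f : 0.0f;
    if (keepCache) keep_[nm] = keep;
    return x % keep / (1 - theta_);
  }

  FCube dropoutBwd(const std::string& nm, const FCube& g) {
    std::map<std::string, FCube>::const_iterator it = keep_.find(nm);
    if (it == keep_.end()) return g;
    return g % it->second / (1 - theta_);
  }

  FCube pool(const std::string& nm, const FCube& x, bool keepCache) {
    const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
    const int Ho = H / 2, Wo = W / 2;
    FCube y(Ho, Wo, C);
    arma::uvec idx(static_cast<size_t>(Ho) * Wo * C);
    size_t p = 0;
    const float* xm = x.memptr();
    for (int c = 0; c < C; ++c)
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++p) {
          float best = -std::numeric_limits<float>::infinity();
          size_t bi = 0;
          for (int b = 0; b < 2; ++b)
            for (int a = 0; a < 2; ++a) {
              const size_t at = (2 * h + a) + static_cast<size_t>(H) * (2 * w + b) +
                                static_cast<size_t>(H) * W * c;
              if (xm[at] > best) {
                best = xm[at];
                bi = at;
              }
            }
          y(h, w, c) = best;
          idx[p] = bi;
        }
    if (keepCache) {
      poolIdx_[nm] = std::move(idx);
      poolDim_[nm] = arma::uvec{static_cast<arma::uword>(H),
                                static_cast<arma::uword>(W),
                                static_cast<arma::uword>(C)};
    }
    return y;
  }

  FCube poolBwd(const std::string& nm, const FCube& gy) {
    const arma::uvec& d = poolDim_[nm];
    const arma::uvec& idx = poolIdx_[nm];
    FCube gx(d[0], d[1], d[2], arma::fill::zeros);
    for (size_t p = 0; p < idx.n_elem; ++p) gx[idx[p]] += gy[p];
    return gx;
  }

  void accumulate(const std::string& nm, const FMat& gw, const FVec& gb) {
    std::map<std::string, FMat>::iterator it = gW_.find(nm);
    if (it == gW_.end()) {
      gW_[nm] = gw;
      gB_[nm] = gb;
    } else {
      it->second += gw;
      gB_[nm] += gb;
    }
  }

  int depth_;
  float theta_;
  bool drop_;
  std::map<std::string, FMat> W_, cols_, gW_;
  std::map<std::string, FVec> B_, gB_;
  std::map<std::string, FCube> act_, ins_, keep_;
  std::map<std::string, arma::uvec> poolIdx_, poolDim_;
};

static FCube asFCube(SEXP s) {
  NumericVector v(s);
  IntegerVector d = v.attr("dim");
  FCube out(d[0], d[1], d.size() == 3 ? d[2] : 1);
  std::copy(v.begin(), v.end(), out.memptr());
  return out;
}

// [[Rcpp::export(name = ".unetForwardCpp")]]
arma::cube unetForwardCpp(const List& weights, const int depth,
                          const double theta, const bool dropoutActive,
                          SEXP x) {
  UNetRun run(weights, depth, theta, dropoutActive);
  FCube p = run.forward(asFCube(x), false);
  arma::cube out(p.n_rows, p.n_cols, p.n_slices);
  std::copy(p.begin(), p.end(), out.memptr());
  return out;
}

// One optimizer-step worth of work: forward + masked cross-entropy loss +
// backward for every image in the batch, gradients summed. Loss:
//   L = -(1/N) sum_n (1/denom_n) sum_m Mask * log(p[true class])
// with denom_n = M (all pixels; the default) or the per-image count of
// masked-in pixels. Probabilities are clipped at `eps` before the log.
// [[Rcpp::export(name = ".unetTrainStepCpp")]]
List unetTrainStep(const List& weights, const int depth, const double theta,
                   const bool dropoutActive, const List& images,
                   const List& labels, const List& masks,
                   const std::string& normalizeBy, const double eps) {
  UNetRun run(weights, depth, theta, dropoutActive);
  const int N = images.size();
  double loss = 0;
  for (int n = 0; n < N; ++n) {
    const FCube x = asFCube(images[n]);
    const IntegerMatrix lab = labels[n];
    const IntegerMatrix msk = masks[n];
    FCube p = run.forward(x, true);
    const size_t M = p.n_rows * p.n_cols;
    const size_t C = p.n_slices;
    const double denom =
        (normalizeBy == "masked")
            ? static_cast<double>(std::accumulate(msk.begin(), msk.end(), 0))
            : static_cast<double>(M);
    if (denom == 0) continue;  // fully masked-out image contributes nothing
    FCube gz(p.n_rows, p.n_cols, C);
    const float scale = static_cast<float>(1.0 / (denom * N));
    for (size_t px = 0; px < M; ++px) {
      const float m = static_cast<float>(msk[px]);
      const int y = lab[px];
      for (size_t c = 0; c < C; ++c) {
        const float onehot = (static_cast<int>(c) == y) ? 1.0f : 0.0f;
        gz[px + c * M] = m * (p[px + c * M] - onehot) * scale;
      }
      if (m != 0)
        loss -= std::log(std::max(
                    static_cast<double>(p[px + static_cast<size_t>(y) * M]),
                    eps)) /
                (denom * N);
    }
    run.backward(gz);
  }
  return List::create(_["loss"] = loss, _["grads"] = run.gradients());
}

// Connected-component labelling of a binary matrix, 4- or 8-connectivity,
// flood fill with an explicit stack. Returns 0 for background, 1..n for
// components in first-encounter order (column-major scan).
// [[Rcpp::export(name = ".labelComponents")]]
IntegerMatrix labelComponentsCpp(const IntegerMatrix& mask,
                                 const int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dh8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dw8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) == 0 || lab(h, w) != 0) continue;
      ++next;
      stack.push_back(std::make_pair(h, w));
      lab(h, w) = next;
      while (!stack.empty()) {
        const std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int d = 0; d < nd; ++d) {
          const int hh = p.first + dh8[d], ww = p.second + dw8[d];
          if (hh < 0 || hh >= H || ww < 0 || ww >= W) continue;
          if (mask(hh, ww) != 0 && lab(hh, ww) == 0) {
            lab(hh, ww) = next;
            stack.push_back(std::make_pair(hh, ww));
          }
        }
      }
    }
  }
  return lab;
}
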