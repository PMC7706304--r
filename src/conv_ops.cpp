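// Low-level layer primitives for the FCN-8 network.
// All spatial arrays use R's column-major layout with dim (h, w, channels):
// element (r, c, ch) sits at r + h*(c + w*ch). Convolutions are stride-1
// "same" correlations realised as im2col + BLAS gemm; transposed
// convolutions (learned upsampling) are direct scatter loops, cheap because
// they only ever carry the class channels.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline void get_dim3(const NumericVector& x, int& h, int& w, int& c) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 3) stop("expected a 3-d array (h, w, channels)");
  h = d[0]; w = d[1]; c = d[2];
}

// Persistent grow-only scratch buffers for the im2col workspaces. R runs
// single-threaded, and reusing these avoids repeated multi-megabyte
// malloc/munmap cycles (a measurable cost at training time).
static std::vector<double>& scratch(int which, size_t n) {
  static std::vector<double> bufs[2];
  if (bufs[which].size() < n) bufs[which].resize(n);
  return bufs[which];
}

// Fill `cols` (npix x fan_in) from x with zero padding. Column index is
// ki + kh*(kj + kw*ci), matching the memory order of a weight array with
// dim (kh, kw, cin, cout); row index is the pixel r + h*c. This layout
// makes every fill a contiguous column-segment copy.
static void im2col(const double* x, int h, int w, int cin,
                   int kh, int kw, int pad, arma::mat& cols) {
  const int npix = h * w;
  cols.zeros();
  for (int ci = 0; ci < cin; ++ci) {
    const double* xc = x + static_cast<size_t>(ci) * npix;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        double* col = cols.colptr(ki + kh * (kj + kw * ci));
        const int r0 = std::max(0, pad - ki);
        const int r1 = std::min(h, h + pad - ki);
        if (r1 <= r0) continue;
        for (int c = 0; c < w; ++c) {
          const int sc = c + kj - pad;
          if (sc < 0 || sc >= w) continue;
          std::memcpy(col + static_cast<size_t>(c) * h + r0,
                      xc + static_cast<size_t>(sc) * h + (r0 + ki - pad),
                      static_cast<size_t>(r1 - r0) * sizeof(double));
        }
      }
    }
  }
}

// Scatter-add the column representation back into image layout (adjoint of
// im2col); used for the data gradient of a convolution.
static void col2im(const arma::mat& cols, int h, int w, int cin,
                   int kh, int kw, int pad, double* x) {
  const int npix = h * w;
  std::fill(x, x + static_cast<size_t>(npix) * cin, 0.0);
  for (int ci = 0; ci < cin; ++ci) {
    double* xc = x + static_cast<size_t>(ci) * npix;
    for (int kj = 0; kj < kw; ++kj) {
      for (int ki = 0; ki < kh; ++ki) {
        const double* col = cols.colptr(ki + kh * (kj + kw * ci));
        const int r0 = std::max(0, pad - ki);
        const int r1 = std::min(h, h + pad - ki);
        if (r1 <= r0) continue;
        for (int c = 0; c < w; ++c) {
          const int sc = c + kj - pad;
          if (sc < 0 || sc >= w) continue;
          double* dst = xc + static_cast<size_t>(sc) * h + (r0 + ki - pad);
          const double* src = col + static_cast<size_t>(c) * h + r0;
          for (int r = r0; r < r1; ++r) *dst++ += *src++;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fw")]]
NumericVector conv2d_fw(NumericVector x, NumericVector W, NumericVector b,
                        int pad) {
  int h, w, cin; get_dim3(x, h, w, cin);
  IntegerVector wd = W.attr("dim");
  if (wd.size() != 4) stop("weights must have dim (kh, kw, cin, cout)");
  const int kh = wd[0], kw = wd[1], wcin = wd[2], cout = wd[3];
  if (wcin != cin) stop("conv2d: input has %d channels, weights expect %d", cin, wcin);
  if (b.size() != cout) stop("conv2d: bias length mismatch");

  const int npix = h * w;
  const size_t fan_in = static_cast<size_t>(kh) * kw * cin;
  arma::mat cols(scratch(0, fan_in * npix).data(), npix, fan_in, false, true);
  im2col(x.begin(), h, w, cin, kh, kw, pad, cols);
  const arma::mat Wm(const_cast<double*>(W.begin()), fan_in, cout, false, true);

  NumericVector y(no_init(static_cast<R_xlen_t>(npix) * cout));
  arma::mat ym(y.begin(), npix, cout, false, true);
  ym = cols * Wm;                           // (npix x cout), matches R layout
  for (int co = 0; co < cout; ++co) ym.col(co) += b[co];
  y.attr("dim") = IntegerVector::create(h, w, cout);
  return y;
}

// [[Rcpp::export(name = ".conv2d_bw")]]
List conv2d_bw(NumericVector x, NumericVector W, NumericVector dy, int pad) {
  int h, w, cin; get_dim3(x, h, w, cin);
  IntegerVector wd = W.attr("dim");
  const int kh = wd[0], kw = wd[1], cout = wd[3];
  const int npix = h * w;

  const size_t fan_in = static_cast<size_t>(kh) * kw * cin;
  arma::mat cols(scratch(0, fan_in * npix).data(), npix, fan_in, false, true);
  im2col(x.begin(), h, w, cin, kh, kw, pad, cols);
  const arma::mat dym(const_cast<double*>(dy.begin()), npix, cout, false, true);

  NumericVector dW(no_init(W.size()));
  arma::mat dWm(dW.begin(), fan_in, cout, false, true);
  dWm = cols.t() * dym;
  dW.attr("dim") = wd;

  NumericVector db(cout);
  for (int co = 0; co < cout; ++co) db[co] = arma::accu(dym.col(co));

  const arma::mat Wm(const_cast<double*>(W.begin()), fan_in, cout, false, true);
  arma::mat dcols(scratch(1, fan_in * npix).data(), npix, fan_in, false, true);
  dcols = dym * Wm.t();                     // npix x fan_in
  NumericVector dx(no_init(x.size()));
  col2im(dcols, h, w, cin, kh, kw, pad, dx.begin());
  dx.attr("dim") = IntegerVector::create(h, w, cin);

  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// 2x2 max pooling with stride 2 (floor semantics on odd extents). Returns
// the pooled map and, per output element, the linear index of its argmax in
// the input so the backward pass is a pure scatter.
// [[Rcpp::export(name = ".maxpool2_fw")]]
List maxpool2_fw(NumericVector x) {
  int h, w, c; get_dim3(x, h, w, c);
  const int oh = h / 2, ow = w / 2;
  if (oh < 1 || ow < 1) stop("maxpool: input smaller than pooling window");
  NumericVector y(static_cast<R_xlen_t>(oh) * ow * c);
  IntegerVector idx(y.size());
  const double* px = x.begin();
  for (int ci = 0; ci < c; ++ci) {
    const size_t xoff = static_cast<size_t>(ci) * h * w;
    const size_t yoff = static_cast<size_t>(ci) * oh * ow;
    for (int oc = 0; oc < ow; ++oc) {
      for (int orr = 0; orr < oh; ++orr) {
        const int r = 2 * orr, cc = 2 * oc;
        size_t best = xoff + static_cast<size_t>(cc) * h + r;
        double bv = px[best];
        const size_t cand[3] = { best + 1, best + h, best + h + 1 };
        for (int k = 0; k < 3; ++k) {
          if (px[cand[k]] > bv) { bv = px[cand[k]]; best = cand[k]; }
        }
        y[yoff + static_cast<size_t>(oc) * oh + orr] = bv;
        idx[yoff + static_cast<size_t>(oc) * oh + orr] = static_cast<int>(best);
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, c);
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bw")]]
NumericVector maxpool2_bw(NumericVector dy, IntegerVector idx,
                          int h, int w, int c) {
  NumericVector dx(static_cast<R_xlen_t>(h) * w * c);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  dx.attr("dim") = IntegerVector::create(h, w, c);
  return dx;
}

// Transposed convolution (backward convolution / learned upsampling).
// Output extent: stride*(in-1) + k - 2*pad. Weight dim (kh, kw, cin, cout).
// [[Rcpp::export(name = ".convtr_fw")]]
NumericVector convtr_fw(NumericVector x, NumericVector W, NumericVector b,
                        int stride, int pad) {
  int h, w, cin; get_dim3(x, h, w, cin);
  IntegerVector wd = W.attr("dim");
  const int kh = wd[0], kw = wd[1], wcin = wd[2], cout = wd[3];
  if (wcin != cin) stop("convtr: channel mismatch");
  const int oh = stride * (h - 1) + kh - 2 * pad;
  const int ow = stride * (w - 1) + kw - 2 * pad;
  if (oh < 1 || ow < 1) stop("convtr: degenerate output size");

  NumericVector y(static_cast<R_xlen_t>(oh) * ow * cout);
  double* py = y.begin();
  const double* px = x.begin();
  const double* pw = W.begin();
  for (int co = 0; co < cout; ++co) {
    double* yc = py + static_cast<size_t>(co) * oh * ow;
    for (size_t i = 0; i < static_cast<size_t>(oh) * ow; ++i) yc[i] = b[co];
    for (int ci = 0; ci < cin; ++ci) {
      const double* xc = px + static_cast<size_t>(ci) * h * w;
      const double* wc = pw + (static_cast<size_t>(ci) + static_cast<size_t>(cin) * co) * kh * kw;
      for (int c = 0; c < w; ++c) {
        for (int r = 0; r < h; ++r) {
          const double xv = xc[static_cast<size_t>(c) * h + r];
          if (xv == 0.0) continue;
          const int orb = r * stride - pad, ocb = c * stride - pad;
          for (int kj = 0; kj < kw; ++kj) {
            const int oc = ocb + kj;
            if (oc < 0 || oc >= ow) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int orr = orb + ki;
              if (orr < 0 || orr >= oh) continue;
              yc[static_cast<size_t>(oc) * oh + orr] += xv * wc[ki + kh * kj];
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(oh, ow, cout);
  return y;
}

// [[Rcpp::export(name = ".convtr_bw")]]
List convtr_bw(NumericVector x, NumericVector W, NumericVector dy,
               int stride, int pad) {
  int h, w, cin; get_dim3(x, h, w, cin);
  int oh, ow, cout2; get_dim3(dy, oh, ow, cout2);
  IntegerVector wd = W.attr("dim");
  const int kh = wd[0], kw = wd[1], cout = wd[3];
  if (cout != cout2) stop("convtr_bw: channel mismatch");

  NumericVector dx(x.size()), dW(W.size()), db(cout);
  const double* px = x.begin();
  const double* pw = W.begin();
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  double* pdw = dW.begin();
  for (int co = 0; co < cout; ++co) {
    const double* dyc = pdy + static_cast<size_t>(co) * oh * ow;
    double acc = 0.0;
    for (size_t i = 0; i < static_cast<size_t>(oh) * ow; ++i) acc += dyc[i];
    db[co] = acc;
    for (int ci = 0; ci < cin; ++ci) {
      const double* xc = px + static_cast<size_t>(ci) * h * w;
      double* dxc = pdx + static_cast<size_t>(ci) * h * w;
      const double* wc = pw + (static_cast<size_t>(ci) + static_cast<size_t>(cin) * co) * kh * kw;
      double* dwc = pdw + (static_cast<size_t>(ci) + static_cast<size_t>(cin) * co) * kh * kw;
      for (int c = 0; c < w; ++c) {
        for (int r = 0; r < h; ++r) {
          const double xv = xc[static_cast<size_t>(c) * h + r];
          const int orb = r * stride - pad, ocb = c * stride - pad;
          double g = 0.0;
          for (int kj = 0; kj < kw; ++kj) {
            const int oc = ocb + kj;
            if (oc < 0 || oc >= ow) continue;
            for (int ki = 0; ki < kh; ++ki) {
              const int orr = orb + ki;
              if (orr < 0 || orr >= oh) continue;
              const double dv = dyc[static_cast<size_t>(oc) * oh + orr];
              g += wc[ki + kh * kj] * dv;
              dwc[ki + kh * kj] += xv * dv;
            }
          }
          dxc[static_cast<size_t>(c) * h + r] += g;
        }
      }
    }
  }
  dx.attr("dim") = IntegerVector::create(h, w, cin);
  dW.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".relu_fw")]]
NumericVector relu_fw(NumericVector x) {
  NumericVector y = clone(x);
  for (R_xlen_t i = 0; i < y.size(); ++i) if (y[i] < 0) y[i] = 0;
  return y;
}

// [[Rcpp::export(name = ".relu_bw")]]
NumericVector relu_bw(NumericVector dy, NumericVector x) {
  NumericVector dx = clone(dy);
  for (R_xlen_t i = 0; i < dx.size(); ++i) if (x[i] <= 0) dx[i] = 0;
  return dx;
}

// Channel-wise softmax over the last dim of an (h, w, cl) array.
// [[Rcpp::export(name = ".softmax_channels")]]
NumericVector softmax_channels(NumericVector x) {
  int h, w, cl; get_dim3(x, h, w, cl);
  const size_t npix = static_cast<size_t>(h) * w;
  NumericVector y(x.size());
  const double* px = x.begin();
  double* py = y.begin();
  for (size_t p = 0; p < npix; ++p) {
    double m = px[p];
    for (int k = 1; k < cl; ++k) m = std::max(m, px[p + k * npix]);
    double s = 0.0;
    for (int k = 0; k < cl; ++k) {
      const double e = std::exp(px[p + k * npix] - m);
      py[p + k * npix] = e;
      s += e;
    }
    for (int k = 0; k < cl; ++k) py[p + k * npix] /= s;
  }
  y.attr("dim") = IntegerVector::create(h, w, cl);
  return y;
}
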