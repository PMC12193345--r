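#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Feature maps are numeric arrays with dim (h, w, c), column-major:
// linear index = y + h*x + h*w*ch (0-based). im2col rows follow the same
// convention for output pixels (r = oy + oh*ox), so `cols %*% W` reshapes
// straight back into an (oh, ow, cout) array. im2col columns flatten the
// (k, k, cin) patch with ky fastest, matching an R array dim c(k, k, cin).

static inline int out_size(int n, int k, int s, int p) {
  return (n + 2 * p - k) / s + 1;
}

// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int h, int w, int c,
                         int k, int s, int p) {
  const int oh = out_size(h, k, s, p), ow = out_size(w, k, s, p);
  NumericMatrix cols(oh * ow, k * k * c);
  const double* px = x.begin();
  for (int ci = 0; ci < c; ++ci) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = ky + k * kx + k * k * ci;
        double* pc = &cols(0, col);
        for (int ox = 0; ox < ow; ++ox) {
          const int ix = ox * s - p + kx;
          for (int oy = 0; oy < oh; ++oy) {
            const int iy = oy * s - p + ky;
            double v = 0.0;
            if (iy >= 0 && iy < h && ix >= 0 && ix < w)
              v = px[iy + h * ix + h * w * ci];
            pc[oy + oh * ox] = v;
          }
        }
      }
    }
  }
  return cols;
}

// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int h, int w, int c,
                         int k, int s, int p) {
  const int oh = out_size(h, k, s, p), ow = out_size(w, k, s, p);
  NumericVector dx(h * w * c);
  double* pd = dx.begin();
  for (int ci = 0; ci < c; ++ci) {
    for (int kx = 0; kx < k; ++kx) {
      for (int ky = 0; ky < k; ++ky) {
        const int col = ky + k * kx + k * k * ci;
        const double* pc = &cols(0, col);
        for (int ox = 0; ox < ow; ++ox) {
          const int ix = ox * s - p + kx;
          if (ix < 0 || ix >= w) continue;
          for (int oy = 0; oy < oh; ++oy) {
            const int iy = oy * s - p + ky;
            if (iy < 0 || iy >= h) continue;
            pd[iy + h * ix + h * w * ci] += pc[oy + oh * ox];
          }
        }
      }
    }
  }
  return dx;
}

// Depthwise k x k convolution; W has dim (k, k, c).
// pad_mode 0 = zero padding, 1 = replicate (edge) padding.
// [[Rcpp::export]]
NumericVector dwconv_fwd_cpp(NumericVector x, int h, int w, int c,
                             NumericVector W, int k, int s, int p,
                             int pad_mode) {
  const int oh = out_size(h, k, s, p), ow = out_size(w, k, s, p);
  NumericVector y(oh * ow * c);
  const double* px = x.begin();
  const double* pw = W.begin();
  double* py = y.begin();
  for (int ci = 0; ci < c; ++ci) {
    const double* xc = px + h * w * ci;
    const double* wc = pw + k * k * ci;
    double* yc = py + oh * ow * ci;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        double acc = 0.0;
        for (int kx = 0; kx < k; ++kx) {
          int ix = ox * s - p + kx;
          if (pad_mode == 1) ix = std::min(std::max(ix, 0), w - 1);
          else if (ix < 0 || ix >= w) continue;
          for (int ky = 0; ky < k; ++ky) {
            int iy = oy * s - p + ky;
            if (pad_mode == 1) iy = std::min(std::max(iy, 0), h - 1);
            else if (iy < 0 || iy >= h) continue;
            acc += xc[iy + h * ix] * wc[ky + k * kx];
          }
        }
        yc[oy + oh * ox] = acc;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List dwconv_bwd_cpp(NumericVector dy, NumericVector x, int h, int w, int c,
                    NumericVector W, int k, int s, int p, int pad_mode) {
  const int oh = out_size(h, k, s, p), ow = out_size(w, k, s, p);
  NumericVector dx(h * w * c), dW(k * k * c);
  const double* px = x.begin();
  const double* pw = W.begin();
  const double* pdy = dy.begin();
  for (int ci = 0; ci < c; ++ci) {
    const double* xc = px + h * w * ci;
    const double* wc = pw + k * k * ci;
    const double* dyc = pdy + oh * ow * ci;
    double* dxc = dx.begin() + h * w * ci;
    double* dwc = dW.begin() + k * k * ci;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        const double g = dyc[oy + oh * ox];
        if (g == 0.0) continue;
        for (int kx = 0; kx < k; ++kx) {
          int ix = ox * s - p + kx;
          if (pad_mode == 1) ix = std::min(std::max(ix, 0), w - 1);
          else if (ix < 0 || ix >= w) continue;
          for (int ky = 0; ky < k; ++ky) {
            int iy = oy * s - p + ky;
            if (pad_mode == 1) iy = std::min(std::max(iy, 0), h - 1);
            else if (iy < 0 || iy >= h) continue;
            dxc[iy + h * ix] += g * wc[ky + k * kx];
            dwc[ky + k * kx] += g * xc[iy + h * ix];
          }
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW);
}

// 3x3 stride-1 average pooling, padding 1, divisor counting only valid
// (in-image) cells, so a spatially constant map is reproduced exactly
// at the borders.
// [[Rcpp::export]]
NumericVector avgpool3_valid_fwd_cpp(NumericVector x, int h, int w, int c) {
  NumericVector y(h * w * c);
  const double* px = x.begin();
  double* py = y.begin();
  for (int ci = 0; ci < c; ++ci) {
    const double* xc = px + h * w * ci;
    double* yc = py + h * w * ci;
    for (int ox = 0; ox < w; ++ox) {
      const int x0 = std::max(0, ox - 1), x1 = std::min(w - 1, ox + 1);
      for (int oy = 0; oy < h; ++oy) {
        const int y0 = std::max(0, oy - 1), y1 = std::min(h - 1, oy + 1);
        double acc = 0.0;
        for (int ix = x0; ix <= x1; ++ix)
          for (int iy = y0; iy <= y1; ++iy)
            acc += xc[iy + h * ix];
        yc[oy + h * ox] = acc / ((x1 - x0 + 1) * (y1 - y0 + 1));
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool3_valid_bwd_cpp(NumericVector dy, int h, int w, int c) {
  NumericVector dx(h * w * c);
  const double* pdy = dy.begin();
  double* pdx = dx.begin();
  for (int ci = 0; ci < c; ++ci) {
    const double* dyc = pdy + h * w * ci;
    double* dxc = pdx + h * w * ci;
    for (int ox = 0; ox < w; ++ox) {
      const int x0 = std::max(0, ox - 1), x1 = std::min(w - 1, ox + 1);
      for (int oy = 0; oy < h; ++oy) {
        const int y0 = std::max(0, oy - 1), y1 = std::min(h - 1, oy + 1);
        const double g = dyc[oy + h * ox] / ((x1 - x0 + 1) * (y1 - y0 + 1));
        for (int ix = x0; ix <= x1; ++ix)
          for (int iy = y0; iy <= y1; ++iy)
            dxc[iy + h * ix] += g;
      }
    }
  }
  return dx;
}

// Max pooling (used by SPPF: k = 5, s = 1, p = 2). Padding cells count as
// -Inf. Returns pooled values and 1-based argmax linear indices.
// [[Rcpp::export]]
List maxpool_fwd_cpp(NumericVector x, int h, int w, int c,
                     int k, int s, int p) {
  const int oh = out_size(h, k, s, p), ow = out_size(w, k, s, p);
  NumericVector y(oh * ow * c);
  IntegerVector am(oh * ow * c);
  const double* px = x.begin();
  for (int ci = 0; ci < c; ++ci) {
    const double* xc = px + h * w * ci;
    for (int ox = 0; ox < ow; ++ox) {
      for (int oy = 0; oy < oh; ++oy) {
        double best = R_NegInf;
        int bidx = -1;
        for (int kx = 0; kx < k; ++kx) {
          const int ix = ox * s - p + kx;
          if (ix < 0 || ix >= w) continue;
          for (int ky = 0; ky < k; ++ky) {
            const int iy = oy * s - p + ky;
            if (iy < 0 || iy >= h) continue;
            const double v = xc[iy + h * ix];
            if (v > best) { best = v; bidx = iy + h * ix + h * w * ci; }
          }
        }
        y[oy + oh * ox + oh * ow * ci] = best;
        am[oy + oh * ox + oh * ow * ci] = bidx + 1;
      }
    }
  }
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool_bwd_cpp(NumericVector dy, IntegerVector argmax, int n) {
  NumericVector dx(n);
  for (int i = 0; i < dy.size(); ++i) dx[argmax[i] - 1] += dy[i];
  return dx;
}

// Adaptive average pooling to (oh, ow): window [floor(i*h/oh), ceil((i+1)*h/oh)).
// [[Rcpp::export]]
NumericVector adaptive_avgpool_fwd_cpp(NumericVector x, int h, int w, int c,
                                       int oh, int ow) {
  NumericVector y(oh * ow * c);
  const double* px = x.begin();
  for (int ci = 0; ci < c; ++ci) {
    const double* xc = px + h * w * ci;
    for (int ox = 0; ox < ow; ++ox) {
      const int x0 = (int)std::floor((double)ox * w / ow);
      const int x1 = (int)std::ceil((double)(ox + 1) * w / ow);
      for (int oy = 0; oy < oh; ++oy) {
        const int y0 = (int)std::floor((double)oy * h / oh);
        const int y1 = (int)std::ceil((double)(oy + 1) * h / oh);
        double acc = 0.0;
        for (int ix = x0; ix < x1; ++ix)
          for (int iy = y0; iy < y1; ++iy)
            acc += xc[iy + h * ix];
        y[oy + oh * ox + oh * ow * ci] = acc / ((x1 - x0) * (y1 - y0));
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector adaptive_avgpool_bwd_cpp(NumericVector dy, int h, int w, int c,
                                       int oh, int ow) {
  NumericVector dx(h * w * c);
  const double* pdy = dy.begin();
  for (int ci = 0; ci < c; ++ci) {
    double* dxc = dx.begin() + h * w * ci;
    for (int ox = 0; ox < ow; ++ox) {
      const int x0 = (int)std::floor((double)ox * w / ow);
      const int x1 = (int)std::ceil((double)(ox + 1) * w / ow);
      for (int oy = 0; oy < oh; ++oy) {
        const int y0 = (int)std::floor((double)oy * h / oh);
        const int y1 = (int)std::ceil((double)(oy + 1) * h / oh);
        const double g = pdy[oy + oh * ox + oh * ow * ci] /
          ((x1 - x0) * (y1 - y0));
        for (int ix = x0; ix < x1; ++ix)
          for (int iy = y0; iy < y1; ++iy)
            dxc[iy + h * ix] += g;
      }
    }
  }
  return dx;
}

// Bilinear resize, half-pixel centers (align_corners = FALSE convention).
static inline void lin_coeff(int o, int in, int out, int* i0, int* i1,
                             double* w1) {
  double src = (o + 0.5) * ((double)in / out) - 0.5;
  if (src < 0) src = 0;
  if (src > in - 1) src = in - 1;
  *i0 = (int)std::floor(src);
  *i1 = std::min(*i0 + 1, in - 1);
  *w1 = src - *i0;
}

// [[Rcpp::export]]
NumericVector bilinear_fwd_cpp(NumericVector x, int h, int w, int c,
                               int oh, int ow) {
  NumericVector y(oh * ow * c);
  const double* px = x.begin();
  for (int ox = 0; ox < ow; ++ox) {
    int x0, x1; double wx;
    lin_coeff(ox, w, ow, &x0, &x1, &wx);
    for (int oy = 0; oy < oh; ++oy) {
      int y0, y1; double wy;
      lin_coeff(oy, h, oh, &y0, &y1, &wy);
      for (int ci = 0; ci < c; ++ci) {
        const double* xc = px + h * w * ci;
        const double v =
          (1 - wy) * ((1 - wx) * xc[y0 + h * x0] + wx * xc[y0 + h * x1]) +
          wy * ((1 - wx) * xc[y1 + h * x0] + wx * xc[y1 + h * x1]);
        y[oy + oh * ox + oh * ow * ci] = v;
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector bilinear_bwd_cpp(NumericVector dy, int h, int w, int c,
                               int oh, int ow) {
  NumericVector dx(h * w * c);
  const double* pdy = dy.begin();
  for (int ox = 0; ox < ow; ++ox) {
    int x0, x1; double wx;
    lin_coeff(ox, w, ow, &x0, &x1, &wx);
    for (int oy = 0; oy < oh; ++oy) {
      int y0, y1; double wy;
      lin_coeff(oy, h, oh, &y0, &y1, &wy);
      for (int ci = 0; ci < c; ++ci) {
        double* dxc = dx.begin() + h * w * ci;
        const double g = pdy[oy + oh * ox + oh * ow * ci];
        dxc[y0 + h * x0] += g * (1 - wy) * (1 - wx);
        dxc[y0 + h * x1] += g * (1 - wy) * wx;
        dxc[y1 + h * x0] += g * wy * (1 - wx);
        dxc[y1 + h * x1] += g * wy * wx;
      }
    }
  }
  return dx;
}
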