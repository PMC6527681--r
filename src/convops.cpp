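#include <Rcpp.h>
using namespace Rcpp;

// Lower a (h, w, c, n) activation array into the im2col matrix used for
// convolution-as-matmul. Rows are ordered (ki, kj, channel); columns are
// ordered (output row, output col, image) with the row index fastest,
// matching the prior-lattice ordering used on the R side.
// [[Rcpp::export]]
NumericMatrix im2col_cpp(NumericVector x, int k, int stride, int pad) {
  IntegerVector d = x.attr("dim");
  const int h = d[0], w = d[1], c = d[2], n = d[3];
  const int oh = (h + 2 * pad - k) / stride + 1;
  const int ow = (w + 2 * pad - k) / stride + 1;
  NumericMatrix out(k * k * c, (R_xlen_t)oh * ow * n);
  double* po = out.begin();
  const double* px = x.begin();
  const R_xlen_t rows = (R_xlen_t)k * k * c;
  for (int img = 0; img < n; ++img) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        const R_xlen_t col = i + (R_xlen_t)oh * (j + (R_xlen_t)ow * img);
        double* pcol = po + rows * col;
        const int y0 = i * stride - pad;
        const int x0 = j * stride - pad;
        for (int ch = 0; ch < c; ++ch) {
          const double* pch = px + (R_xlen_t)h * w * (ch + (R_xlen_t)c * img);
          for (int kj = 0; kj < k; ++kj) {
            const int xx = x0 + kj;
            const bool xin = xx >= 0 && xx < w;
            for (int ki = 0; ki < k; ++ki) {
              const int yy = y0 + ki;
              double v = 0.0;
              if (xin && yy >= 0 && yy < h) v = pch[yy + (R_xlen_t)h * xx];
              pcol[ki + k * (kj + k * ch)] = v;
            }
          }
        }
      }
    }
  }
  return out;
}

// Adjoint of im2col_cpp: scatter-add column gradients back onto the input
// raster. Needed for backpropagation through a convolution layer.
// [[Rcpp::export]]
NumericVector col2im_cpp(NumericMatrix cols, int h, int w, int c, int n,
                         int k, int stride, int pad) {
  const int oh = (h + 2 * pad - k) / stride + 1;
  const int ow = (w + 2 * pad - k) / stride + 1;
  NumericVector out((R_xlen_t)h * w * c * n);
  out.attr("dim") = IntegerVector::create(h, w, c, n);
  double* po = out.begin();
  const double* pc = cols.begin();
  const R_xlen_t rows = (R_xlen_t)k * k * c;
  for (int img = 0; img < n; ++img) {
    for (int j = 0; j < ow; ++j) {
      for (int i = 0; i < oh; ++i) {
        const R_xlen_t col = i + (R_xlen_t)oh * (j + (R_xlen_t)ow * img);
        const double* pcol = pc + rows * col;
        const int y0 = i * stride - pad;
        const int x0 = j * stride - pad;
        for (int ch = 0; ch < c; ++ch) {
          double* pch = po + (R_xlen_t)h * w * (ch + (R_xlen_t)c * img);
          for (int kj = 0; kj < k; ++kj) {
            const int xx = x0 + kj;
            if (xx < 0 || xx >= w) continue;
            for (int ki = 0; ki < k; ++ki) {
              const int yy = y0 + ki;
              if (yy < 0 || yy >= h) continue;
              pch[yy + (R_xlen_t)h * xx] += pcol[ki + k * (kj + k * ch)];
            }
          }
        }
      }
    }
  }
  return out;
}

// Bilinear resampling of a grayscale raster (values in [0,1], rows = y).
// Pixel centres map as x_in = (x_out + 0.5) * w/ow - 0.5, clamped at the
// border, which keeps the operation monotone and reproducible.
// [[Rcpp::export]]
NumericMatrix resize_bilinear_cpp(NumericMatrix img, int oh, int ow) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(oh, ow);
  for (int j = 0; j < ow; ++j) {
    double xs = (j + 0.5) * (double)w / ow - 0.5;
    if (xs < 0) xs = 0;
    if (xs > w - 1) xs = w - 1;
    const int x0 = (int)std::floor(xs);
    const int x1 = x0 + 1 < w ? x0 + 1 : x0;
    const double fx = xs - x0;
    for (int i = 0; i < oh; ++i) {
      double ys = (i + 0.5) * (double)h / oh - 0.5;
      if (ys < 0) ys = 0;
      if (ys > h - 1) ys = h - 1;
      const int y0 = (int)std::floor(ys);
      const int y1 = y0 + 1 < h ? y0 + 1 : y0;
      const double fy = ys - y0;
      const double top = img(y0, x0) * (1 - fx) + img(y0, x1) * fx;
      const double bot = img(y1, x0) * (1 - fx) + img(y1, x1) * fx;
      out(i, j) = top * (1 - fy) + bot * fy;
    }
  }
  return out;
}
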