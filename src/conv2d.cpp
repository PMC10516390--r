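// 2D same-padding, stride-1 convolution (cross-correlation) kernels used by
// the reverse-mode tape in R/autograd.R.  Arrays are column-major with
// dimensions (height, width, channels, batch); kernels are
// (kh, kw, in_channels, out_channels) with odd kh, kw.
//
// Forward and backward both go through an explicit im2col buffer so the
// heavy lifting is a single BLAS GEMM per call.  The buffer is filled
// column by column (one column per output pixel) so writes are sequential.

#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// The tape allocates and frees many multi-megabyte arrays per training
// step; keeping glibc from returning those blocks to the kernel (mmap /
// trim churn) makes reuse cheap.  Grow-only scratch buffers below serve
// the same purpose for the im2col workspaces.
static void tune_allocator() {
#ifdef __GLIBC__
  static bool done = false;
  if (!done) {
    mallopt(M_MMAP_MAX, 0);
    mallopt(M_TRIM_THRESHOLD, -1);
    done = true;
  }
#endif
}

static std::vector<double> g_buf_c, g_buf_y, g_buf_d;

static double *scratch(std::vector<double> &buf, size_t need) {
  if (buf.size() < need) buf.resize(need);
  return buf.data();
}

static void get_dims(const NumericVector &x, int d[4]) {
  IntegerVector dd = x.attr("dim");
  if (dd.size() != 4) stop("expected a 4-axis array");
  for (int k = 0; k < 4; ++k) d[k] = dd[k];
}

// Fill column-major im2col matrix C of size (kh*kw*ci) x (H*W*n).
// Row r = di + kh*(dj + kw*c); column = i + H*j + H*W*s.  For one column
// the rows are filled in order, reading kh-long contiguous runs of x.
static void im2col(const double *x, int H, int W, int ci, int n,
                   int kh, int kw, double *dst) {
  const int ph = kh / 2, pw = kw / 2;
  for (int s = 0; s < n; ++s) {
    const double *xs = x + (size_t)H * W * ci * s;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        // one column: rows ordered di (fastest), dj, c
        for (int c = 0; c < ci; ++c) {
          const double *xc = xs + (size_t)H * W * c;
          for (int dj = 0; dj < kw; ++dj) {
            const int jj = j + dj - pw;
            if (jj < 0 || jj >= W) {
              for (int di = 0; di < kh; ++di) *dst++ = 0.0;
            } else {
              const double *col = xc + (size_t)H * jj;
              const int base = i - ph;
              for (int di = 0; di < kh; ++di) {
                const int ii = base + di;
                *dst++ = (ii >= 0 && ii < H) ? col[ii] : 0.0;
              }
            }
          }
        }
      }
    }
  }
}

// Scatter-add transpose of im2col: dx += col2im(dC); reads sequential.
static void col2im(const arma::mat &dC, int H, int W, int ci, int n,
                   int kh, int kw, double *dx) {
  const int ph = kh / 2, pw = kw / 2;
  const double *src = dC.memptr();
  for (int s = 0; s < n; ++s) {
    double *xs = dx + (size_t)H * W * ci * s;
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        for (int c = 0; c < ci; ++c) {
          double *xc = xs + (size_t)H * W * c;
          for (int dj = 0; dj < kw; ++dj) {
            const int jj = j + dj - pw;
            if (jj < 0 || jj >= W) {
              src += kh;
            } else {
              double *col = xc + (size_t)H * jj;
              const int base = i - ph;
              for (int di = 0; di < kh; ++di) {
                const int ii = base + di;
                if (ii >= 0 && ii < H) col[ii] += *src;
                ++src;
              }
            }
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  int dx[4], dw[4];
  get_dims(x, dx);
  get_dims(w, dw);
  const int H = dx[0], W = dx[1], ci = dx[2], n = dx[3];
  const int kh = dw[0], kw = dw[1], co = dw[3];
  if (dw[2] != ci) stop("kernel in-channels (%d) != input channels (%d)", dw[2], ci);
  if (kh % 2 == 0 || kw % 2 == 0) stop("kernel spatial dims must be odd");
  if (b.size() != co) stop("bias length != out channels");
  tune_allocator();

  const arma::uword K = (arma::uword)kh * kw * ci;
  const arma::uword cols = (arma::uword)H * W * n;
  arma::mat C(scratch(g_buf_c, (size_t)K * cols), K, cols, false, true);
  im2col(REAL(x), H, W, ci, n, kh, kw, C.memptr());
  const arma::mat Wm(const_cast<double *>(REAL(w)), K, co, false, true);
  arma::mat Y(scratch(g_buf_y, (size_t)cols * co), cols, co, false, true);
  Y = C.t() * Wm; // (H*W*n) x co

  NumericVector y((size_t)H * W * co * n);
  y.attr("dim") = IntegerVector::create(H, W, co, n);
  double *yp = REAL(y);
  const size_t hw = (size_t)H * W;
  for (int s = 0; s < n; ++s)
    for (int o = 0; o < co; ++o) {
      double *dst = yp + hw * (o + (size_t)co * s);
      const double *src = Y.colptr(o) + hw * s;
      const double bo = b[o];
      for (size_t p = 0; p < hw; ++p) dst[p] = src[p] + bo;
    }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy, bool want_dx) {
  int dx_[4], dw_[4], dd[4];
  get_dims(x, dx_);
  get_dims(w, dw_);
  get_dims(dy, dd);
  const int H = dx_[0], W = dx_[1], ci = dx_[2], n = dx_[3];
  const int kh = dw_[0], kw = dw_[1], co = dw_[3];
  const arma::uword K = (arma::uword)kh * kw * ci;
  const size_t hw = (size_t)H * W;
  const arma::uword cols = (arma::uword)H * W * n;
  tune_allocator();

  // repack dy as (H*W*n) x co
  arma::mat dY(scratch(g_buf_y, (size_t)cols * co), cols, co, false, true);
  const double *dyp = REAL(dy);
  for (int s = 0; s < n; ++s)
    for (int o = 0; o < co; ++o) {
      const double *src = dyp + hw * (o + (size_t)co * s);
      double *dst = dY.colptr(o) + hw * s;
      for (size_t p = 0; p < hw; ++p) dst[p] = src[p];
    }

  arma::mat C(scratch(g_buf_c, (size_t)K * cols), K, cols, false, true);
  im2col(REAL(x), H, W, ci, n, kh, kw, C.memptr());
  const arma::mat Wm(const_cast<double *>(REAL(w)), K, co, false, true);

  arma::mat dWm = C * dY; // K x co

  NumericVector dwv(K * co);
  dwv.attr("dim") = IntegerVector::create(kh, kw, ci, co);
  std::copy(dWm.begin(), dWm.end(), REAL(dwv));

  NumericVector dbv(co);
  for (int o = 0; o < co; ++o) dbv[o] = arma::accu(dY.col(o));

  if (!want_dx) {
    return List::create(_["dx"] = R_NilValue, _["dw"] = dwv, _["db"] = dbv);
  }
  arma::mat dC(scratch(g_buf_d, (size_t)K * cols), K, cols, false, true);
  dC = Wm * dY.t(); // K x (H*W*n)
  NumericVector dxv((size_t)H * W * ci * n);
  dxv.attr("dim") = IntegerVector::create(H, W, ci, n);
  col2im(dC, H, W, ci, n, kh, kw, REAL(dxv));
  return List::create(_["dx"] = dxv, _["dw"] = dwv, _["db"] = dbv);
}
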