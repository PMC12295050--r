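// Batched 3D neural-network primitives used by the pyramid segmentation
// network. Activations are (C x H*W*D*B) matrices, column-major with the
// voxel index nested as h (fastest), w, d, b. 3x3x3 convolutions are
// evaluated as 27 shifted GEMMs (no im2col buffer), which keeps peak memory
// at ~2x the activation size.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct Dims { int H, W, D, B; long V() const { return (long)H * W * D * B; } };

static Dims get_dims(const Rcpp::IntegerVector& d) {
  return Dims{d[0], d[1], d[2], d[3]};
}

// out(:, (h,w,d,b)) = X(:, (h+dh, w+dw, d+dd, b)) with zero outside.
static void shift_copy(const mat& X, mat& out, const Dims& dm,
                       int dh, int dw, int dd) {
  out.zeros();
  const int H = dm.H, W = dm.W, D = dm.D, B = dm.B;
  int h0 = std::max(0, -dh), h1 = std::min(H, H - dh); // dest h range
  if (h1 <= h0) return;
  for (int b = 0; b < B; ++b) {
    for (int d = 0; d < D; ++d) {
      int ds = d + dd; if (ds < 0 || ds >= D) continue;
      for (int w = 0; w < W; ++w) {
        int ws = w + dw; if (ws < 0 || ws >= W) continue;
        long dst = h0 + (long)H * (w + (long)W * (d + (long)D * b));
        long src = (h0 + dh) + (long)H * (ws + (long)W * (ds + (long)D * b));
        out.cols(dst, dst + (h1 - h0) - 1) = X.cols(src, src + (h1 - h0) - 1);
      }
    }
  }
}

// Scatter-add the reverse shift: dX(:, src) += T(:, dst).
static void shift_add(mat& dX, const mat& T, const Dims& dm,
                      int dh, int dw, int dd) {
  const int H = dm.H, W = dm.W, D = dm.D, B = dm.B;
  int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
  if (h1 <= h0) return;
  for (int b = 0; b < B; ++b) {
    for (int d = 0; d < D; ++d) {
      int ds = d + dd; if (ds < 0 || ds >= D) continue;
      for (int w = 0; w < W; ++w) {
        int ws = w + dw; if (ws < 0 || ws >= W) continue;
        long dst = h0 + (long)H * (w + (long)W * (d + (long)D * b));
        long src = (h0 + dh) + (long)H * (ws + (long)W * (ds + (long)D * b));
        dX.cols(src, src + (h1 - h0) - 1) += T.cols(dst, dst + (h1 - h0) - 1);
      }
    }
  }
}

// Weight layout: Wm is C_out x (27*C_in); offset o = dh+1 + 3*(dw+1) + 9*(dd+1)
// owns the C_in block starting at o*C_in.

// [[Rcpp::export]]
arma::mat conv3d_forward(const arma::mat& X, const arma::mat& Wm,
                         const arma::vec& bias, Rcpp::IntegerVector dims) {
  Dims dm = get_dims(dims);
  const int Cin = X.n_rows;
  mat Y(Wm.n_rows, X.n_cols, fill::zeros);
  mat Xs(Cin, X.n_cols);
  for (int dd = -1; dd <= 1; ++dd)
    for (int dw = -1; dw <= 1; ++dw)
      for (int dh = -1; dh <= 1; ++dh) {
        int o = (dh + 1) + 3 * (dw + 1) + 9 * (dd + 1);
        shift_copy(X, Xs, dm, dh, dw, dd);
        Y += Wm.cols(o * Cin, (o + 1) * Cin - 1) * Xs;
      }
  Y.each_col() += bias;
  return Y;
}

// [[Rcpp::export]]
Rcpp::List conv3d_backward(const arma::mat& X, const arma::mat& Wm,
                           const arma::mat& dY, Rcpp::IntegerVector dims) {
  Dims dm = get_dims(dims);
  const int Cin = X.n_rows;
  mat dW(Wm.n_rows, Wm.n_cols, fill::zeros);
  mat dX(Cin, X.n_cols, fill::zeros);
  mat Xs(Cin, X.n_cols);
  for (int dd = -1; dd <= 1; ++dd)
    for (int dw = -1; dw <= 1; ++dw)
      for (int dh = -1; dh <= 1; ++dh) {
        int o = (dh + 1) + 3 * (dw + 1) + 9 * (dd + 1);
        shift_copy(X, Xs, dm, dh, dw, dd);
        dW.cols(o * Cin, (o + 1) * Cin - 1) = dY * Xs.t();
        mat T = Wm.cols(o * Cin, (o + 1) * Cin - 1).t() * dY;
        shift_add(dX, T, dm, dh, dw, dd);
      }
  vec db = sum(dY, 1);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dW") = dW,
                            Rcpp::Named("db") = db);
}

// 2x2x2 max pooling, stride 2. Odd trailing extents are truncated (all our
// stage sizes are even). Returns pooled values and 0-based argmax columns.

// [[Rcpp::export]]
Rcpp::List maxpool3d_forward(const arma::mat& X, Rcpp::IntegerVector dims) {
  Dims dm = get_dims(dims);
  const int C = X.n_rows;
  const int H2 = dm.H / 2, W2 = dm.W / 2, D2 = dm.D / 2, B = dm.B;
  long V2 = (long)H2 * W2 * D2 * B;
  mat Y(C, V2);
  umat arg(C, V2);
  for (int b = 0; b < B; ++b)
    for (int d = 0; d < D2; ++d)
      for (int w = 0; w < W2; ++w)
        for (int h = 0; h < H2; ++h) {
          long vo = h + (long)H2 * (w + (long)W2 * (d + (long)D2 * b));
          for (int c = 0; c < C; ++c) { Y(c, vo) = -datum::inf; }
          for (int kd = 0; kd < 2; ++kd)
            for (int kw = 0; kw < 2; ++kw)
              for (int kh = 0; kh < 2; ++kh) {
                long vi = (2 * h + kh) + (long)dm.H *
                          ((2 * w + kw) + (long)dm.W * ((2 * d + kd) + (long)dm.D * b));
                for (int c = 0; c < C; ++c)
                  if (X(c, vi) > Y(c, vo)) { Y(c, vo) = X(c, vi); arg(c, vo) = vi; }
              }
        }
  return Rcpp::List::create(Rcpp::Named("Y") = Y, Rcpp::Named("argmax") = arg);
}

// [[Rcpp::export]]
arma::mat maxpool3d_backward(const arma::mat& dY, const arma::umat& arg,
                             int Cin, long Vin) {
  mat dX(Cin, Vin, fill::zeros);
  for (uword j = 0; j < dY.n_cols; ++j)
    for (uword c = 0; c < dY.n_rows; ++c)
      dX(c, arg(c, j)) += dY(c, j);
  return dX;
}

// Trilinear upsampling by integer factors (align_corners = FALSE sampling:
// source coord = (i + 0.5)/scale - 0.5, clamped). Forward and its exact
// adjoint share the per-axis weight tables.

struct AxisTab { std::vector<int> i0, i1; std::vector<double> w1; };

static AxisTab axis_tab(int n_in, int n_out) {
  AxisTab t; t.i0.resize(n_out); t.i1.resize(n_out); t.w1.resize(n_out);
  double scale = (double)n_out / n_in;
  for (int i = 0; i < n_out; ++i) {
    double s = (i + 0.5) / scale - 0.5;
    if (s < 0) s = 0; if (s > n_in - 1) s = n_in - 1;
    int i0 = (int)std::floor(s);
    int i1 = std::min(i0 + 1, n_in - 1);
    t.i0[i] = i0; t.i1[i] = i1; t.w1[i] = s - i0;
  }
  return t;
}

// [[Rcpp::export]]
arma::mat upsample3d_forward(const arma::mat& X, Rcpp::IntegerVector in_dims,
                             Rcpp::IntegerVector out_dims) {
  Dims di = get_dims(in_dims), dz = get_dims(out_dims);
  const int C = X.n_rows;
  AxisTab th = axis_tab(di.H, dz.H), tw = axis_tab(di.W, dz.W), td = axis_tab(di.D, dz.D);
  mat Y(C, dz.V(), fill::zeros);
  const double* xp = X.memptr();
  double* yp = Y.memptr();
  for (int b = 0; b < dz.B; ++b)
    for (int d = 0; d < dz.D; ++d)
      for (int w = 0; w < dz.W; ++w)
        for (int h = 0; h < dz.H; ++h) {
          long vo = h + (long)dz.H * (w + (long)dz.W * (d + (long)dz.D * b));
          double wh = th.w1[h], ww = tw.w1[w], wd = td.w1[d];
          int hs[2] = {th.i0[h], th.i1[h]}, ws[2] = {tw.i0[w], tw.i1[w]},
              dsz[2] = {td.i0[d], td.i1[d]};
          double fw[2] = {1 - wh, wh}, gw[2] = {1 - ww, ww}, hw[2] = {1 - wd, wd};
          double* dst = yp + (long)C * vo;
          for (int a = 0; a < 2; ++a)
            for (int bb = 0; bb < 2; ++bb)
              for (int cc = 0; cc < 2; ++cc) {
                double wt = fw[a] * gw[bb] * hw[cc];
                if (wt == 0) continue;
                long vi = hs[a] + (long)di.H * (ws[bb] + (long)di.W * (dsz[cc] + (long)di.D * b));
                const double* src = xp + (long)C * vi;
                for (int c = 0; c < C; ++c) dst[c] += wt * src[c];
              }
        }
  return Y;
}

// [[Rcpp::export]]
arma::mat upsample3d_backward(const arma::mat& dY, Rcpp::IntegerVector in_dims,
                              Rcpp::IntegerVector out_dims) {
  Dims di = get_dims(in_dims), dz = get_dims(out_dims);
  const int C = dY.n_rows;
  AxisTab th = axis_tab(di.H, dz.H), tw = axis_tab(di.W, dz.W), td = axis_tab(di.D, dz.D);
  mat dX(C, di.V(), fill::zeros);
  for (int b = 0; b < dz.B; ++b)
    for (int d = 0; d < dz.D; ++d)
      for (int w = 0; w < dz.W; ++w)
        for (int h = 0; h < dz.H; ++h) {
          long vo = h + (long)dz.H * (w + (long)dz.W * (d + (long)dz.D * b));
          double wh = th.w1[h], ww = tw.w1[w], wd = td.w1[d];
          int hs[2] = {th.i0[h], th.i1[h]}, ws[2] = {tw.i0[w], tw.i1[w]},
              dsz[2] = {td.i0[d], td.i1[d]};
          double fw[2] = {1 - wh, wh}, gw[2] = {1 - ww, ww}, hw[2] = {1 - wd, wd};
          for (int a = 0; a < 2; ++a)
            for (int bb = 0; bb < 2; ++bb)
              for (int cc = 0; cc < 2; ++cc) {
                double wt = fw[a] * gw[bb] * hw[cc];
                if (wt == 0) continue;
                long vi = hs[a] + (long)di.H * (ws[bb] + (long)di.W * (dsz[cc] + (long)di.D * b));
                double* dst = dX.memptr() + (long)C * vi;
                const double* src = dY.memptr() + (long)C * vo;
                for (int c = 0; c < C; ++c) dst[c] += wt * src[c];
              }
        }
  return dX;
}

// Directed surface distances for HD95: for every row of A (points, mm),
// the distance to the nearest row of B. Brute force; surfaces are small.

// [[Rcpp::export]]
arma::vec directed_min_dists(const arma::mat& A, const arma::mat& B) {
  vec out(A.n_rows);
  for (uword i = 0; i < A.n_rows; ++i) {
    double best = datum::inf;
    for (uword j = 0; j < B.n_rows; ++j) {
      double dx = A(i, 0) - B(j, 0), dy = A(i, 1) - B(j, 1), dz = A(i, 2) - B(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out(i) = std::sqrt(best);
  }
  return out;
}
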