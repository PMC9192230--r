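// Low-level numeric kernels for the segmentation network.
// Feature maps are h x w x c cubes (channels in slices); convolution weights
// arrive as k x k x cin x cout arrays whose first three dims flatten to the
// rows of a (k*k*cin) x cout matrix, matching the im2col patch layout below.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat im2col(const arma::cube& x, const int k, const int pad) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  arma::mat P(h * w, k * k * cin, arma::fill::zeros);
  for (int ci = 0; ci < cin; ++ci) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * kj + k * k * ci;
        for (int cc = 0; cc < w; ++cc) {
          const int sc = cc + kj - pad;
          if (sc < 0 || sc >= w) continue;
          for (int r = 0; r < h; ++r) {
            const int sr = r + ki - pad;
            if (sr < 0 || sr >= h) continue;
            P(r + h * cc, col) = x(sr, sc, ci);
          }
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
arma::cube conv2d_fwd(const arma::cube& x, const NumericVector& wgt,
                      const arma::vec& bias, const int k, const int pad) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = bias.n_elem;
  const arma::mat Wm(const_cast<double*>(wgt.begin()), k * k * cin, cout, false);
  arma::mat Y = im2col(x, k, pad) * Wm;
  Y.each_row() += bias.t();
  arma::cube out(h, w, cout);
  std::memcpy(out.memptr(), Y.memptr(), sizeof(double) * h * w * cout);
  return out;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(const arma::cube& x, const NumericVector& wgt,
                const arma::cube& gy, const int k, const int pad) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int cout = gy.n_slices;
  const arma::mat Wm(const_cast<double*>(wgt.begin()), k * k * cin, cout, false);
  const arma::mat G(const_cast<double*>(gy.memptr()), h * w, cout, false);

  arma::mat P = im2col(x, k, pad);
  arma::mat dW = P.t() * G;                    // (k*k*cin) x cout
  arma::vec db = arma::sum(G, 0).t();
  arma::mat dP = G * Wm.t();                   // (h*w) x (k*k*cin)

  arma::cube dx(h, w, cin, arma::fill::zeros); // col2im scatter-add
  for (int ci = 0; ci < cin; ++ci) {
    for (int kj = 0; kj < k; ++kj) {
      for (int ki = 0; ki < k; ++ki) {
        const int col = ki + k * kj + k * k * ci;
        for (int cc = 0; cc < w; ++cc) {
          const int sc = cc + kj - pad;
          if (sc < 0 || sc >= w) continue;
          for (int r = 0; r < h; ++r) {
            const int sr = r + ki - pad;
            if (sr < 0 || sr >= h) continue;
            dx(sr, sc, ci) += dP(r + h * cc, col);
          }
        }
      }
    }
  }
  NumericVector dWv(dW.memptr(), dW.memptr() + dW.n_elem);
  dWv.attr("dim") = IntegerVector::create(k, k, cin, cout);
  return List::create(_["dx"] = dx, _["dw"] = dWv, _["db"] = db);
}

// 2x2 max pooling, stride 2; returns pooled map and linear argmax indices
// (1-based into the input cube) so the backward pass is a pure scatter.
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int oh = h / 2, ow = w / 2;
  arma::cube y(oh, ow, c);
  IntegerVector idx(oh * ow * c);
  int p = 0;
  for (int ci = 0; ci < c; ++ci)
    for (int cc = 0; cc < ow; ++cc)
      for (int r = 0; r < oh; ++r) {
        double best = -1e300; int bi = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int sr = 2 * r + di, sc = 2 * cc + dj;
            const double v = x(sr, sc, ci);
            if (v > best) { best = v; bi = sr + h * sc + h * w * ci; }
          }
        y(r, cc, ci) = best;
        idx[p++] = bi + 1;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
arma::cube maxpool2_bwd(const arma::cube& gy, const IntegerVector& idx,
                        const int h, const int w) {
  const int c = gy.n_slices;
  arma::cube dx(h, w, c, arma::fill::zeros);
  const double* g = gy.memptr();
  for (int p = 0; p < (int)idx.size(); ++p) dx.memptr()[idx[p] - 1] += g[p];
  return dx;
}

struct LinW { int i0, i1; double w0, w1; };

static std::vector<LinW> lin_weights(const int n_in, const int n_out) {
  // align-corners bilinear sampling grid along one axis
  std::vector<LinW> ws(n_out);
  const double scale = (n_out > 1) ? (double)(n_in - 1) / (n_out - 1) : 0.0;
  for (int o = 0; o < n_out; ++o) {
    const double s = o * scale;
    int i0 = (int)std::floor(s);
    if (i0 > n_in - 2) i0 = std::max(0, n_in - 2);
    const double t = (n_in > 1) ? s - i0 : 0.0;
    ws[o] = {i0, std::min(i0 + 1, n_in - 1), 1.0 - t, t};
  }
  return ws;
}

// [[Rcpp::export(name = ".resize_bilinear_fwd")]]
arma::cube resize_bilinear_fwd(const arma::cube& x, const int oh, const int ow) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const std::vector<LinW> rw = lin_weights(h, oh), cw = lin_weights(w, ow);
  arma::cube y(oh, ow, c);
  for (int ci = 0; ci < c; ++ci)
    for (int cc = 0; cc < ow; ++cc)
      for (int r = 0; r < oh; ++r)
        y(r, cc, ci) =
          rw[r].w0 * (cw[cc].w0 * x(rw[r].i0, cw[cc].i0, ci) +
                      cw[cc].w1 * x(rw[r].i0, cw[cc].i1, ci)) +
          rw[r].w1 * (cw[cc].w0 * x(rw[r].i1, cw[cc].i0, ci) +
                      cw[cc].w1 * x(rw[r].i1, cw[cc].i1, ci));
  return y;
}

// [[Rcpp::export(name = ".resize_bilinear_bwd")]]
arma::cube resize_bilinear_bwd(const arma::cube& gy, const int h, const int w) {
  const int oh = gy.n_rows, ow = gy.n_cols, c = gy.n_slices;
  const std::vector<LinW> rw = lin_weights(h, oh), cw = lin_weights(w, ow);
  arma::cube dx(h, w, c, arma::fill::zeros);
  for (int ci = 0; ci < c; ++ci)
    for (int cc = 0; cc < ow; ++cc)
      for (int r = 0; r < oh; ++r) {
        const double g = gy(r, cc, ci);
        dx(rw[r].i0, cw[cc].i0, ci) += rw[r].w0 * cw[cc].w0 * g;
        dx(rw[r].i0, cw[cc].i1, ci) += rw[r].w0 * cw[cc].w1 * g;
        dx(rw[r].i1, cw[cc].i0, ci) += rw[r].w1 * cw[cc].w0 * g;
        dx(rw[r].i1, cw[cc].i1, ci) += rw[r].w1 * cw[cc].w1 * g;
      }
  return dx;
}
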