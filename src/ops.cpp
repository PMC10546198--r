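// Low-level pixel and tensor primitives.
// Convention: images are R matrices (column-major, rows = image rows),
// values on [0,1]. All coordinates crossing the R boundary are 1-based.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// symmetric (half-sample) reflection for border handling
static inline int reflect_idx(int i, int n) {
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_box_mean(const NumericMatrix& x, int k) {
  const int h = x.nrow(), w = x.ncol(), r = k / 2;
  NumericMatrix tmp(h, w), out(h, w);
  // horizontal pass
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d) s += x(i, reflect_idx(j + d, w));
      tmp(i, j) = s / k;
    }
  // vertical pass
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double s = 0.0;
      for (int d = -r; d <= r; ++d) s += tmp(reflect_idx(i + d, h), j);
      out(i, j) = s / k;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& x, double sigma) {
  const int h = x.nrow(), w = x.ncol();
  const int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> ker(2 * r + 1);
  double s = 0.0;
  for (int d = -r; d <= r; ++d) {
    ker[d + r] = std::exp(-0.5 * d * d / (sigma * sigma));
    s += ker[d + r];
  }
  for (auto& v : ker) v /= s;
  NumericMatrix tmp(h, w), out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += ker[d + r] * x(i, reflect_idx(j + d, w));
      tmp(i, j) = acc;
    }
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int d = -r; d <= r; ++d) acc += ker[d + r] * tmp(reflect_idx(i + d, h), j);
      out(i, j) = acc;
    }
  return out;
}

// Contrast limited adaptive histogram equalization on [0,1] data.
// clip is relative: per-tile histogram counts are clipped at
// max(1, clip * tile_area) and the excess is redistributed uniformly.
// Tile mappings are plain CDFs; pixel values are bilinearly interpolated
// between the four surrounding tile centers.
// [[Rcpp::export]]
NumericMatrix cpp_clahe(const NumericMatrix& x, int nbins, double clip,
                        int tiles_row, int tiles_col) {
  const int h = x.nrow(), w = x.ncol();
  const int ty = tiles_row, tx = tiles_col;
  // per-tile CDF maps: map[t][b] in [0,1]
  std::vector<std::vector<double>> map(ty * tx, std::vector<double>(nbins, 0.0));
  std::vector<double> cy(ty), cx(tx); // tile centers
  for (int a = 0; a < ty; ++a) {
    int r0 = (int)std::floor((double)a * h / ty);
    int r1 = (int)std::floor((double)(a + 1) * h / ty);
    cy[a] = 0.5 * (r0 + r1 - 1);
    for (int b = 0; b < tx; ++b) {
      int c0 = (int)std::floor((double)b * w / tx);
      int c1 = (int)std::floor((double)(b + 1) * w / tx);
      if (a == 0) cx[b] = 0.5 * (c0 + c1 - 1);
      std::vector<double> hist(nbins, 0.0);
      double area = (double)(r1 - r0) * (c1 - c0);
      for (int j = c0; j < c1; ++j)
        for (int i = r0; i < r1; ++i) {
          int bin = (int)(x(i, j) * nbins);
          if (bin >= nbins) bin = nbins - 1;
          if (bin < 0) bin = 0;
          hist[bin] += 1.0;
        }
      double limit = std::max(1.0, clip * area);
      double excess = 0.0;
      for (int b2 = 0; b2 < nbins; ++b2)
        if (hist[b2] > limit) { excess += hist[b2] - limit; hist[b2] = limit; }
      double add = excess / nbins;
      double cdf = 0.0;
      for (int b2 = 0; b2 < nbins; ++b2) {
        cdf += hist[b2] + add;
        map[a * tx + b][b2] = cdf / area;
      }
    }
  }
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j) {
    // locate horizontal tile pair
    int b1 = 0;
    while (b1 + 1 < tx && cx[b1 + 1] <= j) ++b1;
    int b2 = std::min(b1 + 1, tx - 1);
    double wx = 0.0;
    if (b2 != b1 && j >= cx[b1]) wx = (j - cx[b1]) / (cx[b2] - cx[b1]);
    if (j < cx[0]) { b1 = b2 = 0; wx = 0.0; }
    if (j > cx[tx - 1]) { b1 = b2 = tx - 1; wx = 0.0; }
    for (int i = 0; i < h; ++i) {
      int a1 = 0;
      while (a1 + 1 < ty && cy[a1 + 1] <= i) ++a1;
      int a2 = std::min(a1 + 1, ty - 1);
      double wy = 0.0;
      if (a2 != a1 && i >= cy[a1]) wy = (i - cy[a1]) / (cy[a2] - cy[a1]);
      if (i < cy[0]) { a1 = a2 = 0; wy = 0.0; }
      if (i > cy[ty - 1]) { a1 = a2 = ty - 1; wy = 0.0; }
      int bin = (int)(x(i, j) * nbins);
      if (bin >= nbins) bin = nbins - 1;
      if (bin < 0) bin = 0;
      double v =
        (1 - wy) * ((1 - wx) * map[a1 * tx + b1][bin] + wx * map[a1 * tx + b2][bin]) +
        wy * ((1 - wx) * map[a2 * tx + b1][bin] + wx * map[a2 * tx + b2][bin]);
      out(i, j) = std::min(1.0, std::max(0.0, v));
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_resize_bilinear(const NumericMatrix& x, int oh, int ow) {
  const int h = x.nrow(), w = x.ncol();
  NumericMatrix out(oh, ow);
  const double sy = (double)h / oh, sx = (double)w / ow;
  for (int j = 0; j < ow; ++j) {
    double fx = (j + 0.5) * sx - 0.5;
    if (fx < 0) fx = 0; if (fx > w - 1) fx = w - 1;
    int x0 = (int)std::floor(fx), x1 = std::min(x0 + 1, w - 1);
    double wx = fx - x0;
    for (int i = 0; i < oh; ++i) {
      double fy = (i + 0.5) * sy - 0.5;
      if (fy < 0) fy = 0; if (fy > h - 1) fy = h - 1;
      int y0 = (int)std::floor(fy), y1 = std::min(y0 + 1, h - 1);
      double wy = fy - y0;
      out(i, j) = (1 - wy) * ((1 - wx) * x(y0, x0) + wx * x(y0, x1)) +
                  wy * ((1 - wx) * x(y1, x0) + wx * x(y1, x1));
    }
  }
  return out;
}

// rotation about the image center, bilinear, zero fill
// [[Rcpp::export]]
NumericMatrix cpp_rotate_bilinear(const NumericMatrix& x, double angle_deg) {
  const int h = x.nrow(), w = x.ncol();
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (h - 1) / 2.0, cx = (w - 1) / 2.0;
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      // inverse map: rotate output coordinate by -theta
      double dy = i - cy, dx = j - cx;
      double sy = ct * dy + st * dx + cy;
      double sx = -st * dy + ct * dx + cx;
      if (sy < 0 || sy > h - 1 || sx < 0 || sx > w - 1) { out(i, j) = 0.0; continue; }
      int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
      int y1 = std::min(y0 + 1, h - 1), x1 = std::min(x0 + 1, w - 1);
      double wy = sy - y0, wx = sx - x0;
      out(i, j) = (1 - wy) * ((1 - wx) * x(y0, x0) + wx * x(y0, x1)) +
                  wy * ((1 - wx) * x(y1, x0) + wx * x(y1, x1));
    }
  return out;
}

// mean of (max-min)/(max+min) over all fully interior 3x3 windows;
// windows with max+min == 0 contribute 0
// [[Rcpp::export]]
List cpp_local_contrast(const NumericMatrix& x) {
  const int h = x.nrow(), w = x.ncol();
  double acc = 0.0;
  long n = 0;
  for (int j = 1; j < w - 1; ++j)
    for (int i = 1; i < h - 1; ++i) {
      double mx = x(i - 1, j - 1), mn = mx;
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          double v = x(i + di, j + dj);
          if (v > mx) mx = v;
          if (v < mn) mn = v;
        }
      double den = mx + mn;
      if (den > 0) acc += (mx - mn) / den;
      ++n;
    }
  return List::create(_["C"] = (n > 0 ? acc / n : 0.0), _["n_windows"] = (double)n);
}

static void sobel(const NumericMatrix& x, NumericMatrix& gx, NumericMatrix& gy,
                  NumericMatrix& mag) {
  const int h = x.nrow(), w = x.ncol();
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i) {
      int im = reflect_idx(i - 1, h), ip = reflect_idx(i + 1, h);
      int jm = reflect_idx(j - 1, w), jp = reflect_idx(j + 1, w);
      double sx = (x(im, jp) + 2 * x(i, jp) + x(ip, jp)) -
                  (x(im, jm) + 2 * x(i, jm) + x(ip, jm));
      double sy = (x(ip, jm) + 2 * x(ip, j) + x(ip, jp)) -
                  (x(im, jm) + 2 * x(im, j) + x(im, jp));
      gx(i, j) = sx;
      gy(i, j) = sy;
      mag(i, j) = std::sqrt(sx * sx + sy * sy);
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_sobel_mag(const NumericMatrix& x) {
  NumericMatrix gx(x.nrow(), x.ncol()), gy(x.nrow(), x.ncol()),
    mag(x.nrow(), x.ncol());
  sobel(x, gx, gy, mag);
  return mag;
}

// Gradient-direction Hough circle vote. Edge pixels (gradient magnitude
// above the given quantile) vote for candidate centers at distance r along
// +/- the gradient direction, for every radius in [rmin, rmax]. Returns the
// best accumulator peak; score is votes normalised by the circle perimeter.
// Returned center/radius are 1-based (R convention).
// [[Rcpp::export]]
List cpp_hough_circle(const NumericMatrix& x, int rmin, int rmax,
                      double edge_quantile) {
  const int h = x.nrow(), w = x.ncol();
  NumericMatrix gx(h, w), gy(h, w), mag(h, w);
  sobel(x, gx, gy, mag);
  std::vector<double> mv(mag.begin(), mag.end());
  std::sort(mv.begin(), mv.end());
  double thr = mv[(size_t)std::min((double)mv.size() - 1,
                                   std::floor(edge_quantile * mv.size()))];
  if (thr <= 0) thr = 1e-12;
  std::vector<int> ei, ej;
  std::vector<double> ux, uy;
  for (int j = 0; j < w; ++j)
    for (int i = 0; i < h; ++i)
      if (mag(i, j) >= thr && mag(i, j) > 0) {
        ei.push_back(i); ej.push_back(j);
        ux.push_back(gx(i, j) / mag(i, j));
        uy.push_back(gy(i, j) / mag(i, j));
      }
  if (ei.empty())
    return List::create(_["cy"] = NA_REAL, _["cx"] = NA_REAL, _["r"] = NA_REAL,
                        _["votes"] = 0.0, _["score"] = 0.0);
  // peak search on a 3x3 box-summed accumulator: votes for one circle are
  // spread over neighbouring cells by rounding, so the raw argmax is noisy
  int best_votes = -1, best_cy = 0, best_cx = 0, best_r = rmin;
  std::vector<int> acc((size_t)h * w);
  for (int r = rmin; r <= rmax; ++r) {
    std::fill(acc.begin(), acc.end(), 0);
    for (size_t e = 0; e < ei.size(); ++e) {
      for (int s = -1; s <= 1; s += 2) {
        int ci = (int)std::lround(ei[e] + s * r * uy[e]);
        int cj = (int)std::lround(ej[e] + s * r * ux[e]);
        if (ci >= 0 && ci < h && cj >= 0 && cj < w) acc[(size_t)cj * h + ci]++;
      }
    }
    for (int j = 1; j < w - 1; ++j)
      for (int i = 1; i < h - 1; ++i) {
        int v = 0;
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di)
            v += acc[(size_t)(j + dj) * h + (i + di)];
        if (v > best_votes) { best_votes = v; best_cy = i; best_cx = j; best_r = r; }
      }
  }
  double score = best_votes / (2.0 * M_PI * best_r);
  return List::create(_["cy"] = best_cy + 1.0, _["cx"] = best_cx + 1.0,
                      _["r"] = (double)best_r, _["votes"] = (double)best_votes,
                      _["score"] = score);
}

static double ring_score(const NumericMatrix& mag, double cy, double cx, double r) {
  const int h = mag.nrow(), w = mag.ncol();
  int n = std::max(64, (int)std::lround(2 * M_PI * r));
  double acc = 0.0;
  for (int t = 0; t < n; ++t) {
    double th = 2 * M_PI * t / n;
    double fy = cy + r * std::sin(th), fx = cx + r * std::cos(th);
    if (fy < 0 || fy > h - 1 || fx < 0 || fx > w - 1) continue;
    int y0 = (int)std::floor(fy), x0 = (int)std::floor(fx);
    int y1 = std::min(y0 + 1, h - 1), x1 = std::min(x0 + 1, w - 1);
    double wy = fy - y0, wx = fx - x0;
    acc += (1 - wy) * ((1 - wx) * mag(y0, x0) + wx * mag(y0, x1)) +
           wy * ((1 - wx) * mag(y1, x0) + wx * mag(y1, x1));
  }
  return acc / n;
}

// local full-resolution refinement of a circle by maximising mean gradient
// magnitude along the perimeter; in/out 1-based
// [[Rcpp::export]]
List cpp_ring_refine(const NumericMatrix& x, double cy1, double cx1, double r0,
                     int win) {
  NumericMatrix gx(x.nrow(), x.ncol()), gy(x.nrow(), x.ncol()),
    mag(x.nrow(), x.ncol());
  sobel(x, gx, gy, mag);
  double cy = cy1 - 1, cx = cx1 - 1;
  double best = -1, bcy = cy, bcx = cx, br = r0;
  for (int dr = -win; dr <= win; ++dr) {
    double r = r0 + dr;
    if (r < 3) continue;
    for (int di = -win; di <= win; ++di)
      for (int dj = -win; dj <= win; ++dj) {
        double s = ring_score(mag, cy + di, cx + dj, r);
        if (s > best) { best = s; bcy = cy + di; bcx = cx + dj; br = r; }
      }
  }
  return List::create(_["cy"] = bcy + 1.0, _["cx"] = bcx + 1.0, _["r"] = br,
                      _["score"] = best);
}

// canvas <- max(canvas, amp * exp(-d^2 / (2 sigma^2))) around each stamp
// point; used to rasterise vessel centerlines with a soft cross-section.
// Points are 1-based (row, col) and may be fractional.
// [[Rcpp::export]]
NumericMatrix cpp_stamp_max(NumericMatrix canvas, const NumericVector& ys,
                            const NumericVector& xs, const NumericVector& sigma,
                            const NumericVector& amp) {
  const int h = canvas.nrow(), w = canvas.ncol();
  NumericMatrix out = clone(canvas);
  for (int p = 0; p < ys.size(); ++p) {
    double py = ys[p] - 1, px = xs[p] - 1, sg = sigma[p], am = amp[p];
    int rad = std::max(1, (int)std::ceil(3.0 * sg));
    int i0 = std::max(0, (int)std::floor(py) - rad);
    int i1 = std::min(h - 1, (int)std::ceil(py) + rad);
    int j0 = std::max(0, (int)std::floor(px) - rad);
    int j1 = std::min(w - 1, (int)std::ceil(px) + rad);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        double d2 = (i - py) * (i - py) + (j - px) * (j - px);
        double v = am * std::exp(-0.5 * d2 / (sg * sg));
        if (v > out(i, j)) out(i, j) = v;
      }
  }
  return out;
}

// ---------------------------------------------------------------------------
// CNN primitives: 3x3 same-padding convolution via im2col, 2x2 max pooling.
// Activations are arma::cube (H x W x C). Weights are (k*k*Cin) x Cout with
// patch entries ordered c-major then di then dj: q = (c*k + di)*k + dj.

static arma::mat im2col(const arma::cube& x, int k, int pad) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  arma::mat cols((size_t)h * w, (size_t)k * k * c, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch)
    for (int di = 0; di < k; ++di)
      for (int dj = 0; dj < k; ++dj) {
        size_t q = ((size_t)ch * k + di) * k + dj;
        for (int j = 0; j < w; ++j) {
          int sj = j + dj - pad;
          if (sj < 0 || sj >= w) continue;
          for (int i = 0; i < h; ++i) {
            int si = i + di - pad;
            if (si < 0 || si >= h) continue;
            cols((size_t)j * h + i, q) = x(si, sj, ch);
          }
        }
      }
  return cols;
}

// [[Rcpp::export]]
arma::cube cpp_conv_fwd(const arma::cube& x, const arma::mat& wt,
                        const arma::vec& b) {
  const int h = x.n_rows, w = x.n_cols;
  const int k = (int)std::lround(std::sqrt((double)wt.n_rows / x.n_slices));
  arma::mat cols = im2col(x, k, k / 2);
  arma::mat y = cols * wt;
  y.each_row() += b.t();
  arma::cube out(h, w, wt.n_cols);
  for (size_t ch = 0; ch < wt.n_cols; ++ch)
    out.slice(ch) = arma::reshape(y.col(ch), h, w);
  return out;
}

// [[Rcpp::export]]
List cpp_conv_bwd(const arma::cube& x, const arma::mat& wt, const arma::cube& dy) {
  const int h = x.n_rows, w = x.n_cols, cin = x.n_slices;
  const int k = (int)std::lround(std::sqrt((double)wt.n_rows / cin));
  const int pad = k / 2;
  arma::mat cols = im2col(x, k, pad);
  arma::mat dym((size_t)h * w, dy.n_slices);
  for (size_t ch = 0; ch < dy.n_slices; ++ch)
    dym.col(ch) = arma::vectorise(dy.slice(ch));
  arma::mat dW = cols.t() * dym;
  arma::vec db = arma::sum(dym, 0).t();
  arma::mat dcols = dym * wt.t();
  arma::cube dx(h, w, cin, arma::fill::zeros);
  for (int ch = 0; ch < cin; ++ch)
    for (int di = 0; di < k; ++di)
      for (int dj = 0; dj < k; ++dj) {
        size_t q = ((size_t)ch * k + di) * k + dj;
        for (int j = 0; j < w; ++j) {
          int sj = j + dj - pad;
          if (sj < 0 || sj >= w) continue;
          for (int i = 0; i < h; ++i) {
            int si = i + di - pad;
            if (si < 0 || si >= h) continue;
            dx(si, sj, ch) += dcols((size_t)j * h + i, q);
          }
        }
      }
  return List::create(_["dW"] = dW, _["db"] = db, _["dx"] = dx);
}

// [[Rcpp::export]]
List cpp_maxpool_fwd(const arma::cube& x) {
  const int h = x.n_rows, w = x.n_cols, c = x.n_slices;
  const int oh = h / 2, ow = w / 2;
  arma::cube y(oh, ow, c);
  arma::ucube idx(oh, ow, c); // linear index within slice of the argmax
  for (int ch = 0; ch < c; ++ch)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double best = -1e300;
        size_t bidx = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            int si = 2 * i + di, sj = 2 * j + dj;
            double v = x(si, sj, ch);
            if (v > best) { best = v; bidx = (size_t)sj * h + si; }
          }
        y(i, j, ch) = best;
        idx(i, j, ch) = bidx;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool_bwd(const arma::cube& dy, const arma::ucube& idx,
                           int h, int w) {
  const int c = dy.n_slices;
  arma::cube dx(h, w, c, arma::fill::zeros);
  for (int ch = 0; ch < c; ++ch)
    for (size_t j = 0; j < dy.n_cols; ++j)
      for (size_t i = 0; i < dy.n_rows; ++i)
        dx.slice(ch)(idx(i, j, ch)) += dy(i, j, ch);
  return dx;
}
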