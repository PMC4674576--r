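// Pyramidal Lucas-Kanade point tracker used by the Median Flow stage.
// Images are h x w numeric matrices in [0,1]; coordinates are 0-based
// (x = column, y = row) with pixel centers at integers.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double interp(const NumericMatrix& img, double x, double y) {
  int h = img.nrow(), w = img.ncol();
  if (x < 0) x = 0;
  if (x > w - 1) x = w - 1;
  if (y < 0) y = 0;
  if (y > h - 1) y = h - 1;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < w ? x0 + 1 : w - 1;
  int y1 = y0 + 1 < h ? y0 + 1 : h - 1;
  double fx = x - x0, fy = y - y0;
  return (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
         fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
}

// Track points from the first pyramid to the second. Returns tracked
// positions and a status flag (false when the local structure tensor is
// degenerate at every level or the point leaves the image).
// [[Rcpp::export(name = ".lkTrackPyr")]]
List lkTrackPyr(List prevPyr, List nextPyr, NumericMatrix pts,
                int halfwin = 4, int maxIter = 20, double eps = 0.01,
                double minEig = 1e-6) {
  const int n = pts.nrow();
  const int levels = prevPyr.size();
  NumericMatrix out(n, 2);
  LogicalVector status(n);
  const int winN = (2 * halfwin + 1) * (2 * halfwin + 1);
  std::vector<double> Ix(winN), Iy(winN), Tv(winN);

  NumericMatrix finest = prevPyr[0];
  const int W0 = finest.ncol(), H0 = finest.nrow();

  for (int p = 0; p < n; ++p) {
    double dx = 0, dy = 0;
    bool anyValid = false;
    for (int l = levels - 1; l >= 0; --l) {
      NumericMatrix P = prevPyr[l], N = nextPyr[l];
      double scale = 1.0 / double(1 << l);
      double px = pts(p, 0) * scale, py = pts(p, 1) * scale;
      double gxx = 0, gxy = 0, gyy = 0;
      int k = 0;
      for (int wy = -halfwin; wy <= halfwin; ++wy) {
        for (int wx = -halfwin; wx <= halfwin; ++wx, ++k) {
          double x = px + wx, y = py + wy;
          Tv[k] = interp(P, x, y);
          double ix = (interp(P, x + 1, y) - interp(P, x - 1, y)) * 0.5;
          double iy = (interp(P, x, y + 1) - interp(P, x, y - 1)) * 0.5;
          Ix[k] = ix;
          Iy[k] = iy;
          gxx += ix * ix;
          gxy += ix * iy;
          gyy += iy * iy;
        }
      }
      double det = gxx * gyy - gxy * gxy;
      double tr = gxx + gyy;
      double mineig = 0.5 * (tr - std::sqrt(std::max(0.0, tr * tr - 4 * det)));
      if (det <= 0 || mineig / winN < minEig) {
        if (l > 0) { dx *= 2; dy *= 2; }
        continue;
      }
      anyValid = true;
      for (int it = 0; it < maxIter; ++it) {
        double bx = 0, by = 0;
        int k2 = 0;
        for (int wy = -halfwin; wy <= halfwin; ++wy) {
          for (int wx = -halfwin; wx <= halfwin; ++wx, ++k2) {
            double diff = interp(N, px + dx + wx, py + dy + wy) - Tv[k2];
            bx += diff * Ix[k2];
            by += diff * Iy[k2];
          }
        }
        double ux = -(gyy * bx - gxy * by) / det;
        double uy = -(-gxy * bx + gxx * by) / det;
        dx += ux;
        dy += uy;
        if (ux * ux + uy * uy < eps * eps) break;
      }
      if (l > 0) { dx *= 2; dy *= 2; }
    }
    double fx = pts(p, 0) + dx, fy = pts(p, 1) + dy;
    out(p, 0) = fx;
    out(p, 1) = fy;
    status[p] = anyValid && std::isfinite(fx) && std::isfinite(fy) &&
                fx >= 0 && fx <= W0 - 1 && fy >= 0 && fy <= H0 - 1;
  }
  return List::create(_["points"] = out, _["status"] = status);
}
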