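#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Grayscale erosion/dilation against a non-flat, ball-shaped structuring
// element of the given radius (height sqrt(r^2 - dx^2 - dy^2) over the
// disc dx^2 + dy^2 <= r^2).  Offsets falling outside the image are simply
// not considered, for both operations, so that opening by the ball is
// well defined up to the border without padding assumptions.

static inline void ball_offsets(int radius,
                                std::vector<int>& dy,
                                std::vector<int>& dx,
                                std::vector<double>& h) {
  const double r2 = (double)radius * radius;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b) {
      double d2 = (double)a * a + (double)b * b;
      if (d2 <= r2) {
        dy.push_back(a);
        dx.push_back(b);
        h.push_back(std::sqrt(r2 - d2));
      }
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_ball_erode(NumericMatrix img, int radius) {
  int H = img.nrow(), W = img.ncol();
  std::vector<int> dy, dx; std::vector<double> h;
  ball_offsets(radius, dy, dx, h);
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double m = R_PosInf;
      for (size_t k = 0; k < dy.size(); ++k) {
        int yy = y + dy[k], xx = x + dx[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        double v = img(yy, xx) - h[k];
        if (v < m) m = v;
      }
      out(y, x) = m;
    }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_ball_dilate(NumericMatrix img, int radius) {
  int H = img.nrow(), W = img.ncol();
  std::vector<int> dy, dx; std::vector<double> h;
  ball_offsets(radius, dy, dx, h);
  NumericMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      double m = R_NegInf;
      for (size_t k = 0; k < dy.size(); ++k) {
        int yy = y + dy[k], xx = x + dx[k];
        if (yy < 0 || yy >= H || xx < 0 || xx >= W) continue;
        double v = img(yy, xx) + h[k];
        if (v > m) m = v;
      }
      out(y, x) = m;
    }
  return out;
}
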