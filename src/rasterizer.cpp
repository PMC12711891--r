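#include <Rcpp.h>
using namespace Rcpp;

// Z-buffered triangle rasterizer. Inputs are screen-space vertices (pixel
// coordinates, top-left origin), per-vertex inverse view depth (1/z, which
// interpolates linearly in screen space), 0-based triangle indices and one
// flat RGB color per triangle. Samples at pixel centers (x + 0.5, y + 0.5);
// a sample is covered when all barycentric coordinates are >= 0.
// [[Rcpp::export]]
List rasterize_cpp(NumericMatrix uv, NumericVector invz, IntegerMatrix faces,
                   NumericMatrix face_rgb, int width, int height) {
  NumericVector rgb(height * width * 3);
  IntegerMatrix hit(height, width);
  NumericMatrix zbuf(height, width);   // stores max 1/z seen (0 = empty)

  int nf = faces.nrow();
  for (int t = 0; t < nf; ++t) {
    int i0 = faces(t, 0), i1 = faces(t, 1), i2 = faces(t, 2);
    double x0 = uv(i0, 0), y0 = uv(i0, 1);
    double x1 = uv(i1, 0), y1 = uv(i1, 1);
    double x2 = uv(i2, 0), y2 = uv(i2, 1);
    double area = (x1 - x0) * (y2 - y0) - (y1 - y0) * (x2 - x0);
    if (std::fabs(area) < 1e-12) continue;
    int xmin = std::max(0, (int)std::floor(std::min({x0, x1, x2}) - 0.5));
    int xmax = std::min(width - 1, (int)std::ceil(std::max({x0, x1, x2})));
    int ymin = std::max(0, (int)std::floor(std::min({y0, y1, y2}) - 0.5));
    int ymax = std::min(height - 1, (int)std::ceil(std::max({y0, y1, y2})));
    if (xmin > xmax || ymin > ymax) continue;
    double iz0 = invz[i0], iz1 = invz[i1], iz2 = invz[i2];
    for (int py = ymin; py <= ymax; ++py) {
      double sy = py + 0.5;
      for (int px = xmin; px <= xmax; ++px) {
        double sx = px + 0.5;
        double w0 = ((x1 - sx) * (y2 - sy) - (x2 - sx) * (y1 - sy)) / area;
        double w1 = ((x2 - sx) * (y0 - sy) - (x0 - sx) * (y2 - sy)) / area;
        double w2 = 1.0 - w0 - w1;
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double iz = w0 * iz0 + w1 * iz1 + w2 * iz2;
        if (hit(py, px) && iz <= zbuf(py, px)) continue;
        zbuf(py, px) = iz;
        hit(py, px) = 1;
        for (int c = 0; c < 3; ++c)
          rgb[py + height * (px + width * c)] = face_rgb(t, c);
      }
    }
  }
  rgb.attr("dim") = IntegerVector::create(height, width, 3);
  return List::create(_["rgb"] = rgb, _["hit"] = hit, _["zbuf"] = zbuf);
}
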