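#include <Rcpp.h>
using namespace Rcpp;

// Minimum Euclidean distance from each query point to any segment
// (x0,y0)-(x1,y1). Used for exact point-to-polygon-boundary distances.
// [[Rcpp::export]]
NumericVector cpp_min_seg_dist(NumericVector px, NumericVector py,
                               NumericVector x0, NumericVector y0,
                               NumericVector x1, NumericVector y1) {
  R_xlen_t np = px.size(), ns = x0.size();
  NumericVector out(np, R_PosInf);
  for (R_xlen_t s = 0; s < ns; ++s) {
    double ax = x0[s], ay = y0[s];
    double dx = x1[s] - ax, dy = y1[s] - ay;
    double len2 = dx * dx + dy * dy;
    for (R_xlen_t i = 0; i < np; ++i) {
      double qx = px[i] - ax, qy = py[i] - ay;
      double t = len2 > 0.0 ? (qx * dx + qy * dy) / len2 : 0.0;
      if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
      double ex = qx - t * dx, ey = qy - t * dy;
      double d2 = ex * ex + ey * ey;
      if (d2 < out[i]) out[i] = d2;
    }
  }
  for (R_xlen_t i = 0; i < np; ++i) out[i] = std::sqrt(out[i]);
  return out;
}

// Even-odd (crossing number) point-in-ring test. Vertices form an open
// ring (last vertex joins back to first). Points exactly on an edge may
// fall either way; callers that care about the boundary use distances.
// [[Rcpp::export]]
LogicalVector cpp_in_ring(NumericVector px, NumericVector py,
                          NumericVector vx, NumericVector vy) {
  R_xlen_t np = px.size(), nv = vx.size();
  LogicalVector out(np);
  for (R_xlen_t i = 0; i < np; ++i) {
    double x = px[i], y = py[i];
    bool inside = false;
    for (R_xlen_t j = 0, k = nv - 1; j < nv; k = j++) {
      double xj = vx[j], yj = vy[j], xk = vx[k], yk = vy[k];
      if (((yj > y) != (yk > y)) &&
          (x < (xk - xj) * (y - yj) / (yk - yj) + xj))
        inside = !inside;
    }
    out[i] = inside;
  }
  return out;
}

// Count of points inside an axis-aligned window [x, x+side] x [y, y+side]
// for each candidate window origin; used by the hotspot grid search.
// [[Rcpp::export]]
IntegerVector cpp_window_counts(NumericVector px, NumericVector py,
                                NumericVector wx, NumericVector wy,
                                double side) {
  R_xlen_t np = px.size(), nw = wx.size();
  IntegerVector out(nw);
  for (R_xlen_t w = 0; w < nw; ++w) {
    double x0 = wx[w], y0 = wy[w];
    int c = 0;
    for (R_xlen_t i = 0; i < np; ++i) {
      if (px[i] >= x0 && px[i] <= x0 + side &&
          py[i] >= y0 && py[i] <= y0 + side) ++c;
    }
    out[w] = c;
  }
  return out;
}
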