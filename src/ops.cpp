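#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Arc-restricted circle Hough transform.
//
// Each edge point votes only for candidate centers such that the point lies
// within +/-45 degrees of the horizontal line through the center, i.e. the
// point sits on the left or right arc of the candidate circle. This ignores
// the top/bottom arcs that eyelids typically cover.
//
// px, py: 0-based edge point coordinates; W, H: accumulator (patch) size;
// radii: integer radii to scan. Returns c(cx, cy, r, votes, cx_sub, cy_sub,
// r_sub) where the *_sub values are vote-weighted centroids of a small
// window around the peak.
// [[Rcpp::export]]
NumericVector cpp_hough_arc(IntegerVector px, IntegerVector py,
                            int W, int H, IntegerVector radii) {
  const int np = px.size(), nr = radii.size();
  std::vector<std::vector<int> > acc(nr, std::vector<int>(W * H, 0));

  for (int ri = 0; ri < nr; ++ri) {
    const double r = radii[ri];
    std::vector<int>& a = acc[ri];
    const double dphi = 1.0 / r;  // ~1 px steps along the arc
    for (int k = 0; k < np; ++k) {
      const double x = px[k], y = py[k];
      int lastIdx = -1;
      // two 90-degree arcs: phi in (-pi/4, pi/4) and (3pi/4, 5pi/4)
      for (int half = 0; half < 2; ++half) {
        const double phi0 = half == 0 ? -M_PI / 4 : 3 * M_PI / 4;
        const double phi1 = half == 0 ? M_PI / 4 : 5 * M_PI / 4;
        for (double phi = phi0; phi <= phi1; phi += dphi) {
          const int cx = (int)std::lround(x + r * std::cos(phi));
          const int cy = (int)std::lround(y + r * std::sin(phi));
          if (cx < 0 || cx >= W || cy < 0 || cy >= H) continue;
          const int idx = cy * W + cx;
          if (idx == lastIdx) continue;  // skip duplicate rounded cell
          a[idx]++;
          lastIdx = idx;
        }
      }
    }
  }

  // best cell; ties: larger radius, then smaller y, then smaller x
  int bestV = -1, bestX = 0, bestY = 0, bestRi = 0;
  for (int ri = 0; ri < nr; ++ri) {
    const std::vector<int>& a = acc[ri];
    for (int y = 0; y < H; ++y) {
      for (int x = 0; x < W; ++x) {
        const int v = a[y * W + x];
        if (v > bestV ||
            (v == bestV && (radii[ri] > radii[bestRi] ||
                            (radii[ri] == radii[bestRi] &&
                             (y < bestY || (y == bestY && x < bestX)))))) {
          bestV = v; bestX = x; bestY = y; bestRi = ri;
        }
      }
    }
  }

  // sub-cell refinement: vote-weighted centroid over a 5x5 center window
  // and +/-1 radius band around the peak
  double sw = 0, sx = 0, sy = 0, sr = 0;
  for (int ri = std::max(0, bestRi - 1); ri <= std::min(nr - 1, bestRi + 1); ++ri) {
    const std::vector<int>& a = acc[ri];
    for (int y = std::max(0, bestY - 2); y <= std::min(H - 1, bestY + 2); ++y) {
      for (int x = std::max(0, bestX - 2); x <= std::min(W - 1, bestX + 2); ++x) {
        const double v = a[y * W + x];
        sw += v; sx += v * x; sy += v * y; sr += v * radii[ri];
      }
    }
  }
  double cxs = bestX, cys = bestY, rs = radii[bestRi];
  if (sw > 0) { cxs = sx / sw; cys = sy / sw; rs = sr / sw; }

  return NumericVector::create(bestX, bestY, (double)radii[bestRi],
                               (double)bestV, cxs, cys, rs);
}

// Contrast map for photorefraction limbus refinement. For every candidate
// center in a (2*window+1)^2 grid around (cx0, cy0), contrast = mean
// intensity over an outer annulus [r, 1.15 r] minus mean over an inner
// annulus [0.85 r, r), both restricted to +/-45 degree arcs around
// horizontal (|dy| <= |dx|). Out-of-image samples are skipped. Cells with
// an empty annulus get NA.
// [[Rcpp::export]]
NumericMatrix cpp_contrast_map(NumericMatrix gray, int cx0, int cy0,
                               double r, int window) {
  const int H = gray.nrow(), W = gray.ncol();
  const double rin = 0.85 * r, rout = 1.15 * r;
  const int span = (int)std::ceil(rout);

  // precompute annulus offsets once
  std::vector<int> odx, ody; std::vector<char> outer;
  for (int dy = -span; dy <= span; ++dy) {
    for (int dx = -span; dx <= span; ++dx) {
      if (std::abs(dy) > std::abs(dx)) continue;  // arc restriction
      const double d = std::sqrt((double)dx * dx + (double)dy * dy);
      if (d >= rin && d < r) { odx.push_back(dx); ody.push_back(dy); outer.push_back(0); }
      else if (d >= r && d <= rout) { odx.push_back(dx); ody.push_back(dy); outer.push_back(1); }
    }
  }

  const int side = 2 * window + 1;
  NumericMatrix out(side, side);  // [row = dy + window, col = dx + window]
  for (int cy = cy0 - window; cy <= cy0 + window; ++cy) {
    for (int cx = cx0 - window; cx <= cx0 + window; ++cx) {
      double si = 0, so = 0; int ni = 0, no = 0;
      for (size_t k = 0; k < odx.size(); ++k) {
        const int x = cx + odx[k], y = cy + ody[k];
        if (x < 0 || x >= W || y < 0 || y >= H) continue;
        if (outer[k]) { so += gray(y, x); ++no; } else { si += gray(y, x); ++ni; }
      }
      out(cy - cy0 + window, cx - cx0 + window) =
        (ni > 0 && no > 0) ? so / no - si / ni : NA_REAL;
    }
  }
  return out;
}

// Connected component labelling of a logical mask (4- or 8-connectivity).
// Returns an integer matrix; 0 = background, components numbered from 1 in
// raster-scan order of their first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask, int conn = 4) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<std::pair<int,int> > stack;
  const int dx4[] = {1, -1, 0, 0}, dy4[] = {0, 0, 1, -1};
  const int dx8[] = {1, -1, 0, 0, 1, 1, -1, -1}, dy8[] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int nn = (conn == 8) ? 8 : 4;
  const int* ddx = (conn == 8) ? dx8 : dx4;
  const int* ddy = (conn == 8) ? dy8 : dy4;
  int next = 0;
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      lab(y, x) = ++next;
      stack.clear();
      stack.push_back(std::make_pair(x, y));
      while (!stack.empty()) {
        const std::pair<int,int> p = stack.back(); stack.pop_back();
        for (int k = 0; k < nn; ++k) {
          const int nx = p.first + ddx[k], ny = p.second + ddy[k];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          if (mask(ny, nx) && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.push_back(std::make_pair(nx, ny));
          }
        }
      }
    }
  }
  return lab;
}
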