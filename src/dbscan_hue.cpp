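#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Circular distance on the hue wheel (range = number of hue units, 180 by
// default under the half-degree convention).
static inline double circ_dist(double a, double b, double range) {
  double d = std::fabs(a - b);
  return d < range - d ? d : range - d;
}

// Hue-adaptive density clustering of image pixels.
//
// Each non-edge pixel's neighbourhood is its 8 adjacent pixels. A pixel with
// at least `min_neighbors` neighbours within circular hue distance <= eps is
// a core pixel (label 2). A non-core pixel adjacent to a core pixel within
// eps is a boundary pixel (label 1) and joins that core's group (first
// qualifying neighbour in fixed raster order -- deterministic tie-break).
// Everything else, and every pixel within `edge_margin` of the border, is an
// outlier (label -1, no group). Group ids are assigned in raster-scan order
// of the first core pixel of each group.
//
// [[Rcpp::export]]
List dbscan_hue_cpp(NumericMatrix hue, double eps, int min_neighbors,
                    int edge_margin, double hue_range) {
  const int H = hue.nrow(), W = hue.ncol();
  IntegerMatrix lab(H, W), grp(H, W);
  std::fill(lab.begin(), lab.end(), -1);
  std::fill(grp.begin(), grp.end(), -1);

  // neighbour offsets in raster order
  const int dy[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  const int y0 = edge_margin, y1 = H - edge_margin;
  const int x0 = edge_margin, x1 = W - edge_margin;
  if (y0 >= y1 || x0 >= x1)
    return List::create(_["labels"] = lab, _["group_ids"] = grp,
                        _["n_groups"] = 0);

  std::vector<char> core((size_t)H * W, 0);
  for (int y = y0; y < y1; ++y) {
    for (int x = x0; x < x1; ++x) {
      int cnt = 0;
      for (int k = 0; k < 8; ++k) {
        const int ny = y + dy[k], nx = x + dx[k];
        if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
        if (circ_dist(hue(y, x), hue(ny, nx), hue_range) <= eps) ++cnt;
      }
      if (cnt >= min_neighbors) core[(size_t)y * W + x] = 1;
    }
  }

  // connect cores: adjacent core pixels within eps belong to one group
  int next_id = 0;
  std::vector<int> stack;
  for (int ys = y0; ys < y1; ++ys) {
    for (int xs = x0; xs < x1; ++xs) {
      if (!core[(size_t)ys * W + xs] || grp(ys, xs) != -1) continue;
      const int id = next_id++;
      grp(ys, xs) = id;
      lab(ys, xs) = 2;
      stack.push_back(ys * W + xs);
      while (!stack.empty()) {
        const int p = stack.back();
        stack.pop_back();
        const int y = p / W, x = p % W;
        for (int k = 0; k < 8; ++k) {
          const int ny = y + dy[k], nx = x + dx[k];
          if (ny < y0 || ny >= y1 || nx < x0 || nx >= x1) continue;
          if (!core[(size_t)ny * W + nx] || grp(ny, nx) != -1) continue;
          if (circ_dist(hue(y, x), hue(ny, nx), hue_range) > eps) continue;
          grp(ny, nx) = id;
          lab(ny, nx) = 2;
          stack.push_back(ny * W + nx);
        }
      }
    }
  }

  // attach boundary pixels to the group of their first in-range core
  for (int y = y0; y < y1; ++y) {
    for (int x = x0; x < x1; ++x) {
      if (core[(size_t)y * W + x]) continue;
      for (int k = 0; k < 8; ++k) {
        const int ny = y + dy[k], nx = x + dx[k];
        if (ny < y0 || ny >= y1 || nx < x0 || nx >= x1) continue;
        if (!core[(size_t)ny * W + nx]) continue;
        if (circ_dist(hue(y, x), hue(ny, nx), hue_range) <= eps) {
          lab(y, x) = 1;
          grp(y, x) = grp(ny, nx);
          break;
        }
      }
    }
  }

  return List::create(_["labels"] = lab, _["group_ids"] = grp,
                      _["n_groups"] = next_id);
}
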