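#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Voxelwise neighborhood statistics inside a spherical offset set.
//
// vol:      3D intensity array (column-major, dims d)
// support:  voxels usable as neighbors (the skull-stripped brain support)
// eval:     voxels at which statistics are computed (the eroded WM mask)
// offsets:  n x 3 integer displacement matrix, centre excluded by caller
//
// Returns rank fraction (neighbors strictly darker than centre / neighbors)
// and percent contrast 100*(mean(neighbors) - centre)/mean(neighbors).
// NA where the neighborhood is empty or its mean is <= 0.
// [[Rcpp::export]]
List cpp_local_stats(NumericVector vol, LogicalVector support,
                     LogicalVector eval, IntegerMatrix offsets,
                     IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = vol.size();
  const int noff = offsets.nrow();
  NumericVector rank(n, NA_REAL), contrast(n, NA_REAL);

  for (int z = 0; z < d3; ++z) {
    for (int y = 0; y < d2; ++y) {
      for (int x = 0; x < d1; ++x) {
        const R_xlen_t idx = x + (R_xlen_t)d1 * (y + (R_xlen_t)d2 * z);
        if (!eval[idx]) continue;
        const double centre = vol[idx];
        int cnt = 0, below = 0;
        double sum = 0.0;
        for (int o = 0; o < noff; ++o) {
          const int xx = x + offsets(o, 0);
          if (xx < 0 || xx >= d1) continue;
          const int yy = y + offsets(o, 1);
          if (yy < 0 || yy >= d2) continue;
          const int zz = z + offsets(o, 2);
          if (zz < 0 || zz >= d3) continue;
          const R_xlen_t j = xx + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * zz);
          if (!support[j]) continue;
          const double v = vol[j];
          sum += v;
          ++cnt;
          if (v < centre) ++below;
        }
        if (cnt == 0) continue;
        rank[idx] = (double)below / (double)cnt;
        const double mean = sum / (double)cnt;
        if (mean > 0) contrast[idx] = 100.0 * (mean - centre) / mean;
      }
    }
  }
  return List::create(_["rank_fraction"] = rank, _["contrast_pct"] = contrast);
}

// Connected-component labeling of a binary mask.
// connectivity: 6 (face) or 26 (corner-to-corner). Labels 1..n in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;

  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start]) continue;
    labels[start] = ++next;
    q.push(start);
    while (!q.empty()) {
      const R_xlen_t cur = q.front(); q.pop();
      const int x = cur % d1;
      const int y = (cur / d1) % d2;
      const int z = cur / ((R_xlen_t)d1 * d2);
      for (int dz = -1; dz <= 1; ++dz) {
        for (int dy = -1; dy <= 1; ++dy) {
          for (int dx = -1; dx <= 1; ++dx) {
            const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
            if (manh == 0) continue;
            if (connectivity == 6 && manh > 1) continue;
            const int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3)
              continue;
            const R_xlen_t j = xx + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * zz);
            if (mask[j] && !labels[j]) { labels[j] = next; q.push(j); }
          }
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}

// Fill interior holes: background voxels (6-connectivity) not reachable from
// the volume border become foreground.
// [[Rcpp::export]]
LogicalVector cpp_fill_holes(LogicalVector mask, IntegerVector dims) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const R_xlen_t n = mask.size();
  std::vector<char> outside(n, 0);
  std::queue<R_xlen_t> q;

  for (int z = 0; z < d3; ++z)
    for (int y = 0; y < d2; ++y)
      for (int x = 0; x < d1; ++x) {
        if (x > 0 && x < d1 - 1 && y > 0 && y < d2 - 1 && z > 0 && z < d3 - 1)
          continue;
        const R_xlen_t idx = x + (R_xlen_t)d1 * (y + (R_xlen_t)d2 * z);
        if (!mask[idx] && !outside[idx]) { outside[idx] = 1; q.push(idx); }
      }

  const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    const R_xlen_t cur = q.front(); q.pop();
    const int x = cur % d1;
    const int y = (cur / d1) % d2;
    const int z = cur / ((R_xlen_t)d1 * d2);
    for (int s = 0; s < 6; ++s) {
      const int xx = x + step[s][0], yy = y + step[s][1], zz = z + step[s][2];
      if (xx < 0 || xx >= d1 || yy < 0 || yy >= d2 || zz < 0 || zz >= d3)
        continue;
      const R_xlen_t j = xx + (R_xlen_t)d1 * (yy + (R_xlen_t)d2 * zz);
      if (!mask[j] && !outside[j]) { outside[j] = 1; q.push(j); }
    }
  }

  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] || !outside[i];
  return out;
}
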