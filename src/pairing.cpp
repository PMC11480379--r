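#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Nearest-neighbour pairing in 3D.  Correctness is defined by exhaustive
// search (ties broken by lowest observed index); nn_pair_cpp accelerates it
// with a uniform-grid spatial index and falls back to the exhaustive scan
// for tiny inputs.  nn_pair_brute_cpp is the plain exhaustive version.

// [[Rcpp::export]]
IntegerVector nn_pair_brute_cpp(NumericMatrix model, NumericMatrix observed) {
  const int nm = model.nrow(), no = observed.nrow();
  IntegerVector out(nm);
  for (int i = 0; i < nm; ++i) {
    const double px = model(i, 0), py = model(i, 1), pz = model(i, 2);
    double best = R_PosInf;
    int bi = 0;
    for (int j = 0; j < no; ++j) {
      const double dx = px - observed(j, 0);
      const double dy = py - observed(j, 1);
      const double dz = pz - observed(j, 2);
      const double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bi = j; }   // strict '<' keeps lowest index
    }
    out[i] = bi + 1;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector nn_pair_cpp(NumericMatrix model, NumericMatrix observed,
                          double cell = 1.5) {
  const int nm = model.nrow(), no = observed.nrow();
  if ((double)nm * no < 250000.0 || no < 32)
    return nn_pair_brute_cpp(model, observed);

  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int j = 0; j < no; ++j)
    for (int k = 0; k < 3; ++k) {
      const double v = observed(j, k);
      if (v < lo[k]) lo[k] = v;
      if (v > hi[k]) hi[k] = v;
    }
  int dims[3];
  for (int k = 0; k < 3; ++k) {
    dims[k] = std::max(1, (int)std::floor((hi[k] - lo[k]) / cell) + 1);
    dims[k] = std::min(dims[k], 512);
  }
  const double csz[3] = {(hi[0] - lo[0]) / dims[0] + 1e-12,
                         (hi[1] - lo[1]) / dims[1] + 1e-12,
                         (hi[2] - lo[2]) / dims[2] + 1e-12};
  const int ncell = dims[0] * dims[1] * dims[2];
  auto cell_of = [&](double x, double y, double z) {
    int ix = (int)((x - lo[0]) / csz[0]);
    int iy = (int)((y - lo[1]) / csz[1]);
    int iz = (int)((z - lo[2]) / csz[2]);
    ix = std::max(0, std::min(dims[0] - 1, ix));
    iy = std::max(0, std::min(dims[1] - 1, iy));
    iz = std::max(0, std::min(dims[2] - 1, iz));
    return ix + dims[0] * (iy + dims[1] * iz);
  };
  // counting sort of observed points into cells (index order preserved,
  // so within-cell scans meet lower indices first)
  std::vector<int> start(ncell + 1, 0), items(no);
  for (int j = 0; j < no; ++j) start[cell_of(observed(j,0), observed(j,1), observed(j,2)) + 1]++;
  for (int c = 0; c < ncell; ++c) start[c + 1] += start[c];
  {
    std::vector<int> fill(start.begin(), start.end() - 1);
    for (int j = 0; j < no; ++j)
      items[fill[cell_of(observed(j,0), observed(j,1), observed(j,2))]++] = j;
  }
  const double hmin = std::min(csz[0], std::min(csz[1], csz[2]));
  IntegerVector out(nm);
  const int rmax = std::max(dims[0], std::max(dims[1], dims[2]));
  for (int i = 0; i < nm; ++i) {
    const double px = model(i, 0), py = model(i, 1), pz = model(i, 2);
    int ix = (int)std::floor((px - lo[0]) / csz[0]);
    int iy = (int)std::floor((py - lo[1]) / csz[1]);
    int iz = (int)std::floor((pz - lo[2]) / csz[2]);
    double best = R_PosInf;
    int bi = -1;
    if (ix < 0 || ix >= dims[0] || iy < 0 || iy >= dims[1] ||
        iz < 0 || iz >= dims[2]) {
      // outside the observed bounding box: the shell lower bound does not
      // hold, use the exhaustive scan for this point
      for (int j = 0; j < no; ++j) {
        const double dx = px - observed(j, 0);
        const double dy = py - observed(j, 1);
        const double dz = pz - observed(j, 2);
        const double d = dx * dx + dy * dy + dz * dz;
        if (d < best) { best = d; bi = j; }
      }
      out[i] = bi + 1;
      continue;
    }
    for (int r = 0; r <= rmax; ++r) {
      if (bi >= 0) {
        const double dmin = (r - 1) * hmin;   // safe lower bound for shell r
        if (dmin > 0 && dmin * dmin > best) break;
      }
      const int x0 = std::max(0, ix - r), x1 = std::min(dims[0] - 1, ix + r);
      const int y0 = std::max(0, iy - r), y1 = std::min(dims[1] - 1, iy + r);
      const int z0 = std::max(0, iz - r), z1 = std::min(dims[2] - 1, iz + r);
      for (int cz = z0; cz <= z1; ++cz)
        for (int cy = y0; cy <= y1; ++cy)
          for (int cx = x0; cx <= x1; ++cx) {
            // only the shell at Chebyshev radius r (inner cells already done)
            if (std::max(std::abs(cx - ix),
                         std::max(std::abs(cy - iy), std::abs(cz - iz))) != r)
              continue;
            const int c = cx + dims[0] * (cy + dims[1] * cz);
            for (int s = start[c]; s < start[c + 1]; ++s) {
              const int j = items[s];
              const double dx = px - observed(j, 0);
              const double dy = py - observed(j, 1);
              const double dz = pz - observed(j, 2);
              const double d = dx * dx + dy * dy + dz * dz;
              if (d < best || (d == best && j < bi)) { best = d; bi = j; }
            }
          }
    }
    out[i] = bi + 1;
  }
  return out;
}
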