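#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Voxel convention: 0-based integer voxel v spans the half-open cube
// [v, v+1)^3 in continuous voxel coordinates; linear index x + nx*(y + ny*z).

static int build_offsets(const int* dim, int connectivity, int* offs,
                         int (*deltas)[3]) {
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int ord = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (ord == 0) continue;
        if (connectivity == 6 && ord > 1) continue;
        if (connectivity == 18 && ord > 2) continue;
        deltas[n][0] = dx; deltas[n][1] = dy; deltas[n][2] = dz;
        offs[n] = dx + dim[0] * (dy + dim[1] * dz);
        ++n;
      }
  return n;
}

// Label the foreground of a binary volume into connected components.
// Returns integer labels 1..k (0 = background).
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector vol, IntegerVector dim,
                           int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  if (vol.size() != n) stop("volume length does not match dim");
  int offs[26], deltas[26][3];
  int noff = build_offsets(d, connectivity, offs, deltas);

  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!vol[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.clear();
    stack.push_back((int)i);
    while (!stack.empty()) {
      int cur = stack.back();
      stack.pop_back();
      int cx = cur % d[0], cy = (cur / d[0]) % d[1], cz = cur / (d[0] * d[1]);
      for (int k = 0; k < noff; ++k) {
        int nx = cx + deltas[k][0], ny = cy + deltas[k][1],
            nz = cz + deltas[k][2];
        if (nx < 0 || ny < 0 || nz < 0 || nx >= d[0] || ny >= d[1] ||
            nz >= d[2])
          continue;
        int j = cur + offs[k];
        if (vol[j] && lab[j] == 0) {
          lab[j] = next;
          stack.push_back(j);
        }
      }
    }
  }
  return lab;
}

// Threshold-free cluster enhancement of the positive part of a statistic map:
// TFCE(p) = sum over h = dh, 2dh, ... <= max(stat) of e_h(p)^E * h^H * dh,
// where e_h(p) is the voxel count of the connected component containing p in
// the supra-threshold set {stat >= h}.
// [[Rcpp::export(name = ".tfce_cpp")]]
NumericVector tfce_cpp(NumericVector stat, IntegerVector dim, double H,
                       double E, double dh, int connectivity) {
  if (dim.size() != 3) stop("dim must have length 3");
  if (!(dh > 0)) stop("dh must be positive");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  if (stat.size() != n) stop("volume length does not match dim");
  NumericVector out(n, 0.0);
  double mx = 0.0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!R_finite(stat[i])) stop("statistic map must be finite");
    if (stat[i] > mx) mx = stat[i];
  }
  if (mx <= 0.0) return out;
  int K = (int)std::floor(mx / dh + 1e-9);
  if (K < 1) return out;

  int offs[26], deltas[26][3];
  int noff = build_offsets(d, connectivity, offs, deltas);
  std::vector<int> lab(n, 0);
  std::vector<int> stack;
  std::vector<double> csize;

  // voxels that can ever be supra-threshold, in index order; the supra set
  // at threshold h is always a subset of this list
  std::vector<int> active;
  for (R_xlen_t i = 0; i < n; ++i)
    if (stat[i] >= dh) active.push_back((int)i);

  for (int k = 1; k <= K; ++k) {
    double h = k * dh;
    for (size_t a = 0; a < active.size(); ++a) lab[active[a]] = 0;
    csize.clear();
    csize.push_back(0.0); // label 0 unused
    int next = 0;
    for (size_t a = 0; a < active.size(); ++a) {
      int i = active[a];
      if (stat[i] < h || lab[i] != 0) continue;
      ++next;
      csize.push_back(0.0);
      lab[i] = next;
      csize[next] += 1.0;
      stack.clear();
      stack.push_back(i);
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int cx = cur % d[0], cy = (cur / d[0]) % d[1],
            cz = cur / (d[0] * d[1]);
        for (int m = 0; m < noff; ++m) {
          int nx = cx + deltas[m][0], ny = cy + deltas[m][1],
              nz = cz + deltas[m][2];
          if (nx < 0 || ny < 0 || nz < 0 || nx >= d[0] || ny >= d[1] ||
              nz >= d[2])
            continue;
          int j = cur + offs[m];
          if (stat[j] >= h && lab[j] == 0) {
            lab[j] = next;
            csize[next] += 1.0;
            stack.push_back(j);
          }
        }
      }
    }
    double hH = std::pow(h, H);
    for (size_t a = 0; a < active.size(); ++a) {
      int i = active[a];
      if (lab[i] != 0) out[i] += std::pow(csize[lab[i]], E) * hH * dh;
    }
    // drop voxels that fell below the next threshold
    size_t w = 0;
    for (size_t a = 0; a < active.size(); ++a)
      if (stat[active[a]] >= (k + 1) * dh) active[w++] = active[a];
    active.resize(w);
  }
  return out;
}

// Digital-line walk (Amanatides & Woo) of the segment a->b, pushing every
// voxel the segment passes through. Voxels outside the grid are skipped but
// traversal continues.
static void walk_segment(const double* a, const double* b, const int* d,
                         std::vector<int>& out) {
  double dir[3];
  int v[3], ve[3], step[3];
  double tMax[3], tDelta[3];
  const double INF = std::numeric_limits<double>::infinity();
  int span = 0;
  for (int i = 0; i < 3; ++i) {
    dir[i] = b[i] - a[i];
    v[i] = (int)std::floor(a[i]);
    ve[i] = (int)std::floor(b[i]);
    span += std::abs(ve[i] - v[i]);
    if (dir[i] > 0) {
      step[i] = 1;
      tMax[i] = ((v[i] + 1) - a[i]) / dir[i];
      tDelta[i] = 1.0 / dir[i];
    } else if (dir[i] < 0) {
      step[i] = -1;
      tMax[i] = (v[i] - a[i]) / dir[i];
      tDelta[i] = -1.0 / dir[i];
    } else {
      step[i] = 0;
      tMax[i] = INF;
      tDelta[i] = INF;
    }
  }
  int maxit = span + 3;
  for (int it = 0;; ++it) {
    if (v[0] >= 0 && v[1] >= 0 && v[2] >= 0 && v[0] < d[0] && v[1] < d[1] &&
        v[2] < d[2])
      out.push_back(v[0] + d[0] * (v[1] + d[1] * v[2]));
    if ((v[0] == ve[0] && v[1] == ve[1] && v[2] == ve[2]) || it >= maxit)
      break;
    int m = 0;
    if (tMax[1] < tMax[m]) m = 1;
    if (tMax[2] < tMax[m]) m = 2;
    v[m] += step[m];
    tMax[m] += tDelta[m];
  }
}

// Binary visitation volume of a set of streamlines (list of n-by-3 matrices
// of continuous voxel coordinates).
// [[Rcpp::export(name = ".sl_visit_cpp")]]
LogicalVector sl_visit_cpp(List streamlines, IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  LogicalVector vis(n, false);
  std::vector<int> buf;
  for (R_xlen_t s = 0; s < streamlines.size(); ++s) {
    NumericMatrix pts = streamlines[s];
    if (pts.ncol() != 3) stop("streamline points must be n-by-3");
    int np = pts.nrow();
    double a[3], b[3];
    for (int i = 0; i + 1 < np; ++i) {
      for (int c = 0; c < 3; ++c) {
        a[c] = pts(i, c);
        b[c] = pts(i + 1, c);
      }
      buf.clear();
      walk_segment(a, b, d, buf);
      for (size_t k = 0; k < buf.size(); ++k) vis[buf[k]] = true;
    }
  }
  return vis;
}

// For each streamline, TRUE iff any of its segments passes through a TRUE
// voxel of the mask.
// [[Rcpp::export(name = ".sl_select_cpp")]]
LogicalVector sl_select_cpp(List streamlines, LogicalVector mask,
                            IntegerVector dim) {
  if (dim.size() != 3) stop("dim must have length 3");
  int d[3] = {dim[0], dim[1], dim[2]};
  R_xlen_t n = (R_xlen_t)d[0] * d[1] * d[2];
  if (mask.size() != n) stop("mask length does not match dim");
  LogicalVector sel(streamlines.size(), false);
  std::vector<int> buf;
  for (R_xlen_t s = 0; s < streamlines.size(); ++s) {
    NumericMatrix pts = streamlines[s];
    if (pts.ncol() != 3) stop("streamline points must be n-by-3");
    int np = pts.nrow();
    double a[3], b[3];
    bool hit = false;
    for (int i = 0; i + 1 < np && !hit; ++i) {
      for (int c = 0; c < 3; ++c) {
        a[c] = pts(i, c);
        b[c] = pts(i + 1, c);
      }
      buf.clear();
      walk_segment(a, b, d, buf);
      for (size_t k = 0; k < buf.size(); ++k)
        if (mask[buf[k]]) {
          hit = true;
          break;
        }
    }
    sel[s] = hit;
  }
  return sel;
}
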