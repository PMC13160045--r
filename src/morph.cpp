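#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Shared low-level raster primitives. Conventions used throughout:
//  - matrices are indexed [row, col] = [y, x];
//  - "raster order" ties are broken by R's column-major linear index;
//  - neighborhoods are 8-connected unless stated otherwise.

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// 8-connected component labeling of a logical image. Background (FALSE/NA)
// is 0; labels are assigned in raster order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (m(r, c) != TRUE || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = rr + DR8[k], c2 = cc + DC8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (m(r2, c2) == TRUE && lab(r2, c2) == 0) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

// Sliding-window minimum (monotonic deque) along each column with window
// half-height h, border-clipped.
static void col_min_filter(const NumericMatrix &img, NumericMatrix &out,
                           int h, bool use_max) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> dq(nr + 1);
  for (int c = 0; c < nc; ++c) {
    int head = 0, tail = 0;
    // prime the window with rows [0, h]
    for (int rr = 0; rr <= std::min(h, nr - 1); ++rr) {
      double v = img(rr, c);
      while (tail > head) {
        double back = img(dq[tail - 1], c);
        if (use_max ? (back <= v) : (back >= v)) --tail; else break;
      }
      dq[tail++] = rr;
    }
    for (int r = 0; r < nr; ++r) {
      if (r > 0) {
        int incoming = r + h;
        if (incoming < nr) {
          double v = img(incoming, c);
          while (tail > head) {
            double back = img(dq[tail - 1], c);
            if (use_max ? (back <= v) : (back >= v)) --tail; else break;
          }
          dq[tail++] = incoming;
        }
      }
      while (head < tail && dq[head] < r - h) ++head;
      out(r, c) = img(dq[head], c);
    }
  }
}

// Flat grayscale erosion/dilation with a Euclidean disc of radius r,
// decomposed into per-column sliding windows (one pass per distinct disc
// half-height) followed by a horizontal combine. Border-clipped, exact.
static NumericMatrix disc_morph(NumericMatrix img, int r, bool use_max) {
  int nr = img.nrow(), nc = img.ncol();
  std::vector<int> hy(r + 1);
  for (int dx = 0; dx <= r; ++dx)
    hy[dx] = (int)std::floor(std::sqrt((double)r * r - (double)dx * dx));
  // distinct heights
  std::vector<int> heights(hy);
  std::sort(heights.begin(), heights.end());
  heights.erase(std::unique(heights.begin(), heights.end()), heights.end());
  std::map<int, NumericMatrix> vert;
  for (size_t i = 0; i < heights.size(); ++i) {
    NumericMatrix v(nr, nc);
    col_min_filter(img, v, heights[i], use_max);
    vert[heights[i]] = v;
  }
  NumericMatrix out(nr, nc);
  double init = use_max ? R_NegInf : R_PosInf;
  std::fill(out.begin(), out.end(), init);
  for (int dx = -r; dx <= r; ++dx) {
    NumericMatrix &v = vert[hy[std::abs(dx)]];
    int c0 = std::max(0, -dx), c1 = std::min(nc, nc - dx);
    for (int c = c0; c < c1; ++c) {
      for (int rr = 0; rr < nr; ++rr) {
        double x = v(rr, c + dx);
        if (use_max ? (x > out(rr, c)) : (x < out(rr, c))) out(rr, c) = x;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_disc_erode(NumericMatrix img, int r) {
  return disc_morph(img, r, false);
}

// [[Rcpp::export]]
NumericMatrix cpp_disc_dilate(NumericMatrix img, int r) {
  return disc_morph(img, r, true);
}

struct SrgEntry {
  double value;
  int label;
  int idx;  // column-major linear index of the pixel
};
struct SrgCompare {
  bool operator()(const SrgEntry &a, const SrgEntry &b) const {
    if (a.value != b.value) return a.value > b.value;
    if (a.label != b.label) return a.label > b.label;
    return a.idx > b.idx;
  }
};

// Seeded region growing. Seeds are positive labels in `seeds`; growth is
// restricted to `mask`, proceeds in ascending image intensity and uses the
// deterministic tie-break (intensity, label id, raster order). All mask
// pixels reachable from a seed are labeled on return.
// [[Rcpp::export]]
IntegerMatrix cpp_srg(NumericMatrix img, IntegerMatrix seeds,
                      LogicalMatrix mask) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<SrgEntry, std::vector<SrgEntry>, SrgCompare> q;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c) == TRUE) lab(r, c) = seeds(r, c);
  // enqueue unlabeled mask neighbors of every seed pixel
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) == 0) continue;
      for (int k = 0; k < 8; ++k) {
        int r2 = r + DR8[k], c2 = c + DC8[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (mask(r2, c2) == TRUE && lab(r2, c2) == 0) {
          SrgEntry e = {img(r2, c2), lab(r, c), r2 + c2 * nr};
          q.push(e);
        }
      }
    }
  }
  while (!q.empty()) {
    SrgEntry e = q.top();
    q.pop();
    int r = e.idx % nr, c = e.idx / nr;
    if (lab(r, c) != 0) continue;  // stale entry
    lab(r, c) = e.label;
    for (int k = 0; k < 8; ++k) {
      int r2 = r + DR8[k], c2 = c + DC8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (mask(r2, c2) == TRUE && lab(r2, c2) == 0) {
        SrgEntry e2 = {img(r2, c2), e.label, r2 + c2 * nr};
        q.push(e2);
      }
    }
  }
  return lab;
}

// Morphological reconstruction by erosion of `marker` over `ref`
// (marker >= ref pointwise), restricted to `mask`. Used for the h-minima
// transform: reconstruct (img + h) over img, then take regional minima.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_erode(NumericMatrix marker, NumericMatrix ref,
                                    LogicalMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J = clone(marker);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (mask(r, c) != TRUE) J(r, c) = R_PosInf;
  bool changed = true;
  while (changed) {
    changed = false;
    // forward raster sweep
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        if (mask(r, c) != TRUE) continue;
        double v = J(r, c);
        for (int k = 0; k < 8; ++k) {
          int r2 = r + DR8[k], c2 = c + DC8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (J(r2, c2) < v) v = J(r2, c2);
        }
        if (v < ref(r, c)) v = ref(r, c);
        if (v < J(r, c)) { J(r, c) = v; changed = true; }
      }
    }
    // backward sweep
    for (int c = nc - 1; c >= 0; --c) {
      for (int r = nr - 1; r >= 0; --r) {
        if (mask(r, c) != TRUE) continue;
        double v = J(r, c);
        for (int k = 0; k < 8; ++k) {
          int r2 = r + DR8[k], c2 = c + DC8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (J(r2, c2) < v) v = J(r2, c2);
        }
        if (v < ref(r, c)) v = ref(r, c);
        if (v < J(r, c)) { J(r, c) = v; changed = true; }
      }
    }
  }
  return J;
}

// Regional minima within a mask: 8-connected plateaus of constant value with
// no strictly lower 8-neighbor inside the mask. Returns plateau labels
// (0 elsewhere), numbered in raster order of discovery.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_minima(NumericMatrix img, LogicalMatrix mask) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix lab(nr, nc);
  IntegerMatrix visited(nr, nc);
  int next = 0;
  std::vector<int> comp, stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) != TRUE || visited(r, c)) continue;
      double v = img(r, c);
      bool is_min = true;
      comp.clear();
      stack.clear();
      stack.push_back(r + c * nr);
      visited(r, c) = 1;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        comp.push_back(idx);
        int rr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = rr + DR8[k], c2 = cc + DC8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) != TRUE) continue;
          double v2 = img(r2, c2);
          if (v2 == v) {
            if (!visited(r2, c2)) {
              visited(r2, c2) = 1;
              stack.push_back(r2 + c2 * nr);
            }
          } else if (v2 < v) {
            is_min = false;
          }
        }
      }
      if (is_min) {
        ++next;
        for (size_t i = 0; i < comp.size(); ++i)
          lab(comp[i] % nr, comp[i] / nr) = next;
      }
    }
  }
  return lab;
}
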