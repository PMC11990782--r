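// Keypoint primitives for camera motion compensation: FAST-9 corner
// detection, BRIEF-256 binary descriptors on a box-smoothed image, and
// brute-force 2-NN Hamming matching with Lowe's ratio test.
//
// Images arrive as R numeric matrices (rows = y, cols = x, values in
// [0, 255]); keypoint coordinates returned are 0-based (x, y) to match
// the package's internal pixel convention.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 16-pixel Bresenham circle of radius 3 around the candidate
static const int CIRC_DX[16] = {0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1};
static const int CIRC_DY[16] = {-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3};

struct KP { int x; int y; double score; };

// Does the circle contain >= 9 contiguous pixels all brighter than
// c + t or all darker than c - t?
static bool fast9_test(const double *img, int nrow, int ncol,
                       int x, int y, double t, double *score_out) {
  double c = img[y + (size_t)x * nrow];
  int state[16]; // 1 bright, -1 dark, 0 neither
  double absdiff[16];
  for (int k = 0; k < 16; ++k) {
    double p = img[(y + CIRC_DY[k]) + (size_t)(x + CIRC_DX[k]) * nrow];
    double d = p - c;
    absdiff[k] = std::fabs(d);
    state[k] = (d > t) ? 1 : (d < -t ? -1 : 0);
  }
  for (int sgn = -1; sgn <= 1; sgn += 2) {
    int run = 0, best = 0;
    for (int k = 0; k < 32; ++k) { // doubled for wrap-around
      if (state[k & 15] == sgn) { if (++run > best) best = run; }
      else run = 0;
      if (best >= 9) break;
    }
    if (best >= 9) {
      double s = 0;
      for (int k = 0; k < 16; ++k)
        if (state[k] == sgn) s += absdiff[k] - t;
      *score_out = s;
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
IntegerMatrix fast_corners_cpp(NumericMatrix img, LogicalMatrix mask,
                               double threshold, int max_keypoints) {
  int nrow = img.nrow(), ncol = img.ncol();
  const double *p = img.begin();
  NumericMatrix scores(nrow, ncol);
  std::vector<KP> kps;
  for (int x = 3; x < ncol - 3; ++x) {
    for (int y = 3; y < nrow - 3; ++y) {
      if (!mask(y, x)) continue;
      double s;
      if (fast9_test(p, nrow, ncol, x, y, threshold, &s))
        scores(y, x) = s;
    }
  }
  // 3x3 non-maximum suppression
  for (int x = 3; x < ncol - 3; ++x) {
    for (int y = 3; y < nrow - 3; ++y) {
      double s = scores(y, x);
      if (s <= 0) continue;
      bool is_max = true;
      for (int dx = -1; dx <= 1 && is_max; ++dx)
        for (int dy = -1; dy <= 1; ++dy) {
          if (dx == 0 && dy == 0) continue;
          double sn = scores(y + dy, x + dx);
          if (sn > s || (sn == s && (dx < 0 || (dx == 0 && dy < 0)))) {
            is_max = false; break;
          }
        }
      if (is_max) kps.push_back({x, y, s});
    }
  }
  std::sort(kps.begin(), kps.end(), [](const KP &a, const KP &b) {
    if (a.score != b.score) return a.score > b.score;
    if (a.x != b.x) return a.x < b.x;
    return a.y < b.y;
  });
  int n = std::min((int)kps.size(), max_keypoints);
  IntegerMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = kps[i].x; out(i, 1) = kps[i].y; }
  return out;
}

// 5x5 box blur with edge clamping (the smoothing BRIEF assumes)
// [[Rcpp::export]]
NumericMatrix box_blur5_cpp(NumericMatrix img) {
  int nrow = img.nrow(), ncol = img.ncol();
  NumericMatrix out(nrow, ncol);
  for (int x = 0; x < ncol; ++x) {
    for (int y = 0; y < nrow; ++y) {
      double s = 0;
      for (int dx = -2; dx <= 2; ++dx)
        for (int dy = -2; dy <= 2; ++dy) {
          int xx = std::min(std::max(x + dx, 0), ncol - 1);
          int yy = std::min(std::max(y + dy, 0), nrow - 1);
          s += img(yy, xx);
        }
      out(y, x) = s / 25.0;
    }
  }
  return out;
}

// Fixed BRIEF-256 sampling pattern inside a 25x25 window, generated once
// from a compiled-in LCG so descriptors are identical across runs.
static void brief_pattern(int *ax, int *ay, int *bx, int *by) {
  uint32_t s = 123456789u;
  auto nxt = [&s]() { s = 1103515245u * s + 12345u; return (s >> 8) % 25; };
  for (int i = 0; i < 256; ++i) {
    ax[i] = (int)nxt() - 12; ay[i] = (int)nxt() - 12;
    bx[i] = (int)nxt() - 12; by[i] = (int)nxt() - 12;
  }
}

// [[Rcpp::export]]
List brief_descriptors_cpp(NumericMatrix smoothed, IntegerMatrix keypoints) {
  static int ax[256], ay[256], bx[256], by[256];
  static bool init = false;
  if (!init) { brief_pattern(ax, ay, bx, by); init = true; }
  int nrow = smoothed.nrow(), ncol = smoothed.ncol();
  int n = keypoints.nrow();
  std::vector<int> keep;
  for (int i = 0; i < n; ++i) {
    int x = keypoints(i, 0), y = keypoints(i, 1);
    if (x >= 12 && x < ncol - 12 && y >= 12 && y < nrow - 12) keep.push_back(i);
  }
  int m = (int)keep.size();
  IntegerMatrix desc(m, 8); // 256 bits packed into 8 words
  IntegerMatrix pts(m, 2);
  for (int r = 0; r < m; ++r) {
    int i = keep[r];
    int x = keypoints(i, 0), y = keypoints(i, 1);
    pts(r, 0) = x; pts(r, 1) = y;
    for (int w = 0; w < 8; ++w) {
      uint32_t word = 0;
      for (int b = 0; b < 32; ++b) {
        int k = w * 32 + b;
        double pa = smoothed(y + ay[k], x + ax[k]);
        double pb = smoothed(y + by[k], x + bx[k]);
        if (pa < pb) word |= (1u << b);
      }
      desc(r, w) = (int32_t)word;
    }
  }
  return List::create(Named("points") = pts, Named("descriptors") = desc);
}

static inline int hamming8(const int *a, const int *b) {
  int d = 0;
  for (int w = 0; w < 8; ++w) {
    uint32_t x = (uint32_t)a[w] ^ (uint32_t)b[w];
    // portable popcount
    x = x - ((x >> 1) & 0x55555555u);
    x = (x & 0x33333333u) + ((x >> 2) & 0x33333333u);
    d += (int)((((x + (x >> 4)) & 0x0F0F0F0Fu) * 0x01010101u) >> 24);
  }
  return d;
}

// 2-NN Hamming matching with Lowe ratio filter; returns 1-based index
// pairs (i in desc1, j in desc2).
// [[Rcpp::export]]
IntegerMatrix match_knn_cpp(IntegerMatrix desc1, IntegerMatrix desc2,
                            double ratio) {
  int n1 = desc1.nrow(), n2 = desc2.nrow();
  std::vector<std::pair<int, int>> pairs;
  if (n1 == 0 || n2 == 0) return IntegerMatrix(0, 2);
  std::vector<int> d1(8), d2row(8);
  for (int i = 0; i < n1; ++i) {
    int best = 1 << 30, second = 1 << 30, bj = -1;
    for (int w = 0; w < 8; ++w) d1[w] = desc1(i, w);
    for (int j = 0; j < n2; ++j) {
      for (int w = 0; w < 8; ++w) d2row[w] = desc2(j, w);
      int d = hamming8(d1.data(), d2row.data());
      if (d < best) { second = best; best = d; bj = j; }
      else if (d < second) second = d;
    }
    if (bj >= 0 && (n2 == 1 || best < ratio * second)) {
      pairs.push_back({i + 1, bj + 1});
    }
  }
  IntegerMatrix out((int)pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first; out(k, 1) = pairs[k].second;
  }
  return out;
}
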