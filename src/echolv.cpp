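#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pixels are addressed (row, col), 0-based internally.  "Raster order"
// throughout means rows outer, columns inner, i.e. image rows scanned
// top to bottom.  All neighbourhoods are 8-connected.

static const int DR[8] = { -1, -1, -1,  0, 0,  1, 1, 1 };
static const int DC[8] = { -1,  0,  1, -1, 1, -1, 0, 1 };

struct QItem {
  double value;
  long long seq;   // FIFO tie-break: lower seq popped first on equal value
  int idx;
};

struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.value != b.value) return a.value > b.value;
    return a.seq > b.seq;
  }
};

// Marker-controlled watershed by immersion (Meyer's flooding with
// explicit dam pixels).  markers: 0 = unlabeled, k >= 1 = seed label.
// Output: basin labels; 0 marks dam (watershed line) pixels and any
// pixel left unreachable because it is fully enclosed by dams.
// Ties in flooding order are broken first-in-first-out, with the
// initial frontier enqueued in raster order.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(NumericMatrix img, IntegerMatrix markers) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  std::vector<char> queued((size_t) H * W, 0);
  std::vector<char> dam((size_t) H * W, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long seq = 0;

  for (int r = 0; r < H; r++)
    for (int c = 0; c < W; c++)
      lab(r, c) = markers(r, c);

  // initial frontier: unlabeled pixels 8-adjacent to a marker
  for (int r = 0; r < H; r++) {
    for (int c = 0; c < W; c++) {
      if (lab(r, c) != 0) continue;
      bool front = false;
      for (int k = 0; k < 8 && !front; k++) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr >= 0 && rr < H && cc >= 0 && cc < W && lab(rr, cc) > 0)
          front = true;
      }
      if (front) {
        pq.push(QItem{ img(r, c), seq++, r * W + c });
        queued[(size_t) (r * W + c)] = 1;
      }
    }
  }

  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    int r = it.idx / W, c = it.idx % W;
    if (lab(r, c) != 0 || dam[(size_t) it.idx]) continue;
    int found = 0;  // single neighbouring basin label, if unique
    bool multi = false;
    for (int k = 0; k < 8; k++) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      int l = lab(rr, cc);
      if (l > 0) {
        if (found == 0) found = l;
        else if (l != found) { multi = true; break; }
      }
    }
    if (multi) {
      dam[(size_t) it.idx] = 1;           // dam: basins must not merge
    } else if (found > 0) {
      lab(r, c) = found;
      for (int k = 0; k < 8; k++) {
        int rr = r + DR[k], cc = c + DC[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        int j = rr * W + cc;
        if (lab(rr, cc) == 0 && !queued[(size_t) j] && !dam[(size_t) j]) {
          pq.push(QItem{ img(rr, cc), seq++, j });
          queued[(size_t) j] = 1;
        }
      }
    }
    // found == 0 cannot occur: a pixel is only queued from a basin
    // neighbour, and basin labels are never retracted.
  }
  return lab;
}

// Morphological reconstruction by dilation (hybrid raster/queue
// algorithm): largest image <= mask whose value at each pixel is
// reachable from marker by 8-connected geodesic dilation.
// Requires marker <= mask elementwise.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_dilation(NumericMatrix marker, NumericMatrix mask) {
  int H = marker.nrow(), W = marker.ncol();
  NumericMatrix J(clone(marker));
  // forward raster pass
  for (int r = 0; r < H; r++) {
    for (int c = 0; c < W; c++) {
      double m = J(r, c);
      static const int FR[4] = { -1, -1, -1, 0 };
      static const int FC[4] = { -1,  0,  1, -1 };
      for (int k = 0; k < 4; k++) {
        int rr = r + FR[k], cc = c + FC[k];
        if (rr >= 0 && rr < H && cc >= 0 && cc < W && J(rr, cc) > m)
          m = J(rr, cc);
      }
      if (m > mask(r, c)) m = mask(r, c);
      J(r, c) = m;
    }
  }
  // backward raster pass + queue seeding
  std::queue<int> fifo;
  for (int r = H - 1; r >= 0; r--) {
    for (int c = W - 1; c >= 0; c--) {
      double m = J(r, c);
      static const int BR[4] = { 1, 1, 1, 0 };
      static const int BC[4] = { -1, 0, 1, 1 };
      for (int k = 0; k < 4; k++) {
        int rr = r + BR[k], cc = c + BC[k];
        if (rr >= 0 && rr < H && cc >= 0 && cc < W && J(rr, cc) > m)
          m = J(rr, cc);
      }
      if (m > mask(r, c)) m = mask(r, c);
      J(r, c) = m;
      for (int k = 0; k < 4; k++) {
        int rr = r + BR[k], cc = c + BC[k];
        if (rr >= 0 && rr < H && cc >= 0 && cc < W &&
            J(rr, cc) < J(r, c) && J(rr, cc) < mask(rr, cc)) {
          fifo.push(r * W + c);
          k = 4;
        }
      }
    }
  }
  while (!fifo.empty()) {
    int idx = fifo.front(); fifo.pop();
    int r = idx / W, c = idx % W;
    for (int k = 0; k < 8; k++) {
      int rr = r + DR[k], cc = c + DC[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (J(rr, cc) < J(r, c) && mask(rr, cc) != J(rr, cc)) {
        double v = J(r, c) < mask(rr, cc) ? J(r, c) : mask(rr, cc);
        if (v > J(rr, cc)) {
          J(rr, cc) = v;
          fifo.push(rr * W + cc);
        }
      }
    }
  }
  return J;
}

// Regional minima: 8-connected plateaus with no lower 8-neighbour.
// Returns 0/1 mask.
// [[Rcpp::export]]
IntegerMatrix cpp_regional_minima(NumericMatrix img) {
  int H = img.nrow(), W = img.ncol();
  IntegerMatrix out(H, W);
  std::vector<char> visited((size_t) H * W, 0);
  std::vector<int> comp;
  for (int r0 = 0; r0 < H; r0++) {
    for (int c0 = 0; c0 < W; c0++) {
      int i0 = r0 * W + c0;
      if (visited[(size_t) i0]) continue;
      double v = img(r0, c0);
      comp.clear();
      std::queue<int> q;
      q.push(i0);
      visited[(size_t) i0] = 1;
      bool is_min = true;
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        comp.push_back(idx);
        int r = idx / W, c = idx % W;
        for (int k = 0; k < 8; k++) {
          int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          double u = img(rr, cc);
          if (u < v) { is_min = false; continue; }
          if (u == v) {
            int j = rr * W + cc;
            if (!visited[(size_t) j]) { visited[(size_t) j] = 1; q.push(j); }
          }
        }
      }
      if (is_min)
        for (size_t k = 0; k < comp.size(); k++)
          out(comp[k] / W, comp[k] % W) = 1;
    }
  }
  return out;
}

// 8-connected component labelling of a 0/1 mask; labels 1..K assigned
// in raster order of each component's first pixel.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<int> q;
  for (int r0 = 0; r0 < H; r0++) {
    for (int c0 = 0; c0 < W; c0++) {
      if (mask(r0, c0) == 0 || lab(r0, c0) != 0) continue;
      next++;
      lab(r0, c0) = next;
      q.push(r0 * W + c0);
      while (!q.empty()) {
        int idx = q.front(); q.pop();
        int r = idx / W, c = idx % W;
        for (int k = 0; k < 8; k++) {
          int rr = r + DR[k], cc = c + DC[k];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(rr * W + cc);
          }
        }
      }
    }
  }
  return lab;
}

// 2D convolution with reflective (mirror) border handling.
// Kernel dimensions must be odd.
// [[Rcpp::export]]
NumericMatrix cpp_convolve_reflect(NumericMatrix img, NumericMatrix kernel) {
  int H = img.nrow(), W = img.ncol();
  int kh = kernel.nrow(), kw = kernel.ncol();
  int rh = kh / 2, rw = kw / 2;
  NumericMatrix out(H, W);
  for (int r = 0; r < H; r++) {
    for (int c = 0; c < W; c++) {
      double s = 0.0;
      for (int i = -rh; i <= rh; i++) {
        int rr = r + i;
        if (rr < 0) rr = -rr - 1;           // mirror without edge repeat
        else if (rr >= H) rr = 2 * H - rr - 1;
        for (int j = -rw; j <= rw; j++) {
          int cc = c + j;
          if (cc < 0) cc = -cc - 1;
          else if (cc >= W) cc = 2 * W - cc - 1;
          s += img(rr, cc) * kernel(rh - i, rw - j);
        }
      }
      out(r, c) = s;
    }
  }
  return out;
}
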