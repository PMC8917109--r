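#include <Rcpp.h>
using namespace Rcpp;

// Connected-component labeling on a logical mask.
// connectivity: 8 (edges or corners adjacent) or 4 (edges only).
// Labels are assigned in raster-scan order (row-major over [row, col])
// of each component's first pixel, starting at 1.
// [[Rcpp::export]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity) {
  const int h = mask.nrow(), w = mask.ncol();
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  IntegerMatrix labels(h, w);
  std::vector<int> qr(static_cast<size_t>(h) * w), qc(qr.size());

  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {-1, 1, 0, 0};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = connectivity;

  int next = 0;
  // raster scan: rows outer so the first pixel of each component is the
  // top-most, then left-most, foreground pixel not yet labeled
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) {
      if (!mask(i, j) || labels(i, j) != 0) continue;
      ++next;
      int head = 0, tail = 0;
      qr[tail] = i; qc[tail] = j; ++tail;
      labels(i, j) = next;
      while (head < tail) {
        int r = qr[head], c = qc[head]; ++head;
        for (int k = 0; k < nn; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= h || cc < 0 || cc >= w) continue;
          if (mask(rr, cc) && labels(rr, cc) == 0) {
            labels(rr, cc) = next;
            qr[tail] = rr; qc[tail] = cc; ++tail;
          }
        }
      }
    }
  }
  return labels;
}

// Circular Hough vote accumulation for one radius. Edge pixel coordinates
// are 1-based (row, col); offsets is a k x 2 integer matrix of (drow, dcol)
// positions on the circle perimeter of the given radius. Returns the vote
// count per candidate center.
// [[Rcpp::export]]
IntegerMatrix hough_votes(const IntegerVector& edge_row,
                          const IntegerVector& edge_col,
                          int h, int w,
                          const IntegerMatrix& offsets) {
  IntegerMatrix acc(h, w);
  const int n = edge_row.size(), k = offsets.nrow();
  for (int i = 0; i < n; ++i) {
    const int r = edge_row[i] - 1, c = edge_col[i] - 1;
    for (int j = 0; j < k; ++j) {
      const int rr = r + offsets(j, 0), cc = c + offsets(j, 1);
      if (rr >= 0 && rr < h && cc >= 0 && cc < w) acc(rr, cc)++;
    }
  }
  return acc;
}

// Outer-boundary length of the single connected region in `mask`, by
// Moore-neighbor contour tracing with Jacob's stopping criterion.
// Consecutive contour points contribute their Euclidean distance
// (1 for edge moves, sqrt(2) for diagonal moves); the closing segment is
// included. A single pixel has length 0.
// [[Rcpp::export]]
double trace_perimeter(const LogicalMatrix& mask) {
  const int h = mask.nrow(), w = mask.ncol();
  int sr = -1, sc = -1;
  for (int i = 0; i < h && sr < 0; ++i)
    for (int j = 0; j < w; ++j)
      if (mask(i, j)) { sr = i; sc = j; break; }
  if (sr < 0) return NA_REAL;

  // clockwise Moore neighborhood starting W, visiting W,NW,N,NE,E,SE,S,SW
  const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  auto fg = [&](int r, int c) {
    return r >= 0 && r < h && c >= 0 && c < w && mask(r, c);
  };

  bool lone = true;
  for (int k = 0; k < 8; ++k)
    if (fg(sr + dr[k], sc + dc[k])) { lone = false; break; }
  if (lone) return 0.0;

  double per = 0.0;
  // start pixel is entered scanning from the west, so the initial
  // backtrack cell is its west neighbor (background by raster order)
  int pr = sr, pc = sc;
  int br = sr, bc = sc - 1;
  int first_dir = -1;
  const long max_steps = 4L * h * w + 8;
  for (long step = 0; step < max_steps; ++step) {
    // locate the backtrack cell in the ring around p
    int k0 = 0;
    for (int k = 0; k < 8; ++k)
      if (pr + dr[k] == br && pc + dc[k] == bc) { k0 = k; break; }
    int found = -1, prev = k0;
    for (int t = 1; t <= 8; ++t) {
      int k = (k0 + t) % 8;
      if (fg(pr + dr[k], pc + dc[k])) { found = k; break; }
      prev = k;
    }
    // found >= 0 guaranteed: the region is connected and not a lone pixel
    if (step == 0) first_dir = found;
    else if (pr == sr && pc == sc && found == first_dir) break;  // Jacob's criterion
    per += (dr[found] != 0 && dc[found] != 0) ? std::sqrt(2.0) : 1.0;
    br = pr + dr[prev]; bc = pc + dc[prev];
    pr += dr[found]; pc += dc[found];
  }
  return per;
}
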