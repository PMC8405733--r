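#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// 8-connected component labeling of a binary matrix.
// Labels are assigned in raster order (column-major, as R stores matrices),
// so the labeling is deterministic.
// [[Rcpp::export(name = ".cc_label8")]]
IntegerMatrix cc_label8(const IntegerMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::vector<int> stack;
  stack.reserve(256);
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(c * H + r);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int nr = pr + dr, nc = pc + dc;
            if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
            if (mask(nr, nc) != 0 && lab(nr, nc) == 0) {
              lab(nr, nc) = next;
              stack.push_back(nc * H + nr);
            }
          }
        }
      }
    }
  }
  return lab;
}

// Seeded watershed with watershed lines (Meyer's flooding), restricted to
// `region`. topo: topography (lower floods first); seeds: 0 = unseeded,
// k >= 1 = basin id. Output: basin id >= 1, -1 on watershed-line (dam)
// pixels where two basins meet, 0 outside the region. Labels are decided
// when a pixel is popped from the priority queue, from the basin labels of
// its already-labeled neighbours; ties in topography are broken FIFO
// (raster order of discovery), so the result is deterministic.
struct QNode {
  double h; long order; int idx;
};
struct QCmp {
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.h != b.h) return a.h > b.h;   // min-heap on height
    return a.order > b.order;           // FIFO among equal heights
  }
};

// [[Rcpp::export(name = ".watershed_seeded")]]
IntegerMatrix watershed_seeded(const NumericMatrix& topo,
                               const IntegerMatrix& seeds,
                               const LogicalMatrix& region) {
  const int H = topo.nrow(), W = topo.ncol();
  IntegerMatrix lab(H, W);
  LogicalMatrix queued(H, W);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  long order = 0;
  auto push_neighbours = [&](int pr, int pc) {
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        int nr = pr + dr, nc = pc + dc;
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        if (!region(nr, nc) || lab(nr, nc) != 0 || queued(nr, nc)) continue;
        queued(nr, nc) = true;
        pq.push(QNode{topo(nr, nc), order++, nc * H + nr});
      }
    }
  };
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (region(r, c) && seeds(r, c) > 0)
        lab(r, c) = seeds(r, c);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      if (region(r, c) && seeds(r, c) > 0)
        push_neighbours(r, c);
  while (!pq.empty()) {
    QNode q = pq.top(); pq.pop();
    int pr = q.idx % H, pc = q.idx / H;
    int found = 0;
    for (int dc = -1; dc <= 1 && found >= 0; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        if (dr == 0 && dc == 0) continue;
        int nr = pr + dr, nc = pc + dc;
        if (nr < 0 || nr >= H || nc < 0 || nc >= W) continue;
        int l = lab(nr, nc);
        if (l <= 0) continue;
        if (found == 0) found = l;
        else if (found != l) { found = -1; break; }  // two basins meet: dam
      }
    }
    lab(pr, pc) = found == 0 ? -1 : found;  // isolated queued pixel: dam-safe
    if (found > 0) push_neighbours(pr, pc);
  }
  return lab;
}
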