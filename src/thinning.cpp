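#include <Rcpp.h>
using namespace Rcpp;

// Topology-preserving thinning of a binary mask (Zhang & Suen 1984),
// followed by a staircase cleanup that removes residual fully-set 2x2
// blocks while preserving 8-connectivity. Out-of-image pixels are
// treated as background.

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || c < 0 || r >= m.nrow() || c >= m.ncol()) return 0;
  return m(r, c);
}

// number of 0->1 transitions in the ordered 8-neighbourhood P2..P9,P2
static inline int crossings(int p[8]) {
  int a = 0;
  for (int i = 0; i < 8; ++i) a += (p[i] == 0 && p[(i + 1) % 8] == 1);
  return a;
}

static inline void nbhd(const IntegerMatrix &m, int r, int c, int p[8]) {
  // clockwise from north: P2 P3 P4 P5 P6 P7 P8 P9
  p[0] = px(m, r - 1, c);
  p[1] = px(m, r - 1, c + 1);
  p[2] = px(m, r, c + 1);
  p[3] = px(m, r + 1, c + 1);
  p[4] = px(m, r + 1, c);
  p[5] = px(m, r + 1, c - 1);
  p[6] = px(m, r, c - 1);
  p[7] = px(m, r - 1, c - 1);
}

// [[Rcpp::export(name = ".thin_zhang_suen")]]
LogicalMatrix thin_zhang_suen(const LogicalMatrix &input) {
  const int H = input.nrow(), W = input.ncol();
  IntegerMatrix m(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) m(r, c) = input(r, c) ? 1 : 0;

  std::vector<std::pair<int, int> > del;
  int p[8];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!m(r, c)) continue;
          nbhd(m, r, c, p);
          int B = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
          if (B < 2 || B > 6) continue;
          if (crossings(p) != 1) continue;
          // p[0]=P2 (N), p[2]=P4 (E), p[4]=P6 (S), p[6]=P8 (W)
          if (sub == 0) {
            if (p[0] * p[2] * p[4] != 0) continue;
            if (p[2] * p[4] * p[6] != 0) continue;
          } else {
            if (p[0] * p[2] * p[6] != 0) continue;
            if (p[0] * p[4] * p[6] != 0) continue;
          }
          del.push_back(std::make_pair(r, c));
        }
      }
      for (size_t i = 0; i < del.size(); ++i) m(del[i].first, del[i].second) = 0;
      if (!del.empty()) changed = true;
    }
  }

  // Minimality pass: Zhang-Suen leaves two-pixel-wide diagonal "ladders"
  // whose chain length reads as an axial staircase (up to +41% on a 45
  // degree fiber). Sequentially delete 8-simple, non-endpoint pixels
  // (Yokoi connectivity number Nc8 == 1) until the skeleton is minimal;
  // this collapses ladders into clean diagonal runs while preserving
  // topology and endpoints.
  {
    bool again2 = true;
    while (again2) {
      again2 = false;
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (!m(r, c)) continue;
          // ring order: N NE E SE S SW W NW
          int x[8];
          x[0] = px(m, r - 1, c);     x[1] = px(m, r - 1, c + 1);
          x[2] = px(m, r, c + 1);     x[3] = px(m, r + 1, c + 1);
          x[4] = px(m, r + 1, c);     x[5] = px(m, r + 1, c - 1);
          x[6] = px(m, r, c - 1);     x[7] = px(m, r - 1, c - 1);
          int B = x[0] + x[1] + x[2] + x[3] + x[4] + x[5] + x[6] + x[7];
          if (B < 2) continue;  // endpoints and isolated pixels stay
          int nc8 = 0;
          for (int k = 0; k < 8; k += 2) {
            int a = 1 - x[k], b = 1 - x[(k + 1) % 8], d = 1 - x[(k + 2) % 8];
            nc8 += a - a * b * d;
          }
          if (nc8 == 1) {
            m(r, c) = 0;
            again2 = true;
          }
        }
      }
    }
  }

  // staircase cleanup: no 2x2 block may remain fully set; delete pixels
  // that are 8-simple (single crossing) and not endpoints until none left
  bool again = true;
  while (again) {
    again = false;
    for (int c = 0; c + 1 < W && !again; ++c) {
      for (int r = 0; r + 1 < H && !again; ++r) {
        if (!(m(r, c) && m(r + 1, c) && m(r, c + 1) && m(r + 1, c + 1)))
          continue;
        const int rr[4] = {r, r + 1, r, r + 1};
        const int cc[4] = {c, c, c + 1, c + 1};
        for (int k = 0; k < 4; ++k) {
          nbhd(m, rr[k], cc[k], p);
          int B = p[0] + p[1] + p[2] + p[3] + p[4] + p[5] + p[6] + p[7];
          if (B > 1 && crossings(p) == 1) {
            m(rr[k], cc[k]) = 0;
            again = true;
            break;
          }
        }
        if (!again) {
          // degenerate isolated square: keep a single pixel
          m(r + 1, c) = 0; m(r, c + 1) = 0; m(r + 1, c + 1) = 0;
          again = true;
        }
      }
    }
  }

  LogicalMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) out(r, c) = m(r, c) == 1;
  return out;
}
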