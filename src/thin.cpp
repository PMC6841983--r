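#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Topological thinning and connected-component labelling for binary rasters.
// Pixels outside the image are treated as background throughout.

static inline int px(const LogicalMatrix& M, int r, int c) {
  if (r < 0 || c < 0 || r >= M.nrow() || c >= M.ncol()) return 0;
  return M(r, c) == TRUE ? 1 : 0;
}

// 8-neighbourhood in the classic clockwise order starting north:
// p[0]=N p[1]=NE p[2]=E p[3]=SE p[4]=S p[5]=SW p[6]=W p[7]=NW
static inline void neighbours(const LogicalMatrix& M, int r, int c, int* p) {
  p[0] = px(M, r - 1, c);
  p[1] = px(M, r - 1, c + 1);
  p[2] = px(M, r, c + 1);
  p[3] = px(M, r + 1, c + 1);
  p[4] = px(M, r + 1, c);
  p[5] = px(M, r + 1, c - 1);
  p[6] = px(M, r, c - 1);
  p[7] = px(M, r - 1, c - 1);
}

// Rutovitz crossing number: 0->1 transitions around the neighbour cycle
static inline int transitions(const int* p) {
  int a = 0;
  for (int k = 0; k < 8; ++k) a += (p[k] == 0 && p[(k + 1) % 8] == 1);
  return a;
}

static inline int nsum(const int* p) {
  int b = 0;
  for (int k = 0; k < 8; ++k) b += p[k];
  return b;
}

// Hilditch/Yokoi connectivity number for 8-connected foreground: the number
// of 4-connected background components adjacent to p. A foreground pixel is
// 8-simple (deletable without changing topology) iff this equals 1.
static inline int yokoi8(const int* p) {
  int c = 0;
  for (int k = 0; k < 8; k += 2) {
    int b0 = 1 - p[k], b1 = 1 - p[(k + 1) % 8], b2 = 1 - p[(k + 2) % 8];
    c += b0 - b0 * b1 * b2;
  }
  return c;
}

// Zhang-Suen-family thinning. Candidates for each directional sub-pass are
// marked on a frozen copy of the image (so the erosion front advances
// symmetrically from opposite boundaries and the skeleton settles on the
// centreline), then deleted sequentially in raster order with the
// simplicity conditions re-checked on the current image. The re-check makes
// every deletion topology-preserving: 8-connected components are never
// split or removed, unlike fully parallel deletion, which can erase a 2x2
// blob outright. A final clean-up removes residual fully-foreground 2x2
// blocks (junction/staircase leftovers) one 8-simple pixel at a time.
// [[Rcpp::export(name = ".thin_mask_cpp")]]
LogicalMatrix thin_mask_cpp(LogicalMatrix M) {
  LogicalMatrix S = clone(M);
  const int nr = S.nrow(), nc = S.ncol();
  int p[8];
  std::vector<std::pair<int, int> > cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      cand.clear();
      for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
          if (!S(r, c)) continue;
          neighbours(S, r, c, p);
          int b = nsum(p);
          if (b < 2 || b > 6) continue;
          if (transitions(p) != 1) continue;
          bool mark;
          if (sub == 0)
            mark = (p[0] * p[2] * p[4] == 0) && (p[2] * p[4] * p[6] == 0);
          else
            mark = (p[0] * p[2] * p[6] == 0) && (p[0] * p[4] * p[6] == 0);
          if (mark) cand.push_back(std::make_pair(r, c));
        }
      }
      for (size_t i = 0; i < cand.size(); ++i) {
        int r = cand[i].first, c = cand[i].second;
        neighbours(S, r, c, p);
        int b = nsum(p);
        if (b < 2 || b > 6) continue;       // became endpoint/isolated: keep
        if (transitions(p) != 1) continue;  // no longer simple: keep
        S(r, c) = FALSE;
        changed = true;
      }
    }
  }
  // dissolve remaining solid 2x2 blocks while preserving topology
  bool again = true;
  while (again) {
    again = false;
    for (int r = 0; r + 1 < nr; ++r) {
      for (int c = 0; c + 1 < nc; ++c) {
        if (!(S(r, c) && S(r + 1, c) && S(r, c + 1) && S(r + 1, c + 1)))
          continue;
        const int rr[4] = {r, r, r + 1, r + 1};
        const int cc[4] = {c, c + 1, c, c + 1};
        for (int k = 0; k < 4; ++k) {
          neighbours(S, rr[k], cc[k], p);
          int b = nsum(p);
          if (b >= 2 && b <= 7 && yokoi8(p) == 1) {
            S(rr[k], cc[k]) = FALSE;
            again = true;
            break;
          }
        }
      }
    }
  }
  return S;
}

// BFS labelling of foreground components (connectivity 4 or 8).
// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix M, int connectivity = 8) {
  const int nr = M.nrow(), nc = M.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[4] = {-1, 0, 0, 1};
  const int dc4[4] = {0, -1, 1, 0};
  const int* dr = connectivity == 8 ? dr8 : dr4;
  const int* dc = connectivity == 8 ? dc8 : dc4;
  const int nd = connectivity == 8 ? 8 : 4;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!M(r, c) || lab(r, c)) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> cur = q.front();
        q.pop();
        for (int k = 0; k < nd; ++k) {
          int r2 = cur.first + dr[k], c2 = cur.second + dc[k];
          if (r2 < 0 || c2 < 0 || r2 >= nr || c2 >= nc) continue;
          if (M(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            q.push(std::make_pair(r2, c2));
          }
        }
      }
    }
  }
  return lab;
}
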