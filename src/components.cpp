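#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labelling on a binary matrix, iterative flood fill.
// connectivity: 4 or 8. Returns labels (0 = background), per-label stats.
// Boxes are 0-based half-open [x0, x1) x [y0, y1), x = column, y = row.
// [[Rcpp::export(name = ".cc_label")]]
List cc_label(IntegerMatrix mask, int connectivity = 8) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix labels(H, W);
  std::vector<int> x0, y0, x1, y1, area;
  std::vector<double> cy, cx;
  std::vector<int> stack;
  stack.reserve(1024);

  const int dy8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dy4[] = {-1, 0, 0, 1};
  const int dx4[] = {0, -1, 1, 0};
  const int *dy = connectivity == 8 ? dy8 : dy4;
  const int *dx = connectivity == 8 ? dx8 : dx4;
  const int nd = connectivity == 8 ? 8 : 4;

  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || labels(r, c) != 0) continue;
      ++next;
      int bx0 = c, bx1 = c, by0 = r, by1 = r, n = 0;
      double sy = 0.0, sx = 0.0;
      stack.clear();
      stack.push_back(r + c * H);
      labels(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int rr = idx % H, cc = idx / H;
        ++n;
        sy += rr; sx += cc;
        if (cc < bx0) bx0 = cc;
        if (cc > bx1) bx1 = cc;
        if (rr < by0) by0 = rr;
        if (rr > by1) by1 = rr;
        for (int k = 0; k < nd; ++k) {
          int r2 = rr + dy[k], c2 = cc + dx[k];
          if (r2 < 0 || r2 >= H || c2 < 0 || c2 >= W) continue;
          if (mask(r2, c2) != 0 && labels(r2, c2) == 0) {
            labels(r2, c2) = next;
            stack.push_back(r2 + c2 * H);
          }
        }
      }
      x0.push_back(bx0); x1.push_back(bx1 + 1);
      y0.push_back(by0); y1.push_back(by1 + 1);
      area.push_back(n);
      cx.push_back(sx / n); cy.push_back(sy / n);
    }
  }
  return List::create(
    _["labels"] = labels, _["n"] = next,
    _["x0"] = wrap(x0), _["y0"] = wrap(y0),
    _["x1"] = wrap(x1), _["y1"] = wrap(y1),
    _["area"] = wrap(area), _["cx"] = wrap(cx), _["cy"] = wrap(cy));
}

static inline int px(const IntegerMatrix &m, int r, int c) {
  if (r < 0 || r >= m.nrow() || c < 0 || c >= m.ncol()) return 0;
  return m(r, c) != 0 ? 1 : 0;
}

// Zhang-Suen thinning to a (mostly) 1-px-wide 8-connected skeleton.
// [[Rcpp::export(name = ".zs_thin")]]
IntegerMatrix zs_thin(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img(clone(mask));
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) img(r, c) = img(r, c) != 0 ? 1 : 0;

  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int c = 0; c < W; ++c) {
        for (int r = 0; r < H; ++r) {
          if (img(r, c) == 0) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = px(img, r - 1, c),     p3 = px(img, r - 1, c + 1);
          int p4 = px(img, r, c + 1),     p5 = px(img, r + 1, c + 1);
          int p6 = px(img, r + 1, c),     p7 = px(img, r + 1, c - 1);
          int p8 = px(img, r, c - 1),     p9 = px(img, r - 1, c - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(r + c * H);
        }
      }
      if (!kill.empty()) changed = true;
      for (size_t i = 0; i < kill.size(); ++i)
        img(kill[i] % H, kill[i] / H) = 0;
    }
  }
  return img;
}

// Remove skeleton spurs: branches of at most max_len pixels that terminate
// at a junction (pixel with >= 3 neighbours). Whole short components and
// genuine path ends are kept. Repeats until stable.
// [[Rcpp::export(name = ".prune_spurs")]]
IntegerMatrix prune_spurs(IntegerMatrix sk, int max_len) {
  const int H = sk.nrow(), W = sk.ncol();
  IntegerMatrix img(clone(sk));
  const int dy[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dx[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  bool changed = true;
  while (changed) {
    changed = false;
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        if (img(r, c) == 0) continue;
        int deg = 0;
        for (int k = 0; k < 8; ++k) deg += px(img, r + dy[k], c + dx[k]);
        if (deg != 1) continue;                    // endpoints only
        // trace towards the junction
        std::vector<int> path;
        int pr = -1, pc = -1, cr = r, cc = c;
        bool prune = false;
        while ((int)path.size() <= max_len) {
          std::vector<int> nr, nc;
          for (int k = 0; k < 8; ++k) {
            int r2 = cr + dy[k], c2 = cc + dx[k];
            if (r2 == pr && c2 == pc) continue;
            bool on_path = false;
            for (size_t i = 0; i < path.size(); ++i) {
              if (path[i] == r2 + c2 * H) { on_path = true; break; }
            }
            if (!on_path && px(img, r2, c2)) { nr.push_back(r2); nc.push_back(c2); }
          }
          if (nr.size() == 1) {
            path.push_back(cr + cc * H);
            pr = cr; pc = cc; cr = nr[0]; cc = nc[0];
          } else if (nr.size() == 0) {
            break;                                 // isolated path: keep
          } else {
            path.push_back(cr + cc * H);           // junction ahead: prune
            prune = true;
            break;
          }
        }
        if (prune) {
          for (size_t i = 0; i < path.size(); ++i)
            img(path[i] % H, path[i] / H) = 0;
          changed = true;
        }
      }
    }
  }
  return img;
}

// Weighted step count along a skeleton: 1 per 4-adjacent pair, sqrt(2) per
// diagonal pair unless a bridging 4-neighbour short-circuits the diagonal.
// [[Rcpp::export(name = ".skeleton_steps")]]
double skeleton_steps(IntegerMatrix sk) {
  const int H = sk.nrow(), W = sk.ncol();
  double len = 0.0;
  const double SQ2 = 1.4142135623730951;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (sk(r, c) == 0) continue;
      if (px(sk, r + 1, c)) len += 1.0;           // south
      if (px(sk, r, c + 1)) len += 1.0;           // east
      if (px(sk, r + 1, c + 1) && !px(sk, r + 1, c) && !px(sk, r, c + 1))
        len += SQ2;                               // south-east
      if (px(sk, r - 1, c + 1) && !px(sk, r - 1, c) && !px(sk, r, c + 1))
        len += SQ2;                               // north-east
    }
  }
  return len;
}
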