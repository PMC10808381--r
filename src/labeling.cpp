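#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Combined contour tracing and region labeling on a binary mask.
//
// Single raster scan over the (background-padded) mask. Meeting an
// unlabeled foreground pixel whose upper neighbour is background starts a
// new component: its outer contour is traced with a Moore-neighbourhood
// tracer and labeled. Meeting a foreground pixel above an unmarked
// background pixel traces an inner (hole) contour under the same label,
// marking the hole boundary so it can never seed a spurious component.
// All other foreground pixels inherit the label of their left neighbour.
// Components are 8-connected (background 4-connected), labels are
// consecutive from 1 in order of first encounter, and each outer contour
// is a closed cycle oriented clockwise in image coordinates (row down,
// col right).

// 8 neighbour directions, clockwise on screen, 0 = east.
static const int DR[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int DC[8] = {1, 1, 0, -1, -1, -1, 0, 1};

struct Pt {
  int r, c;
  bool operator==(const Pt& o) const { return r == o.r && c == o.c; }
};

// Find the first foreground neighbour of p, scanning clockwise from
// direction d0; background pixels inspected on the way are marked -1 in
// lab (so inner-contour starts are suppressed later). Returns false for
// an isolated pixel.
static bool tracer(const LogicalMatrix& mask, IntegerMatrix& lab,
                   const Pt& p, int d0, Pt& nxt, int& dir) {
  for (int i = 0; i < 8; ++i) {
    int d = (d0 + i) % 8;
    int r = p.r + DR[d], c = p.c + DC[d];
    if (mask(r, c)) {
      nxt.r = r; nxt.c = c; dir = d;
      return true;
    }
    if (lab(r, c) == 0) lab(r, c) = -1;
  }
  return false;
}

// Trace a full closed contour from start pixel s. d0 = 7 (NE) for outer
// contours, 3 (SW) for inner ones. Labels every contour pixel. The trace
// terminates when the start pixel is re-entered and its successor is the
// same second pixel as on the first pass.
static std::vector<Pt> trace_contour(const LogicalMatrix& mask,
                                     IntegerMatrix& lab,
                                     const Pt& s, int d0, int label) {
  std::vector<Pt> contour;
  lab(s.r, s.c) = label;
  contour.push_back(s);
  Pt second; int d;
  if (!tracer(mask, lab, s, d0, second, d)) return contour;  // isolated
  Pt cur = second;
  for (;;) {
    lab(cur.r, cur.c) = label;
    contour.push_back(cur);
    Pt nxt; int nd;
    tracer(mask, lab, cur, (d + 6) % 8, nxt, nd);  // always succeeds
    if (cur == s && nxt == second) {
      contour.pop_back();  // drop the duplicated start point
      break;
    }
    cur = nxt; d = nd;
  }
  return contour;
}

// [[Rcpp::export(name = ".label_regions_cpp")]]
List label_regions_cpp(LogicalMatrix mask_in) {
  int H = mask_in.nrow(), W = mask_in.ncol();
  // pad with one background pixel on every side so the tracer and the
  // marking of visited background never index out of bounds
  LogicalMatrix mask(H + 2, W + 2);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c)
      mask(r + 1, c + 1) = mask_in(r, c);
  IntegerMatrix lab(H + 2, W + 2);
  std::vector< std::vector<Pt> > contours;
  int nlab = 0;

  for (int r = 1; r <= H; ++r) {
    for (int c = 1; c <= W; ++c) {
      if (!mask(r, c)) continue;
      Pt p = {r, c};
      if (lab(r, c) == 0 && !mask(r - 1, c)) {
        // new outer contour
        ++nlab;
        contours.push_back(trace_contour(mask, lab, p, 7, nlab));
      }
      if (!mask(r + 1, c) && lab(r + 1, c) == 0) {
        // unmarked background below: inner (hole) contour
        if (lab(r, c) == 0) lab(r, c) = lab(r, c - 1);
        trace_contour(mask, lab, p, 3, lab(r, c));
      } else if (lab(r, c) == 0) {
        lab(r, c) = lab(r, c - 1);
      }
    }
  }

  // strip padding; clear background marks
  IntegerMatrix out(H, W);
  for (int r = 0; r < H; ++r)
    for (int c = 0; c < W; ++c) {
      int v = lab(r + 1, c + 1);
      out(r, c) = (v > 0 && mask_in(r, c)) ? v : 0;
    }

  List clist(nlab);
  for (int i = 0; i < nlab; ++i) {
    const std::vector<Pt>& ct = contours[i];
    IntegerMatrix m(ct.size(), 2);
    for (size_t j = 0; j < ct.size(); ++j) {
      m(j, 0) = ct[j].r;  // already 1-based thanks to the padding offset
      m(j, 1) = ct[j].c;
    }
    colnames(m) = CharacterVector::create("row", "col");
    clist[i] = m;
  }
  return List::create(_["labels"] = out, _["contours"] = clist);
}
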