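#include <Rcpp.h>
using namespace Rcpp;

// 8-connected component labelling of a binary mask (column-major matrix).
// Flood fill with an explicit stack; labels are 1..n in column-major
// discovery order, matching the scan order used downstream.
// [[Rcpp::export]]
IntegerMatrix cc_label_8(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int rr = idx % nr, cc = idx / nr;
        for (int dc = -1; dc <= 1; ++dc) {
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            const int r2 = rr + dr, c2 = cc + dc;
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            if (mask(r2, c2) && !lab(r2, c2)) {
              lab(r2, c2) = next;
              stack.push_back(r2 + c2 * nr);
            }
          }
        }
      }
    }
  }
  lab.attr("n_labels") = next;
  return lab;
}

// Moore-neighbour outer-contour tracing per component. The perimeter is the
// chain length through successive boundary pixel centers: axis steps count
// 1, diagonal steps sqrt(2). Single-pixel components get the length of
// their crack boundary (4).
// Clockwise neighbour order starting west (dr, dc) with r increasing down:
static const int DR[8] = { 0, -1, -1, -1,  0,  1,  1,  1};
static const int DC[8] = {-1, -1,  0,  1,  1,  1,  0, -1};

// [[Rcpp::export]]
NumericVector cc_perimeter(const IntegerMatrix& lab, const int n_labels) {
  const int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(n_labels, 0.0);
  std::vector<char> seen(n_labels, 0);
  const double SQRT2 = std::sqrt(2.0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      const int id = lab(r, c);
      if (id == 0 || seen[id - 1]) continue;
      seen[id - 1] = 1;
      // (r, c) is the first pixel of the component in column-major order,
      // so its west neighbour is background: start tracing from there.
      const int sr = r, sc = c;
      int cr = sr, cc = sc;
      int back = 0;  // direction index of the backtrack pixel (west)
      double len = 0.0;
      bool single = true;
      // components here are filled shapes whose outer contour is a simple
      // cycle through the start pixel, so returning to the start closes the
      // walk; the guard bounds pathological cases
      long guard = 8L * (long)nr * nc + 16;
      while (guard-- > 0) {
        int found = -1;
        for (int k = 1; k <= 8; ++k) {
          const int d = (back + k) % 8;
          const int r2 = cr + DR[d], c2 = cc + DC[d];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (lab(r2, c2) == id) { found = d; break; }
        }
        if (found < 0) break;  // isolated pixel
        single = false;
        len += (DR[found] != 0 && DC[found] != 0) ? SQRT2 : 1.0;
        cr += DR[found];
        cc += DC[found];
        // new backtrack: the previous current pixel, seen from the new one
        back = (found + 4) % 8;
        if (cr == sr && cc == sc) break;
      }
      per[id - 1] = single ? 4.0 : len;
    }
  }
  return per;
}
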