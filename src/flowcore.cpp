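#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Horn-Schunck optical flow between two frames.
//
// Layout: frames are rows x cols matrices; u is the displacement along
// columns (+right), v along rows (+down), in pixels per frame pair.
//
// Spatial/temporal derivatives use the classical 4-point cube stencils
// (averages over the 2x2x2 cube spanned by pixel (i,j) and its +1
// neighbours), with replicate (Neumann) handling at the last row/column.
// The smoothness term uses the weighted 8-neighbour average (edge
// neighbours 1/6, diagonal neighbours 1/12); at grid borders and next to
// invalid pixels the weights of the missing neighbours are dropped and the
// remaining weights renormalised. Invalid pixels carry zero flow and do not
// contribute to any average. Iteration is Jacobi from a zero initial field:
//   u <- ubar - Ex (Ex ubar + Ey vbar + Et) / (alpha^2 + Ex^2 + Ey^2)
// and analogously for v.
// [[Rcpp::export(name = ".hs_flow_cpp")]]
List hs_flow_cpp(NumericMatrix a, NumericMatrix b, double alpha, int iters,
                 LogicalMatrix valid) {
  const int nr = a.nrow(), nc = a.ncol();
  if (b.nrow() != nr || b.ncol() != nc)
    stop("frame shape mismatch");
  if (valid.nrow() != nr || valid.ncol() != nc)
    stop("valid mask shape mismatch");

  NumericMatrix Ex(nr, nc), Ey(nr, nc), Et(nr, nc);
  auto clampi = [&](int i, int n) { return i < n ? i : n - 1; };
  for (int j = 0; j < nc; ++j) {
    int j1 = clampi(j + 1, nc);
    for (int i = 0; i < nr; ++i) {
      int i1 = clampi(i + 1, nr);
      // x = column direction, y = row direction
      Ex(i, j) = 0.25 * ((a(i, j1) - a(i, j)) + (a(i1, j1) - a(i1, j)) +
                         (b(i, j1) - b(i, j)) + (b(i1, j1) - b(i1, j)));
      Ey(i, j) = 0.25 * ((a(i1, j) - a(i, j)) + (a(i1, j1) - a(i, j1)) +
                         (b(i1, j) - b(i, j)) + (b(i1, j1) - b(i, j1)));
      Et(i, j) = 0.25 * ((b(i, j) - a(i, j)) + (b(i1, j) - a(i1, j)) +
                         (b(i, j1) - a(i, j1)) + (b(i1, j1) - a(i1, j1)));
    }
  }

  NumericMatrix u(nr, nc), v(nr, nc), un(nr, nc), vn(nr, nc);
  const double a2 = alpha * alpha;
  const int di[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const double w[8] = {1.0 / 6, 1.0 / 6, 1.0 / 6, 1.0 / 6,
                       1.0 / 12, 1.0 / 12, 1.0 / 12, 1.0 / 12};

  for (int it = 0; it < iters; ++it) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        if (!valid(i, j)) { un(i, j) = 0.0; vn(i, j) = 0.0; continue; }
        double su = 0.0, sv = 0.0, sw = 0.0;
        for (int k = 0; k < 8; ++k) {
          int ii = i + di[k], jj = j + dj[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (!valid(ii, jj)) continue;
          su += w[k] * u(ii, jj);
          sv += w[k] * v(ii, jj);
          sw += w[k];
        }
        double ubar = sw > 0 ? su / sw : 0.0;
        double vbar = sw > 0 ? sv / sw : 0.0;
        double ex = Ex(i, j), ey = Ey(i, j);
        double num = ex * ubar + ey * vbar + Et(i, j);
        double den = a2 + ex * ex + ey * ey;
        un(i, j) = ubar - ex * num / den;
        vn(i, j) = vbar - ey * num / den;
      }
    }
    std::swap(u, un);
    std::swap(v, vn);
  }
  return List::create(_["u"] = u, _["v"] = v);
}

// 8-connected component labelling of a logical matrix. Returns an integer
// matrix with 0 for background and 1..n for components, numbered by first
// (column-major) encounter.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(LogicalMatrix m) {
  const int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!m(i, j) || lab(i, j)) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = pi + di, jj = pj + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (m(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              stack.push_back(ii + jj * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
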