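#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Topographic prominence of every local maximum of a 2-D height field,
// computed as 0-dimensional persistence: pixels are activated in order of
// decreasing height and merged by union-find over 8-connectivity. When two
// growing components meet, the one whose peak is lower dies; its prominence
// is peak height minus the merge (saddle) level. Peaks that never die
// (one per connected component of the field, in practice the global
// maximum) get prominence = peak height - global minimum.

static int find_root(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// [[Rcpp::export]]
DataFrame cpp_peak_prominence(NumericMatrix h) {
  const int nr = h.nrow(), nc = h.ncol(), n = nr * nc;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  const double* hp = h.begin();
  // Decreasing height; ties broken by linear index so plateaus are handled
  // deterministically (first pixel of a flat top becomes the peak).
  std::stable_sort(order.begin(), order.end(), [hp](int a, int b) {
    if (hp[a] != hp[b]) return hp[a] > hp[b];
    return a < b;
  });

  std::vector<int> parent(n, -1);        // -1 = not yet activated
  std::vector<int> peak_of_root(n, -1);  // root -> linear index of its peak
  std::vector<int> peaks;
  std::vector<double> prom;              // parallel to peaks; NA until death
  std::vector<int> peak_slot(n, -1);     // linear index -> slot in peaks

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (int k = 0; k < n; ++k) {
    const int i = order[k];
    const int r = i % nr, c = i / nr;
    const double level = hp[i];

    int roots[8];
    int nroots = 0;
    for (int m = 0; m < 8; ++m) {
      const int rr = r + dr[m], cc = c + dc[m];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      const int j = rr + cc * nr;
      if (parent[j] < 0) continue;
      const int root = find_root(parent, j);
      bool seen = false;
      for (int q = 0; q < nroots; ++q) if (roots[q] == root) { seen = true; break; }
      if (!seen) roots[nroots++] = root;
    }

    if (nroots == 0) {
      parent[i] = i;
      peak_of_root[i] = i;
      peak_slot[i] = (int)peaks.size();
      peaks.push_back(i);
      prom.push_back(NA_REAL);
    } else {
      // survivor = component with the highest peak (ties: lower peak index)
      int win = roots[0];
      for (int q = 1; q < nroots; ++q) {
        const int pk_w = peak_of_root[win], pk_q = peak_of_root[roots[q]];
        if (hp[pk_q] > hp[pk_w] || (hp[pk_q] == hp[pk_w] && pk_q < pk_w))
          win = roots[q];
      }
      for (int q = 0; q < nroots; ++q) {
        const int rt = roots[q];
        if (rt == win) continue;
        const int pk = peak_of_root[rt];
        prom[peak_slot[pk]] = hp[pk] - level;  // dies at this saddle
        parent[rt] = win;
      }
      parent[i] = win;
    }
  }

  const double hmin = *std::min_element(hp, hp + n);
  const int npk = (int)peaks.size();
  IntegerVector row(npk), col(npk);
  NumericVector height(npk), prominence(npk);
  for (int s = 0; s < npk; ++s) {
    const int i = peaks[s];
    row[s] = i % nr + 1;
    col[s] = i / nr + 1;
    height[s] = hp[i];
    prominence[s] = ISNA(prom[s]) ? hp[i] - hmin : prom[s];
  }
  return DataFrame::create(_["row"] = row, _["col"] = col,
                           _["height"] = height, _["prominence"] = prominence);
}
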