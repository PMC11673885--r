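// Raster kernels for lesion-instance counting: connected-component
// labeling, exact Euclidean distance transform, and a per-component
// marker-controlled watershed that splits touching lesions.
//
// Conventions: matrices are column-major (R layout); pixel (r, c) has
// linear index r + c * nrow.  Labels are 1..k in first-encounter order
// of a column-major scan, so results are fully deterministic.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// [[Rcpp::export]]
IntegerMatrix cc_label(const LogicalMatrix& mask, int connectivity,
                       int min_size) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  if (min_size < 1) stop("min_size must be >= 1");
  const int nr = mask.nrow(), nc = mask.ncol();
  const int nn = (connectivity == 8) ? 8 : 4;
  IntegerMatrix lab(nr, nc);
  std::vector<int> sizes;  // sizes[k-1] = area of provisional label k
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      int area = 0;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        ++area;
        int pr = idx % nr, pc = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int qr = pr + DR8[k], qc = pc + DC8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
      sizes.push_back(area);
    }
  }
  // drop undersized components, relabel consecutively in scan order
  std::vector<int> remap(next + 1, 0);
  int kept = 0;
  for (int k = 1; k <= next; ++k)
    remap[k] = (sizes[k - 1] >= min_size) ? ++kept : 0;
  for (int i = 0; i < nr * nc; ++i) lab[i] = remap[lab[i]];
  lab.attr("n_instances") = kept;
  return lab;
}

// 1D squared-distance lower envelope (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance to the nearest background (or
// off-image) pixel.  Background pixels get 0.
// [[Rcpp::export]]
NumericMatrix edt_squared(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix d(nr, nc);
  int nmax = std::max(nr, nc);
  std::vector<double> f(nmax), dd(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  // pass 1: along columns
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    dt1d(f, dd, v, z, nr);
    for (int r = 0; r < nr; ++r) d(r, c) = dd[r];
  }
  // pass 2: along rows
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d(r, c);
    dt1d(f, dd, v, z, nc);
    for (int c = 0; c < nc; ++c) d(r, c) = dd[c];
  }
  // image border counts as background one pixel beyond the frame
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      double b = std::min(std::min(r + 1, nr - r), std::min(c + 1, nc - c));
      if (b * b < d(r, c)) d(r, c) = b * b;
    }
  }
  return d;
}

struct QNode {
  double dist;
  long long order;
  int idx;
  int lab;
};
struct QCmp {
  // max-heap on dist; FIFO among equal distances (deterministic)
  bool operator()(const QNode& a, const QNode& b) const {
    if (a.dist != b.dist) return a.dist < b.dist;
    return a.order > b.order;
  }
};

static int uf_find(std::vector<int>& parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

// Split touching lesions: per connected component, find local maxima of
// the distance transform (plateaus collapsed to one representative),
// keep maxima pairwise separated by >= min_dist (greedy, highest first),
// and if a component holds m >= 2 markers run a marker-controlled
// watershed (priority flood on decreasing distance) over its pixels.
// Regions whose peak rises less than min_prom above the saddle joining
// them to a neighbour are merged back (maxima dynamics, Kruskal order),
// which removes spurious peaks born of grid discretization.
// Returns new labels 1..k; foreground support is exactly preserved.
// [[Rcpp::export]]
IntegerMatrix ws_split(const IntegerMatrix& labels, const NumericMatrix& dist,
                       double min_dist, double min_prom) {
  const int nr = labels.nrow(), nc = labels.ncol();
  if (min_dist < 1) stop("marker_min_distance must be >= 1");
  int ncomp = 0;
  for (int i = 0; i < nr * nc; ++i) if (labels[i] > ncomp) ncomp = labels[i];

  IntegerMatrix out(nr, nc);
  if (ncomp == 0) { out.attr("n_instances") = 0; return out; }

  // 1. candidate maxima: dist >= every same-component pixel within a
  //    small Euclidean window (radius 2).  A plain 8-neighbour test
  //    admits spurious saddle peaks created by grid discretization; a
  //    window as wide as min_dist suppresses genuine secondary lesions
  //    whose cores sit below a larger neighbour's distance basin.
  const int wr = 2;
  std::vector<std::pair<int, int>> woff;
  for (int dr = -wr; dr <= wr; ++dr)
    for (int dc = -wr; dc <= wr; ++dc)
      if ((dr || dc) && dr * dr + dc * dc <= wr * wr)
        woff.push_back(std::make_pair(dr, dc));
  std::vector<char> cand(nr * nc, 0);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int L = labels(r, c);
      if (L == 0) continue;
      bool mx = true;
      for (size_t k = 0; k < woff.size() && mx; ++k) {
        int qr = r + woff[k].first, qc = c + woff[k].second;
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (labels(qr, qc) == L && dist(qr, qc) > dist(r, c)) mx = false;
      }
      if (mx) cand[r + c * nr] = 1;
    }
  }

  // 2. collapse 8-connected plateaus of candidates (within a component)
  //    to one representative: highest dist, then lowest linear index
  std::vector<int> plat(nr * nc, 0);
  std::vector<int> rep;      // representative pixel per plateau
  std::vector<int> repcomp;  // component of each plateau
  std::vector<int> stack;
  int np = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = r + c * nr;
      if (!cand[idx] || plat[idx] != 0) continue;
      ++np;
      int L = labels(r, c);
      int best = idx;
      stack.clear();
      stack.push_back(idx);
      plat[idx] = np;
      while (!stack.empty()) {
        int p = stack.back();
        stack.pop_back();
        if (dist[p] > dist[best] || (dist[p] == dist[best] && p < best))
          best = p;
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 8; ++k) {
          int qr = pr + DR8[k], qc = pc + DC8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          int q = qr + qc * nr;
          if (cand[q] && plat[q] == 0 && labels(qr, qc) == L) {
            plat[q] = np;
            stack.push_back(q);
          }
        }
      }
      rep.push_back(best);
      repcomp.push_back(L);
    }
  }

  // 3. per component, greedy marker selection (dist desc, index asc),
  //    enforcing pairwise separation >= min_dist
  std::vector<std::vector<int>> comp_reps(ncomp + 1);
  for (int p = 0; p < np; ++p) comp_reps[repcomp[p]].push_back(rep[p]);
  const double md2 = min_dist * min_dist;
  std::vector<std::vector<int>> markers(ncomp + 1);
  for (int L = 1; L <= ncomp; ++L) {
    std::vector<int>& cr = comp_reps[L];
    std::sort(cr.begin(), cr.end(), [&](int a, int b) {
      if (dist[a] != dist[b]) return dist[a] > dist[b];
      return a < b;
    });
    for (int cand_idx : cr) {
      int ar = cand_idx % nr, ac = cand_idx / nr;
      bool ok = true;
      for (int m : markers[L]) {
        double dr = ar - m % nr, dc = ac - m / nr;
        if (dr * dr + dc * dc < md2) { ok = false; break; }
      }
      if (ok) markers[L].push_back(cand_idx);
    }
  }

  // 4. assign output labels; flood components with >= 2 markers
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  long long order = 0;
  int next = 0;
  std::vector<int> single(ncomp + 1, 0);  // out-label of unsplit components
  std::vector<double> peak(1, 0.0);       // marker height per out-label
  for (int L = 1; L <= ncomp; ++L) {
    if (markers[L].size() >= 2) {
      for (int m : markers[L]) {
        ++next;
        out[m] = next;
        peak.push_back(dist[m]);
        QNode nd = {dist[m], order++, m, next};
        pq.push(nd);
      }
    } else {
      single[L] = ++next;
      peak.push_back(0.0);
    }
  }
  for (int i = 0; i < nr * nc; ++i)
    if (labels[i] > 0 && single[labels[i]] > 0) out[i] = single[labels[i]];

  while (!pq.empty()) {
    QNode nd = pq.top();
    pq.pop();
    int pr = nd.idx % nr, pc = nd.idx / nr;
    int L = labels(pr, pc);
    for (int k = 0; k < 8; ++k) {
      int qr = pr + DR8[k], qc = pc + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (labels(qr, qc) == L && out(qr, qc) == 0) {
        out(qr, qc) = nd.lab;
        QNode nb = {dist(qr, qc), order++, qr + qc * nr, nd.lab};
        pq.push(nb);
      }
    }
  }

  // 5. merge shallow regions: saddle height per adjacent region pair,
  //    then Kruskal over saddles (deepest first) computes each
  //    maximum's dynamics; regions with dynamics < min_prom merge
  std::map<std::pair<int, int>, double> saddle;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l1 = out(r, c);
      if (l1 == 0) continue;
      for (int k = 0; k < 8; ++k) {
        int qr = r + DR8[k], qc = c + DC8[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int l2 = out(qr, qc);
        if (l2 == 0 || l2 == l1 || labels(qr, qc) != labels(r, c))
          continue;
        std::pair<int, int> key(std::min(l1, l2), std::max(l1, l2));
        double s = std::min(dist(r, c), dist(qr, qc));
        std::map<std::pair<int, int>, double>::iterator it =
          saddle.find(key);
        if (it == saddle.end()) saddle[key] = s;
        else if (s > it->second) it->second = s;
      }
    }
  }
  std::vector<std::pair<double, std::pair<int, int>>> edges;
  for (std::map<std::pair<int, int>, double>::iterator it = saddle.begin();
       it != saddle.end(); ++it)
    edges.push_back(std::make_pair(it->second, it->first));
  std::sort(edges.begin(), edges.end(),
            [](const std::pair<double, std::pair<int, int>>& a,
               const std::pair<double, std::pair<int, int>>& b) {
              if (a.first != b.first) return a.first > b.first;
              return a.second < b.second;
            });
  std::vector<int> parent(next + 1);
  for (int i = 0; i <= next; ++i) parent[i] = i;
  for (size_t e = 0; e < edges.size(); ++e) {
    int a = uf_find(parent, edges[e].second.first);
    int b = uf_find(parent, edges[e].second.second);
    if (a == b) continue;
    double s = edges[e].first;
    if (std::min(peak[a], peak[b]) - s < min_prom) {
      // weaker maximum lacks prominence: absorb into the stronger
      if (peak[a] >= peak[b]) parent[b] = a; else parent[a] = b;
    }
  }
  std::vector<int> remap(next + 1, 0);
  int kept = 0;
  for (int l = 1; l <= next; ++l) {
    int root = uf_find(parent, l);
    if (remap[root] == 0) remap[root] = ++kept;
    remap[l] = remap[root];
  }
  for (int i = 0; i < nr * nc; ++i) if (out[i] > 0) out[i] = remap[out[i]];

  out.attr("n_instances") = kept;
  return out;
}
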