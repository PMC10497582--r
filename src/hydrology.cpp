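#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// D8 neighbour offsets, clockwise starting at East.
// Direction codes: 1..8 = E,SE,S,SW,W,NW,N,NE; 0 = outlet; NA = nodata.
static const int DR[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int DC[8] = {1, 1, 0, -1, -1, -1, 0, 1};

struct Cell {
  double z;
  long order;  // insertion sequence, for deterministic pops among equal z
  int idx;
};
struct CellCmp {
  bool operator()(const Cell &a, const Cell &b) const {
    if (a.z != b.z) return a.z > b.z;   // min-heap on elevation
    return a.order > b.order;           // FIFO among equals
  }
};

static inline bool valid_cell(const NumericMatrix &z, int r, int c) {
  return r >= 0 && c >= 0 && r < z.nrow() && c < z.ncol() &&
         !NumericMatrix::is_na(z(r, c));
}

// Priority-flood depression filling (boundary-seeded min-heap, epsilon-free).
// Boundary = grid edge or any valid cell 8-adjacent to a nodata cell.
// [[Rcpp::export]]
NumericMatrix fill_depressions_cpp(NumericMatrix dem) {
  int nr = dem.nrow(), nc = dem.ncol();
  NumericMatrix z = clone(dem);
  LogicalMatrix seen(nr, nc);
  std::priority_queue<Cell, std::vector<Cell>, CellCmp> pq;
  long order = 0;
  int nvalid = 0;

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!valid_cell(z, r, c)) continue;
      ++nvalid;
      bool boundary = (r == 0 || c == 0 || r == nr - 1 || c == nc - 1);
      if (!boundary) {
        for (int k = 0; k < 8 && !boundary; ++k)
          if (!valid_cell(z, r + DR[k], c + DC[k])) boundary = true;
      }
      if (boundary) {
        pq.push({z(r, c), order++, r * nc + c});
        seen(r, c) = true;
      }
    }
  }
  if (nvalid == 0) stop("empty terrain");
  if (pq.empty()) stop("empty terrain");  // no drainable boundary

  while (!pq.empty()) {
    Cell cur = pq.top();
    pq.pop();
    int r = cur.idx / nc, c = cur.idx % nc;
    for (int k = 0; k < 8; ++k) {
      int rn = r + DR[k], cn = c + DC[k];
      if (!valid_cell(z, rn, cn) || seen(rn, cn)) continue;
      if (z(rn, cn) < cur.z) z(rn, cn) = cur.z;  // raise to pour elevation
      seen(rn, cn) = true;
      pq.push({z(rn, cn), order++, rn * nc + cn});
    }
  }
  return z;
}

// D8 steepest-descent directions on a depression-filled grid.
// Ties among equal steepest drops take the first neighbour clockwise from E.
// Flats are resolved by BFS from their spill cells (equal-elevation neighbours
// that already drain), so flow converges on the flat's outlet.
// Edge cells (or cells beside nodata) with no downslope neighbour are outlets.
// [[Rcpp::export]]
IntegerMatrix d8_flow_direction_cpp(NumericMatrix z) {
  int nr = z.nrow(), nc = z.ncol();
  IntegerMatrix dir(nr, nc);
  std::fill(dir.begin(), dir.end(), NA_INTEGER);
  const double sq2 = std::sqrt(2.0);
  std::queue<int> flatq;

  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!valid_cell(z, r, c)) continue;
      double best = 0.0;
      int bestk = -1;
      bool edge = (r == 0 || c == 0 || r == nr - 1 || c == nc - 1);
      for (int k = 0; k < 8; ++k) {
        int rn = r + DR[k], cn = c + DC[k];
        if (!valid_cell(z, rn, cn)) { edge = true; continue; }
        double dist = (DR[k] != 0 && DC[k] != 0) ? sq2 : 1.0;
        double drop = (z(r, c) - z(rn, cn)) / dist;
        if (drop > best) { best = drop; bestk = k; }  // strict > keeps first tie
      }
      if (bestk >= 0) dir(r, c) = bestk + 1;
      else if (edge) dir(r, c) = 0;  // drains off-grid
      // else: flat interior cell, resolved below
    }
  }

  // Seed the flat BFS with unresolved cells adjacent to an equal-elevation
  // resolved cell; each flat cell then points at its BFS predecessor, so all
  // paths lead to the flat's spill.
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (!valid_cell(z, r, c) || dir(r, c) != NA_INTEGER) continue;
      for (int k = 0; k < 8; ++k) {
        int rn = r + DR[k], cn = c + DC[k];
        if (valid_cell(z, rn, cn) && dir(rn, cn) != NA_INTEGER &&
            z(rn, cn) == z(r, c)) {
          dir(r, c) = k + 1;
          flatq.push(r * nc + c);
          break;
        }
      }
    }
  while (!flatq.empty()) {
    int idx = flatq.front();
    flatq.pop();
    int r = idx / nc, c = idx % nc;
    for (int k = 0; k < 8; ++k) {
      int rn = r + DR[k], cn = c + DC[k];
      if (!valid_cell(z, rn, cn) || dir(rn, cn) != NA_INTEGER) continue;
      if (z(rn, cn) != z(r, c)) continue;
      // neighbour flows into the just-resolved cell: reverse of offset k
      dir(rn, cn) = ((k + 4) % 8) + 1;
      flatq.push(rn * nc + cn);
    }
  }

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (valid_cell(z, r, c) && dir(r, c) == NA_INTEGER)
        stop("unresolved flat region with no outlet at cell (%d, %d)",
             r + 1, c + 1);
  return dir;
}

static inline int receiver(const IntegerMatrix &dir, int r, int c) {
  int d = dir(r, c);
  if (d == NA_INTEGER || d == 0) return -1;
  int rn = r + DR[d - 1], cn = c + DC[d - 1];
  if (rn < 0 || cn < 0 || rn >= dir.nrow() || cn >= dir.ncol()) return -1;
  if (dir(rn, cn) == NA_INTEGER) return -1;
  return rn * dir.ncol() + cn;
}

// Flow accumulation by Kahn topological sweep; count includes the cell itself.
// [[Rcpp::export]]
NumericMatrix flow_accumulation_cpp(IntegerMatrix dir) {
  int nr = dir.nrow(), nc = dir.ncol(), n = nr * nc;
  NumericMatrix acc(nr, nc);
  std::vector<int> indeg(n, 0);
  std::vector<int> recv(n, -1);
  int nvalid = 0;

  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      if (dir(r, c) == NA_INTEGER) { acc(r, c) = NA_REAL; continue; }
      ++nvalid;
      recv[r * nc + c] = receiver(dir, r, c);
    }
  for (int i = 0; i < n; ++i)
    if (recv[i] >= 0) ++indeg[recv[i]];

  std::queue<int> q;
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (dir(r, c) != NA_INTEGER) {
        acc(r, c) = 1.0;
        if (indeg[r * nc + c] == 0) q.push(r * nc + c);
      }

  int done = 0;
  while (!q.empty()) {
    int i = q.front();
    q.pop();
    ++done;
    int to = recv[i];
    if (to >= 0) {
      acc(to / nc, to % nc) += acc(i / nc, i % nc);
      if (--indeg[to] == 0) q.push(to);
    }
  }
  if (done != nvalid) stop("cycle detected in flow directions");
  return acc;
}

// All cells draining through any seed cell (upstream set, seeds included).
// seed_rows/seed_cols are 1-based.
// [[Rcpp::export]]
LogicalMatrix catchment_mask_cpp(IntegerMatrix dir, IntegerVector seed_rows,
                                 IntegerVector seed_cols) {
  int nr = dir.nrow(), nc = dir.ncol(), n = nr * nc;
  std::vector<int> recv(n, -1);
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c)
      if (dir(r, c) != NA_INTEGER) recv[r * nc + c] = receiver(dir, r, c);

  // donor adjacency in CSR form
  std::vector<int> cnt(n + 1, 0);
  for (int i = 0; i < n; ++i)
    if (recv[i] >= 0) ++cnt[recv[i] + 1];
  for (int i = 0; i < n; ++i) cnt[i + 1] += cnt[i];
  std::vector<int> donors(cnt[n]);
  std::vector<int> pos(cnt.begin(), cnt.end() - 1);
  for (int i = 0; i < n; ++i)
    if (recv[i] >= 0) donors[pos[recv[i]]++] = i;

  LogicalMatrix mask(nr, nc);
  std::queue<int> q;
  for (int s = 0; s < seed_rows.size(); ++s) {
    int r = seed_rows[s] - 1, c = seed_cols[s] - 1;
    if (r < 0 || c < 0 || r >= nr || c >= nc || dir(r, c) == NA_INTEGER)
      stop("seed cell outside valid grid");
    if (!mask(r, c)) { mask(r, c) = true; q.push(r * nc + c); }
  }
  while (!q.empty()) {
    int i = q.front();
    q.pop();
    for (int j = cnt[i]; j < cnt[i + 1]; ++j) {
      int d = donors[j];
      if (!mask(d / nc, d % nc)) {
        mask(d / nc, d % nc) = true;
        q.push(d);
      }
    }
  }
  return mask;
}
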