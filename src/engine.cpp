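// Compute kernels for the lazy-random-walk surface diffusion engine.
//
// All kernels operate on a compressed sparse row (CSR) view of the
// face-adjacency graph of a voxel surface: ptr is the 0-based offset
// vector (length n+1) and idx the concatenated 0-based neighbour lists.
// The graph is undirected, so the CSR doubles as CSC.

#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Wave-front (breadth-first) geodesic distance transform.
// Every hop between face-adjacent surface nodes costs one node unit.
// Returns integer hop counts; -1 flags nodes unreachable from the start.
// [[Rcpp::export(name = ".bfs_csr")]]
IntegerVector bfs_csr(IntegerVector ptr, IntegerVector idx, int start0) {
  const int n = ptr.size() - 1;
  IntegerVector dist(n, -1);
  std::vector<int> frontier, next;
  frontier.reserve(1024);
  next.reserve(1024);
  frontier.push_back(start0);
  dist[start0] = 0;
  int lev = 0;
  while (!frontier.empty()) {
    ++lev;
    next.clear();
    for (size_t f = 0; f < frontier.size(); ++f) {
      const int i = frontier[f];
      for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
        const int nb = idx[k];
        if (dist[nb] < 0) {
          dist[nb] = lev;
          next.push_back(nb);
        }
      }
    }
    frontier.swap(next);
  }
  return dist;
}

// Lazy-walk probability propagation u[t+1] = D u[t] with
// D(i,i) = 0.5 (1.0 on isolated nodes) and D(i,j) = 0.5/deg(j) for
// face-adjacent i, j: half of the mass at each node is redistributed
// equally among its surface neighbours every iteration.
//
// Nodes must be ordered by geodesic distance from the start node so that
// the support of the field at iteration t is a prefix of the node list
// (it is contained in the graph ball of radius t).  ball[t+1] gives the
// number of nodes within distance t (R indexing); the update at
// iteration t only touches that prefix, which is the expanding-region
// optimization.  Passing ball = n for every t disables it; results are
// identical either way because mass can travel at most one hop per
// iteration.
//
// W holds per-node squared distances, one column per metric; the
// population MSD for each metric, the total mass and the count of nodes
// carrying mass > occ_threshold are accumulated at every iteration.
// Dense field snapshots are returned for the iterations listed in
// record.
// [[Rcpp::export(name = ".propagate_csr")]]
List propagate_csr(IntegerVector ptr, IntegerVector idx, NumericVector wcol,
                   NumericVector selfw, int start0, int niter,
                   NumericMatrix W, NumericVector ball, IntegerVector record,
                   double occ_threshold) {
  const int n = ptr.size() - 1;
  const int m = W.ncol();
  if (m > 3) stop("at most three metric columns are supported");
  std::vector<double> v(n, 0.0), vn(n, 0.0);
  v[start0] = 1.0;
  NumericMatrix msd(niter + 1, std::max(m, 1));
  NumericVector mass(niter + 1), occupied(niter + 1);
  mass[0] = 1.0;
  occupied[0] = (occ_threshold < 1.0) ? 1.0 : 0.0;
  List snaps;
  IntegerVector snap_iters;
  std::vector<int> rec(record.begin(), record.end());
  std::sort(rec.begin(), rec.end());
  size_t ri = 0;
  while (ri < rec.size() && rec[ri] < 1) ++ri;
  const double *w0 = (m > 0) ? &W(0, 0) : 0;
  const double *w1 = (m > 1) ? &W(0, 1) : 0;
  const double *w2 = (m > 2) ? &W(0, 2) : 0;
  for (int t = 1; t <= niter; ++t) {
    int kafter = n;  // nodes that can carry mass after this step
    if (t < ball.size()) {
      const double b = ball[t];
      if (b < n) kafter = (int)b;
    }
    for (int i = 0; i < kafter; ++i) {
      double acc = selfw[i] * v[i];
      for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
        const int j = idx[k];
        acc += wcol[j] * v[j];
      }
      vn[i] = acc;
    }
    std::copy(vn.begin(), vn.begin() + kafter, v.begin());
    double s = 0.0, a0 = 0.0, a1 = 0.0, a2 = 0.0;
    int occ = 0;
    for (int i = 0; i < kafter; ++i) {
      const double vi = v[i];
      s += vi;
      if (vi > occ_threshold) ++occ;
      if (w0) a0 += vi * w0[i];
      if (w1) a1 += vi * w1[i];
      if (w2) a2 += vi * w2[i];
    }
    mass[t] = s;
    occupied[t] = occ;
    if (m > 0) msd(t, 0) = a0;
    if (m > 1) msd(t, 1) = a1;
    if (m > 2) msd(t, 2) = a2;
    if (ri < rec.size() && rec[ri] == t) {
      snaps.push_back(NumericVector(v.begin(), v.end()));
      snap_iters.push_back(t);
      while (ri < rec.size() && rec[ri] == t) ++ri;
    }
    if ((t & 255) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["msd"] = msd, _["mass"] = mass,
                      _["occupied"] = occupied, _["snapshots"] = snaps,
                      _["snapshot_iterations"] = snap_iters);
}

// Stochastic single-particle tracks of the same lazy walk: per
// iteration a particle stays put with probability 0.5 and otherwise
// moves to a uniformly chosen surface neighbour.  One uniform draw per
// iteration drives both decisions (u < 0.5 stays; otherwise
// (u - 0.5)/0.5 picks the neighbour), so a track is reproducible from
// the R RNG state alone.  Records node ids (1-based) every
// record_every iterations plus the final iteration; rows are recorded
// iterations, columns tracks.
// [[Rcpp::export(name = ".sample_tracks_csr")]]
IntegerMatrix sample_tracks_csr(IntegerVector ptr, IntegerVector idx,
                                int start0, int n_tracks, int n_iter,
                                int record_every) {
  std::vector<int> recs;
  for (int t = 0; t <= n_iter; t += record_every) recs.push_back(t);
  if (recs.back() != n_iter) recs.push_back(n_iter);
  IntegerMatrix out(recs.size(), n_tracks);
  RNGScope scope;
  for (int tr = 0; tr < n_tracks; ++tr) {
    int pos = start0;
    size_t ri = 0;
    if (recs[0] == 0) {
      out(0, tr) = pos + 1;
      ri = 1;
    }
    for (int t = 1; t <= n_iter; ++t) {
      const double u = unif_rand();
      if (u >= 0.5) {
        const int deg = ptr[pos + 1] - ptr[pos];
        if (deg > 0) {
          int k = (int)((u - 0.5) * 2.0 * deg);
          if (k >= deg) k = deg - 1;
          pos = idx[ptr[pos] + k];
        }
      }
      if (ri < recs.size() && recs[ri] == t) {
        out(ri, tr) = pos + 1;
        ++ri;
      }
    }
  }
  out.attr("iterations") = IntegerVector(recs.begin(), recs.end());
  return out;
}
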