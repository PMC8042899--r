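// Event-driven structured-coalescent simulator for independent loci.
//
// Demes hold diploid sizes N (coalescence rate k(k-1)/(4N) per generation,
// continuous-time approximation); backward migration rates m[i][j] are the
// per-generation probability that a lineage in i traces to j. Demographic
// events (deme joins, size changes, migration-rate changes) are applied at
// fixed times, backward from the present. Mutations follow the
// infinite-sites model: Poisson(mu * L * total tree length) mutations
// dropped uniformly on branches.
//
// Uses R's RNG so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
List sim_loci_cpp(IntegerVector sample_sizes, NumericVector deme_sizes0,
                  NumericMatrix mig0, DataFrame events, double mu,
                  double locus_bp, int n_loci) {
  const int nd = sample_sizes.size();
  if (deme_sizes0.size() != nd || mig0.nrow() != nd || mig0.ncol() != nd)
    stop("deme dimensions disagree");
  NumericVector ev_time = events["time"];
  IntegerVector ev_type = events["type"];   // 0 join, 1 size, 2 mig
  IntegerVector ev_i = events["i"];
  IntegerVector ev_j = events["j"];
  NumericVector ev_x = events["x"];
  const int nev = ev_time.size();
  int n = 0;
  for (int d = 0; d < nd; ++d) n += sample_sizes[d];
  if (n < 2) stop("need at least 2 sampled haplotypes");
  const int n_nodes = 2 * n - 1;

  List out(n_loci);
  std::vector<int> parent(n_nodes);
  std::vector<double> ntime(n_nodes);
  std::vector<int> lin_node(n), lin_deme(n);
  std::vector<double> sizes(nd);
  std::vector<double> mig(nd * nd);
  std::vector<double> coal_r(nd), mig_r(nd), mig_row(nd);

  for (int locus = 0; locus < n_loci; ++locus) {
    for (int v = 0; v < n_nodes; ++v) { parent[v] = -1; ntime[v] = 0.0; }
    int nl = 0;
    for (int d = 0; d < nd; ++d)
      for (int s = 0; s < sample_sizes[d]; ++s) {
        lin_node[nl] = nl; lin_deme[nl] = d; ++nl;
      }
    for (int d = 0; d < nd; ++d) sizes[d] = deme_sizes0[d];
    for (int i = 0; i < nd; ++i)
      for (int j = 0; j < nd; ++j) mig[i * nd + j] = mig0(i, j);
    double t = 0.0;
    int eptr = 0, next_node = n;

    while (nl > 1) {
      double tot = 0.0;
      std::vector<int> k(nd, 0);
      for (int l = 0; l < nl; ++l) k[lin_deme[l]]++;
      for (int d = 0; d < nd; ++d) {
        coal_r[d] = (k[d] > 1 && sizes[d] > 0.0)
          ? k[d] * (k[d] - 1.0) / (4.0 * sizes[d]) : 0.0;
        mig_row[d] = 0.0;
        for (int j = 0; j < nd; ++j) mig_row[d] += mig[d * nd + j];
        mig_r[d] = k[d] * mig_row[d];
        tot += coal_r[d] + mig_r[d];
      }
      double t_next = R_PosInf;
      if (tot > 0.0) t_next = t + R::exp_rand() / tot;
      if (eptr < nev && ev_time[eptr] <= t_next) {
        t = ev_time[eptr];
        while (eptr < nev && ev_time[eptr] <= t) {
          int ty = ev_type[eptr], i = ev_i[eptr], j = ev_j[eptr];
          if (ty == 0) {                 // join: i -> j
            for (int l = 0; l < nl; ++l)
              if (lin_deme[l] == i) lin_deme[l] = j;
            for (int d = 0; d < nd; ++d) {
              mig[i * nd + d] = 0.0; mig[d * nd + i] = 0.0;
            }
          } else if (ty == 1) {
            sizes[i] = ev_x[eptr];
          } else {
            mig[i * nd + j] = ev_x[eptr];
          }
          ++eptr;
        }
        continue;
      }
      if (!R_finite(t_next))
        stop("lineages cannot coalesce: disconnected demes with no events left");
      t = t_next;
      double u = unif_rand() * tot;
      int d = 0; bool is_coal = true;
      for (d = 0; d < nd; ++d) {
        if (u < coal_r[d]) { is_coal = true; break; }
        u -= coal_r[d];
        if (u < mig_r[d]) { is_coal = false; break; }
        u -= mig_r[d];
      }
      if (d == nd) d = nd - 1;          // numerical edge
      if (is_coal) {
        // pick two distinct lineages in deme d
        int a = (int)(unif_rand() * k[d]); if (a >= k[d]) a = k[d] - 1;
        int b = (int)(unif_rand() * (k[d] - 1)); if (b >= k[d] - 1) b = k[d] - 2;
        if (b >= a) ++b;
        int ia = -1, ib = -1, seen = 0;
        for (int l = 0; l < nl; ++l) {
          if (lin_deme[l] == d) {
            if (seen == a) ia = l;
            if (seen == b) ib = l;
            ++seen;
          }
        }
        int v = next_node++;
        ntime[v] = t;
        parent[lin_node[ia]] = v;
        parent[lin_node[ib]] = v;
        lin_node[ia] = v;
        lin_node[ib] = lin_node[nl - 1];
        lin_deme[ib] = lin_deme[nl - 1];
        --nl;
      } else {
        int a = (int)(unif_rand() * k[d]); if (a >= k[d]) a = k[d] - 1;
        int ia = -1, seen = 0;
        for (int l = 0; l < nl; ++l)
          if (lin_deme[l] == d) { if (seen == a) { ia = l; break; } ++seen; }
        double w = unif_rand() * mig_row[d];
        int j = 0;
        for (j = 0; j < nd; ++j) {
          if (w < mig[d * nd + j]) break;
          w -= mig[d * nd + j];
        }
        if (j == nd) j = nd - 1;
        lin_deme[ia] = j;
      }
    }

    // branch lengths (root excluded: parent == -1)
    std::vector<double> blen(n_nodes, 0.0);
    double total_len = 0.0;
    for (int v = 0; v < n_nodes; ++v) {
      if (parent[v] >= 0) {
        blen[v] = ntime[parent[v]] - ntime[v];
        total_len += blen[v];
      }
    }
    int S = (int) R::rpois(mu * locus_bp * total_len);
    IntegerMatrix G(n, S);
    if (S > 0) {
      // cumulative branch lengths for uniform placement
      std::vector<double> cum(n_nodes, 0.0);
      double acc = 0.0;
      for (int v = 0; v < n_nodes; ++v) { acc += blen[v]; cum[v] = acc; }
      // children lists for descendant collection
      std::vector<std::vector<int> > child(n_nodes);
      for (int v = 0; v < n_nodes; ++v)
        if (parent[v] >= 0) child[parent[v]].push_back(v);
      std::vector<int> stack;
      for (int s = 0; s < S; ++s) {
        double u = unif_rand() * total_len;
        int lo = 0, hi = n_nodes - 1;
        while (lo < hi) {
          int mid = (lo + hi) / 2;
          if (cum[mid] < u) lo = mid + 1; else hi = mid;
        }
        stack.clear();
        stack.push_back(lo);
        while (!stack.empty()) {
          int v = stack.back(); stack.pop_back();
          if (v < n) G(v, s) = 1;
          else for (size_t c = 0; c < child[v].size(); ++c)
            stack.push_back(child[v][c]);
        }
      }
    }
    out[locus] = G;
  }
  return out;
}
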