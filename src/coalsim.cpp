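#include <Rcpp.h>
using namespace Rcpp;

// Discrete-generation structured coalescent, run backward in time.
//
// Within each deme of current size N, every unordered pair of lineages
// coalesces with probability 1/N per generation; collisions are resolved
// by random disjoint pairing, so a lineage joins at most one merger per
// generation.  Every lineage outside the source deme migrates into it
// with probability `mig` per generation.  At the horizon all survivors
// are placed in the source deme, which persists at `post_size` until the
// MRCA; there the per-generation scheme is preserved exactly but waiting
// times are sampled geometrically for speed.
//
// Uses R's RNG throughout, so set.seed() in R gives full determinism.

// number of coalescing pair-proposals this generation, conditioned >= 1,
// for Binomial(npairs, p) (walk the conditional CDF; p is typically tiny)
static int rbinom_ge1(double npairs, double p) {
  if (p >= 1.0) return (int)npairs;
  double pmf = std::pow(1.0 - p, npairs);       // P(0)
  double u = unif_rand() * (1.0 - pmf);
  double cum = 0.0;
  double ratio = p / (1.0 - p);
  int m = 0;
  while (cum < u && m < (int)npairs) {
    m++;
    pmf *= (npairs - m + 1.0) / m * ratio;
    cum += pmf;
  }
  return m > 0 ? m : 1;
}

// [[Rcpp::export]]
List sim_genealogy_cpp(IntegerVector leaf_deme, NumericMatrix deme_sizes,
                       int source, double mig, int horizon,
                       double post_size) {
  const int n = leaf_deme.size();
  const int D = deme_sizes.nrow();
  const int ntot = 2 * n - 1;
  IntegerVector parent(ntot, 0);
  NumericVector node_time(ntot, 0.0);

  if (n == 1) {
    return List::create(_["parent"] = parent, _["time"] = node_time,
                        _["n_migrations"] = 0);
  }

  std::vector<int> act(n), deme(n);
  for (int i = 0; i < n; i++) {
    act[i] = i;                       // 0-based node id
    int d = leaf_deme[i];
    if (d < 1 || d > D) stop("leaf deme id out of range");
    deme[i] = d;
  }
  int next_node = n;
  long n_mig = 0;

  std::vector<int> idx;               // scratch: positions within one deme
  std::vector<char> dead;
  std::vector<int> cnt(D + 1), start(D + 2), order_buf;

  // ---- pre-horizon: explicit generation loop --------------------------
  for (int tau = 1; tau <= horizon && act.size() > 1; tau++) {
    // bucket active lineages by deme in one pass (counting sort)
    std::fill(cnt.begin(), cnt.end(), 0);
    for (size_t i = 0; i < act.size(); i++) cnt[deme[i]]++;
    start[1] = 0;
    for (int d = 1; d <= D; d++) start[d + 1] = start[d] + cnt[d];
    order_buf.assign(act.size(), 0);
    {
      std::vector<int> pos(start.begin() + 1, start.begin() + D + 2);
      for (size_t i = 0; i < act.size(); i++)
        order_buf[pos[deme[i] - 1]++] = (int)i;
    }
    // coalescence within each deme at size N_d(tau)
    dead.assign(act.size(), 0);
    bool any_dead = false;
    for (int d = 1; d <= D; d++) {
      int k = cnt[d];
      if (k < 2) continue;
      idx.assign(order_buf.begin() + start[d],
                 order_buf.begin() + start[d] + k);
      double N = deme_sizes(d - 1, tau - 1);
      if (N < 1.0) N = 1.0;
      double p = 1.0 / N;
      double npairs = k * (k - 1.0) / 2.0;
      int m = (int)R::rbinom(npairs, p);
      if (m <= 0) continue;
      int nmerge = std::min(m, k / 2);
      // random disjoint pairing: partial Fisher-Yates for 2*nmerge slots
      for (int i = 0; i < 2 * nmerge; i++) {
        int j = i + (int)(unif_rand() * (k - i));
        if (j >= k) j = k - 1;
        std::swap(idx[i], idx[j]);
      }
      for (int j = 0; j < nmerge; j++) {
        int a = idx[2 * j], b = idx[2 * j + 1];
        parent[act[a]] = next_node + 1;   // 1-based parent ids
        parent[act[b]] = next_node + 1;
        node_time[next_node] = tau;
        act[a] = next_node;               // merged lineage stays in deme d
        dead[b] = 1;
        any_dead = true;
        next_node++;
      }
    }
    if (any_dead) {
      size_t w = 0;
      for (size_t i = 0; i < act.size(); i++) {
        if (!dead[i]) { act[w] = act[i]; deme[w] = deme[i]; w++; }
      }
      act.resize(w); deme.resize(w);
    }
    // backward migration into the source deme
    if (mig > 0.0) {
      for (size_t i = 0; i < act.size(); i++) {
        if (deme[i] != source && unif_rand() < mig) {
          deme[i] = source;
          n_mig++;
        }
      }
    }
  }

  // ---- post-horizon: single persistent source deme --------------------
  double t = horizon;
  if (post_size < 1.0) post_size = 1.0;
  double p = 1.0 / post_size;
  while (act.size() > 1) {
    int k = (int)act.size();
    double npairs = k * (k - 1.0) / 2.0;
    double q = 1.0 - std::pow(1.0 - p, npairs);   // P(>=1 merger per gen)
    double skip = (q >= 1.0) ? 0.0 : R::rgeom(q); // failures before event
    t += skip + 1.0;
    int m = rbinom_ge1(npairs, p);
    int nmerge = std::min(m, k / 2);
    for (int i = 0; i < 2 * nmerge; i++) {
      int j = i + (int)(unif_rand() * (k - i));
      if (j >= k) j = k - 1;
      std::swap(act[i], act[j]);
    }
    size_t w = 0;
    std::vector<int> keep;
    keep.reserve(k);
    for (int j = 0; j < nmerge; j++) {
      parent[act[2 * j]] = next_node + 1;
      parent[act[2 * j + 1]] = next_node + 1;
      node_time[next_node] = t;
      keep.push_back(next_node);
      next_node++;
    }
    for (int i = 2 * nmerge; i < k; i++) keep.push_back(act[i]);
    act = keep;
    (void)w;
  }

  return List::create(_["parent"] = parent, _["time"] = node_time,
                      _["n_migrations"] = (double)n_mig);
}
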