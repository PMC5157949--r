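// Kingman coalescent under piecewise-exponential demography, with
// finite-sites Jukes-Cantor mutation dropping.
//
// Conventions: time in generations before present; diploid sizes N; a pair
// of lineages coalesces at rate 1/(2N(t)) per generation; within an epoch
// N(u) = N_recent * exp(-rho * (u - t_start)) going backwards. All
// randomness comes from R's RNG so R-level set.seed() gives full
// reproducibility.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

struct Model {
  std::vector<double> dur, N, rho, tstart, seg; // seg: pair intensity of whole epoch
  int k;
};

static Model make_model(const NumericMatrix& epochs) {
  Model m;
  m.k = epochs.nrow();
  m.dur.resize(m.k); m.N.resize(m.k); m.rho.resize(m.k);
  m.tstart.resize(m.k); m.seg.resize(m.k);
  double t = 0.0;
  for (int e = 0; e < m.k; ++e) {
    m.dur[e] = epochs(e, 0);
    m.N[e]   = epochs(e, 1);
    m.rho[e] = epochs(e, 2);
    m.tstart[e] = t;
    if (R_finite(m.dur[e])) t += m.dur[e];
    if (!R_finite(m.dur[e])) {
      m.seg[e] = R_PosInf;
    } else if (m.rho[e] == 0.0) {
      m.seg[e] = m.dur[e] / (2.0 * m.N[e]);
    } else {
      m.seg[e] = expm1(m.rho[e] * m.dur[e]) / (2.0 * m.N[e] * m.rho[e]);
    }
  }
  return m;
}

// pair intensity accumulated between absolute times a < b inside epoch e
static double seg_intensity(const Model& m, int e, double a, double b) {
  double ta = m.tstart[e];
  if (m.rho[e] == 0.0) return (b - a) / (2.0 * m.N[e]);
  return (exp(m.rho[e] * (b - ta)) - exp(m.rho[e] * (a - ta))) /
         (2.0 * m.N[e] * m.rho[e]);
}

// absolute time at which pair intensity `h` accumulates, starting from
// absolute time a inside epoch e (assumes it is reachable within the epoch)
static double seg_invert(const Model& m, int e, double a, double h) {
  double ta = m.tstart[e];
  if (m.rho[e] == 0.0) return a + 2.0 * m.N[e] * h;
  double v = exp(m.rho[e] * (a - ta)) + 2.0 * m.N[e] * m.rho[e] * h;
  return ta + log(v) / m.rho[e];
}

static int epoch_of(const Model& m, double t) {
  int e = 0;
  while (e + 1 < m.k && t >= m.tstart[e + 1]) ++e;
  return e;
}

// waiting time until the next coalescence among k lineages starting at t0;
// returns the absolute coalescence time
static double next_coal_time(const Model& m, int k, double t0) {
  double target = R::exp_rand() / (0.5 * k * (k - 1)); // pair-units hazard
  int e = epoch_of(m, t0);
  double a = t0;
  for (;;) {
    double epoch_end = R_finite(m.dur[e]) ? m.tstart[e] + m.dur[e] : R_PosInf;
    double avail = R_finite(epoch_end) ? seg_intensity(m, e, a, epoch_end) : R_PosInf;
    if (target <= avail) return seg_invert(m, e, a, target);
    target -= avail;
    a = epoch_end;
    ++e;
  }
}

// [[Rcpp::export]]
List cpp_coal_times(int n, NumericMatrix epochs, int reps) {
  Model m = make_model(epochs);
  NumericVector sum_t(n - 1), sumsq_t(n - 1); // index k-2 holds level k
  NumericVector tmrca(reps), tlen(reps);
  for (int r = 0; r < reps; ++r) {
    double t = 0.0, len = 0.0;
    for (int k = n; k >= 2; --k) {
      double tc = next_coal_time(m, k, t);
      double Tk = tc - t;
      sum_t[k - 2] += Tk;
      sumsq_t[k - 2] += Tk * Tk;
      len += k * Tk;
      t = tc;
    }
    tmrca[r] = t;
    tlen[r] = len;
  }
  return List::create(_["sum_t"] = sum_t, _["sumsq_t"] = sumsq_t,
                      _["tmrca"] = tmrca, _["tlen"] = tlen, _["reps"] = reps);
}

struct Tree {
  // nodes 0..n-1 leaves, n..2n-2 internal in coalescence order (root last)
  std::vector<int> parent;
  std::vector<double> age, blen, cumlen;
  std::vector<int> order;     // nodes sorted by decreasing age (root first)
  std::vector<int> leafcount; // leaves subtended by each node
  double tlen;
  int n;
};

static void finish_tree(Tree& tr) {
  int tot = 2 * tr.n - 1;
  tr.blen.assign(tot, 0.0);
  tr.cumlen.assign(tot, 0.0);
  double acc = 0.0;
  for (int v = 0; v < tot; ++v) {
    if (tr.parent[v] >= 0) tr.blen[v] = tr.age[tr.parent[v]] - tr.age[v];
    acc += tr.blen[v];
    tr.cumlen[v] = acc;
  }
  tr.tlen = acc;
  tr.order.resize(tot);
  for (int v = 0; v < tot; ++v) tr.order[v] = v;
  std::sort(tr.order.begin(), tr.order.end(),
            [&tr](int a, int b) { return tr.age[a] > tr.age[b]; });
  tr.leafcount.assign(tot, 0);
  for (int v = 0; v < tr.n; ++v) tr.leafcount[v] = 1;
  // children are younger than parents: accumulate youngest-first
  for (int idx = tot - 1; idx >= 0; --idx) {
    int v = tr.order[idx];
    if (tr.parent[v] >= 0) tr.leafcount[tr.parent[v]] += tr.leafcount[v];
  }
}

static void sim_tree(const Model& m, int n, Tree& tr) {
  int tot = 2 * n - 1;
  tr.n = n;
  tr.parent.assign(tot, -1);
  tr.age.assign(tot, 0.0);
  std::vector<int> active(n);
  for (int i = 0; i < n; ++i) active[i] = i;
  double t = 0.0;
  int next_node = n;
  for (int k = n; k >= 2; --k) {
    t = next_coal_time(m, k, t);
    int i = (int)(R::unif_rand() * k); if (i >= k) i = k - 1;
    int j = (int)(R::unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
    if (j >= i) ++j;
    int a = active[i], b = active[j];
    tr.parent[a] = next_node; tr.parent[b] = next_node;
    tr.age[next_node] = t;
    // replace i by the new node, drop j
    active[i] = next_node;
    active[j] = active[k - 1];
    ++next_node;
  }
  finish_tree(tr);
}

// Draw from Poisson(lambda) conditioned on being >= 1.
static int rpois_pos(double lambda) {
  double p0 = exp(-lambda);
  double u = R::unif_rand() * (1.0 - p0);
  double cum = 0.0, term = p0;
  for (int k = 1; k < 1000; ++k) {
    term *= lambda / k;
    cum += term;
    if (u <= cum) return k;
  }
  return 1000;
}

struct MutEdge {
  int node;                  // child end of the mutated edge
  std::vector<double> times; // mutation ages on this edge (sorted desc)
  unsigned char base_after;  // base below the youngest mutation
  int region;                // leaves whose innermost mutated edge is this
  int anc;                   // index of nearest mutated ancestor edge, -1 root
};

// Drop `nmut` Jukes-Cantor mutations on the tree and classify the site.
// Leaf alleles are resolved without touching every node: mutated edges are
// processed ancestors-first, each edge's incoming base is read off its
// nearest mutated ancestor, and allele counts follow from subtree leaf
// counts of the nested mutation regions. Returns the number of distinct
// leaf alleles; fills minor and derived counts (derived = non-root allele;
// if the root allele is absent from the leaves the minor allele is
// reported as derived).
static int drop_site(const Tree& tr, int nmut,
                     std::vector<MutEdge>& edges,
                     int& minor, int& derived) {
  int tot = 2 * tr.n - 1;
  int root = tot - 1;
  edges.clear();
  for (int j = 0; j < nmut; ++j) {
    double u = R::unif_rand() * tr.tlen;
    int lo = 0, hi = tot - 1;
    while (lo < hi) { // first node with cumlen >= u
      int mid = (lo + hi) / 2;
      if (tr.cumlen[mid] >= u) hi = mid; else lo = mid + 1;
    }
    int v = lo;
    double tmut = tr.age[v] + R::unif_rand() * tr.blen[v];
    int found = -1;
    for (size_t q = 0; q < edges.size(); ++q) {
      if (edges[q].node == v) { found = (int)q; break; }
    }
    if (found < 0) {
      edges.push_back(MutEdge());
      found = (int)edges.size() - 1;
      edges[found].node = v;
    }
    edges[found].times.push_back(tmut);
  }
  int rootbase = (int)(R::unif_rand() * 4.0); if (rootbase > 3) rootbase = 3;
  // ancestors first: sort by child age descending (ancestor edges span
  // strictly older ages than descendant edges)
  std::sort(edges.begin(), edges.end(),
            [&tr](const MutEdge& a, const MutEdge& b) {
              return tr.age[a.node] > tr.age[b.node];
            });
  int k = (int)edges.size();
  for (int q = 0; q < k; ++q) {
    MutEdge& e = edges[q];
    std::sort(e.times.begin(), e.times.end(), std::greater<double>());
    // nearest mutated ancestor: walk up until a mutated edge or the root
    e.anc = -1;
    int a = tr.parent[e.node];
    while (a >= 0 && a != root) {
      int hit = -1;
      for (int q2 = 0; q2 < q; ++q2) if (edges[q2].node == a) { hit = q2; break; }
      if (hit >= 0) { e.anc = hit; break; }
      a = tr.parent[a];
    }
    unsigned char b = (e.anc >= 0) ? edges[e.anc].base_after
                                   : (unsigned char)rootbase;
    for (size_t jm = 0; jm < e.times.size(); ++jm) {
      int shift = 1 + (int)(R::unif_rand() * 3.0); if (shift > 3) shift = 3;
      b = (unsigned char)((b + shift) % 4);
    }
    e.base_after = b;
    e.region = tr.leafcount[e.node];
  }
  int cnt[4] = {0, 0, 0, 0};
  int outside = tr.n;
  // subtract each edge's subtree from the region of its nearest mutated
  // ancestor (or from the unmutated root region)
  for (int q = k - 1; q >= 0; --q) {
    if (edges[q].anc >= 0) edges[edges[q].anc].region -= tr.leafcount[edges[q].node];
    else outside -= tr.leafcount[edges[q].node];
  }
  for (int q = 0; q < k; ++q) cnt[edges[q].base_after] += edges[q].region;
  cnt[rootbase] += outside;
  int nall = 0;
  for (int a = 0; a < 4; ++a) if (cnt[a] > 0) ++nall;
  minor = 0; derived = 0;
  if (nall == 2) {
    int a1 = -1, a2 = -1;
    for (int a = 0; a < 4; ++a) if (cnt[a] > 0) { if (a1 < 0) a1 = a; else a2 = a; }
    minor = std::min(cnt[a1], cnt[a2]);
    if (a1 == rootbase) derived = cnt[a2];
    else if (a2 == rootbase) derived = cnt[a1];
    else derived = minor;
  }
  return nall;
}

// Simulate sequence blocks at one mutation rate (or a lognormal mixture of
// rates when sigma > 0) until `min_biallelic` biallelic sites accumulate.
// [[Rcpp::export]]
List cpp_grid_point(int n, NumericMatrix epochs, double M, double sigma,
                    int L, int min_biallelic, int max_trees, int rare_max) {
  Model m = make_model(epochs);
  Tree tr;
  std::vector<MutEdge> muts;
  double n_sites = 0.0;
  long long n_bi = 0, n_tri = 0, n_quad = 0, n_rare = 0, n_trees = 0;
  NumericVector sfs_derived(n - 1);
  double lcorr = -0.5 * sigma * sigma * M_LN10; // mean-preserving log10 shift
  while (n_bi < min_biallelic && n_trees < max_trees) {
    sim_tree(m, n, tr);
    ++n_trees;
    n_sites += L;
    if (sigma == 0.0) {
      double p = -expm1(-M * tr.tlen);
      int nmutsites = (int)R::rbinom((double)L, p);
      double lam = M * tr.tlen;
      for (int s = 0; s < nmutsites; ++s) {
        int nmut = rpois_pos(lam);
        int minor, derived;
        int nall = drop_site(tr, nmut, muts, minor, derived);
        if (nall == 2) {
          ++n_bi;
          if (minor <= rare_max) ++n_rare;
          if (derived >= 1 && derived <= n - 1) sfs_derived[derived - 1] += 1;
        } else if (nall == 3) ++n_tri;
        else if (nall == 4) ++n_quad;
      }
    } else {
      for (int s = 0; s < L; ++s) {
        double z = R::norm_rand();
        double rate = M * pow(10.0, sigma * z + lcorr);
        int nmut = (int)R::rpois(rate * tr.tlen);
        if (nmut == 0) continue;
        int minor, derived;
        int nall = drop_site(tr, nmut, muts, minor, derived);
        if (nall == 2) {
          ++n_bi;
          if (minor <= rare_max) ++n_rare;
          if (derived >= 1 && derived <= n - 1) sfs_derived[derived - 1] += 1;
        } else if (nall == 3) ++n_tri;
        else if (nall == 4) ++n_quad;
      }
    }
    if (n_trees % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(
    _["n_sites"] = n_sites, _["n_biallelic"] = (double)n_bi,
    _["n_tri"] = (double)n_tri, _["n_quad"] = (double)n_quad,
    _["n_rare"] = (double)n_rare, _["n_trees"] = (double)n_trees,
    _["sfs_derived"] = sfs_derived);
}

// Unfolded derived-allele spectra at several mutation rates evaluated on a
// SHARED stream of genealogies, so rate comparisons are paired and
// genealogy-level noise cancels in spectrum differences.
// [[Rcpp::export]]
List cpp_paired_spectra(int n, NumericMatrix epochs, NumericVector rates,
                        double sigma, int L, int n_trees) {
  Model m = make_model(epochs);
  Tree tr;
  std::vector<MutEdge> muts;
  int nr = rates.size();
  NumericMatrix sfs(n - 1, nr);
  NumericVector n_bi(nr), n_sites(nr);
  double lcorr = -0.5 * sigma * sigma * M_LN10;
  for (int t = 0; t < n_trees; ++t) {
    sim_tree(m, n, tr);
    for (int r = 0; r < nr; ++r) {
      double M = rates[r];
      n_sites[r] += L;
      for (int s = 0; s < L; ++s) {
        double rate = M;
        if (sigma > 0) rate = M * pow(10.0, sigma * R::norm_rand() + lcorr);
        int nmut = (int)R::rpois(rate * tr.tlen);
        if (nmut == 0) continue;
        int minor, derived;
        int nall = drop_site(tr, nmut, muts, minor, derived);
        if (nall == 2 && derived >= 1 && derived <= n - 1) {
          sfs(derived - 1, r) += 1;
          n_bi[r] += 1;
        }
      }
    }
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["sfs"] = sfs, _["n_biallelic"] = n_bi,
                      _["n_sites"] = n_sites, _["n_trees"] = n_trees);
}

// One genealogy, returned as parent pointers + node ages (R assembles phylo).
// [[Rcpp::export]]
List cpp_sim_genealogy(int n, NumericMatrix epochs) {
  Model m = make_model(epochs);
  Tree tr;
  sim_tree(m, n, tr);
  return List::create(_["parent"] = IntegerVector(tr.parent.begin(), tr.parent.end()),
                      _["age"] = NumericVector(tr.age.begin(), tr.age.end()),
                      _["tlen"] = tr.tlen);
}

// Jukes-Cantor mutation dropping on a fixed genealogy.
// parent: 0-based parent pointers (root -1); age: node ages in generations.
// [[Rcpp::export]]
IntegerMatrix cpp_mutate_sites(IntegerVector parent, NumericVector age,
                               int n, double M, int L) {
  Tree tr;
  tr.n = n;
  tr.parent.assign(parent.begin(), parent.end());
  tr.age.assign(age.begin(), age.end());
  finish_tree(tr);

  std::vector<MutEdge> muts;
  IntegerMatrix out(L, 4); // n_mutations, n_alleles, minor, derived
  for (int s = 0; s < L; ++s) {
    int nmut = (int)R::rpois(M * tr.tlen);
    int minor = 0, derived = 0;
    int nall = 1;
    if (nmut > 0) nall = drop_site(tr, nmut, muts, minor, derived);
    out(s, 0) = nmut; out(s, 1) = nall; out(s, 2) = minor; out(s, 3) = derived;
  }
  return out;
}

// Weighted-genealogy estimator for the ancestral-polymorphism bound: per
// genealogy, weight = total branch length (mutation opportunity), indicator
// = at least two lineages ancestral to the sample at t_split.
// worst_case: all n lineages survive to t_ooa (no coalescence allowed before
// the terminal epoch), then coalesce in the constant terminal epoch.
// [[Rcpp::export]]
List cpp_ancestral_bound(int n, NumericMatrix epochs, double t_split,
                         bool worst_case, int reps) {
  Model m = make_model(epochs);
  double t_ooa = m.tstart[m.k - 1];
  NumericVector w(reps);
  LogicalVector shared(reps);
  for (int r = 0; r < reps; ++r) {
    double t, len;
    if (worst_case) { t = t_ooa; len = n * t_ooa; } else { t = 0.0; len = 0.0; }
    bool ge2 = t >= t_split && n >= 2;
    for (int k = n; k >= 2; --k) {
      double tc = next_coal_time(m, k, t);
      if (t <= t_split && t_split < tc) ge2 = true; // k >= 2 lineages span t_split
      len += k * (tc - t);
      t = tc;
    }
    w[r] = len;
    shared[r] = ge2;
    if (r % 1024 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["weight"] = w, _["shared"] = shared);
}
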