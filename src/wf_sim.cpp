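// Forward-in-time Wright-Fisher engine over one linear chromosome.
//
// Haplotypes are sorted vectors of derived-allele positions (infinite-sites
// on integer bp, collisions re-drawn).  All randomness comes from R's RNG so
// a set.seed() in R makes runs byte-identical across platforms.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>

using namespace Rcpp;

typedef std::vector<int> Hap;

static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// Meiosis: recombine a parent's two haplotypes.  Crossover count is
// Poisson(rec_len); breakpoints are uniform on [0, L) so a cut at c splits
// positions <= c from positions > c.
static Hap recombine(const Hap &h0, const Hap &h1, int L, double rec_len) {
  int ncx = (rec_len > 0.0) ? (int)R::rpois(rec_len) : 0;
  int first = (unif_rand() < 0.5) ? 0 : 1;
  if (ncx == 0) return first == 0 ? h0 : h1;
  std::vector<int> cuts((size_t)ncx);
  for (int i = 0; i < ncx; ++i) cuts[(size_t)i] = (int)(unif_rand() * L);
  std::sort(cuts.begin(), cuts.end());
  cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
  Hap child;
  child.reserve(std::max(h0.size(), h1.size()));
  const Hap *cur = (first == 0) ? &h0 : &h1;
  int prev = 0;  // copy (prev, hi]
  for (size_t c = 0; c <= cuts.size(); ++c) {
    int hi = (c < cuts.size()) ? cuts[c] : L;
    if (hi > prev) {
      Hap::const_iterator a = std::upper_bound(cur->begin(), cur->end(), prev);
      Hap::const_iterator b = std::upper_bound(cur->begin(), cur->end(), hi);
      child.insert(child.end(), a, b);
      prev = hi;
    }
    cur = (cur == &h0) ? &h1 : &h0;
  }
  return child;
}

static void mutate(Hap &child, int L, double mu_len,
                   std::unordered_set<int> &active) {
  if (mu_len <= 0.0) return;
  int nm = (int)R::rpois(mu_len);
  for (int i = 0; i < nm; ++i) {
    int pos, guard = 0;
    do {
      pos = 1 + (int)(unif_rand() * L);
      if (pos > L) pos = L;
    } while (active.count(pos) && ++guard < 1000000);
    if (guard >= 1000000) stop("mutation position space exhausted");
    active.insert(pos);
    child.insert(std::lower_bound(child.begin(), child.end(), pos), pos);
  }
}

// Remove fixed sites from every haplotype and drop lost sites from the
// active-position registry (keeps lists short; fixed differences carry no
// within-simulation information under infinite sites).
static void purge(std::vector<std::vector<Hap> > &pop,
                  const std::vector<bool> &active_deme,
                  std::unordered_set<int> &active_pos) {
  std::unordered_map<int, int> cnt;
  long tot = 0;
  for (size_t d = 0; d < pop.size(); ++d) {
    if (!active_deme[d]) continue;
    tot += (long)pop[d].size();
    for (size_t h = 0; h < pop[d].size(); ++h)
      for (size_t k = 0; k < pop[d][h].size(); ++k) cnt[pop[d][h][k]]++;
  }
  std::unordered_set<int> fixed;
  active_pos.clear();
  for (std::unordered_map<int, int>::iterator it = cnt.begin(); it != cnt.end(); ++it) {
    if ((long)it->second == tot) fixed.insert(it->first);
    else active_pos.insert(it->first);
  }
  if (fixed.empty()) return;
  for (size_t d = 0; d < pop.size(); ++d) {
    if (!active_deme[d]) continue;
    for (size_t h = 0; h < pop[d].size(); ++h) {
      Hap &hp = pop[d][h];
      Hap keep;
      keep.reserve(hp.size());
      for (size_t k = 0; k < hp.size(); ++k)
        if (!fixed.count(hp[k])) keep.push_back(hp[k]);
      hp.swap(keep);
    }
  }
}

// events: list of list(gen, type, deme, source, size, fraction)
//   type: 0 = bottleneck/resize, 1 = split (activate deme from source),
//         2 = admixture pulse (one generation, fraction of gametes in deme
//             drawn from source)
// Deme indices are 0-based; all demes are pre-declared, inactive ones have
// active0 = FALSE and are activated by a split event.
// [[Rcpp::export(name = ".wf_sim_cpp")]]
List wf_sim_cpp(int seq_length, double mu, double rec,
                IntegerVector deme_sizes, LogicalVector active0,
                NumericMatrix migration, int n_generations, List events,
                IntegerVector sample_sizes, int purge_interval) {
  int D = deme_sizes.size();
  if (migration.nrow() != D || migration.ncol() != D)
    stop("migration matrix dimension mismatch");
  std::vector<int> N(D);
  std::vector<bool> act(D);
  for (int d = 0; d < D; ++d) {
    N[d] = deme_sizes[d];
    act[d] = active0[d];
  }

  int ne = events.size();
  std::vector<int> ev_gen(ne), ev_type(ne), ev_deme(ne), ev_src(ne), ev_size(ne);
  std::vector<double> ev_frac(ne);
  for (int e = 0; e < ne; ++e) {
    List ev = events[e];
    ev_gen[e] = as<int>(ev["gen"]);
    ev_type[e] = as<int>(ev["type"]);
    ev_deme[e] = as<int>(ev["deme"]);
    ev_src[e] = ev.containsElementNamed("source") ? as<int>(ev["source"]) : -1;
    ev_size[e] = ev.containsElementNamed("size") ? as<int>(ev["size"]) : -1;
    ev_frac[e] = ev.containsElementNamed("fraction") ? as<double>(ev["fraction"]) : 0.0;
    if (ev_gen[e] < 1 || ev_gen[e] > n_generations)
      stop("event generation outside simulated range");
  }

  std::vector<std::vector<Hap> > pop(D), old(D);
  for (int d = 0; d < D; ++d)
    if (act[d]) pop[d].assign((size_t)(2 * N[d]), Hap());

  std::unordered_set<int> active_pos;
  double mu_len = mu * seq_length, rec_len = rec * seq_length;

  std::vector<int> forced(D), pulse_src(D);
  std::vector<double> pulse_frac(D);

  for (int g = 1; g <= n_generations; ++g) {
    if (g % 64 == 0) Rcpp::checkUserInterrupt();
    std::vector<int> oldN(N);
    std::vector<bool> oldact(act);
    std::fill(forced.begin(), forced.end(), -1);
    std::fill(pulse_src.begin(), pulse_src.end(), -1);
    std::fill(pulse_frac.begin(), pulse_frac.end(), 0.0);

    for (int e = 0; e < ne; ++e) {
      if (ev_gen[e] != g) continue;
      int d = ev_deme[e];
      if (ev_type[e] == 0) {  // resize
        if (!act[d]) stop("resize of inactive deme");
        N[d] = ev_size[e];
      } else if (ev_type[e] == 1) {  // split
        if (act[d]) stop("split target already active");
        if (ev_src[e] < 0 || !oldact[ev_src[e]]) stop("split source inactive");
        act[d] = true;
        N[d] = ev_size[e] > 0 ? ev_size[e] : deme_sizes[d];
        forced[d] = ev_src[e];
      } else if (ev_type[e] == 2) {  // admixture pulse
        if (!act[d] || ev_src[e] < 0 || !oldact[ev_src[e]])
          stop("admixture pulse on inactive deme");
        pulse_src[d] = ev_src[e];
        pulse_frac[d] = ev_frac[e];
      }
    }

    old.swap(pop);
    for (int d = 0; d < D; ++d) {
      pop[d].clear();
      if (!act[d]) continue;
      pop[d].resize((size_t)(2 * N[d]));
      for (int i = 0; i < N[d]; ++i) {
        for (int gamete = 0; gamete < 2; ++gamete) {
          int s;
          if (forced[d] >= 0) {
            s = forced[d];
          } else {
            s = d;
            if (pulse_src[d] >= 0 && unif_rand() < pulse_frac[d]) {
              s = pulse_src[d];
            } else {
              double u = unif_rand(), acc = 0.0;
              for (int d2 = 0; d2 < D; ++d2) {
                if (d2 == d || !oldact[d2] || oldN[d2] <= 0) continue;
                acc += migration(d, d2);
                if (u < acc) { s = d2; break; }
              }
            }
          }
          if (!oldact[s] || oldN[s] <= 0) s = d;  // defensive: stay home
          int p = rand_below(oldN[s]);
          Hap child = recombine(old[s][(size_t)(2 * p)], old[s][(size_t)(2 * p + 1)],
                                seq_length, rec_len);
          mutate(child, seq_length, mu_len, active_pos);
          pop[d][(size_t)(2 * i + gamete)].swap(child);
        }
      }
    }
    if (g % purge_interval == 0) purge(pop, act, active_pos);
  }
  purge(pop, act, active_pos);

  // sample the first sample_sizes[d] diploids of each deme
  std::vector<std::pair<int, int> > hap_ids;  // (deme, hap index)
  for (int d = 0; d < D; ++d) {
    if (sample_sizes[d] <= 0) continue;
    if (!act[d] || sample_sizes[d] > N[d])
      stop("sample size exceeds deme size (or deme never activated)");
    for (int i = 0; i < 2 * sample_sizes[d]; ++i)
      hap_ids.push_back(std::make_pair(d, i));
  }
  int H = (int)hap_ids.size();
  std::unordered_map<int, int> cnt;
  for (int h = 0; h < H; ++h) {
    const Hap &hp = pop[hap_ids[(size_t)h].first][(size_t)hap_ids[(size_t)h].second];
    for (size_t k = 0; k < hp.size(); ++k) cnt[hp[k]]++;
  }
  std::vector<int> segpos;
  for (std::unordered_map<int, int>::iterator it = cnt.begin(); it != cnt.end(); ++it)
    if (it->second > 0 && it->second < H) segpos.push_back(it->first);
  std::sort(segpos.begin(), segpos.end());
  int S = (int)segpos.size();
  std::unordered_map<int, int> row_of;
  for (int i = 0; i < S; ++i) row_of[segpos[(size_t)i]] = i;

  IntegerMatrix hapmat(S, H);
  IntegerVector deme_of(H);
  for (int h = 0; h < H; ++h) {
    deme_of[h] = hap_ids[(size_t)h].first;
    const Hap &hp = pop[hap_ids[(size_t)h].first][(size_t)hap_ids[(size_t)h].second];
    for (size_t k = 0; k < hp.size(); ++k) {
      std::unordered_map<int, int>::iterator it = row_of.find(hp[k]);
      if (it != row_of.end()) hapmat(it->second, h) = 1;
    }
  }
  return List::create(_["positions"] = wrap(segpos), _["haplotypes"] = hapmat,
                      _["deme_of_hap"] = deme_of,
                      _["final_sizes"] = wrap(N));
}
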