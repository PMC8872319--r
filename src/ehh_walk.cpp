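#include <Rcpp.h>
#include <unordered_map>
using namespace Rcpp;

// One-directional EHH walk from a core SNP.
//
// haps: full haplotype matrix (2S x V, NA = missing)
// carriers: 1-based row indices of haplotypes carrying the core allele
// sites: 1-based column indices in walk order (away from the core)
// pos: positions of those sites (same order)
// pos0: core position; cutoff/max_extend/max_gap: stopping rules.
//
// Returns signed offsets (pos - pos0), EHH values, and a truncation flag
// (TRUE when the walk ended before EHH fell below the cutoff).
// [[Rcpp::export(name = ".ehh_walk")]]
List ehh_walk(IntegerMatrix haps, IntegerVector carriers,
              IntegerVector sites, NumericVector pos,
              double pos0, double cutoff, double max_extend,
              double max_gap) {
  const int K = carriers.size();
  const double pairs_K = (double)K * (K - 1) / 2.0;
  std::vector<int> g(K, 0), key(K);
  std::vector<double> offs, vals;
  bool truncated = true;
  double prev = pos0;

  for (int t = 0; t < sites.size(); ++t) {
    const int s = sites[t] - 1;
    const double p = pos[t];
    if (std::fabs(p - pos0) > max_extend) break;
    if (std::fabs(p - prev) > max_gap) break;
    prev = p;

    bool has_na = false;
    for (int i = 0; i < K; ++i) {
      const int a = haps(carriers[i] - 1, s);
      if (a == NA_INTEGER) { has_na = true; break; }
      key[i] = g[i] * 2 + a;
    }
    if (has_na) continue;  // uninformative extension site

    std::unordered_map<int, int> relabel;
    int next_id = 0;
    for (int i = 0; i < K; ++i) {
      auto it = relabel.find(key[i]);
      if (it == relabel.end()) {
        relabel.emplace(key[i], next_id);
        g[i] = next_id++;
      } else g[i] = it->second;
    }
    std::vector<int> tab(next_id, 0);
    for (int i = 0; i < K; ++i) tab[g[i]]++;
    double hom = 0.0;
    for (int c : tab) hom += (double)c * (c - 1) / 2.0;
    const double e = hom / pairs_K;

    offs.push_back(p - pos0);
    vals.push_back(e);
    if (e < cutoff) { truncated = false; break; }
  }
  return List::create(_["offs"] = offs, _["vals"] = vals,
                      _["truncated"] = truncated);
}
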