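#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Chromatic Gibbs chain on a cyclic H x W lattice.
//
// One sweep updates the colour groups in their given, fixed order; within a
// group no two sites interact, so the in-place sequential update equals the
// simultaneous ("parallel") update against the pre-update state of the other
// groups. Site states are 0-based; sites are indexed column-major (p + q*H).
// Draws use R's RNG so results are reproducible from set.seed().
//
// Returns an nKept x (H*W) integer matrix: rows are flattened kept
// configurations (every `thin`-th sweep after `burnIn`), nKept = nSweeps/thin.
// The attribute "final" carries the final chain state for continuation.
// [[Rcpp::export(name = ".gibbsChain")]]
IntegerMatrix gibbsChain(IntegerMatrix init, IntegerMatrix offsets,
                         List potentials, double beta, int nStates,
                         List groups, int burnIn, int nSweeps, int thin) {
  const int H = init.nrow(), W = init.ncol(), n = H * W;
  const int nOff = offsets.nrow();

  // neighbour index tables for each offset and its negation
  std::vector< std::vector<int> > nbp(nOff), nbm(nOff);
  for (int o = 0; o < nOff; ++o) {
    nbp[o].resize(n);
    nbm[o].resize(n);
    const int dy = offsets(o, 0), dx = offsets(o, 1);
    for (int q = 0; q < W; ++q) {
      for (int p = 0; p < H; ++p) {
        const int i = p + q * H;
        const int pp = ((p + dy) % H + H) % H, qp = ((q + dx) % W + W) % W;
        const int pm = ((p - dy) % H + H) % H, qm = ((q - dx) % W + W) % W;
        nbp[o][i] = pp + qp * H;
        nbm[o][i] = pm + qm * H;
      }
    }
  }

  std::vector<NumericMatrix> U(nOff);
  for (int o = 0; o < nOff; ++o) U[o] = as<NumericMatrix>(potentials[o]);

  std::vector<int> s(init.begin(), init.end());

  const int nGroups = groups.size();
  std::vector< std::vector<int> > grp(nGroups);
  for (int g = 0; g < nGroups; ++g) {
    IntegerVector gv = groups[g];
    grp[g].assign(gv.begin(), gv.end());
  }

  const int nKept = (thin > 0) ? nSweeps / thin : 0;
  IntegerMatrix out(nKept, n);
  std::vector<double> ener(nStates), prob(nStates);

  int kept = 0;
  const int total = burnIn + nSweeps;
  for (int t = 1; t <= total; ++t) {
    for (int g = 0; g < nGroups; ++g) {
      const std::vector<int>& sites = grp[g];
      for (size_t si = 0; si < sites.size(); ++si) {
        const int i = sites[si];
        double emin = R_PosInf;
        for (int k = 0; k < nStates; ++k) {
          double e = 0.0;
          for (int o = 0; o < nOff; ++o) {
            e += U[o](k, s[nbp[o][i]]);   // pair (site, site + o)
            e += U[o](s[nbm[o][i]], k);   // pair (site - o, site)
          }
          ener[k] = e;
          if (e < emin) emin = e;
        }
        double z = 0.0;
        for (int k = 0; k < nStates; ++k) {
          prob[k] = std::exp(-beta * (ener[k] - emin));
          z += prob[k];
        }
        const double u = unif_rand() * z;
        double c = 0.0;
        int knew = nStates - 1;
        for (int k = 0; k < nStates; ++k) {
          c += prob[k];
          if (u <= c) { knew = k; break; }
        }
        s[i] = knew;
      }
    }
    if (t > burnIn && thin > 0 && (t - burnIn) % thin == 0 && kept < nKept) {
      for (int i = 0; i < n; ++i) out(kept, i) = s[i];
      ++kept;
    }
  }

  IntegerMatrix fin(H, W);
  std::copy(s.begin(), s.end(), fin.begin());
  out.attr("final") = fin;
  return out;
}
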