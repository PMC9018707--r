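#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Discrete-generation Wright-Fisher evolution of a phased haplotype matrix.
//
// Recombination model: at most one effective crossover per adjacent-marker
// gap per meiosis, with probability p_gap = rho_per_bp * gap_bp. Switch
// events are generated as a thinned Poisson process with per-gap intensity
// lam_gap = -0.5 * log(1 - 2 p_gap); an odd number of events in a gap (each
// event toggles the template strand) then occurs with probability exactly
// p_gap, independently across gaps. Chromosomes assort freely: the template
// strand is re-drawn at every chromosome start (their boundary gaps must
// carry lam = 0).
//
// Selection: diploid fitness 1 / 1+hs / 1+s for 0/1/2 copies of the derived
// allele (code `derived_code`) at marker `focal` (focal < 0: neutral).
// Parents are drawn fitness-proportionally with replacement each generation.
//
// Internally haplotypes are stored marker-contiguous (one column per
// haplotype) so each meiosis is a handful of contiguous segment copies.
// Uses R's RNG, so results are reproducible under set.seed().
//
// Returns the final matrix (2*n_dip rows, markers in columns), the
// per-generation derived-allele frequency at the focal marker (NA when
// neutral without a focal marker), and population copies at the requested
// snapshot generations (1-based: snap_gens == 1 is the population after one
// round of reproduction).
// [[Rcpp::export]]
List cpp_wf_evolve(IntegerMatrix hap0, NumericVector lam,
                   LogicalVector chrom_start, int n_dip, int n_gen,
                   double s, double h, int focal, int derived_code,
                   IntegerVector snap_gens) {
  const int m = hap0.ncol();
  const int n_hap0 = hap0.nrow();
  if (m > 0 && lam.size() != m - 1)
    stop("lam must have length ncol(hap) - 1");

  double Lam = 0.0;
  std::vector<double> cumlam(std::max(m - 1, 0));
  for (int g = 0; g < m - 1; ++g) { Lam += lam[g]; cumlam[g] = Lam; }
  std::vector<int> chrom_breaks;          // markers where a new chromosome starts
  for (int j = 1; j < m; ++j) if (chrom_start[j]) chrom_breaks.push_back(j);

  // transpose input: column = haplotype, markers contiguous
  std::vector<unsigned char> cur((size_t)m * n_hap0), nxt((size_t)m * 2 * n_dip);
  for (int r = 0; r < n_hap0; ++r)
    for (int j = 0; j < m; ++j)
      cur[(size_t)r * m + j] = (unsigned char)hap0(r, j);
  int n_par = n_hap0 / 2;

  NumericVector traj(std::max(n_gen, 0), NA_REAL);
  std::vector< std::vector<unsigned char> > snaps(snap_gens.size());
  std::vector<double> cw;
  std::vector<int> events, bounds;

  for (int gen = 1; gen <= n_gen; ++gen) {
    // fitness-proportional cumulative parent weights
    cw.resize(n_par);
    double tot = 0.0;
    if (focal >= 0 && s != 0.0) {
      for (int i = 0; i < n_par; ++i) {
        int dose = (cur[(size_t)(2 * i) * m + focal] == derived_code) +
                   (cur[(size_t)(2 * i + 1) * m + focal] == derived_code);
        tot += dose == 2 ? 1.0 + s : (dose == 1 ? 1.0 + h * s : 1.0);
        cw[i] = tot;
      }
    } else {
      for (int i = 0; i < n_par; ++i) { tot += 1.0; cw[i] = tot; }
    }

    for (int o = 0; o < 2 * n_dip; ++o) {
      double u = unif_rand() * tot;
      int par = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
      if (par >= n_par) par = n_par - 1;
      // strand-change points: crossovers toggle, chromosome starts re-draw
      events.clear();
      if (Lam > 0.0) {
        int K = (int)R::rpois(Lam);
        for (int k = 0; k < K; ++k) {
          double v = unif_rand() * Lam;
          int gpos = (int)(std::lower_bound(cumlam.begin(), cumlam.end(), v) -
                           cumlam.begin());
          if (gpos >= m - 1) gpos = m - 2;
          events.push_back(gpos + 1);   // strand changes *at* marker gpos+1
        }
      }
      bounds.clear();
      bounds.insert(bounds.end(), events.begin(), events.end());
      bounds.insert(bounds.end(), chrom_breaks.begin(), chrom_breaks.end());
      bounds.push_back(m);
      std::sort(bounds.begin(), bounds.end());
      int strand = unif_rand() < 0.5 ? 0 : 1;
      int seg_start = 0;
      unsigned char* dst = nxt.data() + (size_t)o * m;
      size_t bi = 0, ei = 0;
      while (seg_start < m) {
        int seg_end = bounds[bi];
        while (bi + 1 < bounds.size() && bounds[bi + 1] == seg_end) ++bi;
        const unsigned char* srcp = cur.data() + (size_t)(2 * par + strand) * m;
        if (seg_end > seg_start)
          std::copy(srcp + seg_start, srcp + seg_end, dst + seg_start);
        if (seg_end >= m) break;
        // how many crossover events fall exactly here? (parity)
        int n_ev = 0;
        while (ei < events.size() && events[ei] <= seg_end) {
          if (events[ei] == seg_end) ++n_ev;
          ++ei;
        }
        bool is_break = std::binary_search(chrom_breaks.begin(),
                                           chrom_breaks.end(), seg_end);
        if (is_break) strand = unif_rand() < 0.5 ? 0 : 1;
        else if (n_ev % 2 == 1) strand ^= 1;
        seg_start = seg_end;
        ++bi;
      }
    }
    std::swap(cur, nxt);
    n_par = n_dip;
    if ((int)nxt.size() != m * 2 * n_dip) nxt.assign((size_t)m * 2 * n_dip, 0);

    if (focal >= 0) {
      int cnt = 0;
      for (int r = 0; r < 2 * n_dip; ++r)
        if (cur[(size_t)r * m + focal] == derived_code) ++cnt;
      traj[gen - 1] = (double)cnt / (2.0 * n_dip);
    }
    for (int si = 0; si < snap_gens.size(); ++si)
      if (snap_gens[si] == gen) snaps[si] = cur;
  }

  // transpose back to haplotypes-in-rows
  const int n_out = (n_gen > 0) ? 2 * n_dip : n_hap0;
  IntegerMatrix hap_out(n_out, m);
  for (int r = 0; r < n_out; ++r)
    for (int j = 0; j < m; ++j)
      hap_out(r, j) = cur[(size_t)r * m + j];
  List snap_out(snap_gens.size());
  for (int si = 0; si < snap_gens.size(); ++si) {
    IntegerMatrix sm(2 * n_dip, m);
    if (!snaps[si].empty())
      for (int r = 0; r < 2 * n_dip; ++r)
        for (int j = 0; j < m; ++j)
          sm(r, j) = snaps[si][(size_t)r * m + j];
    snap_out[si] = sm;
  }
  return List::create(_["hap"] = hap_out, _["traj"] = traj,
                      _["snapshots"] = snap_out);
}
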