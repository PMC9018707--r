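#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Outward walk from a core marker, refining haplotype identity groups one
// marker at a time. EHH at marker x is the probability that two random
// haplotypes from the included set are identical over [core, x]:
//   sum_h n_h (n_h - 1) / denom,   denom = value of the sum at the core.
// trunc: 0 = cutoff crossed (last sub-cutoff point kept), 1 = chromosome end,
// 2 = max extension exceeded (last in-range point kept).
static void walk_arm(const IntegerMatrix& hap, const std::vector<int>& rows,
                     std::vector<int> grp, int n_grp0, double denom,
                     int core, int step, double cutoff, double max_ext,
                     const NumericVector& pos,
                     std::vector<int>& idx_out, std::vector<double>& ehh_out,
                     int& trunc) {
  const int m = hap.ncol();
  const int n = (int)rows.size();
  idx_out.push_back(core);
  ehh_out.push_back(1.0);
  trunc = 1;
  int n_grp = n_grp0;
  std::vector<int> newid(2 * n, -1);
  for (int j = core + step; j >= 0 && j < m; j += step) {
    if (std::fabs(pos[j] - pos[core]) > max_ext) { trunc = 2; break; }
    std::fill(newid.begin(), newid.begin() + 2 * n_grp, -1);
    int next = 0;
    for (int r = 0; r < n; ++r) {
      int key = 2 * grp[r] + hap(rows[r], j);
      if (newid[key] < 0) newid[key] = next++;
      grp[r] = newid[key];
    }
    n_grp = next;
    std::vector<int> cnt(n_grp, 0);
    for (int r = 0; r < n; ++r) cnt[grp[r]]++;
    double s = 0.0;
    for (int c : cnt) s += (double)c * (c - 1);
    double e = s / denom;
    idx_out.push_back(j);
    ehh_out.push_back(e);
    if (e < cutoff || e <= 0.0) { trunc = 0; break; }
  }
}

// Set up the included rows and initial grouping for one core.
// allele >= 0: carriers of that allele, single initial group (EHH).
// allele == -1: all haplotypes, grouped by their core allele (site EHH).
static bool setup_core(const IntegerMatrix& hap, int core, int allele,
                       std::vector<int>& rows, std::vector<int>& grp,
                       int& n_grp0, double& denom) {
  const int n_hap = hap.nrow();
  rows.clear(); grp.clear();
  if (allele >= 0) {
    for (int r = 0; r < n_hap; ++r)
      if (hap(r, core) == allele) rows.push_back(r);
    const int nc = (int)rows.size();
    if (nc < 2) return false;
    grp.assign(nc, 0);
    n_grp0 = 1;
    denom = (double)nc * (nc - 1);
  } else {
    if (n_hap < 2) return false;
    int c1 = 0;
    rows.resize(n_hap); grp.resize(n_hap);
    for (int r = 0; r < n_hap; ++r) {
      rows[r] = r;
      grp[r] = hap(r, core);
      c1 += hap(r, core);
    }
    n_grp0 = 2;
    const int c0 = n_hap - c1;
    denom = (double)c0 * (c0 - 1) + (double)c1 * (c1 - 1);
    if (denom <= 0.0) return false;
  }
  return true;
}

// [[Rcpp::export]]
List cpp_ehh_profile(IntegerMatrix hap, NumericVector pos, int core,
                     int allele, double cutoff, double max_ext) {
  std::vector<int> rows, grp;
  int n_grp0 = 0; double denom = 0.0;
  if (!setup_core(hap, core, allele, rows, grp, n_grp0, denom))
    stop("core marker needs >= 2 haplotypes carrying the requested allele");
  std::vector<int> li, ri; std::vector<double> le, re;
  int lt = 1, rt = 1;
  walk_arm(hap, rows, grp, n_grp0, denom, core, -1, cutoff, max_ext, pos,
           li, le, lt);
  walk_arm(hap, rows, grp, n_grp0, denom, core, +1, cutoff, max_ext, pos,
           ri, re, rt);
  return List::create(
    _["left_idx"] = wrap(li), _["left_ehh"] = wrap(le), _["left_trunc"] = lt,
    _["right_idx"] = wrap(ri), _["right_ehh"] = wrap(re), _["right_trunc"] = rt,
    _["n_carriers"] = (int)rows.size());
}

// Trapezoid over one arm (bp x EHH); closed at the last emitted point.
static double arm_integral(const std::vector<int>& idx,
                           const std::vector<double>& ehh,
                           const NumericVector& pos) {
  double s = 0.0;
  for (size_t k = 1; k < idx.size(); ++k)
    s += 0.5 * (ehh[k] + ehh[k - 1]) * std::fabs(pos[idx[k]] - pos[idx[k - 1]]);
  return s;
}

// iHH for both allele codes at every marker of one chromosome; cores with
// compute[core] == FALSE are skipped (left NA).
// [[Rcpp::export]]
List cpp_scan_ihh(IntegerMatrix hap, NumericVector pos, double cutoff,
                  double max_ext, LogicalVector compute) {
  const int m = hap.ncol();
  NumericVector ihh0(m, NA_REAL), ihh1(m, NA_REAL);
  LogicalVector end0(m), end1(m);
  std::vector<int> rows, grp, li, ri;
  std::vector<double> le, re;
  for (int core = 0; core < m; ++core) {
    if (!compute[core]) continue;
    for (int allele = 0; allele <= 1; ++allele) {
      int n_grp0 = 0; double denom = 0.0;
      if (!setup_core(hap, core, allele, rows, grp, n_grp0, denom)) continue;
      li.clear(); le.clear(); ri.clear(); re.clear();
      int lt = 1, rt = 1;
      walk_arm(hap, rows, grp, n_grp0, denom, core, -1, cutoff, max_ext, pos,
               li, le, lt);
      walk_arm(hap, rows, grp, n_grp0, denom, core, +1, cutoff, max_ext, pos,
               ri, re, rt);
      double v = arm_integral(li, le, pos) + arm_integral(ri, re, pos);
      bool at_end = (lt == 1) || (rt == 1);
      if (allele == 0) { ihh0[core] = v; end0[core] = at_end; }
      else             { ihh1[core] = v; end1[core] = at_end; }
    }
  }
  return List::create(_["ihh0"] = ihh0, _["ihh1"] = ihh1,
                      _["end0"] = end0, _["end1"] = end1);
}

// iES (integral of site EHH) at every marker of one chromosome; cores with
// compute[core] == FALSE are skipped (left NA).
// [[Rcpp::export]]
List cpp_scan_ies(IntegerMatrix hap, NumericVector pos, double cutoff,
                  double max_ext, LogicalVector compute) {
  const int m = hap.ncol();
  NumericVector ies(m, NA_REAL);
  LogicalVector at_end(m);
  std::vector<int> rows, grp, li, ri;
  std::vector<double> le, re;
  for (int core = 0; core < m; ++core) {
    if (!compute[core]) continue;
    int n_grp0 = 0; double denom = 0.0;
    if (!setup_core(hap, core, -1, rows, grp, n_grp0, denom)) continue;
    li.clear(); le.clear(); ri.clear(); re.clear();
    int lt = 1, rt = 1;
    walk_arm(hap, rows, grp, n_grp0, denom, core, -1, cutoff, max_ext, pos,
             li, le, lt);
    walk_arm(hap, rows, grp, n_grp0, denom, core, +1, cutoff, max_ext, pos,
             ri, re, rt);
    ies[core] = arm_integral(li, le, pos) + arm_integral(ri, re, pos);
    at_end[core] = (lt == 1) || (rt == 1);
  }
  return List::create(_["ies"] = ies, _["at_end"] = at_end);
}
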