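// Inner loop of the EHH decay walk: extends the haplotype-class partition
// site by site outward from a core and reports the homozygosity at each
// included site.  Semantics (truncation / gap / edge / max-extension) match
// the R-level ehh_curve() documentation; this is the single code path.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static double ehh_of_counts(const std::vector<int>& counts, int m,
                            bool pooled) {
  if (m < 2) return NA_REAL;
  long num = 0;
  if (pooled && counts.size() >= 2) {
    int t1 = 0, t2 = 0;  // two largest class sizes
    for (int c : counts) {
      if (c > t1) { t2 = t1; t1 = c; }
      else if (c > t2) t2 = c;
    }
    long top = t1 + t2;
    num = top * (top - 1);
    for (int c : counts) {
      if (c == t1) { t1 = -1; continue; }   // skip the two pooled classes once
      if (c == t2) { t2 = -1; continue; }
      num += (long) c * (c - 1);
    }
  } else {
    for (int c : counts) num += (long) c * (c - 1);
  }
  return (double) num / ((double) m * (m - 1));
}

// [[Rcpp::export]]
List ehh_walk_cpp(IntegerMatrix al, IntegerVector carriers, int core,
                  int step, NumericVector bp, double truncation,
                  double max_gap, double max_extend, bool extend_in_sites,
                  bool pooled, bool split_by_core) {
  int m = carriers.size();
  int n_snp = al.ncol();
  std::vector<int> cls(m), cls_new(m);
  std::vector<int> counts;
  // initial partition at the core
  {
    std::vector<int> map(3, -1);
    int nc = 0;
    for (int i = 0; i < m; ++i) {
      int a = split_by_core ? al(carriers[i] - 1, core - 1) : 0;
      if (map[a] < 0) map[a] = nc++;
      cls[i] = map[a];
    }
    counts.assign(nc, 0);
    for (int i = 0; i < m; ++i) counts[cls[i]]++;
  }
  std::vector<int> offs;
  std::vector<double> ehhs;
  offs.push_back(core);
  ehhs.push_back(ehh_of_counts(counts, m, pooled));
  std::string status = "ok";
  int j = core;
  std::vector<int> remap;
  while (true) {
    double cur = ehhs.back();
    if (cur < truncation) break;
    int jn = j + step;
    if (jn < 1 || jn > n_snp) {
      if (cur >= truncation && cur > 0) status = "edge";
      break;
    }
    if (std::abs(bp[jn - 1] - bp[j - 1]) > max_gap) {
      status = "gap";
      break;
    }
    double ext = extend_in_sites ? std::abs((double)(jn - core))
                                 : std::abs(bp[jn - 1] - bp[core - 1]);
    if (ext > max_extend) break;  // truncate, not a failure
    int ncls = (int) counts.size();
    remap.assign(2 * ncls, -1);
    int nc = 0;
    for (int i = 0; i < m; ++i) {
      int key = cls[i] * 2 + al(carriers[i] - 1, jn - 1);
      if (remap[key] < 0) remap[key] = nc++;
      cls_new[i] = remap[key];
    }
    std::swap(cls, cls_new);
    counts.assign(nc, 0);
    for (int i = 0; i < m; ++i) counts[cls[i]]++;
    offs.push_back(jn);
    ehhs.push_back(ehh_of_counts(counts, m, pooled));
    j = jn;
  }
  return List::create(_["offsets"] = wrap(offs), _["ehh"] = wrap(ehhs),
                      _["status"] = status);
}
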