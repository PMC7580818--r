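#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// EHH decay walk from a core site in one direction.
//
// EHH at a site j is sum_g C(n_g,2) / C(n_c,2) over groups g of carriers
// whose haplotypes are identical from the core out to j. The denominator
// is fixed at the carrier count at the core; haplotypes with a missing
// allele in the extension are dropped from the numerator groups at and
// beyond that site, which keeps the curve monotone non-increasing.
//
// The walk stops at the first site where EHH < minEhh (that point is kept
// as the final curve point and included in the trapezoid integral), at a
// gap > maxGap between consecutive sites (side flagged; the statistic is
// discarded upstream), or at the chromosome end (integral kept).

struct SideResult {
  double integral;
  int reason;  // 0 = below cutoff, 1 = gap, 2 = chrom end
  std::vector<double> off;
  std::vector<double> ehh;
};

static SideResult walk_side(const IntegerMatrix& A, const NumericVector& pos,
                            int core, int allele, int dir, double maxGap,
                            double minEhh, bool keepCurve) {
  const int nHap = A.nrow(), nSite = A.ncol();
  std::vector<int> active;
  active.reserve(nHap);
  for (int h = 0; h < nHap; ++h) {
    int a = A(h, core);
    if (a != NA_INTEGER && a == allele) active.push_back(h);
  }
  const double denom = active.size() * (active.size() - 1.0) / 2.0;
  SideResult res;
  res.integral = 0.0;
  res.reason = 2;
  if (keepCurve) {
    res.off.push_back(0.0);
    res.ehh.push_back(1.0);
  }
  if (denom <= 0) return res;
  std::vector<int> grp(active.size(), 0);
  double prevEhh = 1.0, prevPos = pos[core];
  const double corePos = pos[core];
  for (int j = core + dir; j >= 0 && j < nSite; j += dir) {
    if (std::fabs(pos[j] - prevPos) > maxGap) {
      res.reason = 1;
      break;
    }
    std::unordered_map<long long, int> remap;
    std::vector<int> newGrp, newActive, cnt;
    newGrp.reserve(active.size());
    newActive.reserve(active.size());
    for (size_t k = 0; k < active.size(); ++k) {
      int a = A(active[k], j);
      if (a == NA_INTEGER) continue;
      long long key = 2LL * grp[k] + a;
      auto it = remap.find(key);
      int id;
      if (it == remap.end()) {
        id = (int)cnt.size();
        remap.emplace(key, id);
        cnt.push_back(0);
      } else {
        id = it->second;
      }
      ++cnt[id];
      newActive.push_back(active[k]);
      newGrp.push_back(id);
    }
    double num = 0.0;
    for (int c : cnt) num += c * (c - 1.0) / 2.0;
    double e = num / denom;
    double d = std::fabs(pos[j] - corePos);
    res.integral += 0.5 * (prevEhh + e) * (d - std::fabs(prevPos - corePos));
    if (keepCurve) {
      res.off.push_back(d);
      res.ehh.push_back(e);
    }
    active.swap(newActive);
    grp.swap(newGrp);
    prevEhh = e;
    prevPos = pos[j];
    if (e < minEhh) {
      res.reason = 0;
      break;
    }
  }
  return res;
}

// [[Rcpp::export(name = ".ehh_side_cpp")]]
List ehh_side_cpp(IntegerMatrix alleles, NumericVector positions, int core,
                  int allele, int dir, double maxGap, double minEhh) {
  SideResult r = walk_side(alleles, positions, core - 1, allele, dir, maxGap,
                           minEhh, true);
  return List::create(_["offset"] = r.off, _["ehh"] = r.ehh,
                      _["integral"] = r.integral, _["reason"] = r.reason);
}

// [[Rcpp::export(name = ".ihs_scan_cpp")]]
DataFrame ihs_scan_cpp(IntegerMatrix alleles, NumericVector positions,
                       IntegerVector cores, double maxGap, double minEhh) {
  const int n = cores.size();
  NumericVector ihhA(n), ihhD(n);
  LogicalVector gapA(n), gapD(n);
  IntegerVector nA(n), nD(n);
  for (int i = 0; i < n; ++i) {
    int core = cores[i] - 1;
    int cA = 0, cD = 0;
    for (int h = 0; h < alleles.nrow(); ++h) {
      int a = alleles(h, core);
      if (a == NA_INTEGER) continue;
      if (a == 0) ++cA; else ++cD;
    }
    nA[i] = cA;
    nD[i] = cD;
    SideResult aL = walk_side(alleles, positions, core, 0, -1, maxGap, minEhh, false);
    SideResult aR = walk_side(alleles, positions, core, 0, +1, maxGap, minEhh, false);
    SideResult dL = walk_side(alleles, positions, core, 1, -1, maxGap, minEhh, false);
    SideResult dR = walk_side(alleles, positions, core, 1, +1, maxGap, minEhh, false);
    ihhA[i] = aL.integral + aR.integral;
    ihhD[i] = dL.integral + dR.integral;
    gapA[i] = (aL.reason == 1) || (aR.reason == 1);
    gapD[i] = (dL.reason == 1) || (dR.reason == 1);
  }
  return DataFrame::create(_["ihhA"] = ihhA, _["ihhD"] = ihhD,
                           _["gapA"] = gapA, _["gapD"] = gapD,
                           _["nAnc"] = nA, _["nDer"] = nD);
}
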