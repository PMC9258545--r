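// Extended haplotype homozygosity and the integrated haplotype score.
// EHH at a marker j (relative to a core and a core allele) is the
// probability that two random carriers of the core allele are identical at
// every marker between the core and j:
//   EHH_j = sum_h C(c_h, 2) / C(n_c, 2)
// over the distinct extended haplotypes h among the n_c carriers. The iHS
// integrals accumulate EHH over genetic distance (trapezoid rule), with a
// final linearly interpolated point at the cutoff crossing.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double choose2(double n) { return n * (n - 1.0) / 2.0; }

// walk one direction from the core, splitting haplotype classes marker by
// marker; appends (marker index, ehh) pairs until ehh drops below `stopAt`
// (the first such point is included), the walk leaves `maxExtendBp` of the
// core (0 = unbounded), or the chromosome end is reached; returns 1 when
// the stop level was crossed, 2 when the extension bound truncated the
// walk, 0 when the chromosome end was reached above the stop level
static int ehhWalk(const IntegerMatrix &H, const std::vector<int> &car,
                    int core, int dir, double stopAt,
                    const NumericVector &bp, double maxExtendBp,
                    std::vector<int> &outIdx, std::vector<double> &outEhh) {
  int nc = (int)car.size();
  int m = H.ncol();
  double denom = choose2((double)nc);
  std::vector<int> grp(nc, 0);
  std::vector<int> remap(2 * nc, -1);
  std::vector<int> sz(nc, 0);
  std::vector<int> touched;
  touched.reserve(2 * nc);
  for (int j = core + dir; j >= 0 && j < m; j += dir) {
    if (maxExtendBp > 0 && std::abs(bp[j] - bp[core]) > maxExtendBp)
      return 2;
    touched.clear();
    int nNew = 0;
    for (int i = 0; i < nc; ++i) {
      int key = 2 * grp[i] + H(car[i], j);
      if (remap[key] < 0) {
        remap[key] = nNew;
        sz[nNew] = 0;
        ++nNew;
        touched.push_back(key);
      }
      grp[i] = remap[key];
      sz[grp[i]] += 1;
    }
    for (size_t k = 0; k < touched.size(); ++k) remap[touched[k]] = -1;
    double num = 0.0;
    for (int k = 0; k < nNew; ++k) num += choose2((double)sz[k]);
    double ehh = num / denom;
    outIdx.push_back(j);
    outEhh.push_back(ehh);
    if (ehh < stopAt || ehh <= 0.0) return 1;
  }
  return 0;  // chromosome end reached above stopAt
}

// [[Rcpp::export(name = ".ehh_curve")]]
List ehh_curve(IntegerMatrix H, int core0, int allele, double stopAt) {
  std::vector<int> car;
  for (int i = 0; i < H.nrow(); ++i)
    if (H(i, core0) == allele) car.push_back(i);
  if ((int)car.size() < 2)
    return List::create(_["n_carriers"] = (int)car.size(),
                        _["left_idx"] = IntegerVector(0),
                        _["left_ehh"] = NumericVector(0),
                        _["right_idx"] = IntegerVector(0),
                        _["right_ehh"] = NumericVector(0));
  std::vector<int> li, ri;
  std::vector<double> le, re;
  NumericVector bp(0);
  ehhWalk(H, car, core0, -1, stopAt, bp, 0.0, li, le);
  ehhWalk(H, car, core0, +1, stopAt, bp, 0.0, ri, re);
  return List::create(_["n_carriers"] = (int)car.size(),
                      _["left_idx"] = wrap(li), _["left_ehh"] = wrap(le),
                      _["right_idx"] = wrap(ri), _["right_ehh"] = wrap(re));
}

// one-sided EHH integral out to the interpolated crossing of `cutoff`,
// truncated at the physical extension bound when one is set (the selscan
// --max-extend behaviour); ok becomes false only when the curve is still
// above the cutoff at a chromosome end, in which case the core is skipped
static double ihhSide(const IntegerMatrix &H, const std::vector<int> &car,
                      int core, int dir, const NumericVector &cm,
                      const NumericVector &bp, double maxExtendBp,
                      double cutoff, bool &ok) {
  std::vector<int> idx;
  std::vector<double> ehh;
  int status = ehhWalk(H, car, core, dir, cutoff, bp, maxExtendBp, idx, ehh);
  double integral = 0.0, prevPos = cm[core], prevE = 1.0;
  ok = status != 0;
  for (size_t k = 0; k < idx.size(); ++k) {
    double pos = cm[idx[k]];
    double width = std::abs(pos - prevPos);
    if (ehh[k] <= cutoff) {
      // interpolate the exact crossing in genetic distance
      double frac = (prevE > ehh[k])
                        ? (prevE - cutoff) / (prevE - ehh[k])
                        : 1.0;
      return integral + width * frac * (prevE + cutoff) / 2.0;
    }
    integral += width * (prevE + ehh[k]) / 2.0;
    prevPos = pos;
    prevE = ehh[k];
  }
  return integral;  // truncated at the bound (or failed at the end)
}

// [[Rcpp::export(name = ".ihs_cores")]]
DataFrame ihs_cores(IntegerMatrix H, NumericVector cm, NumericVector bp,
                    IntegerVector cores0, double minMaf, double cutoff,
                    double maxExtendBp) {
  int n = H.nrow();
  int k = cores0.size();
  NumericVector daf(k), ihhA(k), ihhD(k), uihs(k);
  IntegerVector skip(k);  // 0 ok, 1 maf, 2 no cutoff crossing, 3 <2 carriers
  for (int c = 0; c < k; ++c) {
    int core = cores0[c];
    int nd = 0;
    for (int i = 0; i < n; ++i) nd += H(i, core);
    double p = (double)nd / n;
    daf[c] = p;
    ihhA[c] = ihhD[c] = uihs[c] = NA_REAL;
    if (p < minMaf || p > 1.0 - minMaf) {
      skip[c] = 1;
      continue;
    }
    std::vector<int> carA, carD;
    for (int i = 0; i < n; ++i)
      (H(i, core) ? carD : carA).push_back(i);
    if (carA.size() < 2 || carD.size() < 2) {
      skip[c] = 3;
      continue;
    }
    bool okAL, okAR, okDL, okDR;
    double aL = ihhSide(H, carA, core, -1, cm, bp, maxExtendBp, cutoff, okAL);
    double aR = ihhSide(H, carA, core, +1, cm, bp, maxExtendBp, cutoff, okAR);
    double dL = ihhSide(H, carD, core, -1, cm, bp, maxExtendBp, cutoff, okDL);
    double dR = ihhSide(H, carD, core, +1, cm, bp, maxExtendBp, cutoff, okDR);
    if (!(okAL && okAR && okDL && okDR)) {
      skip[c] = 2;
      continue;
    }
    ihhA[c] = aL + aR;
    ihhD[c] = dL + dR;
    if (ihhA[c] > 0 && ihhD[c] > 0) {
      uihs[c] = std::log(ihhD[c] / ihhA[c]);
      skip[c] = 0;
    } else {
      skip[c] = 2;
    }
    if ((c & 63) == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["core"] = cores0 + 1, _["daf"] = daf,
                           _["ihh_a"] = ihhA, _["ihh_d"] = ihhD,
                           _["uihs"] = uihs, _["skip"] = skip);
}
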