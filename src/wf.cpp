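// Forward Wright-Fisher diploid engine with infinite-sites mutation and
// uniform crossover. Haplotypes are sorted vectors of real-valued mutation
// positions in [0, L); uniqueness of new positions is almost sure. All
// randomness comes from R's RNG, so set.seed() on the R side makes runs
// reproducible byte-for-byte.
#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

typedef std::vector<double> Hap;
typedef std::vector<Hap> Deme;  // 2N haplotypes; 2i, 2i+1 = individual i

// one meiosis: recombine a parent's two chromosomes
static Hap meiosis(const Hap &a, const Hap &b, double recL, double L) {
  int ncx = (int)R::rpois(recL);
  if (ncx == 0)
    return (unif_rand() < 0.5) ? a : b;
  std::vector<double> bks(ncx);
  for (int k = 0; k < ncx; ++k) bks[k] = unif_rand() * L;
  std::sort(bks.begin(), bks.end());
  Hap out;
  out.reserve(std::max(a.size(), b.size()) + 8);
  const Hap *cur = (unif_rand() < 0.5) ? &a : &b;
  const Hap *oth = (cur == &a) ? &b : &a;
  double prev = 0.0;
  for (int k = 0; k <= ncx; ++k) {
    double end = (k < ncx) ? bks[k] : L;
    Hap::const_iterator lo =
        std::lower_bound(cur->begin(), cur->end(), prev);
    Hap::const_iterator hi = std::lower_bound(cur->begin(), cur->end(), end);
    out.insert(out.end(), lo, hi);
    prev = end;
    std::swap(cur, oth);
  }
  return out;
}

static void mutate(Hap &h, double muL, double L) {
  int nm = (int)R::rpois(muL);
  for (int k = 0; k < nm; ++k) {
    double p = unif_rand() * L;
    Hap::iterator it = std::lower_bound(h.begin(), h.end(), p);
    h.insert(it, p);
  }
}

// remove positions fixed across every haplotype of the active demes
static void dropFixed(std::vector<Deme *> &demes) {
  Hap cand;
  bool first = true;
  for (size_t d = 0; d < demes.size(); ++d) {
    Deme &D = *demes[d];
    for (size_t i = 0; i < D.size(); ++i) {
      if (first) {
        cand = D[i];
        first = false;
      } else {
        Hap tmp;
        tmp.reserve(cand.size());
        std::set_intersection(cand.begin(), cand.end(), D[i].begin(),
                              D[i].end(), std::back_inserter(tmp));
        cand.swap(tmp);
      }
      if (cand.empty()) return;
    }
  }
  if (cand.empty()) return;
  for (size_t d = 0; d < demes.size(); ++d) {
    Deme &D = *demes[d];
    for (size_t i = 0; i < D.size(); ++i) {
      Hap tmp;
      tmp.reserve(D[i].size() - cand.size());
      std::set_difference(D[i].begin(), D[i].end(), cand.begin(), cand.end(),
                          std::back_inserter(tmp));
      D[i].swap(tmp);
    }
  }
}

// advance one generation: offspring deme of n diploids whose parents are
// drawn from `self` (and, with per-draw probability admix, from `src`)
static Deme nextGen(const Deme &self, const Deme *src, int n, double selfing,
                    double admix, double muL, double recL, double L) {
  Deme kids(2 * (size_t)n);
  int nSelf = (int)self.size() / 2;
  int nSrc = src ? (int)src->size() / 2 : 0;
  for (int i = 0; i < n; ++i) {
    const Deme *d1, *d2;
    int p1, p2;
    bool fromSrc1 = (admix > 0 && nSrc > 0 && unif_rand() < admix);
    d1 = fromSrc1 ? src : &self;
    p1 = (int)(unif_rand() * (fromSrc1 ? nSrc : nSelf));
    if (selfing > 0 && unif_rand() < selfing) {
      d2 = d1;
      p2 = p1;
    } else {
      bool fromSrc2 = (admix > 0 && nSrc > 0 && unif_rand() < admix);
      d2 = fromSrc2 ? src : &self;
      p2 = (int)(unif_rand() * (fromSrc2 ? nSrc : nSelf));
    }
    kids[2 * i] = meiosis((*d1)[2 * p1], (*d1)[2 * p1 + 1], recL, L);
    kids[2 * i + 1] = meiosis((*d2)[2 * p2], (*d2)[2 * p2 + 1], recL, L);
    mutate(kids[2 * i], muL, L);
    mutate(kids[2 * i + 1], muL, L);
  }
  return kids;
}

static List demeToList(const Deme &D) {
  List out(D.size());
  for (size_t i = 0; i < D.size(); ++i) out[i] = wrap(D[i]);
  return out;
}

static Deme listToDeme(List x) {
  Deme D(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    NumericVector v = x[i];
    D[i] = Hap(v.begin(), v.end());
  }
  return D;
}

// [[Rcpp::export(name = ".wf_burnin")]]
List wf_burnin(int n, int gens, double L, double mu, double rec,
               int fixInterval = 50) {
  Deme pop(2 * (size_t)n);
  double muL = mu * L, recL = rec * L;
  std::vector<Deme *> active;
  for (int t = 0; t < gens; ++t) {
    pop = nextGen(pop, NULL, n, 0.0, 0.0, muL, recL, L);
    if ((t + 1) % fixInterval == 0) {
      active.clear();
      active.push_back(&pop);
      dropFixed(active);
    }
    if ((t & 255) == 0) Rcpp::checkUserInterrupt();
  }
  active.clear();
  active.push_back(&pop);
  dropFixed(active);
  return demeToList(pop);
}

static Deme sampleDeme(const Deme &D, int nSample) {
  int nD = (int)D.size() / 2;
  if (nSample > nD) stop("sample larger than final population");
  std::vector<int> idx(nD);
  for (int i = 0; i < nD; ++i) idx[i] = i;
  for (int i = 0; i < nSample; ++i) {
    int j = i + (int)(unif_rand() * (nD - i));
    std::swap(idx[i], idx[j]);
  }
  Deme out(2 * (size_t)nSample);
  for (int i = 0; i < nSample; ++i) {
    out[2 * i] = D[2 * idx[i]];
    out[2 * i + 1] = D[2 * idx[i] + 1];
  }
  return out;
}

// Runs the post-burn-in plan. neA/neB/selfing/admix have one entry per
// generation, oldest first; generation 0 of the plan is produced from the
// supplied ancestral population (the split). Returns haplotypes sampled
// without replacement from deme B's final generation (and, when
// nSampleA > 0, from the source deme A, kept alive to the end).
// [[Rcpp::export(name = ".wf_continue")]]
List wf_continue(List ancestral, IntegerVector neA, IntegerVector neB,
                 NumericVector selfing, NumericVector admix, double L,
                 double mu, double rec, int nSample, int fixInterval = 50,
                 int nSampleA = 0) {
  Deme A = listToDeme(ancestral);
  Deme B = A;  // both demes start as copies of the ancestral pool
  double muL = mu * L, recL = rec * L;
  int G = neB.size();
  std::vector<Deme *> active;
  for (int t = 0; t < G; ++t) {
    bool keepA = nSampleA > 0;
    for (int u = t; u < G && !keepA; ++u)
      if (admix[u] > 0) { keepA = true; break; }
    Deme newB = nextGen(B, keepA || admix[t] > 0 ? &A : NULL, neB[t],
                        selfing[t], admix[t], muL, recL, L);
    if (keepA) {
      Deme newA = nextGen(A, NULL, neA[t], 0.0, 0.0, muL, recL, L);
      A.swap(newA);
    } else {
      A.clear();
    }
    B.swap(newB);
    if ((t + 1) % fixInterval == 0) {
      active.clear();
      active.push_back(&B);
      if (!A.empty()) active.push_back(&A);
      dropFixed(active);
    }
    Rcpp::checkUserInterrupt();
  }
  Deme outB = sampleDeme(B, nSample);
  if (nSampleA > 0) {
    Deme outA = sampleDeme(A, nSampleA);
    return List::create(_["B"] = demeToList(outB),
                        _["A"] = demeToList(outA));
  }
  return demeToList(outB);
}
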