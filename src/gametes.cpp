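#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Haplotypes are stored sites x haplotypes (one column per haplotype;
// columns 2i and 2i+1, 0-based, belong to diploid individual i), so parental
// reads and gamete writes are contiguous.
//
// Crossover model: per chromosome, crossover count ~ Poisson(length in
// Morgans), positions uniform on [0, L], no interference, no obligate
// chiasma; the starting haplotype is chosen with probability 1/2. All
// randomness goes through R's RNG so runs are reproducible under set.seed().

static inline void one_gamete(const int* hapA, const int* hapB, int* out,
                              const double* pos, const int* chrStart,
                              const int* chrEnd, const double* chrLen,
                              int nChr, std::vector<double>& xo) {
  for (int c = 0; c < nChr; ++c) {
    const double L = chrLen[c];
    int nxo = (L > 0.0) ? static_cast<int>(R::rpois(L)) : 0;
    xo.resize(nxo);
    for (int i = 0; i < nxo; ++i) xo[i] = R::unif_rand() * L;
    std::sort(xo.begin(), xo.end());
    int cur = (R::unif_rand() < 0.5) ? 0 : 1;
    int k = 0;
    for (int s = chrStart[c]; s <= chrEnd[c]; ++s) {
      while (k < nxo && xo[k] <= pos[s]) { cur ^= 1; ++k; }
      out[s] = (cur == 0) ? hapA[s] : hapB[s];
    }
  }
}

static inline void mutate_gamete(int* out, int nS, double mutRate) {
  if (mutRate <= 0.0) return;
  int nMut = static_cast<int>(R::rpois(mutRate * nS));
  for (int i = 0; i < nMut; ++i) {
    int s = static_cast<int>(R::unif_rand() * nS);
    if (s >= nS) s = nS - 1;
    out[s] = 1 - out[s];
  }
}

static inline const int* col_ptr(const IntegerMatrix& H, int col) {
  if (col < 0 || col >= H.ncol()) stop("haplotype column index out of range");
  return INTEGER(H) + static_cast<size_t>(col) * H.nrow();
}

// Generate one gamete per (hapA, hapB) parental haplotype-column pair.
// hapA/hapB are 0-based column indices into H; pos holds within-chromosome
// Morgan positions; chrStart/chrEnd are 0-based inclusive site ranges per
// chromosome. Returns sites x gametes.
// [[Rcpp::export(name = ".gametes_cpp")]]
IntegerMatrix gametes_cpp(const IntegerMatrix& H, const IntegerVector& hapA,
                          const IntegerVector& hapB, const NumericVector& pos,
                          const IntegerVector& chrStart,
                          const IntegerVector& chrEnd,
                          const NumericVector& chrLen, double mutRate) {
  const int nG = hapA.size(), nS = H.nrow(), nChr = chrLen.size();
  if (hapB.size() != nG) stop("hapA and hapB lengths differ");
  IntegerMatrix G(nS, nG);
  std::vector<double> xo;
  for (int i = 0; i < nG; ++i) {
    int* out = INTEGER(G) + static_cast<size_t>(i) * nS;
    one_gamete(col_ptr(H, hapA[i]), col_ptr(H, hapB[i]), out, REAL(pos),
               INTEGER(chrStart), INTEGER(chrEnd), REAL(chrLen), nChr, xo);
    mutate_gamete(out, nS, mutRate);
  }
  return G;
}

// Make n progeny: maternal gamete in column 2k, paternal in column 2k + 1
// (0-based), one meiosis each. moA/moB (faA/faB) are the 0-based haplotype
// column indices of each progeny's mother (father).
// [[Rcpp::export(name = ".progeny_cpp")]]
IntegerMatrix progeny_cpp(const IntegerMatrix& H, const IntegerVector& moA,
                          const IntegerVector& moB, const IntegerVector& faA,
                          const IntegerVector& faB, const NumericVector& pos,
                          const IntegerVector& chrStart,
                          const IntegerVector& chrEnd,
                          const NumericVector& chrLen) {
  const int n = moA.size(), nS = H.nrow(), nChr = chrLen.size();
  IntegerMatrix out(nS, 2 * n);
  std::vector<double> xo;
  for (int k = 0; k < n; ++k) {
    for (int par = 0; par < 2; ++par) {
      const int cA = par == 0 ? moA[k] : faA[k];
      const int cB = par == 0 ? moB[k] : faB[k];
      int* g = INTEGER(out) + static_cast<size_t>(2 * k + par) * nS;
      one_gamete(col_ptr(H, cA), col_ptr(H, cB), g, REAL(pos),
                 INTEGER(chrStart), INTEGER(chrEnd), REAL(chrLen), nChr, xo);
    }
  }
  return out;
}

// Genetic intercept and slope per individual: g0 = X b, s = X m where X is
// the dosage matrix at the QTN rows (qtn 0-based). Single pass, no
// intermediate dosage matrix.
// [[Rcpp::export(name = ".genetic_values_cpp")]]
List genetic_values_cpp(const IntegerMatrix& H, const IntegerVector& qtn,
                        const NumericVector& b, const NumericVector& m) {
  const int nInd = H.ncol() / 2, nQ = qtn.size(), nS = H.nrow();
  NumericVector g0(nInd), s(nInd);
  const int* h = INTEGER(H);
  for (int i = 0; i < nInd; ++i) {
    const int* h1 = h + static_cast<size_t>(2 * i) * nS;
    const int* h2 = h + static_cast<size_t>(2 * i + 1) * nS;
    double gi = 0.0, si = 0.0;
    for (int j = 0; j < nQ; ++j) {
      const int d = h1[qtn[j]] + h2[qtn[j]];
      if (d) { gi += d * b[j]; si += d * m[j]; }
    }
    g0[i] = gi; s[i] = si;
  }
  return List::create(_["g0"] = g0, _["s"] = s);
}

// Discrete-generation Wright-Fisher burn-in: constant population size nInd,
// random mating (selfing excluded when nInd > 1), symmetric two-state
// mutation at rate mutRate per site per transmitted gamete. Starts from a
// monomorphic (all-zero) population and returns the final haplotypes (sites
// x haplotypes) plus the expected-heterozygosity trajectory (mean over sites
// of 2p(1-p)).
// [[Rcpp::export(name = ".wf_burnin_cpp")]]
List wf_burnin_cpp(int nInd, int nGen, const NumericVector& pos,
                   const IntegerVector& chrStart, const IntegerVector& chrEnd,
                   const NumericVector& chrLen, double mutRate) {
  const int nS = pos.size(), nChr = chrLen.size(), nHap = 2 * nInd;
  std::vector<int> cur(static_cast<size_t>(nHap) * nS, 0);
  std::vector<int> nxt(static_cast<size_t>(nHap) * nS, 0);
  std::vector<double> xo;
  NumericVector het(nGen);
  // haplotype h of individual i lives at offset (2i + h) * nS
  for (int gen = 0; gen < nGen; ++gen) {
    for (int i = 0; i < nInd; ++i) {
      int mo = static_cast<int>(R::unif_rand() * nInd);
      if (mo >= nInd) mo = nInd - 1;
      int fa = mo;
      while (nInd > 1 && fa == mo) {
        fa = static_cast<int>(R::unif_rand() * nInd);
        if (fa >= nInd) fa = nInd - 1;
      }
      for (int par = 0; par < 2; ++par) {
        const int p = par == 0 ? mo : fa;
        int* g = nxt.data() + (static_cast<size_t>(2 * i + par) * nS);
        one_gamete(cur.data() + static_cast<size_t>(2 * p) * nS,
                   cur.data() + static_cast<size_t>(2 * p + 1) * nS, g,
                   REAL(pos), INTEGER(chrStart), INTEGER(chrEnd), REAL(chrLen),
                   nChr, xo);
        mutate_gamete(g, nS, mutRate);
      }
    }
    cur.swap(nxt);
    double h = 0.0;
    for (int s = 0; s < nS; ++s) {
      int cnt = 0;
      for (int r = 0; r < nHap; ++r) cnt += cur[static_cast<size_t>(r) * nS + s];
      double p = static_cast<double>(cnt) / nHap;
      h += 2.0 * p * (1.0 - p);
    }
    het[gen] = h / nS;
  }
  IntegerMatrix H(nS, nHap);
  std::copy(cur.begin(), cur.end(), INTEGER(H));
  return List::create(_["H"] = H, _["het"] = het);
}
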