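// Hot loops of the breeding simulator: gamete formation (Poisson recombination
// + per-locus mutation), allele-dose extraction, in-silico projection of F1
// intercross pairs to near-inbred descendants, and batched evaluation of the
// genetic-algorithm fitness for parent subsets.
//
// Haplotypes are stored as raw (uint8) matrices, loci in rows (column =
// one haplotype of one individual), so a haplotype is contiguous in memory.
// All randomness goes through R's RNG so set.seed() controls everything.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// One gamete from parent haplotypes h1/h2 (contiguous, n_loci long).
// chr_start: 0-based locus offsets, length n_chr + 1; pos: map positions (cM);
// chr_len: chromosome lengths (cM). Crossover count per chromosome is
// Poisson(xo_lambda); crossover positions are uniform on (0, chr_len).
static void gamete_core(const Rbyte* h1, const Rbyte* h2, Rbyte* out,
                        int n_chr, const int* chr_start,
                        const double* pos, const double* chr_len,
                        double xo_lambda, double mu) {
  std::vector<double> xo;
  for (int c = 0; c < n_chr; ++c) {
    const int lo = chr_start[c], hi = chr_start[c + 1];
    int k = (int) R::rpois(xo_lambda);
    const Rbyte* cur = (unif_rand() < 0.5) ? h1 : h2;
    const Rbyte* oth = (cur == h1) ? h2 : h1;
    if (k == 0) {
      std::copy(h1 == cur ? h1 + lo : h2 + lo, (h1 == cur ? h1 : h2) + hi, out + lo);
    } else {
      xo.resize(k);
      for (int j = 0; j < k; ++j) xo[j] = unif_rand() * chr_len[c];
      std::sort(xo.begin(), xo.end());
      int i = lo, x = 0;
      while (i < hi) {
        // copy from `cur` until next crossover position
        double lim = (x < k) ? xo[x] : R_PosInf;
        int j = i;
        while (j < hi && pos[j] < lim) ++j;
        std::copy(cur + i, cur + j, out + i);
        i = j;
        if (x < k) { std::swap(cur, oth); ++x; } else break;
      }
      if (i < hi) std::copy(cur + i, cur + hi, out + i);
    }
  }
  if (mu > 0) {
    const int L = chr_start[n_chr];
    int nmut = (int) R::rbinom((double) L, mu);
    for (int j = 0; j < nmut; ++j) {
      int at = (int) (unif_rand() * L);
      if (at >= L) at = L - 1;
      out[at] ^= 1;
    }
  }
}

// [[Rcpp::export]]
RawMatrix cpp_gametes(RawMatrix H1, RawMatrix H2, IntegerVector parents,
                      IntegerVector chr_start, NumericVector pos,
                      NumericVector chr_len, double xo_lambda, double mu) {
  const int L = H1.nrow(), n = parents.size(), n_chr = chr_len.size();
  if (chr_start.size() != n_chr + 1 || chr_start[n_chr] != L || pos.size() != L)
    stop("map does not match haplotype matrix");
  RawMatrix out(L, n);
  for (int i = 0; i < n; ++i) {
    int p = parents[i] - 1;
    if (p < 0 || p >= H1.ncol()) stop("parent index out of range");
    gamete_core(&H1(0, p), &H2(0, p), &out(0, i), n_chr, chr_start.begin(),
                pos.begin(), chr_len.begin(), xo_lambda, mu);
  }
  return out;
}

// Allele dose (0/1/2) of selected individuals at selected loci,
// individuals in rows (ready for X %*% beta style products).
// [[Rcpp::export]]
NumericMatrix cpp_dose(RawMatrix H1, RawMatrix H2, IntegerVector loci,
                       IntegerVector inds) {
  const int n = inds.size(), m = loci.size();
  NumericMatrix out(n, m);
  for (int j = 0; j < m; ++j) {
    int l = loci[j] - 1;
    for (int i = 0; i < n; ++i) {
      int p = inds[i] - 1;
      out(i, j) = (double) H1(l, p) + (double) H2(l, p);
    }
  }
  return out;
}

// Exact Poisson(lambda) sampler by inversion (one uniform; lambda is small
// here, about 1).
static inline int rpois_inv(double lambda) {
  double u = unif_rand();
  double p = std::exp(-lambda), c = p;
  int k = 0;
  while (u > c && k < 200) {
    ++k;
    p *= lambda / k;
    c += p;
  }
  return k;
}

// Segment representation of a descendant haplotype: a sorted list of
// (start locus, source haplotype id) runs over the genome. Meiosis merges
// the two parental segment lists at Poisson-recombination breakpoints;
// this is the same stochastic process as the per-locus copy in
// gamete_core, only the data structure differs.
struct Seg { int start; int src; };

static void gamete_seg(const std::vector<Seg>& A, const std::vector<Seg>& B,
                       std::vector<Seg>& out, int n_chr, const int* chr_start,
                       const double* pos, const double* chr_len,
                       double xo_lambda, std::vector<int>& xo) {
  out.clear();
  size_t iA = 0, iB = 0;
  for (int c = 0; c < n_chr; ++c) {
    const int lo = chr_start[c], hi = chr_start[c + 1];
    int k = rpois_inv(xo_lambda);
    xo.clear();
    for (int j = 0; j < k; ++j) {
      double x = unif_rand() * chr_len[c];
      // first locus at or beyond the crossover position
      int b = (int)(std::lower_bound(pos + lo, pos + hi, x) - pos);
      if (b > lo && b < hi) xo.push_back(b);
    }
    std::sort(xo.begin(), xo.end());
    bool useA = unif_rand() < 0.5;
    int s = lo;
    size_t x = 0;
    while (s < hi) {
      int e = (x < xo.size()) ? xo[x] : hi;
      const std::vector<Seg>& src = useA ? A : B;
      size_t& is = useA ? iA : iB;
      while (is + 1 < src.size() && src[is + 1].start <= s) ++is;
      size_t j = is;
      while (j < src.size() && src[j].start < e) {
        out.push_back({std::max(src[j].start, s), src[j].src});
        ++j;
      }
      s = e;
      useA = !useA;
      ++x;
    }
  }
}

// Project F1 intercross pairs to near-inbred descendants and score them.
// H1/H2: marker-panel haplotypes of the F1 pool. pairs: P x 2 (1-based F1
// indices). For each pair, n_virtual descendants: one gamete from each F1
// forms the cross progeny, then n_self selfing meioses (single seed
// descent), mutation off. Each descendant haplotype is a mosaic of the four
// parental haplotypes, tracked as breakpoint segments; scores (allele dose
// of the final line times B, the m x T marker effects) are read off
// per-haplotype prefix sums of the effects. Returns (P * n_virtual) x T,
// pair-major.
// [[Rcpp::export]]
NumericMatrix cpp_project_pairs(RawMatrix H1, RawMatrix H2, IntegerMatrix pairs,
                                int n_virtual, int n_self,
                                IntegerVector chr_start, NumericVector pos,
                                NumericVector chr_len, double xo_lambda,
                                NumericMatrix B) {
  const int L = H1.nrow(), P = pairs.nrow(), T = B.ncol(), nF = H1.ncol();
  const int n_chr = chr_len.size();
  if (B.nrow() != L) stop("effects not aligned to marker panel");
  // prefix[(t * 2nF + h) * (L+1) + i] = sum of hap_h[k] * B[k,t] for k < i
  const int nh = 2 * nF;
  std::vector<double> prefix((size_t)T * nh * (L + 1));
  for (int t = 0; t < T; ++t) {
    const double* bt = &B(0, t);
    for (int f = 0; f < nF; ++f) {
      for (int which = 0; which < 2; ++which) {
        const Rbyte* h = which ? &H2(0, f) : &H1(0, f);
        double* pr = &prefix[((size_t)t * nh + 2 * f + which) * (L + 1)];
        pr[0] = 0.0;
        for (int k = 0; k < L; ++k) pr[k + 1] = pr[k] + (double)h[k] * bt[k];
      }
    }
  }
  NumericMatrix out(P * n_virtual, T);
  std::vector<Seg> pa(1), pb(1), g1, g2, t1, t2;
  std::vector<int> xo;
  for (int p = 0; p < P; ++p) {
    const int a = pairs(p, 0) - 1, b = pairs(p, 1) - 1;
    for (int v = 0; v < n_virtual; ++v) {
      // the F1 parents' haplotypes are single-source segment lists
      std::vector<Seg> A1{{0, 2 * a}}, A2{{0, 2 * a + 1}};
      std::vector<Seg> B1{{0, 2 * b}}, B2{{0, 2 * b + 1}};
      gamete_seg(A1, A2, g1, n_chr, chr_start.begin(), pos.begin(),
                 chr_len.begin(), xo_lambda, xo);
      gamete_seg(B1, B2, g2, n_chr, chr_start.begin(), pos.begin(),
                 chr_len.begin(), xo_lambda, xo);
      for (int s = 0; s < n_self; ++s) {
        gamete_seg(g1, g2, t1, n_chr, chr_start.begin(), pos.begin(),
                   chr_len.begin(), xo_lambda, xo);
        gamete_seg(g1, g2, t2, n_chr, chr_start.begin(), pos.begin(),
                   chr_len.begin(), xo_lambda, xo);
        g1.swap(t1);
        g2.swap(t2);
      }
      const int row = p * n_virtual + v;
      for (int t = 0; t < T; ++t) {
        double sc = 0.0;
        const double* pt = &prefix[(size_t)t * nh * (L + 1)];
        for (const std::vector<Seg>* g : {&g1, &g2}) {
          const std::vector<Seg>& gg = *g;
          for (size_t i = 0; i < gg.size(); ++i) {
            int e = (i + 1 < gg.size()) ? gg[i + 1].start : L;
            const double* pr = pt + (size_t)gg[i].src * (L + 1);
            sc += pr[e] - pr[gg[i].start];
          }
        }
        out(row, t) = sc;
      }
    }
  }
  return out;
}

// Batched GA fitness: for each candidate subset (column of `subsets`,
// 1-based indices into the pool), fitness = mean(index) - l1 * meanRel -
// l2 * NAF, where meanRel is the mean off-diagonal of the pool GRM G
// restricted to the subset and NAF counts marker loci fixed within the
// subset (dose all 0 or all 2; any heterozygote breaks fixation).
// [[Rcpp::export]]
List cpp_ga_fitness(NumericMatrix G, IntegerMatrix dose, IntegerMatrix subsets,
                    NumericVector index_vals, double l1, double l2) {
  const int k = subsets.nrow(), np = subsets.ncol(), m = dose.ncol();
  NumericVector fit(np), mind(np), mrel(np), naf(np);
  for (int s = 0; s < np; ++s) {
    double si = 0.0, sg = 0.0;
    for (int i = 0; i < k; ++i) {
      const int a = subsets(i, s) - 1;
      si += index_vals[a];
      for (int j = i + 1; j < k; ++j) sg += G(a, subsets(j, s) - 1);
    }
    const double rel = 2.0 * sg / ((double) k * (k - 1));
    int nfix = 0;
    for (int j = 0; j < m; ++j) {
      const int first = dose(subsets(0, s) - 1, j);
      if (first == 1) continue;
      bool fixed = true;
      for (int i = 1; i < k; ++i) {
        if (dose(subsets(i, s) - 1, j) != first) { fixed = false; break; }
      }
      if (fixed) ++nfix;
    }
    mind[s] = si / k;
    mrel[s] = rel;
    naf[s] = nfix;
    fit[s] = mind[s] - l1 * rel - l2 * nfix;
  }
  return List::create(_["fitness"] = fit, _["mean_index"] = mind,
                      _["mean_rel"] = mrel, _["naf"] = naf);
}
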