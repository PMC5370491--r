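#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Base order A=0, C=1, G=2, T=3 throughout.
// The 10 unordered diploid genotypes, in fixed order
// AA AC AG AT CC CG CT GG GT TT.
static const int GT1[10] = {0, 0, 0, 0, 1, 1, 1, 2, 2, 3};
static const int GT2[10] = {0, 1, 2, 3, 1, 2, 3, 2, 3, 3};

// Transitions are A<->G and C<->T; with this encoding two distinct
// bases are a transition iff their sum is even.
static inline bool is_transition(int a, int b) {
  return a != b && ((a + b) % 2 == 0);
}

// Per-read emission matrix E[w][x] = P(called state x | true state w):
// correct call with prob 1 - (eps_ts + 2 eps_tv), transition-type error
// with prob eps_ts, each transversion-type error with prob eps_tv.
static void emission_matrix(double eps_ts, double eps_tv, double E[4][4]) {
  double s = 1.0 - (eps_ts + 2.0 * eps_tv);
  for (int w = 0; w < 4; ++w)
    for (int x = 0; x < 4; ++x)
      E[w][x] = (w == x) ? s : (is_transition(w, x) ? eps_ts : eps_tv);
}

// Genotype emission at gamma = 0: reads pick one of the two gametic
// alleles with prob 1/2 each, then pass through the error channel.
static void genotype_emission(const double E[4][4], double G0[10][4]) {
  for (int g = 0; g < 10; ++g)
    for (int x = 0; x < 4; ++x)
      G0[g][x] = 0.5 * (E[GT1[g]][x] + E[GT2[g]][x]);
}

// Per-quartet log-likelihood of the contamination-aware read-count model.
// R: N x 4 read counts; F: N x 4 population allele frequencies at the
// quartet's position; Fp: N x 4 read-frequency vector excluding the focal
// individual (rows summing to 0 signal "no non-focal reads": the quartet
// falls back to gamma = 0). het2 toggles the Hardy-Weinberg factor 2 on
// heterozygote priors; include_coef adds the multinomial coefficient.
// [[Rcpp::export]]
NumericVector cpp_quartet_loglik(IntegerMatrix R, NumericMatrix F,
                                 NumericMatrix Fp, double eps_ts,
                                 double eps_tv, double gamma, bool het2,
                                 bool include_coef) {
  int N = R.nrow();
  NumericVector out(N);
  double E[4][4], G0[10][4];
  emission_matrix(eps_ts, eps_tv, E);
  genotype_emission(E, G0);

  for (int i = 0; i < N; ++i) {
    int r[4], rtot = 0, nz[4], nnz = 0;
    for (int x = 0; x < 4; ++x) {
      r[x] = R(i, x);
      rtot += r[x];
      if (r[x] > 0) nz[nnz++] = x;
    }
    if (rtot == 0) { out[i] = 0.0; continue; }

    double gi = gamma;
    double c[4] = {0, 0, 0, 0};
    if (gamma > 0) {
      double fpsum = 0;
      for (int w = 0; w < 4; ++w) fpsum += Fp(i, w);
      if (fpsum <= 0) {
        gi = 0.0;  // no non-focal reads: contaminant term undefined
      } else {
        for (int x = 0; x < 4; ++x)
          for (int w = 0; w < 4; ++w) c[x] += Fp(i, w) * E[w][x];
      }
    }

    double lw[10], lmax = R_NegInf;
    for (int g = 0; g < 10; ++g) {
      double w = F(i, GT1[g]) * F(i, GT2[g]);
      if (het2 && GT1[g] != GT2[g]) w *= 2.0;
      if (w <= 0) { lw[g] = R_NegInf; continue; }
      double acc = std::log(w);
      for (int k = 0; k < nnz; ++k) {
        int x = nz[k];
        double q = (1.0 - gi) * G0[g][x] + gi * c[x];
        if (q <= 0) { acc = R_NegInf; break; }
        acc += r[x] * std::log(q);
      }
      lw[g] = acc;
      if (acc > lmax) lmax = acc;
    }
    if (!std::isfinite(lmax)) { out[i] = R_NegInf; continue; }
    double s = 0;
    for (int g = 0; g < 10; ++g)
      if (std::isfinite(lw[g])) s += std::exp(lw[g] - lmax);
    double ll = lmax + std::log(s);
    if (include_coef) {
      ll += std::lgamma(rtot + 1.0);
      for (int k = 0; k < nnz; ++k) ll -= std::lgamma(r[nz[k]] + 1.0);
    }
    out[i] = ll;
  }
  return out;
}

// Unnormalised genotype log-posteriors (prior x multinomial term, the
// multinomial coefficient cancels). Returns N x 10 in the fixed genotype
// order AA AC AG AT CC CG CT GG GT TT.
// [[Rcpp::export]]
NumericMatrix cpp_genotype_logpost(IntegerMatrix R, NumericMatrix F,
                                   NumericMatrix Fp, double eps_ts,
                                   double eps_tv, double gamma, bool het2) {
  int N = R.nrow();
  NumericMatrix out(N, 10);
  double E[4][4], G0[10][4];
  emission_matrix(eps_ts, eps_tv, E);
  genotype_emission(E, G0);

  for (int i = 0; i < N; ++i) {
    int r[4], nz[4], nnz = 0;
    for (int x = 0; x < 4; ++x) {
      r[x] = R(i, x);
      if (r[x] > 0) nz[nnz++] = x;
    }
    double gi = gamma;
    double c[4] = {0, 0, 0, 0};
    if (gamma > 0) {
      double fpsum = 0;
      for (int w = 0; w < 4; ++w) fpsum += Fp(i, w);
      if (fpsum <= 0) gi = 0.0;
      else
        for (int x = 0; x < 4; ++x)
          for (int w = 0; w < 4; ++w) c[x] += Fp(i, w) * E[w][x];
    }
    for (int g = 0; g < 10; ++g) {
      double w = F(i, GT1[g]) * F(i, GT2[g]);
      if (het2 && GT1[g] != GT2[g]) w *= 2.0;
      double acc = (w > 0) ? std::log(w) : R_NegInf;
      for (int k = 0; k < nnz && std::isfinite(acc); ++k) {
        int x = nz[k];
        double q = (1.0 - gi) * G0[g][x] + gi * c[x];
        acc = (q > 0) ? acc + r[x] * std::log(q) : R_NegInf;
      }
      out(i, g) = acc;
    }
  }
  return out;
}
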