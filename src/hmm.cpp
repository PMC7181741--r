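// Forward-backward for the two-way diploid local-ancestry HMM.
//
// Hidden state at each site is the unordered ancestry pair of the two
// chromosomes: 0 = AA (no Papuan copy), 1 = PA, 2 = PP.  The two chromosomes
// switch ancestry independently along the genetic map: over a gap of d
// Morgans a chromosome keeps its ancestry with probability exp(-T*d) and
// otherwise redraws from the stationary mixture (m Papuan, 1-m Asian).
// Emissions are genotype dosages given two Bernoulli draws from the local
// ancestry's panel frequency; missing genotypes (NA) emit likelihood 1.

#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export(name = ".hmm_dosage_cpp")]]
List hmm_dosage_cpp(IntegerMatrix geno, NumericVector fP, NumericVector fA,
                    NumericVector dMorgan, double T, double m) {
  const int n = geno.nrow();
  const int S = geno.ncol();
  if (fP.size() != S || fA.size() != S || dMorgan.size() != S)
    stop("panel frequency / distance vectors must match the variant count");

  // per-site emission table: em[site][state * 3 + genotype]
  std::vector<double> em(std::size_t(S) * 9);
  for (int j = 0; j < S; ++j) {
    double p = fP[j], a = fA[j];
    double* e = &em[std::size_t(j) * 9];
    e[0 * 3 + 0] = (1 - a) * (1 - a);            // AA state
    e[0 * 3 + 1] = 2 * a * (1 - a);
    e[0 * 3 + 2] = a * a;
    e[1 * 3 + 0] = (1 - p) * (1 - a);            // PA state
    e[1 * 3 + 1] = p * (1 - a) + (1 - p) * a;
    e[1 * 3 + 2] = p * a;
    e[2 * 3 + 0] = (1 - p) * (1 - p);            // PP state
    e[2 * 3 + 1] = 2 * p * (1 - p);
    e[2 * 3 + 2] = p * p;
  }

  // per-gap diploid transition matrices: tr[site][from * 3 + to], site >= 1
  std::vector<double> tr(std::size_t(S) * 9);
  for (int j = 1; j < S; ++j) {
    double e = std::exp(-T * dMorgan[j]);
    double u = 1 - e;
    double hPP = e + u * m;        // P -> P
    double hPA = u * (1 - m);      // P -> A
    double hAP = u * m;            // A -> P
    double hAA = e + u * (1 - m);  // A -> A
    double* q = &tr[std::size_t(j) * 9];
    q[0 * 3 + 0] = hAA * hAA;
    q[0 * 3 + 1] = 2 * hAP * hAA;
    q[0 * 3 + 2] = hAP * hAP;
    q[1 * 3 + 0] = hPA * hAA;
    q[1 * 3 + 1] = hPP * hAA + hPA * hAP;
    q[1 * 3 + 2] = hPP * hAP;
    q[2 * 3 + 0] = hPA * hPA;
    q[2 * 3 + 1] = 2 * hPP * hPA;
    q[2 * 3 + 2] = hPP * hPP;
  }

  double pi[3] = {(1 - m) * (1 - m), 2 * m * (1 - m), m * m};

  NumericMatrix dos(n, S);
  NumericMatrix post0(n, S), post1(n, S), post2(n, S);
  double totLL = 0;

  std::vector<double> alpha(std::size_t(S) * 3);
  std::vector<double> scale(S);

  for (int i = 0; i < n; ++i) {
    // forward
    for (int j = 0; j < S; ++j) {
      int g = geno(i, j);
      double eobs[3];
      for (int s = 0; s < 3; ++s)
        eobs[s] = (g == NA_INTEGER) ? 1.0 : em[std::size_t(j) * 9 + s * 3 + g];
      double* aj = &alpha[std::size_t(j) * 3];
      if (j == 0) {
        for (int s = 0; s < 3; ++s) aj[s] = pi[s] * eobs[s];
      } else {
        const double* ap = &alpha[std::size_t(j - 1) * 3];
        const double* q = &tr[std::size_t(j) * 9];
        for (int s = 0; s < 3; ++s) {
          double v = ap[0] * q[0 * 3 + s] + ap[1] * q[1 * 3 + s] +
                     ap[2] * q[2 * 3 + s];
          aj[s] = v * eobs[s];
        }
      }
      double c = aj[0] + aj[1] + aj[2];
      if (c <= 0) stop("zero forward likelihood at site %d", j + 1);
      scale[j] = c;
      for (int s = 0; s < 3; ++s) aj[s] /= c;
      totLL += std::log(c);
    }
    // backward + posterior
    double beta[3] = {1, 1, 1};
    for (int j = S - 1; j >= 0; --j) {
      const double* aj = &alpha[std::size_t(j) * 3];
      double p0 = aj[0] * beta[0], p1 = aj[1] * beta[1], p2 = aj[2] * beta[2];
      double ps = p0 + p1 + p2;
      p0 /= ps; p1 /= ps; p2 /= ps;
      post0(i, j) = p0; post1(i, j) = p1; post2(i, j) = p2;
      dos(i, j) = p1 + 2 * p2;
      if (j > 0) {
        int g = geno(i, j);
        double eobs[3];
        for (int s = 0; s < 3; ++s)
          eobs[s] = (g == NA_INTEGER) ? 1.0 : em[std::size_t(j) * 9 + s * 3 + g];
        const double* q = &tr[std::size_t(j) * 9];
        double nb[3];
        for (int s = 0; s < 3; ++s) {
          nb[s] = (q[s * 3 + 0] * eobs[0] * beta[0] +
                   q[s * 3 + 1] * eobs[1] * beta[1] +
                   q[s * 3 + 2] * eobs[2] * beta[2]) / scale[j];
        }
        beta[0] = nb[0]; beta[1] = nb[1]; beta[2] = nb[2];
      }
    }
  }

  return List::create(_["dosage"] = dos, _["loglik"] = totLL,
                      _["postAA"] = post0, _["postPA"] = post1,
                      _["postPP"] = post2);
}
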