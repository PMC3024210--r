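#include <Rcpp.h>
using namespace Rcpp;

// Poisson log-likelihood ratio of a circular window (one zone).
// Zero unless the inside relative risk exceeds 1; the outside term is
// 0*log(0) = 0 when all cases fall inside the zone.
static inline double zone_llr(double cz, double nz, double C, double N) {
  double mu = C * nz / N;
  if (cz <= mu) return 0.0;
  double llr = cz * std::log(cz / mu);
  double rem = C - cz;
  if (rem > 0) llr += rem * std::log(rem / (C - mu));
  return llr;
}

// Scan one case vector over all circular windows.
//
// ord:    K x K, ord(j, c) = 1-based index of the j-th nearest area to
//         center c (ord(0, c) == c).
// popcum: K x K cumulative population along each center's ordering.
// limit:  per-center number of nested windows within the population cap.
//
// Ties in LLR are broken by smaller zone population, then fewer member
// areas, then lower center index; iteration order (centers ascending,
// window sizes ascending) makes the rule deterministic.
static void scan_one(const IntegerMatrix& ord, const NumericMatrix& popcum,
                     const IntegerVector& limit, const double* cases,
                     double C, double N,
                     double& best_llr, int& best_center, int& best_size,
                     double& best_pop) {
  const int K = ord.nrow();
  best_llr = 0.0; best_center = -1; best_size = 0; best_pop = 0.0;
  for (int c = 0; c < K; ++c) {
    double cz = 0.0;
    const int lim = limit[c];
    for (int j = 0; j < lim; ++j) {
      cz += cases[ord(j, c) - 1];
      double nz = popcum(j, c);
      double llr = zone_llr(cz, nz, C, N);
      if (llr > best_llr ||
          (llr == best_llr && best_center >= 0 &&
           (nz < best_pop || (nz == best_pop && j + 1 < best_size)))) {
        if (llr > 0.0) {
          best_llr = llr; best_center = c + 1; best_size = j + 1; best_pop = nz;
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".scan_mlc_cpp")]]
List scan_mlc_cpp(IntegerMatrix ord, NumericMatrix popcum, IntegerVector limit,
                  NumericVector cases, double C, double N) {
  double llr, pop; int center, size;
  scan_one(ord, popcum, limit, REAL(cases), C, N, llr, center, size, pop);
  return List::create(_["llr"] = llr, _["center"] = center, _["size"] = size);
}

// Scan each column of a K x B case matrix; returns per-replicate max LLR
// and the (center, size) of the attaining window.
// [[Rcpp::export(name = ".scan_batch_cpp")]]
List scan_batch_cpp(IntegerMatrix ord, NumericMatrix popcum, IntegerVector limit,
                    NumericMatrix cases, double C, double N) {
  const int B = cases.ncol();
  NumericVector llr(B);
  IntegerVector center(B), size(B);
  for (int b = 0; b < B; ++b) {
    double l, pop; int c, s;
    scan_one(ord, popcum, limit, &cases(0, b), C, N, l, c, s, pop);
    llr[b] = l; center[b] = c; size[b] = s;
  }
  return List::create(_["llr"] = llr, _["center"] = center, _["size"] = size);
}
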