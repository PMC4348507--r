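#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Two-state HMM over a pair of haplotype allele vectors.
// State 1 = IBD, state 0 = not IBD.  Stationary prior pi = kinship phi
// (clipped).  Transitions over genetic distance d (cM) follow the
// continuous-time two-state chain with rate lambda per cM:
//   P(IBD -> IBD)     = pi + (1 - pi) * exp(-lambda * d)
//   P(nonIBD -> IBD)  = pi * (1 - exp(-lambda * d))
// Emissions depend only on whether the two alleles match:
//   IBD:    match (1-eps)^2 + eps^2,  mismatch 2 eps (1-eps)
//   nonIBD: match p^2 + q^2,          mismatch 2 p q     (p = alt freq)
// A missing allele on either haplotype emits 1 in both states.
// Scaled forward-backward keeps everything in the linear domain without
// underflow for chromosomes of 1e5+ markers.

static inline void emissions(int a, int b, double p, double eps,
                             double &e0, double &e1) {
  if (a == NA_INTEGER || b == NA_INTEGER) {
    e0 = 1.0;
    e1 = 1.0;
    return;
  }
  double q = 1.0 - p;
  if (a == b) {
    e1 = (1.0 - eps) * (1.0 - eps) + eps * eps;
    e0 = p * p + q * q;
  } else {
    e1 = 2.0 * eps * (1.0 - eps);
    e0 = 2.0 * p * q;
  }
}

static inline double clip_prob(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Forward-backward posterior of the IBD state for one haplotype pair on one
// chromosome slice [from, to) (0-based columns of the marker arrays).
// Writes posteriors into post[0 .. to-from).
static void fb_posterior_core(const int *hapA, const int *hapB,
                              const double *cm, const double *freq,
                              int from, int to, double phi, double lambda,
                              double eps, double *post, double *fwd0,
                              double *fwd1) {
  int m = to - from;
  if (m <= 0) return;
  double pi = clip_prob(phi, 1e-4, 1.0 - 1e-4);
  double e0, e1;

  emissions(hapA[from], hapB[from], freq[from], eps, e0, e1);
  double a0 = (1.0 - pi) * e0;
  double a1 = pi * e1;
  double sc = a0 + a1;
  fwd0[0] = a0 / sc;
  fwd1[0] = a1 / sc;

  for (int t = 1; t < m; ++t) {
    double d = cm[from + t] - cm[from + t - 1];
    if (d < 1e-9) d = 1e-9;
    double ex = std::exp(-lambda * d);
    double t11 = pi + (1.0 - pi) * ex;        // IBD -> IBD
    double t01 = pi * (1.0 - ex);             // nonIBD -> IBD
    double t10 = 1.0 - t11;
    double t00 = 1.0 - t01;
    emissions(hapA[from + t], hapB[from + t], freq[from + t], eps, e0, e1);
    a0 = (fwd0[t - 1] * t00 + fwd1[t - 1] * t10) * e0;
    a1 = (fwd0[t - 1] * t01 + fwd1[t - 1] * t11) * e1;
    sc = a0 + a1;
    fwd0[t] = a0 / sc;
    fwd1[t] = a1 / sc;
  }

  // backward pass, scaled per step; combine on the fly
  double b0 = 1.0, b1 = 1.0;
  {
    double g0 = fwd0[m - 1] * b0, g1 = fwd1[m - 1] * b1;
    post[m - 1] = g1 / (g0 + g1);
  }
  for (int t = m - 2; t >= 0; --t) {
    double d = cm[from + t + 1] - cm[from + t];
    if (d < 1e-9) d = 1e-9;
    double ex = std::exp(-lambda * d);
    double t11 = pi + (1.0 - pi) * ex;
    double t01 = pi * (1.0 - ex);
    double t10 = 1.0 - t11;
    double t00 = 1.0 - t01;
    emissions(hapA[from + t + 1], hapB[from + t + 1], freq[from + t + 1], eps,
              e0, e1);
    double nb0 = t00 * e0 * b0 + t01 * e1 * b1;
    double nb1 = t10 * e0 * b0 + t11 * e1 * b1;
    double s = nb0 + nb1;
    b0 = nb0 / s;
    b1 = nb1 / s;
    double g0 = fwd0[t] * b0, g1 = fwd1[t] * b1;
    post[t] = g1 / (g0 + g1);
  }
}

// [[Rcpp::export(name = ".fb_pair_posterior")]]
NumericVector fb_pair_posterior(IntegerVector hapA, IntegerVector hapB,
                                NumericVector cm, NumericVector freq,
                                double phi, double lambda, double eps) {
  int m = hapA.size();
  if (hapB.size() != m || cm.size() != m || freq.size() != m)
    stop("haplotype, map and frequency vectors must have equal length");
  NumericVector post(m);
  std::vector<double> f0(m), f1(m);
  fb_posterior_core(hapA.begin(), hapB.begin(), cm.begin(), freq.begin(), 0, m,
                    phi, lambda, eps, post.begin(), f0.data(), f1.data());
  return post;
}

// Scan a set of haplotype pairs for IBD segments.  `haps` is n_hap x m with
// NA for missing; `pairs` is P x 2 (1-based row indices); `phi` and `lambda`
// are per-pair; `chrom_start`/`chrom_end` give 1-based half-open column
// ranges of each chromosome.  Segments are maximal runs of posterior >=
// threshold of at least min_markers markers; marker indices returned are
// 1-based and half-open [start, end).
// [[Rcpp::export(name = ".ibd_scan")]]
List ibd_scan(IntegerMatrix haps, IntegerMatrix pairs, NumericVector phi,
              NumericVector lambda, NumericVector cm, NumericVector freq,
              double eps, double threshold, int min_markers,
              IntegerVector chrom_start, IntegerVector chrom_end) {
  int P = pairs.nrow();
  int m = haps.ncol();
  int n_chrom = chrom_start.size();
  if (phi.size() != P || lambda.size() != P) stop("phi/lambda length mismatch");
  if (cm.size() != m || freq.size() != m) stop("map length mismatch");

  std::vector<double> post(m), f0(m), f1(m);
  std::vector<int> out_a, out_b, out_chrom, out_start, out_end;
  std::vector<double> out_post;

  // column-major copies of the two rows for cache-friendly access
  std::vector<int> rowA(m), rowB(m);

  for (int p = 0; p < P; ++p) {
    int ia = pairs(p, 0) - 1;
    int ib = pairs(p, 1) - 1;
    for (int j = 0; j < m; ++j) {
      rowA[j] = haps(ia, j);
      rowB[j] = haps(ib, j);
    }
    for (int c = 0; c < n_chrom; ++c) {
      int from = chrom_start[c] - 1;
      int to = chrom_end[c] - 1;  // half-open: columns [from, to)
      int len = to - from;
      if (len <= 0) continue;
      fb_posterior_core(rowA.data(), rowB.data(), cm.begin(), freq.begin(),
                        from, to, phi[p], lambda[p], eps, post.data(),
                        f0.data(), f1.data());
      int run_start = -1;
      double run_sum = 0.0;
      for (int t = 0; t <= len; ++t) {
        bool high = (t < len) && (post[t] >= threshold);
        if (high) {
          if (run_start < 0) {
            run_start = t;
            run_sum = 0.0;
          }
          run_sum += post[t];
        } else if (run_start >= 0) {
          int run_len = t - run_start;
          if (run_len >= min_markers) {
            out_a.push_back(ia + 1);
            out_b.push_back(ib + 1);
            out_chrom.push_back(c + 1);
            out_start.push_back(from + run_start + 1);
            out_end.push_back(from + t + 1);  // half-open
            out_post.push_back(run_sum / run_len);
          }
          run_start = -1;
        }
      }
    }
    if (p % 1024 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["hap_a"] = wrap(out_a), _["hap_b"] = wrap(out_b),
      _["chrom_index"] = wrap(out_chrom), _["start"] = wrap(out_start),
      _["end"] = wrap(out_end), _["mean_posterior"] = wrap(out_post));
}
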