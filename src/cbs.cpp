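#include <Rcpp.h>
using namespace Rcpp;

// Circular binary segmentation core.
//
// The split statistic for an interval x[0..m) circularized is the pooled
// two-sample t-like statistic comparing the arc x[i..j) against its
// complement, with the variance estimated once from the whole interval:
//
//   T(i, j) = | mean(arc) - mean(complement) | / sqrt( s2 * (1/k + 1/(m-k)) )
//
// where k = j - i and s2 is the (population) variance of the interval.
// Arcs that wrap past the interval end are complements of non-wrapping arcs
// and give the same T, so enumerating 0 <= i < j <= m covers every circular
// split; the pair (i, j) maps back to at most two linear cut points.
// Ties are broken toward the first pair in (i ascending, j ascending) order,
// i.e. the leftmost start and, within a start, the shortest arc.

struct Split {
  int i;
  int j;
  double t;
  bool found;
};

static Split max_split(const double *x, int m, int min_width) {
  Split best = {-1, -1, 0.0, false};
  if (m < 2 * min_width) return best;

  std::vector<double> cs(m + 1);
  cs[0] = 0.0;
  double tot = 0.0;
  for (int p = 0; p < m; ++p) {
    tot += x[p];
    cs[p + 1] = tot;
  }
  double mean = tot / m;
  double sst = 0.0;
  for (int p = 0; p < m; ++p) {
    double d = x[p] - mean;
    sst += d * d;
  }
  double s2 = sst / m;
  if (s2 < 1e-20) return best;  // flat interval: no split

  for (int i = 0; i < m; ++i) {
    int jlo = i + min_width;
    int jhi = std::min(m, i + (m - min_width));
    for (int j = jlo; j <= jhi; ++j) {
      int k = j - i;
      double m1 = (cs[j] - cs[i]) / k;
      double m2 = (tot - cs[j] + cs[i]) / (m - k);
      double t = std::fabs(m1 - m2) / std::sqrt(s2 * (1.0 / k + 1.0 / (m - k)));
      if (t > best.t) {
        best.i = i;
        best.j = j;
        best.t = t;
        best.found = true;
      }
    }
  }
  return best;
}

// Permutation acceptance test for one candidate split. Shuffles the interval
// values (R's RNG, so set.seed() in R governs reproducibility) and compares
// the shuffled max split statistic with the observed one. Early stop: once
// enough exceedances have accrued that (n_exceed + 1)/(nperm + 1) must
// exceed alpha, the split is rejected without finishing the loop.
static bool accept_split(const double *x, int m, int min_width, double t_obs,
                         double alpha, int nperm) {
  std::vector<double> perm(x, x + m);
  int limit = (int)std::floor(alpha * (nperm + 1.0)) - 1;  // max tolerated n_exceed
  if (limit < 0) return false;
  int n_exceed = 0;
  for (int b = 0; b < nperm; ++b) {
    for (int p = m - 1; p > 0; --p) {
      int q = (int)(unif_rand() * (p + 1));
      if (q > p) q = p;
      std::swap(perm[p], perm[q]);
    }
    Split s = max_split(perm.data(), m, min_width);
    if (s.found && s.t >= t_obs) {
      if (++n_exceed > limit) return false;
    }
  }
  return true;
}

static void segment_recurse(const double *x, int lo, int hi, int min_width,
                            double alpha, int nperm, std::vector<int> &cps) {
  int m = hi - lo;
  if (m < 2 * min_width) return;
  Split s = max_split(x + lo, m, min_width);
  if (!s.found) return;
  if (!accept_split(x + lo, m, min_width, s.t, alpha, nperm)) return;

  int a = s.i;  // interval-relative cuts; 0 or m mean "no cut at that end"
  int b = s.j;
  std::vector<int> bounds;
  bounds.push_back(0);
  if (a > 0) bounds.push_back(a);
  if (b < m) bounds.push_back(b);
  bounds.push_back(m);
  for (size_t p = 1; p + 1 < bounds.size(); ++p) cps.push_back(lo + bounds[p]);
  for (size_t p = 0; p + 1 < bounds.size(); ++p)
    segment_recurse(x, lo + bounds[p], lo + bounds[p + 1], min_width, alpha,
                    nperm, cps);
}

// [[Rcpp::export(name = ".cbs_max_split_cpp")]]
List cbs_max_split_cpp(NumericVector x, int min_width) {
  Split s = max_split(REAL(x), x.size(), min_width);
  return List::create(_["i"] = s.i, _["j"] = s.j, _["t"] = s.t,
                      _["found"] = s.found);
}

// [[Rcpp::export(name = ".cbs_segment_cpp")]]
IntegerVector cbs_segment_cpp(NumericVector x, double alpha, int nperm,
                              int min_width) {
  std::vector<int> cps;
  GetRNGstate();
  segment_recurse(REAL(x), 0, x.size(), min_width, alpha, nperm, cps);
  PutRNGstate();
  std::sort(cps.begin(), cps.end());
  cps.erase(std::unique(cps.begin(), cps.end()), cps.end());
  return wrap(cps);
}

// Max split statistic only (used for the permutation split test oracle and
// for fast null-distribution work from R).
// [[Rcpp::export(name = ".cbs_max_t_cpp")]]
double cbs_max_t_cpp(NumericVector x, int min_width) {
  Split s = max_split(REAL(x), x.size(), min_width);
  return s.found ? s.t : 0.0;
}
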