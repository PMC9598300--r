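#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Allocation of `total` organisms over `m` cells from the spacing kernel:
// m sorted uniforms give m spacings (first element kept as the gap from 0);
// normalised spacings are mixed with the uniform share by weight p, and the
// real-valued cell shares are integerised by largest-remainder rounding so
// conservation is exact.  The caller permutes the result across cells.
// [[Rcpp::export]]
IntegerVector cpp_spacing_alloc(double total, int m, double p) {
  if (m < 1) stop("number_of_cells must be >= 1");
  if (total < 0) stop("total must be >= 0");
  IntegerVector out(m);
  long long tot = (long long) (total + 0.5);
  if (tot == 0) return out;

  std::vector<double> u(m);
  for (int i = 0; i < m; ++i) u[i] = unif_rand();
  std::sort(u.begin(), u.end());
  // spacings: first element plus successive differences; they sum to u[m-1]
  std::vector<double> f(m);
  double s = u[m - 1];
  f[0] = u[0];
  for (int i = 1; i < m; ++i) f[i] = u[i] - u[i - 1];
  for (int i = 0; i < m; ++i)
    f[i] = (1.0 - p) / m + p * (s > 0 ? f[i] / s : 1.0 / m);

  // largest-remainder integerisation
  std::vector<std::pair<double, int> > frac(m);
  long long base_sum = 0;
  for (int i = 0; i < m; ++i) {
    double x = total * f[i];
    double b = std::floor(x);
    out[i] = (int) b;
    base_sum += (long long) b;
    frac[i] = std::make_pair(x - b, i);
  }
  long long rem = tot - base_sum;
  if (rem < 0) rem = 0;
  if (rem > m) rem = m;
  if (rem > 0) {
    std::partial_sort(frac.begin(), frac.begin() + rem, frac.end(),
                      [](const std::pair<double, int>& a,
                         const std::pair<double, int>& b) {
                        if (a.first != b.first) return a.first > b.first;
                        return a.second < b.second;
                      });
    for (long long j = 0; j < rem; ++j) out[frac[j].second] += 1;
  }
  return out;
}

// Neighbourhood scatter: every organism in cell i is independently
// reassigned to a uniform cell of the window of `radius` cells on each side
// of i (origin included).  On a ring a window covering the lattice collapses
// to one uniform multinomial; on a transect windows are truncated at edges.
// [[Rcpp::export]]
IntegerVector cpp_disperse_n(IntegerVector counts, int radius, bool wrap) {
  int m = counts.size();
  if (radius <= 0) return clone(counts);
  IntegerVector out(m);
  std::vector<double> prob;
  std::vector<int> rn;

  if (wrap && 2 * radius + 1 >= m) {
    long long total = 0;
    for (int i = 0; i < m; ++i) total += counts[i];
    if (total == 0) return out;
    prob.assign(m, 1.0 / m);
    rn.assign(m, 0);
    ::rmultinom((int) total, prob.data(), m, rn.data());
    for (int i = 0; i < m; ++i) out[i] = rn[i];
    return out;
  }

  for (int i = 0; i < m; ++i) {
    int c = counts[i];
    if (c <= 0) continue;
    if (wrap) {
      int k = 2 * radius + 1;
      prob.assign(k, 1.0 / k);
      rn.assign(k, 0);
      ::rmultinom(c, prob.data(), k, rn.data());
      for (int j = 0; j < k; ++j) {
        int dest = (i - radius + j) % m;
        if (dest < 0) dest += m;
        out[dest] += rn[j];
      }
    } else {
      int lo = std::max(0, i - radius), hi = std::min(m - 1, i + radius);
      int k = hi - lo + 1;
      prob.assign(k, 1.0 / k);
      rn.assign(k, 0);
      ::rmultinom(c, prob.data(), k, rn.data());
      for (int j = 0; j < k; ++j) out[lo + j] += rn[j];
    }
  }
  return out;
}

// Within-cell scramble competition with per-species resource needs: all
// occupants are processed in a uniformly random order; each consumes its
// species' need if enough resources remain, otherwise it dies.  Used when
// needs are unequal; the unit-need case has a vectorised hypergeometric
// path on the R side.
// [[Rcpp::export]]
IntegerVector cpp_compete_order(IntegerVector occupants, double resources,
                                IntegerVector needs) {
  int S = occupants.size();
  if (needs.size() != S) stop("needs must match occupants length");
  long long total = 0;
  for (int s = 0; s < S; ++s) {
    if (occupants[s] < 0) stop("occupants must be >= 0");
    total += occupants[s];
  }
  IntegerVector surv(S);
  if (total == 0) return surv;
  std::vector<int> order;
  order.reserve(total);
  for (int s = 0; s < S; ++s)
    for (int j = 0; j < occupants[s]; ++j) order.push_back(s);
  for (long long i = total - 1; i > 0; --i) {
    long long j = (long long) (unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(order[i], order[j]);
  }
  double rem = resources;
  for (long long i = 0; i < total; ++i) {
    int s = order[i];
    if (needs[s] <= rem) {
      rem -= needs[s];
      surv[s] += 1;
    }
  }
  return surv;
}
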