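#include <Rcpp.h>
#include <vector>
#include <limits>

using namespace Rcpp;

// Penalized least-squares changepoint detection by PELT.
//
// Objective: sum over segments of the within-segment sum of squared
// deviations from the segment mean, plus penalty * (number of changepoints).
// A changepoint t is the last index of a segment (1 <= t < N).
//
// Cost of a segment [a, b] (1-based, inclusive) from prefix sums:
//   C(a:b) = S2[b] - S2[a-1] - (S1[b] - S1[a-1])^2 / (b - a + 1)
// Plain double prefix sums are used so that cost values are bit-identical
// to an R implementation using cumsum() with the same summation order;
// this keeps tie-breaking reproducible across the two code paths.
//
// Pruning uses the K = 0 condition valid for nonnegative costs: a candidate
// t is discarded at time s once F[t] + C(t+1:s) > F[s], and can then never
// be optimal for any s' > s.  Candidates are scanned in ascending order and
// replaced only on strict improvement, so the smallest last-changepoint
// index wins on ties (and "no split" beats a cost-neutral split).

static inline double seg_cost(const std::vector<double> &S1,
                              const std::vector<double> &S2,
                              int a, int b) {
    double s = S1[b] - S1[a - 1];
    double q = S2[b] - S2[a - 1];
    double w = (double)(b - a + 1);
    return q - s * s / w;
}

// [[Rcpp::export(name = ".pelt_cpp")]]
List pelt_cpp(NumericVector x, double penalty) {
    const int N = x.size();
    if (N < 1) stop("empty series");
    if (penalty < 0) stop("penalty must be >= 0");

    std::vector<double> S1(N + 1, 0.0), S2(N + 1, 0.0);
    for (int i = 0; i < N; ++i) {
        S1[i + 1] = S1[i] + x[i];
        S2[i + 1] = S2[i] + x[i] * x[i];
    }

    const double inf = std::numeric_limits<double>::infinity();
    std::vector<double> F(N + 1);
    std::vector<int> prev(N + 1, 0);
    F[0] = -penalty;

    std::vector<int> cand;   // candidate last-changepoints, ascending
    cand.reserve(64);
    cand.push_back(0);

    std::vector<double> val; // F[t] + C(t+1:s) for current s
    val.reserve(64);

    for (int s = 1; s <= N; ++s) {
        double best = inf;
        int bestt = 0;
        val.resize(cand.size());
        for (size_t j = 0; j < cand.size(); ++j) {
            int t = cand[j];
            double v = F[t] + seg_cost(S1, S2, t + 1, s);
            val[j] = v;
            double tot = v + penalty;
            if (tot < best) { best = tot; bestt = t; }
        }
        F[s] = best;
        prev[s] = bestt;

        // prune, then admit s as a candidate for the next step
        std::vector<int> keep;
        keep.reserve(cand.size() + 1);
        for (size_t j = 0; j < cand.size(); ++j)
            if (val[j] <= F[s]) keep.push_back(cand[j]);
        keep.push_back(s);
        cand.swap(keep);
    }

    std::vector<int> cps;
    for (int t = prev[N]; t > 0; t = prev[t]) cps.push_back(t);
    IntegerVector out(cps.rbegin(), cps.rend());

    return List::create(_["changepoints"] = out,
                        _["objective"] = F[N]);
}
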