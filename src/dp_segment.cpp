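#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact least-squares segmentation of a numeric vector into piecewise
// constant segments, minimising  SSE + penalty * (number of breakpoints)
// with the breakpoint count capped at max_breakpoints.  Classical
// O(K * n^2) dynamic programme over segment counts; ties are broken in
// favour of fewer breakpoints and, within a level, the earliest split.
//
// [[Rcpp::export]]
List dp_segment_cpp(NumericVector x, double penalty, int max_breakpoints) {
    const int n = x.size();
    if (n < 1) stop("empty input vector");
    if (penalty < 0) stop("penalty must be non-negative");

    std::vector<long double> s(n + 1, 0.0L), s2(n + 1, 0.0L);
    for (int i = 0; i < n; ++i) {
        s[i + 1]  = s[i]  + (long double) x[i];
        s2[i + 1] = s2[i] + (long double) x[i] * x[i];
    }
    // SSE of x[i..j] (0-based, inclusive) around its own mean
    auto sse = [&](int i, int j) -> double {
        const long double m  = (long double) (j - i + 1);
        const long double su = s[j + 1] - s[i];
        const long double sq = s2[j + 1] - s2[i];
        long double v = sq - su * su / m;
        if (v < 0) v = 0;
        return (double) v;
    };

    // Fast path: unconstrained penalised optimal partitioning, O(n^2).
    // cost[i+1] = min over j of cost[j] + sse(j..i) + penalty, with the
    // first segment exempt from the penalty. If the optimum respects the
    // breakpoint cap it is also the optimum of the capped problem.
    {
        std::vector<double> cst(n + 1);
        std::vector<int> prev(n + 1, -1);
        cst[0] = -penalty;
        for (int i = 0; i < n; ++i) {
            double best = R_PosInf; int bj = -1;
            for (int j = 0; j <= i; ++j) {
                const double c = cst[j] + sse(j, i) + penalty;
                if (c < best - 1e-12) { best = c; bj = j; }
            }
            cst[i + 1] = best;
            prev[i + 1] = bj;
        }
        std::vector<int> bounds;  // segment start indices, reversed
        int i = n;
        while (i > 0) { bounds.push_back(prev[i]); i = prev[i]; }
        const int nseg = (int) bounds.size();
        if (nseg - 1 <= max_breakpoints) {
            IntegerVector seg_start(nseg), seg_end(nseg);
            NumericVector seg_mean(nseg);
            for (int k = 0; k < nseg; ++k) {
                const int a = bounds[nseg - 1 - k];
                const int b = (k == nseg - 1) ? (n - 1)
                              : (bounds[nseg - 2 - k] - 1);
                seg_start[k] = a + 1;
                seg_end[k]   = b + 1;
                seg_mean[k]  = (double) ((s[b + 1] - s[a]) / (b - a + 1));
            }
            return List::create(_["start"] = seg_start,
                                _["end"] = seg_end,
                                _["mean"] = seg_mean,
                                _["n_breakpoints"] = nseg - 1,
                                _["objective"] = cst[n]);
        }
    }

    const int K = std::min(max_breakpoints, n - 1);  // breakpoints allowed
    // cost[k][i]: minimal SSE of x[0..i] using exactly k breakpoints
    std::vector< std::vector<double> > cost(K + 1, std::vector<double>(n));
    std::vector< std::vector<int> >    back(K + 1, std::vector<int>(n, -1));
    for (int i = 0; i < n; ++i) cost[0][i] = sse(0, i);
    for (int k = 1; k <= K; ++k) {
        for (int i = 0; i < n; ++i) {
            if (i < k) { cost[k][i] = R_PosInf; continue; }
            double best = R_PosInf; int bj = -1;
            // last breakpoint sits after index j: x[j+1..i] is final segment
            for (int j = k - 1; j < i; ++j) {
                const double c = cost[k - 1][j] + sse(j + 1, i);
                if (c < best) { best = c; bj = j; }
            }
            cost[k][i] = best;
            back[k][i] = bj;
        }
    }

    // pick the breakpoint count minimising the penalised objective,
    // preferring fewer breakpoints when the improvement is negligible
    int    bestk   = 0;
    double bestobj = cost[0][n - 1];
    for (int k = 1; k <= K; ++k) {
        const double obj = cost[k][n - 1] + penalty * k;
        if (obj < bestobj - 1e-10) { bestobj = obj; bestk = k; }
    }

    // backtrack: ends[] are 0-based last indices of each segment
    std::vector<int> ends(bestk + 1);
    int i = n - 1;
    for (int k = bestk; k >= 1; --k) {
        ends[k] = i;
        i = back[k][i];
    }
    ends[0] = i;
    // convert to 1-based segment bounds
    IntegerVector seg_start(bestk + 1), seg_end(bestk + 1);
    NumericVector seg_mean(bestk + 1);
    int prev = -1;
    for (int k = 0; k <= bestk; ++k) {
        seg_start[k] = prev + 2;          // 1-based
        seg_end[k]   = ends[k] + 1;
        const int a = prev + 1, b = ends[k];
        seg_mean[k]  = (double) ((s[b + 1] - s[a]) / (b - a + 1));
        prev = ends[k];
    }
    return List::create(_["start"] = seg_start,
                        _["end"] = seg_end,
                        _["mean"] = seg_mean,
                        _["n_breakpoints"] = bestk,
                        _["objective"] = bestobj);
}
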