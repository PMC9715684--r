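#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-tau correlator on a dense binned (optionally weighted) photon
// trace.  The lag grid is quasi-logarithmic: lags 1..16 bins at the base
// resolution, then lags 9..16 after each factor-2 coarsening of the trace
// (8 points per octave).  The estimator is the symmetrically normalized
// fluctuation correlation
//   G(m*dt) = < c_k c_{k+m} > / ( mean(head) * mean(tail) ) - 1
// which converges to 0 at large lags.
//
// [[Rcpp::export]]
List multitau_cpp(NumericVector times, NumericVector weights,
                  double duration, double dt0, double max_lag) {
    const R_xlen_t np = times.size();
    R_xlen_t n0 = (R_xlen_t)std::ceil(duration / dt0);
    if (n0 < 2) stop("duration too short for the requested base lag");
    std::vector<double> trace((size_t)n0, 0.0);
    const bool havew = weights.size() == np;
    for (R_xlen_t i = 0; i < np; ++i) {
        R_xlen_t b = (R_xlen_t)(times[i] / dt0);
        if (b < 0 || b >= n0) continue;  // outside the chunk
        trace[(size_t)b] += havew ? weights[i] : 1.0;
    }
    std::vector<double> lags, G, dts;
    double dt = dt0;
    R_xlen_t n = n0;
    int level = 0;
    while (true) {
        int m_lo = (level == 0) ? 1 : 9;
        int m_hi = 16;
        if (n < 2 * m_hi) break;
        for (int m = m_lo; m <= m_hi; ++m) {
            double lag = m * dt;
            if (lag > max_lag) break;
            const R_xlen_t nn = n - m;
            double s = 0.0, sh = 0.0, st = 0.0;
            for (R_xlen_t k = 0; k < nn; ++k) {
                s  += trace[(size_t)k] * trace[(size_t)(k + m)];
                sh += trace[(size_t)k];
                st += trace[(size_t)(k + m)];
            }
            double mh = sh / nn, mt = st / nn;
            double g = (mh > 0 && mt > 0) ? (s / nn) / (mh * mt) - 1.0
                                          : NA_REAL;
            lags.push_back(lag);
            G.push_back(g);
            dts.push_back(dt);
        }
        if (16.0 * dt >= max_lag) break;
        // coarsen by 2
        R_xlen_t nh = n / 2;
        for (R_xlen_t k = 0; k < nh; ++k) {
            trace[(size_t)k] = trace[(size_t)(2 * k)] +
                               trace[(size_t)(2 * k + 1)];
        }
        trace.resize((size_t)nh);
        n = nh;
        dt *= 2.0;
        ++level;
    }
    return List::create(_["lag"] = wrap(lags), _["G"] = wrap(G),
                        _["dt"] = wrap(dts));
}
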