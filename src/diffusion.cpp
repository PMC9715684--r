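#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Brownian diffusion of point emitters through a set of laterally shifted
// 3D Gaussian detection volumes (one per detector element), with an
// optional circular scan of the focus.  Photon emission is an
// inhomogeneous Poisson process evaluated on a regular simulation grid:
// within a step the per-channel rates are frozen, the total photon count
// is Poisson, photon times are uniform in the step and channels are drawn
// from the per-channel rate shares.  Positions use periodic boundaries.
//
// A small self-contained xoshiro256+ generator keeps the hot loop off the
// R RNG; the seed is an explicit argument so runs are reproducible.

namespace {

struct Rng {
    uint64_t s[4];
    explicit Rng(uint64_t seed) {
        // splitmix64 expansion of the seed
        uint64_t z = seed;
        for (int i = 0; i < 4; ++i) {
            z += 0x9e3779b97f4a7c15ULL;
            uint64_t t = z;
            t = (t ^ (t >> 30)) * 0xbf58476d1ce4e5b9ULL;
            t = (t ^ (t >> 27)) * 0x94d049bb133111ebULL;
            s[i] = t ^ (t >> 31);
        }
    }
    static uint64_t rotl(uint64_t x, int k) {
        return (x << k) | (x >> (64 - k));
    }
    uint64_t next() {
        const uint64_t result = s[0] + s[3];
        const uint64_t t = s[1] << 17;
        s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
        s[2] ^= t; s[3] = rotl(s[3], 45);
        return result;
    }
    double unif() {  // (0, 1)
        return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
    }
    bool have_spare = false;
    double spare = 0.0;
    double norm() {  // Box-Muller
        if (have_spare) { have_spare = false; return spare; }
        double u = unif(), v = unif();
        double r = std::sqrt(-2.0 * std::log(u));
        double a = 6.283185307179586 * v;
        spare = r * std::sin(a);
        have_spare = true;
        return r * std::cos(a);
    }
    int poisson(double lambda) {  // Knuth; lambda is small here
        double L = std::exp(-lambda), p = 1.0;
        int k = 0;
        do { ++k; p *= unif(); } while (p > L);
        return k - 1;
    }
};

inline double wrap(double x, double l) {
    // periodic boundary without fmod (keeps glibc symbol needs minimal)
    return x - l * std::floor(x / l);
}

}  // namespace

// [[Rcpp::export]]
List sim_diffusion_cpp(int n_particles, double D, NumericVector box,
                       NumericVector shift_x, NumericVector shift_y,
                       double w0, double kecc, double brightness_hz,
                       double duration, double dt,
                       double scan_R, double scan_T,
                       double seed) {
    if (box.size() != 3) stop("box must have 3 elements");
    const int nch = shift_x.size();
    if (shift_y.size() != nch) stop("shift vectors must match");
    Rng rng((uint64_t)seed);
    const double lx = box[0], ly = box[1], lz = box[2];
    const double step_sd = std::sqrt(2.0 * D * dt);
    const double wz = kecc * w0;
    const double inv_w2 = 2.0 / (w0 * w0);
    const double inv_wz2 = 2.0 / (wz * wz);
    // particle positions, uniform start, focus path centred in the box
    std::vector<double> px(n_particles), py(n_particles), pz(n_particles);
    for (int p = 0; p < n_particles; ++p) {
        px[p] = rng.unif() * lx;
        py[p] = rng.unif() * ly;
        pz[p] = rng.unif() * lz;
    }
    const double cx = lx / 2, cy = ly / 2, cz = lz / 2;
    const R_xlen_t nsteps = (R_xlen_t)(duration / dt);
    std::vector<double> out_t;
    std::vector<int> out_ch;
    out_t.reserve(1024);
    std::vector<double> rate(nch);
    const double two_pi = 6.283185307179586;
    for (R_xlen_t st = 0; st < nsteps; ++st) {
        const double t0 = st * dt;
        double fx = cx, fy = cy;
        if (scan_R > 0 && scan_T > 0) {
            const double ph = two_pi * t0 / scan_T;
            fx += scan_R * std::cos(ph);
            fy += scan_R * std::sin(ph);
        }
        double tot = 0.0;
        for (int c = 0; c < nch; ++c) rate[c] = 0.0;
        for (int p = 0; p < n_particles; ++p) {
            // diffusion step (periodic box)
            px[p] = wrap(px[p] + step_sd * rng.norm(), lx);
            py[p] = wrap(py[p] + step_sd * rng.norm(), ly);
            pz[p] = wrap(pz[p] + step_sd * rng.norm(), lz);
            const double dz = pz[p] - cz;
            const double gz = std::exp(-dz * dz * inv_wz2);
            if (gz < 1e-8) continue;
            const double dx = px[p] - fx, dy = py[p] - fy;
            // separable lateral factors over the element grid
            for (int c = 0; c < nch; ++c) {
                const double ddx = dx - shift_x[c];
                const double ddy = dy - shift_y[c];
                const double g = std::exp(-(ddx * ddx + ddy * ddy) * inv_w2);
                const double r = brightness_hz * g * gz;
                rate[c] += r;
                tot += r;
            }
        }
        if (tot <= 0) continue;
        const int nph = rng.poisson(tot * dt);
        for (int q = 0; q < nph; ++q) {
            out_t.push_back(t0 + rng.unif() * dt);
            double u = rng.unif() * tot;
            int c = 0;
            double acc = rate[0];
            while (acc < u && c < nch - 1) acc += rate[++c];
            out_ch.push_back(c);
        }
    }
    return List::create(_["time_s"] = wrap(out_t),
                        _["channel"] = wrap(out_ch));
}
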