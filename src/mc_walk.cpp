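// Random-walk Monte-Carlo simulation of diffusion inside an impermeable
// sphere under an effective gradient waveform. Walkers take fixed-length
// steps sqrt(6 D dt) in uniform random directions with elastic specular
// reflection at the boundary; the accumulated phase along the gradient
// axis (z) is phi = gamma * sum g(t_i) z_i dt. A dedicated mt19937_64
// stream seeded explicitly makes runs bit-reproducible independent of R's
// RNG state.

#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

namespace {

struct Vec3 { double x, y, z; };

inline double norm2(const Vec3 &v) { return v.x * v.x + v.y * v.y + v.z * v.z; }

// specular reflection of the segment p -> p2 at the sphere |x| = R
inline Vec3 reflect_into_sphere(Vec3 p, Vec3 p2, double R) {
  for (int iter = 0; iter < 8 && norm2(p2) > R * R; ++iter) {
    // intersection p + s (p2 - p) with the sphere, s in (0, 1]
    Vec3 d{p2.x - p.x, p2.y - p.y, p2.z - p.z};
    double a = norm2(d);
    if (a <= 0) break;
    double b = 2.0 * (p.x * d.x + p.y * d.y + p.z * d.z);
    double c = norm2(p) - R * R;
    double disc = b * b - 4.0 * a * c;
    if (disc < 0) disc = 0;
    double s = (-b + std::sqrt(disc)) / (2.0 * a);
    if (s < 0) s = 0; else if (s > 1) s = 1;
    Vec3 hit{p.x + s * d.x, p.y + s * d.y, p.z + s * d.z};
    double hn = std::sqrt(norm2(hit));
    if (hn <= 0) break;
    Vec3 n{hit.x / hn, hit.y / hn, hit.z / hn};
    Vec3 rem{p2.x - hit.x, p2.y - hit.y, p2.z - hit.z};
    double rn = rem.x * n.x + rem.y * n.y + rem.z * n.z;
    p2 = Vec3{hit.x + rem.x - 2.0 * rn * n.x,
              hit.y + rem.y - 2.0 * rn * n.y,
              hit.z + rem.z - 2.0 * rn * n.z};
    p = hit;
  }
  if (norm2(p2) > R * R) {  // pathological multi-bounce: clamp to boundary
    double f = (R * (1.0 - 1e-12)) / std::sqrt(norm2(p2));
    p2.x *= f; p2.y *= f; p2.z *= f;
  }
  return p2;
}

} // namespace

// Phases (rad) accumulated by each walker; g is the effective gradient
// (mT/m) pre-sampled on the n_steps MC time grid, gamma_i in
// rad ms^-1 (mT/m)^-1 um^-1, axis in {0,1,2} selects the gradient axis.
// [[Rcpp::export(name = ".mc_walk_phases")]]
NumericVector mc_walk_phases(double R, double D, NumericVector g,
                             double step_dt, int n_walkers,
                             double gamma_i, int seed, int axis = 2) {
  const int n_steps = g.size();
  const double L = std::sqrt(6.0 * D * step_dt);
  std::mt19937_64 rng(static_cast<unsigned long long>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  NumericVector phases(n_walkers);

  for (int wlk = 0; wlk < n_walkers; ++wlk) {
    // uniform start inside the sphere (rejection)
    Vec3 p;
    do {
      p = Vec3{R * (2.0 * unif(rng) - 1.0), R * (2.0 * unif(rng) - 1.0),
               R * (2.0 * unif(rng) - 1.0)};
    } while (norm2(p) > R * R);
    double phi = 0.0;
    for (int t = 0; t < n_steps; ++t) {
      // uniform direction (Marsaglia)
      double u1, u2, s2;
      do {
        u1 = 2.0 * unif(rng) - 1.0;
        u2 = 2.0 * unif(rng) - 1.0;
        s2 = u1 * u1 + u2 * u2;
      } while (s2 >= 1.0 || s2 == 0.0);
      double root = 2.0 * std::sqrt(1.0 - s2);
      Vec3 dir{u1 * root, u2 * root, 1.0 - 2.0 * s2};
      Vec3 p2{p.x + L * dir.x, p.y + L * dir.y, p.z + L * dir.z};
      if (norm2(p2) > R * R) p2 = reflect_into_sphere(p, p2, R);
      p = p2;
      double coord = (axis == 0) ? p.x : (axis == 1) ? p.y : p.z;
      phi += gamma_i * g[t] * coord * step_dt;
    }
    phases[wlk] = phi;
  }
  return phases;
}
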