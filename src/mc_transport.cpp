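// Photon-packet Monte Carlo transport in a homogeneous slab, MCML-style
// hop-drop-spin with weighted absorption, Fresnel/TIR at the top surface,
// matched absorbing bottom, and Russian-roulette termination.
//
// Uses R's RNG (unif_rand) so runs are reproducible via set.seed() in the
// calling R code.

#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

namespace {

const double kPi = 3.14159265358979323846;

// Unpolarized Fresnel reflectance for a photon inside the medium hitting the
// top surface with |cos(theta_i)| = cos_i, going from index n_i to n_t.
double fresnel_reflectance(double n_i, double n_t, double cos_i) {
  if (cos_i > 1.0) cos_i = 1.0;
  double sin_i = std::sqrt(std::max(0.0, 1.0 - cos_i * cos_i));
  double sin_t = n_i / n_t * sin_i;
  if (sin_t >= 1.0) return 1.0;  // total internal reflection
  double cos_t = std::sqrt(1.0 - sin_t * sin_t);
  double rs = (n_i * cos_i - n_t * cos_t) / (n_i * cos_i + n_t * cos_t);
  double rp = (n_i * cos_t - n_t * cos_i) / (n_i * cos_t + n_t * cos_i);
  return 0.5 * (rs * rs + rp * rp);
}

// Henyey-Greenstein cosine sample (isotropic when g == 0).
double sample_cos_theta(double g) {
  double u = unif_rand();
  if (std::fabs(g) < 1e-12) return 2.0 * u - 1.0;
  double tmp = (1.0 - g * g) / (1.0 - g + 2.0 * g * u);
  double ct = (1.0 + g * g - tmp * tmp) / (2.0 * g);
  if (ct > 1.0) ct = 1.0;
  if (ct < -1.0) ct = -1.0;
  return ct;
}

void spin(double &ux, double &uy, double &uz, double g) {
  double ct = sample_cos_theta(g);
  double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
  double phi = 2.0 * kPi * unif_rand();
  double cp = std::cos(phi), sp = std::sin(phi);
  double nux, nuy, nuz;
  if (std::fabs(uz) > 0.99999) {
    nux = st * cp;
    nuy = st * sp;
    nuz = (uz >= 0.0 ? ct : -ct);
  } else {
    double den = std::sqrt(1.0 - uz * uz);
    nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
    nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
    nuz = -st * cp * den + uz * ct;
  }
  double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
  ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
}

inline double wrap(double v, double L) {
  // periodic reduction without std::fmod (keeps the binary linkable
  // against older glibc versions of libm)
  v -= L * std::floor(v / L);
  if (v >= L) v = 0.0;  // guard the v/L rounding edge
  return v;
}

}  // namespace

// beam_type: 0 = infinite uniform (periodic lateral wrap),
//            1 = disc of given diameter centred on the grid (lateral escape).
// [[Rcpp::export]]
List mc_transport_cpp(double mu_a, double mu_s, double g,
                      double n_tissue, double n_ambient,
                      int n_photons,
                      double dx, double dy, double dz,
                      int nx, int ny, int nz,
                      int beam_type, double beam_diameter,
                      double roulette_threshold, double roulette_survival) {
  const double Lx = nx * dx, Ly = ny * dy, Zmax = nz * dz;
  const double mu_t = mu_a + mu_s;
  const double n_rel = n_tissue / n_ambient;
  const double r_sp = (n_rel - 1.0) * (n_rel - 1.0) /
                      ((n_rel + 1.0) * (n_rel + 1.0));
  const double beam_r = 0.5 * beam_diameter;

  NumericVector grid(static_cast<R_xlen_t>(nx) * ny * nz);  // x fastest
  double absorbed = 0.0, diffuse = 0.0, transmitted = 0.0;
  double roulette_gain = 0.0, roulette_loss = 0.0;

  for (int ip = 0; ip < n_photons; ++ip) {
    double x, y;
    if (beam_type == 1) {
      // uniform over disc, rejection-free polar sample
      double r = beam_r * std::sqrt(unif_rand());
      double phi = 2.0 * kPi * unif_rand();
      x = 0.5 * Lx + r * std::cos(phi);
      y = 0.5 * Ly + r * std::sin(phi);
    } else {
      x = Lx * unif_rand();
      y = Ly * unif_rand();
    }
    double z = 0.0, ux = 0.0, uy = 0.0, uz = 1.0;
    double w = 1.0 - r_sp;  // specular loss handled analytically

    bool alive = true;
    if (mu_t <= 0.0) {  // transparent medium: straight through
      transmitted += w;
      alive = false;
    }

    while (alive) {
      double s = -std::log(unif_rand()) / mu_t;

      // hop, resolving top/bottom boundary hits within the sampled step
      while (s > 0.0) {
        double db = R_PosInf;
        if (uz < 0.0) db = -z / uz;
        else if (uz > 0.0) db = (Zmax - z) / uz;
        if (s < db) {
          x += s * ux; y += s * uy; z += s * uz;
          s = 0.0;
        } else {
          x += db * ux; y += db * uy; z += db * uz;
          s -= db;
          if (uz < 0.0) {  // top surface: Fresnel / TIR
            z = 0.0;
            if (unif_rand() < fresnel_reflectance(n_tissue, n_ambient, -uz)) {
              uz = -uz;
            } else {
              diffuse += w;
              alive = false;
              break;
            }
          } else {  // bottom: matched, absorbing
            transmitted += w;
            alive = false;
            break;
          }
        }
        // lateral handling after each positional move
        if (beam_type == 1) {
          if (x < 0.0 || x >= Lx || y < 0.0 || y >= Ly) {
            transmitted += w;  // escaped laterally
            alive = false;
            break;
          }
        } else {
          x = wrap(x, Lx); y = wrap(y, Ly);
        }
      }
      if (!alive) break;

      // drop
      double dw = w * mu_a / mu_t;
      if (dw > 0.0) {
        int ix = static_cast<int>(x / dx); if (ix >= nx) ix = nx - 1; if (ix < 0) ix = 0;
        int iy = static_cast<int>(y / dy); if (iy >= ny) iy = ny - 1; if (iy < 0) iy = 0;
        int iz = static_cast<int>(z / dz); if (iz >= nz) iz = nz - 1; if (iz < 0) iz = 0;
        grid[static_cast<R_xlen_t>(iz) * nx * ny +
             static_cast<R_xlen_t>(iy) * nx + ix] += dw;
        absorbed += dw;
        w -= dw;
      }

      // roulette
      if (w < roulette_threshold) {
        if (w <= 0.0) break;
        if (unif_rand() < roulette_survival) {
          roulette_gain += w * (1.0 / roulette_survival - 1.0);
          w /= roulette_survival;
        } else {
          roulette_loss += w;
          break;
        }
      }

      // spin
      spin(ux, uy, uz, g);
    }
  }

  return List::create(
      _["grid"] = grid,
      _["specular"] = static_cast<double>(n_photons) * r_sp,
      _["diffuse"] = diffuse,
      _["absorbed"] = absorbed,
      _["transmitted"] = transmitted,
      _["roulette_gain"] = roulette_gain,
      _["roulette_loss"] = roulette_loss);
}
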