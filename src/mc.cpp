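// Layered-slab photon Monte Carlo (validation oracle).
//
// Weighted random walk with exponential optical-depth step sampling,
// Henyey-Greenstein scattering, Fresnel reflection/refraction at the
// external top/bottom boundaries (internal interfaces are index-matched),
// Russian roulette, and collision-estimator fluence scoring: at each
// interaction the pre-collision weight divided by mu_t is added to the
// (rho, z) and (rho, z, t) histograms, so fluence = score / (bin volume x
// photons), and per (bin volume x dt) in the time domain. The lateral
// geometry is an infinite slab: the cylindrical side wall of the diffusion
// model is neglected, which is why comparisons use large radii.
//
// Uses R's RNG (single-threaded), so runs are reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double runif_pos() {
  double u;
  do { u = unif_rand(); } while (u <= 0.0 || u >= 1.0);
  return u;
}

// [[Rcpp::export(name = ".mc_run_cpp")]]
List mc_run_cpp(int n_photons,
                NumericVector mu_a, NumericVector mu_s,
                NumericVector z_bot,  // cumulative layer bottoms, length nl
                double n_rel, double n_out, double g, double z0,
                double dr, double dz, double dt,
                int nr, int nz, int nt, double dz_td,
                double roulette_threshold, double roulette_factor,
                int n_batches, bool collimated) {
  const int nl = mu_a.size();
  const double L = z_bot[nl - 1];
  const double c0 = 29.9792458;
  const double inv_v = n_rel / c0;     // ns per cm of path
  const bool matched = std::abs(n_rel - n_out) < 1e-12;

  std::vector<double> z_top(nl), mu_t(nl);
  for (int k = 0; k < nl; ++k) {
    z_top[k] = (k == 0) ? 0.0 : z_bot[k - 1];
    mu_t[k] = mu_a[k] + mu_s[k];
    if (mu_t[k] <= 0.0) stop("Each layer needs mu_a + mu_s > 0.");
  }

  NumericVector ss(static_cast<R_xlen_t>(n_batches) * nr * nz);
  NumericVector td(static_cast<R_xlen_t>(n_batches) * nr * nt);
  double dep = 0.0, esc_top = 0.0, esc_bot = 0.0, killed = 0.0, gained = 0.0;

  for (int ip = 0; ip < n_photons; ++ip) {
    const int ib = static_cast<int>((static_cast<double>(ip) * n_batches) / n_photons);
    // isotropic point source on the axis at depth z0 (or a collimated
    // normally incident beam for analytic checks)
    double x = 0.0, y = 0.0, z, ux, uy, uz;
    if (collimated) {
      z = 1e-12; ux = 0.0; uy = 0.0; uz = 1.0;
    } else {
      z = z0;
      uz = 2.0 * unif_rand() - 1.0;
      double phi = 2.0 * M_PI * unif_rand();
      double sr = std::sqrt(std::max(0.0, 1.0 - uz * uz));
      ux = sr * std::cos(phi); uy = sr * std::sin(phi);
    }
    int k = 0;
    while (z > z_bot[k]) ++k;
    double w = 1.0, tof = 0.0;
    bool alive = true;

    while (alive) {
      double tau = -std::log(runif_pos());      // optical depth to next collision
      // propagate, crossing interfaces at constant optical depth
      while (true) {
        double s_geo = tau / mu_t[k];
        double db = 1e30;
        if (uz > 0.0)      db = (z_bot[k] - z) / uz;
        else if (uz < 0.0) db = (z_top[k] - z) / uz;
        if (db > s_geo) {  // collision inside current layer
          x += ux * s_geo; y += uy * s_geo; z += uz * s_geo;
          tof += s_geo * inv_v;
          break;
        }
        // move to the boundary
        x += ux * db; y += uy * db; z += uz * db;
        tof += db * inv_v;
        tau -= db * mu_t[k];
        if (uz > 0.0 && k == nl - 1) {          // bottom external boundary
          double R = 1.0;
          if (!matched) {
            double ci = std::fabs(uz), si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
            double st = n_rel / n_out * si;
            if (st >= 1.0) R = 1.0;
            else {
              double ct = std::sqrt(1.0 - st * st);
              double rs = (n_rel * ci - n_out * ct) / (n_rel * ci + n_out * ct);
              double rp = (n_rel * ct - n_out * ci) / (n_rel * ct + n_out * ci);
              R = 0.5 * (rs * rs + rp * rp);
            }
          } else R = 0.0;
          if (unif_rand() < R) { uz = -uz; z = L; }
          else { esc_bot += w; alive = false; break; }
        } else if (uz < 0.0 && k == 0) {        // top external boundary
          double R = 1.0;
          if (!matched) {
            double ci = std::fabs(uz), si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
            double st = n_rel / n_out * si;
            if (st >= 1.0) R = 1.0;
            else {
              double ct = std::sqrt(1.0 - st * st);
              double rs = (n_rel * ci - n_out * ct) / (n_rel * ci + n_out * ct);
              double rp = (n_rel * ct - n_out * ci) / (n_rel * ct + n_out * ci);
              R = 0.5 * (rs * rs + rp * rp);
            }
          } else R = 0.0;
          if (unif_rand() < R) { uz = -uz; z = 0.0; }
          else { esc_top += w; alive = false; break; }
        } else {                                // internal, index-matched
          k += (uz > 0.0) ? 1 : -1;
        }
      }
      if (!alive) break;

      // collision: score fluence (w / mu_t per bin volume), deposit, scatter
      const double rad = std::sqrt(x * x + y * y);
      const int ir = static_cast<int>(rad / dr);
      const int iz = static_cast<int>(z / dz);
      const double score = w / mu_t[k];
      if (ir >= 0 && ir < nr) {
        if (iz >= 0 && iz < nz)
          ss[(static_cast<R_xlen_t>(ib) * nz + iz) * nr + ir] += score;
        if (z < dz_td) {
          const int it = static_cast<int>(tof / dt);
          if (it >= 0 && it < nt)
            td[(static_cast<R_xlen_t>(ib) * nt + it) * nr + ir] += score;
        }
      }
      const double dw = w * mu_a[k] / mu_t[k];
      dep += dw;
      w -= dw;

      if (mu_s[k] <= 0.0) { killed += w; break; }  // pure absorber: walk ends

      // Henyey-Greenstein deflection
      double ct;
      if (g == 0.0) ct = 2.0 * unif_rand() - 1.0;
      else {
        double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
        ct = (1.0 + g * g - f * f) / (2.0 * g);
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      }
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double ph = 2.0 * M_PI * unif_rand();
      double cp = std::cos(ph), sp = std::sin(ph);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0.0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nux = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double nuy = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nuz = -den * st * cp + uz * ct;
        double norm = std::sqrt(nux * nux + nuy * nuy + nuz * nuz);
        ux = nux / norm; uy = nuy / norm; uz = nuz / norm;
      }

      // Russian roulette
      if (w < roulette_threshold) {
        if (unif_rand() < 1.0 / roulette_factor) {
          gained += w * (roulette_factor - 1.0);
          w *= roulette_factor;
        } else {
          killed += w;
          alive = false;
        }
      }
    }
  }

  return List::create(
    _["ss"] = ss, _["td"] = td,
    _["deposited"] = dep, _["escaped_top"] = esc_top,
    _["escaped_bottom"] = esc_bot, _["killed"] = killed, _["gained"] = gained);
}

// Empirical check helper: sample n Henyey-Greenstein deflection cosines.
// [[Rcpp::export(name = ".mc_sample_hg_cpp")]]
NumericVector mc_sample_hg_cpp(int n, double g) {
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (g == 0.0) out[i] = 2.0 * unif_rand() - 1.0;
    else {
      double f = (1.0 - g * g) / (1.0 - g + 2.0 * g * unif_rand());
      double ct = (1.0 + g * g - f * f) / (2.0 * g);
      out[i] = std::max(-1.0, std::min(1.0, ct));
    }
  }
  return out;
}
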