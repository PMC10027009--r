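#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Photon random walk in a three-layer slab (epidermis / upper dermis /
// semi-infinite lower dermis) in reflection geometry. Transport uses a
// Henyey-Greenstein phase function with configurable anisotropy g_t and the
// scattering coefficient mus_t = musp / (1 - g_t) (similarity-preserving;
// g_t = 0 gives isotropic transport at the reduced scattering coefficient).
// Absorption is NOT applied during transport - it is added afterwards per
// model via Beer-Lambert on the stored per-layer path lengths. The
// tissue-air boundary at z = 0 applies unpolarized Fresnel reflection
// (n_tissue / n_outside); internal boundaries are index matched and only
// matter for path-length bookkeeping. Every photon transmitted through the
// surface is detected (wide-field imaging of diffuse reflectance). Detected
// photons are accumulated into a joint 3-D histogram over
// (l_epi, l_dermis_upper, l_dermis_lower).

static inline int bin_of(double l, const NumericVector &edges) {
  // edges[0] = 0; bin i covers [edges[i], edges[i+1]); overflow clamps.
  int n = edges.size() - 1;
  if (l <= edges[0]) return 0;
  if (l >= edges[n]) return n - 1;
  int lo = 0, hi = n; // find i with edges[i] <= l < edges[i+1]
  while (hi - lo > 1) {
    int mid = (lo + hi) / 2;
    if (edges[mid] <= l) lo = mid; else hi = mid;
  }
  return lo;
}

static inline double fresnel_R(double ci, double n_rel) {
  // unpolarized Fresnel reflectance, incidence cosine ci inside the tissue,
  // n_rel = n_tissue / n_outside > 1
  double si = std::sqrt(std::max(0.0, 1.0 - ci * ci));
  double st = n_rel * si;             // Snell: n_in sin(i) = n_out sin(t)
  if (st >= 1.0) return 1.0;          // total internal reflection
  double ct = std::sqrt(1.0 - st * st);
  double rs = (n_rel * ci - ct) / (n_rel * ci + ct);
  double rp = (n_rel * ct - ci) / (n_rel * ct + ci);
  return 0.5 * (rs * rs + rp * rp);
}

// [[Rcpp::export]]
List mc_layer_slab(double t_epi, double t_dermis_upper, double musp,
                   int n_photons, double n_rel, double g_t,
                   NumericVector edges1, NumericVector edges2,
                   NumericVector edges3,
                   double z_max, double l_total_max) {
  const int nb1 = edges1.size() - 1, nb2 = edges2.size() - 1,
            nb3 = edges3.size() - 1;
  NumericVector counts(nb1 * nb2 * nb3);
  const double mus_t = musp / (1.0 - g_t);   // similarity-preserving
  const double mfp = 1.0 / mus_t;
  const double z1 = t_epi, z2 = t_epi + t_dermis_upper;
  double n_detected = 0, n_deep = 0, n_killed = 0;
  double sum_l1 = 0, sum_l2 = 0, sum_l3 = 0;

  for (int ip = 0; ip < n_photons; ip++) {
    double z = 0.0;
    double ux = 0.0, uy = 0.0, uz = 1.0;   // launched normally into tissue
    double l1 = 0, l2 = 0, l3 = 0, ltot = 0;
    bool alive = true, detected = false;

    while (alive) {
      double step = -std::log(unif_rand()) * mfp;
      while (step > 0) {
        // distance to surface along current direction (only z = 0 is optical)
        double d_surf = (uz < 0) ? (z / (-uz)) : R_PosInf;
        double seg = std::min(step, d_surf);
        double z_new = z + seg * uz;
        // split segment across layer boundaries by z-overlap
        double zlo = std::min(z, z_new), zhi = std::max(z, z_new);
        double dz = zhi - zlo;
        if (dz < 1e-12) {
          if (z < z1) l1 += seg; else if (z < z2) l2 += seg; else l3 += seg;
        } else {
          double f1 = std::max(0.0, std::min(zhi, z1) - zlo) / dz;
          double f2 = std::max(0.0, std::min(zhi, z2) - std::max(zlo, z1)) / dz;
          double f3 = std::max(0.0, zhi - std::max(zlo, z2)) / dz;
          l1 += seg * f1; l2 += seg * f2; l3 += seg * f3;
        }
        ltot += seg;
        z = z_new;
        step -= seg;

        if (z <= 1e-12 && uz < 0) {
          double R = fresnel_R(-uz, n_rel);
          if (unif_rand() < R) {
            z = 0.0; uz = -uz;       // internally reflected, finish the step
          } else {
            detected = true; alive = false; step = 0;
          }
        }
        if (alive && (z > z_max || ltot > l_total_max)) {
          alive = false; step = 0;
          if (z > z_max) n_deep += 1; else n_killed += 1;
        }
      }
      if (!alive) break;
      // scatter: Henyey-Greenstein polar angle (isotropic for g_t = 0)
      double ct;
      if (g_t > 1e-9) {
        double tmp = (1.0 - g_t * g_t) / (1.0 - g_t + 2.0 * g_t * unif_rand());
        ct = (1.0 + g_t * g_t - tmp * tmp) / (2.0 * g_t);
        if (ct > 1.0) ct = 1.0; else if (ct < -1.0) ct = -1.0;
      } else {
        ct = 2.0 * unif_rand() - 1.0;
      }
      double st = std::sqrt(std::max(0.0, 1.0 - ct * ct));
      double phi = 2.0 * M_PI * unif_rand();
      double cp = std::cos(phi), sp = std::sin(phi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp; uy = st * sp; uz = ct * (uz >= 0 ? 1.0 : -1.0);
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nx = (st * (ux * uz * cp - uy * sp)) / den + ux * ct;
        double ny = (st * (uy * uz * cp + ux * sp)) / den + uy * ct;
        double nz = -den * st * cp + uz * ct;
        double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
        ux = nx / norm; uy = ny / norm; uz = nz / norm;
      }
    }

    if (detected) {
      n_detected += 1;
      sum_l1 += l1; sum_l2 += l2; sum_l3 += l3;
      int i = bin_of(l1, edges1), j = bin_of(l2, edges2), k = bin_of(l3, edges3);
      counts[i + nb1 * (j + nb2 * k)] += 1.0;
    }
  }

  counts.attr("dim") = IntegerVector::create(nb1, nb2, nb3);
  return List::create(
    _["counts"] = counts,
    _["n_detected"] = n_detected,
    _["n_deep"] = n_deep,
    _["n_killed"] = n_killed,
    _["mean_l"] = NumericVector::create(
        sum_l1 / std::max(1.0, n_detected),
        sum_l2 / std::max(1.0, n_detected),
        sum_l3 / std::max(1.0, n_detected)));
}
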