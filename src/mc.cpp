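// Photon transport for a single fiber in contact with a semi-infinite
// scattering medium (no absorption). The fiber face is a disk of radius
// `radius` centred at the origin in the z = 0 plane; the medium occupies
// z > 0. Photons are launched uniformly over the disk into the acceptance
// cone and are detected if they return to the disk within the acceptance
// angle and survive Fresnel transmission into the fiber.

#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

namespace {

// xoshiro256++, seeded through splitmix64: bit-reproducible for a given
// seed, independent of R's RNG state
struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  inline double uniform() {  // in [0, 1)
    return (next() >> 11) * 0x1.0p-53;
  }
};

inline double fresnel_R(double cosi, double n1, double n2) {
  double sini2 = 1.0 - cosi * cosi;
  double sint2 = (n1 / n2) * (n1 / n2) * sini2;
  if (sint2 >= 1.0) return 1.0;  // total internal reflection
  double cost = std::sqrt(1.0 - sint2);
  double rs = (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost);
  double rp = (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi);
  return 0.5 * (rs * rs + rp * rp);
}

}  // namespace

// theta_table: equiprobable inverse-CDF table of the polar scattering angle
// launch_mode: 0 = polar angle uniform on [0, theta_acc],
//              1 = uniform over the solid angle of the acceptance cone
// [[Rcpp::export(name = ".mc_run")]]
List mc_run_cpp(double n_photons, double mus, double radius,
                double theta_acc, double n_sample, double n_fiber,
                double n_external, NumericVector theta_table,
                double termination, int launch_mode, double seed) {
  const long n = (long)n_photons;
  const int M = theta_table.size() - 1;
  const double *tt = REAL(theta_table);
  const double cos_acc = std::cos(theta_acc);
  const double r2max = radius * radius;
  const double T2 = termination * termination;
  const double crit_ext = n_external / n_sample;  // sin of TIR angle, if < 1

  Xoshiro rng((uint64_t)seed);

  long n_detected = 0, n_escaped = 0, n_terminated = 0;
  std::vector<int> det_nscatter, det_nback;
  std::vector<double> det_path, det_maxdist;
  std::vector<double> hist(180, 0.0);
  int phist[180];

  for (long ip = 0; ip < n; ++ip) {
    // launch position uniform over the source disk
    double rr = radius * std::sqrt(rng.uniform());
    double phi = 2.0 * M_PI * rng.uniform();
    double x = rr * std::cos(phi), y = rr * std::sin(phi), z = 0.0;
    // launch direction inside the acceptance cone, pointing into the medium
    double th0;
    if (launch_mode == 0) {
      th0 = theta_acc * rng.uniform();
    } else {
      th0 = std::acos(1.0 - rng.uniform() * (1.0 - cos_acc));
    }
    double ps0 = 2.0 * M_PI * rng.uniform();
    double st0 = std::sin(th0);
    double ux = st0 * std::cos(ps0), uy = st0 * std::sin(ps0);
    double uz = std::cos(th0);

    std::memset(phist, 0, sizeof(phist));
    int nscatter = 0, nback = 0;
    double path = 0.0, maxd2 = rr * rr;
    int fate = -1;  // 0 detected, 1 escaped, 2 terminated

    double s = -std::log(1.0 - rng.uniform()) / mus;
    while (fate < 0) {
      // handle surface crossings within the current step
      while (uz < 0.0 && z + s * uz < 0.0) {
        double sb = z / (-uz);
        x += sb * ux;
        y += sb * uy;
        z = 0.0;
        path += sb;
        s -= sb;
        double rho2 = x * x + y * y;
        if (rho2 > maxd2) maxd2 = rho2;
        double cosi = -uz;
        if (rho2 <= r2max) {  // tissue -> fiber face
          double R = fresnel_R(cosi, n_sample, n_fiber);
          if (rng.uniform() >= R) {
            fate = (cosi >= cos_acc) ? 0 : 1;
            break;
          }
        } else {  // tissue -> external medium
          double sini = std::sqrt(1.0 - cosi * cosi);
          double R = (crit_ext < 1.0 && sini >= crit_ext)
                         ? 1.0
                         : fresnel_R(cosi, n_sample, n_external);
          if (rng.uniform() >= R) {
            fate = 1;
            break;
          }
        }
        uz = -uz;  // internally reflected, continue with remaining step
      }
      if (fate >= 0) break;

      x += s * ux;
      y += s * uy;
      z += s * uz;
      path += s;
      double d2 = x * x + y * y + z * z;
      if (d2 > maxd2) maxd2 = d2;
      if (d2 > T2) {
        fate = 2;
        break;
      }

      // scatter: draw polar angle from the tabulated inverse CDF
      double u = rng.uniform() * M;
      int i = (int)u;
      if (i >= M) i = M - 1;
      double frac = u - i;
      double theta = tt[i] * (1.0 - frac) + tt[i + 1] * frac;
      ++nscatter;
      if (theta > M_PI_2) ++nback;
      int bin = (int)(theta * (180.0 / M_PI));
      if (bin > 179) bin = 179;
      ++phist[bin];

      double ct = std::cos(theta), st = std::sin(theta);
      double psi = 2.0 * M_PI * rng.uniform();
      double cp = std::cos(psi), sp = std::sin(psi);
      if (std::fabs(uz) > 0.99999) {
        ux = st * cp;
        uy = st * sp;
        uz = (uz >= 0.0) ? ct : -ct;
      } else {
        double den = std::sqrt(1.0 - uz * uz);
        double nx = st * (ux * uz * cp - uy * sp) / den + ux * ct;
        double ny = st * (uy * uz * cp + ux * sp) / den + uy * ct;
        double nz = -st * cp * den + uz * ct;
        double norm = std::sqrt(nx * nx + ny * ny + nz * nz);
        ux = nx / norm;
        uy = ny / norm;
        uz = nz / norm;
      }
      s = -std::log(1.0 - rng.uniform()) / mus;
    }

    if (fate == 0) {
      ++n_detected;
      det_nscatter.push_back(nscatter);
      det_nback.push_back(nback);
      det_path.push_back(path);
      det_maxdist.push_back(std::sqrt(maxd2));
      for (int b = 0; b < 180; ++b) hist[b] += phist[b];
    } else if (fate == 1) {
      ++n_escaped;
    } else {
      ++n_terminated;
    }
  }

  return List::create(
      _["n_launched"] = (double)n, _["n_detected"] = (double)n_detected,
      _["n_escaped"] = (double)n_escaped,
      _["n_terminated"] = (double)n_terminated,
      _["det_nscatter"] = IntegerVector(det_nscatter.begin(),
                                        det_nscatter.end()),
      _["det_nback"] = IntegerVector(det_nback.begin(), det_nback.end()),
      _["det_path"] = NumericVector(det_path.begin(), det_path.end()),
      _["det_maxdist"] = NumericVector(det_maxdist.begin(),
                                       det_maxdist.end()),
      _["angle_hist"] = NumericVector(hist.begin(), hist.end()));
}
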