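// Lattice gradient ("Perlin") noise in 3D.
//
// Gradients are derived from a counter-based hash of (seed, lattice node), so
// fields are pure functions of (seed, coordinates): slabs generated with a
// coordinate offset tile seamlessly, which is what lets phantom assembly work
// one z-slab at a time.

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

static inline uint64_t hash_node(uint64_t seed, int64_t xi, int64_t yi, int64_t zi) {
  uint64_t h = splitmix64(seed ^ 0xA24BAED4963EE407ULL);
  h = splitmix64(h ^ (uint64_t)xi);
  h = splitmix64(h ^ (uint64_t)yi);
  h = splitmix64(h ^ (uint64_t)zi);
  return h;
}

// uniform in [0,1) from the top 53 bits
static inline double u01(uint64_t h) {
  return (double)(h >> 11) * (1.0 / 9007199254740992.0);
}

// Seeded table of random unit gradients, uniform on the sphere. Lattice
// nodes index the table through the coordinate hash, so gradients stay a
// pure function of (seed, node) at a fraction of the per-corner trig cost.
#define GRAD_TABLE_SIZE 4096
struct GradTable {
  double g[GRAD_TABLE_SIZE][3];
  explicit GradTable(uint64_t seed) {
    uint64_t s = splitmix64(seed ^ 0x1C69B3F74AC4DB31ULL);
    for (int i = 0; i < GRAD_TABLE_SIZE; ++i) {
      s = splitmix64(s);
      double z = 2.0 * u01(s) - 1.0;
      uint64_t s2 = splitmix64(s ^ 0x632BE59BD9B4E019ULL);
      double phi = 6.283185307179586476925287 * u01(s2);
      double r = std::sqrt(std::max(0.0, 1.0 - z * z));
      g[i][0] = r * std::cos(phi);
      g[i][1] = r * std::sin(phi);
      g[i][2] = z;
    }
  }
};

// quintic fade 6t^5 - 15t^4 + 10t^3
static inline double fade(double t) { return t * t * t * (t * (t * 6.0 - 15.0) + 10.0); }

static double perlin_at(double x, double y, double z, uint64_t seed,
                        const GradTable& tab) {
  double fx = std::floor(x), fy = std::floor(y), fz = std::floor(z);
  int64_t x0 = (int64_t)fx, y0 = (int64_t)fy, z0 = (int64_t)fz;
  double dx = x - fx, dy = y - fy, dz = z - fz;
  double u = fade(dx), v = fade(dy), w = fade(dz);

  double c[8];
  int idx = 0;
  for (int k = 0; k <= 1; ++k)
    for (int j = 0; j <= 1; ++j)
      for (int i = 0; i <= 1; ++i) {
        const double* g = tab.g[hash_node(seed, x0 + i, y0 + j, z0 + k) &
                                (GRAD_TABLE_SIZE - 1)];
        c[idx++] = g[0] * (dx - i) + g[1] * (dy - j) + g[2] * (dz - k);
      }

  double x00 = c[0] + u * (c[1] - c[0]);
  double x10 = c[2] + u * (c[3] - c[2]);
  double x01 = c[4] + u * (c[5] - c[4]);
  double x11 = c[6] + u * (c[7] - c[6]);
  double y0v = x00 + v * (x10 - x00);
  double y1v = x01 + v * (x11 - x01);
  return y0v + w * (y1v - y0v);
}

static inline uint64_t octave_seed(double seed, int octave) {
  return splitmix64((uint64_t)(int64_t)seed + 0x9E3779B97F4A7C15ULL * (uint64_t)(octave + 1));
}

// [[Rcpp::export]]
NumericVector perlin_grid_cpp(IntegerVector dims, NumericVector offset,
                              double scale, double seed) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx <= 0 || ny <= 0 || nz <= 0) stop("all grid dimensions must be positive");
  uint64_t s = octave_seed(seed, 0);
  GradTable tab(s);
  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k) {
    double z = (offset[2] + k) * scale;
    for (int j = 0; j < ny; ++j) {
      double y = (offset[1] + j) * scale;
      for (int i = 0; i < nx; ++i) {
        double x = (offset[0] + i) * scale;
        out[p++] = perlin_at(x, y, z, s, tab);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector fractal_grid_cpp(IntegerVector dims, NumericVector offset,
                               double scale, int octaves, double lacunarity,
                               double persistence, double seed) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx <= 0 || ny <= 0 || nz <= 0) stop("all grid dimensions must be positive");
  std::vector<uint64_t> seeds(octaves);
  std::vector<double> freq(octaves), amp(octaves);
  std::vector<GradTable> tabs;
  tabs.reserve(octaves);
  for (int o = 0; o < octaves; ++o) {
    seeds[o] = octave_seed(seed, o);
    freq[o] = scale * std::pow(lacunarity, o);
    amp[o] = std::pow(persistence, o);
    tabs.emplace_back(seeds[o]);
  }
  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int o = 0; o < octaves; ++o) {
          acc += amp[o] * perlin_at((offset[0] + i) * freq[o],
                                    (offset[1] + j) * freq[o],
                                    (offset[2] + k) * freq[o], seeds[o],
                                    tabs[o]);
        }
        out[p++] = acc;
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector fractal_points_cpp(NumericVector x, NumericVector y, NumericVector z,
                                 int octaves, double lacunarity, double persistence,
                                 double seed) {
  R_xlen_t n = x.size();
  if (y.size() != n || z.size() != n) stop("coordinate vectors must have equal length");
  std::vector<uint64_t> seeds(octaves);
  std::vector<double> freq(octaves), amp(octaves);
  std::vector<GradTable> tabs;
  tabs.reserve(octaves);
  for (int o = 0; o < octaves; ++o) {
    seeds[o] = octave_seed(seed, o);
    freq[o] = std::pow(lacunarity, o);
    amp[o] = std::pow(persistence, o);
    tabs.emplace_back(seeds[o]);
  }
  NumericVector out(n);
  for (R_xlen_t p = 0; p < n; ++p) {
    double acc = 0.0;
    for (int o = 0; o < octaves; ++o)
      acc += amp[o] * perlin_at(x[p] * freq[o], y[p] * freq[o], z[p] * freq[o], seeds[o], tabs[o]);
    out[p] = acc;
  }
  return out;
}
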