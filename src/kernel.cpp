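// Photon-transport kernel: quadric CSG tracking, Klein-Nishina sampling,
// and the Monte Carlo history loop with per-history counter-based RNG
// streams (results independent of how histories are partitioned).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

static const double NUDGE = 1e-6;      // cm advanced past a crossed surface
static const double TMIN = 1e-9;       // smallest accepted crossing distance
static const double ELECTRON_REST = 0.511;
static const double PAIR_THRESHOLD = 1.022;

// ---------------------------------------------------------------- RNG ------
// splitmix64; one independent stream per (seed, history index).
struct Rng {
  uint64_t s;
  explicit Rng(uint64_t state) : s(state) {}
  uint64_t next_u64() {
    s += 0x9E3779B97F4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double uniform() { return (next_u64() >> 11) * (1.0 / 9007199254740992.0); }
};

static uint64_t mix64(uint64_t x) {
  x ^= x >> 33; x *= 0xFF51AFD7ED558CCDULL;
  x ^= x >> 33; x *= 0xC4CEB9FE1A85EC53ULL;
  x ^= x >> 33; return x;
}

static Rng history_rng(uint64_t seed, uint64_t hist) {
  return Rng(mix64(seed * 0x9E3779B97F4A7C15ULL + (hist + 1) *
                   0xBF58476D1CE4E5B9ULL));
}

// ----------------------------------------------------------- geometry ------
struct Geom {
  const double* coef;   // ns x 10, column-major from R
  int ns;
  const int* tokens;
  const int* off;
  const int* len;
  int ncell;
  int world;
};

static inline double quadric(const Geom& g, int s, const double* p) {
  const double* c = g.coef;
  int n = g.ns;
  double x = p[0], y = p[1], z = p[2];
  return c[s] * x * x + c[s + n] * y * y + c[s + 2 * n] * z * z +
         c[s + 3 * n] * x * y + c[s + 4 * n] * y * z + c[s + 5 * n] * z * x +
         c[s + 6 * n] * x + c[s + 7 * n] * y + c[s + 8 * n] * z + c[s + 9 * n];
}

// Evaluate one cell's postfix expression given per-surface senses.
static bool cell_contains(const Geom& g, int cell, const std::vector<char>& pos) {
  bool stack[128];
  int sp = 0;
  const int* t = g.tokens + g.off[cell];
  int m = g.len[cell];
  for (int i = 0; i < m; ++i) {
    int tk = t[i];
    if (tk >= 1) {
      int si = (tk - 1) >> 1;
      bool want_pos = (tk - 1) & 1;
      stack[sp++] = (pos[si] != 0) == want_pos;
    } else if (tk == -1) { --sp; stack[sp - 1] = stack[sp - 1] && stack[sp]; }
    else if (tk == -2) { --sp; stack[sp - 1] = stack[sp - 1] || stack[sp]; }
    else { stack[sp - 1] = !stack[sp - 1]; }
  }
  return stack[0];
}

static void surface_senses(const Geom& g, const double* p, std::vector<char>& pos) {
  for (int s = 0; s < g.ns; ++s) pos[s] = quadric(g, s, p) >= 0 ? 1 : 0;
}

// First-match locate; -1 if nothing matches.
static int locate(const Geom& g, const double* p, std::vector<char>& scratch) {
  surface_senses(g, p, scratch);
  for (int c = 0; c < g.ncell; ++c)
    if (cell_contains(g, c, scratch)) return c;
  return -1;
}

// Smallest positive crossing distance out of `cell` along u; returns
// surface index or -1 (unbounded: distance = +inf).
static double boundary_distance(const Geom& g, int cell, const double* p,
                                const double* u, int* surf_out) {
  const double* c = g.coef;
  int n = g.ns;
  double best = R_PosInf;
  int best_s = -1;
  const int* t = g.tokens + g.off[cell];
  int m = g.len[cell];
  // visit each referenced surface once (duplicates are cheap enough to skip
  // via a small linear check)
  for (int i = 0; i < m; ++i) {
    int tk = t[i];
    if (tk < 1) continue;
    int s = (tk - 1) >> 1;
    bool seen = false;
    for (int j = 0; j < i; ++j)
      if (t[j] >= 1 && ((t[j] - 1) >> 1) == s) { seen = true; break; }
    if (seen) continue;
    double A = c[s], B = c[s + n], C = c[s + 2 * n], D = c[s + 3 * n],
           E = c[s + 4 * n], F = c[s + 5 * n], G = c[s + 6 * n],
           H = c[s + 7 * n], I = c[s + 8 * n];
    double x = p[0], y = p[1], z = p[2];
    double ux = u[0], uy = u[1], uz = u[2];
    double qa = A * ux * ux + B * uy * uy + C * uz * uz + D * ux * uy +
                E * uy * uz + F * uz * ux;
    double qb = 2.0 * (A * x * ux + B * y * uy + C * z * uz) +
                D * (x * uy + y * ux) + E * (y * uz + z * uy) +
                F * (z * ux + x * uz) + G * ux + H * uy + I * uz;
    double qc = quadric(g, s, p);
    double t1 = -1.0, t2 = -1.0;
    if (std::fabs(qa) < 1e-30) {
      if (std::fabs(qb) > 1e-30) t1 = -qc / qb;
    } else {
      double disc = qb * qb - 4.0 * qa * qc;
      if (disc >= 0.0) {
        double sq = std::sqrt(disc);
        double q = (qb >= 0.0) ? -0.5 * (qb + sq) : -0.5 * (qb - sq);
        t1 = q / qa;
        if (std::fabs(q) > 1e-300) t2 = qc / q;
      }
    }
    if (t1 > TMIN && t1 < best) { best = t1; best_s = s; }
    if (t2 > TMIN && t2 < best) { best = t2; best_s = s; }
  }
  *surf_out = best_s;
  return best;
}

static Geom make_geom(const NumericMatrix& surf, const IntegerVector& tokens,
                      const IntegerVector& off, const IntegerVector& len,
                      int world) {
  Geom g;
  g.coef = surf.begin();
  g.ns = surf.nrow();
  g.tokens = tokens.begin();
  g.off = off.begin();
  g.len = len.begin();
  g.ncell = off.size();
  g.world = world;
  return g;
}

// [[Rcpp::export]]
List cpp_locate_points(NumericMatrix surf, IntegerVector tokens,
                       IntegerVector off, IntegerVector len,
                       NumericMatrix pts, bool full_audit) {
  Geom g = make_geom(surf, tokens, off, len, -1);
  int np = pts.nrow();
  IntegerVector nmatch(np), first(np), second(np);
  std::vector<char> pos(g.ns);
  double p[3];
  for (int i = 0; i < np; ++i) {
    p[0] = pts(i, 0); p[1] = pts(i, 1); p[2] = pts(i, 2);
    surface_senses(g, p, pos);
    int cnt = 0, f = -1, s2 = -1;
    for (int c = 0; c < g.ncell; ++c) {
      if (cell_contains(g, c, pos)) {
        if (cnt == 0) f = c; else if (cnt == 1) s2 = c;
        ++cnt;
        if (!full_audit) break;
      }
    }
    nmatch[i] = cnt; first[i] = f; second[i] = s2;
  }
  return List::create(_["n_matches"] = nmatch, _["first"] = first,
                      _["second"] = second);
}

// [[Rcpp::export]]
List cpp_distance_to_boundary(NumericMatrix surf, IntegerVector tokens,
                              IntegerVector off, IntegerVector len,
                              int cell, NumericVector p, NumericVector u) {
  Geom g = make_geom(surf, tokens, off, len, -1);
  int s = -1;
  double d = boundary_distance(g, cell, p.begin(), u.begin(), &s);
  return List::create(_["distance"] = d, _["surface"] = s);
}

// [[Rcpp::export]]
List cpp_ray_trace(NumericMatrix surf, IntegerVector tokens,
                   IntegerVector off, IntegerVector len, int world,
                   NumericVector p0, NumericVector u, int max_segments) {
  Geom g = make_geom(surf, tokens, off, len, world);
  std::vector<char> pos(g.ns);
  double p[3] = {p0[0], p0[1], p0[2]};
  std::vector<int> cells;
  std::vector<double> lens;
  int cell = locate(g, p, pos);
  int status = 0;
  for (int seg = 0; ; ++seg) {
    if (seg >= max_segments) { status = 1; break; }
    if (cell < 0) { status = 2; break; }
    int s;
    double d = boundary_distance(g, cell, p, u.begin(), &s);
    if (!R_FINITE(d)) {
      if (cell != world) status = 2;
      break;   // escaped to unbounded space
    }
    cells.push_back(cell);
    lens.push_back(d);
    p[0] += u[0] * (d + NUDGE);
    p[1] += u[1] * (d + NUDGE);
    p[2] += u[2] * (d + NUDGE);
    cell = locate(g, p, pos);
  }
  return List::create(_["status"] = status,
                      _["cell"] = IntegerVector(cells.begin(), cells.end()),
                      _["length"] = NumericVector(lens.begin(), lens.end()));
}

// ------------------------------------------------------------ physics ------
struct Phys {
  double loge0, dloge;
  int ne, nmat;
  const double* mu_pe;    // nmat x ne
  const double* mu_inc;
  const double* mu_pair;
  const double* kappa;    // heating response MeV * cm^-1
};

static inline void interp_mu(const Phys& ph, int mat, double E,
                             double* pe, double* inc, double* pr, double* kap) {
  double fi = (std::log(E) - ph.loge0) / ph.dloge;
  if (fi < 0) fi = 0;
  if (fi > ph.ne - 1.000001) fi = ph.ne - 1.000001;
  int i = (int)fi;
  double f = fi - i;
  int a = mat + ph.nmat * i, b = mat + ph.nmat * (i + 1);
  *pe  = ph.mu_pe[a]  + f * (ph.mu_pe[b]  - ph.mu_pe[a]);
  *inc = ph.mu_inc[a] + f * (ph.mu_inc[b] - ph.mu_inc[a]);
  *pr  = ph.mu_pair[a] + f * (ph.mu_pair[b] - ph.mu_pair[a]);
  *kap = ph.kappa[a]  + f * (ph.kappa[b]  - ph.kappa[a]);
}

// Klein-Nishina rejection sampler: returns scattering cosine.
// Envelope: f(mu) = r^3 + r - r^2 (1 - mu^2) <= 2, r = E'/E.
static double kn_sample_mu(double E, Rng& rng) {
  double k = E / ELECTRON_REST;
  for (;;) {
    double mu = 2.0 * rng.uniform() - 1.0;
    double r = 1.0 / (1.0 + k * (1.0 - mu));
    double f = r * r * r + r - r * r * (1.0 - mu * mu);
    if (2.0 * rng.uniform() <= f) return mu;
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_kn_sample(double E, int n, double seed) {
  NumericMatrix out(n, 2);
  Rng rng = history_rng((uint64_t)seed, 0);
  double k = E / ELECTRON_REST;
  for (int i = 0; i < n; ++i) {
    double mu = kn_sample_mu(E, rng);
    out(i, 0) = E / (1.0 + k * (1.0 - mu));
    out(i, 1) = mu;
  }
  return out;
}

// Rotate direction d by polar cosine mu_s and azimuth phi about itself.
static void rotate_direction(double* d, double mu_s, double phi) {
  double sin_t = std::sqrt(std::max(0.0, 1.0 - mu_s * mu_s));
  double cphi = std::cos(phi), sphi = std::sin(phi);
  double ux = d[0], uy = d[1], uz = d[2];
  double a = std::sqrt(std::max(1e-30, 1.0 - uz * uz));
  double nx, ny, nz;
  if (a > 1e-10) {
    nx = ux * uz / a * cphi - uy / a * sphi;
    ny = uy * uz / a * cphi + ux / a * sphi;
    nz = -a * cphi;
  } else {            // beam along +-z: any transverse frame
    nx = cphi; ny = sphi; nz = 0.0;
  }
  d[0] = mu_s * ux + sin_t * nx;
  d[1] = mu_s * uy + sin_t * ny;
  d[2] = mu_s * uz + sin_t * nz;
  double norm = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
  d[0] /= norm; d[1] /= norm; d[2] /= norm;
}

static void isotropic_direction(double* d, Rng& rng) {
  double mu = 2.0 * rng.uniform() - 1.0;
  double phi = 2.0 * M_PI * rng.uniform();
  double s = std::sqrt(std::max(0.0, 1.0 - mu * mu));
  d[0] = s * std::cos(phi); d[1] = s * std::sin(phi); d[2] = mu;
}

struct Photon {
  double p[3], u[3], E, w;
  int ncoll;
  bool primary;
};

// ----------------------------------------------------------- run batch -----
// [[Rcpp::export]]
List cpp_run_batch(NumericMatrix surf, IntegerVector tokens,
                   IntegerVector off, IntegerVector len, int world,
                   IntegerVector cell_mat, NumericVector cell_mu_scale,
                   double loge0, double dloge,
                   NumericMatrix mu_pe, NumericMatrix mu_inc,
                   NumericMatrix mu_pair, NumericMatrix kappa,
                   int src_type, NumericVector src_pos, NumericVector src_axis,
                   double cos_half, int spec_mode, NumericVector spec_e,
                   NumericVector spec_cdf,
                   double cutoff, bool analog, double rr_threshold,
                   double rr_survival, int max_segments,
                   int spec_surf, NumericVector spec_edges,
                   double hist_start, int n_hist, double seed) {
  Geom g = make_geom(surf, tokens, off, len, world);
  Phys ph;
  ph.loge0 = loge0; ph.dloge = dloge;
  ph.ne = mu_pe.ncol(); ph.nmat = mu_pe.nrow();
  ph.mu_pe = mu_pe.begin(); ph.mu_inc = mu_inc.begin();
  ph.mu_pair = mu_pair.begin(); ph.kappa = kappa.begin();

  int nc = g.ncell;
  int nb = std::max(0, (int)spec_edges.size() - 1);
  std::vector<double> coll(nc, 0.0), coll2(nc, 0.0), tl(nc, 0.0),
      tl2(nc, 0.0), path(nc, 0.0), spec(nb, 0.0);
  std::vector<double> h_coll(nc), h_tl(nc), h_path(nc), h_spec(nb);
  std::vector<char> senses(g.ns);
  double emitted = 0.0, escaped = 0.0, rouletted = 0.0;
  int uncollided = 0, lost = 0, done = 0;

  std::vector<Photon> stack;
  stack.reserve(16);

  for (int h = 0; h < n_hist; ++h) {
    Rng rng = history_rng((uint64_t)seed, (uint64_t)(hist_start + h));
    std::fill(h_coll.begin(), h_coll.end(), 0.0);
    std::fill(h_tl.begin(), h_tl.end(), 0.0);
    std::fill(h_path.begin(), h_path.end(), 0.0);
    std::fill(h_spec.begin(), h_spec.end(), 0.0);
    double h_escaped = 0.0, h_rouletted = 0.0;
    int h_uncollided = 0;
    bool h_lost = false;

    // ---- emit primary
    Photon prim;
    prim.p[0] = src_pos[0]; prim.p[1] = src_pos[1]; prim.p[2] = src_pos[2];
    if (src_type == 0) {                     // isotropic point
      isotropic_direction(prim.u, rng);
    } else if (src_type == 1) {              // cone beam about axis
      double mu = 1.0 - rng.uniform() * (1.0 - cos_half);
      double phi = 2.0 * M_PI * rng.uniform();
      prim.u[0] = src_axis[0]; prim.u[1] = src_axis[1]; prim.u[2] = src_axis[2];
      rotate_direction(prim.u, mu, phi);
    } else {                                 // pencil beam
      prim.u[0] = src_axis[0]; prim.u[1] = src_axis[1]; prim.u[2] = src_axis[2];
    }
    { // sample energy
      double xi = rng.uniform();
      int nseg = spec_cdf.size();
      int lo = 0, hi = nseg - 1;
      while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (spec_cdf[mid] < xi) lo = mid + 1; else hi = mid;
      }
      if (spec_mode == 0) prim.E = spec_e[lo];
      else {  // histogram: spec_e are nseg+1 bin edges
        double f = rng.uniform();
        prim.E = spec_e[lo] + f * (spec_e[lo + 1] - spec_e[lo]);
      }
    }
    prim.w = 1.0; prim.ncoll = 0; prim.primary = true;
    double h_emitted = prim.E;
    stack.clear();
    stack.push_back(prim);

    // ---- transport
    while (!stack.empty() && !h_lost) {
      Photon ph_state = stack.back();
      stack.pop_back();
      double* p = ph_state.p;
      double* u = ph_state.u;
      int cell = locate(g, p, senses);
      int nseg = 0;
      while (!h_lost) {
        if (cell < 0) { h_lost = true; break; }
        if (cell == world) {
          h_escaped += ph_state.w * ph_state.E;
          if (ph_state.primary && ph_state.ncoll == 0) h_uncollided++;
          break;
        }
        if (++nseg > max_segments) { h_lost = true; break; }
        int mat = cell_mat[cell];
        double mpe = 0, minc = 0, mpr = 0, kap = 0, mtot = 0;
        if (mat >= 0) {
          interp_mu(ph, mat, ph_state.E, &mpe, &minc, &mpr, &kap);
          double sc = cell_mu_scale[cell];
          mpe *= sc; minc *= sc; mpr *= sc; kap *= sc;
          mtot = mpe + minc + mpr;
        }
        int csurf;
        double db = boundary_distance(g, cell, p, u, &csurf);
        double dc = (mtot > 0.0) ? -std::log(1.0 - rng.uniform()) / mtot
                                 : R_PosInf;
        if (!R_FINITE(db) && !R_FINITE(dc)) { h_lost = true; break; }
        double step = dc < db ? dc : db;
        h_tl[cell] += ph_state.w * step * kap;
        h_path[cell] += ph_state.w * step;

        if (dc < db) {
          // ---- collision
          p[0] += u[0] * dc; p[1] += u[1] * dc; p[2] += u[2] * dc;
          ph_state.ncoll++;
          if (analog) {
            double xi = rng.uniform() * mtot;
            if (xi < mpe) {                       // photoelectric
              h_coll[cell] += ph_state.w * ph_state.E;
              break;
            } else if (xi < mpe + minc) {         // Compton
              double mu_s = kn_sample_mu(ph_state.E, rng);
              double Ep = ph_state.E /
                (1.0 + ph_state.E / ELECTRON_REST * (1.0 - mu_s));
              h_coll[cell] += ph_state.w * (ph_state.E - Ep);
              ph_state.E = Ep;
              rotate_direction(u, mu_s, 2.0 * M_PI * rng.uniform());
            } else {                              // pair
              h_coll[cell] += ph_state.w * (ph_state.E - PAIR_THRESHOLD);
              Photon a = ph_state;
              a.E = ELECTRON_REST; a.ncoll = 1; a.primary = false;
              isotropic_direction(a.u, rng);
              Photon b = a;
              b.u[0] = -a.u[0]; b.u[1] = -a.u[1]; b.u[2] = -a.u[2];
              stack.push_back(a);
              stack.push_back(b);
              break;
            }
          } else {
            // implicit capture
            double fabsb = (mtot > 0.0) ? mpe / mtot : 0.0;
            h_coll[cell] += ph_state.w * fabsb * ph_state.E;
            ph_state.w *= (1.0 - fabsb);
            double scat = minc + mpr;
            if (scat <= 0.0 || ph_state.w <= 0.0) break;
            if (rng.uniform() * scat < minc) {
              double mu_s = kn_sample_mu(ph_state.E, rng);
              double Ep = ph_state.E /
                (1.0 + ph_state.E / ELECTRON_REST * (1.0 - mu_s));
              h_coll[cell] += ph_state.w * (ph_state.E - Ep);
              ph_state.E = Ep;
              rotate_direction(u, mu_s, 2.0 * M_PI * rng.uniform());
            } else {
              h_coll[cell] += ph_state.w * (ph_state.E - PAIR_THRESHOLD);
              Photon a = ph_state;
              a.E = ELECTRON_REST; a.ncoll = 1; a.primary = false;
              isotropic_direction(a.u, rng);
              Photon b = a;
              b.u[0] = -a.u[0]; b.u[1] = -a.u[1]; b.u[2] = -a.u[2];
              stack.push_back(a);
              stack.push_back(b);
              break;
            }
            // Russian roulette
            if (ph_state.w < rr_threshold) {
              if (rng.uniform() < ph_state.w / rr_survival) {
                ph_state.w = rr_survival;
              } else {
                h_rouletted += ph_state.w * ph_state.E;
                break;
              }
            }
          }
          if (ph_state.E <= cutoff) {     // local deposition below cutoff
            h_coll[cell] += ph_state.w * ph_state.E;
            break;
          }
        } else {
          // ---- boundary crossing
          if (csurf == spec_surf && nb > 0) {
            int bi = -1;
            for (int b = 0; b < nb; ++b)
              if (ph_state.E >= spec_edges[b] && ph_state.E < spec_edges[b + 1])
                { bi = b; break; }
            if (bi >= 0) h_spec[bi] += ph_state.w;
          }
          p[0] += u[0] * (db + NUDGE);
          p[1] += u[1] * (db + NUDGE);
          p[2] += u[2] * (db + NUDGE);
          cell = locate(g, p, senses);
        }
      }
    }

    if (h_lost) { lost++; continue; }
    done++;
    emitted += h_emitted;
    escaped += h_escaped;
    rouletted += h_rouletted;
    uncollided += h_uncollided;
    for (int c = 0; c < nc; ++c) {
      coll[c] += h_coll[c]; coll2[c] += h_coll[c] * h_coll[c];
      tl[c] += h_tl[c]; tl2[c] += h_tl[c] * h_tl[c];
      path[c] += h_path[c];
    }
    for (int b = 0; b < nb; ++b) spec[b] += h_spec[b];
  }

  return List::create(
    _["coll"] = NumericVector(coll.begin(), coll.end()),
    _["coll2"] = NumericVector(coll2.begin(), coll2.end()),
    _["tl"] = NumericVector(tl.begin(), tl.end()),
    _["tl2"] = NumericVector(tl2.begin(), tl2.end()),
    _["path"] = NumericVector(path.begin(), path.end()),
    _["spec_counts"] = NumericVector(spec.begin(), spec.end()),
    _["emitted"] = emitted, _["escaped"] = escaped,
    _["rouletted"] = rouletted, _["uncollided"] = uncollided,
    _["lost"] = lost, _["n_done"] = done);
}
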