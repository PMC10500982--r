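// Nonbonded energy kernels and Metropolis Monte Carlo sampler for small
// periodic solute/water toy systems.  Conventions follow CHARMM: LJ minima
// (r_min, epsilon) combined by Lorentz-Berthelot on (r_min/2, eps), potential
// (VSWI / OpenMM smoothstep) or force (VFSW, Steinbach-Brooks) switching
// between r_on and r_off, minimum-image cubic periodicity.
//
// Switch kinds: 0 = NONE (hard truncation), 1 = VSWI, 2 = OMM_VSWI, 3 = VFSW.
// Coupling modes: 0 = per-solute-atom charge/LJ scale factors (SAI states),
//                 1 = single-lambda separation-shifted soft-core path.

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const int SW_NONE = 0, SW_VSWI = 1, SW_OMM = 2, SW_VFSW = 3;

// potential-switch multiplier (VSWI / OMM smoothstep); 1 below r_on, 0 above r_off
static inline double pswitch(double r, double ron, double roff, int kind) {
  if (r >= roff) return 0.0;
  if (r <= ron) return 1.0;
  if (kind == SW_OMM) {
    double x = (r - ron) / (roff - ron);
    return 1.0 - x * x * x * (10.0 - 15.0 * x + 6.0 * x * x);
  }
  // CHARMM VSWI (also used as the Coulomb taper for VFSW runs)
  double r2 = r * r, ron2 = ron * ron, roff2 = roff * roff;
  double d = roff2 - ron2;
  double a = roff2 - r2;
  return a * a * (roff2 + 2.0 * r2 - 3.0 * ron2) / (d * d * d);
}

// plain LJ: U = eps[(rm/r)^12 - 2(rm/r)^6]
static inline double lj_plain(double r2, double rm, double eps) {
  if (eps == 0.0 || rm <= 0.0) return 0.0;
  double s = rm * rm / r2;
  double s6 = s * s * s;
  return eps * (s6 * s6 - 2.0 * s6);
}

// LJ with the configured cutoff treatment; cutoff=false means vacuum (plain)
static inline double lj_switched(double r2, double rm, double eps,
                                 double ron, double roff, int kind,
                                 bool cutoff) {
  if (eps == 0.0 || rm <= 0.0) return 0.0;
  if (!cutoff) return lj_plain(r2, rm, eps);
  double r = std::sqrt(r2);
  if (r >= roff) return 0.0;
  if (kind == SW_NONE) return lj_plain(r2, rm, eps);
  if (kind == SW_VFSW) {
    // Steinbach-Brooks force switch applied per inverse-power term:
    //   U = A r^-12 - B r^-6,  A = eps rm^12, B = 2 eps rm^6
    double rm2 = rm * rm;
    double rm6 = rm2 * rm2 * rm2;
    double A = eps * rm6 * rm6, B = 2.0 * eps * rm6;
    double ron3 = ron * ron * ron, roff3 = roff * roff * roff;
    double ron6 = ron3 * ron3, roff6 = roff3 * roff3;
    double r6 = r2 * r2 * r2;
    if (r <= ron) {
      // energy-shifted plain form; shift constant -(ron*roff)^{-p/2} per term
      double c12 = 1.0 / (ron6 * roff6);
      double c6 = 1.0 / (ron3 * roff3);
      return A * (1.0 / r6 / r6 - c12) - B * (1.0 / r6 - c6);
    }
    double a12 = roff6 / (roff6 - ron6);
    double a6 = roff3 / (roff3 - ron3);
    double d12 = 1.0 / r6 - 1.0 / roff6;
    double r3 = r * r2;
    double d6 = 1.0 / r3 - 1.0 / roff3;
    return A * a12 * d12 * d12 - B * a6 * d6 * d6;
  }
  return lj_plain(r2, rm, eps) * pswitch(r, ron, roff, kind);
}

// Coulomb taper: potential switch for all smooth kinds, step for NONE
static inline double coul_switched(double r, double ron, double roff, int kind,
                                   bool cutoff) {
  if (!cutoff) return 1.0;
  if (r >= roff) return 0.0;
  if (kind == SW_NONE) return 1.0;
  return pswitch(r, ron, roff, kind == SW_OMM ? SW_OMM : SW_VSWI);
}

struct Coupling {
  int mode;                    // 0 scaled, 1 softcore path
  std::vector<double> qs, ljs; // per-solute-atom factors (mode 0)
  double lambda, alpha;        // mode 1
};

struct System {
  std::vector<double> x, y, z, q, rmin, eps;
  int n, ns, nw; // sites, solute sites, waters (3 sites each)
  double box;
  bool periodic;
  std::vector<int> excl;                // ns*ns, 1 = excluded intra-solute pair
  std::vector<double> bi, bj, br0, bk;  // harmonic bonds (0-based indices)
  // nonbonded settings
  double ron, roff, kcoul;
  int kind;

  bool excluded(int i, int j) const { return excl[i * ns + j] != 0; }

  inline double dist2(int i, int j) const {
    double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
    if (periodic) {
      dx -= box * std::nearbyint(dx / box);
      dy -= box * std::nearbyint(dy / box);
      dz -= box * std::nearbyint(dz / box);
    }
    return dx * dx + dy * dy + dz * dz;
  }

  // nonbonded energy of pair (i, j) under the coupling; exclusions are the
  // caller's responsibility
  inline double pair_energy(int i, int j, const Coupling &cp) const {
    double r2 = dist2(i, j);
    // every interaction is tapered or truncated to zero at r_off
    if (periodic && r2 >= roff * roff) return 0.0;
    bool i_sol = i < ns, j_sol = j < ns;
    double e = 0.0;
    if (cp.mode == 0) {
      double si = i_sol ? cp.ljs[i] : 1.0, sj = j_sol ? cp.ljs[j] : 1.0;
      double rm = 0.5 * (rmin[i] * si + rmin[j] * sj);
      double ee = std::sqrt(eps[i] * si * eps[j] * sj);
      double qq = (i_sol ? q[i] * cp.qs[i] : q[i]) *
                  (j_sol ? q[j] * cp.qs[j] : q[j]);
      e = lj_switched(r2, rm, ee, ron, roff, kind, periodic);
      if (qq != 0.0) {
        double r = std::sqrt(r2);
        e += kcoul * qq / r * coul_switched(r, ron, roff, kind, periodic);
      }
    } else {
      double rm = 0.5 * (rmin[i] + rmin[j]);
      double ee = std::sqrt(eps[i] * eps[j]);
      double qq = q[i] * q[j];
      if (i_sol || j_sol) {
        double lam = 1.0 - cp.lambda;
        if (lam > 0.0) {
          double shift = cp.alpha * (1.0 - lam);
          double r = std::sqrt(r2);
          double sw = periodic
                          ? ((kind == SW_NONE) ? (r < roff ? 1.0 : 0.0)
                                               : pswitch(r, ron, roff,
                                                         kind == SW_OMM
                                                             ? SW_OMM
                                                             : SW_VSWI))
                          : 1.0;
          if (sw > 0.0) {
            e = lam * lj_plain(r2 + shift, rm, ee) * sw;
            if (qq != 0.0)
              e += lam * kcoul * qq / std::sqrt(r2 + shift) * sw;
          }
        }
      } else {
        e = lj_switched(r2, rm, ee, ron, roff, kind, periodic);
        if (qq != 0.0) {
          double r = std::sqrt(r2);
          e += kcoul * qq / r * coul_switched(r, ron, roff, kind, periodic);
        }
      }
    }
    return e;
  }

  // d/dlambda of pair (i, j) on the soft-core path (mode 1); zero for
  // solvent-solvent pairs
  inline double pair_dudl(int i, int j, const Coupling &cp) const {
    bool i_sol = i < ns, j_sol = j < ns;
    if (!i_sol && !j_sol) return 0.0;
    double r2 = dist2(i, j);
    if (periodic && r2 >= roff * roff) return 0.0;
    double lam = 1.0 - cp.lambda;
    double rm = 0.5 * (rmin[i] + rmin[j]);
    double ee = std::sqrt(eps[i] * eps[j]);
    double qq = q[i] * q[j];
    double shift = cp.alpha * (1.0 - lam);
    double y = r2 + shift;
    double r = std::sqrt(r2);
    double sw = periodic ? ((kind == SW_NONE)
                                ? (r < roff ? 1.0 : 0.0)
                                : pswitch(r, ron, roff,
                                          kind == SW_OMM ? SW_OMM : SW_VSWI))
                         : 1.0;
    if (sw == 0.0) return 0.0;
    // U(lam) = lam * g(r2 + alpha(1-lam)) * sw + lam * kq / sqrt(y) * sw
    // dU/dlambda = -dU/dlam
    double dudlam = 0.0;
    if (ee > 0.0 && rm > 0.0) {
      double rm2 = rm * rm;
      double s = rm2 / y;
      double s3 = s * s * s;
      double g = ee * (s3 * s3 - 2.0 * s3);
      double gp = 6.0 * ee * (s3 / y) * (1.0 - s3); // g'(y) = -6 eps (s6 - s3)/y
      // y = r2 + alpha*(1 - lam)  =>  dy/dlam = -alpha
      // d/dlam [lam g(y)] = g(y) + lam g'(y) dy/dlam = g - lam*alpha*g'
      dudlam += g - lam * cp.alpha * gp;
    }
    if (qq != 0.0) {
      double kq = kcoul * qq;
      // d/dlam [lam kq y^-1/2] = kq y^-1/2 + lam kq (-1/2) y^-3/2 (-alpha)
      dudlam += kq / std::sqrt(y) + lam * kq * 0.5 * cp.alpha / (y * std::sqrt(y));
    }
    return -dudlam * sw;
  }

  double bond_energy() const {
    double e = 0.0;
    for (size_t b = 0; b < bi.size(); ++b) {
      int i = (int)bi[b], j = (int)bj[b];
      double d = std::sqrt(dist2(i, j)) - br0[b];
      e += bk[b] * d * d;
    }
    return e;
  }

  double bond_energy_atom(int a) const {
    double e = 0.0;
    for (size_t b = 0; b < bi.size(); ++b) {
      int i = (int)bi[b], j = (int)bj[b];
      if (i != a && j != a) continue;
      double d = std::sqrt(dist2(i, j)) - br0[b];
      e += bk[b] * d * d;
    }
    return e;
  }

  inline int water_of(int site) const {
    return site < ns ? -1 : (site - ns) / 3;
  }

  // components: [0] solute-solvent, [1] intra-solute, [2] solvent-solvent
  void total_energy(const Coupling &cp, double comps[3]) const {
    comps[0] = comps[1] = comps[2] = 0.0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (i < ns && j < ns) {
          if (excluded(i, j)) continue;
          comps[1] += pair_energy(i, j, cp);
        } else if (i >= ns && j >= ns) {
          if (water_of(i) == water_of(j)) continue;
          comps[2] += pair_energy(i, j, cp);
        } else {
          comps[0] += pair_energy(i, j, cp);
        }
      }
    }
  }

  // interaction energy of solute atom a with everything else (+ its bonds)
  double atom_energy(int a, const Coupling &cp) const {
    double e = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == a) continue;
      if (j < ns && excluded(a, j)) continue;
      e += pair_energy(a, j, cp);
    }
    return e + bond_energy_atom(a);
  }

  // interaction energy of water w with everything outside w
  double water_energy(int w, const Coupling &cp) const {
    double e = 0.0;
    int s0 = ns + 3 * w;
    for (int k = 0; k < 3; ++k) {
      int i = s0 + k;
      for (int j = 0; j < n; ++j) {
        if (j >= s0 && j < s0 + 3) continue;
        e += pair_energy(i, j, cp);
      }
    }
    return e;
  }

  // solute-environment energy (solute-solvent + intra-solute), used for
  // rigid whole-solute moves where intra terms are invariant
  double solute_external_energy(const Coupling &cp) const {
    double e = 0.0;
    for (int i = 0; i < ns; ++i)
      for (int j = ns; j < n; ++j) e += pair_energy(i, j, cp);
    return e;
  }
};

static System make_system(const List &sys, const List &settings) {
  System S;
  NumericMatrix xyz = sys["coords"];
  NumericVector q = sys["q"], rmin = sys["rmin"], eps = sys["eps"];
  S.n = xyz.nrow();
  S.ns = as<int>(sys["ns"]);
  S.nw = as<int>(sys["nw"]);
  S.box = as<double>(sys["box"]);
  S.periodic = as<bool>(sys["periodic"]);
  S.x.resize(S.n); S.y.resize(S.n); S.z.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.x[i] = xyz(i, 0); S.y[i] = xyz(i, 1); S.z[i] = xyz(i, 2);
  }
  S.q = as<std::vector<double> >(q);
  S.rmin = as<std::vector<double> >(rmin);
  S.eps = as<std::vector<double> >(eps);
  IntegerMatrix ex = sys["excl"];
  S.excl.assign(S.ns * S.ns, 0);
  for (int i = 0; i < S.ns; ++i)
    for (int j = 0; j < S.ns; ++j) S.excl[i * S.ns + j] = ex(i, j);
  NumericMatrix bonds = sys["bonds"]; // i, j (0-based), r0, k
  for (int b = 0; b < bonds.nrow(); ++b) {
    S.bi.push_back(bonds(b, 0)); S.bj.push_back(bonds(b, 1));
    S.br0.push_back(bonds(b, 2)); S.bk.push_back(bonds(b, 3));
  }
  S.ron = as<double>(settings["r_on"]);
  S.roff = as<double>(settings["r_off"]);
  S.kind = as<int>(settings["kind"]);
  S.kcoul = as<double>(settings["kcoul"]);
  return S;
}

static Coupling make_coupling(const List &cp, int ns) {
  Coupling C;
  C.mode = as<int>(cp["mode"]);
  if (C.mode == 0) {
    C.qs = as<std::vector<double> >(cp["qs"]);
    C.ljs = as<std::vector<double> >(cp["ljs"]);
    if ((int)C.qs.size() != ns || (int)C.ljs.size() != ns)
      stop("coupling factor length does not match solute size");
    C.lambda = 0.0; C.alpha = 0.0;
  } else {
    C.lambda = as<double>(cp["lambda"]);
    C.alpha = as<double>(cp["alpha"]);
  }
  return C;
}

// [[Rcpp::export]]
NumericVector cpp_switch_factor(NumericVector r, double ron, double roff,
                                int kind) {
  int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = (kind == SW_NONE) ? (r[i] < roff ? 1.0 : 0.0)
                               : pswitch(r[i], ron, roff, kind);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_lj_energy(NumericVector r, double rmin, double eps,
                            double ron, double roff, int kind, bool cutoff) {
  int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = lj_switched(r[i] * r[i], rmin, eps, ron, roff, kind, cutoff);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_softcore_lj(NumericVector r, double lam, double rmin,
                              double eps, double alpha) {
  int n = r.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = lam * lj_plain(r[i] * r[i] + alpha * (1.0 - lam), rmin, eps);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_total_energy(List sys, List settings, List coupling) {
  System S = make_system(sys, settings);
  Coupling C = make_coupling(coupling, S.ns);
  double comps[3];
  S.total_energy(C, comps);
  double eb = S.bond_energy();
  NumericVector out = NumericVector::create(
      _["total"] = comps[0] + comps[1] + comps[2] + eb,
      _["solute_solvent"] = comps[0], _["intra_solute"] = comps[1],
      _["solvent_solvent"] = comps[2], _["bonded"] = eb);
  return out;
}

// Re-evaluate stored frames under K couplings.
// frames: numeric array dim (nframes, nsites, 3); boxes: per-frame box edge.
// [[Rcpp::export]]
NumericMatrix cpp_energy_frames(NumericVector frames, NumericVector boxes,
                                List sys, List settings, List couplings) {
  System S = make_system(sys, settings);
  IntegerVector dim = frames.attr("dim");
  int nf = dim[0], nsite = dim[1];
  if (nsite != S.n) stop("frame site count mismatch");
  int K = couplings.size();
  std::vector<Coupling> cps;
  for (int k = 0; k < K; ++k)
    cps.push_back(make_coupling(couplings[k], S.ns));
  NumericMatrix U(nf, K);
  for (int f = 0; f < nf; ++f) {
    for (int i = 0; i < nsite; ++i) {
      S.x[i] = frames[f + nf * i];
      S.y[i] = frames[f + nf * (i + nsite)];
      S.z[i] = frames[f + nf * (i + 2 * nsite)];
    }
    S.box = boxes[f];
    double eb = S.bond_energy();
    for (int k = 0; k < K; ++k) {
      double comps[3];
      S.total_energy(cps[k], comps);
      U(f, k) = comps[0] + comps[1] + comps[2] + eb;
    }
  }
  return U;
}

// Per-frame dU/dlambda on the soft-core path at a given lambda.
// [[Rcpp::export]]
NumericVector cpp_dudl_frames(NumericVector frames, NumericVector boxes,
                              List sys, List settings, double lambda,
                              double alpha) {
  System S = make_system(sys, settings);
  IntegerVector dim = frames.attr("dim");
  int nf = dim[0], nsite = dim[1];
  if (nsite != S.n) stop("frame site count mismatch");
  Coupling C; C.mode = 1; C.lambda = lambda; C.alpha = alpha;
  NumericVector out(nf);
  for (int f = 0; f < nf; ++f) {
    for (int i = 0; i < nsite; ++i) {
      S.x[i] = frames[f + nf * i];
      S.y[i] = frames[f + nf * (i + nsite)];
      S.z[i] = frames[f + nf * (i + 2 * nsite)];
    }
    S.box = boxes[f];
    double acc = 0.0;
    for (int i = 0; i < S.n; ++i)
      for (int j = i + 1; j < S.n; ++j) {
        if (i < S.ns && j < S.ns && S.excluded(i, j)) continue;
        if (i >= S.ns && j >= S.ns) continue; // solvent-solvent: no coupling
        if (i >= S.ns && S.water_of(i) == S.water_of(j)) continue;
        acc += S.pair_dudl(i, j, C);
      }
    out[f] = acc;
  }
  return out;
}

static inline void rot_axis_angle(double ux, double uy, double uz, double th,
                                  double &vx, double &vy, double &vz) {
  // Rodrigues rotation of v about unit axis u by angle th
  double c = std::cos(th), s = std::sin(th);
  double dot = ux * vx + uy * vy + uz * vz;
  double cx = uy * vz - uz * vy, cy = uz * vx - ux * vz, cz = ux * vy - uy * vx;
  double nx = vx * c + cx * s + ux * dot * (1.0 - c);
  double ny = vy * c + cy * s + uy * dot * (1.0 - c);
  double nz = vz * c + cz * s + uz * dot * (1.0 - c);
  vx = nx; vy = ny; vz = nz;
}

static inline void rand_unit(double &ux, double &uy, double &uz) {
  double n2;
  do {
    ux = norm_rand(); uy = norm_rand(); uz = norm_rand();
    n2 = ux * ux + uy * uy + uz * uz;
  } while (n2 < 1e-12);
  double n = std::sqrt(n2);
  ux /= n; uy /= n; uz /= n;
}

// Metropolis MC: single-solute-atom translations, rigid whole-solute
// translation/rotation, rigid water translation+rotation, optional
// isotropic ln-V volume moves (NPT).  Uses R's RNG (seeded from R).
// [[Rcpp::export]]
List cpp_mc_sample(List sys, List settings, List coupling, List control) {
  System S = make_system(sys, settings);
  Coupling C = make_coupling(coupling, S.ns);
  double beta = as<double>(control["beta"]);
  double pres = as<double>(control["pressure_red"]); // kcal/mol/A^3
  bool npt = as<bool>(control["npt"]);
  int ntune = as<int>(control["n_tune"]);
  int nsweeps = as<int>(control["n_sweeps"]);
  int save_every = as<int>(control["save_every"]);

  double step_atom = as<double>(control["step_atom"]);
  double step_sol = as<double>(control["step_solute"]);
  double ang_sol = 0.5, step_wat = as<double>(control["step_water"]);
  double ang_wat = 0.6, step_vol = 0.02; // d(ln V)

  double comps[3];
  S.total_energy(C, comps);
  double etot = comps[0] + comps[1] + comps[2] + S.bond_energy();

  long att[4] = {0, 0, 0, 0}, acc[4] = {0, 0, 0, 0};

  int nsave = nsweeps / save_every;
  NumericVector frames(Dimension(nsave, S.n, 3));
  NumericVector volumes(nsave), boxes(nsave);
  int isave = 0;

  for (int sweep = 0; sweep < ntune + nsweeps; ++sweep) {
    bool tuning = sweep < ntune;
    // single solute atom translations
    for (int a = 0; a < S.ns; ++a) {
      double e0 = S.atom_energy(a, C);
      double ox = S.x[a], oy = S.y[a], oz = S.z[a];
      S.x[a] += step_atom * (unif_rand() - 0.5) * 2.0;
      S.y[a] += step_atom * (unif_rand() - 0.5) * 2.0;
      S.z[a] += step_atom * (unif_rand() - 0.5) * 2.0;
      double e1 = S.atom_energy(a, C);
      att[0]++;
      if (e1 - e0 <= 0.0 || unif_rand() < std::exp(-beta * (e1 - e0))) {
        etot += e1 - e0; acc[0]++;
      } else {
        S.x[a] = ox; S.y[a] = oy; S.z[a] = oz;
      }
    }
    // rigid whole-solute translation + rotation (when solvent present)
    if (S.ns > 0 && S.nw > 0) {
      double e0 = S.solute_external_energy(C);
      std::vector<double> sx(S.x.begin(), S.x.begin() + S.ns),
          sy(S.y.begin(), S.y.begin() + S.ns),
          sz(S.z.begin(), S.z.begin() + S.ns);
      double dx = step_sol * (unif_rand() - 0.5) * 2.0;
      double dy = step_sol * (unif_rand() - 0.5) * 2.0;
      double dz = step_sol * (unif_rand() - 0.5) * 2.0;
      double cx = 0, cy = 0, cz = 0;
      for (int i = 0; i < S.ns; ++i) { cx += S.x[i]; cy += S.y[i]; cz += S.z[i]; }
      cx /= S.ns; cy /= S.ns; cz /= S.ns;
      double ux, uy, uz; rand_unit(ux, uy, uz);
      double th = ang_sol * (unif_rand() - 0.5) * 2.0;
      for (int i = 0; i < S.ns; ++i) {
        double vx = S.x[i] - cx, vy = S.y[i] - cy, vz = S.z[i] - cz;
        if (S.ns > 1) rot_axis_angle(ux, uy, uz, th, vx, vy, vz);
        S.x[i] = cx + vx + dx; S.y[i] = cy + vy + dy; S.z[i] = cz + vz + dz;
      }
      double e1 = S.solute_external_energy(C);
      att[1]++;
      if (e1 - e0 <= 0.0 || unif_rand() < std::exp(-beta * (e1 - e0))) {
        etot += e1 - e0; acc[1]++;
      } else {
        for (int i = 0; i < S.ns; ++i) { S.x[i] = sx[i]; S.y[i] = sy[i]; S.z[i] = sz[i]; }
      }
    }
    // rigid water moves
    for (int w = 0; w < S.nw; ++w) {
      int s0 = S.ns + 3 * w;
      double e0 = S.water_energy(w, C);
      double ox[3], oy[3], oz[3];
      for (int k = 0; k < 3; ++k) { ox[k] = S.x[s0 + k]; oy[k] = S.y[s0 + k]; oz[k] = S.z[s0 + k]; }
      double dx = step_wat * (unif_rand() - 0.5) * 2.0;
      double dy = step_wat * (unif_rand() - 0.5) * 2.0;
      double dz = step_wat * (unif_rand() - 0.5) * 2.0;
      double ux, uy, uz; rand_unit(ux, uy, uz);
      double th = ang_wat * (unif_rand() - 0.5) * 2.0;
      for (int k = 1; k < 3; ++k) { // rotate H about O
        double vx = S.x[s0 + k] - S.x[s0], vy = S.y[s0 + k] - S.y[s0],
               vz = S.z[s0 + k] - S.z[s0];
        rot_axis_angle(ux, uy, uz, th, vx, vy, vz);
        S.x[s0 + k] = S.x[s0] + vx; S.y[s0 + k] = S.y[s0] + vy; S.z[s0 + k] = S.z[s0] + vz;
      }
      for (int k = 0; k < 3; ++k) { S.x[s0 + k] += dx; S.y[s0 + k] += dy; S.z[s0 + k] += dz; }
      double e1 = S.water_energy(w, C);
      att[2]++;
      if (e1 - e0 <= 0.0 || unif_rand() < std::exp(-beta * (e1 - e0))) {
        etot += e1 - e0; acc[2]++;
      } else {
        for (int k = 0; k < 3; ++k) { S.x[s0 + k] = ox[k]; S.y[s0 + k] = oy[k]; S.z[s0 + k] = oz[k]; }
      }
    }
    // volume move
    if (npt && S.periodic) {
      double v0 = S.box * S.box * S.box;
      double lnv1 = std::log(v0) + step_vol * (unif_rand() - 0.5) * 2.0;
      double v1 = std::exp(lnv1);
      double sc = std::cbrt(v1 / v0);
      std::vector<double> keepx = S.x, keepy = S.y, keepz = S.z;
      double oldbox = S.box;
      // scale solute centroid and water O positions; rigid geometry kept
      if (S.ns > 0) {
        double cx = 0, cy = 0, cz = 0;
        for (int i = 0; i < S.ns; ++i) { cx += S.x[i]; cy += S.y[i]; cz += S.z[i]; }
        cx /= S.ns; cy /= S.ns; cz /= S.ns;
        for (int i = 0; i < S.ns; ++i) {
          S.x[i] += cx * (sc - 1.0); S.y[i] += cy * (sc - 1.0); S.z[i] += cz * (sc - 1.0);
        }
      }
      for (int w = 0; w < S.nw; ++w) {
        int s0 = S.ns + 3 * w;
        double dx = S.x[s0] * (sc - 1.0), dy = S.y[s0] * (sc - 1.0),
               dz = S.z[s0] * (sc - 1.0);
        for (int k = 0; k < 3; ++k) { S.x[s0 + k] += dx; S.y[s0 + k] += dy; S.z[s0 + k] += dz; }
      }
      S.box = std::cbrt(v1);
      S.total_energy(C, comps);
      double e1 = comps[0] + comps[1] + comps[2] + S.bond_energy();
      int nmol = S.nw + (S.ns > 0 ? 1 : 0);
      double arg = -beta * (e1 - etot) - beta * pres * (v1 - v0) +
                   (nmol + 1) * std::log(v1 / v0);
      att[3]++;
      if (arg >= 0.0 || unif_rand() < std::exp(arg)) {
        etot = e1; acc[3]++;
      } else {
        S.x = keepx; S.y = keepy; S.z = keepz; S.box = oldbox;
      }
    }
    // step-size tuning during the tune phase
    if (tuning && (sweep + 1) % 20 == 0) {
      double rates[3];
      for (int c = 0; c < 3; ++c)
        rates[c] = att[c] > 0 ? (double)acc[c] / att[c] : 0.4;
      if (rates[0] > 0.5) step_atom *= 1.2; else if (rates[0] < 0.3) step_atom *= 0.8;
      if (rates[1] > 0.5) step_sol *= 1.2; else if (rates[1] < 0.3) step_sol *= 0.8;
      if (rates[2] > 0.5) { step_wat *= 1.2; ang_wat *= 1.15; }
      else if (rates[2] < 0.3) { step_wat *= 0.8; ang_wat *= 0.85; }
      double cap = S.periodic ? S.box * 0.45 : 10.0;
      step_atom = std::min(std::max(step_atom, 1e-3), cap);
      step_sol = std::min(std::max(step_sol, 1e-3), cap);
      step_wat = std::min(std::max(step_wat, 1e-3), cap);
      ang_wat = std::min(std::max(ang_wat, 0.02), 3.1);
      for (int c = 0; c < 4; ++c) { att[c] = 0; acc[c] = 0; }
    }
    if (tuning && sweep == ntune - 1)
      for (int c = 0; c < 4; ++c) { att[c] = 0; acc[c] = 0; }
    // save production frames (wrapped into the primary box)
    if (!tuning && ((sweep - ntune + 1) % save_every == 0) && isave < nsave) {
      std::vector<double> fx = S.x, fy = S.y, fz = S.z;
      if (S.periodic) {
        // wrap by molecule so monomers stay whole
        if (S.ns > 0) {
          double cx = 0, cy = 0, cz = 0;
          for (int i = 0; i < S.ns; ++i) { cx += fx[i]; cy += fy[i]; cz += fz[i]; }
          cx /= S.ns; cy /= S.ns; cz /= S.ns;
          double wx = cx - S.box * std::floor(cx / S.box) - cx;
          double wy = cy - S.box * std::floor(cy / S.box) - cy;
          double wz = cz - S.box * std::floor(cz / S.box) - cz;
          for (int i = 0; i < S.ns; ++i) { fx[i] += wx; fy[i] += wy; fz[i] += wz; }
        }
        for (int w = 0; w < S.nw; ++w) {
          int s0 = S.ns + 3 * w;
          double wx = fx[s0] - S.box * std::floor(fx[s0] / S.box) - fx[s0];
          double wy = fy[s0] - S.box * std::floor(fy[s0] / S.box) - fy[s0];
          double wz = fz[s0] - S.box * std::floor(fz[s0] / S.box) - fz[s0];
          for (int k = 0; k < 3; ++k) { fx[s0 + k] += wx; fy[s0 + k] += wy; fz[s0 + k] += wz; }
        }
      }
      for (int i = 0; i < S.n; ++i) {
        frames[isave + nsave * i] = fx[i];
        frames[isave + nsave * (i + S.n)] = fy[i];
        frames[isave + nsave * (i + 2 * S.n)] = fz[i];
      }
      volumes[isave] = S.box * S.box * S.box;
      boxes[isave] = S.box;
      isave++;
    }
  }

  NumericVector rates(4);
  for (int c = 0; c < 4; ++c)
    rates[c] = att[c] > 0 ? (double)acc[c] / att[c] : NA_REAL;
  rates.names() = CharacterVector::create("atom", "solute", "water", "volume");
  return List::create(_["frames"] = frames, _["volumes"] = volumes,
                      _["boxes"] = boxes, _["acceptance"] = rates,
                      _["final_energy"] = etot,
                      _["steps"] = NumericVector::create(
                          _["atom"] = step_atom, _["solute"] = step_sol,
                          _["water"] = step_wat));
}
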