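#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// small vector helpers on raw double[3]
// ---------------------------------------------------------------------------
static inline void vsub(const double* a, const double* b, double* out) {
  out[0] = a[0] - b[0]; out[1] = a[1] - b[1]; out[2] = a[2] - b[2];
}
static inline void vcross(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}
static inline double vdot(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}
static inline double vnorm(const double* a) { return std::sqrt(vdot(a, a)); }

// ---------------------------------------------------------------------------
// Gaussian entanglement kernels
// ---------------------------------------------------------------------------

// Per-bond-pair Gauss terms for one chain: entry (i, j) =
// (1/4pi) (R_i - R_j) / |R_i - R_j|^3 . (dR_i x dR_j)
// with R_i the bond midpoint and dR_i the bond vector. Symmetric in (i, j).
// [[Rcpp::export]]
NumericMatrix gauss_pair_matrix_cpp(NumericMatrix coords) {
  const int n = coords.nrow();
  if (n < 2) stop("need at least 2 points");
  const int nb = n - 1;
  std::vector<double> mid(3 * nb), dr(3 * nb);
  for (int i = 0; i < nb; ++i) {
    for (int k = 0; k < 3; ++k) {
      mid[3 * i + k] = 0.5 * (coords(i + 1, k) + coords(i, k));
      dr[3 * i + k] = coords(i + 1, k) - coords(i, k);
    }
  }
  NumericMatrix M(nb, nb);
  bool warned = false;
  const double c = 1.0 / (4.0 * M_PI);
  for (int i = 0; i < nb; ++i) {
    for (int j = i + 1; j < nb; ++j) {
      double sep[3], cr[3];
      vsub(&mid[3 * i], &mid[3 * j], sep);
      double d = vnorm(sep);
      if (d < 1e-12) {
        if (!warned) { warning("coincident bond midpoints; entry set to 0"); warned = true; }
        continue;
      }
      vcross(&dr[3 * i], &dr[3 * j], cr);
      double val = c * vdot(sep, cr) / (d * d * d);
      M(i, j) = val;
      M(j, i) = val;
    }
  }
  return M;
}

// Gauss double sum between two separate polygonal curves (linking number
// estimate when both are closed). Curves are vertex matrices; closed curves
// wrap around (bond from last vertex back to the first).
// [[Rcpp::export]]
double gauss_linking_cpp(NumericMatrix a, NumericMatrix b, bool closed_a, bool closed_b) {
  const int na = a.nrow(), nb = b.nrow();
  const int nba = closed_a ? na : na - 1;
  const int nbb = closed_b ? nb : nb - 1;
  if (nba < 1 || nbb < 1) stop("curves need at least one segment");
  std::vector<double> ma(3 * nba), da(3 * nba), mb(3 * nbb), db(3 * nbb);
  for (int i = 0; i < nba; ++i) {
    int ip = (i + 1) % na;
    for (int k = 0; k < 3; ++k) {
      ma[3 * i + k] = 0.5 * (a(ip, k) + a(i, k));
      da[3 * i + k] = a(ip, k) - a(i, k);
    }
  }
  for (int j = 0; j < nbb; ++j) {
    int jp = (j + 1) % nb;
    for (int k = 0; k < 3; ++k) {
      mb[3 * j + k] = 0.5 * (b(jp, k) + b(j, k));
      db[3 * j + k] = b(jp, k) - b(j, k);
    }
  }
  double s = 0.0;
  for (int i = 0; i < nba; ++i) {
    for (int j = 0; j < nbb; ++j) {
      double sep[3], cr[3];
      vsub(&ma[3 * i], &mb[3 * j], sep);
      double d = vnorm(sep);
      if (d < 1e-12) stop("curves touch: Gauss kernel singular");
      vcross(&da[3 * i], &db[3 * j], cr);
      s += vdot(sep, cr) / (d * d * d);
    }
  }
  return s / (4.0 * M_PI);
}

// Maximal-|G'| thread for one loop, via loop-row column sums and prefix sums.
// Residue indices are 1-based; loop (i1, i2); admissible threads (j1, j2) with
// j2 - j1 >= mj lie entirely in [1, i1] or [i2, n]. Ties: smaller j1, then j2.
// Returns c(j1, j2, gprime); j1 = j2 = 0 when no admissible thread exists.
// [[Rcpp::export]]
NumericVector max_thread_cpp(NumericMatrix M, int i1, int i2, int n, int mj) {
  const int nb = n - 1;
  if (M.nrow() != nb) stop("pair matrix size does not match n");
  // column sums over loop bond rows i1..i2-1 (1-based residues -> rows i1-1..i2-2)
  std::vector<double> colsum(nb, 0.0), P(nb + 1, 0.0);
  for (int j = 0; j < nb; ++j) {
    double s = 0.0;
    for (int i = i1 - 1; i <= i2 - 2; ++i) s += M(i, j);
    colsum[j] = s;
  }
  for (int j = 0; j < nb; ++j) P[j + 1] = P[j] + colsum[j];
  // thread residues (j1, j2) -> bonds j1..j2-1 -> G = P[j2-1] - P[j1-1]
  double best = -1.0; int bj1 = 0, bj2 = 0;
  // scan one residue range [lo, hi]
  auto scan = [&](int lo, int hi) {
    if (hi - lo < mj) return;
    // running min/max of P[u-1] for candidate j1 = u, keeping earliest index
    double pmin = R_PosInf, pmax = R_NegInf; int amin = 0, amax = 0;
    for (int j2 = lo + mj; j2 <= hi; ++j2) {
      int u = j2 - mj; // newly admissible j1
      double pu = P[u - 1];
      if (pu < pmin) { pmin = pu; amin = u; }
      if (pu > pmax) { pmax = pu; amax = u; }
      double g1 = P[j2 - 1] - pmin; // most positive
      double g2 = P[j2 - 1] - pmax; // most negative
      double cand; int cu;
      if (std::fabs(g1) > std::fabs(g2) ||
          (std::fabs(g1) == std::fabs(g2) && amin <= amax)) {
        cand = g1; cu = amin;
      } else {
        cand = g2; cu = amax;
      }
      if (std::fabs(cand) > best + 1e-15) { best = std::fabs(cand); bj1 = cu; bj2 = j2; }
    }
  };
  scan(1, i1);
  scan(i2, n);
  NumericVector out(3);
  if (bj1 == 0) { out[0] = 0; out[1] = 0; out[2] = 0; return out; }
  out[0] = bj1; out[1] = bj2;
  out[2] = P[bj2 - 1] - P[bj1 - 1];
  return out;
}

// Per-snapshot entanglement: for each formed contact (loop), find the maximal
// thread, then combine with Hill weights into the whole-chain indicator.
// Returns a list with per-contact records plus H and the indicator.
// [[Rcpp::export]]
List snapshot_entanglement_cpp(NumericMatrix coords, IntegerVector ci, IntegerVector cj,
                               int mj, double g0, double hill_m) {
  const int n = coords.nrow();
  const int nc = ci.size();
  NumericMatrix M = gauss_pair_matrix_cpp(coords);
  NumericVector gp(nc), h(nc);
  IntegerVector j1(nc), j2(nc);
  double H = 0.0, num = 0.0;
  for (int c = 0; c < nc; ++c) {
    NumericVector r = max_thread_cpp(M, ci[c], cj[c], n, mj);
    j1[c] = (int)r[0]; j2[c] = (int)r[1]; gp[c] = r[2];
    double ga = std::fabs(gp[c]);
    double w = (ga > 0) ? 1.0 / (1.0 + std::pow(g0 / ga, hill_m)) : 0.0;
    h[c] = w;
    H += w;
    num += gp[c] * w;
  }
  double ind = (H > 0) ? num / H : 0.0;
  return List::create(_["gprime"] = gp, _["j1"] = j1, _["j2"] = j2,
                      _["h"] = h, _["H"] = H, _["indicator"] = ind);
}

// ---------------------------------------------------------------------------
// internal geometry (bonds, pseudo-angles, pseudo-dihedrals)
// ---------------------------------------------------------------------------

// Signed dihedral in (-pi, pi] about the central bond b2, atan2 convention.
static inline double dihedral_angle(const double* b1, const double* b2, const double* b3) {
  double n1[3], n2[3], m[3];
  vcross(b1, b2, n1);
  vcross(b2, b3, n2);
  double b2n = vnorm(b2);
  vcross(n1, n2, m);
  double y = vdot(m, b2) / b2n;
  double x = vdot(n1, n2);
  return std::atan2(y, x);
}

// [[Rcpp::export]]
List internal_geometry_cpp(NumericMatrix coords) {
  const int n = coords.nrow();
  if (n < 2) stop("need at least 2 residues");
  NumericVector r0(std::max(n - 1, 0)), th0(std::max(n - 2, 0)), ph0(std::max(n - 3, 0));
  for (int i = 0; i < n - 1; ++i) {
    double b[3];
    double p[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    double q[3] = {coords(i + 1, 0), coords(i + 1, 1), coords(i + 1, 2)};
    vsub(q, p, b);
    r0[i] = vnorm(b);
  }
  for (int i = 0; i < n - 2; ++i) {
    double a[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    double b[3] = {coords(i + 1, 0), coords(i + 1, 1), coords(i + 1, 2)};
    double c[3] = {coords(i + 2, 0), coords(i + 2, 1), coords(i + 2, 2)};
    double u[3], v[3];
    vsub(a, b, u);
    vsub(c, b, v);
    double ct = vdot(u, v) / (vnorm(u) * vnorm(v));
    if (ct > 1.0) ct = 1.0;
    if (ct < -1.0) ct = -1.0;
    th0[i] = std::acos(ct);
  }
  for (int i = 0; i < n - 3; ++i) {
    double b1[3], b2[3], b3[3];
    double p0[3] = {coords(i, 0), coords(i, 1), coords(i, 2)};
    double p1[3] = {coords(i + 1, 0), coords(i + 1, 1), coords(i + 1, 2)};
    double p2[3] = {coords(i + 2, 0), coords(i + 2, 1), coords(i + 2, 2)};
    double p3[3] = {coords(i + 3, 0), coords(i + 3, 1), coords(i + 3, 2)};
    vsub(p1, p0, b1);
    vsub(p2, p1, b2);
    vsub(p3, p2, b3);
    ph0[i] = dihedral_angle(b1, b2, b3);
  }
  return List::create(_["bond_lengths"] = r0, _["angles"] = th0, _["dihedrals"] = ph0);
}

// ---------------------------------------------------------------------------
// Go-model potential energy and analytic forces
// ---------------------------------------------------------------------------

struct GoParams {
  double eps_bond, eps_angle, eps_dihedral, eps_contact, eps_nn;
  double sigma_nn, native_cutoff_factor, nn_cutoff, flavour_1210_cutoff_factor;
  bool flavour_1210;
};

static GoParams unpack_params(const List& params) {
  GoParams p;
  p.eps_bond = as<double>(params["eps_bond"]);
  p.eps_angle = as<double>(params["eps_angle"]);
  p.eps_dihedral = as<double>(params["eps_dihedral"]);
  p.eps_contact = as<double>(params["eps_contact"]);
  p.eps_nn = as<double>(params["eps_nn"]);
  p.sigma_nn = as<double>(params["sigma_nn"]);
  p.native_cutoff_factor = as<double>(params["native_cutoff_factor"]);
  p.flavour_1210 = as<std::string>(params["lj_flavour"]) == "12-10";
  p.flavour_1210_cutoff_factor = as<double>(params["flavour_1210_cutoff_factor"]);
  p.nn_cutoff = std::pow(2.0, 1.0 / 6.0) * p.sigma_nn;
  return p;
}

// Preprocessed topology for the raw-array force kernel.
struct Topo {
  int n;
  std::vector<double> r0_bond, theta0, phi0, r0_c;
  std::vector<double> cphi0, sphi0; // precomputed cos / sin of native dihedrals
  std::vector<int> ci, cj;          // 0-based contact indices
  std::vector<char> native;         // n x n lookup
};

static Topo make_topo(int n, const NumericVector& r0_bond, const NumericVector& theta0,
                      const NumericVector& phi0, const IntegerVector& ci,
                      const IntegerVector& cj, const NumericVector& r0_c) {
  Topo t;
  t.n = n;
  t.r0_bond.assign(r0_bond.begin(), r0_bond.end());
  t.theta0.assign(theta0.begin(), theta0.end());
  t.phi0.assign(phi0.begin(), phi0.end());
  for (double ph : t.phi0) {
    t.cphi0.push_back(std::cos(ph));
    t.sphi0.push_back(std::sin(ph));
  }
  t.r0_c.assign(r0_c.begin(), r0_c.end());
  t.native.assign((size_t)n * n, 0);
  for (int c = 0; c < ci.size(); ++c) {
    t.ci.push_back(ci[c] - 1);
    t.cj.push_back(cj[c] - 1);
    t.native[(size_t)(ci[c] - 1) * n + (cj[c] - 1)] = 1;
    t.native[(size_t)(cj[c] - 1) * n + (ci[c] - 1)] = 1;
  }
  return t;
}

// Energy (and forces when f != nullptr) on raw arrays; components gets the
// 5-way split (bond, angle, dihedral, native, nonnative) when non-null.
// Non-native repulsion acts on every pair with j >= i + 2 that is not native.
static double go_force_raw(const Topo& t, const GoParams& p, const double* x,
                           double* f, double* components) {
  const int n = t.n;
  double e_bond = 0, e_angle = 0, e_dih = 0, e_nat = 0, e_nn = 0;
  if (f) std::fill(f, f + 3 * n, 0.0);

  // bonds
  for (int i = 0; i < n - 1; ++i) {
    double b[3];
    vsub(&x[3 * (i + 1)], &x[3 * i], b);
    double r = vnorm(b);
    if (r < 1e-10) stop("zero interparticle distance in bond %d", i + 1);
    double d = r - t.r0_bond[i];
    e_bond += p.eps_bond * d * d;
    if (f) {
      double fac = -2.0 * p.eps_bond * d / r;
      for (int k = 0; k < 3; ++k) {
        f[3 * (i + 1) + k] += fac * b[k];
        f[3 * i + k] -= fac * b[k];
      }
    }
  }

  // angles
  for (int i = 0; i < n - 2; ++i) {
    double u[3], v[3];
    vsub(&x[3 * i], &x[3 * (i + 1)], u);
    vsub(&x[3 * (i + 2)], &x[3 * (i + 1)], v);
    double nu = vnorm(u), nv = vnorm(v);
    double ct = vdot(u, v) / (nu * nv);
    const double lim = 1.0 - 1e-10;
    if (ct > lim) ct = lim;
    if (ct < -lim) ct = -lim;
    double th = std::acos(ct);
    double d = th - t.theta0[i];
    e_angle += p.eps_angle * d * d;
    if (f) {
      double st = std::sqrt(1.0 - ct * ct);
      double coef = 2.0 * p.eps_angle * d / st; // -dV/dcos
      for (int k = 0; k < 3; ++k) {
        double dci = (v[k] / (nu * nv)) - ct * u[k] / (nu * nu);
        double dck = (u[k] / (nu * nv)) - ct * v[k] / (nv * nv);
        f[3 * i + k] += coef * dci;
        f[3 * (i + 2) + k] += coef * dck;
        f[3 * (i + 1) + k] -= coef * (dci + dck);
      }
    }
  }

  // dihedrals: trig-free via angle-difference identities on cos/sin of phi
  for (int i = 0; i < n - 3; ++i) {
    double b1[3], b2[3], b3[3], n1[3], n2[3], cr12[3];
    vsub(&x[3 * (i + 1)], &x[3 * i], b1);
    vsub(&x[3 * (i + 2)], &x[3 * (i + 1)], b2);
    vsub(&x[3 * (i + 3)], &x[3 * (i + 2)], b3);
    vcross(b1, b2, n1);
    vcross(b2, b3, n2);
    double n1sq = vdot(n1, n1), n2sq = vdot(n2, n2);
    if (n1sq < 1e-16 || n2sq < 1e-16) continue; // collinear: torque-free
    double b2n = vnorm(b2);
    double hh = std::sqrt(n1sq * n2sq);
    vcross(n1, n2, cr12);
    double cphi = vdot(n1, n2) / hh;
    double sphi = vdot(cr12, b2) / (b2n * hh);
    // cos/sin of (phi - phi0) and of the tripled angle
    double cd = cphi * t.cphi0[i] + sphi * t.sphi0[i];
    double sd = sphi * t.cphi0[i] - cphi * t.sphi0[i];
    double c3 = (4.0 * cd * cd - 3.0) * cd;
    double s3 = (3.0 - 4.0 * sd * sd) * sd;
    e_dih += p.eps_dihedral * ((1.0 - cd) + 0.5 * (1.0 - c3));
    if (f) {
      double dVdphi = p.eps_dihedral * (sd + 1.5 * s3);
      double t1[3], t4[3];
      for (int k = 0; k < 3; ++k) {
        t1[k] = -(b2n / n1sq) * n1[k];
        t4[k] = (b2n / n2sq) * n2[k];
      }
      double c12 = vdot(b1, b2) / (b2n * b2n);
      double c32 = vdot(b3, b2) / (b2n * b2n);
      for (int k = 0; k < 3; ++k) {
        double t2 = -t1[k] - c12 * t1[k] + c32 * t4[k];
        double t3 = -t4[k] + c12 * t1[k] - c32 * t4[k];
        f[3 * i + k] -= dVdphi * t1[k];
        f[3 * (i + 1) + k] -= dVdphi * t2;
        f[3 * (i + 2) + k] -= dVdphi * t3;
        f[3 * (i + 3) + k] -= dVdphi * t4[k];
      }
    }
  }

  // native contacts
  const double sfac = std::pow(2.0, -1.0 / 6.0);
  for (size_t c = 0; c < t.ci.size(); ++c) {
    int a = t.ci[c], b = t.cj[c];
    double d[3];
    vsub(&x[3 * a], &x[3 * b], d);
    double r = vnorm(d);
    if (r < 1e-10) stop("zero interparticle distance in contact (%d, %d)", a + 1, b + 1);
    double e = 0, dVdr = 0;
    if (!p.flavour_1210) {
      double s = sfac * t.r0_c[c];
      if (r <= p.native_cutoff_factor * s) {
        double sr2 = (s / r) * (s / r);
        double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
        e = 4.0 * p.eps_contact * (sr12 - sr6);
        dVdr = 4.0 * p.eps_contact * (-12.0 * sr12 + 6.0 * sr6) / r;
      }
    } else {
      if (r <= p.flavour_1210_cutoff_factor * t.r0_c[c]) {
        double q2 = (t.r0_c[c] / r) * (t.r0_c[c] / r);
        double q10 = q2 * q2 * q2 * q2 * q2, q12 = q10 * q2;
        e = p.eps_contact * (5.0 * q12 - 6.0 * q10);
        dVdr = p.eps_contact * (-60.0 * q12 + 60.0 * q10) / r;
      }
    }
    e_nat += e;
    if (f && dVdr != 0) {
      for (int k = 0; k < 3; ++k) {
        double fk = -dVdr * d[k] / r;
        f[3 * a + k] += fk;
        f[3 * b + k] -= fk;
      }
    }
  }

  // non-native repulsion (truncated at 2^{1/6} sigma_nn, shifted to 0)
  const double rc2 = p.nn_cutoff * p.nn_cutoff;
  const double s2 = p.sigma_nn * p.sigma_nn;
  for (int i = 0; i < n - 2; ++i) {
    for (int j = i + 2; j < n; ++j) {
      if (t.native[(size_t)i * n + j]) continue;
      double d[3];
      vsub(&x[3 * i], &x[3 * j], d);
      double r2 = vdot(d, d);
      if (r2 >= rc2) continue;
      if (r2 < 1e-20) stop("zero interparticle distance in pair (%d, %d)", i + 1, j + 1);
      double sr2 = s2 / r2;
      double sr6 = sr2 * sr2 * sr2, sr12 = sr6 * sr6;
      e_nn += 4.0 * p.eps_nn * (sr12 - sr6) + p.eps_nn;
      if (f) {
        double dVdr_r = 4.0 * p.eps_nn * (-12.0 * sr12 + 6.0 * sr6) / r2; // (dV/dr)/r
        for (int k = 0; k < 3; ++k) {
          double fk = -dVdr_r * d[k];
          f[3 * i + k] += fk;
          f[3 * j + k] -= fk;
        }
      }
    }
  }

  if (components) {
    components[0] = e_bond; components[1] = e_angle; components[2] = e_dih;
    components[3] = e_nat; components[4] = e_nn;
  }
  return e_bond + e_angle + e_dih + e_nat + e_nn;
}

static List go_eval(const NumericMatrix& coords, const NumericVector& r0_bond,
                    const NumericVector& theta0, const NumericVector& phi0,
                    const IntegerVector& ci, const IntegerVector& cj,
                    const NumericVector& r0_c, const GoParams& p, bool want_forces) {
  const int n = coords.nrow();
  Topo t = make_topo(n, r0_bond, theta0, phi0, ci, cj, r0_c);
  std::vector<double> x(3 * n), f(want_forces ? 3 * n : 0);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
  double comp[5];
  double total = go_force_raw(t, p, x.data(), want_forces ? f.data() : nullptr, comp);
  NumericVector components = NumericVector::create(
      _["bond"] = comp[0], _["angle"] = comp[1], _["dihedral"] = comp[2],
      _["native"] = comp[3], _["nonnative"] = comp[4]);
  if (!want_forces) return List::create(_["total"] = total, _["components"] = components);
  NumericMatrix F(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) F(i, k) = f[3 * i + k];
  return List::create(_["total"] = total, _["components"] = components, _["forces"] = F);
}

// [[Rcpp::export]]
List go_energy_cpp(NumericMatrix coords, NumericVector r0_bond, NumericVector theta0,
                   NumericVector phi0, IntegerVector ci, IntegerVector cj,
                   NumericVector r0_c, List params) {
  return go_eval(coords, r0_bond, theta0, phi0, ci, cj, r0_c, unpack_params(params), false);
}

// [[Rcpp::export]]
List go_forces_cpp(NumericMatrix coords, NumericVector r0_bond, NumericVector theta0,
                   NumericVector phi0, IntegerVector ci, IntegerVector cj,
                   NumericVector r0_c, List params) {
  return go_eval(coords, r0_bond, theta0, phi0, ci, cj, r0_c, unpack_params(params), true);
}

// ---------------------------------------------------------------------------
// Langevin dynamics: Gronbech-Jensen / Farago velocity-Verlet discretization.
// Noise comes from an internal xoshiro256++ stream (Marsaglia polar normals);
// the chunk seed is drawn from R's RNG, so set.seed() fixes trajectories.
// ---------------------------------------------------------------------------

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
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
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  bool have_spare = false;
  double spare = 0;
  inline double norm() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, q;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      q = u * u + v * v;
    } while (q >= 1.0 || q == 0.0);
    double fac = std::sqrt(-2.0 * std::log(q) / q);
    spare = v * fac;
    have_spare = true;
    return u * fac;
  }
};

// Integrate n_steps inner steps; returns list(coords, vels).
// [[Rcpp::export]]
List langevin_chunk_cpp(NumericMatrix coords, NumericMatrix vels,
                        NumericVector r0_bond, NumericVector theta0, NumericVector phi0,
                        IntegerVector ci, IntegerVector cj, NumericVector r0_c,
                        List params, int n_steps, double dt, double gamma_,
                        double mass, double temp, double chunk_seed) {
  GoParams p = unpack_params(params);
  const int n = coords.nrow();
  Topo t = make_topo(n, r0_bond, theta0, phi0, ci, cj, r0_c);
  std::vector<double> x(3 * n), v(3 * n), f(3 * n), f2(3 * n);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      x[3 * i + k] = coords(i, k);
      v[3 * i + k] = vels(i, k);
    }
  }
  const double b = 1.0 / (1.0 + gamma_ * dt / (2.0 * mass));
  const double a = b * (1.0 - gamma_ * dt / (2.0 * mass));
  const double sig = std::sqrt(2.0 * gamma_ * temp * dt);
  const double c_x_v = b * dt, c_x_f = b * dt * dt / (2.0 * mass);
  const double c_x_b = b * dt / (2.0 * mass), c_v_f = dt / (2.0 * mass);
  const double c_v_b = b / mass;

  go_force_raw(t, p, x.data(), f.data(), nullptr);

  Xoshiro rng((uint64_t)chunk_seed);
  for (int s = 0; s < n_steps; ++s) {
    for (int i = 0; i < 3 * n; ++i) {
      double beta = sig * rng.norm();
      x[i] += c_x_v * v[i] + c_x_f * f[i] + c_x_b * beta;
      v[i] = a * v[i] + c_v_f * a * f[i] + c_v_b * beta; // f2 term added below
    }
    go_force_raw(t, p, x.data(), f2.data(), nullptr);
    for (int i = 0; i < 3 * n; ++i) {
      v[i] += c_v_f * f2[i];
      f[i] = f2[i];
    }
    if ((s & 2047) == 0) {
      for (int i = 0; i < 3 * n; ++i)
        if (!std::isfinite(x[i]) || std::fabs(x[i]) > 1e6)
          stop("numeric blow-up at inner step %d (bead %d)", s, i / 3 + 1);
    }
  }
  NumericMatrix xo(n, 3), vo(n, 3);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) {
      xo(i, k) = x[3 * i + k];
      vo(i, k) = v[3 * i + k];
    }
  }
  return List::create(_["coords"] = xo, _["vels"] = vo);
}

// Fraction of native contacts and the formed-contact indicator vector.
// [[Rcpp::export]]
List fraction_native_cpp(NumericMatrix coords, IntegerVector ci, IntegerVector cj,
                         NumericVector r0_c, double g) {
  const int nc = ci.size();
  LogicalVector formed(nc);
  int nf = 0;
  for (int c = 0; c < nc; ++c) {
    double d[3] = {coords(ci[c] - 1, 0) - coords(cj[c] - 1, 0),
                   coords(ci[c] - 1, 1) - coords(cj[c] - 1, 1),
                   coords(ci[c] - 1, 2) - coords(cj[c] - 1, 2)};
    bool ok = vnorm(d) < g * r0_c[c];
    formed[c] = ok;
    if (ok) ++nf;
  }
  return List::create(_["q"] = nc > 0 ? (double)nf / nc : NA_REAL, _["formed"] = formed);
}
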