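// Classical energy model and analytic forces for the repair workflow.
// Units: kcal/mol, Angstrom, radians, atomic charges in e.
// Bonded conventions follow CHARMM: V_bond = k (b - b0)^2 (no 1/2),
// V_angle = k (theta - theta0)^2, V_dihedral = k (1 + cos(n phi - delta)),
// V_improper = k (phi - phi0)^2 with periodic wrapping.

#include <Rcpp.h>
#include <unordered_set>
#include <cmath>
using namespace Rcpp;

static const double COULOMB = 332.0636; // kcal mol^-1 A e^-2

static inline double wrapPi(double x) {
  while (x > M_PI) x -= 2.0 * M_PI;
  while (x <= -M_PI) x += 2.0 * M_PI;
  return x;
}

struct V3 {
  double x, y, z;
  V3() : x(0), y(0), z(0) {}
  V3(double a, double b, double c) : x(a), y(b), z(c) {}
};
static inline V3 sub(const V3& a, const V3& b) { return V3(a.x-b.x, a.y-b.y, a.z-b.z); }
static inline V3 add(const V3& a, const V3& b) { return V3(a.x+b.x, a.y+b.y, a.z+b.z); }
static inline V3 scale(const V3& a, double s) { return V3(a.x*s, a.y*s, a.z*s); }
static inline double dot(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
static inline V3 cross(const V3& a, const V3& b) {
  return V3(a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x);
}
static inline double norm(const V3& a) { return std::sqrt(dot(a, a)); }

// CHARMM switching function on r^2, active between switchOn and cutoff.
// Returns s and ds/dr.
static inline void switchFn(double r, double switchOn, double cutoff,
                            double& s, double& dsdr) {
  if (r <= switchOn) { s = 1.0; dsdr = 0.0; return; }
  if (r >= cutoff) { s = 0.0; dsdr = 0.0; return; }
  double c2 = cutoff * cutoff, o2 = switchOn * switchOn, r2 = r * r;
  double denom = (c2 - o2); denom = denom * denom * denom;
  s = (c2 - r2) * (c2 - r2) * (c2 + 2.0 * r2 - 3.0 * o2) / denom;
  double dsdr2 = 6.0 * (c2 - r2) * (o2 - r2) / denom;
  dsdr = 2.0 * r * dsdr2;
}

// dihedral angle and its gradient over the four atoms
static double dihedralGrad(const V3& ri, const V3& rj, const V3& rk, const V3& rl,
                           V3& gi, V3& gj, V3& gk, V3& gl) {
  V3 b1 = sub(rj, ri), b2 = sub(rk, rj), b3 = sub(rl, rk);
  V3 m = cross(b1, b2), n = cross(b2, b3);
  double B = norm(b2);
  double m2 = dot(m, m), n2 = dot(n, n);
  if (B < 1e-10 || m2 < 1e-20 || n2 < 1e-20) {
    gi = gj = gk = gl = V3();
    return 0.0;
  }
  double phi = std::atan2(dot(cross(m, n), b2) / B, dot(m, n));
  gi = scale(m, -B / m2);
  gl = scale(n,  B / n2);
  double s1 = dot(b1, b2) / (B * B);
  double s2 = dot(b3, b2) / (B * B);
  // gj = (-s1-1) gi + s2 gl ; gk = s1 gi - (s2+1) gl  (sum of four = 0)
  gj = add(scale(gi, -s1 - 1.0), scale(gl, s2));
  gk = sub(scale(gi, s1), scale(gl, s2 + 1.0));
  return phi;
}

// [[Rcpp::export(name = ".lbeEnergyForces")]]
List lbeEnergyForces(NumericMatrix coordsM,
                     IntegerMatrix bonds, NumericVector bondK, NumericVector bondB0,
                     IntegerMatrix angles, NumericVector angK, NumericVector angTh0,
                     IntegerMatrix dihedrals, NumericVector dihK, IntegerVector dihN,
                     NumericVector dihDelta,
                     IntegerMatrix impropers, NumericVector impK, NumericVector impPhi0,
                     NumericVector eps, NumericVector rmin2, NumericVector charge,
                     IntegerMatrix excl,
                     IntegerVector flaggedIdx,
                     double dielectric, double cutoff, double switchOn, double scDelta,
                     LogicalVector termOn,
                     IntegerVector prAtom, NumericMatrix prTarget, NumericVector prK,
                     List sepA, List sepB, NumericVector sepTarget, NumericVector sepK,
                     NumericVector mass,
                     NumericMatrix hillCenter, NumericVector hillRadius,
                     NumericVector hillHeight, List hillExempt,
                     IntegerMatrix chirIdx, NumericVector chirK, NumericVector chirPhi0) {
  const int N = coordsM.nrow();
  std::vector<V3> r(N), f(N, V3());
  for (int i = 0; i < N; ++i) r[i] = V3(coordsM(i,0), coordsM(i,1), coordsM(i,2));

  std::vector<bool> flagged(N, false);
  for (int i = 0; i < flaggedIdx.size(); ++i) flagged[flaggedIdx[i] - 1] = true;

  std::unordered_set<long long> excluded;
  for (int e = 0; e < excl.nrow(); ++e) {
    long long a = excl(e,0) - 1, b = excl(e,1) - 1;
    if (a > b) std::swap(a, b);
    excluded.insert(a * N + b);
  }

  double eBond = 0, eAngle = 0, eDih = 0, eImp = 0, eLJ = 0, eCoul = 0;
  double ePoint = 0, eSep = 0, eHill = 0, eChir = 0;

  // ---- bonds
  if (termOn[0]) {
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b,0) - 1, j = bonds(b,1) - 1;
      V3 d = sub(r[i], r[j]);
      double L = norm(d);
      double dev = L - bondB0[b];
      eBond += bondK[b] * dev * dev;
      if (L > 1e-12) {
        double pref = -2.0 * bondK[b] * dev / L;
        f[i] = add(f[i], scale(d, pref));
        f[j] = sub(f[j], scale(d, pref));
      }
    }
  }

  // ---- angles
  if (termOn[1]) {
    for (int a = 0; a < angles.nrow(); ++a) {
      int i = angles(a,0) - 1, j = angles(a,1) - 1, k = angles(a,2) - 1;
      V3 u = sub(r[i], r[j]), v = sub(r[k], r[j]);
      double lu = norm(u), lv = norm(v);
      if (lu < 1e-12 || lv < 1e-12) continue;
      double cosT = dot(u, v) / (lu * lv);
      cosT = std::max(-1.0, std::min(1.0, cosT));
      double th = std::acos(cosT);
      double sinT = std::sqrt(std::max(1.0 - cosT * cosT, 1e-16));
      double dev = th - angTh0[a];
      eAngle += angK[a] * dev * dev;
      double dVdth = 2.0 * angK[a] * dev;
      // dth/dri = (cosT*u/lu - v/lv) / (lu * sinT)
      V3 dti = scale(sub(scale(u, cosT / lu), scale(v, 1.0 / lv)), 1.0 / (lu * sinT));
      V3 dtk = scale(sub(scale(v, cosT / lv), scale(u, 1.0 / lu)), 1.0 / (lv * sinT));
      V3 dtj = scale(add(dti, dtk), -1.0);
      f[i] = sub(f[i], scale(dti, dVdth));
      f[j] = sub(f[j], scale(dtj, dVdth));
      f[k] = sub(f[k], scale(dtk, dVdth));
    }
  }

  // ---- proper dihedrals
  if (termOn[2]) {
    for (int d = 0; d < dihedrals.nrow(); ++d) {
      int i = dihedrals(d,0) - 1, j = dihedrals(d,1) - 1,
          k = dihedrals(d,2) - 1, l = dihedrals(d,3) - 1;
      V3 gi, gj, gk, gl;
      double phi = dihedralGrad(r[i], r[j], r[k], r[l], gi, gj, gk, gl);
      double arg = dihN[d] * phi - dihDelta[d];
      eDih += dihK[d] * (1.0 + std::cos(arg));
      double dVdphi = -dihK[d] * dihN[d] * std::sin(arg);
      f[i] = sub(f[i], scale(gi, dVdphi));
      f[j] = sub(f[j], scale(gj, dVdphi));
      f[k] = sub(f[k], scale(gk, dVdphi));
      f[l] = sub(f[l], scale(gl, dVdphi));
    }
  }

  // ---- impropers (harmonic, wrapped)
  if (termOn[3]) {
    for (int d = 0; d < impropers.nrow(); ++d) {
      int i = impropers(d,0) - 1, j = impropers(d,1) - 1,
          k = impropers(d,2) - 1, l = impropers(d,3) - 1;
      V3 gi, gj, gk, gl;
      double phi = dihedralGrad(r[i], r[j], r[k], r[l], gi, gj, gk, gl);
      double dev = wrapPi(phi - impPhi0[d]);
      eImp += impK[d] * dev * dev;
      double dVdphi = 2.0 * impK[d] * dev;
      f[i] = sub(f[i], scale(gi, dVdphi));
      f[j] = sub(f[j], scale(gj, dVdphi));
      f[k] = sub(f[k], scale(gk, dVdphi));
      f[l] = sub(f[l], scale(gl, dVdphi));
    }
  }

  // ---- nonbonded (LJ + Coulomb), switched, soft-core on flagged pairs
  bool doLJ = termOn[4], doCoul = termOn[5];
  int worstI = -1, worstJ = -1;
  double worstR2 = 1e30;
  if (doLJ || doCoul) {
    double cut2 = cutoff * cutoff;
    double d2sc = scDelta * scDelta;
    for (int i = 0; i < N - 1; ++i) {
      for (int j = i + 1; j < N; ++j) {
        V3 d = sub(r[i], r[j]);
        double r2 = dot(d, d);
        if (r2 >= cut2) continue;
        long long key = (long long)i * N + j;
        if (excluded.count(key)) continue;
        bool soft = flagged[i] || flagged[j];
        double re2 = soft ? (r2 + d2sc) : r2;
        if (!soft && r2 < worstR2) { worstR2 = r2; worstI = i; worstJ = j; }
        double re = std::sqrt(re2);
        double rr = std::sqrt(r2);
        double s, dsdr;
        switchFn(rr, switchOn, cutoff, s, dsdr);
        double V = 0.0, dVdre = 0.0;
        if (doLJ) {
          double em = std::sqrt(eps[i] * eps[j]);
          double rm = rmin2[i] + rmin2[j];
          double q6 = std::pow(rm / re, 6.0);
          double q12 = q6 * q6;
          V += em * (q12 - 2.0 * q6);
          dVdre += em * (-12.0 * q12 + 12.0 * q6) / re;
        }
        if (doCoul) {
          double vc = COULOMB * charge[i] * charge[j] / (dielectric * re);
          V += vc;
          dVdre += -vc / re;
        }
        double epair = s * V;
        if (doLJ) {
          // split bookkeeping: recompute LJ piece for the breakdown
          double em = std::sqrt(eps[i] * eps[j]);
          double rm = rmin2[i] + rmin2[j];
          double q6 = std::pow(rm / re, 6.0);
          eLJ += s * em * (q6 * q6 - 2.0 * q6);
        }
        if (doCoul)
          eCoul += s * COULOMB * charge[i] * charge[j] / (dielectric * re);
        // dE/dr = dsdr V + s dVdre * (r/re); force along unit vector d/rr
        double pref = s * dVdre / re;           // multiplies d directly
        if (rr > 1e-12) pref += dsdr * V / rr;  // switching part
        // F_i = -dE/dri = -pref * d
        f[i] = sub(f[i], scale(d, pref));
        f[j] = add(f[j], scale(d, pref));
        (void)epair;
      }
    }
  }

  // ---- harmonic point restraints: 1/2 k |r - t|^2
  for (int p = 0; p < prAtom.size(); ++p) {
    int i = prAtom[p] - 1;
    V3 t(prTarget(p,0), prTarget(p,1), prTarget(p,2));
    V3 d = sub(r[i], t);
    ePoint += 0.5 * prK[p] * dot(d, d);
    f[i] = sub(f[i], scale(d, prK[p]));
  }

  // ---- one-sided COM separation biases: 1/2 k (d - target)^2 for d < target
  for (int b = 0; b < sepA.size(); ++b) {
    IntegerVector ga = sepA[b], gb = sepB[b];
    double MA = 0, MB = 0;
    V3 ca, cb;
    for (int u = 0; u < ga.size(); ++u) {
      int i = ga[u] - 1; MA += mass[i]; ca = add(ca, scale(r[i], mass[i]));
    }
    for (int u = 0; u < gb.size(); ++u) {
      int i = gb[u] - 1; MB += mass[i]; cb = add(cb, scale(r[i], mass[i]));
    }
    ca = scale(ca, 1.0 / MA); cb = scale(cb, 1.0 / MB);
    V3 d = sub(ca, cb);
    double dist = norm(d);
    if (dist >= sepTarget[b]) continue;
    double dev = dist - sepTarget[b];
    eSep += 0.5 * sepK[b] * dev * dev;
    // at coincident centers the separation direction (and hence the force)
    // is undefined; the energy stays continuous and other biases break the tie
    if (dist < 1e-8) continue;
    double dVdd = sepK[b] * dev;
    V3 u = scale(d, 1.0 / dist);
    for (int v = 0; v < ga.size(); ++v) {
      int i = ga[v] - 1;
      f[i] = sub(f[i], scale(u, dVdd * mass[i] / MA));
    }
    for (int v = 0; v < gb.size(); ++v) {
      int i = gb[v] - 1;
      f[i] = add(f[i], scale(u, dVdd * mass[i] / MB));
    }
  }

  // ---- repulsive Gaussian density hills
  for (int h = 0; h < hillHeight.size(); ++h) {
    V3 c(hillCenter(h,0), hillCenter(h,1), hillCenter(h,2));
    double sig = hillRadius[h] / 2.0;
    double s2 = sig * sig;
    IntegerVector ex = hillExempt[h];
    std::unordered_set<int> exempt;
    for (int u = 0; u < ex.size(); ++u) exempt.insert(ex[u] - 1);
    for (int i = 0; i < N; ++i) {
      if (exempt.count(i)) continue;
      V3 d = sub(r[i], c);
      double rho2 = dot(d, d);
      if (rho2 > 9.0 * 4.0 * s2) continue;  // beyond 6 sigma: < 1e-7 of height
      double e = hillHeight[h] * std::exp(-rho2 / (2.0 * s2));
      eHill += e;
      // F = -dE/dr = e * d / s2
      f[i] = add(f[i], scale(d, e / s2));
    }
  }

  // ---- chirality improper restraints
  for (int d = 0; d < chirIdx.nrow(); ++d) {
    int i = chirIdx(d,0) - 1, j = chirIdx(d,1) - 1,
        k = chirIdx(d,2) - 1, l = chirIdx(d,3) - 1;
    V3 gi, gj, gk, gl;
    double phi = dihedralGrad(r[i], r[j], r[k], r[l], gi, gj, gk, gl);
    double dev = wrapPi(phi - chirPhi0[d]);
    eChir += chirK[d] * dev * dev;
    double dVdphi = 2.0 * chirK[d] * dev;
    f[i] = sub(f[i], scale(gi, dVdphi));
    f[j] = sub(f[j], scale(gj, dVdphi));
    f[k] = sub(f[k], scale(gk, dVdphi));
    f[l] = sub(f[l], scale(gl, dVdphi));
  }

  double total = eBond + eAngle + eDih + eImp + eLJ + eCoul +
                 ePoint + eSep + eHill + eChir;
  if (!std::isfinite(total)) {
    if (worstI >= 0)
      stop("non-finite energy; worst (closest unflagged) pair: atoms %d and %d at r = %g A",
           worstI + 1, worstJ + 1, std::sqrt(worstR2));
    stop("non-finite energy");
  }

  NumericMatrix forces(N, 3);
  for (int i = 0; i < N; ++i) {
    forces(i,0) = f[i].x; forces(i,1) = f[i].y; forces(i,2) = f[i].z;
  }
  return List::create(
    _["energy"] = total,
    _["forces"] = forces,
    _["terms"] = NumericVector::create(
      _["bonds"] = eBond, _["angles"] = eAngle, _["dihedrals"] = eDih,
      _["impropers"] = eImp, _["lj"] = eLJ, _["coulomb"] = eCoul,
      _["point"] = ePoint, _["separation"] = eSep, _["hills"] = eHill,
      _["chirality"] = eChir));
}
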