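// Compiled kernels: Debye scattering sums, the coarse-grained energy
// function, and the replica-exchange Monte Carlo engine.
#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// sin(x)/x with series fallback near 0
static inline double sinc(double x) {
  if (std::fabs(x) < 1e-4) { double x2 = x * x; return 1.0 - x2 / 6.0 + x2 * x2 / 120.0; }
  return std::sin(x) / x;
}
// second derivative of sin(x)/x
static inline double sinc2d(double x) {
  if (std::fabs(x) < 1e-2) { double x2 = x * x; return -1.0 / 3.0 + x2 / 10.0 - x2 * x2 / 168.0; }
  return ((2.0 - x * x) * std::sin(x) - 2.0 * x * std::cos(x)) / (x * x * x);
}

// [[Rcpp::export]]
NumericVector cpp_debye_direct(NumericMatrix coords, NumericVector q, NumericMatrix F) {
  const int N = coords.nrow(), nq = q.size();
  NumericVector I(nq);
  for (int m = 0; m < nq; ++m) {
    double s = 0.0;
    for (int i = 0; i < N; ++i) s += F(m, i) * F(m, i);
    I[m] = s;
  }
  for (int i = 0; i < N; ++i) {
    const double xi = coords(i, 0), yi = coords(i, 1), zi = coords(i, 2);
    for (int j = i + 1; j < N; ++j) {
      const double dx = xi - coords(j, 0), dy = yi - coords(j, 1), dz = zi - coords(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int m = 0; m < nq; ++m)
        I[m] += 2.0 * F(m, i) * F(m, j) * sinc(q[m] * r);
    }
  }
  return I;
}

// Histogram-accelerated Debye sum: per-bin zeroth/first/second distance
// moments give a second-order-corrected approximation of the pair sum.
// [[Rcpp::export]]
NumericVector cpp_debye_hist(NumericMatrix coords, NumericVector q,
                             NumericVector w, NumericVector gq, double binWidth) {
  const int N = coords.nrow(), nq = q.size();
  double lo[3] = {coords(0,0), coords(0,1), coords(0,2)};
  double hi[3] = {coords(0,0), coords(0,1), coords(0,2)};
  for (int i = 0; i < N; ++i) for (int d = 0; d < 3; ++d) {
    if (coords(i,d) < lo[d]) lo[d] = coords(i,d);
    if (coords(i,d) > hi[d]) hi[d] = coords(i,d);
  }
  double diag = 0.0;
  for (int d = 0; d < 3; ++d) diag += (hi[d]-lo[d]) * (hi[d]-lo[d]);
  diag = std::sqrt(diag);
  const int nb = (int)(diag / binWidth) + 2;
  std::vector<double> W(nb, 0.0), Wr(nb, 0.0), Wr2(nb, 0.0);
  for (int i = 0; i < N; ++i) {
    const double xi = coords(i,0), yi = coords(i,1), zi = coords(i,2), wi = w[i];
    for (int j = i + 1; j < N; ++j) {
      const double dx = xi - coords(j,0), dy = yi - coords(j,1), dz = zi - coords(j,2);
      const double r = std::sqrt(dx*dx + dy*dy + dz*dz);
      int b = (int)(r / binWidth); if (b >= nb) b = nb - 1;
      const double ww = wi * w[j];
      W[b] += ww; Wr[b] += ww * r; Wr2[b] += ww * r * r;
    }
  }
  double self = 0.0;
  for (int i = 0; i < N; ++i) self += w[i] * w[i];
  NumericVector I(nq);
  for (int m = 0; m < nq; ++m) {
    const double qm = q[m];
    double s = self;
    for (int b = 0; b < nb; ++b) {
      if (W[b] <= 0.0) continue;
      const double rbar = Wr[b] / W[b];
      const double m2 = Wr2[b] - W[b] * rbar * rbar;  // weighted within-bin variance * W
      const double x = qm * rbar;
      s += 2.0 * (W[b] * sinc(x) + 0.5 * qm * qm * m2 * sinc2d(x));
    }
    I[m] = gq[m] * gq[m] * s;
  }
  return I;
}

// per-model Rg (unit weights) and Dmax for a flattened pool
// [[Rcpp::export]]
NumericMatrix cpp_rg_dmax(NumericVector coords, int N, int K) {
  NumericMatrix out(K, 2);
  for (int k = 0; k < K; ++k) {
    const double *X = &coords[(size_t)k * N * 3];
    double c[3] = {0,0,0};
    for (int i = 0; i < N; ++i) for (int d = 0; d < 3; ++d) c[d] += X[3*i+d];
    for (int d = 0; d < 3; ++d) c[d] /= N;
    double s = 0.0, dmax2 = 0.0;
    for (int i = 0; i < N; ++i) {
      for (int d = 0; d < 3; ++d) { double u = X[3*i+d] - c[d]; s += u*u; }
      for (int j = i + 1; j < N; ++j) {
        double r2 = 0.0;
        for (int d = 0; d < 3; ++d) { double u = X[3*i+d] - X[3*j+d]; r2 += u*u; }
        if (r2 > dmax2) dmax2 = r2;
      }
    }
    out(k, 0) = std::sqrt(s / N);
    out(k, 1) = std::sqrt(dmax2);
  }
  return out;
}

// ---------------------------------------------------------------- sampler ----

struct EParams {
  double ks, r0, kb, th0, hard2, kattr;
  std::vector<double> tc, tphi;
  std::vector<int> tn;
};

static inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

struct RNG {
  uint64_t s;
  explicit RNG(uint64_t seed) : s(seed) {}
  uint64_t next() { s = splitmix64(s) + 0x9E3779B97F4A7C15ULL; return splitmix64(s); }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int pick(int n) { return (int)(unif() * n) % n; }
  void sphere(double *u) {
    double n2;
    do {
      u[0] = 2.0 * unif() - 1.0; u[1] = 2.0 * unif() - 1.0; u[2] = 2.0 * unif() - 1.0;
      n2 = u[0]*u[0] + u[1]*u[1] + u[2]*u[2];
    } while (n2 < 1e-12 || n2 > 1.0);
    const double n = std::sqrt(n2);
    u[0] /= n; u[1] /= n; u[2] /= n;
  }
};

class CGEngine {
public:
  int N;
  std::vector<int> segId, unitId;                  // unitId 0 = flexible bead
  std::vector<std::array<int,2>> bonds;
  std::vector<std::array<int,3>> angles;
  std::vector<std::array<int,4>> torsions;
  std::unordered_set<int64_t> bondedSet;
  EParams ep;
  // moves
  std::vector<int> pivotCenter;
  std::vector<std::vector<int>> pivotMoved;
  std::vector<std::vector<int>> pivotBonds, pivotAngles, pivotTors;
  std::vector<std::array<int,3>> cranks;           // j, a, b
  std::vector<int> displBeads;
  std::vector<std::vector<int>> beadBonds, beadAngles, beadTors;
  std::vector<std::vector<int>> components;
  std::vector<std::vector<int>> unitMembers;       // 1-based unit id -> beads
  // amplitudes
  double aDispl, aPivot, aCrank, aRigidRot, aRigidTrans;
  double pCat[4];                                   // cumulative category probs
  int attempts;

  CGEngine(List layout, List epar, List amps) {
    IntegerVector seg = layout["segId"], unit = layout["unitId"];
    N = seg.size();
    segId.assign(seg.begin(), seg.end());
    unitId.assign(unit.begin(), unit.end());
    IntegerMatrix B = layout["bonds"], A = layout["angles"], T = layout["torsions"];
    for (int i = 0; i < B.nrow(); ++i) {
      std::array<int,2> b = {B(i,0)-1, B(i,1)-1}; bonds.push_back(b);
      int u = std::min(b[0], b[1]), v = std::max(b[0], b[1]);
      bondedSet.insert((int64_t)u * N + v);
    }
    for (int i = 0; i < A.nrow(); ++i) angles.push_back({A(i,0)-1, A(i,1)-1, A(i,2)-1});
    for (int i = 0; i < T.nrow(); ++i) torsions.push_back({T(i,0)-1, T(i,1)-1, T(i,2)-1, T(i,3)-1});

    ep.ks = as<double>(epar["ks"]); ep.r0 = as<double>(epar["r0"]);
    ep.kb = as<double>(epar["kb"]); ep.th0 = as<double>(epar["th0"]);
    double hr = as<double>(epar["hardRadius"]);
    ep.hard2 = 4.0 * hr * hr;
    ep.kattr = as<double>(epar["kattr"]);
    NumericVector tc = epar["tc"], tphi = epar["tphi"]; IntegerVector tn = epar["tn"];
    ep.tc.assign(tc.begin(), tc.end());
    ep.tphi.assign(tphi.begin(), tphi.end());
    ep.tn.assign(tn.begin(), tn.end());

    IntegerVector pc = layout["pivotCenter"];
    List pm = layout["pivotMoved"];
    for (int i = 0; i < pc.size(); ++i) {
      pivotCenter.push_back(pc[i] - 1);
      IntegerVector mv = pm[i];
      std::vector<int> v(mv.size());
      for (int j = 0; j < mv.size(); ++j) v[j] = mv[j] - 1;
      pivotMoved.push_back(v);
    }
    IntegerMatrix CK = layout["crank"];
    for (int i = 0; i < CK.nrow(); ++i) cranks.push_back({CK(i,0)-1, CK(i,1)-1, CK(i,2)-1});
    IntegerVector db = layout["displBeads"];
    for (int i = 0; i < db.size(); ++i) displBeads.push_back(db[i] - 1);
    List comps = layout["components"];
    for (int i = 0; i < comps.size(); ++i) {
      IntegerVector cv = comps[i];
      std::vector<int> v(cv.size());
      for (int j = 0; j < cv.size(); ++j) v[j] = cv[j] - 1;
      components.push_back(v);
    }
    List um = layout["unitMembers"];
    for (int i = 0; i < um.size(); ++i) {
      IntegerVector uv = um[i];
      std::vector<int> v(uv.size());
      for (int j = 0; j < uv.size(); ++j) v[j] = uv[j] - 1;
      unitMembers.push_back(v);
    }
    attempts = std::max(1, as<int>(layout["mobileDof"]));

    aDispl = as<double>(amps["displ"]); aPivot = as<double>(amps["pivot"]);
    aCrank = as<double>(amps["crank"]);
    aRigidRot = as<double>(amps["rigidRot"]); aRigidTrans = as<double>(amps["rigidTrans"]);

    // category weights, zeroed when a category has no instances
    double wcat[4] = {0.45 * (displBeads.size() > 0), 0.30 * (pivotCenter.size() > 0),
                      0.15 * (cranks.size() > 0), 0.10 * (components.size() > 0)};
    double tot = wcat[0] + wcat[1] + wcat[2] + wcat[3];
    if (tot <= 0) stop("no moves available");
    double c = 0.0;
    for (int i = 0; i < 4; ++i) { c += wcat[i] / tot; pCat[i] = c; }

    // per-move affected bonded terms
    std::vector<char> inM(N, 0);
    for (size_t p = 0; p < pivotMoved.size(); ++p) {
      for (int b : pivotMoved[p]) inM[b] = 1;
      std::vector<int> bi, ai, ti;
      for (size_t i = 0; i < bonds.size(); ++i) {
        int c1 = inM[bonds[i][0]] + inM[bonds[i][1]];
        if (c1 > 0 && c1 < 2) bi.push_back((int)i);
      }
      for (size_t i = 0; i < angles.size(); ++i) {
        int c1 = inM[angles[i][0]] + inM[angles[i][1]] + inM[angles[i][2]];
        if (c1 > 0 && c1 < 3) ai.push_back((int)i);
      }
      for (size_t i = 0; i < torsions.size(); ++i) {
        int c1 = inM[torsions[i][0]] + inM[torsions[i][1]] + inM[torsions[i][2]] + inM[torsions[i][3]];
        if (c1 > 0 && c1 < 4) ti.push_back((int)i);
      }
      pivotBonds.push_back(bi); pivotAngles.push_back(ai); pivotTors.push_back(ti);
      for (int b : pivotMoved[p]) inM[b] = 0;
    }
    beadBonds.assign(N, {}); beadAngles.assign(N, {}); beadTors.assign(N, {});
    for (size_t i = 0; i < bonds.size(); ++i)
      for (int d = 0; d < 2; ++d) beadBonds[bonds[i][d]].push_back((int)i);
    for (size_t i = 0; i < angles.size(); ++i)
      for (int d = 0; d < 3; ++d) beadAngles[angles[i][d]].push_back((int)i);
    for (size_t i = 0; i < torsions.size(); ++i)
      for (int d = 0; d < 4; ++d) beadTors[torsions[i][d]].push_back((int)i);
  }

  bool isBonded(int i, int j) const {
    int u = std::min(i, j), v = std::max(i, j);
    return bondedSet.count((int64_t)u * N + v) > 0;
  }

  double bondE(const double *X, int t) const {
    const int i = bonds[t][0], j = bonds[t][1];
    double r = 0.0;
    for (int d = 0; d < 3; ++d) { double u = X[3*i+d] - X[3*j+d]; r += u*u; }
    r = std::sqrt(r);
    const double dr = r - ep.r0;
    return 0.5 * ep.ks * dr * dr;
  }
  double angleE(const double *X, int t) const {
    const int i = angles[t][0], j = angles[t][1], k = angles[t][2];
    double a[3], b[3], na = 0.0, nb = 0.0, dot = 0.0;
    for (int d = 0; d < 3; ++d) {
      a[d] = X[3*i+d] - X[3*j+d]; b[d] = X[3*k+d] - X[3*j+d];
      na += a[d]*a[d]; nb += b[d]*b[d]; dot += a[d]*b[d];
    }
    double c = dot / std::sqrt(na * nb);
    if (c > 1.0) c = 1.0; if (c < -1.0) c = -1.0;
    const double dth = std::acos(c) - ep.th0;
    return 0.5 * ep.kb * dth * dth;
  }
  double torsE(const double *X, int t) const {
    const int i = torsions[t][0], j = torsions[t][1], k = torsions[t][2], l = torsions[t][3];
    double b1[3], b2[3], b3[3];
    for (int d = 0; d < 3; ++d) {
      b1[d] = X[3*j+d] - X[3*i+d];
      b2[d] = X[3*k+d] - X[3*j+d];
      b3[d] = X[3*l+d] - X[3*k+d];
    }
    double n1[3] = {b1[1]*b2[2]-b1[2]*b2[1], b1[2]*b2[0]-b1[0]*b2[2], b1[0]*b2[1]-b1[1]*b2[0]};
    double n2[3] = {b2[1]*b3[2]-b2[2]*b3[1], b2[2]*b3[0]-b2[0]*b3[2], b2[0]*b3[1]-b2[1]*b3[0]};
    double m1[3] = {n1[1]*n2[2]-n1[2]*n2[1], n1[2]*n2[0]-n1[0]*n2[2], n1[0]*n2[1]-n1[1]*n2[0]};
    double nb2 = std::sqrt(b2[0]*b2[0] + b2[1]*b2[1] + b2[2]*b2[2]);
    double x = n1[0]*n2[0] + n1[1]*n2[1] + n1[2]*n2[2];
    double y = (m1[0]*b2[0] + m1[1]*b2[1] + m1[2]*b2[2]) / (nb2 > 0 ? nb2 : 1.0);
    double phi = std::atan2(y, x);
    double e = 0.0;
    for (size_t n = 0; n < ep.tc.size(); ++n)
      e += ep.tc[n] * (1.0 + std::cos(ep.tn[n] * phi - ep.tphi[n]));
    return e;
  }

  double termsEnergy(const double *X, const std::vector<int> &bi,
                     const std::vector<int> &ai, const std::vector<int> &ti) const {
    double e = 0.0;
    for (int t : bi) e += bondE(X, t);
    for (int t : ai) e += angleE(X, t);
    for (int t : ti) e += torsE(X, t);
    return e;
  }

  // hard-core violation between moved beads and all static beads;
  // a bounding sphere around the moved set prunes most static beads
  bool clashMovedStatic(const double *X, const std::vector<int> &M,
                        const std::vector<char> &inM) const {
    double c[3] = {0, 0, 0};
    for (int i : M) for (int d = 0; d < 3; ++d) c[d] += X[3*i+d];
    for (int d = 0; d < 3; ++d) c[d] /= M.size();
    double rad2 = 0.0;
    for (int i : M) {
      double r2 = 0.0;
      for (int d = 0; d < 3; ++d) { double t = X[3*i+d] - c[d]; r2 += t*t; }
      if (r2 > rad2) rad2 = r2;
    }
    const double reach = std::sqrt(rad2) + std::sqrt(ep.hard2);
    const double reach2 = reach * reach;
    for (int j = 0; j < N; ++j) {
      if (inM[j]) continue;
      const double xj = X[3*j], yj = X[3*j+1], zj = X[3*j+2];
      {
        double dx = xj - c[0], dy = yj - c[1], dz = zj - c[2];
        if (dx*dx + dy*dy + dz*dz > reach2) continue;
      }
      const int uj = unitId[j];
      for (int i : M) {
        if (uj > 0 && unitId[i] == uj) continue;
        double dx = xj - X[3*i], dy = yj - X[3*i+1], dz = zj - X[3*i+2];
        double r2 = dx*dx + dy*dy + dz*dz;
        if (r2 < ep.hard2 && !isBonded(i, j)) return true;
      }
    }
    return false;
  }

  double fullEnergy(const double *X) const {
    double e = 0.0;
    for (size_t t = 0; t < bonds.size(); ++t) e += bondE(X, (int)t);
    for (size_t t = 0; t < angles.size(); ++t) e += angleE(X, (int)t);
    for (size_t t = 0; t < torsions.size(); ++t) e += torsE(X, (int)t);
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        if (unitId[i] > 0 && unitId[i] == unitId[j]) continue;
        double dx = X[3*i]-X[3*j], dy = X[3*i+1]-X[3*j+1], dz = X[3*i+2]-X[3*j+2];
        if (dx*dx + dy*dy + dz*dz < ep.hard2 && !isBonded(i, j))
          return R_PosInf;
      }
    if (ep.kattr > 0) e += attractEnergy(X);
    return e;
  }

  void unitCentroid(const double *X, int u, double *c) const {
    c[0] = c[1] = c[2] = 0.0;
    const std::vector<int> &mem = unitMembers[u];
    for (int i : mem) for (int d = 0; d < 3; ++d) c[d] += X[3*i+d];
    for (int d = 0; d < 3; ++d) c[d] /= mem.size();
  }
  double attractEnergy(const double *X) const {
    const int U = (int)unitMembers.size();
    if (U < 2) return 0.0;
    std::vector<double> cen(3 * U);
    for (int u = 0; u < U; ++u) unitCentroid(X, u, &cen[3*u]);
    double e = 0.0;
    for (int u = 0; u < U; ++u)
      for (int v = u + 1; v < U; ++v) {
        double r2 = 0.0;
        for (int d = 0; d < 3; ++d) { double t = cen[3*u+d] - cen[3*v+d]; r2 += t*t; }
        e += 0.5 * ep.kattr * r2;
      }
    return e;
  }
};

static void rotMatrix(const double *u, double t, double R[3][3]) {
  const double c = std::cos(t), s = std::sin(t), cc = 1.0 - c;
  R[0][0] = c + u[0]*u[0]*cc;     R[0][1] = u[0]*u[1]*cc - u[2]*s; R[0][2] = u[0]*u[2]*cc + u[1]*s;
  R[1][0] = u[1]*u[0]*cc + u[2]*s; R[1][1] = c + u[1]*u[1]*cc;     R[1][2] = u[1]*u[2]*cc - u[0]*s;
  R[2][0] = u[2]*u[0]*cc - u[1]*s; R[2][1] = u[2]*u[1]*cc + u[0]*s; R[2][2] = c + u[2]*u[2]*cc;
}

// [[Rcpp::export]]
double cpp_full_energy(NumericMatrix coords, List layout, List epar) {
  List amps = List::create(_["displ"] = 0.3, _["pivot"] = 0.5, _["crank"] = 1.0,
                           _["rigidRot"] = 0.3, _["rigidTrans"] = 2.0);
  CGEngine eng(layout, epar, amps);
  std::vector<double> X(3 * eng.N);
  for (int i = 0; i < eng.N; ++i) for (int d = 0; d < 3; ++d) X[3*i+d] = coords(i, d);
  return eng.fullEnergy(X.data());
}

// Replica-exchange MC. betas are reduced inverse temperatures (300 K ref).
// Returns saved frames from all replicas plus acceptance bookkeeping.
// [[Rcpp::export]]
List cpp_remc(NumericMatrix coords0, List layout, List epar, NumericVector betas,
              double nSweepsD, double saveEveryD, double exchangeEveryD,
              List amps, double seedD) {
  CGEngine eng(layout, epar, amps);
  const int N = eng.N, nrep = betas.size();
  const long nSweeps = (long)nSweepsD, saveEvery = (long)saveEveryD;
  const long exchangeEvery = (long)exchangeEveryD;
  const uint64_t seed = (uint64_t)seedD;

  std::vector<std::vector<double>> X(nrep, std::vector<double>(3 * N));
  std::vector<double> E(nrep);
  std::vector<RNG> rng;
  for (int r = 0; r < nrep; ++r) rng.emplace_back(splitmix64(seed ^ (0xA5A5A5A5ULL + r)));
  RNG xrng(splitmix64(seed ^ 0xDEADBEEFULL));

  for (int r = 0; r < nrep; ++r) {
    for (int i = 0; i < N; ++i) for (int d = 0; d < 3; ++d) X[r][3*i+d] = coords0(i, d);
    E[r] = eng.fullEnergy(X[r].data());
    if (!R_finite(E[r])) stop("initial conformation has infinite energy (steric clash)");
  }

  const long nSaves = nSweeps / saveEvery;
  NumericVector saved((size_t)nSaves * nrep * N * 3);
  IntegerVector savedRep(nSaves * nrep), savedSweep(nSaves * nrep);
  NumericVector savedE(nSaves * nrep);
  IntegerMatrix moveAtt(4, 1), moveAcc(4, 1);
  IntegerVector exchAtt(std::max(nrep - 1, 1)), exchAcc(std::max(nrep - 1, 1));

  std::vector<char> inM(N, 0);
  std::vector<double> backup;
  std::vector<int> singleSet(1);
  long parity = 0, saveIdx = 0;

  for (long sweep = 1; sweep <= nSweeps; ++sweep) {
    for (int rep = 0; rep < nrep; ++rep) {
      double *Xr = X[rep].data();
      const double beta = betas[rep];
      for (int att = 0; att < eng.attempts; ++att) {
        const double u = rng[rep].unif();
        int cat = 3;
        for (int c = 0; c < 4; ++c) if (u < eng.pCat[c]) { cat = c; break; }
        const std::vector<int> *M;
        const std::vector<int> *bi, *ai, *ti;
        static const std::vector<int> noTerms;
        double R[3][3], cen[3], trans[3] = {0,0,0};
        bool useRot = true;

        if (cat == 0) {            // single-bead displacement
          int j = eng.displBeads[rng[rep].pick((int)eng.displBeads.size())];
          singleSet[0] = j;
          M = &singleSet; bi = &eng.beadBonds[j]; ai = &eng.beadAngles[j]; ti = &eng.beadTors[j];
          useRot = false;
          for (int d = 0; d < 3; ++d) trans[d] = eng.aDispl * (2.0 * rng[rep].unif() - 1.0);
        } else if (cat == 1) {     // pivot
          int p = rng[rep].pick((int)eng.pivotCenter.size());
          M = &eng.pivotMoved[p]; bi = &eng.pivotBonds[p]; ai = &eng.pivotAngles[p]; ti = &eng.pivotTors[p];
          double axis[3]; rng[rep].sphere(axis);
          rotMatrix(axis, eng.aPivot * (2.0 * rng[rep].unif() - 1.0), R);
          const int c0 = eng.pivotCenter[p];
          for (int d = 0; d < 3; ++d) cen[d] = Xr[3*c0+d];
        } else if (cat == 2) {     // crankshaft
          int c0 = rng[rep].pick((int)eng.cranks.size());
          int j = eng.cranks[c0][0], a = eng.cranks[c0][1], b = eng.cranks[c0][2];
          singleSet[0] = j;
          M = &singleSet; bi = &eng.beadBonds[j]; ai = &eng.beadAngles[j]; ti = &eng.beadTors[j];
          double axis[3]; double nn = 0.0;
          for (int d = 0; d < 3; ++d) { axis[d] = Xr[3*b+d] - Xr[3*a+d]; nn += axis[d]*axis[d]; }
          nn = std::sqrt(nn);
          if (nn < 1e-10) continue;
          for (int d = 0; d < 3; ++d) axis[d] /= nn;
          rotMatrix(axis, eng.aCrank * (2.0 * rng[rep].unif() - 1.0), R);
          for (int d = 0; d < 3; ++d) cen[d] = Xr[3*a+d];
        } else {                   // whole-component rigid move
          int c0 = rng[rep].pick((int)eng.components.size());
          M = &eng.components[c0]; bi = &noTerms; ai = &noTerms; ti = &noTerms;
          double axis[3]; rng[rep].sphere(axis);
          rotMatrix(axis, eng.aRigidRot * (2.0 * rng[rep].unif() - 1.0), R);
          cen[0] = cen[1] = cen[2] = 0.0;
          for (int i : *M) for (int d = 0; d < 3; ++d) cen[d] += Xr[3*i+d];
          for (int d = 0; d < 3; ++d) cen[d] /= M->size();
          for (int d = 0; d < 3; ++d) trans[d] = eng.aRigidTrans * (2.0 * rng[rep].unif() - 1.0);
        }

        moveAtt(cat, 0)++;
        double attrBefore = 0.0;
        if (eng.ep.kattr > 0) attrBefore = eng.attractEnergy(Xr);
        const double eBefore = eng.termsEnergy(Xr, *bi, *ai, *ti);

        backup.resize(3 * M->size());
        size_t bb = 0;
        for (int i : *M) { for (int d = 0; d < 3; ++d) backup[bb++] = Xr[3*i+d]; inM[i] = 1; }
        for (int i : *M) {
          double v[3] = {Xr[3*i], Xr[3*i+1], Xr[3*i+2]};
          if (useRot) {
            double w[3] = {v[0]-cen[0], v[1]-cen[1], v[2]-cen[2]};
            for (int d = 0; d < 3; ++d)
              v[d] = cen[d] + R[d][0]*w[0] + R[d][1]*w[1] + R[d][2]*w[2] + trans[d];
          } else {
            for (int d = 0; d < 3; ++d) v[d] += trans[d];
          }
          Xr[3*i] = v[0]; Xr[3*i+1] = v[1]; Xr[3*i+2] = v[2];
        }

        bool reject = eng.clashMovedStatic(Xr, *M, inM);
        double dE = 0.0;
        if (!reject) {
          dE = eng.termsEnergy(Xr, *bi, *ai, *ti) - eBefore;
          if (eng.ep.kattr > 0) dE += eng.attractEnergy(Xr) - attrBefore;
          if (dE > 0 && rng[rep].unif() >= std::exp(-beta * dE)) reject = true;
        }
        if (reject) {
          bb = 0;
          for (int i : *M) { for (int d = 0; d < 3; ++d) Xr[3*i+d] = backup[bb++]; }
        } else {
          E[rep] += dE;
          moveAcc(cat, 0)++;
        }
        for (int i : *M) inM[i] = 0;
      }
    }

    if (nrep > 1 && exchangeEvery > 0 && sweep % exchangeEvery == 0) {
      for (int i = (int)(parity % 2); i + 1 < nrep; i += 2) {
        exchAtt[i]++;
        const double del = (betas[i] - betas[i+1]) * (E[i] - E[i+1]);
        if (del >= 0 || xrng.unif() < std::exp(del)) {
          std::swap(X[i], X[i+1]); std::swap(E[i], E[i+1]);
          exchAcc[i]++;
        }
      }
      parity++;
    }

    if (sweep % saveEvery == 0) {
      for (int rep = 0; rep < nrep; ++rep) {
        double *dst = &saved[(size_t)saveIdx * N * 3];
        for (int i = 0; i < 3 * N; ++i) dst[i] = X[rep][i];
        savedRep[saveIdx] = rep + 1;
        savedSweep[saveIdx] = (int)sweep;
        savedE[saveIdx] = E[rep];
        ++saveIdx;
      }
    }
    if (sweep % 256 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix finalX(N, 3 * nrep);
  for (int rep = 0; rep < nrep; ++rep)
    for (int i = 0; i < N; ++i)
      for (int d = 0; d < 3; ++d) finalX(i, 3*rep + d) = X[rep][3*i+d];

  return List::create(
    _["coords"] = saved, _["replica"] = savedRep, _["sweep"] = savedSweep,
    _["energy"] = savedE, _["moveAtt"] = moveAtt, _["moveAcc"] = moveAcc,
    _["exchAtt"] = exchAtt, _["exchAcc"] = exchAcc,
    _["finalCoords"] = finalX, _["finalEnergy"] = NumericVector(E.begin(), E.end()));
}
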