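// Metropolis Monte Carlo core for the coarse-grained genome model.
//
// Energy surface: harmonic bonds, Kratky-Porod bending, soft-core excluded
// volume, harmonic confinement / nucleolar-exclusion penalties,
// flat-bottomed anchor wells and flat-bottomed contact springs.  Hard
// constraints (confinement, nucleolar exclusion, bond-length window,
// excluded-volume floor) are enforced by rejecting violating moves, so a
// feasible input conformation stays feasible throughout.
//
// All randomness comes from R's RNG (RNGScope), so set.seed() in R makes
// every run reproducible.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

struct Geom {
  double R, rg, nucR;
  double nucC[3], spb[3];
  double spbZone, periWidth, nucSurfWidth;
};

struct Params {
  double kBond, b0, kappa, kEx, kConf, kContact, contactRest;
  double evFloor;   // hard minimum non-bonded centre distance
  double bondLo, bondHi;
};

static inline double dist2_(const double* a, const double* b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}
static inline double dist3(const double* a, const double* b) {
  return std::sqrt(dist2_(a, b));
}
static inline double norm3(const double* a) {
  return std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
}

class Model {
public:
  int n;
  std::vector<double> x;            // n*3, row-major
  std::vector<int> chrom;           // 1-based chromosome id per granule
  Geom g;
  Params p;
  // contacts
  std::vector<int> ci, cj;
  std::vector<std::vector<int>> cAdj;   // per-granule contact partner list
  // anchors: target 1=SPB_zone 2=periphery 3=nucleolar_surface
  std::vector<int> aG, aT;
  std::vector<double> aK;
  std::vector<int> anchorOf;            // -1 or index into aG

  Model(NumericMatrix coords, IntegerVector chromId, List geom, List params,
        IntegerMatrix pairs, IntegerVector anchorG, IntegerVector anchorT,
        NumericVector anchorK) {
    n = coords.nrow();
    x.resize(n * 3);
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) x[3 * i + k] = coords(i, k);
    chrom.assign(chromId.begin(), chromId.end());

    g.R = as<double>(geom["R"]);
    g.rg = as<double>(geom["rg"]);
    g.nucR = as<double>(geom["nucRadius"]);
    NumericVector nc = geom["nucCenter"], sp = geom["spb"];
    for (int k = 0; k < 3; ++k) { g.nucC[k] = nc[k]; g.spb[k] = sp[k]; }
    g.spbZone = as<double>(geom["spbZoneRadius"]);
    g.periWidth = as<double>(geom["peripheryWidth"]);
    g.nucSurfWidth = as<double>(geom["nucleolarSurfaceWidth"]);

    p.kBond = as<double>(params["kBond"]);
    p.b0 = as<double>(params["bondLength"]);
    p.kappa = as<double>(params["kappa"]);
    p.kEx = as<double>(params["kExcluded"]);
    p.kConf = as<double>(params["kConfine"]);
    p.kContact = as<double>(params["kContact"]);
    p.contactRest = as<double>(params["contactRest"]);
    p.evFloor = 0.99 * 2.0 * g.rg;
    p.bondLo = 0.8 * p.b0;
    p.bondHi = 1.2 * p.b0;

    cAdj.assign(n, {});
    for (int r = 0; r < pairs.nrow(); ++r) {
      int a = pairs(r, 0) - 1, b = pairs(r, 1) - 1;
      ci.push_back(a); cj.push_back(b);
      cAdj[a].push_back(b); cAdj[b].push_back(a);
    }
    anchorOf.assign(n, -1);
    for (int a = 0; a < anchorG.size(); ++a) {
      aG.push_back(anchorG[a] - 1);
      aT.push_back(anchorT[a]);
      aK.push_back(anchorK[a]);
      anchorOf[anchorG[a] - 1] = a;
    }
  }

  inline bool bonded(int a, int b) const {
    return std::abs(a - b) == 1 && chrom[a] == chrom[b];
  }

  // --- individual energy terms -------------------------------------------
  double bondTerm(const double* X, int a, int b) const {
    double d = dist3(X + 3 * a, X + 3 * b) - p.b0;
    return 0.5 * p.kBond * d * d;
  }
  // bending at interior granule m (angle between bonds m-1->m and m->m+1)
  double bendTerm(const double* X, int m) const {
    const double *a = X + 3 * (m - 1), *b = X + 3 * m, *c = X + 3 * (m + 1);
    double u[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
    double v[3] = { c[0] - b[0], c[1] - b[1], c[2] - b[2] };
    double nu = norm3(u), nv = norm3(v);
    if (nu < 1e-12 || nv < 1e-12) return 0.0;
    double ct = (u[0] * v[0] + u[1] * v[1] + u[2] * v[2]) / (nu * nv);
    if (ct > 1) ct = 1;
    if (ct < -1) ct = -1;
    return p.kappa * (1.0 - ct);
  }
  double evTerm(const double* X, int a, int b) const {
    double dm = 2.0 * g.rg;
    double d2 = dist2_(X + 3 * a, X + 3 * b);
    if (d2 >= dm * dm) return 0.0;
    double s = dm - std::sqrt(d2);
    return 0.5 * p.kEx * s * s;
  }
  double confTerm(const double* X, int i) const {
    double r = norm3(X + 3 * i), lim = g.R - g.rg;
    if (r <= lim) return 0.0;
    double d = r - lim;
    return 0.5 * p.kConf * d * d;
  }
  double nucTerm(const double* X, int i) const {
    if (g.nucR <= 0) return 0.0;
    double d = dist3(X + 3 * i, g.nucC), lim = g.nucR + g.rg;
    if (d >= lim) return 0.0;
    double s = lim - d;
    return 0.5 * p.kConf * s * s;
  }
  // distance outside the anchor region (0 inside)
  double anchorDelta(const double* X, int a) const {
    const double* xi = X + 3 * aG[a];
    if (aT[a] == 1) {                       // SPB zone
      double d = dist3(xi, g.spb);
      return d > g.spbZone ? d - g.spbZone : 0.0;
    } else if (aT[a] == 2) {                // peripheral shell
      double r = norm3(xi), lim = g.R - g.periWidth;
      return r < lim ? lim - r : 0.0;
    } else {                                // nucleolar surface shell
      double d = dist3(xi, g.nucC), lim = g.nucR + g.nucSurfWidth + g.rg;
      return d > lim ? d - lim : 0.0;
    }
  }
  double anchorTerm(const double* X, int a) const {
    double d = anchorDelta(X, a);
    return 0.5 * aK[a] * d * d;
  }
  double contactTerm(const double* X, int a, int b) const {
    double d2 = dist2_(X + 3 * a, X + 3 * b);
    if (d2 <= p.contactRest * p.contactRest) return 0.0;
    double s = std::sqrt(d2) - p.contactRest;
    return 0.5 * p.kContact * s * s;
  }

  // --- total energy with per-term breakdown ------------------------------
  NumericVector totalEnergy(const double* X) const {
    double eb = 0, ea = 0, ee = 0, ec = 0, en = 0, et = 0, ek = 0;
    for (int i = 0; i + 1 < n; ++i)
      if (bonded(i, i + 1)) eb += bondTerm(X, i, i + 1);
    for (int m = 1; m + 1 < n; ++m)
      if (bonded(m - 1, m) && bonded(m, m + 1)) ea += bendTerm(X, m);
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j)
        if (!bonded(i, j)) ee += evTerm(X, i, j);
      ec += confTerm(X, i);
      en += nucTerm(X, i);
    }
    for (size_t a = 0; a < aG.size(); ++a) et += anchorTerm(X, (int)a);
    for (size_t c = 0; c < ci.size(); ++c) ek += contactTerm(X, ci[c], cj[c]);
    return NumericVector::create(
      _["bond"] = eb, _["bending"] = ea, _["excluded"] = ee,
      _["confinement"] = ec, _["nucleolus"] = en, _["anchor"] = et,
      _["contact"] = ek,
      _["total"] = eb + ea + ee + ec + en + et + ek);
  }

  // --- feasibility (hard constraints) for granules in the moved set ------
  bool feasibleSet(const double* X, const std::vector<int>& M,
                   const std::vector<char>& inM) const {
    const double rlim = g.R - g.rg + 1e-9, rlim2 = rlim * rlim;
    const double nlim = g.nucR + g.rg - 1e-9;
    const double nlim2 = nlim > 0 ? nlim * nlim : -1.0;
    const double lo2 = p.bondLo * p.bondLo, hi2 = p.bondHi * p.bondHi;
    const double ev2 = p.evFloor * p.evFloor;
    const double origin[3] = { 0, 0, 0 };
    for (int m : M) {
      const double* xm = X + 3 * m;
      if (dist2_(xm, origin) > rlim2) return false;
      if (g.nucR > 0 && dist2_(xm, g.nucC) < nlim2) return false;
      if (m > 0 && bonded(m - 1, m)) {
        double d2 = dist2_(X + 3 * (m - 1), xm);
        if (d2 < lo2 || d2 > hi2) return false;
      }
      if (m + 1 < n && bonded(m, m + 1)) {
        double d2 = dist2_(xm, X + 3 * (m + 1));
        if (d2 < lo2 || d2 > hi2) return false;
      }
      for (int j = 0; j < n; ++j) {
        if (j == m || bonded(m, j)) continue;
        if (inM[j] && j < m) continue;   // moved-moved pair counted once
        if (dist2_(xm, X + 3 * j) < ev2) return false;
      }
    }
    return true;
  }

  // energy of all terms touching the moved set M
  double localEnergy(const double* X, const std::vector<int>& M,
                     const std::vector<char>& inM) const {
    double e = 0;
    for (int m : M) {
      if (m > 0 && bonded(m - 1, m) && !inM[m - 1])
        e += bondTerm(X, m - 1, m);
      if (m + 1 < n && bonded(m, m + 1) && !inM[m + 1])
        e += bondTerm(X, m, m + 1);
      e += confTerm(X, m) + nucTerm(X, m);
      if (anchorOf[m] >= 0) e += anchorTerm(X, anchorOf[m]);
      for (int b : cAdj[m])
        if (!inM[b] || b > m) e += contactTerm(X, m, b);
      for (int j = 0; j < n; ++j) {
        if (j == m || bonded(m, j)) continue;
        if (inM[j] && j < m) continue;
        e += evTerm(X, m, j);
      }
    }
    // bonds internal to M (count once)
    for (int m : M)
      if (m + 1 < n && bonded(m, m + 1) && inM[m + 1])
        e += bondTerm(X, m, m + 1);
    // bending angles touching M
    std::vector<char> seen(n, 0);
    for (int m : M)
      for (int c = m - 1; c <= m + 1; ++c) {
        if (c < 1 || c + 1 >= n || seen[c]) continue;
        if (bonded(c - 1, c) && bonded(c, c + 1)) {
          e += bendTerm(X, c);
          seen[c] = 1;
        }
      }
    return e;
  }
};

static void rodrigues(const double* axis, double angle, const double* v,
                      double* out) {
  double c = std::cos(angle), s = std::sin(angle);
  double k0 = axis[0], k1 = axis[1], k2 = axis[2];
  double cx0 = k1 * v[2] - k2 * v[1];
  double cx1 = k2 * v[0] - k0 * v[2];
  double cx2 = k0 * v[1] - k1 * v[0];
  double dot = k0 * v[0] + k1 * v[1] + k2 * v[2];
  out[0] = v[0] * c + cx0 * s + k0 * dot * (1 - c);
  out[1] = v[1] * c + cx1 * s + k1 * dot * (1 - c);
  out[2] = v[2] * c + cx2 * s + k2 * dot * (1 - c);
}

static void randAxis(double* ax) {
  double nrm = 0;
  do {
    for (int k = 0; k < 3; ++k) ax[k] = norm_rand();
    nrm = norm3(ax);
  } while (nrm < 1e-12);
  for (int k = 0; k < 3; ++k) ax[k] /= nrm;
}

// [[Rcpp::export]]
NumericVector cpp_total_energy(NumericMatrix coords, IntegerVector chromId,
                               List geom, List params, IntegerMatrix pairs,
                               IntegerVector anchorG, IntegerVector anchorT,
                               NumericVector anchorK) {
  Model m(coords, chromId, geom, params, pairs, anchorG, anchorT, anchorK);
  return m.totalEnergy(m.x.data());
}

// [[Rcpp::export]]
List cpp_mc_optimize(NumericMatrix coords, IntegerVector chromId, List geom,
                     List params, IntegerMatrix pairs, IntegerVector anchorG,
                     IntegerVector anchorT, NumericVector anchorK,
                     List schedule) {
  RNGScope scope;
  Model M(coords, chromId, geom, params, pairs, anchorG, anchorT, anchorK);
  const int n = M.n;

  double T0 = as<double>(schedule["t0"]);
  double alpha = as<double>(schedule["alpha"]);
  int nTemps = as<int>(schedule["nTemps"]);
  int sweeps = as<int>(schedule["sweepsPerTemp"]);
  double maxStep = as<double>(schedule["maxStep"]);
  double pCrank = as<double>(schedule["pCrank"]);
  double pPivot = as<double>(schedule["pPivot"]);
  double pTrans = as<double>(schedule["pTrans"]);
  double pivotMaxAngle = as<double>(schedule["pivotMaxAngle"]);
  double transMaxStep = as<double>(schedule["transMaxStep"]);

  // chromosome extents (granules are grouped by chromosome id)
  std::vector<int> chrStart, chrEnd;
  for (int i = 0; i < n; ++i) {
    if (i == 0 || M.chrom[i] != M.chrom[i - 1]) chrStart.push_back(i);
    if (i == n - 1 || M.chrom[i] != M.chrom[i + 1]) chrEnd.push_back(i);
  }
  int nChrom = chrStart.size();

  std::vector<double>& x = M.x;
  std::vector<double> xNew(x);
  std::vector<char> inM(n, 0);
  long nAccept = 0, nAttempt = 0;

  for (int t = 0; t < nTemps; ++t) {
    double T = T0 * std::pow(alpha, t);
    for (int sw = 0; sw < sweeps; ++sw) {
      for (int mv = 0; mv < n; ++mv) {
        ++nAttempt;
        double u = unif_rand();
        std::vector<int> Mset;
        if (u < pTrans && nChrom > 0) {
          // rigid translation of one whole chromosome
          int c = (int)(unif_rand() * nChrom);
          if (c >= nChrom) c = nChrom - 1;
          double dx[3];
          for (int k = 0; k < 3; ++k)
            dx[k] = (2 * unif_rand() - 1) * transMaxStep;
          for (int i = chrStart[c]; i <= chrEnd[c]; ++i) {
            Mset.push_back(i);
            for (int k = 0; k < 3; ++k) xNew[3 * i + k] = x[3 * i + k] + dx[k];
          }
        } else if (u < pTrans + pPivot) {
          // pivot: rotate a short chain tail (<= maxPivotTail granules)
          // about a granule near one end; short tails keep the move cheap
          // and acceptable in crowded conformations
          const int maxPivotTail = 20;
          int c = (int)(unif_rand() * nChrom);
          if (c >= nChrom) c = nChrom - 1;
          int len = chrEnd[c] - chrStart[c] + 1;
          if (len < 3) continue;
          int tlen = 1 + (int)(unif_rand() * std::min(maxPivotTail, len - 2));
          bool tail = unif_rand() < 0.5;
          int lo, hi, piv;
          if (tail) { piv = chrEnd[c] - tlen; lo = piv + 1; hi = chrEnd[c]; }
          else { piv = chrStart[c] + tlen; lo = chrStart[c]; hi = piv - 1; }
          if (lo > hi || piv < chrStart[c] || piv > chrEnd[c]) continue;
          double ax[3]; randAxis(ax);
          double ang = (2 * unif_rand() - 1) * pivotMaxAngle;
          const double* origin = x.data() + 3 * piv;
          for (int i = lo; i <= hi; ++i) {
            Mset.push_back(i);
            double v[3] = { x[3 * i] - origin[0], x[3 * i + 1] - origin[1],
                            x[3 * i + 2] - origin[2] };
            double w[3]; rodrigues(ax, ang, v, w);
            for (int k = 0; k < 3; ++k) xNew[3 * i + k] = origin[k] + w[k];
          }
        } else if (u < pTrans + pPivot + pCrank) {
          // crankshaft: rotate one interior granule about its neighbour axis
          int gidx = (int)(unif_rand() * n);
          if (gidx >= n) gidx = n - 1;
          if (gidx == 0 || gidx == n - 1 ||
              !M.bonded(gidx - 1, gidx) || !M.bonded(gidx, gidx + 1))
            continue;
          const double* a = x.data() + 3 * (gidx - 1);
          const double* b = x.data() + 3 * (gidx + 1);
          double ax[3] = { b[0] - a[0], b[1] - a[1], b[2] - a[2] };
          double nrm = norm3(ax);
          if (nrm < 1e-9) continue;
          for (int k = 0; k < 3; ++k) ax[k] /= nrm;
          double ang = (2 * unif_rand() - 1) * M_PI;
          double v[3] = { x[3 * gidx] - a[0], x[3 * gidx + 1] - a[1],
                          x[3 * gidx + 2] - a[2] };
          double w[3]; rodrigues(ax, ang, v, w);
          Mset.push_back(gidx);
          for (int k = 0; k < 3; ++k) xNew[3 * gidx + k] = a[k] + w[k];
        } else {
          // single-granule displacement
          int gidx = (int)(unif_rand() * n);
          if (gidx >= n) gidx = n - 1;
          Mset.push_back(gidx);
          for (int k = 0; k < 3; ++k)
            xNew[3 * gidx + k] = x[3 * gidx + k] +
              (2 * unif_rand() - 1) * maxStep;
        }
        if (Mset.empty()) continue;
        for (int i : Mset) inM[i] = 1;
        bool ok = M.feasibleSet(xNew.data(), Mset, inM);
        if (ok) {
          double eOld = M.localEnergy(x.data(), Mset, inM);
          double eNew = M.localEnergy(xNew.data(), Mset, inM);
          double dE = eNew - eOld;
          if (dE <= 0 || unif_rand() < std::exp(-dE / T)) {
            for (int i : Mset)
              for (int k = 0; k < 3; ++k) x[3 * i + k] = xNew[3 * i + k];
            ++nAccept;
            ok = true;
          } else ok = false;
        }
        if (!ok)
          for (int i : Mset)
            for (int k = 0; k < 3; ++k) xNew[3 * i + k] = x[3 * i + k];
        for (int i : Mset) inM[i] = 0;
      }
    }
  }

  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = x[3 * i + k];
  NumericVector terms = M.totalEnergy(x.data());
  return List::create(_["coords"] = out, _["energy"] = terms,
                      _["acceptRate"] = nAttempt ? (double)nAccept / nAttempt
                                                 : NA_REAL);
}

// [[Rcpp::export]]
IntegerVector cpp_hard_violations(NumericMatrix coords, IntegerVector chromId,
                                  List geom, List params) {
  Model M(coords, chromId, geom, params,
          IntegerMatrix(0, 2), IntegerVector(0), IntegerVector(0),
          NumericVector(0));
  int conf = 0, nuc = 0, bond = 0, ev = 0;
  const double* X = M.x.data();
  for (int i = 0; i < M.n; ++i) {
    if (norm3(X + 3 * i) > M.g.R - M.g.rg + 1e-6) ++conf;
    if (M.g.nucR > 0 &&
        dist3(X + 3 * i, M.g.nucC) < M.g.nucR + M.g.rg - 1e-6) ++nuc;
    if (i + 1 < M.n && M.bonded(i, i + 1)) {
      double d = dist3(X + 3 * i, X + 3 * (i + 1));
      if (d < M.p.bondLo - 1e-6 || d > M.p.bondHi + 1e-6) ++bond;
    }
    for (int j = i + 1; j < M.n; ++j)
      if (!M.bonded(i, j) &&
          dist3(X + 3 * i, X + 3 * j) < M.p.evFloor - 1e-6) ++ev;
  }
  return IntegerVector::create(_["confinement"] = conf, _["nucleolus"] = nuc,
                               _["bond"] = bond, _["excluded"] = ev);
}
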