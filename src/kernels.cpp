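#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Atom-kind codes used throughout the point-cloud machinery:
// 0 = N, 1 = CA, 2 = C, 3 = O, 4 = CB.

// cfg layout (see ccs_kernel_cfg() on the R side):
// [0] overlap_fraction  [1] n_o_clash_distance  [2] cb_contact_cutoff
// [3] hb_lo  [4] hb_hi  [5] lj_eps  [6] lj_cap  [7] lj_cutoff
// [8] contact_switch_lo [9] contact_switch_hi  [10] sr_separation

static const int T_CLASH = 0, T_HBSR = 1, T_HBLR = 2, T_CBSTEP = 3,
                 T_LJ = 4, T_CBSMOOTH = 5, N_TERMS = 6;

static inline void accumulate_pair(const double* ax, const double* ay,
                                   const double* az, const int* ka,
                                   const double* ra, const double* da,
                                   const int* ia, const double* aox,
                                   const double* aoy, const double* aoz,
                                   int na,
                                   const double* bx, const double* by,
                                   const double* bz, const int* kb,
                                   const double* rb, const double* db,
                                   const int* ib, const double* box,
                                   const double* boy, const double* boz,
                                   int nb,
                                   const double* cfg, bool clash_only,
                                   double* terms, bool* stop) {
  const double maxr = cfg[7] > cfg[2] ? cfg[7] : cfg[2];
  const double maxr2 = maxr * maxr;
  const double one_minus_ov = 1.0 - cfg[0];
  // truncated-and-shifted LJ: subtract the value at the cutoff
  const double eps = cfg[5], ljcut = cfg[7];
  for (int i = 0; i < na; ++i) {
    const double xi = ax[i], yi = ay[i], zi = az[i];
    const int ki = ka[i];
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - bx[j], dy = yi - by[j], dz = zi - bz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > maxr2) continue;
      const double d = std::sqrt(d2);
      const int kj = kb[j];
      const bool n_o = (ki == 0 && kj == 3) || (ki == 3 && kj == 0);
      const double rsum = ra[i] + rb[j];
      const double clash_d = n_o ? cfg[1] : one_minus_ov * rsum;
      if (d < clash_d) {
        terms[T_CLASH] += 1.0;
        if (clash_only) { *stop = true; return; }
      }
      if (clash_only) continue;
      if (d < ljcut && d > 1e-6) {
        const double q = rsum / d, qc = rsum / ljcut;
        const double q6 = q * q * q * q * q * q;
        const double qc6 = qc * qc * qc * qc * qc * qc;
        double e = eps * (q6 * q6 - 2.0 * q6) - eps * (qc6 * qc6 - 2.0 * qc6);
        if (e > cfg[6]) e = cfg[6];
        terms[T_LJ] += e;
      }
      if (n_o && d >= cfg[3] && d <= cfg[4]) {
        // donor N ... acceptor O with carbonyl direction stored on the O
        double ux, uy, uz, vx, vy, vz;
        if (ki == 3) { // i is the acceptor
          ux = aox[i]; uy = aoy[i]; uz = aoz[i];
          vx = -dx / d; vy = -dy / d; vz = -dz / d; // O -> N
        } else {       // j is the acceptor
          ux = box[j]; uy = boy[j]; uz = boz[j];
          vx = dx / d; vy = dy / d; vz = dz / d;
        }
        const double dot = ux * vx + uy * vy + uz * vz;
        if (dot > 0) {
          double w = std::sin(M_PI * (d - cfg[3]) / (cfg[4] - cfg[3]));
          w *= w;
          const double e = -w * dot * dot;
          if (std::abs(ia[i] - ib[j]) < cfg[10]) terms[T_HBSR] += e;
          else terms[T_HBLR] += e;
        }
      }
      if (ki == 4 && kj == 4 && d <= cfg[2]) {
        const double wd = da[i] * db[j];
        terms[T_CBSTEP] += wd;
        double s = 1.0;
        if (d >= cfg[8])
          s = 0.5 * (1.0 + std::cos(M_PI * (d - cfg[8]) / (cfg[9] - cfg[8])));
        terms[T_CBSMOOTH] += wd * s;
      }
    }
  }
}

// Interaction terms between two rigid copies of a point cloud (or two
// different clouds), coordinates given in absolute space.
// [[Rcpp::export]]
NumericVector cpp_pair_terms(NumericMatrix xa, IntegerVector ka,
                             NumericVector ra, NumericVector da,
                             IntegerVector ia, NumericMatrix oa,
                             NumericMatrix xb, IntegerVector kb,
                             NumericVector rb, NumericVector db,
                             IntegerVector ib, NumericMatrix ob,
                             NumericVector cfg, bool clash_only = false) {
  const int na = xa.nrow(), nb = xb.nrow();
  std::vector<double> AX(na), AY(na), AZ(na), BX(nb), BY(nb), BZ(nb);
  std::vector<double> AOX(na), AOY(na), AOZ(na), BOX(nb), BOY(nb), BOZ(nb);
  for (int i = 0; i < na; ++i) {
    AX[i] = xa(i, 0); AY[i] = xa(i, 1); AZ[i] = xa(i, 2);
    AOX[i] = oa(i, 0); AOY[i] = oa(i, 1); AOZ[i] = oa(i, 2);
  }
  for (int j = 0; j < nb; ++j) {
    BX[j] = xb(j, 0); BY[j] = xb(j, 1); BZ[j] = xb(j, 2);
    BOX[j] = ob(j, 0); BOY[j] = ob(j, 1); BOZ[j] = ob(j, 2);
  }
  NumericVector out(N_TERMS);
  double terms[N_TERMS] = {0, 0, 0, 0, 0, 0};
  bool stop = false;
  accumulate_pair(AX.data(), AY.data(), AZ.data(), INTEGER(ka), REAL(ra),
                  REAL(da), INTEGER(ia), AOX.data(), AOY.data(), AOZ.data(),
                  na, BX.data(), BY.data(), BZ.data(), INTEGER(kb), REAL(rb),
                  REAL(db), INTEGER(ib), BOX.data(), BOY.data(), BOZ.data(),
                  nb, REAL(cfg), clash_only, terms, &stop);
  for (int t = 0; t < N_TERMS; ++t) out[t] = terms[t];
  return out;
}

static inline void rot_apply(const double R[9], double x, double y, double z,
                             double* ox, double* oy, double* oz) {
  *ox = R[0] * x + R[1] * y + R[2] * z;
  *oy = R[3] * x + R[4] * y + R[5] * z;
  *oz = R[6] * x + R[7] * y + R[8] * z;
}

static void rot_mult(const double A[9], const double B[9], double C[9]) {
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      C[3 * i + j] = 0;
      for (int k = 0; k < 3; ++k) C[3 * i + j] += A[3 * i + k] * B[3 * k + j];
    }
}

// Score the main subunit of a symmetric placement against all its partner
// copies. `pts` are subunit points centered on the subunit center of mass;
// `rots` holds the K point-group rotations stacked row-wise (3K x 3), the
// identity among them (it is skipped). Placement: intrinsic Z-Y-Z Euler
// rotation about the COM, optional 180-degree flip about x, translation to
// (x, 0, z), rotation by lambda about z, then group expansion.
// Returns the six pair terms plus the number of partner chains evaluated.
// [[Rcpp::export]]
NumericVector cpp_score_placement(NumericMatrix pts, IntegerVector kind,
                                  NumericVector radius, NumericVector density,
                                  IntegerVector resi, NumericMatrix odir,
                                  NumericMatrix rots, NumericVector par,
                                  int flip, NumericVector cfg,
                                  bool clash_only = false) {
  const int n = pts.nrow();
  const int K = rots.nrow() / 3;
  const double d2r = M_PI / 180.0;
  const double cps = std::cos(par[0] * d2r), sps = std::sin(par[0] * d2r);
  const double cth = std::cos(par[1] * d2r), sth = std::sin(par[1] * d2r);
  const double cph = std::cos(par[2] * d2r), sph = std::sin(par[2] * d2r);
  const double cla = std::cos(par[5] * d2r), sla = std::sin(par[5] * d2r);
  const double Rzpsi[9] = {cps, -sps, 0, sps, cps, 0, 0, 0, 1};
  const double Ryth[9] = {cth, 0, sth, 0, 1, 0, -sth, 0, cth};
  const double Rzphi[9] = {cph, -sph, 0, sph, cph, 0, 0, 0, 1};
  const double Rzlam[9] = {cla, -sla, 0, sla, cla, 0, 0, 0, 1};
  double E1[9], E[9], M[9], R0[9];
  rot_mult(Ryth, Rzphi, E1);
  rot_mult(Rzpsi, E1, E);
  if (flip) { // 180-degree turn about the global x axis through the COM
    const double Rx180[9] = {1, 0, 0, 0, -1, 0, 0, 0, -1};
    rot_mult(Rx180, E, M);
  } else {
    for (int i = 0; i < 9; ++i) M[i] = E[i];
  }
  rot_mult(Rzlam, M, R0);
  double t0[3];
  rot_apply(Rzlam, par[4], 0.0, par[3], &t0[0], &t0[1], &t0[2]);

  std::vector<double> X(n), Y(n), Z(n), OX(n), OY(n), OZ(n);
  double rb = 0; // bounding radius of the centered subunit
  for (int i = 0; i < n; ++i) {
    double x, y, z;
    rot_apply(R0, pts(i, 0), pts(i, 1), pts(i, 2), &x, &y, &z);
    const double rr = x * x + y * y + z * z;
    if (rr > rb) rb = rr;
    X[i] = x + t0[0]; Y[i] = y + t0[1]; Z[i] = z + t0[2];
    rot_apply(R0, odir(i, 0), odir(i, 1), odir(i, 2), &OX[i], &OY[i], &OZ[i]);
  }
  rb = std::sqrt(rb);
  const double maxr = cfg[7] > cfg[2] ? cfg[7] : cfg[2];

  NumericVector out(N_TERMS + 1);
  double terms[N_TERMS] = {0, 0, 0, 0, 0, 0};
  int used = 0;
  std::vector<double> BX(n), BY(n), BZ(n), BOX(n), BOY(n), BOZ(n);
  bool stop = false;
  for (int k = 0; k < K && !stop; ++k) {
    double G[9];
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) G[3 * a + b] = rots(3 * k + a, b);
    // skip the identity (the main subunit itself)
    const double idev = std::abs(G[0] - 1) + std::abs(G[4] - 1) +
                        std::abs(G[8] - 1) + std::abs(G[1]) + std::abs(G[2]) +
                        std::abs(G[3]) + std::abs(G[5]) + std::abs(G[6]) +
                        std::abs(G[7]);
    if (idev < 1e-9) continue;
    double ck[3];
    rot_apply(G, t0[0], t0[1], t0[2], &ck[0], &ck[1], &ck[2]);
    const double dcx = t0[0] - ck[0], dcy = t0[1] - ck[1], dcz = t0[2] - ck[2];
    const double dcom = std::sqrt(dcx * dcx + dcy * dcy + dcz * dcz);
    if (dcom - 2.0 * rb > maxr) continue; // cannot interact
    for (int i = 0; i < n; ++i) {
      rot_apply(G, X[i], Y[i], Z[i], &BX[i], &BY[i], &BZ[i]);
      rot_apply(G, OX[i], OY[i], OZ[i], &BOX[i], &BOY[i], &BOZ[i]);
    }
    ++used;
    accumulate_pair(X.data(), Y.data(), Z.data(), INTEGER(kind), REAL(radius),
                    REAL(density), INTEGER(resi), OX.data(), OY.data(),
                    OZ.data(), n, BX.data(), BY.data(), BZ.data(),
                    INTEGER(kind), REAL(radius), REAL(density), INTEGER(resi),
                    BOX.data(), BOY.data(), BOZ.data(), n, REAL(cfg),
                    clash_only, terms, &stop);
  }
  for (int t = 0; t < N_TERMS; ++t) out[t] = terms[t];
  out[N_TERMS] = used;
  return out;
}

// Shrake-Rupley solvent accessible surface area with a deterministic
// Fibonacci-spiral sphere point set.
// [[Rcpp::export]]
NumericVector cpp_sasa(NumericMatrix coords, NumericVector radii,
                       double probe = 1.4, int npts = 960) {
  const int n = coords.nrow();
  std::vector<double> px(npts), py(npts), pz(npts);
  const double ga = M_PI * (3.0 - std::sqrt(5.0)); // golden angle
  for (int i = 0; i < npts; ++i) {
    const double z = 1.0 - 2.0 * (i + 0.5) / npts;
    const double r = std::sqrt(1.0 - z * z);
    px[i] = r * std::cos(ga * i);
    py[i] = r * std::sin(ga * i);
    pz[i] = z;
  }
  NumericVector sasa(n);
  std::vector<int> nbr;
  for (int i = 0; i < n; ++i) {
    const double ri = radii[i] + probe;
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = coords(i, 0) - coords(j, 0);
      const double dy = coords(i, 1) - coords(j, 1);
      const double dz = coords(i, 2) - coords(j, 2);
      const double lim = ri + radii[j] + probe;
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < npts; ++p) {
      const double qx = coords(i, 0) + ri * px[p];
      const double qy = coords(i, 1) + ri * py[p];
      const double qz = coords(i, 2) + ri * pz[p];
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        const int j = nbr[m];
        const double rj = radii[j] + probe;
        const double dx = qx - coords(j, 0), dy = qy - coords(j, 1),
                     dz = qz - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { buried = true; break; }
      }
      if (!buried) ++acc;
    }
    sasa[i] = 4.0 * M_PI * ri * ri * acc / npts;
  }
  return sasa;
}
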