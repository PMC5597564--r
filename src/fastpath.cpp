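// Fast path for the search inner loop: genome -> coordinates -> energy in
// one call.  Mirrors the reference R implementations (decodePose +
// scorePose); the test suite asserts agreement to 1e-9 on random systems.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_decode")]]
NumericMatrix cpp_decode(NumericVector genome, NumericMatrix refCoords,
                         IntegerVector rootAtoms, IntegerMatrix torsAxis,
                         List torsMoved) {
  const int n = refCoords.nrow();
  const int T = torsAxis.nrow();
  NumericMatrix X(n, 3);
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) X(i, c) = refCoords(i, c);

  // torsions, root -> leaf in record order
  for (int k = 0; k < T; ++k) {
    const double ang = genome[7 + k];
    if (ang == 0.0) continue;
    const int a = torsAxis(k, 0) - 1, b = torsAxis(k, 1) - 1;
    double u0 = X(b, 0) - X(a, 0), u1 = X(b, 1) - X(a, 1), u2 = X(b, 2) - X(a, 2);
    const double nu = std::sqrt(u0 * u0 + u1 * u1 + u2 * u2);
    u0 /= nu; u1 /= nu; u2 /= nu;
    const double ca = std::cos(ang), sa = std::sin(ang);
    IntegerVector moved = torsMoved[k];
    for (int mi = 0; mi < moved.size(); ++mi) {
      const int i = moved[mi] - 1;
      const double v0 = X(i, 0) - X(b, 0), v1 = X(i, 1) - X(b, 1), v2 = X(i, 2) - X(b, 2);
      const double c0 = u1 * v2 - u2 * v1, c1 = u2 * v0 - u0 * v2, c2 = u0 * v1 - u1 * v0;
      const double du = u0 * v0 + u1 * v1 + u2 * v2;
      X(i, 0) = X(b, 0) + v0 * ca + c0 * sa + u0 * du * (1.0 - ca);
      X(i, 1) = X(b, 1) + v1 * ca + c1 * sa + u1 * du * (1.0 - ca);
      X(i, 2) = X(b, 2) + v2 * ca + c2 * sa + u2 * du * (1.0 - ca);
    }
  }

  // whole-body rotation about the ROOT-block centroid, then translation
  double qw = genome[3], qx = genome[4], qy = genome[5], qz = genome[6];
  const double qn = std::sqrt(qw * qw + qx * qx + qy * qy + qz * qz);
  qw /= qn; qx /= qn; qy /= qn; qz /= qn;
  const double R00 = 1 - 2 * (qy * qy + qz * qz), R01 = 2 * (qx * qy - qw * qz),
               R02 = 2 * (qx * qz + qw * qy);
  const double R10 = 2 * (qx * qy + qw * qz), R11 = 1 - 2 * (qx * qx + qz * qz),
               R12 = 2 * (qy * qz - qw * qx);
  const double R20 = 2 * (qx * qz - qw * qy), R21 = 2 * (qy * qz + qw * qx),
               R22 = 1 - 2 * (qx * qx + qy * qy);
  double c0 = 0, c1 = 0, c2 = 0;
  for (int ri = 0; ri < rootAtoms.size(); ++ri) {
    const int i = rootAtoms[ri] - 1;
    c0 += X(i, 0); c1 += X(i, 1); c2 += X(i, 2);
  }
  c0 /= rootAtoms.size(); c1 /= rootAtoms.size(); c2 /= rootAtoms.size();
  const double t0 = c0 + genome[0], t1 = c1 + genome[1], t2 = c2 + genome[2];
  for (int i = 0; i < n; ++i) {
    const double v0 = X(i, 0) - c0, v1 = X(i, 1) - c1, v2 = X(i, 2) - c2;
    X(i, 0) = R00 * v0 + R01 * v1 + R02 * v2 + t0;
    X(i, 1) = R10 * v0 + R11 * v1 + R12 * v2 + t1;
    X(i, 2) = R20 * v0 + R21 * v1 + R22 * v2 + t2;
  }
  return X;
}

static inline double pair_energy(double r, double A12, double B6, double C12,
                                 double D10, double qq, double ds,
                                 double cutoff, double clashDist,
                                 double clashSlope, double dieA, double dieB,
                                 double dieLambda, double dieK,
                                 double twoSigma2, double wv, double wh,
                                 double we, double wd) {
  if (r > cutoff) return 0.0;
  const double rc = r < clashDist ? clashDist : r;
  const double inv2 = 1.0 / (rc * rc);
  const double inv6 = inv2 * inv2 * inv2;
  const double inv10 = inv6 * inv2 * inv2;
  const double inv12 = inv6 * inv6;
  double vdw = A12 * inv12 - B6 * inv6;
  const double hb = C12 * inv12 - D10 * inv10;
  if (r < clashDist) vdw += clashSlope * (clashDist - r);
  const double eps = dieA + dieB / (1.0 + dieK * std::exp(-dieLambda * dieB * rc));
  const double elec = qq / (eps * rc);
  const double des = ds * std::exp(-(rc * rc) / twoSigma2);
  return wv * vdw + wh * hb + we * elec + wd * des;
}

// [[Rcpp::export(name = ".cpp_eval")]]
double cpp_eval(NumericVector genome, NumericMatrix refCoords,
                IntegerVector rootAtoms, IntegerMatrix torsAxis,
                List torsMoved, NumericMatrix rec, NumericMatrix A12,
                NumericMatrix B6, NumericMatrix C12, NumericMatrix D10,
                NumericMatrix qq, NumericMatrix ds, IntegerVector intraI,
                IntegerVector intraJ, NumericVector intraA12,
                NumericVector intraB6, NumericVector intraC12,
                NumericVector intraD10, NumericVector intraQq,
                NumericVector intraDs, NumericVector par);

// [[Rcpp::export(name = ".cpp_energy")]]
double cpp_energy(NumericMatrix lig, NumericMatrix rec, NumericMatrix A12,
                  NumericMatrix B6, NumericMatrix C12, NumericMatrix D10,
                  NumericMatrix qq, NumericMatrix ds, IntegerVector intraI,
                  IntegerVector intraJ, NumericVector intraA12,
                  NumericVector intraB6, NumericVector intraC12,
                  NumericVector intraD10, NumericVector intraQq,
                  NumericVector intraDs, NumericVector par) {
  // par: cutoff, clashDist, clashSlope, dieA, dieB(=eps0-A), dieLambda,
  //      dieK, sigma, wVdw, wHbond, wElec, wDesolv, torPenalty
  const double cutoff = par[0], clashDist = par[1], clashSlope = par[2];
  const double dieA = par[3], dieB = par[4], dieLambda = par[5], dieK = par[6];
  const double twoSigma2 = 2.0 * par[7] * par[7];
  const double wv = par[8], wh = par[9], we = par[10], wd = par[11];
  double total = par[12];  // torsional penalty
  const int nl = lig.nrow(), nr = rec.nrow();
  for (int i = 0; i < nl; ++i) {
    const double xi = lig(i, 0), yi = lig(i, 1), zi = lig(i, 2);
    for (int j = 0; j < nr; ++j) {
      const double dx = xi - rec(j, 0), dy = yi - rec(j, 1), dz = zi - rec(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      total += pair_energy(r, A12(i, j), B6(i, j), C12(i, j), D10(i, j),
                           qq(i, j), ds(i, j), cutoff, clashDist, clashSlope,
                           dieA, dieB, dieLambda, dieK, twoSigma2,
                           wv, wh, we, wd);
    }
  }
  for (int k = 0; k < intraI.size(); ++k) {
    const int i = intraI[k] - 1, j = intraJ[k] - 1;
    const double dx = lig(i, 0) - lig(j, 0), dy = lig(i, 1) - lig(j, 1),
                 dz = lig(i, 2) - lig(j, 2);
    const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    total += pair_energy(r, intraA12[k], intraB6[k], intraC12[k], intraD10[k],
                         intraQq[k], intraDs[k], cutoff, clashDist, clashSlope,
                         dieA, dieB, dieLambda, dieK, twoSigma2,
                         wv, wh, we, wd);
  }
  return total;
}

double cpp_eval(NumericVector genome, NumericMatrix refCoords,
                IntegerVector rootAtoms, IntegerMatrix torsAxis,
                List torsMoved, NumericMatrix rec, NumericMatrix A12,
                NumericMatrix B6, NumericMatrix C12, NumericMatrix D10,
                NumericMatrix qq, NumericMatrix ds, IntegerVector intraI,
                IntegerVector intraJ, NumericVector intraA12,
                NumericVector intraB6, NumericVector intraC12,
                NumericVector intraD10, NumericVector intraQq,
                NumericVector intraDs, NumericVector par) {
  NumericMatrix lig = cpp_decode(genome, refCoords, rootAtoms, torsAxis,
                                 torsMoved);
  return cpp_energy(lig, rec, A12, B6, C12, D10, qq, ds, intraI, intraJ,
                    intraA12, intraB6, intraC12, intraD10, intraQq, intraDs,
                    par);
}
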