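#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Structured bilinear FE assembly for the upscaled corneal strain energy.
//
// Fields r(R,Phi), phi(R,Phi) are stored node-wise with the radial index
// fastest: node = j*(nR+1) + i.  All quantities are dimensionless (lengths
// scaled by the corneal thickness, stiffnesses by the lamellar stiffness).
//
// Energy density (per unit reference area, measure D*R dR dPhi):
//   W = 1/(2*kappa*R*D) * [ (kappa*R)^2 K1 (lamPhi-1)^2 + K2 (lamR-1)^2
//        + (1+(kappa*R)^2) K3 ((lam+ -1)^2 + (lam- -1)^2) ]
// with
//   lamPhi = sqrt(rP^2 + (r*pP)^2)/R
//   lamR   = sqrt(rR^2 + (r*pR)^2)
//   lam+-  = w * sqrt((rR +- kappa*rP)^2 + (r*(pR +- kappa*pP))^2),
//   w = 1/sqrt(1+(kappa*R)^2).
// K1 and K3 may vary per quadrature point (damage fields); K2 is uniform.

namespace {

struct Fam5 {
  // accumulate one fibre-family contribution to W, dW/dv, d2W/dv2
  // v = (r, rR, rP, pR, pP); a, b are the two components of the family
  // stretch vector, lam = s*sqrt(a^2+b^2).
  static void add(double a, double b, double s, double c,
                  const double da[5], const double db[5],
                  int n2b, const int d2bu[2], const int d2bv[2],
                  const double d2bc[2],
                  double &Wq, double g5[5], double H5[25], int what) {
    double m2 = a * a + b * b;
    double m = std::sqrt(m2);
    double lam = s * m;
    double e = lam - 1.0;
    Wq += c * e * e;
    if (what < 1) return;
    double P[5];
    for (int u = 0; u < 5; ++u) P[u] = a * da[u] + b * db[u];
    double f1 = 2.0 * c * e * s / m;
    for (int u = 0; u < 5; ++u) g5[u] += f1 * P[u];
    if (what < 2) return;
    double s2m2 = 2.0 * c * s * s / m2;
    double fm = 2.0 * c * e * s / m;
    double fm3 = 2.0 * c * e * s / (m2 * m);
    for (int u = 0; u < 5; ++u)
      for (int v = 0; v < 5; ++v)
        H5[u * 5 + v] += s2m2 * P[u] * P[v] +
          fm * (da[u] * da[v] + db[u] * db[v]) - fm3 * P[u] * P[v];
    // bilinear terms of b (a is linear in v for all families)
    for (int k = 0; k < n2b; ++k) {
      double t = fm * b / 1.0;  // coefficient of d2b/m: fm includes 1/m
      // careful: contribution is 2c(lam-1)*s * (b * d2b_uv) / m = fm * b * coef
      double add = t * d2bc[k];
      H5[d2bu[k] * 5 + d2bv[k]] += add;
      H5[d2bv[k] * 5 + d2bu[k]] += add;
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List cm_assemble(int nR, int nP, NumericVector Rnodes, double dR, double dPhi,
                 NumericVector r, NumericVector phi, double kappa,
                 NumericVector K1qp, NumericVector K3qp, double K2, double D,
                 IntegerVector dofR, IntegerVector dofPhi, int nfree,
                 int what) {
  const int nn = (nR + 1) * (nP + 1);
  if (r.size() != nn || phi.size() != nn) stop("state size mismatch");
  const double is3 = 1.0 / std::sqrt(3.0);
  const double gs[2] = {-is3, is3};

  double energy = 0.0;
  double mindet = R_PosInf;
  NumericVector grad;
  if (what >= 1) grad = NumericVector(2 * nn);
  std::vector<int> ti, tj;
  std::vector<double> tx;
  if (what >= 2) {
    ti.reserve((size_t)nR * nP * 64);
    tj.reserve((size_t)nR * nP * 64);
    tx.reserve((size_t)nR * nP * 64);
  }

  for (int eJ = 0; eJ < nP; ++eJ) {
    for (int eI = 0; eI < nR; ++eI) {
      int n00 = eJ * (nR + 1) + eI;
      int nodes[4] = {n00, n00 + 1, n00 + (nR + 1), n00 + (nR + 1) + 1};
      double rn[4], pn[4];
      for (int n = 0; n < 4; ++n) { rn[n] = r[nodes[n]]; pn[n] = phi[nodes[n]]; }
      double He[64];
      if (what >= 2) for (int k = 0; k < 64; ++k) He[k] = 0.0;
      double ge[8];
      if (what >= 1) for (int k = 0; k < 8; ++k) ge[k] = 0.0;

      for (int g = 0; g < 4; ++g) {
        int gi = g % 2, gj = g / 2;
        double xi = gs[gi], eta = gs[gj];
        double S[4] = {0.25 * (1 - xi) * (1 - eta), 0.25 * (1 + xi) * (1 - eta),
                       0.25 * (1 - xi) * (1 + eta), 0.25 * (1 + xi) * (1 + eta)};
        double dSx[4] = {-0.25 * (1 - eta), 0.25 * (1 - eta),
                         -0.25 * (1 + eta), 0.25 * (1 + eta)};
        double dSe[4] = {-0.25 * (1 - xi), -0.25 * (1 + xi),
                         0.25 * (1 - xi), 0.25 * (1 + xi)};
        double SR[4], SP[4];
        for (int n = 0; n < 4; ++n) {
          SR[n] = dSx[n] * 2.0 / dR;
          SP[n] = dSe[n] * 2.0 / dPhi;
        }
        double Rq = Rnodes[eI] + 0.5 * (1.0 + xi) * dR;
        double rq = 0, aR = 0, aP = 0, cR = 0, cP = 0;
        for (int n = 0; n < 4; ++n) {
          rq += S[n] * rn[n];
          aR += SR[n] * rn[n];
          aP += SP[n] * rn[n];
          cR += SR[n] * pn[n];
          cP += SP[n] * pn[n];
        }
        double det = (rq / Rq) * (aR * cP - aP * cR);
        if (det < mindet) mindet = det;

        size_t q = ((size_t)(eJ * nR + eI)) * 4 + g;
        double K1 = K1qp[q], K3 = K3qp[q];
        double kR = kappa * Rq;
        double w2 = 1.0 / (1.0 + kR * kR);
        double wq = std::sqrt(w2);
        double cPhi = kR * K1 / (2.0 * D);
        double cRad = K2 / (2.0 * kR * D);
        double cpm = (1.0 + kR * kR) * K3 / (2.0 * kR * D);
        double wt = D * Rq * dR * dPhi * 0.25;

        double Wq = 0.0;
        double g5[5] = {0, 0, 0, 0, 0};
        double H5[25];
        if (what >= 2) for (int k = 0; k < 25; ++k) H5[k] = 0.0;

        // azimuthal (lamellar) family: a = rP, b = r*pP, s = 1/R
        {
          double da[5] = {0, 0, 1, 0, 0};
          double db[5] = {cP, 0, 0, 0, rq};
          int uu[2] = {0}, vv[2] = {4};
          double cc[2] = {1.0};
          Fam5::add(aP, rq * cP, 1.0 / Rq, cPhi, da, db, 1, uu, vv, cc, Wq, g5,
                    H5, what);
        }
        // radial (crosslink) family: a = rR, b = r*pR, s = 1
        {
          double da[5] = {0, 1, 0, 0, 0};
          double db[5] = {cR, 0, 0, rq, 0};
          int uu[2] = {0}, vv[2] = {3};
          double cc[2] = {1.0};
          Fam5::add(aR, rq * cR, 1.0, cRad, da, db, 1, uu, vv, cc, Wq, g5, H5,
                    what);
        }
        // diagonal families: a = rR +- kappa*rP, b = r*(pR +- kappa*pP), s = w
        for (int sgn = 0; sgn < 2; ++sgn) {
          double sg = sgn == 0 ? 1.0 : -1.0;
          double a = aR + sg * kappa * aP;
          double b = rq * (cR + sg * kappa * cP);
          double da[5] = {0, 1, sg * kappa, 0, 0};
          double db[5] = {cR + sg * kappa * cP, 0, 0, rq, sg * kappa * rq};
          int uu[2] = {0, 0}, vv[2] = {3, 4};
          double cc[2] = {1.0, sg * kappa};
          Fam5::add(a, b, wq, cpm, da, db, 2, uu, vv, cc, Wq, g5, H5, what);
        }

        energy += wt * Wq;
        if (what >= 1) {
          for (int n = 0; n < 4; ++n) {
            ge[n] += wt * (g5[0] * S[n] + g5[1] * SR[n] + g5[2] * SP[n]);
            ge[4 + n] += wt * (g5[3] * SR[n] + g5[4] * SP[n]);
          }
        }
        if (what >= 2) {
          // P maps local dof (r0..r3, p0..p3) to v = (r, rR, rP, pR, pP)
          double P[5][8];
          for (int u = 0; u < 5; ++u)
            for (int d = 0; d < 8; ++d) P[u][d] = 0.0;
          for (int n = 0; n < 4; ++n) {
            P[0][n] = S[n];
            P[1][n] = SR[n];
            P[2][n] = SP[n];
            P[3][4 + n] = SR[n];
            P[4][4 + n] = SP[n];
          }
          for (int p = 0; p < 8; ++p) {
            for (int q2 = 0; q2 < 8; ++q2) {
              double acc = 0.0;
              for (int u = 0; u < 5; ++u) {
                if (P[u][p] == 0.0) continue;
                double row = 0.0;
                for (int v = 0; v < 5; ++v) row += H5[u * 5 + v] * P[v][q2];
                acc += P[u][p] * row;
              }
              He[p * 8 + q2] += wt * acc;
            }
          }
        }
      }  // qp

      if (what >= 1) {
        for (int n = 0; n < 4; ++n) {
          grad[2 * nodes[n]] += ge[n];
          grad[2 * nodes[n] + 1] += ge[4 + n];
        }
      }
      if (what >= 2) {
        int gd[8];
        for (int n = 0; n < 4; ++n) {
          gd[n] = dofR[nodes[n]];
          gd[4 + n] = dofPhi[nodes[n]];
        }
        for (int p = 0; p < 8; ++p) {
          if (gd[p] < 0) continue;
          for (int q2 = 0; q2 < 8; ++q2) {
            if (gd[q2] < 0) continue;
            ti.push_back(gd[p]);
            tj.push_back(gd[q2]);
            tx.push_back(He[p * 8 + q2]);
          }
        }
      }
    }
  }

  List out = List::create(Named("energy") = energy, Named("mindet") = mindet);
  if (what >= 1) out["grad"] = grad;
  if (what >= 2) {
    out["ti"] = IntegerVector(ti.begin(), ti.end());
    out["tj"] = IntegerVector(tj.begin(), tj.end());
    out["tx"] = NumericVector(tx.begin(), tx.end());
  }
  return out;
}
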