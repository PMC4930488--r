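#include <Rcpp.h>
using namespace Rcpp;

// Orthotropic membrane (constant-strain triangle, St. Venant-Kirchhoff plane
// stress) energy + analytic gradient for a closed pressurized surface.
//
// Internal units: um (length), MPa (stress), so energy is in pJ and nodal
// forces in uN.  x is the flattened node matrix (n x 3, column-major).
// tri is 1-based (nel x 3).  Bm holds the inverse rest-edge matrix per
// element, columns (b11, b21, b12, b22).  Q holds plane-stress stiffness
// (Q11, Q22, Q12, Q66) per element.  tw is element wall thickness (um).
// P is internal pressure (MPa), applied through -P * enclosed volume;
// pw weights each element's volume contribution (1 for the outer surface,
// 0 for internal shared walls, which see equal pressure on both sides).
//
// Optional rigid-sphere contact: center (3), radius R, penalty k; energy
// 0.5*k*pen^2 per penetrating node, pen = R - |x - c|.
// [[Rcpp::export]]
List membrane_eg(NumericVector x, IntegerMatrix tri, NumericMatrix Bm,
                 NumericVector A0, NumericVector tw, NumericMatrix Q,
                 double P, NumericVector pw,
                 Nullable<List> contact = R_NilValue) {
  const int n = x.size() / 3;
  const int nel = tri.nrow();
  const double *X = x.begin();
  NumericVector grad(3 * n);
  double *G = grad.begin();
  double W = 0.0, V = 0.0;

  for (int e = 0; e < nel; ++e) {
    const int i1 = tri(e, 0) - 1, i2 = tri(e, 1) - 1, i3 = tri(e, 2) - 1;
    double p1[3], p2[3], p3[3], e1[3], e2[3];
    for (int c = 0; c < 3; ++c) {
      p1[c] = X[i1 + c * n];
      p2[c] = X[i2 + c * n];
      p3[c] = X[i3 + c * n];
      e1[c] = p2[c] - p1[c];
      e2[c] = p3[c] - p1[c];
    }
    const double b11 = Bm(e, 0), b21 = Bm(e, 1), b12 = Bm(e, 2), b22 = Bm(e, 3);
    // F = [e1 e2] * inv(Dm): 3x2, columns F1, F2
    double F1[3], F2[3];
    for (int c = 0; c < 3; ++c) {
      F1[c] = e1[c] * b11 + e2[c] * b21;
      F2[c] = e1[c] * b12 + e2[c] * b22;
    }
    const double C11 = F1[0]*F1[0] + F1[1]*F1[1] + F1[2]*F1[2];
    const double C22 = F2[0]*F2[0] + F2[1]*F2[1] + F2[2]*F2[2];
    const double C12 = F1[0]*F2[0] + F1[1]*F2[1] + F1[2]*F2[2];
    const double E11 = 0.5 * (C11 - 1.0);
    const double E22 = 0.5 * (C22 - 1.0);
    const double E12 = 0.5 * C12;
    const double S11 = Q(e, 0) * E11 + Q(e, 2) * E22;
    const double S22 = Q(e, 2) * E11 + Q(e, 1) * E22;
    const double S12 = Q(e, 3) * 2.0 * E12;
    const double Vel = A0[e] * tw[e];
    W += Vel * (0.5 * (E11 * S11 + E22 * S22) + E12 * S12);
    // dW/dF1 = Vel*(F1*S11 + F2*S12); dW/dF2 = Vel*(F2*S22 + F1*S12)
    // dW/de1 = g1*b11 + g2*b12; dW/de2 = g1*b21 + g2*b22
    for (int c = 0; c < 3; ++c) {
      const double g1 = Vel * (F1[c] * S11 + F2[c] * S12);
      const double g2 = Vel * (F2[c] * S22 + F1[c] * S12);
      const double ge1 = g1 * b11 + g2 * b12;
      const double ge2 = g1 * b21 + g2 * b22;
      G[i2 + c * n] += ge1;
      G[i3 + c * n] += ge2;
      G[i1 + c * n] -= ge1 + ge2;
    }
    // signed volume contribution and gradient (divergence form)
    const double cr23[3] = { p2[1]*p3[2] - p2[2]*p3[1],
                             p2[2]*p3[0] - p2[0]*p3[2],
                             p2[0]*p3[1] - p2[1]*p3[0] };
    const double cr31[3] = { p3[1]*p1[2] - p3[2]*p1[1],
                             p3[2]*p1[0] - p3[0]*p1[2],
                             p3[0]*p1[1] - p3[1]*p1[0] };
    const double cr12[3] = { p1[1]*p2[2] - p1[2]*p2[1],
                             p1[2]*p2[0] - p1[0]*p2[2],
                             p1[0]*p2[1] - p1[1]*p2[0] };
    const double pwe = pw[e];
    V += pwe * (p1[0]*cr23[0] + p1[1]*cr23[1] + p1[2]*cr23[2]) / 6.0;
    for (int c = 0; c < 3; ++c) {
      G[i1 + c * n] -= pwe * P / 6.0 * cr23[c];
      G[i2 + c * n] -= pwe * P / 6.0 * cr31[c];
      G[i3 + c * n] -= pwe * P / 6.0 * cr12[c];
    }
  }
  W -= P * V;

  double fc[3] = {0.0, 0.0, 0.0};
  int ncontact = 0;
  if (contact.isNotNull()) {
    List ct(contact);
    NumericVector cen = ct["center"];
    const double R = as<double>(ct["radius"]);
    const double k = as<double>(ct["k"]);
    IntegerVector cand = ct["nodes"];  // 1-based candidate node ids
    std::string type = "sphere";
    if (ct.containsElementNamed("type")) type = as<std::string>(ct["type"]);
    if (type == "plane") {
      // rigid plane z = cen[2] pressed downward onto the surface
      const double zp = cen[2];
      for (int ii = 0; ii < cand.size(); ++ii) {
        const int i = cand[ii] - 1;
        const double pen = X[i + 2 * n] - zp;
        if (pen > 0.0) {
          W += 0.5 * k * pen * pen;
          G[i + 2 * n] += k * pen;
          fc[2] += k * pen;  // upward reaction on the plate
          ++ncontact;
        }
      }
      return List::create(_["W"] = W, _["G"] = grad, _["V"] = V,
                          _["fcontact"] =
                              NumericVector::create(fc[0], fc[1], fc[2]),
                          _["ncontact"] = ncontact);
    }
    for (int ii = 0; ii < cand.size(); ++ii) {
      const int i = cand[ii] - 1;
      const double dx = X[i] - cen[0];
      const double dy = X[i + n] - cen[1];
      const double dz = X[i + 2 * n] - cen[2];
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < R && d > 1e-12) {
        const double pen = R - d;
        W += 0.5 * k * pen * pen;
        const double coef = -k * pen / d;  // dW/dx = -k*pen * (x-c)/d
        G[i] += coef * dx;
        G[i + n] += coef * dy;
        G[i + 2 * n] += coef * dz;
        // reaction on the sphere (equal and opposite to wall force)
        fc[0] += -coef * dx;
        fc[1] += -coef * dy;
        fc[2] += -coef * dz;
        ++ncontact;
      }
    }
  }

  return List::create(_["W"] = W, _["G"] = grad, _["V"] = V,
                      _["fcontact"] = NumericVector::create(fc[0], fc[1], fc[2]),
                      _["ncontact"] = ncontact);
}
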