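#include <Rcpp.h>
using namespace Rcpp;

// Planar discrete elastic rod with intrinsic curvature and breakable
// Kelvin-Voigt seed tethers, integrated by velocity-Verlet.  SI units.
//
// Bending: at interior node i the turning angle theta_i between adjacent
// segments gives energy 0.5 * (B/h) * (theta_i - h*kap0_i)^2.
// Axial: per segment 0.5 * (EA/h) * (|d| - h)^2 (near-inextensible).
// Tether: force max(0, k*delta + c*ddelta) along the seed-attachment line,
// breaks irreversibly at delta > delta_c.
// Damping: mass-proportional, F = -damping * m * v.
//
// seeds: columns (seg [1-based], w, mass, k, c, delta_c).
// clamp: number of leading nodes held fixed (0 or 2).
// Returns decimated frames, energy ledger and per-seed release events.

static inline void rod_forces(int n, const double *px, const double *py,
                              const double *vx, const double *vy,
                              double h, double EA, const double *B,
                              const double *kap0, double damping,
                              double axdamp, double bend_damp,
                              const double *mass,
                              double *fx, double *fy,
                              double *Ebend_out, double *Eax_out) {
  for (int i = 0; i < n; ++i) { fx[i] = 0.0; fy[i] = 0.0; }
  double Ebend = 0.0, Eax = 0.0;
  // axial; the stiff spring stands in for an inextensibility constraint, so
  // its extension rate is damped (a numerical regularization, not physical
  // rod damping) with coefficient axdamp (N s/m per segment)
  for (int s = 0; s < n - 1; ++s) {
    const double dx = px[s + 1] - px[s], dy = py[s + 1] - py[s];
    const double len = std::sqrt(dx * dx + dy * dy);
    const double ux = dx / len, uy = dy / len;
    double f = EA / h * (len - h);
    Eax += 0.5 * EA / h * (len - h) * (len - h);
    if (axdamp > 0.0) {
      const double lrate = (vx[s + 1] - vx[s]) * ux + (vy[s + 1] - vy[s]) * uy;
      f += axdamp * lrate;
    }
    fx[s] += f * ux;     fy[s] += f * uy;
    fx[s + 1] -= f * ux; fy[s + 1] -= f * uy;
  }
  // bending
  for (int i = 1; i < n - 1; ++i) {
    const double e1x = px[i] - px[i - 1], e1y = py[i] - py[i - 1];
    const double e2x = px[i + 1] - px[i], e2y = py[i + 1] - py[i];
    const double cr = e1x * e2y - e1y * e2x;
    const double dt_ = e1x * e2x + e1y * e2y;
    const double theta = std::atan2(cr, dt_);
    const double th0 = h * kap0[i - 1];
    double m = B[i - 1] / h * (theta - th0);
    Ebend += 0.5 * B[i - 1] / h * (theta - th0) * (theta - th0);
    const double l1s = e1x * e1x + e1y * e1y;
    const double l2s = e2x * e2x + e2y * e2y;
    // dtheta/dx_{i-1} = e1perp/|e1|^2 ; dtheta/dx_{i+1} = e2perp/|e2|^2
    // dtheta/dx_i = -(both); with vperp = (-vy, vx)
    const double g0x = -e1y / l1s, g0y = e1x / l1s;
    const double g2x = -e2y / l2s, g2y = e2x / l2s;
    if (bend_damp > 0.0) {
      // Kelvin-Voigt tissue viscoelasticity: internal moment proportional
      // to the turning-angle rate (damps flexural ringing, conserves
      // linear and angular momentum, vanishes at equilibrium)
      const double thdot =
          g0x * vx[i - 1] + g0y * vy[i - 1] + g2x * vx[i + 1] + g2y * vy[i + 1]
          - (g0x + g2x) * vx[i] - (g0y + g2y) * vy[i];
      m += bend_damp * B[i - 1] / h * thdot;
    }
    fx[i - 1] -= m * g0x; fy[i - 1] -= m * g0y;
    fx[i + 1] -= m * g2x; fy[i + 1] -= m * g2y;
    fx[i] += m * (g0x + g2x); fy[i] += m * (g0y + g2y);
  }
  // damping
  if (damping > 0.0)
    for (int i = 0; i < n; ++i) {
      fx[i] -= damping * mass[i] * vx[i];
      fy[i] -= damping * mass[i] * vy[i];
    }
  *Ebend_out = Ebend;
  *Eax_out = Eax;
}

// [[Rcpp::export]]
List rod_simulate(NumericMatrix X0, NumericMatrix V0, NumericVector mass,
                  double h, double EA, NumericVector B, NumericVector kap0,
                  NumericMatrix seeds, double dt, int nsteps, double damping,
                  int clamp, int stride, double clamp_release_step = -1.0,
                  double axdamp = 0.0, double bend_damp = 0.0) {
  const int n = X0.nrow();
  const int nseed = seeds.nrow();
  std::vector<double> px(n), py(n), vx(n), vy(n), fx(n), fy(n), ax(n), ay(n);
  for (int i = 0; i < n; ++i) {
    px[i] = X0(i, 0); py[i] = X0(i, 1);
    vx[i] = V0(i, 0); vy[i] = V0(i, 1);
  }
  std::vector<double> sx(nseed), sy(nseed), svx(nseed), svy(nseed);
  std::vector<int> attached(nseed, 1);
  for (int s = 0; s < nseed; ++s) {
    const int seg = (int)seeds(s, 0) - 1;
    const double w = seeds(s, 1);
    sx[s] = (1.0 - w) * px[seg] + w * px[seg + 1];
    sy[s] = (1.0 - w) * py[seg] + w * py[seg + 1];
    svx[s] = 0.0; svy[s] = 0.0;
  }
  const int nframes = nsteps / stride + 1;
  NumericMatrix framesX(nframes, n), framesY(nframes, n);
  NumericMatrix seedX(nframes, std::max(nseed, 1)), seedY(nframes, std::max(nseed, 1));
  NumericMatrix energies(nframes, 5);  // t, elastic, kinetic, tether, axial
  NumericVector ftimes(nframes);
  NumericMatrix events(nseed, 7);  // id, t, x, y, vx, vy, released
  for (int s = 0; s < nseed; ++s) { events(s, 0) = s + 1; events(s, 6) = 0.0; }

  int clamped = clamp;
  double Ebend = 0.0, Eax = 0.0;
  bool unstable = false;
  double E0 = NA_REAL;
  int frame = 0;

  // tether force accumulation helper (applied inside the loop)
  std::vector<double> sfx(nseed), sfy(nseed);

  auto apply_tethers = [&](double *fx_, double *fy_, double *Eteth) {
    *Eteth = 0.0;
    for (int s = 0; s < nseed; ++s) {
      sfx[s] = 0.0; sfy[s] = 0.0;
      if (!attached[s]) continue;
      const int seg = (int)seeds(s, 0) - 1;
      const double w = seeds(s, 1);
      const double axp = (1.0 - w) * px[seg] + w * px[seg + 1];
      const double ayp = (1.0 - w) * py[seg] + w * py[seg + 1];
      const double avx = (1.0 - w) * vx[seg] + w * vx[seg + 1];
      const double avy = (1.0 - w) * vy[seg] + w * vy[seg + 1];
      const double dxv = sx[s] - axp, dyv = sy[s] - ayp;
      const double d = std::sqrt(dxv * dxv + dyv * dyv);
      if (d < 1e-15) continue;
      const double ddot = (dxv * (svx[s] - avx) + dyv * (svy[s] - avy)) / d;
      double f = seeds(s, 3) * d + seeds(s, 4) * ddot;
      if (f < 0.0) f = 0.0;
      *Eteth += 0.5 * seeds(s, 3) * d * d;
      const double ux = dxv / d, uy = dyv / d;
      sfx[s] = -f * ux; sfy[s] = -f * uy;   // pulls seed toward valve
      fx_[seg] += (1.0 - w) * f * ux; fy_[seg] += (1.0 - w) * f * uy;
      fx_[seg + 1] += w * f * ux;     fy_[seg + 1] += w * f * uy;
    }
  };

  double Eteth = 0.0;
  rod_forces(n, px.data(), py.data(), vx.data(), vy.data(), h, EA, B.begin(),
             kap0.begin(), damping, axdamp, bend_damp, mass.begin(),
             fx.data(), fy.data(), &Ebend, &Eax);
  apply_tethers(fx.data(), fy.data(), &Eteth);
  for (int i = 0; i < n; ++i) { ax[i] = fx[i] / mass[i]; ay[i] = fy[i] / mass[i]; }

  for (int step = 0; step <= nsteps; ++step) {
    const double t = step * dt;
    if (clamp_release_step >= 0 && step >= clamp_release_step) clamped = 0;
    for (int i = 0; i < clamped; ++i) { vx[i] = vy[i] = ax[i] = ay[i] = 0.0; }

    if (step % stride == 0 && frame < nframes) {
      double Ek = 0.0;
      for (int i = 0; i < n; ++i)
        Ek += 0.5 * mass[i] * (vx[i] * vx[i] + vy[i] * vy[i]);
      for (int s = 0; s < nseed; ++s)
        Ek += 0.5 * seeds(s, 2) * (svx[s] * svx[s] + svy[s] * svy[s]);
      ftimes[frame] = t;
      for (int i = 0; i < n; ++i) { framesX(frame, i) = px[i]; framesY(frame, i) = py[i]; }
      for (int s = 0; s < nseed; ++s) { seedX(frame, s) = sx[s]; seedY(frame, s) = sy[s]; }
      const double Eel = Ebend + Eax;
      energies(frame, 0) = t; energies(frame, 1) = Eel;
      energies(frame, 2) = Ek; energies(frame, 3) = Eteth;
      energies(frame, 4) = Eax;
      const double Etot = Eel + Ek + Eteth;
      if (step == 0) E0 = Etot;
      if (damping == 0.0 && axdamp == 0.0 && bend_damp == 0.0 &&
          Etot > 1.05 * E0 + 1e-15) {
        unstable = true; ++frame; break;
      }
      ++frame;
    }
    if (step == nsteps) break;

    // velocity-Verlet
    for (int i = clamped; i < n; ++i) {
      vx[i] += 0.5 * dt * ax[i]; vy[i] += 0.5 * dt * ay[i];
      px[i] += dt * vx[i];       py[i] += dt * vy[i];
    }
    for (int s = 0; s < nseed; ++s) {
      const double asx = sfx[s] / seeds(s, 2), asy = sfy[s] / seeds(s, 2);
      svx[s] += 0.5 * dt * asx; svy[s] += 0.5 * dt * asy;
      sx[s] += dt * svx[s];     sy[s] += dt * svy[s];
    }
    rod_forces(n, px.data(), py.data(), vx.data(), vy.data(), h, EA, B.begin(),
               kap0.begin(), damping, axdamp, bend_damp, mass.begin(),
               fx.data(), fy.data(), &Ebend, &Eax);
    apply_tethers(fx.data(), fy.data(), &Eteth);
    for (int i = 0; i < clamped; ++i) { fx[i] = fy[i] = 0.0; }
    for (int i = 0; i < n; ++i) { ax[i] = fx[i] / mass[i]; ay[i] = fy[i] / mass[i]; }
    for (int i = clamped; i < n; ++i) {
      vx[i] += 0.5 * dt * ax[i]; vy[i] += 0.5 * dt * ay[i];
    }
    for (int s = 0; s < nseed; ++s) {
      svx[s] += 0.5 * dt * sfx[s] / seeds(s, 2);
      svy[s] += 0.5 * dt * sfy[s] / seeds(s, 2);
    }
    // rupture check
    for (int s = 0; s < nseed; ++s) {
      if (!attached[s]) continue;
      const int seg = (int)seeds(s, 0) - 1;
      const double w = seeds(s, 1);
      const double axp = (1.0 - w) * px[seg] + w * px[seg + 1];
      const double ayp = (1.0 - w) * py[seg] + w * py[seg + 1];
      const double dxv = sx[s] - axp, dyv = sy[s] - ayp;
      if (std::sqrt(dxv * dxv + dyv * dyv) > seeds(s, 5)) {
        attached[s] = 0;
        events(s, 1) = t + dt; events(s, 2) = sx[s]; events(s, 3) = sy[s];
        events(s, 4) = svx[s]; events(s, 5) = svy[s]; events(s, 6) = 1.0;
      }
    }
  }

  return List::create(
      _["times"] = ftimes, _["X"] = framesX, _["Y"] = framesY,
      _["seedX"] = seedX, _["seedY"] = seedY, _["energies"] = energies,
      _["events"] = events, _["unstable"] = unstable, _["nframes"] = frame);
}
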