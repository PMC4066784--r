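#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter vector layout (length 16), shared with R/parameters.R:
//   0 b_e, 1 b_g, 2 k_e, 3 k_g, 4..7 f1..f4, 8..11 K1..K4, 12..15 n1..n4
// Perturbation scalars (one segment = constant perturbation):
//   se, sg  — synthesis scaling (siRNA efficiency; 0 under cycloheximide)
//   ici_act — fraction of ERalpha that remains regulatorily active, 1/(1+dose/K50)
//   k_loss  — ICI-induced first-order ERalpha loss rate, per hour

static inline double hillF(double x, double f, double K, double n) {
  if (x <= 0.0) return 1.0;
  double u = std::pow(x / K, n);
  return (1.0 + f * u) / (1.0 + u);
}

struct Model {
  double be, bg, ke, kg;
  double f[4], K[4], n[4];
  double se, sg, ici_act, k_loss;

  Model(const NumericVector& th, double se_, double sg_,
        double ici_act_, double k_loss_) {
    be = th[0]; bg = th[1]; ke = th[2]; kg = th[3];
    for (int j = 0; j < 4; ++j) {
      f[j] = th[4 + j]; K[j] = th[8 + j]; n[j] = th[12 + j];
    }
    se = se_; sg = sg_; ici_act = ici_act_; k_loss = k_loss_;
  }

  inline void deriv(const double* y, double* dy) const {
    double e = y[0] > 0.0 ? y[0] : 0.0;
    double g = y[1] > 0.0 ? y[1] : 0.0;
    double ea = e * ici_act;
    double F1 = hillF(ea, f[0], K[0], n[0]);
    double F2 = hillF(g,  f[1], K[1], n[1]);
    double F3 = hillF(ea, f[2], K[2], n[2]);
    double F4 = hillF(g,  f[3], K[3], n[3]);
    dy[0] = se * be * F1 * F2 - (ke + k_loss) * y[0];
    dy[1] = sg * bg * F3 * F4 - kg * y[1];
  }
};

// Cash-Karp embedded Runge-Kutta 4(5) coefficients
static const double CK_A[6] = {0.0, 1.0/5, 3.0/10, 3.0/5, 1.0, 7.0/8};
static const double CK_B[6][5] = {
  {0, 0, 0, 0, 0},
  {1.0/5, 0, 0, 0, 0},
  {3.0/40, 9.0/40, 0, 0, 0},
  {3.0/10, -9.0/10, 6.0/5, 0, 0},
  {-11.0/54, 5.0/2, -70.0/27, 35.0/27, 0},
  {1631.0/55296, 175.0/512, 575.0/13824, 44275.0/110592, 253.0/4096}
};
static const double CK_C5[6] = {37.0/378, 0, 250.0/621, 125.0/594, 0, 512.0/1771};
static const double CK_C4[6] = {2825.0/27648, 0, 18575.0/48384, 13525.0/55296,
                                277.0/14336, 1.0/4};

// One adaptive Cash-Karp step attempt; returns error estimate scale
static inline double ck_step(const Model& m, const double* y, double h,
                             double* yout, double rtol, double atol) {
  double k[6][2], ytmp[2], dy[2];
  m.deriv(y, k[0]);
  for (int s = 1; s < 6; ++s) {
    for (int i = 0; i < 2; ++i) {
      double acc = 0.0;
      for (int q = 0; q < s; ++q) acc += CK_B[s][q] * k[q][i];
      ytmp[i] = y[i] + h * acc;
    }
    m.deriv(ytmp, k[s]);
  }
  double errmax = 0.0;
  for (int i = 0; i < 2; ++i) {
    double y5 = 0.0, y4 = 0.0;
    for (int s = 0; s < 6; ++s) {
      y5 += CK_C5[s] * k[s][i];
      y4 += CK_C4[s] * k[s][i];
    }
    yout[i] = y[i] + h * y5;
    double err = h * (y5 - y4);
    double sc = atol + rtol * std::max(std::fabs(y[i]), std::fabs(yout[i]));
    errmax = std::max(errmax, std::fabs(err) / sc);
  }
  (void)dy;
  return errmax;
}

// Integrate one constant-perturbation segment from t0, reporting y at `times`
// (all >= t0, strictly increasing). y0 is the state at t0.
// [[Rcpp::export]]
NumericMatrix ode_segment_cpp(NumericVector theta, double se, double sg,
                              double ici_act, double k_loss,
                              NumericVector y0, double t0, NumericVector times,
                              double rtol = 1e-8, double atol = 1e-10) {
  Model m(theta, se, sg, ici_act, k_loss);
  int nt = times.size();
  NumericMatrix out(nt, 2);
  double y[2] = {y0[0], y0[1]};
  double t = t0;
  double h = 0.1;
  int it = 0;
  // report any times equal to t0
  while (it < nt && times[it] <= t0 + 1e-12) {
    out(it, 0) = y[0]; out(it, 1) = y[1]; ++it;
  }
  long steps = 0;
  while (it < nt) {
    double tnext = times[it];
    if (t + h > tnext) h = tnext - t;
    double ynew[2];
    double err = ck_step(m, y, h, ynew, rtol, atol);
    if (err <= 1.0) {
      t += h;
      y[0] = ynew[0] > 0.0 ? ynew[0] : 0.0;
      y[1] = ynew[1] > 0.0 ? ynew[1] : 0.0;
      if (t >= tnext - 1e-12) {
        out(it, 0) = y[0]; out(it, 1) = y[1]; ++it;
        // duplicate-free grids only, but guard identical times
        while (it < nt && times[it] <= t + 1e-12) {
          out(it, 0) = y[0]; out(it, 1) = y[1]; ++it;
        }
      }
      // grow step
      double fac = (err > 1e-10) ? 0.9 * std::pow(err, -0.2) : 5.0;
      h *= std::min(5.0, fac);
    } else {
      h *= std::max(0.1, 0.9 * std::pow(err, -0.25));
    }
    if (h < 1e-12) stop("integrator step size underflow (possible singularity)");
    if (++steps > 50000000L) stop("integrator exceeded step budget");
  }
  return out;
}

// Exact stochastic simulation (Gillespie direct method) of the four channels:
// ERalpha birth/death, GATA3 birth/death, in molecule counts at system size
// omega. Samples the state on a regular grid; uses R's RNG (seed-reproducible
// via set.seed()).
// [[Rcpp::export]]
NumericMatrix gillespie_cpp(NumericVector theta, double se, double sg,
                            double ici_act, double k_loss, double omega,
                            NumericVector y0_counts, double t0, double t_end,
                            double sample_dt) {
  Model m(theta, se, sg, ici_act, k_loss);
  int ns = (int)std::floor((t_end - t0) / sample_dt) + 1;
  NumericMatrix out(ns, 3);
  double E = y0_counts[0], G = y0_counts[1];
  double t = t0;
  int is = 0;
  double tsample = t0;
  while (is < ns) {
    double e = E / omega, g = G / omega;
    double ea = e * ici_act;
    double a1 = omega * se * m.be * hillF(ea, m.f[0], m.K[0], m.n[0]) *
                hillF(g, m.f[1], m.K[1], m.n[1]);
    double a2 = (m.ke + m.k_loss) * E;
    double a3 = omega * sg * m.bg * hillF(ea, m.f[2], m.K[2], m.n[2]) *
                hillF(g, m.f[3], m.K[3], m.n[3]);
    double a4 = m.kg * G;
    double a0 = a1 + a2 + a3 + a4;
    double tau = (a0 > 0.0) ? -std::log(unif_rand()) / a0 : R_PosInf;
    // emit samples that fall before the next event
    while (is < ns && tsample <= t + tau) {
      out(is, 0) = tsample; out(is, 1) = E; out(is, 2) = G;
      ++is; tsample = t0 + is * sample_dt;
    }
    if (is >= ns) break;
    t += tau;
    double r = unif_rand() * a0;
    if (r < a1) E += 1.0;
    else if (r < a1 + a2) E -= 1.0;
    else if (r < a1 + a2 + a3) G += 1.0;
    else G -= 1.0;
    if (E < 0.0) E = 0.0;
    if (G < 0.0) G = 0.0;
  }
  return out;
}
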