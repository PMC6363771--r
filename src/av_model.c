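/* Compiled vector field of the autophagy regulation + pharmacokinetics
 * model, in the standard deSolve compiled-model interface.
 *
 * Parameter vector layout (see R/model.R, pack_parms()):
 *   [0]  timescale T
 *   [1]  C_En   [2] C_Nu
 *   [3]  k1  [4] k2  [5] k3  [6] k4
 *   [7..12]   delta[6]
 *   [13..18]  b[6]
 *   [19..38]  regulation curves h12, h13, h23, h21, h42 (rb, rm, theta, n)
 *   [39..62]  drug curves H1..H6 (rb, rm, theta, n)
 *   [63]      fixed_w flag (1: hold drug concentrations constant)
 *
 * The six injection rates u1..u6 enter as deSolve forcings.
 */
#include <R.h>
#include <math.h>

#define N_PARMS 64

static double parms[N_PARMS];
static double forc[6];

void av_initmod(void (*odeparms)(int *, double *)) {
  int n = N_PARMS;
  odeparms(&n, parms);
}

void av_initforc(void (*odeforcs)(int *, double *)) {
  int n = 6;
  odeforcs(&n, forc);
}

/* activating Hill form: rb + (rm - rb) x^n / (x^n + theta^n) */
static double hill_act(double x, const double *c) {
  double xn = pow(x, c[3]);
  double tn = pow(c[2], c[3]);
  return c[0] + (c[1] - c[0]) * xn / (xn + tn);
}

/* drug (repressive) Hill form: rm - (rm - rb) w^n / (w^n + theta^n) */
static double hill_drug(double w, const double *c) {
  double wn = pow(w, c[3]);
  double tn = pow(c[2], c[3]);
  return c[1] - (c[1] - c[0]) * wn / (wn + tn);
}

void av_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip) {
  const double T = parms[0], CEn = parms[1], CNu = parms[2];
  const double k1 = parms[3], k2 = parms[4], k3 = parms[5], k4 = parms[6];
  const double *delta = parms + 7, *b = parms + 13;
  const double *h12 = parms + 19, *h13 = parms + 23, *h23 = parms + 27,
               *h21 = parms + 31, *h42 = parms + 35;
  const double *HC = parms + 39;
  const int fixed_w = parms[63] != 0;
  double x1 = y[0], x2 = y[1], x3 = y[2], x4 = y[3], x5 = y[4];
  double H[6];
  int i;
  /* guard against integrator excursions outside the admissible box */
  if (x1 < 0) x1 = 0; if (x1 > 1) x1 = 1;
  if (x2 < 0) x2 = 0; if (x2 > 1) x2 = 1;
  if (x3 < 0) x3 = 0; if (x3 > 1) x3 = 1;
  if (x4 < 0) x4 = 0; if (x4 > 1) x4 = 1;
  for (i = 0; i < 6; i++) {
    double w = y[5 + i];
    if (w < 0) w = 0;
    H[i] = hill_drug(w, HC + 4 * i);
  }
  ydot[0] = ((1 - x1) * CNu * H[0] * H[1] -
             x1 * hill_act(x2, h12) * hill_act(x3, h13)) / T;
  ydot[1] = ((1 - x2) * hill_act(x3, h23) * H[2] -
             x2 * hill_act(x1, h21)) / T;
  ydot[2] = ((1 - x3) * k1 * H[3] - CEn * x2 * x3 * H[4]) / T;
  ydot[3] = ((1 - x4) * hill_act(x2, h42) * H[1] * H[5] - k2 * x4) / T;
  ydot[4] = (k3 * x4 - k4 * x5) / T;
  for (i = 0; i < 6; i++) {
    ydot[5 + i] = fixed_w ? 0.0
      : (b[i] * forc[i] - delta[i] * y[5 + i]) / T;
  }
}
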