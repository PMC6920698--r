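/* Compiled right-hand side of the digitalizer ODE system for deSolve.
   Parameter vector (16): alpha_R, beta_R, K_TF, n_act, alpha_S, K_R, n_rep,
   k_pair, delta_mR, delta_mS, delta_R, delta_G, lambda_R, lambda_G, mu, tf_a.
   States (4): mR, mS, R, G. Negative excursions from the integrator are
   clamped to zero before evaluating the rate laws. */

#include <R.h>
#include <math.h>

static double parms[16];

void dig_init(void (*odeparms)(int *, double *)) {
  int n = 16;
  odeparms(&n, parms);
}

void dig_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip) {
  const double alpha_R = parms[0], beta_R = parms[1], K_TF = parms[2],
               n_act = parms[3], alpha_S = parms[4], K_R = parms[5],
               n_rep = parms[6], k_pair = parms[7], delta_mR = parms[8],
               delta_mS = parms[9], delta_R = parms[10], delta_G = parms[11],
               lambda_R = parms[12], lambda_G = parms[13], mu = parms[14],
               tf_a = parms[15];
  double mR = y[0] > 0 ? y[0] : 0;
  double mS = y[1] > 0 ? y[1] : 0;
  double R  = y[2] > 0 ? y[2] : 0;
  double G  = y[3] > 0 ? y[3] : 0;

  double act = 0.0;
  if (tf_a > 0) {
    double xn = pow(tf_a / K_TF, n_act);
    act = xn / (1.0 + xn);
  }
  double rn = R > 0 ? pow(R / K_R, n_rep) : 0.0;
  double rep = 1.0 / (1.0 + rn);
  double pair = k_pair * mR * mS;

  ydot[0] = beta_R + alpha_R * act - (delta_mR + mu) * mR - pair;
  ydot[1] = alpha_S * rep - (delta_mS + mu) * mS - pair;
  ydot[2] = lambda_R * mR - (delta_R + mu) * R;
  ydot[3] = lambda_G * mR - (delta_G + mu) * G;
}
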