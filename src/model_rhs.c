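/* Compiled right-hand side of the 7-state airway smooth muscle Ca2+ model,
 * in the deSolve compiled-model convention. The arithmetic mirrors the
 * reference implementation in R/rhs.R; drug targets are passed as the last
 * four parameter slots and are piecewise constant within one integration
 * segment. */

#include <R.h>
#include <math.h>

static double parms[29];

#define V_p      parms[0]
#define K_p      parms[1]
#define V_s      parms[2]
#define K_s      parms[3]
#define n_s      parms[4]
#define tau_s    parms[5]
#define alpha_0  parms[6]
#define gamma_   parms[7]
#define alpha_1  parms[8]
#define V_e      parms[9]
#define K_e      parms[10]
#define tau_e    parms[11]
#define k_IPR    parms[12]
#define tau_p    parms[13]
#define J_SR     parms[14]
#define K_RYR    parms[15]
#define tau_SR   parms[16]
#define K_1      parms[17]
#define K_2      parms[18]
#define K_3      parms[19]
#define K_4      parms[20]
#define K_5      parms[21]
#define k_m2     parms[22]
#define cpa_block parms[23]
#define tg_agonist parms[24]
#define tg_ryacaf  parms[25]
#define tg_cpa     parms[26]
#define tg_ext     parms[27]
#define unused_    parms[28]

void asmca_initmod(void (*odeparms)(int *, double *))
{
    int n = 29;
    odeparms(&n, parms);
}

void asmca_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double c  = y[0] > 0 ? y[0] : 0;
    double cs = y[1] > 0 ? y[1] : 0;
    double phi = y[2]; double s = y[3];
    double p  = y[4] > 0 ? y[4] : 0;
    double lam = y[5]; double eps = y[6];
    if (phi < 0) phi = 0; if (phi > 1) phi = 1;
    if (s < 0) s = 0;     if (s > 1) s = 1;
    if (eps < 0) eps = 0; if (eps > 1) eps = 1;

    double grad = cs - c;
    double A = p * c * (1 - phi) / ((p + K_1) * (c + K_5));
    double P_open = A * A * A;
    double J_IPR = k_IPR * P_open * grad;
    double J_RyR = lam * grad;
    double J_SR_leak = J_SR * grad;
    double J_rel = J_IPR + J_RyR + J_SR_leak;
    double J_SERCA = eps * V_e * c / (K_e + c);
    double J_PMCA = V_p * c / (K_p + c);
    double J_in = tg_ext * (alpha_0 + alpha_1 * p + V_s * s);

    double km4 = 0.138 * k_m2;
    double a2 = k_m2 / K_2, a4 = km4 / K_4;
    double beta = c * (a2 * p + a4 * K_1) / (p + K_1);
    double alpha = (k_m2 * p + km4 * K_3) / (p + K_3);

    double kn = pow(K_s, n_s);
    double s_inf = kn / (kn + pow(cs, n_s));

    double serca_target = tg_cpa > 0.5 ? 1 - cpa_block : 1;
    double ryr_max = K_RYR * tau_SR * tau_SR;

    ydot[0] = J_rel - J_SERCA + J_in - J_PMCA;
    ydot[1] = gamma_ * (J_SERCA - J_rel);
    ydot[2] = beta * (1 - phi) - alpha * phi;
    ydot[3] = (s_inf - s) / tau_s;
    ydot[4] = (tg_agonist - p) / tau_p;
    ydot[5] = tg_ryacaf > 0.5 ? (ryr_max - lam) / tau_SR : 0;
    ydot[6] = (serca_target - eps) / tau_e;
}
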