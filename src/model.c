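/* Compiled right-hand sides for the three-subpopulation community model,
 * following deSolve's compiled-code interface. Parameters are passed by
 * lsoda through the initializer: (k1, k2, k3, k4, k5, N).
 *
 * Two charts are provided: the linear chart (R, P, M) and a log chart
 * (u = log R, P, M). The log chart removes the stiffness of the spike
 * regime, where R traverses dozens of orders of magnitude between spikes
 * and would otherwise underflow the integrator's step-size control.
 */
#include <R.h>
#include <math.h>

static double parms[6];
#define P_K1 parms[0]
#define P_K2 parms[1]
#define P_K3 parms[2]
#define P_K4 parms[3]
#define P_K5 parms[4]
#define P_NU parms[5]

void biofilm_initmod(void (*odeparms)(int *, double *))
{
    int n = 6;
    odeparms(&n, parms);
}

/* y = (R, P, M) */
void biofilm_deriv_lin(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double R = y[0], P = y[1], M = y[2];
    ydot[0] = P_K1 * P_NU * R - P_K4 * R - P_K2 * R * P;
    ydot[1] = -P_K3 * P + P_K5 * M;
    ydot[2] = P_K4 * R - P_K5 * M;
}

/* y = (u, P, M) with u = log R */
void biofilm_deriv_log(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double u = y[0], P = y[1], M = y[2];
    ydot[0] = P_K1 * P_NU - P_K4 - P_K2 * P;
    ydot[1] = -P_K3 * P + P_K5 * M;
    ydot[2] = P_K4 * exp(u) - P_K5 * M;
}
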