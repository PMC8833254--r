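/* Compiled right-hand side of the six-state chloroplast model, for use with
 * deSolve's compiled-model interface. Parameter vector (length 15, order fixed
 * and mirrored in R/params.R):
 *   0 alpha, 1 c_in, 2 E_star_PSII, 3 v_ETR, 4 v_d, 5 Q_star, 6 v_NPQ,
 *   7 v_p, 8 v_C, 9 eta_NADPH, 10 eta_NADPplus, 11 v_R, 12 d, 13 c_y, 14 PAR
 * PAR is piecewise constant: the simulator restarts integration at every light
 * switch, so within a segment it is an ordinary parameter.
 */
#include <R.h>
#include <math.h>

static double parms[15];
#define P_ALPHA   parms[0]
#define P_CIN     parms[1]
#define P_ESTAR   parms[2]
#define P_VETR    parms[3]
#define P_VD      parms[4]
#define P_QSTAR   parms[5]
#define P_VNPQ    parms[6]
#define P_VP      parms[7]
#define P_VC      parms[8]
#define P_ETANADPH parms[9]
#define P_ETANADPP parms[10]
#define P_VR      parms[11]
#define P_D       parms[12]
#define P_CY      parms[13]
#define P_PAR     parms[14]

#define POOL_EPS 1e-9

void leafode_init(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, parms);
}

void leafode_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    double E = y[0], Q = y[1], P = y[2];
    double NADPH = y[3], NADPplus = y[4], R = y[5];

    double input = P_ALPHA * P_CIN * P_PAR * (1.0 - E / P_ESTAR);
    double etr   = P_VETR * E * NADPplus;
    double diss  = P_VD * E * P * (1.0 - Q / P_QSTAR);
    double cef   = input - etr;
    double dph   = NADPH / fmax(NADPplus, POOL_EPS);

    ydot[0] = input - etr - diss;
    ydot[1] = diss - P_VNPQ * Q;
    ydot[2] = (cef > P_CY) ? P_VP * (1.0 - P) : 0.0;
    ydot[3] = etr * P_ETANADPP - P_VC * R * NADPH * P_ETANADPH;
    ydot[4] = -ydot[3];
    ydot[5] = P_VR * (1.0 - R) * fmin(P_D, dph);
}
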