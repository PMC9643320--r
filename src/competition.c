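/* Tracer-drug competition model right-hand side for deSolve's compiled
 * interface.  States: y[0] = C_ND (Bq/cm^3, free + nonspecific tracer),
 * y[1] = C_S (Bq/cm^3, specifically bound tracer), y[2] = D_ND (nmol/L,
 * non-displaceable drug), y[3] = O (target occupancy fraction).
 * Forcings: forc[0] = C_P(t) tracer parent plasma, forc[1] = D_P(t) drug
 * plasma; both interpolated linearly by the solver.
 */
#include <R.h>

static double parms[9];
static double forc[2];

#define K1     parms[0]  /* tracer plasma->tissue rate, mL/min/cm^3        */
#define k2     parms[1]  /* K1 * fND / fP, 1/min                           */
#define koff   parms[2]  /* tracer dissociation rate, 1/min                */
#define bterm  parms[3]  /* VT * fND / fP - 1 (specific binding capacity)  */
#define K1D    parms[4]  /* drug plasma->tissue rate, mL/min/cm^3          */
#define k2D    parms[5]  /* K1D * fNDD / fPD, 1/min                        */
#define koffD  parms[6]  /* drug dissociation rate, 1/min                  */
#define Bmax   parms[7]  /* total target concentration, nmol/L             */
#define ratioD parms[8]  /* fNDD / KDD, 1/(nmol/L)                         */

#define CP forc[0]
#define DP forc[1]

void sv2a_initmod(void (*odeparms)(int *, double *))
{
    int n = 9;
    odeparms(&n, parms);
}

void sv2a_initforc(void (*odeforcs)(int *, double *))
{
    int n = 2;
    odeforcs(&n, forc);
}

void sv2a_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double cnd = y[0], cs = y[1], dnd = y[2], o = y[3];
    double sb = bterm * (1.0 - o) * cnd - cs;      /* tracer binding flux / koff */
    double db = ratioD * (1.0 - o) * dnd - o;      /* drug binding flux / koffD  */

    ydot[0] = K1 * CP - k2 * cnd - koff * sb;
    ydot[1] = koff * sb;
    ydot[2] = K1D * DP - k2D * dnd - koffD * Bmax * db;
    ydot[3] = koffD * db;
}
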