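/* Modified Rayleigh-Plesset RHS for encapsulated microbubbles, solved with
 * deSolve (lsodar) from R.  The driving acoustic pressure p_ac(t) enters as
 * a deSolve forcing function (linear interpolation of the sampled pulse).
 *
 * State: y[0] = R (m), y[1] = dR/dt (m/s).
 *
 * Parameters (order fixed, see simulate_bubble() in R/bubble.R):
 *   0 rho    fluid density (kg/m^3)
 *   1 pg     equilibrium gas pressure (Pa)
 *   2 pv     vapour pressure (Pa)
 *   3 p0     ambient pressure (Pa)
 *   4 sigma  interfacial tension (N/m)
 *   5 chi    shell stiffness (N/m)
 *   6 gam3   3 * specific heat ratio (dimensionless)
 *   7 dcoef  delta_t * omega * rho (damping term coefficient, Pa s / m^2)
 *   8 R0     equilibrium radius (m)
 *   9 rmin   collapse-guard radius (m); integration halts at R = rmin
 */
#include <R.h>

static double parms[10];
static double forcs[1];

void sonosim_init(void (*odeparms)(int *, double *))
{
    int n = 10;
    odeparms(&n, parms);
}

void sonosim_forc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forcs);
}

void sonosim_deriv(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double rho = parms[0], pg = parms[1], pv = parms[2], p0 = parms[3];
    double sigma = parms[4], chi = parms[5], gam3 = parms[6];
    double dcoef = parms[7], R0 = parms[8];
    double R = y[0], Rd = y[1];
    double pac = forcs[0];
    double bracket;

    bracket = -1.5 * rho * Rd * Rd
        + pg * pow(R0 / R, gam3)
        + pv - p0
        - 2.0 * sigma / R
        - 2.0 * chi * (1.0 / R0 - 1.0 / R)
        - dcoef * R * Rd
        - pac;

    ydot[0] = Rd;
    ydot[1] = bracket / (rho * R);
}

/* Root: collapse guard.  lsodar terminates when R crosses rmin. */
void sonosim_root(int *neq, double *t, double *y, int *ng, double *gout,
                  double *out, int *ip)
{
    gout[0] = y[0] - parms[9];
}
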