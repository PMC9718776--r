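/* Five-level Maxwell-Bloch equations as a deSolve compiled model.
 *
 * State vector (all real): y[0..4] = rho11..rho55, y[5] = Re(rho21),
 * y[6] = Im(rho21). rho12 = conj(rho21) is implicit, which enforces
 * Hermiticity structurally. With g(t) real and the coherence written in
 * real/imaginary parts, the population couplings reduce to
 *   d rho11 =  Omega0 g(t) Im(rho21)
 *   d rho22 = -Omega0 g(t) Im(rho21) - Gamma22 rho22
 * so the population sum is conserved exactly at the level of the RHS.
 *
 * Internal units: time in ps, rates in 1/ps, frequencies in rad/ps.
 */
#include <R.h>
#include <math.h>

static double parms[7];
#define GAMMA22 parms[0]
#define GAMMA33 parms[1]
#define GAMMA44 parms[2]
#define GAMMA21 parms[3]
#define DOMEGA  parms[4]
#define OMEGA0  parms[5]
#define TAUIRF  parms[6]   /* ps */

void initmod_bloch(void (*odeparms)(int *, double *))
{
    int n = 7;
    odeparms(&n, parms);
}

void derivs_bloch(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const double u = *t / TAUIRF;
    const double g = exp(-0.5 * u * u);
    const double drive = OMEGA0 * g;           /* rad/ps */
    const double re21 = y[5], im21 = y[6];
    const double pop_flux = drive * im21;      /* coherent 1<->2 transfer */

    ydot[0] =  pop_flux;
    ydot[1] = -pop_flux - GAMMA22 * y[1];
    ydot[2] =  GAMMA22 * y[1] - GAMMA33 * y[2];
    ydot[3] =  GAMMA33 * y[2] - GAMMA44 * y[3];
    ydot[4] =  GAMMA44 * y[3];
    /* d rho21 = -(i/2) Omega0 g (rho11 - rho22) - (Gamma21 - i dW) rho21 */
    ydot[5] = -GAMMA21 * re21 - DOMEGA * im21;
    ydot[6] = -0.5 * drive * (y[0] - y[1]) - GAMMA21 * im21 + DOMEGA * re21;
}
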