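/* Compiled right-hand sides for the deterministic model variants,
 * in the deSolve compiled-code calling convention. One shared parameter
 * vector (see parms_vector() on the R side):
 *  0 b, 1 K, 2 n, 3 a_prime, 4 b_prime, 5 K_prime, 6 m, 7 epsilon,
 *  8 k_X, 9 a_static, 10 mod_flag, 11 a_bar, 12 delta_a, 13 kappa,
 * 14 X_c, 15 tau, 16 delta, 17 full_flag, 18 t0, 19 XT0
 */
#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>

#define NPARMS 20
static double parms[NPARMS];

void initmod(void (*odeparms)(int *, double *))
{
    int n = NPARMS;
    odeparms(&n, parms);
}

/* lagvalue C entry point provided by deSolve (only valid inside dede) */
static double (*lagvalue_fn)(double, int *, int, double *) = NULL;

static double lag_XT(double t)
{
    int idx = 1; /* 0-based index of X_T in the state vector */
    double ylag;
    if (lagvalue_fn == NULL)
        lagvalue_fn = (double (*)(double, int *, int, double *))
            R_GetCCallable("deSolve", "lagvalue");
    lagvalue_fn(t, &idx, 1, &ylag);
    return ylag;
}

static double hill_f(double X, double a)
{
    double Xn, Kn;
    if (X < 0) X = 0;
    Xn = pow(X, parms[2]);
    Kn = pow(parms[1], parms[2]);
    return a + parms[0] * Xn / (Kn + Xn);
}

static double hill_g(double X)
{
    double Xm, Km;
    if (X < 0) X = 0;
    Xm = pow(X, parms[6]);
    Km = pow(parms[5], parms[6]);
    return parms[3] + parms[4] * Km / (Km + Xm);
}

static double a_of_XT(double XT)
{
    if (parms[10] < 0.5) return parms[9];
    return parms[11] + parms[12] * tanh(parms[13] * (XT - parms[14]));
}

static double kinetics(double X, double XT, double a)
{
    double Xc = X < 0 ? 0 : X;
    return (hill_f(Xc, a) * (XT - Xc) - hill_g(Xc) * Xc) / parms[7];
}

/* dX_T/dt = k_X */
void d_transition(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double a = a_of_XT(y[1]);
    ydot[0] = kinetics(y[0], y[1], a);
    ydot[1] = parms[8];
}

/* delayed modulation: a = a(X_T(t - tau)) */
void d_transition_dde(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double tpast = *t - parms[15];
    double XTlag = (tpast <= parms[18]) ? parms[19] : lag_XT(tpast);
    double a = a_of_XT(XTlag);
    ydot[0] = kinetics(y[0], y[1], a);
    ydot[1] = parms[8];
}

/* dX_T/dt = k_X - X_T X; optional -X^2 term restores the full model */
void d_oscillator(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    double a = a_of_XT(y[1]);
    ydot[0] = kinetics(y[0], y[1], a);
    if (parms[17] > 0.5) ydot[0] -= y[0] * y[0];
    ydot[1] = parms[8] - y[1] * y[0];
}

void d_oscillator_dde(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double tpast = *t - parms[15];
    double XTlag = (tpast <= parms[18]) ? parms[19] : lag_XT(tpast);
    double a = a_of_XT(XTlag);
    ydot[0] = kinetics(y[0], y[1], a);
    if (parms[17] > 0.5) ydot[0] -= y[0] * y[0];
    ydot[1] = parms[8] - y[1] * y[0];
}

/* three-equation model: a relaxes to H(X_T) on timescale delta */
void d_three_eq(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double H = parms[11] + parms[12] * tanh(parms[13] * (y[1] - parms[14]));
    ydot[0] = kinetics(y[0], y[1], y[2]);
    ydot[1] = parms[8] - y[1] * y[0];
    ydot[2] = (H - y[2]) / parms[16];
}
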