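/* Compiled right-hand sides for the AFE -> LP population models.
 *
 * Two lineage structures are provided in the deSolve "compiled model"
 * convention (initializer + derivs pair, looked up by name in this DLL):
 *
 *   M0: states (n_q, c_g, c_l)       -- total live population only
 *   M1: states (n_a, n_p, c_g, c_l)  -- AFE and LP populations
 *
 * Growth and environment codes (passed through the parameter vector):
 *   growth: 1 exponential, 2 logistic, 3 Gompertz
 *   env:    0 none, 1 glu, 2 lac, 3 glulac
 *
 * Units project-wide: time d, densities cells mm^-2, concentrations mmol L^-1.
 * V_g / V_l enter as positive magnitudes; signs are applied here.
 * Negative state excursions (possible transiently with loose tolerances) are
 * floored at 0 inside the rate computations; the Gompertz log is clamped at
 * n >= 1e-9 to avoid the singularity of the functional form at n = 0.
 */

#include <R.h>
#include <math.h>

#define GOMPERTZ_FLOOR 1e-9

static double pm0[11];
static double pm1[14];

void afedyn_initmod_m0(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, pm0);
}

void afedyn_initmod_m1(void (*odeparms)(int *, double *))
{
    int n = 14;
    odeparms(&n, pm1);
}

/* density-dependent per-capita factor f_n(n_j) */
static double f_n(int growth, double n, double n_max)
{
    switch (growth) {
    case 1:
        return 1.0;
    case 2:
        return 1.0 - n / n_max;
    case 3:
        if (n < GOMPERTZ_FLOOR) n = GOMPERTZ_FLOOR;
        return log(n_max / n);
    }
    return 1.0;
}

/* multiplicative environmental factor F_env(c_g, c_l) */
static double f_env(int env, double cg, double cl, double K_g, double K_l)
{
    double f = 1.0;
    if (env == 1 || env == 3) f *= cg / (K_g + cg);
    if (env == 2 || env == 3) f *= K_l / (K_l + cl);
    return f;
}

void afedyn_derivs_m0(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    int growth = (int) pm0[0], env = (int) pm0[1];
    double beta_q = pm0[2], delta_q = pm0[3];
    double V_g = pm0[4], V_l = pm0[5];
    double cbar_g = pm0[6], cbar_l = pm0[7];
    double K_g = pm0[8], K_l = pm0[9], n_max = pm0[10];

    double nq = y[0] > 0 ? y[0] : 0;
    double cg = y[1] > 0 ? y[1] : 0;
    double cl = y[2] > 0 ? y[2] : 0;

    double f = f_env(env, cg, cl, K_g, K_l) * f_n(growth, nq, n_max);

    ydot[0] = beta_q * f * nq - delta_q * nq;
    ydot[1] = -V_g * nq * cg / (cg + cbar_g);
    ydot[2] = V_l * nq * cl / (cl + cbar_l);
}

/* Stacked variants: n independent copies of the same system (shared
 * parameters, different states) integrated in one solver call; used by the
 * likelihood to solve all experimental conditions at once.  The first
 * parameter slot carries the number of stacked blocks. */

static double pmm0[12];
static double pmm1[15];

void afedyn_initmod_m0m(void (*odeparms)(int *, double *))
{
    int n = 12;
    odeparms(&n, pmm0);
}

void afedyn_initmod_m1m(void (*odeparms)(int *, double *))
{
    int n = 15;
    odeparms(&n, pmm1);
}

void afedyn_derivs_m0m(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    int nblk = (int) pmm0[0];
    int growth = (int) pmm0[1], env = (int) pmm0[2];
    double beta_q = pmm0[3], delta_q = pmm0[4];
    double V_g = pmm0[5], V_l = pmm0[6];
    double cbar_g = pmm0[7], cbar_l = pmm0[8];
    double K_g = pmm0[9], K_l = pmm0[10], n_max = pmm0[11];

    for (int b = 0; b < nblk; b++) {
        double *yb = y + 3 * b, *db = ydot + 3 * b;
        double nq = yb[0] > 0 ? yb[0] : 0;
        double cg = yb[1] > 0 ? yb[1] : 0;
        double cl = yb[2] > 0 ? yb[2] : 0;
        double f = f_env(env, cg, cl, K_g, K_l) * f_n(growth, nq, n_max);
        db[0] = beta_q * f * nq - delta_q * nq;
        db[1] = -V_g * nq * cg / (cg + cbar_g);
        db[2] = V_l * nq * cl / (cl + cbar_l);
    }
}

void afedyn_derivs_m1m(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    int nblk = (int) pmm1[0];
    int growth = (int) pmm1[1], env = (int) pmm1[2];
    double beta_a = pmm1[3], p_ap = pmm1[4], delta_a = pmm1[5];
    double beta_p = pmm1[6], delta_p = pmm1[7];
    double V_g = pmm1[8], V_l = pmm1[9];
    double cbar_g = pmm1[10], cbar_l = pmm1[11];
    double K_g = pmm1[12], K_l = pmm1[13], n_max = pmm1[14];

    for (int b = 0; b < nblk; b++) {
        double *yb = y + 4 * b, *db = ydot + 4 * b;
        double na = yb[0] > 0 ? yb[0] : 0;
        double np = yb[1] > 0 ? yb[1] : 0;
        double cg = yb[2] > 0 ? yb[2] : 0;
        double cl = yb[3] > 0 ? yb[3] : 0;
        double env_f = f_env(env, cg, cl, K_g, K_l);
        double b_a = beta_a * env_f * f_n(growth, na, n_max);
        double b_p = beta_p * env_f * f_n(growth, np, n_max);
        double p_a = 2.0 * (1.0 - p_ap) * b_a;
        double ntot = na + np;
        db[0] = b_a * na - delta_a * na - p_a * na;
        db[1] = b_p * np - delta_p * np + p_a * na;
        db[2] = -V_g * ntot * cg / (cg + cbar_g);
        db[3] = V_l * ntot * cl / (cl + cbar_l);
    }
}

void afedyn_derivs_m1(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    int growth = (int) pm1[0], env = (int) pm1[1];
    double beta_a = pm1[2], p_ap = pm1[3], delta_a = pm1[4];
    double beta_p = pm1[5], delta_p = pm1[6];
    double V_g = pm1[7], V_l = pm1[8];
    double cbar_g = pm1[9], cbar_l = pm1[10];
    double K_g = pm1[11], K_l = pm1[12], n_max = pm1[13];

    double na = y[0] > 0 ? y[0] : 0;
    double np = y[1] > 0 ? y[1] : 0;
    double cg = y[2] > 0 ? y[2] : 0;
    double cl = y[3] > 0 ? y[3] : 0;

    double env_f = f_env(env, cg, cl, K_g, K_l);
    double b_a = beta_a * env_f * f_n(growth, na, n_max);
    double b_p = beta_p * env_f * f_n(growth, np, n_max);
    /* symmetric division: renewal with prob p_ap, differentiation flux
     * 2 (1 - p_ap) b_a n_a into the LP pool */
    double p_a = 2.0 * (1.0 - p_ap) * b_a;
    double ntot = na + np;

    ydot[0] = b_a * na - delta_a * na - p_a * na;
    ydot[1] = b_p * np - delta_p * np + p_a * na;
    ydot[2] = -V_g * ntot * cg / (cg + cbar_g);
    ydot[3] = V_l * ntot * cl / (cl + cbar_l);
}
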