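/* Compiled right-hand sides for the chemostat ODEs (deSolve interface).
 *
 * The parameter block is set from R with .Call("chemevo_set_parms", p)
 * before each solve; layout (all doubles):
 *   [0] m  [1] n  [2] R  [3] D  [4] a  [5] monod flag  [6] evolve flag
 *   [7 .. 7+m)            Q
 *   [.. +R)                src (1-based substrate index per reaction)
 *   [.. +R)                dst
 *   [.. +R*n)              v   (reaction x species, column-major)
 *   [.. +R*n)              K
 *   [.. +R*n)              c
 *   [.. +R*n)              E   (used only by the non-evolving model)
 *   [.. +n)                mu * nE/(nE-1) per species
 *
 * State vector: S (m), N (n), then (evolving only) E column-major
 * (reaction fastest within species). Negative S, N are treated as zero and
 * E is clipped to [0, 1] when evaluating fluxes, matching the R reference
 * implementation.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <math.h>
#include <string.h>

static double *pars = NULL;
static R_xlen_t npars = 0;

SEXP chemevo_set_parms(SEXP p)
{
    R_xlen_t len = XLENGTH(p);
    if (pars != NULL) {
        R_Free(pars);
        pars = NULL;
    }
    pars = R_Calloc(len, double);
    memcpy(pars, REAL(p), (size_t) len * sizeof(double));
    npars = len;
    return R_NilValue;
}

#define TRUNC_DELTA 1e-6

/* Truncate allocation change at the [0, 1] boundary: scale outward
 * components down smoothly over a boundary layer of width TRUNC_DELTA,
 * then redistribute the removed change across the other components in
 * proportion to their room to absorb it, keeping the sum at zero. Mirrors
 * .truncate_dE in R/dynamics.R. */
static void truncate_dE(int R, const double *E, double *dE)
{
    int r;
    double deficit = 0.0, su = 0.0;
    double u[256];

    for (r = 0; r < R; r++) {
        double w = 1.0;
        if (dE[r] < 0.0) {
            w = E[r] / TRUNC_DELTA;
            if (w > 1.0) w = 1.0;
        } else if (dE[r] > 0.0) {
            w = (1.0 - E[r]) / TRUNC_DELTA;
            if (w > 1.0) w = 1.0;
        }
        dE[r] *= w;
        deficit += dE[r];
    }
    if (deficit == 0.0) return;
    for (r = 0; r < R; r++) {
        u[r] = (deficit > 0.0) ? E[r] / TRUNC_DELTA
                               : (1.0 - E[r]) / TRUNC_DELTA;
        if (u[r] > 1.0) u[r] = 1.0;
        su += u[r];
    }
    if (su > 1e-12)
        for (r = 0; r < R; r++)
            dE[r] -= deficit * u[r] / su;
}

void chemevo_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    const double *p = pars;
    int m, n, R, monod, evolve, i, k, r;
    double D, a;
    const double *Q, *src, *dst, *vT, *KT, *cT, *ET, *mufac;

    if (p == NULL) error("chemevo parameters not initialized");
    m = (int) p[0]; n = (int) p[1]; R = (int) p[2];
    D = p[3]; a = p[4];
    monod = (int) p[5]; evolve = (int) p[6];
    Q = p + 7;
    src = Q + m;
    dst = src + R;
    vT = dst + R;
    KT = vT + (R_xlen_t) R * n;
    cT = KT + (R_xlen_t) R * n;
    ET = cT + (R_xlen_t) R * n;
    mufac = ET + (R_xlen_t) R * n;

    {
        double Sc[256], dS[256], g[256], dE[256], Ec[256];
        if (m > 256 || R > 256) error("system too large for compiled rhs");

        for (i = 0; i < m; i++) {
            Sc[i] = y[i] > 0.0 ? y[i] : 0.0;
            dS[i] = D * (Q[i] - Sc[i]);
        }
        for (k = 0; k < n; k++) {
            double Nk = y[m + k] > 0.0 ? y[m + k] : 0.0;
            const double *vk = vT + (R_xlen_t) R * k;
            const double *Kk = KT + (R_xlen_t) R * k;
            const double *ck = cT + (R_xlen_t) R * k;
            const double *Ek = evolve ? y + m + n + (R_xlen_t) R * k
                                      : ET + (R_xlen_t) R * k;
            double grow = 0.0;

            for (r = 0; r < R; r++) {
                double E = Ek[r];
                double Ss, mon, Ea, J, q;
                int is = (int) src[r] - 1, id = (int) dst[r] - 1;
                if (E < 0.0) E = 0.0; else if (E > 1.0) E = 1.0;
                Ec[r] = E;
                Ss = Sc[is];
                mon = monod ? Ss / (Kk[r] + Ss) : Ss;
                Ea = (a == 1.0) ? E : pow(E, a);
                J = vk[r] * Ea * mon;
                q = J * Nk;
                dS[is] -= q;
                dS[id] += q;
                grow += ck[r] * J;
                if (evolve)
                    g[r] = ck[r] * vk[r] * mon *
                        ((a == 1.0) ? 1.0 : a * pow(E, a - 1.0));
            }
            ydot[m + k] = (grow - D) * Nk;

            if (evolve) {
                double gm = 0.0;
                for (r = 0; r < R; r++) gm += g[r];
                gm /= R;
                for (r = 0; r < R; r++)
                    dE[r] = mufac[k] * (g[r] - gm);
                truncate_dE(R, Ec, dE);
                for (r = 0; r < R; r++)
                    ydot[m + n + (R_xlen_t) R * k + r] = dE[r];
            }
        }
        for (i = 0; i < m; i++) ydot[i] = dS[i];
    }
}

static const R_CallMethodDef callMethods[] = {
    {"chemevo_set_parms", (DL_FUNC) &chemevo_set_parms, 1},
    {NULL, NULL, 0}
};

void R_init_chemevo(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, callMethods, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
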