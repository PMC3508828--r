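/* Compiled right-hand sides for the cascade ODE systems, used through
 * deSolve's native-code interface. The R closures in k1_engine.R /
 * k2_engine.R are the reference implementations; these evaluators are
 * driven by flat parameter vectors encoding the same flux tables and
 * must agree with them to machine precision (regression-tested).
 *
 * Parameter vector layouts are documented in R/engine.R.
 */

#include <R.h>
#include <R_ext/Rdynload.h>

#define PARMS_MAX 4096
#define RXN_MAX 128

static double pstore[PARMS_MAX];

void cascade_initmod(void (*odeparms)(int *, double *))
{
    int n = PARMS_MAX;
    odeparms(&n, pstore);
}

/* Michaelis-Menten (K1/K2_QSS) scheme: 5 phosphoform states plus the
 * three free kinases recovered from the conservation relations. */
void cascade_derivs_k1(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    const double *p = pstore;
    double val[8];
    int g, off;

    double sig = p[0];
    double neg_tol = p[4];
    int n_groups = (int) p[5];

    val[0] = y[0]; val[1] = y[1]; val[2] = y[2]; val[3] = y[3];
    val[4] = y[4];
    val[5] = p[1] - y[0];               /* free MKKK */
    val[6] = p[2] - y[1] - y[2];        /* free MKK  */
    val[7] = p[3] - y[3] - y[4];        /* free MK   */
    if (val[5] < neg_tol || val[6] < neg_tol || val[7] < neg_tol)
        error("state exceeds kinase conservation totals");

    for (int i = 0; i < 5; i++) ydot[i] = 0.0;

    off = 6;
    for (g = 0; g < n_groups; g++) {
        int e_kind = (int) p[off++];
        double e_ref = p[off++];
        double kse = p[off++];
        int n_seq = (int) p[off++];
        double seq_sum = 0.0;
        for (int s = 0; s < n_seq; s++)
            seq_sum += val[(int) p[off++] - 1];
        int n_mem = (int) p[off];
        off++;

        double E = (e_kind == 0) ? sig :
                   (e_kind == 1) ? val[(int) e_ref - 1] : e_ref;
        /* first pass: denominator */
        double den = 1.0;
        if (kse > 0.0) den += seq_sum / kse;
        int mem_off = off;
        for (int m = 0; m < n_mem; m++) {
            double Km = p[mem_off + 1];
            int sub = (int) p[mem_off + 2];
            den += val[sub - 1] / Km;
            mem_off += 8;
        }
        /* second pass: fluxes and stoichiometry */
        mem_off = off;
        for (int m = 0; m < n_mem; m++) {
            double kcat = p[mem_off];
            double Km = p[mem_off + 1];
            int sub = (int) p[mem_off + 2];
            double flux = kcat * E * (val[sub - 1] / Km) / den;
            for (int i = 0; i < 5; i++)
                ydot[i] += p[mem_off + 3 + i] * flux;
            mem_off += 8;
        }
        off = mem_off;
    }
}

/* Elementary mass-action (K2) scheme over the full species set. */
void cascade_derivs_k2(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    const double *p = pstore;
    double rates[RXN_MAX];

    int sig_off = (int) p[0];
    int sig_idx = (int) p[1] - 1;
    int n_rxn = (int) p[2];
    const double *k = p + 3;
    const double *i1 = p + 3 + n_rxn;
    const double *i2 = p + 3 + 2 * n_rxn;
    int tb = 3 + 3 * n_rxn;
    int n_trip = (int) p[tb];
    const double *rows = p + tb + 1;
    const double *cols = p + tb + 1 + n_trip;
    const double *vals = p + tb + 1 + 2 * n_trip;

    for (int j = 0; j < n_rxn; j++) {
        int a = (int) i1[j] - 1;
        double ya = (sig_off && a == sig_idx) ? 0.0 : y[a];
        double r = k[j] * ya;
        int b = (int) i2[j];
        if (b > 0) {
            double yb = (sig_off && b - 1 == sig_idx) ? 0.0 : y[b - 1];
            r *= yb;
        }
        rates[j] = r;
    }
    for (int i = 0; i < *neq; i++) ydot[i] = 0.0;
    for (int tgt = 0; tgt < n_trip; tgt++)
        ydot[(int) rows[tgt] - 1] += vals[tgt] * rates[(int) cols[tgt] - 1];
    if (sig_off) ydot[sig_idx] = 0.0;
}

static const R_CMethodDef CEntries[] = {
    {"cascade_initmod",  (DL_FUNC) &cascade_initmod,  1},
    {"cascade_derivs_k1", (DL_FUNC) &cascade_derivs_k1, 6},
    {"cascade_derivs_k2", (DL_FUNC) &cascade_derivs_k2, 6},
    {NULL, NULL, 0}
};

void R_init_mapkdesign(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
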