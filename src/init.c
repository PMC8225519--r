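#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_ua_conc(SEXP block, SEXP tvec);
SEXP C_ua_marginal(SEXP s_tmpl, SEXP s_slot, SEXP s_times, SEXP s_sidx,
                   SEXP s_sy, SEXP s_u0, SEXP s_u1, SEXP s_uy,
                   SEXP s_sigma, SEXP s_oinv, SEXP s_pconst, SEXP s_eta0,
                   SEXP s_ctrl);
void ua_init(void (*odeparms)(int *, double *));
void ua_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip);

static const R_CallMethodDef CallEntries[] = {
    {"C_ua_conc", (DL_FUNC) &C_ua_conc, 2},
    {"C_ua_marginal", (DL_FUNC) &C_ua_marginal, 13},
    {NULL, NULL, 0}
};

void R_init_uratesim(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
    /* deSolve looks these up by name */
    R_RegisterCCallable("uratesim", "ua_init", (DL_FUNC) &ua_init);
    R_RegisterCCallable("uratesim", "ua_derivs", (DL_FUNC) &ua_derivs);
}
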