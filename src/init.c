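#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_gauss_conv_plin(SEXP, SEXP, SEXP, SEXP);
void initmod_bloch(void (*)(int *, double *));
void derivs_bloch(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef call_entries[] = {
    {"C_gauss_conv_plin", (DL_FUNC) &C_gauss_conv_plin, 4},
    {NULL, NULL, 0}
};

/* registered so deSolve can look them up by name in this DLL */
static const R_CMethodDef c_entries[] = {
    {"initmod_bloch", (DL_FUNC) &initmod_bloch, 1},
    {"derivs_bloch",  (DL_FUNC) &derivs_bloch,  6},
    {NULL, NULL, 0}
};

void R_init_ppkin(DllInfo *dll)
{
    R_registerRoutines(dll, c_entries, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, FALSE);
}
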