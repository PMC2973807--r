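#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_znorm(SEXP, SEXP);
SEXP C_stationary(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
SEXP C_run_motor(SEXP, SEXP);

static const R_CallMethodDef call_entries[] = {
    {"C_znorm",      (DL_FUNC) &C_znorm,      2},
    {"C_stationary", (DL_FUNC) &C_stationary, 6},
    {"C_run_motor",  (DL_FUNC) &C_run_motor,  2},
    {NULL, NULL, 0}
};

void R_init_neckstep(DllInfo *dll) {
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
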