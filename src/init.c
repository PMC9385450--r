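#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP cometrics_write_png16(SEXP labels, SEXP dims, SEXP path);

static const R_CallMethodDef call_entries[] = {
    {"cometrics_write_png16", (DL_FUNC) &cometrics_write_png16, 3},
    {NULL, NULL, 0}
};

void R_init_cometrics(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
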