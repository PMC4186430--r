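#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void apgsi_init(void (*odeparms)(int *, double *));
void apgsi_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"apgsi_init",   (DL_FUNC) &apgsi_init,   1},
    {"apgsi_derivs", (DL_FUNC) &apgsi_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_apgsi(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
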