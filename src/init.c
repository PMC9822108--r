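#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void initmod_met(void (*odeparms)(int *, double *));
void derivs_met(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);
void initmod_cmb(void (*odeparms)(int *, double *));
void derivs_cmb(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"initmod_met", (DL_FUNC) &initmod_met, 1},
    {"derivs_met",  (DL_FUNC) &derivs_met,  6},
    {"initmod_cmb", (DL_FUNC) &initmod_cmb, 1},
    {"derivs_cmb",  (DL_FUNC) &derivs_cmb,  6},
    {NULL, NULL, 0}
};

void R_init_neurometab(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE); /* deSolve looks up symbols by name */
}
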