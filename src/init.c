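#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* deterministic model RHS entry points (models.c), called by deSolve */
void initmod(void (*odeparms)(int *, double *));
void d_transition(int *, double *, double *, double *, double *, int *);
void d_transition_dde(int *, double *, double *, double *, double *, int *);
void d_oscillator(int *, double *, double *, double *, double *, int *);
void d_oscillator_dde(int *, double *, double *, double *, double *, int *);
void d_three_eq(int *, double *, double *, double *, double *, int *);

/* Rcpp exports (RcppExports.cpp) */
SEXP _dynswitch_ssa_simulate_cpp(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"_dynswitch_ssa_simulate_cpp", (DL_FUNC) &_dynswitch_ssa_simulate_cpp, 7},
    {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
    {"initmod",          (DL_FUNC) &initmod,          1},
    {"d_transition",     (DL_FUNC) &d_transition,     6},
    {"d_transition_dde", (DL_FUNC) &d_transition_dde, 6},
    {"d_oscillator",     (DL_FUNC) &d_oscillator,     6},
    {"d_oscillator_dde", (DL_FUNC) &d_oscillator_dde, 6},
    {"d_three_eq",       (DL_FUNC) &d_three_eq,       6},
    {NULL, NULL, 0}
};

void R_init_dynswitch(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
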