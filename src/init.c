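#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

/* Rcpp attribute wrappers (defined in RcppExports.cpp) */
SEXP _digitalizer_ssa_cell(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                           SEXP, SEXP, SEXP);
SEXP _digitalizer_ssa_population(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP,
                                 SEXP, SEXP);

/* deSolve entry points (defined in ode_rhs.c) */
void dig_init(void (*odeparms)(int *, double *));
void dig_derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
  {"_digitalizer_ssa_cell", (DL_FUNC) &_digitalizer_ssa_cell, 11},
  {"_digitalizer_ssa_population", (DL_FUNC) &_digitalizer_ssa_population, 9},
  {NULL, NULL, 0}
};

static const R_CMethodDef CEntries[] = {
  {"dig_init", (DL_FUNC) &dig_init, 1},
  {"dig_derivs", (DL_FUNC) &dig_derivs, 6},
  {NULL, NULL, 0}
};

void R_init_digitalizer(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
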