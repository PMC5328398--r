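/* Stack-machine evaluator for compiled rate-law expressions.
 *
 * Each reaction's symbolic rate law is translated (in R) into a compact
 * postfix program over the opcodes below; this evaluator computes all
 * reaction rates in one pass.  Operands are the species concentration
 * vector x, the kinetic parameter vector p and a per-program constant
 * table.  Programs are stored as (op, arg) integer pairs.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>

#define OP_CONST 0
#define OP_X     1
#define OP_P     2
#define OP_ADD   3
#define OP_SUB   4
#define OP_MUL   5
#define OP_DIV   6
#define OP_POW   7
#define OP_NEG   8
#define OP_LOG   9

#define STACK_MAX 128

SEXP C_eval_rates(SEXP code, SEXP starts, SEXP lens, SEXP consts,
                  SEXP x, SEXP p, SEXP scale)
{
    const int *cd = INTEGER(code);
    const int *st = INTEGER(starts);
    const int *ln = INTEGER(lens);
    const double *cs = REAL(consts);
    const double *xv = REAL(x);
    const double *pv = REAL(p);
    const double *sc = REAL(scale);
    const int nrx = LENGTH(starts);
    const int nsc = LENGTH(scale);

    SEXP out = PROTECT(allocVector(REALSXP, nrx));
    double *ov = REAL(out);
    double stack[STACK_MAX];

    for (int r = 0; r < nrx; r++) {
        int sp = 0;
        const int *prog = cd + st[r];
        const int n = ln[r];
        for (int k = 0; k < n; k += 2) {
            const int op = prog[k];
            const int arg = prog[k + 1];
            switch (op) {
            case OP_CONST: stack[sp++] = cs[arg]; break;
            case OP_X:     stack[sp++] = xv[arg]; break;
            case OP_P:     stack[sp++] = pv[arg]; break;
            case OP_ADD:   sp--; stack[sp - 1] += stack[sp]; break;
            case OP_SUB:   sp--; stack[sp - 1] -= stack[sp]; break;
            case OP_MUL:   sp--; stack[sp - 1] *= stack[sp]; break;
            case OP_DIV:   sp--; stack[sp - 1] /= stack[sp]; break;
            case OP_POW:   sp--; stack[sp - 1] = pow(stack[sp - 1], stack[sp]); break;
            case OP_NEG:   stack[sp - 1] = -stack[sp - 1]; break;
            case OP_LOG:   stack[sp - 1] = log(stack[sp - 1]); break;
            default: UNPROTECT(1); error("invalid opcode %d", op);
            }
            if (sp >= STACK_MAX) { UNPROTECT(1); error("expression stack overflow"); }
        }
        ov[r] = (nsc == 1 ? sc[0] : sc[r]) * stack[0];
    }
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_eval_rates", (DL_FUNC) &C_eval_rates, 7},
    {NULL, NULL, 0}
};

void R_init_colikin(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
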