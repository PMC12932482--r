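/* Compiled right-hand side of the 3-compartment transwell model.
 *
 * States: X_A, X_C, X_B (pmol). Parameters (set via initfunc):
 *   0 V_A, 1 V_C, 2 V_B (uL), 3 area (cm2),
 *   4 cA_in: total linear A->C clearance per cm2 (active + passive, uL/min),
 *   5 cB_in: total linear B->C clearance per cm2,
 *   6 c_pass_out: passive cell->chamber clearance per cm2,
 *   7 vCA, 8 kmCA: apical efflux Vmax (pmol/min/cm2, pH-scaled) and Km (uM),
 *   9 vCB, 10 kmCB: basolateral efflux.
 * All pH-power factors and unionized fractions are folded into the
 * coefficients by the R caller, so the kernel is pure arithmetic.
 */
#include <R.h>

static double parms[11];

void transwell_init(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

/* Stacked variant: N independent transwell systems integrated jointly so a
 * whole multi-condition assay needs one solver call. Parameters:
 * [0] = N (number of conditions), then 11 per condition as above.
 */
#define MULTI_MAX 128
static double mparms[1 + 11 * MULTI_MAX];

void transwell_multi_init(void (*odeparms)(int *, double *))
{
    int n = 1 + 11 * MULTI_MAX;
    odeparms(&n, mparms);
}

void transwell_multi_derivs(int *neq, double *t, double *y, double *ydot,
                            double *yout, int *ip)
{
    int n = (int) mparms[0];
    for (int c = 0; c < n; c++) {
        const double *p = mparms + 1 + 11 * c;
        const double *yc = y + 3 * c;
        double *dc = ydot + 3 * c;
        double C_A = (yc[0] > 0 ? yc[0] : 0) / p[0];
        double C_C = (yc[1] > 0 ? yc[1] : 0) / p[1];
        double C_B = (yc[2] > 0 ? yc[2] : 0) / p[2];
        double J_AC = p[4] * C_A;
        double J_CA = p[7] * C_C / (p[8] + C_C) + p[6] * C_C;
        double J_BC = p[5] * C_B;
        double J_CB = p[9] * C_C / (p[10] + C_C) + p[6] * C_C;
        dc[0] = p[3] * (J_CA - J_AC);
        dc[2] = p[3] * (J_CB - J_BC);
        dc[1] = -(dc[0] + dc[2]);
    }
}

void transwell_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double V_A = parms[0], V_C = parms[1], V_B = parms[2], area = parms[3];
    double cA_in = parms[4], cB_in = parms[5], c_pass = parms[6];
    double vCA = parms[7], kmCA = parms[8], vCB = parms[9], kmCB = parms[10];

    double C_A = (y[0] > 0 ? y[0] : 0) / V_A;
    double C_C = (y[1] > 0 ? y[1] : 0) / V_C;
    double C_B = (y[2] > 0 ? y[2] : 0) / V_B;

    double J_AC = cA_in * C_A;
    double J_CA = vCA * C_C / (kmCA + C_C) + c_pass * C_C;
    double J_BC = cB_in * C_B;
    double J_CB = vCB * C_C / (kmCB + C_C) + c_pass * C_C;

    ydot[0] = area * (J_CA - J_AC);
    ydot[2] = area * (J_CB - J_BC);
    ydot[1] = -(ydot[0] + ydot[2]);
}
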