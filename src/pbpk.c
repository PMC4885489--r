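/* Minimal-PBPK right-hand side for victim + perpetrator with dynamic
 * CYP3A4 enzyme pools in liver and gut, for use with deSolve.
 *
 * Compartment chain per compound (amounts, mg):
 *   gut lumen -> enterocyte -> portal vein -> liver -> systemic
 * plus cumulative-flux bookkeeping states and a plasma-AUC integral.
 * Two shared enzyme states (relative active CYP3A4, baseline 1): liver, gut.
 *
 * Parameter vector (see R/pbpk_core.R, .pbpk_parms for the builder):
 *   [0] QH   hepatic blood flow, L/h
 *   [1] QPV  portal vein blood flow, L/h
 *   [2] QGUT villous/"Qgut" flow for the gut extraction model, L/h
 *   [3] VENT enterocyte volume, L
 *   [4] VPV  portal vein volume, L
 *   [5] VLIV liver volume, L
 *   [6] KDEGH, [7] KDEGG  enzyme degradation rate constants, 1/h
 *   [8] CLAMP (0/1): if 1, perpetrator driving concentrations are held at
 *   [9] ICONST_LIV_UM and [10] ICONST_GUT_UM (unbound, uM)
 *   then two blocks of 23 per compound (victim = block 0, perp = block 1):
 *   MW, FUP, BP, FUGUT, KA, VSYS, CLR, KP,
 *   CLUH3A4, KMH3A4, CLUHOTH, KMHOTH, CLUG3A4, KMG3A4, CLUGOTH, KMGOTH,
 *   KIU, INDMAXH, INDC50H, INDMAXG, INDC50G, KI_MBI, KINACT
 * Km / Ki / K_I are unbound uM; +Inf disables saturation / inhibition / MBI.
 *
 * State vector: two blocks of 12 then EnzH, EnzG (26 states):
 *   A_lumen, A_ent, A_pv, A_liv, A_sys,
 *   cum_abs, cum_gut_escape, cum_metH_3a4, cum_metH_other, cum_metG,
 *   cum_renal, cum_auc_plasma
 */

#include <R.h>
#include <math.h>

#define N_PARMS 57
#define N_GLOBAL 11
#define N_CPAR 23
#define N_CSTATE 12

static double parms[N_PARMS];

void pbpk_initmod(void (*odeparms)(int *, double *))
{
    int n = N_PARMS;
    odeparms(&n, parms);
}

#define P(i) parms[(i)]
#define CP(c, i) parms[N_GLOBAL + (c) * N_CPAR + (i)]

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const double QH = P(0), QPV = P(1), QGUT = P(2);
    const double VENT = P(3), VPV = P(4), VLIV = P(5);
    const double KDEGH = P(6), KDEGG = P(7);
    const int clamp = (P(8) > 0.5);
    const double IcL = P(9), IcG = P(10);

    const double EnzH = y[24], EnzG = y[25];

    /* per-compound local quantities */
    double Cent[2], Cu_ent_mgL[2], Iu_ent[2];
    double Cpvb[2], Iu_pv[2];
    double Coutb[2], Cu_liv_mgL[2], Iu_liv[2];
    double Csysp[2], Csysb[2], fuB[2];

    int c;
    for (c = 0; c < 2; c++) {
        double MW = CP(c, 0), FUP = CP(c, 1), BP = CP(c, 2),
               FUGUT = CP(c, 3), VSYS = CP(c, 5), KP = CP(c, 7);
        double *yc = y + c * N_CSTATE;
        double uMfac = 1000.0 / MW;

        fuB[c] = FUP / BP;
        Cent[c] = yc[1] / VENT;
        Cu_ent_mgL[c] = FUGUT * Cent[c];
        Iu_ent[c] = Cu_ent_mgL[c] * uMfac;
        Cpvb[c] = yc[2] / VPV;
        Iu_pv[c] = fuB[c] * Cpvb[c] * uMfac;
        Coutb[c] = yc[3] / (VLIV * KP / BP);
        Cu_liv_mgL[c] = fuB[c] * Coutb[c];
        Iu_liv[c] = Cu_liv_mgL[c] * uMfac;
        Csysp[c] = yc[4] / VSYS;
        Csysb[c] = BP * Csysp[c];
    }

    /* clamped perpetrator drivers (perp = compound 1) */
    double drvLiv[2], drvEnt[2], drvPv[2];
    for (c = 0; c < 2; c++) {
        drvLiv[c] = Iu_liv[c];
        drvEnt[c] = Iu_ent[c];
        drvPv[c] = Iu_pv[c];
    }
    if (clamp) {
        drvLiv[1] = IcL;
        drvEnt[1] = IcG;
        drvPv[1] = IcG;
    }

    for (c = 0; c < 2; c++) {
        double KA = CP(c, 4), CLR = CP(c, 6);
        double CLUH3A4 = CP(c, 8), KMH3A4 = CP(c, 9);
        double CLUHOTH = CP(c, 10), KMHOTH = CP(c, 11);
        double CLUG3A4 = CP(c, 12), KMG3A4 = CP(c, 13);
        double CLUGOTH = CP(c, 14), KMGOTH = CP(c, 15);
        double *yc = y + c * N_CSTATE;
        double *dc = ydot + c * N_CSTATE;
        int o = 1 - c;

        /* competitive inhibition of CYP3A4 by the other compound */
        double divH = 1.0, divG = 1.0;
        if (R_FINITE(CP(o, 16))) {
            divH += drvLiv[o] / CP(o, 16);
            divG += drvPv[o] / CP(o, 16);
        }

        double cluH3 = EnzH * CLUH3A4 / ((1.0 + Iu_liv[c] / KMH3A4) * divH);
        double cluHo = CLUHOTH / (1.0 + Iu_liv[c] / KMHOTH);
        double cluG3 = EnzG * CLUG3A4 / ((1.0 + Iu_ent[c] / KMG3A4) * divG);
        double cluGo = CLUGOTH / (1.0 + Iu_ent[c] / KMGOTH);

        double absF = KA * yc[0];
        double gutout = QGUT * Cent[c];
        double metG = (cluG3 + cluGo) * Cu_ent_mgL[c];
        double metH3 = cluH3 * Cu_liv_mgL[c];
        double metHo = cluHo * Cu_liv_mgL[c];
        double renal = CLR * Csysp[c];

        dc[0] = -absF;
        dc[1] = absF - gutout - metG;
        dc[2] = QPV * Csysb[c] + gutout - QPV * Cpvb[c];
        dc[3] = QPV * Cpvb[c] + (QH - QPV) * Csysb[c]
                - QH * Coutb[c] - metH3 - metHo;
        dc[4] = QH * Coutb[c] - QH * Csysb[c] - renal;
        dc[5] = absF;
        dc[6] = gutout;
        dc[7] = metH3;
        dc[8] = metHo;
        dc[9] = metG;
        dc[10] = renal;
        dc[11] = Csysp[c];
    }

    /* enzyme turnover: synthesis stimulated by induction, first-order
     * degradation, optional mechanism-based inactivation */
    double stimH = 0.0, stimG = 0.0, mbiH = 0.0, mbiG = 0.0;
    for (c = 0; c < 2; c++) {
        double IMH = CP(c, 17), IC50H = CP(c, 18);
        double IMG = CP(c, 19), IC50G = CP(c, 20);
        double KI = CP(c, 21), KIN = CP(c, 22);
        if (drvLiv[c] > 0.0) {
            stimH += (IMH - 1.0) * drvLiv[c] / (IC50H + drvLiv[c]);
            if (KIN > 0.0)
                mbiH += KIN * drvLiv[c] / (KI + drvLiv[c]);
        }
        if (drvEnt[c] > 0.0) {
            stimG += (IMG - 1.0) * drvEnt[c] / (IC50G + drvEnt[c]);
            if (KIN > 0.0)
                mbiG += KIN * drvEnt[c] / (KI + drvEnt[c]);
        }
    }
    ydot[24] = KDEGH * (1.0 + stimH) - KDEGH * EnzH - EnzH * mbiH;
    ydot[25] = KDEGG * (1.0 + stimG) - KDEGG * EnzG - EnzG * mbiG;

    if (*ip >= 2) {
        yout[0] = EnzH;
        yout[1] = EnzG;
    }
}
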