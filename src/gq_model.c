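/* Mass-action right-hand side of the CysLT2R -> G-alpha-q/11 -> {TRIO, PLCbeta}
 * activation cycle, in the deSolve compiled-code calling convention.
 *
 * State vector (22 species). For each G-alpha pool p (0 = WT, 1 = mutant),
 * base index b = 9*p:
 *   b+0 HT       heterotrimer GaGDP.Gbg
 *   b+1 GDP      free GaGDP
 *   b+2 GTP      free GaGTP
 *   b+3 EMPTY    nucleotide-free Ga
 *   b+4 GT_TRIO  GaGTP.TRIO complex (active TRIO)
 *   b+5 GT_PLC   GaGTP.PLC complex (active PLCbeta)
 *   b+6 RGS_GA   RGS.GaGTP GAP complex
 *   b+7 GDP_D    GDI-drug-bound free GaGDP
 *   b+8 HT_D     GDI-drug-bound heterotrimer
 * Shared pools: 18 Gbg, 19 TRIO, 20 PLC, 21 RGS.
 *
 * Parameter vector (27 entries), set through deSolve's initfunc:
 *   0  k_gef      receptor-catalyzed GDP->GTP exchange (per conc per time)
 *   1  k_hyd      intrinsic GTP hydrolysis (per time)
 *   2  k_rgs_on   RGS + GaGTP association
 *   3  k_rgs_off  RGS.GaGTP dissociation
 *   4  k_rgs_cat  RGS GAP catalysis
 *   5  k_at1      GaGTP + TRIO association
 *   6  k_dt1      GaGTP.TRIO dissociation
 *   7  k_at2      GaGTP + PLC association
 *   8  k_dt2      GaGTP.PLC dissociation
 *   9  k_hyd2     GAP hydrolysis inside GaGTP.PLC (PLC as GAP)
 *   10 k_gtp_off  GTP release -> nucleotide-free Ga
 *   11 k_nt_load  nucleotide rebinding (pseudo-first-order)
 *   12 k_trimer   GaGDP + Gbg reassociation
 *   13 Ract       effective active-receptor concentration (catalytic)
 *   14 s_hyd_wt   15 s_hyd_mut    pool scaling of intrinsic hydrolysis
 *   16 s_gap_wt   17 s_gap_mut    pool scaling of GAP-stimulated hydrolysis
 *   18 s_at1_wt   19 s_at1_mut    pool scaling of TRIO association
 *   20 s_at2_wt   21 s_at2_mut    pool scaling of PLC association
 *   22 k_on_drug  23 k_off_drug   GDI binding kinetics
 *   24 dose       clamped (buffered) drug concentration
 *   25 bind_free  0/1: drug binds free GaGDP
 *   26 bind_ht    0/1: drug binds the heterotrimer
 *
 * The receptor is catalytic (not consumed); drug dose is clamped, so
 * drug-bound species enter only the G-alpha conservation sums.
 */

#include <R.h>

#define GQ_NPARMS 27
#define GQ_NSTATE 22

static double parms[GQ_NPARMS];

void gq_initmod(void (*odeparms)(int *, double *))
{
    int n = GQ_NPARMS;
    odeparms(&n, parms);
}

void gq_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double k_gef = parms[0], k_hyd = parms[1];
    const double k_rgs_on = parms[2], k_rgs_off = parms[3], k_rgs_cat = parms[4];
    const double k_at1 = parms[5], k_dt1 = parms[6];
    const double k_at2 = parms[7], k_dt2 = parms[8];
    const double k_hyd2 = parms[9], k_gtp_off = parms[10], k_nt_load = parms[11];
    const double k_trimer = parms[12], Ract = parms[13];
    const double k_on_d = parms[22], k_off_d = parms[23], dose = parms[24];
    const double bind_free = parms[25], bind_ht = parms[26];

    const double Gbg = y[18], TRIO = y[19], PLC = y[20], RGS = y[21];
    double dGbg = 0.0, dTRIO = 0.0, dPLC = 0.0, dRGS = 0.0;

    for (int p = 0; p < 2; p++) {
        const int b = 9 * p;
        const double s_hyd = parms[14 + p], s_gap = parms[16 + p];
        const double s_at1 = parms[18 + p], s_at2 = parms[20 + p];

        const double HT = y[b], GDP = y[b + 1], GTP = y[b + 2];
        const double EMPTY = y[b + 3], GT_TRIO = y[b + 4], GT_PLC = y[b + 5];
        const double RGS_GA = y[b + 6], GDP_D = y[b + 7], HT_D = y[b + 8];

        const double v_gef     = k_gef * Ract * HT;
        const double v_hyd     = k_hyd * s_hyd * GTP;
        const double v_rgs_on  = k_rgs_on * RGS * GTP;
        const double v_rgs_off = k_rgs_off * RGS_GA;
        const double v_rgs_cat = k_rgs_cat * s_gap * RGS_GA;
        const double v_at1     = k_at1 * s_at1 * GTP * TRIO;
        const double v_dt1     = k_dt1 * GT_TRIO;
        const double v_at2     = k_at2 * s_at2 * GTP * PLC;
        const double v_dt2     = k_dt2 * GT_PLC;
        const double v_hyd2    = k_hyd2 * s_gap * GT_PLC;
        const double v_off     = k_gtp_off * GTP;
        const double v_load    = k_nt_load * EMPTY;
        const double v_tri     = k_trimer * GDP * Gbg;
        const double v_don_f   = k_on_d * dose * GDP * bind_free;
        const double v_doff_f  = k_off_d * GDP_D;
        const double v_don_h   = k_on_d * dose * HT * bind_ht;
        const double v_doff_h  = k_off_d * HT_D;

        ydot[b]     = -v_gef + v_tri - v_don_h + v_doff_h;
        ydot[b + 1] = v_hyd + v_rgs_cat + v_hyd2 - v_tri - v_don_f + v_doff_f;
        ydot[b + 2] = v_gef - v_hyd - v_rgs_on + v_rgs_off
                      - v_at1 + v_dt1 - v_at2 + v_dt2 - v_off + v_load;
        ydot[b + 3] = v_off - v_load;
        ydot[b + 4] = v_at1 - v_dt1;
        ydot[b + 5] = v_at2 - v_dt2 - v_hyd2;
        ydot[b + 6] = v_rgs_on - v_rgs_off - v_rgs_cat;
        ydot[b + 7] = v_don_f - v_doff_f;
        ydot[b + 8] = v_don_h - v_doff_h;

        dGbg  += v_gef - v_tri;
        dTRIO += -v_at1 + v_dt1;
        dPLC  += -v_at2 + v_dt2 + v_hyd2;
        dRGS  += -v_rgs_on + v_rgs_off + v_rgs_cat;
    }

    ydot[18] = dGbg;
    ydot[19] = dTRIO;
    ydot[20] = dPLC;
    ydot[21] = dRGS;
}
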