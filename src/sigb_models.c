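/* Compiled right-hand sides for the sigma-B partner-switching network,
 * in the deSolve compiled-model convention (initmod/initforc/derivs).
 * The single forcing is the total phosphatase concentration P_T(t).
 * States carry the nine explicit species followed by the integrated
 * totals B_T, RsbW_T, RsbV_T (and, in the competition model, the three
 * RNA-polymerase complexes before the totals).
 */
#include <R.h>
#include <math.h>

static double parms[30];
static double forc[1];

#define k_bw  parms[0]
#define k_dw  parms[1]
#define k_b1  parms[2]
#define k_d1  parms[3]
#define k_b2  parms[4]
#define k_d2  parms[5]
#define k_b3  parms[6]
#define k_d3  parms[7]
#define k_b4  parms[8]
#define k_d4  parms[9]
#define k_b5  parms[10]
#define k_d5  parms[11]
#define k_k1  parms[12]
#define k_k2  parms[13]
#define k_p   parms[14]
#define k_deg parms[15]
#define v_0   parms[16]
#define f_op  parms[17]
#define K_op  parms[18]
#define lam_W parms[19]
#define lam_V parms[20]
/* competition extension */
#define k_bb  parms[21]
#define k_db  parms[22]
#define k_ba  parms[23]
#define k_da  parms[24]
#define k_bpb parms[25]
#define k_dpb parms[26]
#define pB_tot parms[27]
#define R_tot parms[28]
#define A_T   parms[29]

#define P_T_in forc[0]

void sigb_initmod(void (*odeparms)(int *, double *))
{
    int n = 21;
    odeparms(&n, parms);
}

void sigb_comp_initmod(void (*odeparms)(int *, double *))
{
    int n = 30;
    odeparms(&n, parms);
}

void sigb_initforc(void (*odeforcs)(int *, double *))
{
    int n = 1;
    odeforcs(&n, forc);
}

/* shared partner-switching fluxes; fills d[0..8], returns vB-independent
 * part. prod is the total operon synthesis flux for sigma-B. */
static void core_fluxes(double *y, double prod, double *d)
{
    double sigB = y[0], W = y[1], W2 = y[2], V = y[3], VP = y[4];
    double W2sigB = y[5], W2V = y[6], W2V2 = y[7], VPP = y[8];
    double P = P_T_in - VPP;
    if (P < 0) P = 0;

    double r_dim = k_bw * W * W - k_dw * W2;
    double r1 = k_b1 * W2 * V - k_d1 * W2V;
    double r2 = k_b2 * W2V * V - k_d2 * W2V2;
    double rk1 = k_k1 * W2V;
    double rk2 = k_k2 * W2V2;
    double r3 = k_b3 * W2 * sigB - k_d3 * W2sigB;
    double r4 = k_b4 * W2sigB * V - k_d4 * W2V * sigB;
    double r5 = k_b5 * VP * P - k_d5 * VPP;
    double rp = k_p * VPP;

    d[0] = prod - r3 + r4 - k_deg * sigB;
    d[1] = lam_W * prod - 2.0 * r_dim - k_deg * W;
    d[2] = r_dim - r1 + rk1 - r3 - k_deg * W2;
    d[3] = lam_V * prod - r1 - r2 - r4 + rp - k_deg * V;
    d[4] = rk1 + rk2 - r5 - k_deg * VP;
    d[5] = r3 - r4 - k_deg * W2sigB;
    d[6] = r1 - r2 + rk2 - rk1 + r4 - k_deg * W2V;
    d[7] = r2 - rk2 - k_deg * W2V2;
    d[8] = r5 - rp - k_deg * VPP;
}

/* Core model: y = (sigB, W, W2, V, VP, W2sigB, W2V, W2V2, VPP,
 *                  B_T, RsbW_T, RsbV_T); yout = (P, vB). */
void sigb_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double sigB = y[0];
    double vB = v_0 * (1.0 + f_op * sigB / (K_op + sigB));
    core_fluxes(y, vB, ydot);
    ydot[9]  = vB - k_deg * y[9];
    ydot[10] = lam_W * vB - k_deg * y[10];
    ydot[11] = lam_V * vB - k_deg * y[11];
    if (*ip >= 2) {
        double P = P_T_in - y[8];
        yout[0] = P < 0 ? 0 : P;
        yout[1] = vB;
    }
}

/* Competition model: additionally tracks holoenzymes RsigA, RsigB and the
 * promoter-bound RsigBpB; free RNApol, free sigma-A and free promoter come
 * from conservation. Production fires at v0 (basal) plus
 * (v0*f/pB_tot)*[RsigBpB]. Dilution of sigma-B-holoenzymes removes the
 * sigma-B moiety and recycles core polymerase/promoter; sigma-A forms are
 * not diluted (A_T is a fixed total).
 * y = (9 core species, RsigA, RsigB, RsigBpB, B_T, RsbW_T, RsbV_T);
 * yout = (P, prod, Rfree, sigA, pB). */
void sigb_comp_derivs(int *neq, double *t, double *y, double *ydot,
                      double *yout, int *ip)
{
    double sigB = y[0];
    double RsigA = y[9], RsigB = y[10], RsigBpB = y[11];
    double Rfree = R_tot - RsigA - RsigB - RsigBpB;
    double sigA = A_T - RsigA;
    double pB = pB_tot - RsigBpB;

    double prod = v_0 + (pB_tot > 0 ? v_0 * f_op * RsigBpB / pB_tot : 0.0);
    core_fluxes(y, prod, ydot);

    double rA = k_ba * sigA * Rfree - k_da * RsigA;
    double rB = k_bb * sigB * Rfree - k_db * RsigB;
    double rP = k_bpb * RsigB * pB - k_dpb * RsigBpB;

    /* free sigma-B also exchanges with the holoenzyme pool */
    ydot[0] += -rB;
    ydot[9]  = rA;
    ydot[10] = rB - rP - k_deg * RsigB;
    ydot[11] = rP - k_deg * RsigBpB;

    /* totals: B_T counts sigma-B in all forms incl. holoenzymes */
    ydot[12] = prod - k_deg * y[12];
    ydot[13] = lam_W * prod - k_deg * y[13];
    ydot[14] = lam_V * prod - k_deg * y[14];

    if (*ip >= 5) {
        double P = P_T_in - y[8];
        yout[0] = P < 0 ? 0 : P;
        yout[1] = prod;
        yout[2] = Rfree;
        yout[3] = sigA;
        yout[4] = pB;
    }
}
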