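/* Coupled NF-kB / E2F reaction network, compiled right-hand side for deSolve.
 *
 * One master network covers all model variants: the E2F-1 and E2F-4
 * couplings are switched off by zeroing their rate parameters, which
 * makes the nested-variant reductions exact by construction.
 *
 * State vector (nM; compartment noted):
 *  y[0]  IKKn      neutral IKK (cyt)
 *  y[1]  IKKa      active IKK (cyt)
 *  y[2]  IKKi      inactive IKK (cyt)
 *  y[3]  NFkB_c    free RelA (cyt)
 *  y[4]  NFkB_n    free RelA (nuc)
 *  y[5]  IkBa_c    free IkBa (cyt)
 *  y[6]  IkBa_n    free IkBa (nuc)
 *  y[7]  NIkB_c    RelA:IkBa complex (cyt)
 *  y[8]  NIkB_n    RelA:IkBa complex (nuc)
 *  y[9]  tIkBa     IkBa mRNA
 *  y[10] tA20      A20 mRNA
 *  y[11] A20       A20 protein (cyt)
 *  y[12] E2F1_n    free E2F-1 (nuc)
 *  y[13] NE2F1_n   RelA:E2F-1 complex (nuc)
 *  y[14] E2F4_c    free E2F-4 (cyt)
 *  y[15] NIE4_c    ternary RelA:IkBa:E2F-4 complex (cyt); its IkBa is
 *                  protected from IKK-driven degradation
 *
 * Total RelA  = y[3]+y[4]+y[7]+y[8]+y[13]+y[15]  (conserved)
 * Total IKK   = y[0]+y[1]+y[2]                   (conserved)
 *
 * Forcings: forc[0] = E2F-1 synthesis drive, forc[1] = E2F-4 synthesis
 * drive (cell-cycle gating; constant 1 when unused).
 */

#include <R.h>

static double parms[37];
static double forc[2];

#define ka      parms[0]   /* TNF -> IKK activation, /min at saturating dose */
#define kp      parms[1]   /* IKKi -> IKKn recycling, /min                   */
#define k3      parms[2]   /* IKKa spontaneous inactivation, /min            */
#define k2      parms[3]   /* A20-assisted IKKa inactivation, /nM/min        */
#define kaNI    parms[4]   /* RelA + IkBa association, /nM/min               */
#define kdNI    parms[5]   /* RelA:IkBa dissociation, /min                   */
#define kc1     parms[6]   /* IKKa-driven free-IkBa degradation, /nM/min     */
#define kc2     parms[7]   /* IKKa-driven complexed-IkBa degradation         */
#define kdegI   parms[8]   /* constitutive free-IkBa degradation, /min       */
#define kdegIc  parms[9]   /* constitutive complexed-IkBa degradation, /min  */
#define kNin    parms[10]  /* free RelA nuclear import, /min                 */
#define kNIex   parms[11]  /* nuclear RelA:IkBa export, /min                 */
#define kIin    parms[12]  /* IkBa nuclear import, /min                      */
#define kIex    parms[13]  /* IkBa nuclear export, /min                      */
#define ktI     parms[14]  /* NF-kB-driven IkBa transcription, nM/min        */
#define ktI0    parms[15]  /* basal IkBa transcription, nM/min               */
#define KN      parms[16]  /* half-max nuclear RelA for transcription, nM    */
#define hN      parms[17]  /* Hill coefficient (>= 1)                        */
#define kdeg_tI parms[18]  /* IkBa mRNA turnover, /min                       */
#define ktrI    parms[19]  /* IkBa translation, /min                         */
#define ktA     parms[20]  /* NF-kB-driven A20 transcription, nM/min         */
#define ktA0    parms[21]  /* basal A20 transcription, nM/min                */
#define kdeg_tA parms[22]  /* A20 mRNA turnover, /min                        */
#define ktrA    parms[23]  /* A20 translation, /min                          */
#define kdegA   parms[24]  /* A20 protein turnover, /min                     */
#define kE1syn  parms[25]  /* E2F-1 synthesis amplitude, nM/min              */
#define KrepN   parms[26]  /* RelA repression of E2F-1 synthesis, nM         */
#define kdegE1  parms[27]  /* E2F-1 degradation (free and complexed), /min   */
#define kaNE    parms[28]  /* RelA + E2F-1 association, /nM/min              */
#define kdNE    parms[29]  /* RelA:E2F-1 dissociation, /min                  */
#define KrepE   parms[30]  /* E2F-1 repression of IkBa transcription, nM     */
#define kE4syn  parms[31]  /* E2F-1-driven E2F-4 synthesis, /min             */
#define kE4drv  parms[32]  /* direct (cycle-gated) E2F-4 synthesis, nM/min   */
#define kdegE4  parms[33]  /* E2F-4 degradation, /min                        */
#define kaE4    parms[34]  /* E2F-4 + RelA:IkBa association, /nM/min         */
#define kdE4    parms[35]  /* ternary dissociation, /min                     */
#define TR      parms[36]  /* TNF signal level in [0,1]                      */

void nfkb_initmod(void (* odeparms)(int *, double *))
{
    int n = 37;
    odeparms(&n, parms);
}

void nfkb_initforc(void (* odeforcs)(int *, double *))
{
    int n = 2;
    odeforcs(&n, forc);
}

void nfkb_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    double IKKn = y[0], IKKa = y[1], IKKi = y[2];
    double NFkBc = y[3], NFkBn = y[4];
    double IkBac = y[5], IkBan = y[6];
    double NIkBc = y[7], NIkBn = y[8];
    double tIkBa = y[9], tA20 = y[10], A20 = y[11];
    double E2F1n = y[12], NE2F1n = y[13];
    double E2F4c = y[14], NIE4c = y[15];

    /* IKK cycle */
    double v_act  = ka * TR * IKKn;
    double v_inac = (k3 + k2 * TR * A20) * IKKa;

    /* RelA:IkBa binding, both compartments */
    double vb_c = kaNI * NFkBc * IkBac - kdNI * NIkBc;
    double vb_n = kaNI * NFkBn * IkBan - kdNI * NIkBn;

    /* IkBa degradation */
    double v_df = (kc1 * IKKa + kdegI) * IkBac;   /* free, cyt */
    double v_dn = kdegI * IkBan;                  /* free, nuc */
    double v_dc = (kc2 * IKKa + kdegIc) * NIkBc;  /* complexed -> frees RelA */

    /* transport */
    double v_Nin  = kNin * NFkBc;
    double v_NIex = kNIex * NIkBn;
    double v_Iin  = kIin * IkBac;
    double v_Iex  = kIex * IkBan;

    /* transcription: NF-kB drive with E2F-1 repression of the IkBa promoter */
    double hill = 0.0;
    if (NFkBn > 0.0) {
        double num = pow(NFkBn, hN);
        hill = num / (pow(KN, hN) + num);
    }
    double repE = 1.0 / (1.0 + (E2F1n > 0.0 ? E2F1n : 0.0) / KrepE);
    double v_tI = ktI0 + ktI * hill * repE;
    double v_tA = ktA0 + ktA * hill;

    /* E2F-1: cycle-gated synthesis repressed by nuclear RelA */
    double repN = 1.0 / (1.0 + (NFkBn > 0.0 ? NFkBn : 0.0) / KrepN);
    double v_sE1 = kE1syn * forc[0] * repN;
    double vb_E1 = kaNE * NFkBn * E2F1n - kdNE * NE2F1n;

    /* E2F-4: E2F-1-driven plus direct cycle-gated synthesis;
       ternary capture of the cytoplasmic RelA:IkBa complex */
    double v_sE4 = kE4syn * (E2F1n + NE2F1n) + kE4drv * forc[1];
    double vb_E4 = kaE4 * E2F4c * NIkBc - kdE4 * NIE4c;

    ydot[0]  = kp * IKKi - v_act;
    ydot[1]  = v_act - v_inac;
    ydot[2]  = v_inac - kp * IKKi;
    ydot[3]  = -vb_c + v_dc - v_Nin;
    ydot[4]  = v_Nin - vb_n - vb_E1 + kdegE1 * NE2F1n;
    ydot[5]  = ktrI * tIkBa - vb_c - v_df - v_Iin + v_Iex;
    ydot[6]  = v_Iin - v_Iex - vb_n - v_dn;
    ydot[7]  = vb_c - v_dc + v_NIex - vb_E4 + kdegE4 * NIE4c;
    ydot[8]  = vb_n - v_NIex;
    ydot[9]  = v_tI - kdeg_tI * tIkBa;
    ydot[10] = v_tA - kdeg_tA * tA20;
    ydot[11] = ktrA * tA20 - kdegA * A20;
    ydot[12] = v_sE1 - kdegE1 * E2F1n - vb_E1;
    ydot[13] = vb_E1 - kdegE1 * NE2F1n;
    ydot[14] = v_sE4 - kdegE4 * E2F4c - vb_E4;
    /* E2F-4 turnover continues in the ternary complex, releasing the
       RelA:IkBa complex */
    ydot[15] = vb_E4 - kdegE4 * NIE4c;

    if (ip[0] >= 1) {
        /* nuclear:cytoplasmic ratio over all RelA-containing species */
        double nuc = NFkBn + NIkBn + NE2F1n;
        double cyt = NFkBc + NIkBc + NIE4c;
        yout[0] = (cyt > 0.0) ? nuc / cyt : NA_REAL;
    }
}
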