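/* Compiled right-hand side of the six-compartment HPG-axis model.
 * Mirrors the R reference implementation hpg_rhs(); the parameter vector
 * layout is produced by .pack_parms() in R/model.R and must stay in step
 * with the #define indices below. Used through deSolve's compiled-code
 * interface (initfunc = "hpg_init", func = "hpg_derivs").
 */
#include <R.h>
#include <math.h>

#define NPAR 174
static double parms[NPAR];

/* geometry */
#define V_BRN parms[0]
#define V_GON parms[1]
#define V_LIV parms[2]
#define V_OTH parms[3]
#define V_VEN parms[4]
#define F_BRN parms[5]
#define F_GON parms[6]
#define F_LIV parms[7]
#define F_OTH parms[8]
#define F_CAR parms[9]
#define FW_GIL parms[10]
#define BW075 parms[11]
#define KONLY parms[12]
/* tissue:blood partition coefficients, chem-major over the 4 perfused
 * compartments; chem order E2,T,EE2,TB,LH,VTG; comp order brn,gon,liv,oth */
#define LAM(i, j) parms[13 + (i) * 4 + (j)]
#define LAM_E2_BLD parms[37]
#define LAM_EE2_BLD parms[38]
#define LAM_TB_BLD parms[39]
#define KE(i) parms[40 + (i)] /* first-order elimination in "other" */
#define K1_E2ER parms[46]
#define KD_E2ER parms[47]
#define K1_EE2ER parms[48]
#define KD_EE2ER parms[49]
#define K1_TAR parms[50]
#define KD_TAR parms[51]
#define K1_TBAR parms[52]
#define KD_TBAR parms[53]
#define K1_LHLR parms[54]
#define KD_LHLR parms[55]
#define K1_E2SBP parms[56]
#define KD_E2SBP parms[57]
#define K1_TSBP parms[58]
#define KD_TSBP parms[59]
#define K1_EE2SBP parms[60]
#define KD_EE2SBP parms[61]
#define CER_BRN parms[62]
#define CER_GON parms[63]
#define CLR_GON parms[64]
#define CAR_GON parms[65]
#define CAR_LIV parms[66]
#define CSBP_VEN parms[67]
#define MAG_LH parms[68]
#define RHO_U_LH parms[69]
#define RHO_D_LH parms[70]
#define PBG_AR parms[71]
#define K_AR parms[72]
#define KE_AR parms[73]
#define SCVMAX_SCC parms[74]
#define K05_SCC parms[75]
#define N_T parms[76]
#define K_T parms[77]
#define RHO_STAR parms[78]
#define RHO_CHOL parms[79]
#define RHO_E2_LHLR parms[80]
#define VMAX_ARO_GON parms[81]
#define KM_ARO_GON parms[82]
#define VMAX_ARO_BRN parms[83]
#define KM_ARO_BRN parms[84]
#define SCVMAX_VTG parms[85]
#define K05_VTG parms[86]
#define N_VTG parms[87]
#define K_VTG_GON parms[88]
#define PBG_ER parms[89]
#define K_ER parms[90]
#define KE_ER parms[91]
/* exposure segment blocks: nseg then MAXSEG x (t0, t1, c0, kdec) */
#define MAXSEG 10
#define SEG_EE2 92
#define SEG_TB 133

/* chemical / compartment indices */
#define E2 0
#define TST 1
#define EE2 2
#define TB 3
#define LH 4
#define VTG 5
#define BRN 0
#define GON 1
#define LIV 2
#define OTH 3
#define VEN 4

/* state indices */
#define FREE(i, j) ((i) * 5 + (j))
#define E2ER(j) (30 + (j))
#define EE2ER(j) (33 + (j))
#define TAR(j) (36 + (j))
#define TBAR(j) (39 + (j))
#define LHLR 42
#define E2SBP 43
#define TSBP 44
#define EE2SBP 45
#define ERFREE_LIV 46
#define ARFREE_BRN 47
#define NSTATE 48

void hpg_init(void (*odeparms)(int *, double *)) {
  int n = NPAR;
  odeparms(&n, parms);
}

static double clamp0(double x) { return x > 0 ? x : 0; }

static double water_conc(int block, double t) {
  int n = (int) parms[block];
  int k;
  for (k = 0; k < n; k++) {
    double t0 = parms[block + 1 + 4 * k];
    double t1 = parms[block + 1 + 4 * k + 1];
    if (t >= t0 && t < t1) {
      double c0 = parms[block + 1 + 4 * k + 2];
      double kd = parms[block + 1 + 4 * k + 3];
      return kd > 0 ? c0 * exp(-kd * (t - t0)) : c0;
    }
  }
  return 0.0;
}

void hpg_derivs(int *neq, double *t, double *y, double *ydot, double *yout,
                int *ip) {
  double s[NSTATE];
  double V[5], F[4];
  double erfree[3], arfree[3], lrfree, sbpfree;
  double bE2ER[3], bEE2ER[3], bTAR[3], bTBAR[3];
  double bLHLR, bE2SBP, bTSBP, bEE2SBP;
  double cart[6];
  double prod[6][4];
  double bind_loss[6][5];
  int i, j;
  int konly = KONLY > 0.5;

  for (i = 0; i < NSTATE; i++) s[i] = clamp0(y[i]);
  V[BRN] = V_BRN; V[GON] = V_GON; V[LIV] = V_LIV; V[OTH] = V_OTH;
  V[VEN] = V_VEN;
  F[BRN] = F_BRN; F[GON] = F_GON; F[LIV] = F_LIV; F[OTH] = F_OTH;

  /* free receptor pools */
  erfree[BRN] = clamp0(CER_BRN - s[E2ER(BRN)] - s[EE2ER(BRN)]);
  erfree[GON] = clamp0(CER_GON - s[E2ER(GON)] - s[EE2ER(GON)]);
  erfree[LIV] = s[ERFREE_LIV];
  arfree[BRN] = s[ARFREE_BRN];
  arfree[GON] = clamp0(CAR_GON - s[TAR(GON)] - s[TBAR(GON)]);
  arfree[LIV] = clamp0(CAR_LIV - s[TAR(LIV)] - s[TBAR(LIV)]);
  lrfree = clamp0(CLR_GON - s[LHLR]);
  sbpfree = clamp0(CSBP_VEN - s[E2SBP] - s[TSBP] - s[EE2SBP]);

  /* binding net fluxes (nmol/L/hr) */
  for (j = 0; j < 3; j++) {
    bE2ER[j] = K1_E2ER * s[FREE(E2, j)] * erfree[j] -
               K1_E2ER * KD_E2ER * s[E2ER(j)];
    bEE2ER[j] = K1_EE2ER * s[FREE(EE2, j)] * erfree[j] -
                K1_EE2ER * KD_EE2ER * s[EE2ER(j)];
    bTAR[j] = K1_TAR * s[FREE(TST, j)] * arfree[j] -
              K1_TAR * KD_TAR * s[TAR(j)];
    bTBAR[j] = K1_TBAR * s[FREE(TB, j)] * arfree[j] -
               K1_TBAR * KD_TBAR * s[TBAR(j)];
  }
  bLHLR = K1_LHLR * s[FREE(LH, GON)] * lrfree - K1_LHLR * KD_LHLR * s[LHLR];
  bE2SBP = K1_E2SBP * s[FREE(E2, VEN)] * sbpfree -
           K1_E2SBP * KD_E2SBP * s[E2SBP];
  bTSBP = K1_TSBP * s[FREE(TST, VEN)] * sbpfree -
          K1_TSBP * KD_TSBP * s[TSBP];
  bEE2SBP = K1_EE2SBP * s[FREE(EE2, VEN)] * sbpfree -
            K1_EE2SBP * KD_EE2SBP * s[EE2SBP];

  /* arterial concentrations; gill exchange for E2, EE2, TB */
  for (i = 0; i < 6; i++) cart[i] = s[FREE(i, VEN)];
  if (!konly) {
    double lam[3] = {LAM_E2_BLD, LAM_EE2_BLD, LAM_TB_BLD};
    int chem[3] = {E2, EE2, TB};
    int blk[3] = {-1, SEG_EE2, SEG_TB};
    int k;
    for (k = 0; k < 3; k++) {
      double cw = blk[k] < 0 ? 0.0 : water_conc(blk[k], *t);
      double feff = FW_GIL < F_CAR * lam[k] ? FW_GIL : F_CAR * lam[k];
      double uptake = feff * (cw - s[FREE(chem[k], VEN)] / lam[k]);
      cart[chem[k]] = s[FREE(chem[k], VEN)] + uptake / F_CAR;
    }
  }

  for (i = 0; i < 6; i++)
    for (j = 0; j < 4; j++) prod[i][j] = 0.0;
  for (i = 0; i < 6; i++)
    for (j = 0; j < 5; j++) bind_loss[i][j] = 0.0;

  if (!konly) {
    /* productions (nmol/hr) */
    double er_bd_brn = s[E2ER(BRN)] + s[EE2ER(BRN)];
    double ar_bd_brn = s[TAR(BRN)] + s[TBAR(BRN)];
    double er_bd_gon = s[E2ER(GON)] + s[EE2ER(GON)];
    double er_bd_liv = s[E2ER(LIV)] + s[EE2ER(LIV)];
    double p_lh = MAG_LH * (1.0 + sin(2.0 * M_PI * *t / 24.0)) *
                  (1.0 + er_bd_brn / RHO_U_LH) / (1.0 + ar_bd_brn / RHO_D_LH);
    double c_chol = RHO_CHOL * RHO_STAR * s[LHLR];
    double p_t = 0.0, p_e2_gon, p_e2_brn, p_vtg = 0.0;
    if (c_chol > 0) {
      double hn = pow(c_chol, N_T);
      p_t = SCVMAX_SCC * BW075 * hn / (pow(K05_SCC, N_T) + hn) /
            (1.0 + er_bd_gon / K_T);
    }
    p_e2_gon = (1.0 + RHO_E2_LHLR * s[LHLR]) * VMAX_ARO_GON *
               s[FREE(TST, GON)] / (KM_ARO_GON + s[FREE(TST, GON)]);
    p_e2_brn = VMAX_ARO_BRN * s[FREE(TST, BRN)] /
               (KM_ARO_BRN + s[FREE(TST, BRN)]);
    if (er_bd_liv > 0) {
      double hv = pow(er_bd_liv, N_VTG);
      p_vtg = SCVMAX_VTG * BW075 * hv / (pow(K05_VTG, N_VTG) + hv);
    }
    prod[LH][BRN] = p_lh;
    prod[TST][GON] = p_t - p_e2_gon; /* aromatase consumes T */
    prod[TST][BRN] = -p_e2_brn;
    prod[E2][GON] = p_e2_gon;
    prod[E2][BRN] = p_e2_brn;
    prod[VTG][LIV] = p_vtg;
    prod[VTG][GON] = -K_VTG_GON * s[FREE(VTG, GON)] * V_GON;
    for (i = 0; i < 6; i++)
      prod[i][OTH] -= KE(i) * s[FREE(i, OTH)] * V_OTH;
  }

  for (j = 0; j < 3; j++) {
    bind_loss[E2][j] = bE2ER[j];
    bind_loss[EE2][j] = bEE2ER[j];
    bind_loss[TST][j] = bTAR[j];
    bind_loss[TB][j] = bTBAR[j];
  }
  bind_loss[LH][GON] += bLHLR;
  bind_loss[E2][VEN] = bE2SBP;
  bind_loss[TST][VEN] = bTSBP;
  bind_loss[EE2][VEN] = bEE2SBP;

  for (i = 0; i < 6; i++) {
    double ret = 0.0;
    for (j = 0; j < 4; j++) {
      double lam = LAM(i, j);
      double cij = s[FREE(i, j)];
      double transport = F[j] * (cart[i] - cij / lam);
      ydot[FREE(i, j)] = (transport + prod[i][j]) / V[j] - bind_loss[i][j];
      ret += F[j] * cij / lam;
    }
    ydot[FREE(i, VEN)] = (ret - F_CAR * s[FREE(i, VEN)]) / V_VEN -
                         bind_loss[i][VEN];
  }
  for (j = 0; j < 3; j++) {
    ydot[E2ER(j)] = bE2ER[j];
    ydot[EE2ER(j)] = bEE2ER[j];
    ydot[TAR(j)] = bTAR[j];
    ydot[TBAR(j)] = bTBAR[j];
  }
  if (!konly) {
    /* receptor-mediated turnover of the dynamic-pool complexes */
    ydot[E2ER(LIV)] -= KE_ER * s[E2ER(LIV)];
    ydot[EE2ER(LIV)] -= KE_ER * s[EE2ER(LIV)];
    ydot[TAR(BRN)] -= KE_AR * s[TAR(BRN)];
    ydot[TBAR(BRN)] -= KE_AR * s[TBAR(BRN)];
  }
  ydot[LHLR] = bLHLR;
  ydot[E2SBP] = bE2SBP;
  ydot[TSBP] = bTSBP;
  ydot[EE2SBP] = bEE2SBP;
  if (!konly) {
    double er_bd_liv = s[E2ER(LIV)] + s[EE2ER(LIV)];
    ydot[ERFREE_LIV] = PBG_ER + K_ER * er_bd_liv - bE2ER[LIV] - bEE2ER[LIV] -
                       KE_ER * s[ERFREE_LIV];
    ydot[ARFREE_BRN] = PBG_AR * K_AR /
                           (K_AR + s[FREE(TST, BRN)] + s[FREE(TB, BRN)]) -
                       bTAR[BRN] - bTBAR[BRN] - KE_AR * s[ARFREE_BRN];
  } else {
    ydot[ERFREE_LIV] = -bE2ER[LIV] - bEE2ER[LIV];
    ydot[ARFREE_BRN] = -bTAR[BRN] - bTBAR[BRN];
  }
}
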