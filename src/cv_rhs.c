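/* Right-hand side of the closed-loop lumped-parameter circulation,
 * in the deSolve compiled-function convention.
 *
 * States (volumes in mL, flows in mL/s):
 *   y[0] V_la   y[1] V_lv   y[2] V_ra   y[3] V_rv
 *   y[4] V_sas  y[5] V_svn  y[6] V_pas  y[7] V_pvn
 *   y[8] Q_sys (systemic arterial -> venous, inertial branch)
 *   y[9] Q_pul (pulmonary arterial -> venous, inertial branch)
 *   y[10] Q_mi (mitral flow; inertial valve branch, no regurgitation)
 *
 * Units: mmHg, mL, s.  Each beat is integrated on its own clock, so *t is
 * time since beat onset; p[0] (rr) and p[1] (t_sys) are set per beat.
 */

#include <R.h>
#include <math.h>

#define NPAR 32

static double p[NPAR];

enum {
  iRR, iTSYS, iSPLIT,
  iE_LA, iV0_LA,
  iEMAX_LV, iEMIN_LV, iV0_LV,
  iE_RA, iV0_RA,
  iEMAX_RV, iEMIN_RV, iV0_RV,
  iR_MI, iL_MI, iR_AO, iR_TI, iR_PO,
  iC_SAS, iV0_SAS, iR_SYS, iL_SYS,
  iC_SVN, iV0_SVN, iR_SVN,
  iC_PAS, iV0_PAS, iR_PUL, iL_PUL,
  iC_PVN, iV0_PVN, iR_PVN
};

void cv_init(void (*odeparms)(int *, double *))
{
  int n = NPAR;
  odeparms(&n, p);
}

void cv_rhs(int *neq, double *t, double *y, double *ydot, double *yout, int *ip)
{
  /* asymmetric raised-cosine activation: contraction over split*T_sys,
   * relaxation over the remaining (1-split)*T_sys, zero elsewhere */
  double act = 0.0;
  double tc = p[iSPLIT] * p[iTSYS];
  if (*t < tc)
    act = 0.5 * (1.0 - cos(M_PI * (*t) / tc));
  else if (*t < p[iTSYS])
    act = 0.5 * (1.0 + cos(M_PI * (*t - tc) / (p[iTSYS] - tc)));

  /* linear state equations: P = E(t) (V - V_un); atria passive */
  double P_la  = p[iE_LA] * (y[0] - p[iV0_LA]);
  double P_lv  = (p[iEMIN_LV] + act * (p[iEMAX_LV] - p[iEMIN_LV])) * (y[1] - p[iV0_LV]);
  double P_ra  = p[iE_RA] * (y[2] - p[iV0_RA]);
  double P_rv  = (p[iEMIN_RV] + act * (p[iEMAX_RV] - p[iEMIN_RV])) * (y[3] - p[iV0_RV]);
  double P_sas = (y[4] - p[iV0_SAS]) / p[iC_SAS];
  double P_svn = (y[5] - p[iV0_SVN]) / p[iC_SVN];
  double P_pas = (y[6] - p[iV0_PAS]) / p[iC_PAS];
  double P_pvn = (y[7] - p[iV0_PVN]) / p[iC_PVN];

  /* aortic, tricuspid, pulmonary valves: ideal pressure-gated resistive
   * diodes; the mitral valve carries blood inertia (flow state y[10]),
   * so its closure lags the atrioventricular pressure crossover */
  double Q_ao = (P_lv > P_sas) ? (P_lv - P_sas) / p[iR_AO] : 0.0;
  double Q_ti = (P_ra > P_rv)  ? (P_ra - P_rv)  / p[iR_TI] : 0.0;
  double Q_po = (P_rv > P_pas) ? (P_rv - P_pas) / p[iR_PO] : 0.0;
  double Q_mi = (y[10] > 0.0) ? y[10] : 0.0;

  /* venous return branches: purely resistive, bidirectional */
  double Q_svn = (P_svn - P_ra) / p[iR_SVN];
  double Q_pvn = (P_pvn - P_la) / p[iR_PVN];

  double Q_sys = y[8], Q_pul = y[9];

  /* mass conservation */
  ydot[0] = Q_pvn - Q_mi;
  ydot[1] = Q_mi  - Q_ao;
  ydot[2] = Q_svn - Q_ti;
  ydot[3] = Q_ti  - Q_po;
  ydot[4] = Q_ao  - Q_sys;
  ydot[5] = Q_sys - Q_svn;
  ydot[6] = Q_po  - Q_pul;
  ydot[7] = Q_pul - Q_pvn;

  /* equations of motion on the inertial branches */
  ydot[8] = (P_sas - P_svn - p[iR_SYS] * Q_sys) / p[iL_SYS];
  ydot[9] = (P_pas - P_pvn - p[iR_PUL] * Q_pul) / p[iL_PUL];
  /* mitral: momentum equation, with a strong one-sided restoring term that
   * pins the flow state near zero while the valve is closed (the flow used
   * in the mass balance is clamped at zero, so no regurgitation occurs) */
  ydot[10] = (P_la - P_lv - p[iR_MI] * y[10]) / p[iL_MI];
  if (y[10] < 0.0) ydot[10] -= 1.0e5 * y[10];
}
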