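/* Compiled right-hand sides for the metabolism and combined
 * metabolism + neurovascular models, in the deSolve compiled-model
 * convention (initfunc fills the parameter block, derivs evaluates f).
 *
 * The stimulus input u is passed as the last entry of the parameter
 * vector: integration is restarted at every epoch boundary, so u is
 * constant within any one solver call.
 */
#include <R.h>
#include <math.h>

/* ---------------- standalone metabolism model ---------------- */

#define N_PAR_MET 20 /* 19 kinetic parameters + u */
static double pmet[N_PAR_MET];

void initmod_met(void (*odeparms)(int *, double *))
{
    int N = N_PAR_MET;
    odeparms(&N, pmet);
}

/* parameter order (must match .metab_par_names in R/model.R):
 * kstim1 kstim2 kmax_glucc kmax_gluct Glucose_blood
 * kmaxPO KM_Pyr KM_OAA kmaxPyr kmaxPyr2 KM_Pyr2 k1
 * kmaxOG1 kmaxOAA kmaxOG2 kmaxAsp kmaxGln kmaxGlut1 kmaxGlut2 u
 *
 * state order: Stimulus Gluc_c Gluc_t Pyr Lac OAA OG Asp Glut Gln
 */
void derivs_met(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double kstim1 = pmet[0], kstim2 = pmet[1];
    const double kmax_glucc = pmet[2], kmax_gluct = pmet[3];
    const double Glucose_blood = pmet[4];
    const double kmaxPO = pmet[5], KM_Pyr = pmet[6], KM_OAA = pmet[7];
    const double kmaxPyr = pmet[8], kmaxPyr2 = pmet[9], KM_Pyr2 = pmet[10];
    const double k1 = pmet[11];
    const double kmaxOG1 = pmet[12], kmaxOAA = pmet[13], kmaxOG2 = pmet[14];
    const double kmaxAsp = pmet[15], kmaxGln = pmet[16];
    const double kmaxGlut1 = pmet[17], kmaxGlut2 = pmet[18];
    const double u = pmet[19];

    const double Stimulus = y[0], Gluc_c = y[1], Gluc_t = y[2];
    const double Pyr = y[3], Lac = y[4], OAA = y[5], OG = y[6];
    const double Asp = y[7], Glut = y[8], Gln = y[9];

    const double V_Gluc = kmax_glucc * Gluc_c;
    const double V_glycolysis = kmax_gluct * Gluc_t * (1.0 + Stimulus);
    const double V_LDH = kmaxPyr * Pyr;
    const double V_PC = kmaxPyr2 * Pyr / (KM_Pyr2 + Pyr);
    const double V_TCA1 = kmaxPO * Pyr / (KM_Pyr + Pyr) * OAA / (KM_OAA + OAA);
    const double V_TCA2 = kmaxOG1 * OG;
    const double V_GOT = kmaxOAA * OAA;
    const double V_xm = kmaxOG2 * OG;
    const double V_GS = kmaxGln * Gln;
    const double V_PAG = kmaxGlut1 * Glut;
    const double V_clear1 = k1 * Lac;
    const double V_clear2 = kmaxAsp * Asp;
    const double V_clear3 = kmaxGlut2 * Glut;

    ydot[0] = kstim1 * u - kstim2 * Stimulus;
    ydot[1] = Glucose_blood - V_Gluc;
    ydot[2] = V_Gluc - V_glycolysis;
    ydot[3] = V_glycolysis - V_TCA1 - V_LDH - V_PC;
    ydot[4] = V_LDH - V_clear1;
    ydot[5] = V_TCA2 + V_PC - V_TCA1 - V_GOT;
    ydot[6] = V_TCA1 - V_TCA2 - V_xm;
    ydot[7] = V_GOT - V_clear2;
    ydot[8] = V_xm + V_GS - V_PAG - V_clear3;
    ydot[9] = V_PAG - V_GS;
}

/* ------------- combined metabolism + NVC model ------------- */

#define N_PAR_CMB 36 /* 35 kinetic parameters + u */
static double pcmb[N_PAR_CMB];

void initmod_cmb(void (*odeparms)(int *, double *))
{
    int N = N_PAR_CMB;
    odeparms(&N, pcmb);
}

/* parameter order (must match .combined_par_names in R/nvc.R):
 * tau_n kdm1 kdm2 tau_f1 tau_f2 tau_f3 a_F a_V tau_v
 * k_o2in k_o2leak a_O k_o2use k_glcin a_G k_dhb k_wash
 * k_basalMet k_prop1 k_prop2 k_dip
 * kmaxPO KM_Pyr KM_OAA kmaxPyr kmaxPyr2 KM_Pyr2 k1
 * kmaxOG1 kmaxOAA kmaxOG2 kmaxAsp kmaxGln kmaxGlut1 kmaxGlut2 u
 *
 * state order:
 * N Delay_M A1 A2 Fl Vv O2_A Glucose_A dHb
 * Pyr Lac OAA OG Asp Glut Gln
 */
void derivs_cmb(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const double tau_n = pcmb[0], kdm1 = pcmb[1], kdm2 = pcmb[2];
    const double tau_f1 = pcmb[3], tau_f2 = pcmb[4], tau_f3 = pcmb[5];
    const double a_F = pcmb[6], a_V = pcmb[7], tau_v = pcmb[8];
    const double k_o2in = pcmb[9], k_o2leak = pcmb[10], a_O = pcmb[11];
    const double k_o2use = pcmb[12], k_glcin = pcmb[13], a_G = pcmb[14];
    const double k_dhb = pcmb[15], k_wash = pcmb[16];
    const double k_basalMet = pcmb[17], k_prop1 = pcmb[18], k_prop2 = pcmb[19];
    const double k_dip = pcmb[20];
    const double kmaxPO = pcmb[21], KM_Pyr = pcmb[22], KM_OAA = pcmb[23];
    const double kmaxPyr = pcmb[24], kmaxPyr2 = pcmb[25], KM_Pyr2 = pcmb[26];
    const double k1 = pcmb[27];
    const double kmaxOG1 = pcmb[28], kmaxOAA = pcmb[29], kmaxOG2 = pcmb[30];
    const double kmaxAsp = pcmb[31], kmaxGln = pcmb[32];
    const double kmaxGlut1 = pcmb[33], kmaxGlut2 = pcmb[34];
    const double u = pcmb[35];

    const double Nn = y[0], Delay_M = y[1], A1 = y[2], A2 = y[3];
    const double Fl = y[4], Vv = y[5], O2_A = y[6], Glucose_A = y[7];
    const double dHb = y[8];
    const double Pyr = y[9], Lac = y[10], OAA = y[11], OG = y[12];
    const double Asp = y[13], Glut = y[14], Gln = y[15];

    const double CBF = 1.0 + a_F * Fl;
    const double V_baseMet = Glucose_A * k_basalMet * O2_A * k_prop1;
    const double V_stimMet = Glucose_A * Delay_M * O2_A * k_prop2;
    const double V_met = V_baseMet + V_stimMet;

    const double V_LDH = kmaxPyr * Pyr;
    const double V_PC = kmaxPyr2 * Pyr / (KM_Pyr2 + Pyr);
    const double V_TCA1 = kmaxPO * Pyr / (KM_Pyr + Pyr) * OAA / (KM_OAA + OAA);
    const double V_TCA2 = kmaxOG1 * OG;
    const double V_GOT = kmaxOAA * OAA;
    const double V_xm = kmaxOG2 * OG;
    const double V_GS = kmaxGln * Gln;
    const double V_PAG = kmaxGlut1 * Glut;

    ydot[0] = (u - Nn) / tau_n;
    ydot[1] = kdm1 * Nn - kdm2 * Delay_M;
    ydot[2] = (Nn - A1) / tau_f1;
    ydot[3] = (A1 - A2) / tau_f2;
    ydot[4] = (A2 - Fl) / tau_f3;
    ydot[5] = ((1.0 + a_V * Fl) - Vv) / tau_v;
    ydot[6] = k_o2in * (1.0 + a_O * Fl) - k_o2leak * O2_A - k_o2use * V_met;
    ydot[7] = k_glcin * (1.0 + a_G * Fl) - V_met;
    ydot[8] = k_dhb * (k_basalMet * k_prop1 + k_dip * Delay_M)
        - k_wash * (CBF / Vv) * dHb;
    ydot[9] = V_met - V_TCA1 - V_LDH - V_PC;
    ydot[10] = V_LDH - k1 * Lac;
    ydot[11] = V_TCA2 + V_PC - V_TCA1 - V_GOT;
    ydot[12] = V_TCA1 - V_TCA2 - V_xm;
    ydot[13] = V_GOT - kmaxAsp * Asp;
    ydot[14] = V_xm + V_GS - V_PAG - kmaxGlut2 * Glut;
    ydot[15] = V_PAG - V_GS;
}
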