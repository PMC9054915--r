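/* Whole-body perfusion-limited PBPK right-hand side for one victim compound
 * optionally co-dosed with one perpetrator, sharing hepatic and gut CYP3A4
 * pools (Michaelis-Menten saturation, competitive inhibition, mechanism-based
 * inactivation, induction). Called by deSolve::lsoda as a compiled model.
 *
 * Parameter vector layout (must match .pbpk_parms() on the R side):
 *   [0]      n_compounds (1 or 2)
 *   [1]      cardiac output CO (L/h blood)
 *   [2..12]  tissue blood flows Q[0..10]; Q[LU] = CO; Q[LI] = hepatic artery
 *   [13..23] tissue volumes V[0..10] (L)
 *   [24]     arterial blood volume, [25] venous blood volume (L)
 *   [26]     kdeg hepatic (1/h), [27] kdeg gut (1/h)
 *   per compound c (base b = 28 + 27*c):
 *   b+0 MW  b+1 B/P  b+2 fu  b+3 ka  b+4 Qgut  b+5 fu_gut  b+6 CL_R (L/h,
 *   plasma)  b+7 CL_add (L/h, intrinsic on unbound liver water)
 *   b+8 VmaxLiv (umol/h, whole liver)  b+9 VmaxGut (umol/h, whole gut wall)
 *   b+10 Km (uM)  b+11 1/Ki (1/uM; 0 = no competitive inhibition)
 *   b+12 Kapp (uM)  b+13 kinact (1/h; 0 = no TDI)
 *   b+14 ind_max (fold)  b+15 ind_c50 (uM; ignored if ind_max = 0)
 *   b+16..b+26 scaled partition coefficients Kp'[0..10] (= Kp_scalar * Kp)
 *
 * State vector layout (must match .pbpk_state_index() on the R side):
 *   y[0] E_liver, y[1] E_gut (fractions of baseline enzyme)
 *   per compound c (base s = 2 + 18*c):
 *   s+0 oral depot (mg); s+1..s+11 tissue concentrations C[0..10] (mg/L);
 *   s+12 arterial blood conc; s+13 venous blood conc (mg/L);
 *   s+14 cumulative gut-wall metabolism; s+15 cumulative hepatic CYP3A4
 *   metabolism; s+16 cumulative additional hepatic clearance; s+17
 *   cumulative renal excretion (all mg).
 */

#include <R.h>

#define NTIS 11
#define LU 0
#define AD 1
#define BO 2
#define BR 3
#define GU 4
#define HE 5
#define KI 6
#define LI 7
#define MU 8
#define SK 9
#define SP 10

#define NGLOB 28
#define NPCPD 27
#define MAXPAR (NGLOB + 2 * NPCPD)

static double parms[MAXPAR];

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = MAXPAR;
    odeparms(&n, parms);
}

void pbpk_derivs(int *neq, double *t, double *y, double *ydot,
                 double *yout, int *ip)
{
    const int nc = (int) parms[0];
    const double CO = parms[1];
    const double *Q = parms + 2;
    const double *V = parms + 13;
    const double Vart = parms[24], Vven = parms[25];
    const double kdegli = parms[26], kdeggu = parms[27];
    const double Eli = y[0], Egu = y[1];

    double CuLi[2] = {0.0, 0.0};   /* unbound liver water conc, uM */
    double CentU[2] = {0.0, 0.0};  /* unbound enterocyte conc, uM  */

    for (int c = 0; c < nc; c++) {
        const double *p = parms + NGLOB + NPCPD * c;
        const double *ys = y + 2 + 18 * c;
        double mw = p[0], bp = p[1], fu = p[2], ka = p[3];
        double qgut = p[4], fugut = p[5];
        double kppli = p[16 + LI];
        CuLi[c]  = fu * ys[1 + LI] * bp / kppli * 1000.0 / mw;
        CentU[c] = fugut * (ka * ys[0] / qgut) * 1000.0 / mw;
    }

    /* shared enzyme pools */
    double ind_li = 0.0, ind_gu = 0.0, ina_li = 0.0, ina_gu = 0.0;
    for (int c = 0; c < nc; c++) {
        const double *p = parms + NGLOB + NPCPD * c;
        double kinact = p[13], kapp = p[12];
        double indmax = p[14], indc50 = p[15];
        if (kinact > 0.0) {
            ina_li += kinact * CuLi[c]  / (kapp + CuLi[c]);
            ina_gu += kinact * CentU[c] / (kapp + CentU[c]);
        }
        if (indmax > 0.0) {
            ind_li += indmax * CuLi[c]  / (indc50 + CuLi[c]);
            ind_gu += indmax * CentU[c] / (indc50 + CentU[c]);
        }
    }
    ydot[0] = kdegli * (1.0 + ind_li) - kdegli * Eli - Eli * ina_li;
    ydot[1] = kdeggu * (1.0 + ind_gu) - kdeggu * Egu - Egu * ina_gu;

    for (int c = 0; c < nc; c++) {
        const double *p = parms + NGLOB + NPCPD * c;
        const int s = 2 + 18 * c;
        const double *C = y + s + 1;          /* tissue concs [0..10] */
        const double Cart = y[s + 12], Cven = y[s + 13];
        const double mw = p[0], bp = p[1], fu = p[2], ka = p[3];
        const double qgut = p[4], fugut = p[5];
        const double clr = p[6], cladd = p[7];
        const double vmaxli = p[8], vmaxgu = p[9], km = p[10];
        const double *kpp = p + 16;

        double Cout[NTIS];
        for (int ti = 0; ti < NTIS; ti++)
            Cout[ti] = C[ti] * bp / kpp[ti];

        /* competitive inhibition by the co-dosed compound(s) */
        double comp_li = 1.0, comp_gu = 1.0;
        for (int o = 0; o < nc; o++) {
            if (o == c) continue;
            double invki = parms[NGLOB + NPCPD * o + 11];
            comp_li += CuLi[o]  * invki;
            comp_gu += CentU[o] * invki;
        }

        /* oral absorption with dynamic gut-wall first pass */
        double ratein = ka * y[s + 0];         /* mg/h */
        double clint_gu = 0.0;
        if (vmaxgu > 0.0)
            clint_gu = vmaxgu * Egu / (km * comp_gu + CentU[c]); /* L/h */
        double fg = qgut / (qgut + fugut * clint_gu);

        /* hepatic elimination on unbound liver water concentration */
        double cu_mgL = fu * C[LI] * bp / kpp[LI];
        double vcyp = 0.0;
        if (vmaxli > 0.0)
            vcyp = vmaxli * Eli * CuLi[c] / (km * comp_li + CuLi[c])
                   * mw / 1000.0;              /* mg/h */
        double vadd = cladd * cu_mgL;          /* mg/h */
        double renal = clr * Cven / bp;        /* mg/h, venous plasma */

        ydot[s + 0] = -ratein;

        ydot[s + 1 + AD] = Q[AD] * (Cart - Cout[AD]) / V[AD];
        ydot[s + 1 + BO] = Q[BO] * (Cart - Cout[BO]) / V[BO];
        ydot[s + 1 + BR] = Q[BR] * (Cart - Cout[BR]) / V[BR];
        ydot[s + 1 + GU] = Q[GU] * (Cart - Cout[GU]) / V[GU];
        ydot[s + 1 + HE] = Q[HE] * (Cart - Cout[HE]) / V[HE];
        ydot[s + 1 + KI] = Q[KI] * (Cart - Cout[KI]) / V[KI];
        ydot[s + 1 + MU] = Q[MU] * (Cart - Cout[MU]) / V[MU];
        ydot[s + 1 + SK] = Q[SK] * (Cart - Cout[SK]) / V[SK];
        ydot[s + 1 + SP] = Q[SP] * (Cart - Cout[SP]) / V[SP];

        double qhv = Q[LI] + Q[GU] + Q[SP];    /* hepatic venous outflow */
        ydot[s + 1 + LI] = (Q[LI] * Cart + Q[GU] * Cout[GU]
                            + Q[SP] * Cout[SP] - qhv * Cout[LI]
                            + fg * ratein - vcyp - vadd) / V[LI];
        ydot[s + 1 + LU] = CO * (Cven - Cout[LU]) / V[LU];
        ydot[s + 12] = CO * (Cout[LU] - Cart) / Vart;

        double vin = Q[AD] * Cout[AD] + Q[BO] * Cout[BO] + Q[BR] * Cout[BR]
                   + Q[HE] * Cout[HE] + Q[KI] * Cout[KI] + Q[MU] * Cout[MU]
                   + Q[SK] * Cout[SK] + qhv * Cout[LI];
        ydot[s + 13] = (vin - CO * Cven - renal) / Vven;

        ydot[s + 14] = (1.0 - fg) * ratein;
        ydot[s + 15] = vcyp;
        ydot[s + 16] = vadd;
        ydot[s + 17] = renal;
    }
}
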