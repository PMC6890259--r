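/* Right-hand side of the refined two-compartment adipose tissue model,
 * in the deSolve compiled-model interface (initfunc/initforc/derivs).
 *
 * States (11):
 *   0..2  I1_LPL, I2_LPL, I_LPL : insulin delay chain for LPL lipolysis
 *   3..5  I1_AT,  I2_AT,  I_AT  : insulin delay chain for the adipose space
 *   6     GLY_AT                : interstitial adipose glycerol   (mmol/l)
 *   7     NEFA_AT               : interstitial adipose NEFA       (mmol/l)
 *   8     G6P                   : glucose-6-phosphate pool        (flux-scaled)
 *   9     G3P_pro               : G-3-P production signal         (flux-scaled)
 *   10    G3P_AT                : adipose glycerol-3-phosphate
 *
 * Forcings (5, linearly interpolated arterial samples, constant beyond range):
 *   I_art (uU/ml), G_art, TG_art, GLY_art, NEFA_art (mmol/l)
 *
 * Sign convention: reported fluxes follow the measured arteriovenous
 * convention (arterial - venous) x ATBF, i.e. uptake positive, release
 * negative.  Units: umol / 100 ml tissue / min.
 */
#include <R.h>

static double parms[16];
static double forc[5];

#define K_AD     parms[0]
#define TAU_LPL  parms[1]
#define TAU_AT   parms[2]
#define D_SPILL  parms[3]
#define GLUT1_R  parms[4]
#define GLUT4_R  parms[5]
#define P_GLY    parms[6]
#define B_ATL    parms[7]
#define ATL_MAX  parms[8]
#define K_ATL    parms[9]
#define P_NEFA   parms[10]
#define K_REEST  parms[11]
#define FRAC_USE parms[12]
#define TAU_G3P  parms[13]
#define I_BASAL  parms[14]
#define K_SINK   parms[15]

#define I_ART    forc[0]
#define G_ART    forc[1]
#define TG_ART   forc[2]
#define GLY_ART  forc[3]
#define NEFA_ART forc[4]

void adipose_init(void (*odeparms)(int *, double *))
{
    int n = 16;
    odeparms(&n, parms);
}

void adipose_forc(void (*odeforcs)(int *, double *))
{
    int n = 5;
    odeforcs(&n, forc);
}

void adipose_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    if (ip[0] < 14)
        error("nout should be at least 14");

    double i_lpl   = y[2];
    double i_at    = y[5];
    double gly_at  = y[6];
    double nefa_at = y[7];
    double g6p     = y[8];
    double g3p_pro = y[9];
    double g3p_at  = y[10];

    /* three-compartment insulin delay chains (tau > 0 enforced in R) */
    ydot[0] = (I_ART - y[0]) / TAU_LPL;
    ydot[1] = (y[0] - y[1]) / TAU_LPL;
    ydot[2] = (y[1] - y[2]) / TAU_LPL;
    ydot[3] = (I_ART - y[3]) / TAU_AT;
    ydot[4] = (y[3] - y[4]) / TAU_AT;
    ydot[5] = (y[4] - y[5]) / TAU_AT;

    /* LPL hydrolysis of circulating TG (umol TG /100ml/min, uptake) */
    double lpl = K_AD * TG_ART * i_lpl;

    /* fractional spill-over of LPL-derived NEFA, clamped to [0, 1] */
    double f = (I_ART > 0.0) ? 0.01 * D_SPILL * I_BASAL / I_ART : 1.0;
    if (f > 1.0) f = 1.0;
    if (f < 0.0) f = 0.0;

    /* glucose uptake: insulin-independent (GLUT1) + dependent (GLUT4) */
    double glc_uptake = GLUT1_R * G_ART + GLUT4_R * G_ART * i_at;

    /* insulin-inhibited lipolysis of stored TG (ATL), saturable */
    double atl;
    if (K_ATL > 0.0)
        atl = B_ATL + ATL_MAX / (1.0 + i_at / K_ATL);
    else  /* degenerate guard; R-level validation rejects this for users */
        atl = B_ATL + ((i_at > 0.0) ? 0.0 : ATL_MAX);

    double spill      = 3.0 * f * lpl;          /* FA into plasma        */
    double influx     = 3.0 * (1.0 - f) * lpl;  /* FA into adipose space */
    double nefa_pl    = NEFA_ART + spill;       /* local plasma NEFA     */
    double gly_diff   = P_GLY * (gly_at - (GLY_ART + lpl));  /* AT->plasma */
    double nefa_diff  = P_NEFA * (nefa_pl - nefa_at);        /* plasma->AT */
    double reester    = 3.0 * K_REEST * i_at * nefa_at * g3p_at;

    ydot[6]  = -gly_diff + atl - K_SINK * gly_at;
    ydot[7]  = influx + nefa_diff + 3.0 * atl - reester;
    ydot[8]  = (2.0 * FRAC_USE * glc_uptake - g6p) / TAU_G3P;
    ydot[9]  = (g6p - g3p_pro) / TAU_G3P;
    ydot[10] = g3p_pro - reester / 3.0;

    /* measured-convention model fluxes and constituent reaction rates */
    yout[0]  = lpl;                       /* tg_flux (uptake positive)   */
    yout[1]  = f;                         /* spill_fraction              */
    yout[2]  = glc_uptake;                /* glucose_flux                */
    yout[3]  = -(lpl + gly_diff);         /* glycerol_flux               */
    yout[4]  = nefa_diff - spill;         /* nefa_flux                   */
    yout[5]  = lpl;                       /* lpl_rate                    */
    yout[6]  = atl;                       /* atl_rate                    */
    yout[7]  = spill;                     /* spill_rate (FA units)       */
    yout[8]  = influx;                    /* adipose_influx (FA units)   */
    yout[9]  = gly_diff;                  /* gly_diffusion (AT->plasma)  */
    yout[10] = nefa_diff;                 /* nefa_diffusion (plasma->AT) */
    yout[11] = reester;                   /* reester_rate (FA units)     */
    yout[12] = g3p_pro;                   /* g3p_production              */
    yout[13] = nefa_pl;                   /* local plasma NEFA conc      */
}
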