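#include <R.h>

/* parameter block passed from R via deSolve's initfunc mechanism:
   [0] n, [1] nprod, [2] dx, [3] v, [4] D, [5] kp, [6] KP, [7] Yphi,
   [8] m, [9] rhoX, [10] psi, [11] YL, [12] kc, [13] KC, [14] A,
   [15] depleting, [16] A0 */
static double parms[17];

/* The maintenance sink switches off as a tank runs out of nutrient.
   A hard on/off switch at zero makes a BDF integrator chatter, so the
   shutoff is regularized with a saturating gate x/(x + MAINT_EPS); the
   half-saturation point sits orders of magnitude below physiological
   nutrient concentrations, so the bias is negligible and starved tanks
   settle at a small positive equilibrium instead of crossing zero.
   Must match .maint_eps in R/model.R. */
#define MAINT_EPS 1e-4
#define GATE(x) ((x) <= 0.0 ? 0.0 : (x) / ((x) + MAINT_EPS))

void hypha_initmod(void (* odeparms)(int *, double *))
{
    int N = 17;
    odeparms(&N, parms);
}

#define OM(i) y[2*(i) - 1]
#define PH(i) y[2*(i)]
#define DOM(i) ydot[2*(i) - 1]
#define DPH(i) ydot[2*(i)]

void hypha_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    const int n = (int) parms[0];
    const int nprod = (int) parms[1];
    const double dx = parms[2], v = parms[3], D = parms[4];
    const double kp = parms[5], KP = parms[6], Yphi = parms[7];
    const double m = parms[8], rhoX = parms[9], psi = parms[10];
    const double YL = parms[11], kc = parms[12], KC = parms[13];
    const double A = parms[14];
    const int depleting = (int) parms[15];
    const double A0 = parms[16];

    const double om0 = y[0];
    const double L = y[2*n + 1];
    const double hgap = 0.5 * (L + dx);   /* centre-to-centre spacing at the tip interface */
    const double cconv = v / dx;
    const double cdiff = D / (dx * dx);
    const int ifirst = n - nprod;         /* first vesicle-producing tank */

    for (int i = 1; i <= n - 1; i++) {
        double omu = (i == 1) ? om0 : OM(i - 1);
        double phu = (i == 1) ? 0.0 : PH(i - 1);
        double omi = OM(i), phi = PH(i);
        double omc = omi > 0.0 ? omi : 0.0;
        double prod = (i >= ifirst) ? kp * omc / (KP + omc) : 0.0;
        double maint = m * rhoX * GATE(omi);
        double dom = (cconv + cdiff) * (omu - omi) - prod / Yphi - maint;
        if (i < n - 1)
            dom -= cdiff * (omi - OM(i + 1));
        else
            dom -= D / (dx * hgap) * (omi - OM(n));
        DOM(i) = dom;
        DPH(i) = (psi / dx) * (phu - phi) + prod;
    }

    /* tip-tank: variable length L, consumption only */
    double omn = OM(n), phn = PH(n);
    double phc = phn > 0.0 ? phn : 0.0;
    double mm = phc / (KC + phc);
    double dL = YL * kc * mm;
    double maint_n = m * rhoX * GATE(omn);
    DOM(n) = -(omn / L) * dL + (v / L) * OM(n - 1)
             + D / (L * hgap) * (OM(n - 1) - omn) - maint_n;
    DPH(n) = -(phn / L) * dL + (psi / L) * PH(n - 1) - kc * mm / (A * L);
    ydot[2*n + 1] = dL;

    ydot[0] = depleting
        ? -(A / (A0 * dx)) * (v * om0 + (D / dx) * (om0 - OM(1)))
        : 0.0;
}

void hypha_root(int *neq, double *t, double *y, int *ng, double *gout,
                double *out, int *ip)
{
    const int n = (int) parms[0];
    gout[0] = y[2*n + 1] - 2.0 * parms[2];
}
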