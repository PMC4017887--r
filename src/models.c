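/* Compiled right-hand sides for the three conductance-based models,
 * in the deSolve compiled-code convention (initfunc + derivs).
 *
 * Unit systems:
 *   hh      : t in ms, V in mV, currents in uA/cm2, conductances mS/cm2
 *   sd      : t in ms, concentrations in mM, flux factor in mM/ms per uA/cm2
 *   anoxia  : t in s,  concentrations in mM, flux factor in mM/s  per uA/cm2
 */

#include <R.h>
#include <math.h>

/* x / (1 - exp(-x/10)) with the removable singularity at x = 0
 * evaluated by its series limit (10 + x/2 + ...). */
static double xexp10(double x)
{
    if (fabs(x) < 1e-7)
        return 10.0 + 0.5 * x;
    return x / (1.0 - exp(-x / 10.0));
}

/* classical rate functions */
static void rates_classical(double V, double *am, double *bm, double *an,
                            double *bn, double *ah, double *bh)
{
    *am = 0.1  * xexp10(V + 40.0);
    *bm = 4.0  * exp(-(V + 65.0) / 18.0);
    *an = 0.01 * xexp10(V + 55.0);
    *bn = 0.125 * exp(-(V + 65.0) / 80.0);
    *ah = 0.07 * exp(-(V + 65.0) / 20.0);
    *bh = 1.0 / (1.0 + exp(-0.1 * (V + 35.0)));
}

/* shifted rate functions (ion-concentration models) */
static void rates_shifted(double V, double *am, double *bm, double *an,
                          double *bn, double *ah, double *bh)
{
    *am = 0.1  * xexp10(V + 30.0);
    *bm = 4.0  * exp(-(V + 55.0) / 18.0);
    *an = 0.01 * xexp10(V + 34.0);
    *bn = 0.125 * exp(-(V + 44.0) / 80.0);
    *ah = 0.07 * exp(-(V + 44.0) / 20.0);
    *bh = 1.0 / (1.0 + exp(-0.1 * (V + 14.0)));
}

/* mutant rescaling of tau_h: kappa1*tanh(sigma*(V - Vmax)) + kappa2 */
static double tau_factor(double V, double mut, double k1, double k2,
                         double sigma, double Vmax)
{
    if (mut == 0.0)
        return 1.0;
    return k1 * tanh(sigma * (V - Vmax)) + k2;
}

static double pulse_current(double t, double iconst, double amp,
                            double on, double off)
{
    double I = iconst;
    if (amp != 0.0 && t >= on && t < off)
        I += amp;
    return I;
}

/* ------------------------------------------------------------------ */
/* classical Hodgkin-Huxley model: y = (V, m, n, h)                    */
/* ------------------------------------------------------------------ */

#define NP_HH 16
static double ph[NP_HH];

void hhsd_init_hh(void (*odeparms)(int *, double *))
{
    int n = NP_HH;
    odeparms(&n, ph);
}

void hhsd_deriv_hh(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double Cm = ph[0], gNa = ph[1], gK = ph[2], gl = ph[3];
    double ENa = ph[4], EK = ph[5], El = ph[6];
    double V = y[0], m = y[1], n = y[2], h = y[3];
    double am, bm, an, bn, ah, bh, INa, IK, Il, Iapp, fac;

    rates_classical(V, &am, &bm, &an, &bn, &ah, &bh);
    Iapp = pulse_current(*t, ph[12], ph[13], ph[14], ph[15]);

    INa = gNa * m * m * m * h * (V - ENa);
    IK  = gK * n * n * n * n * (V - EK);
    Il  = gl * (V - El);

    fac = tau_factor(V, ph[7], ph[8], ph[9], ph[10], ph[11]);

    ydot[0] = -(INa + IK + Il - Iapp) / Cm;
    ydot[1] = am * (1.0 - m) - bm * m;
    ydot[2] = an * (1.0 - n) - bn * n;
    ydot[3] = (ah * (1.0 - h) - bh * h) / fac;

    if (ip[0] >= 1)
        yout[0] = Iapp;
}

/* ------------------------------------------------------------------ */
/* spreading depression model: y = (V, n, h, Ki, Ke), t in ms          */
/* ------------------------------------------------------------------ */

#define NP_SD 29
static double ps[NP_SD];

void hhsd_init_sd(void (*odeparms)(int *, double *))
{
    int n = NP_SD;
    odeparms(&n, ps);
}

/* piecewise-linear pump scaling: 1 -> floor over [t0,t1], hold to t2,
 * floor -> 1 over [t2,t3]; identically 1 if t0 < 0 */
static double pump_scale(double t, double t0, double t1, double t2,
                         double t3, double fl)
{
    if (t0 < 0.0 || t < t0 || t >= t3)
        return 1.0;
    if (t < t1)
        return 1.0 + (fl - 1.0) * (t - t0) / (t1 - t0);
    if (t < t2)
        return fl;
    return fl + (1.0 - fl) * (t - t2) / (t3 - t2);
}

void hhsd_deriv_sd(int *neq, double *t, double *y, double *ydot,
                   double *yout, int *ip)
{
    double Cm = ps[0], gNal = ps[1], gNag = ps[2], gKl = ps[3], gKg = ps[4];
    double conv_i = ps[5], conv_e = ps[6], rho = ps[7], phi = ps[8];
    double Fdiff = ps[9], Kbath = ps[10];
    double Nai0 = ps[11], Nae0 = ps[12], Ki0 = ps[13], volr = ps[14];
    double V = y[0], n = y[1], h = y[2], Ki = y[3], Ke = y[4];
    double am, bm, an, bn, ah, bh;
    double Nai, Nae, ENa, EK, minf, sp, Ip, INa, IK, Jdiff, Iapp, fac;

    Nai = Nai0 - Ki + Ki0;
    Nae = volr * (Nai0 - Nai) + Nae0;
    ENa = 26.64 * log(Nae / Nai);
    EK  = 26.64 * log(Ke / Ki);

    rates_shifted(V, &am, &bm, &an, &bn, &ah, &bh);
    minf = am / (am + bm);

    sp = pump_scale(*t, ps[24], ps[25], ps[26], ps[27], ps[28]);
    Ip = sp * rho / ((1.0 + exp((25.0 - Nai) / 3.0)) *
                     (1.0 + exp(5.5 - Ke)));

    INa = (gNal + gNag * minf * minf * minf * h) * (V - ENa) + 3.0 * Ip;
    IK  = (gKl + gKg * n * n * n * n) * (V - EK) - 2.0 * Ip;
    Jdiff = Fdiff * (Kbath - Ke);
    Iapp = pulse_current(*t, ps[20], ps[21], ps[22], ps[23]);

    fac = tau_factor(V, ps[15], ps[16], ps[17], ps[18], ps[19]);

    ydot[0] = -(INa + IK - Iapp) / Cm;
    ydot[1] = phi * (an * (1.0 - n) - bn * n);
    ydot[2] = phi * (ah * (1.0 - h) - bh * h) / fac;
    ydot[3] = -conv_i * IK;
    ydot[4] = conv_e * IK + Jdiff;

    if (ip[0] >= 6) {
        yout[0] = Nai;
        yout[1] = Nae;
        yout[2] = ENa;
        yout[3] = EK;
        yout[4] = sp;
        yout[5] = Ip;
    }
}

/* ------------------------------------------------------------------ */
/* anoxia model: y = (V, n, h, Nai, Nae, Ki, Ke, Cli, Cle), t in s     */
/* ------------------------------------------------------------------ */

#define NP_AX 23
static double pa[NP_AX];

void hhsd_init_anoxia(void (*odeparms)(int *, double *))
{
    int n = NP_AX;
    odeparms(&n, pa);
}

void hhsd_deriv_anoxia(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    double Cm = pa[0], gNal = pa[1], gNag = pa[2], gKl = pa[3], gKg = pa[4];
    double gCll = pa[5], conv = pa[6], beta = pa[7], rho = pa[8];
    double phi = pa[9], G = pa[10], eps = pa[11], kinf = pa[12];
    double toff = pa[22];
    double V = y[0], n = y[1], h = y[2];
    double Nai = y[3], Nae = y[4], Ki = y[5], Ke = y[6];
    double Cli = y[7], Cle = y[8];
    double am, bm, an, bn, ah, bh;
    double ENa, EK, ECl, minf, sw, Ip, Ig, Id, INa, IK, ICl, Iapp, fac;

    ENa = 26.64 * log(Nae / Nai);
    EK  = 26.64 * log(Ke / Ki);
    ECl = -26.64 * log(Cle / Cli);

    rates_shifted(V, &am, &bm, &an, &bn, &ah, &bh);
    minf = am / (am + bm);

    /* energy-dependent clearance switched off at t = toff (never if < 0) */
    sw = (toff < 0.0 || *t < toff) ? 1.0 : 0.0;

    Ip = sw * rho / ((1.0 + exp((25.0 - Nai) / 3.0)) *
                     (1.0 + exp(5.5 - Ke)));
    Ig = sw * G / (1.0 + exp((18.0 - Ke) / 2.5));
    Id = sw * eps * (Ke - kinf);

    INa = (gNal + gNag * minf * minf * minf * h) * (V - ENa) + 3.0 * Ip;
    IK  = (gKl + gKg * n * n * n * n) * (V - EK) - 2.0 * Ip;
    ICl = gCll * (V - ECl);
    Iapp = pulse_current(*t, pa[18], pa[19], pa[20], pa[21]);

    fac = tau_factor(V, pa[13], pa[14], pa[15], pa[16], pa[17]);

    /* V and gating are per-ms dynamics; this module integrates in s */
    ydot[0] = -1000.0 * (INa + IK + ICl - Iapp) / Cm;
    ydot[1] = 1000.0 * phi * (an * (1.0 - n) - bn * n);
    ydot[2] = 1000.0 * phi * (ah * (1.0 - h) - bh * h) / fac;

    /* cation fluxes: positive outward current lowers the inside;
     * for Cl- (valence -1) an outward positive current is an inward
     * chloride flux, so the sign is opposite */
    ydot[3] = -conv * INa;
    ydot[4] = beta * conv * INa;
    ydot[5] = -conv * IK;
    ydot[6] = beta * conv * IK - Ig - Id;
    ydot[7] = conv * ICl;
    ydot[8] = -beta * conv * ICl;

    if (ip[0] >= 4) {
        yout[0] = ENa;
        yout[1] = EK;
        yout[2] = ECl;
        yout[3] = sw;
    }
}
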