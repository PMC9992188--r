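/* Flow-limited PBPK mass balance for oral dosing of a volatile alcohol.
 *
 * Compiled right-hand side for deSolve (func = "pbpk_deriv",
 * initfunc = "pbpk_init", dllname = "caaPBPK").
 *
 * Units: mg, L, h.
 *
 * Parameter vector (see param_vector() in R/parameters.R — order is a
 * contract between the two files):
 *   0  ka          first-order absorption rate constant, 1/h
 *   1  vmax        hepatic metabolic capacity, mg/h
 *   2  km          Michaelis constant, mg/L
 *   3  q_total     cardiac output, L/h
 *   4  q_alv       alveolar ventilation, L/h
 *   5  p_ba        blood:air partition coefficient
 *   6-10  q[i]     tissue blood flows, L/h   (liver, fat, bm, richly, slowly)
 *   11-15 v[i]     tissue volumes, L
 *   16-20 p[i]     tissue:blood partition coefficients
 *   21 rinf        gut infusion rate, mg/h (constant within a segment;
 *                  square pulses are realized by restarting integration
 *                  at every pulse edge)
 *
 * State vector:
 *   0      a_gut   unabsorbed amount in the oral dosing compartment, mg
 *   1-5    a[i]    amounts in the five tissues, mg (liver first)
 *   6      a_met   cumulative metabolized, mg
 *   7      a_exh   cumulative exhaled, mg
 *   8      a_abs   cumulative absorbed, mg           (bookkeeping)
 *   9      a_fpe   cumulative first-pass escape, mg  (bookkeeping)
 *   10     auc_v   running integral of venous concentration, mg.h/L
 *
 * Mass conservation: d/dt (a_gut + sum(a[i]) + a_met + a_exh) = rinf.
 */

#include <R.h>

static double parms[22];

#define KA    parms[0]
#define VMAX  parms[1]
#define KM    parms[2]
#define QTOT  parms[3]
#define QALV  parms[4]
#define PBA   parms[5]
#define Q(i)  parms[6 + (i)]
#define V(i)  parms[11 + (i)]
#define P(i)  parms[16 + (i)]
#define RINF  parms[21]

void pbpk_init(void (*odeparms)(int *, double *))
{
    int n = 22;
    odeparms(&n, parms);
}

void pbpk_deriv(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    double cvt[5];              /* venous effluent concentration, tissue i */
    double cv = 0.0;
    int i;

    for (i = 0; i < 5; i++) {
        cvt[i] = y[1 + i] / (V(i) * P(i));
        cv += Q(i) * cvt[i];
    }
    cv /= QTOT;                                  /* mixed venous, mg/L */

    /* steady-state lung: QTOT*cv = QTOT*ca + QALV*ca/PBA (zero inhaled) */
    double ca   = QTOT * cv / (QTOT + QALV / PBA);
    double cvl  = cvt[0];                        /* liver venous, mg/L */
    double rmet = VMAX * cvl / (KM + cvl);       /* mg/h */
    double rabs = KA * y[0];                     /* mg/h */
    double rexh = QALV * ca / PBA;               /* mg/h */

    ydot[0] = RINF - rabs;
    for (i = 0; i < 5; i++)
        ydot[1 + i] = Q(i) * (ca - cvt[i]);
    ydot[1] += rabs - rmet;                      /* liver extras */
    ydot[6] = rmet;
    ydot[7] = rexh;
    ydot[8] = rabs;
    /* instantaneous hepatic escape probability of newly absorbed drug;
       equals the well-stirred Q_L/(Q_L + Vmax/Km) in the linear regime */
    ydot[9] = rabs * Q(0) / (Q(0) + VMAX / (KM + cvl));
    ydot[10] = cv;

    if (ip[0] >= 2) {
        yout[0] = cv;
        yout[1] = ca;
    }
}
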