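/* Uric acid turnover model: compiled right-hand side for deSolve::lsoda,
 * closed-form plasma-concentration evaluation, and a self-contained
 * per-subject Laplace-marginal evaluator (embedded Dormand-Prince 5(4)
 * integrator + damped Newton over the random effects) used by the
 * population-estimation hot path.
 *
 * Parameter vector layout (fixed length UA_NPARMS, padded with zeros):
 *   [0] kin      production rate, mg/h (individual)
 *   [1] feua     baseline fractional excretion (individual)
 *   [2] cl_i     intestinal clearance, L/h
 *   [3] v1       volume of distribution, L
 *   [4] egfr     glomerular filtration flow, L/h
 *   [5] emax_v   verinurad maximum FEUA increase
 *   [6] ec50_v   verinurad EC50, ng/mL (individual)
 *   [7] emax_x   XOI maximum production inhibition
 *   [8] ec50_x   XOI EC50, ng/mL (individual)
 *   [9..]   verinurad exposure block (UA_BLOCKLEN doubles)
 *   [9+B..] XOI exposure block
 *
 * Exposure block: [0] mode (0 none, 1 first-order impulse into depot,
 * 2 zero-order pulse into depot, 3 constant concentration), [1] lag (h),
 * [2] tau0 (h), [3..5] c1..c3 coefficients (ng/mL per mg after dose
 * scaling), [6..8] mu1..mu3 rate constants (1/h), [9] ndose,
 * [10+2d] dose time (h), [11+2d] dose scale.
 *
 * States (12): A1, A2, cumulative intestinal elimination, cumulative
 * production, then sensitivity pairs (dA1, dA2) w.r.t. the log of the
 * individual kin, feua, ec50_v, ec50_x.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <string.h>

#define UA_BLOCKLEN 138
#define UA_MAXDOSE 64
#define UA_NPARMS (9 + 2 * UA_BLOCKLEN)
#define UA_NEQ 12

static double parms[UA_NPARMS];

void ua_init(void (*odeparms)(int *, double *))
{
    int n = UA_NPARMS;
    odeparms(&n, parms);
}

/* concentration at time t for one exposure block */
static double ua_conc_block(const double *b, double t)
{
    int mode = (int) b[0];
    if (mode == 0) return 0.0;
    if (mode == 3) return b[3];        /* constant concentration */
    double lag = b[1], tau0 = b[2];
    const double *cc = b + 3, *mu = b + 6;
    int nd = (int) b[9];
    double s = 0.0;
    for (int d = 0; d < nd; d++) {
        double td = b[10 + 2 * d], sc = b[11 + 2 * d];
        double u = t - td - lag;
        if (u <= 0.0 || sc == 0.0) continue;
        if (mode == 1) {
            for (int i = 0; i < 3; i++)
                s += sc * cc[i] * exp(-mu[i] * u);
        } else {
            /* zero-order input over tau0, convolved impulse response */
            double u1 = u > tau0 ? u - tau0 : 0.0;
            for (int i = 0; i < 3; i++)
                s += (sc / tau0) * (cc[i] / mu[i]) *
                     (exp(-mu[i] * u1) - exp(-mu[i] * u));
        }
    }
    return s > 0.0 ? s : 0.0;
}

/* shared right-hand side */
static void ua_rhs(double t, const double *y, double *ydot, const double *p,
                   double *out5)
{
    double kin = p[0], feua = p[1], cl_i = p[2], v1 = p[3], egfr = p[4],
           emax_v = p[5], ec50_v = p[6], emax_x = p[7], ec50_x = p[8];

    double cv = ua_conc_block(p + 9, t);
    double cx = ua_conc_block(p + 9 + UA_BLOCKLEN, t);

    double inh = 1.0 - emax_x * cx / (ec50_x + cx);
    double prod = kin * inh;
    double ev = emax_v * cv / (ec50_v + cv);
    double fe = feua + ev;

    double c_ua = y[0] / v1;           /* mg/L */
    double kel = (cl_i + egfr * fe) / v1;
    double rr = egfr * fe * c_ua;      /* renal excretion rate mg/h */

    ydot[0] = prod - cl_i * c_ua - rr;
    ydot[1] = rr;
    ydot[2] = cl_i * c_ua;
    ydot[3] = prod;

    /* sensitivities w.r.t. log individual parameters */
    ydot[4] = prod - kel * y[4];
    ydot[5] = egfr * fe * y[4] / v1;
    ydot[6] = -egfr * feua * c_ua - kel * y[6];
    ydot[7] = egfr * (feua * c_ua + fe * y[6] / v1);
    double dfe_e = -ev * ec50_v / (ec50_v + cv);
    ydot[8] = -egfr * dfe_e * c_ua - kel * y[8];
    ydot[9] = egfr * (dfe_e * c_ua + fe * y[8] / v1);
    double dprod_x = kin * emax_x * cx * ec50_x /
                     ((ec50_x + cx) * (ec50_x + cx));
    ydot[10] = dprod_x - kel * y[10];
    ydot[11] = egfr * fe * y[10] / v1;

    if (out5) {
        out5[0] = cv;
        out5[1] = cx;
        out5[2] = fe;
        out5[3] = rr;
        out5[4] = prod;
    }
}

/* deSolve entry point */
void ua_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    ua_rhs(*t, y, ydot, parms, ip[0] >= 5 ? yout : NULL);
}

/* .Call interface: evaluate a single exposure block on a time vector */
SEXP C_ua_conc(SEXP block, SEXP tvec)
{
    if (LENGTH(block) < UA_BLOCKLEN)
        error("exposure block too short");
    int n = LENGTH(tvec);
    SEXP out = PROTECT(allocVector(REALSXP, n));
    double *b = REAL(block), *tt = REAL(tvec), *o = REAL(out);
    for (int i = 0; i < n; i++)
        o[i] = ua_conc_block(b, tt[i]);
    UNPROTECT(1);
    return out;
}

/* ---------------- embedded Dormand-Prince 5(4) integrator -------------- */

/* Integrate the 12-state system from times[0] to times[nt-1], recording
 * the state at every output time into ymat (nt x UA_NEQ, row-major).
 * Breakpoints (derivative kinks from dosing) are landed on exactly.
 * Returns 0 on success, nonzero on failure. */
static int ua_integrate(const double *p, const double *y0,
                        const double *times, int nt,
                        const double *brk, int nbrk,
                        double rtol, double atol, double *ymat)
{
    static const double c2 = 1.0 / 5, c3 = 3.0 / 10, c4 = 4.0 / 5,
        c5 = 8.0 / 9;
    static const double a21 = 1.0 / 5;
    static const double a31 = 3.0 / 40, a32 = 9.0 / 40;
    static const double a41 = 44.0 / 45, a42 = -56.0 / 15, a43 = 32.0 / 9;
    static const double a51 = 19372.0 / 6561, a52 = -25360.0 / 2187,
        a53 = 64448.0 / 6561, a54 = -212.0 / 729;
    static const double a61 = 9017.0 / 3168, a62 = -355.0 / 33,
        a63 = 46732.0 / 5247, a64 = 49.0 / 176, a65 = -5103.0 / 18656;
    static const double b1 = 35.0 / 384, b3 = 500.0 / 1113,
        b4 = 125.0 / 192, b5 = -2187.0 / 6784, b6 = 11.0 / 84;
    static const double e1 = 35.0 / 384 - 5179.0 / 57600,
        e3 = 500.0 / 1113 - 7571.0 / 16695,
        e4 = 125.0 / 192 - 393.0 / 640,
        e5 = -2187.0 / 6784 + 92097.0 / 339200,
        e6 = 11.0 / 84 - 187.0 / 2100, e7 = -1.0 / 40;

    double y[UA_NEQ], k1[UA_NEQ], k2[UA_NEQ], k3[UA_NEQ], k4[UA_NEQ],
        k5[UA_NEQ], k6[UA_NEQ], k7[UA_NEQ], yt[UA_NEQ], yn[UA_NEQ];
    memcpy(y, y0, sizeof(y));
    double t = times[0];
    memcpy(ymat, y, sizeof(y));
    int iout = 1, ibrk = 0;
    while (ibrk < nbrk && brk[ibrk] <= t) ibrk++;

    double h = 0.5;
    long nstep = 0;
    int have_k1 = 0;
    while (iout < nt) {
        if (++nstep > 100000L) return 1;
        double tstop = times[iout];
        if (ibrk < nbrk && brk[ibrk] < tstop) tstop = brk[ibrk];
        if (h > tstop - t) h = tstop - t;
        if (h < 1e-13 * (fabs(t) + 1.0)) {
            /* at a stop point: advance bookkeeping */
            if (ibrk < nbrk && tstop == brk[ibrk]) { ibrk++; have_k1 = 0; }
            if (tstop == times[iout]) {
                memcpy(ymat + (size_t) iout * UA_NEQ, y, sizeof(y));
                iout++;
            }
            h = 0.5;
            continue;
        }
        if (!have_k1) ua_rhs(t, y, k1, p, NULL);
        for (int i = 0; i < UA_NEQ; i++) yt[i] = y[i] + h * a21 * k1[i];
        ua_rhs(t + c2 * h, yt, k2, p, NULL);
        for (int i = 0; i < UA_NEQ; i++)
            yt[i] = y[i] + h * (a31 * k1[i] + a32 * k2[i]);
        ua_rhs(t + c3 * h, yt, k3, p, NULL);
        for (int i = 0; i < UA_NEQ; i++)
            yt[i] = y[i] + h * (a41 * k1[i] + a42 * k2[i] + a43 * k3[i]);
        ua_rhs(t + c4 * h, yt, k4, p, NULL);
        for (int i = 0; i < UA_NEQ; i++)
            yt[i] = y[i] + h * (a51 * k1[i] + a52 * k2[i] + a53 * k3[i] +
                                a54 * k4[i]);
        ua_rhs(t + c5 * h, yt, k5, p, NULL);
        for (int i = 0; i < UA_NEQ; i++)
            yt[i] = y[i] + h * (a61 * k1[i] + a62 * k2[i] + a63 * k3[i] +
                                a64 * k4[i] + a65 * k5[i]);
        ua_rhs(t + h, yt, k6, p, NULL);
        for (int i = 0; i < UA_NEQ; i++)
            yn[i] = y[i] + h * (b1 * k1[i] + b3 * k3[i] + b4 * k4[i] +
                                b5 * k5[i] + b6 * k6[i]);
        ua_rhs(t + h, yn, k7, p, NULL);
        double err = 0.0;
        for (int i = 0; i < UA_NEQ; i++) {
            double ei = h * (e1 * k1[i] + e3 * k3[i] + e4 * k4[i] +
                             e5 * k5[i] + e6 * k6[i] + e7 * k7[i]);
            double sc = atol + rtol * fmax(fabs(y[i]), fabs(yn[i]));
            double r = ei / sc;
            err += r * r;
        }
        err = sqrt(err / UA_NEQ);
        if (!isfinite(err)) return 2;
        if (err <= 1.0) {
            t += h;
            memcpy(y, yn, sizeof(y));
            memcpy(k1, k7, sizeof(k1));  /* FSAL */
            have_k1 = 1;
            if (t >= tstop - 1e-12 * (fabs(tstop) + 1.0)) {
                t = tstop;
                if (ibrk < nbrk && tstop == brk[ibrk]) {
                    ibrk++;
                    have_k1 = 0;  /* derivative kink: re-evaluate */
                }
                if (iout < nt && tstop == times[iout]) {
                    memcpy(ymat + (size_t) iout * UA_NEQ, y, sizeof(y));
                    iout++;
                }
            }
        }
        double fac = err > 1e-10 ? 0.9 * pow(err, -0.2) : 5.0;
        if (fac > 5.0) fac = 5.0;
        if (fac < 0.2) fac = 0.2;
        h *= fac;
        if (h < 1e-12) return 3;
    }
    return 0;
}

/* collect derivative-kink times from one exposure block */
static int ua_kinks(const double *b, double t0, double t1, double *out,
                    int pos)
{
    int mode = (int) b[0];
    if (mode != 1 && mode != 2) return pos;
    double lag = b[1], tau0 = b[2];
    int nd = (int) b[9];
    for (int d = 0; d < nd; d++) {
        double td = b[10 + 2 * d] + lag;
        if (td > t0 && td < t1) out[pos++] = td;
        if (mode == 2 && td + tau0 > t0 && td + tau0 < t1)
            out[pos++] = td + tau0;
    }
    return pos;
}

static int cmp_dbl(const void *a, const void *b)
{
    double d = *(const double *) a - *(const double *) b;
    return (d > 0) - (d < 0);
}

/* ---------------- per-subject Laplace marginal ------------------------- */

typedef struct {
    const double *tmpl;       /* parameter template, UA_NPARMS */
    const int *eta_slot;      /* k entries: 1 kin, 2 feua, 3 ec50v, 4 ec50x */
    int k;
    const double *times; int nt;
    const int *serum_idx; const double *serum_y; int ns; double a_serum;
    const int *uidx0, *uidx1; const double *urine_y; int nu;
    double a_urine, b_urine;
    const double *oinv;       /* k x k */
    double prior_const;       /* -(k log 2pi + log|Omega|)/2 */
    double rtol, atol;
    const double *brk; int nbrk;
    double *ymat;             /* nt x UA_NEQ work */
    double *pwork;            /* UA_NPARMS work */
} ua_subj;

/* sensitivity state indices for each eta slot: A1-sens, A2-sens */
static const int slot_s1[5] = {0, 4, 6, 8, 10};
static const int slot_s2[5] = {0, 5, 7, 9, 11};

/* evaluate joint loglik, gradient, Fisher curvature at eta.
 * Returns 1 on success. */
static int ua_eval_joint(ua_subj *s, const double *eta, double *ll,
                         double *grad, double *fish)
{
    int k = s->k;
    double *p = s->pwork;
    memcpy(p, s->tmpl, UA_NPARMS * sizeof(double));
    for (int j = 0; j < k; j++) {
        double m = exp(eta[j]);
        switch (s->eta_slot[j]) {
        case 1: p[0] *= m; break;
        case 2: p[1] *= m; if (p[1] > 0.999) p[1] = 0.999; break;
        case 3: p[6] *= m; break;
        case 4: p[8] *= m; break;
        }
    }
    double kin = p[0], feua = p[1], cl_i = p[2], v1 = p[3], egfr = p[4];
    double denom = cl_i + egfr * feua;
    double a1_0 = v1 * kin / denom;
    double y0[UA_NEQ] = {0};
    y0[0] = a1_0;
    y0[4] = a1_0;                               /* d a1(0) / d log kin */
    y0[6] = -a1_0 * egfr * feua / denom;        /* d a1(0) / d log feua */
    int rc = ua_integrate(p, y0, s->times, s->nt, s->brk, s->nbrk,
                          s->rtol, s->atol, s->ymat);
    if (rc != 0) return 0;
    double L = 0.0;
    for (int j = 0; j < k; j++) grad[j] = 0.0;
    for (int a = 0; a < k * k; a++) fish[a] = 0.0;
    /* prior */
    for (int a = 0; a < k; a++)
        for (int b = 0; b < k; b++) {
            L -= 0.5 * eta[a] * s->oinv[a + k * b] * eta[b];
            fish[a + k * b] += s->oinv[a + k * b];
        }
    for (int a = 0; a < k; a++)
        for (int b = 0; b < k; b++)
            grad[a] -= s->oinv[a + k * b] * eta[b];
    L += s->prior_const;
    /* serum: additive error on A1/(v1*10) */
    double J[4];
    for (int o = 0; o < s->ns; o++) {
        const double *row = s->ymat + (size_t) s->serum_idx[o] * UA_NEQ;
        double f = row[0] / v1 / 10.0;
        double r = s->serum_y[o] - f;
        double s2 = s->a_serum * s->a_serum;
        L += -0.5 * log(2 * M_PI * s2) - r * r / (2 * s2);
        for (int j = 0; j < k; j++)
            J[j] = row[slot_s1[s->eta_slot[j]]] / v1 / 10.0;
        for (int j = 0; j < k; j++) {
            grad[j] += r * J[j] / s2;
            for (int m = 0; m <= j; m++)
                fish[j + k * m] += J[j] * J[m] / s2;
        }
    }
    /* urine: combined error on interval amount A2(end) - A2(start) */
    for (int o = 0; o < s->nu; o++) {
        const double *r1 = s->ymat + (size_t) s->uidx1[o] * UA_NEQ;
        const double *r0 = s->ymat + (size_t) s->uidx0[o] * UA_NEQ;
        double f = r1[1] - r0[1];
        double s2 = s->a_urine * s->a_urine +
                    s->b_urine * s->b_urine * f * f;
        double sd = sqrt(s2);
        double r = s->urine_y[o] - f;
        L += -0.5 * log(2 * M_PI * s2) - r * r / (2 * s2);
        double dsd_df = s->b_urine * s->b_urine * f / sd;
        for (int j = 0; j < k; j++)
            J[j] = r1[slot_s2[s->eta_slot[j]]] - r0[slot_s2[s->eta_slot[j]]];
        double gcoef = r / s2 + (r * r / (s2 * sd) - 1.0 / sd) * dsd_df;
        double w = 1.0 / s2 + 2.0 * dsd_df * dsd_df / s2;
        for (int j = 0; j < k; j++) {
            grad[j] += gcoef * J[j];
            for (int m = 0; m <= j; m++)
                fish[j + k * m] += w * J[j] * J[m];
        }
    }
    for (int j = 0; j < k; j++)
        for (int m = j + 1; m < k; m++)
            fish[j + k * m] = fish[m + k * j];
    *ll = L;
    return isfinite(L);
}

/* Cholesky of k x k SPD matrix (in place, lower). Returns 0 on success. */
static int chol_k(double *a, int k)
{
    for (int j = 0; j < k; j++) {
        double d = a[j + k * j];
        for (int m = 0; m < j; m++) d -= a[j + k * m] * a[j + k * m];
        if (d <= 0.0) return 1;
        d = sqrt(d);
        a[j + k * j] = d;
        for (int i = j + 1; i < k; i++) {
            double v = a[i + k * j];
            for (int m = 0; m < j; m++) v -= a[i + k * m] * a[j + k * m];
            a[i + k * j] = v / d;
        }
    }
    return 0;
}

static void chol_solve_k(const double *l, int k, const double *b, double *x)
{
    double z[4];
    for (int i = 0; i < k; i++) {
        double v = b[i];
        for (int m = 0; m < i; m++) v -= l[i + k * m] * z[m];
        z[i] = v / l[i + k * i];
    }
    for (int i = k - 1; i >= 0; i--) {
        double v = z[i];
        for (int m = i + 1; m < k; m++) v -= l[m + k * i] * x[m];
        x[i] = v / l[i + k * i];
    }
}

/* damped Newton ascent over eta within |eta| <= 5 */
static int ua_newton(ua_subj *s, double *eta, double *ll, double *grad,
                     double *fish, int maxit, double tol)
{
    double L;
    if (!ua_eval_joint(s, eta, &L, grad, fish)) return 0;
    int k = s->k;
    double lmat[16], step[4], eta_new[4], gnew[4], fnew[16], Lnew;
    for (int it = 0; it < maxit; it++) {
        memcpy(lmat, fish, (size_t) k * k * sizeof(double));
        if (chol_k(lmat, k) == 0) {
            chol_solve_k(lmat, k, grad, step);
        } else {
            double dmax = 0.0;
            for (int j = 0; j < k; j++)
                dmax = fmax(dmax, fabs(fish[j + k * j]));
            for (int j = 0; j < k; j++) step[j] = grad[j] / (dmax + 1.0);
        }
        double lam = 1.0;
        int improved = 0;
        for (int ls = 0; ls < 12; ls++) {
            for (int j = 0; j < k; j++) {
                eta_new[j] = eta[j] + lam * step[j];
                if (eta_new[j] > 5.0) eta_new[j] = 5.0;
                if (eta_new[j] < -5.0) eta_new[j] = -5.0;
            }
            if (ua_eval_joint(s, eta_new, &Lnew, gnew, fnew) &&
                Lnew >= L) { improved = 1; break; }
            lam *= 0.5;
        }
        if (!improved) break;
        double delta = Lnew - L;
        memcpy(eta, eta_new, (size_t) k * sizeof(double));
        memcpy(grad, gnew, (size_t) k * sizeof(double));
        memcpy(fish, fnew, (size_t) k * k * sizeof(double));
        L = Lnew;
        if (delta < tol * (fabs(L) + 1.0) || delta < 1e-10) break;
    }
    *ll = L;
    return 1;
}

/* .Call: Laplace marginal log-likelihood for one subject.
 * args: parms template, eta_slot (int k), times, serum_idx (0-based int),
 * serum_y, urine_idx0, urine_idx1, urine_y, sigma (a_serum, a_urine,
 * b_urine), oinv (k x k), prior_const, eta0, ctrl (rtol, atol, maxit, tol)
 * returns: c(lmarg, ok, eta_hat[k]) */
SEXP C_ua_marginal(SEXP s_tmpl, SEXP s_slot, SEXP s_times, SEXP s_sidx,
                   SEXP s_sy, SEXP s_u0, SEXP s_u1, SEXP s_uy,
                   SEXP s_sigma, SEXP s_oinv, SEXP s_pconst, SEXP s_eta0,
                   SEXP s_ctrl)
{
    ua_subj s;
    if (LENGTH(s_tmpl) != UA_NPARMS) error("bad template length");
    s.tmpl = REAL(s_tmpl);
    s.k = LENGTH(s_slot);
    if (s.k < 1 || s.k > 4) error("1..4 random effects supported");
    s.eta_slot = INTEGER(s_slot);
    s.times = REAL(s_times); s.nt = LENGTH(s_times);
    s.serum_idx = INTEGER(s_sidx); s.ns = LENGTH(s_sidx);
    s.serum_y = REAL(s_sy);
    s.uidx0 = INTEGER(s_u0); s.uidx1 = INTEGER(s_u1);
    s.nu = LENGTH(s_u0); s.urine_y = REAL(s_uy);
    s.a_serum = REAL(s_sigma)[0];
    s.a_urine = REAL(s_sigma)[1];
    s.b_urine = REAL(s_sigma)[2];
    s.oinv = REAL(s_oinv);
    s.prior_const = REAL(s_pconst)[0];
    double rtol = REAL(s_ctrl)[0], atol = REAL(s_ctrl)[1];
    int maxit = (int) REAL(s_ctrl)[2];
    double tol = REAL(s_ctrl)[3];
    s.rtol = rtol; s.atol = atol;
    s.ymat = (double *) R_alloc((size_t) s.nt * UA_NEQ, sizeof(double));
    s.pwork = (double *) R_alloc(UA_NPARMS, sizeof(double));

    /* kink times within the span */
    double *brk = (double *) R_alloc(4 * UA_MAXDOSE + 2, sizeof(double));
    int nbrk = 0;
    double t0 = s.times[0], t1 = s.times[s.nt - 1];
    nbrk = ua_kinks(s.tmpl + 9, t0, t1, brk, nbrk);
    nbrk = ua_kinks(s.tmpl + 9 + UA_BLOCKLEN, t0, t1, brk, nbrk);
    if (nbrk > 1) qsort(brk, nbrk, sizeof(double), cmp_dbl);
    s.brk = brk; s.nbrk = nbrk;

    int k = s.k;
    double eta[4] = {0, 0, 0, 0};
    for (int j = 0; j < k && j < LENGTH(s_eta0); j++) {
        eta[j] = REAL(s_eta0)[j];
        if (eta[j] > 4.9) eta[j] = 4.9;
        if (eta[j] < -4.9) eta[j] = -4.9;
    }
    double ll, grad[4], fish[16];
    int ok = ua_newton(&s, eta, &ll, grad, fish, maxit, tol);
    int warm = 0;
    for (int j = 0; j < k; j++) if (eta[j] != 0.0) warm = 1;
    if (warm || !ok) {
        /* check the prior mode; restart there if it does better */
        double ll0, g0[4], f0[16], eta0[4] = {0, 0, 0, 0};
        if (ua_eval_joint(&s, eta0, &ll0, g0, f0) && (!ok || ll0 > ll)) {
            int ok0 = ua_newton(&s, eta0, &ll0, g0, f0, maxit, tol);
            if (ok0 && (!ok || ll0 > ll)) {
                memcpy(eta, eta0, sizeof(eta));
                memcpy(grad, g0, sizeof(grad));
                memcpy(fish, f0, sizeof(fish));
                ll = ll0;
                ok = 1;
            }
        }
    }
    SEXP out = PROTECT(allocVector(REALSXP, 2 + k));
    double *po = REAL(out);
    if (!ok) {
        po[0] = -1e8; po[1] = 0;
        for (int j = 0; j < k; j++) po[2 + j] = 0.0;
        UNPROTECT(1);
        return out;
    }
    /* Laplace correction with the Fisher curvature at the mode */
    double lmat[16];
    memcpy(lmat, fish, (size_t) k * k * sizeof(double));
    double ldet = 0.0;
    if (chol_k(lmat, k) == 0) {
        for (int j = 0; j < k; j++) ldet += 2.0 * log(lmat[j + k * j]);
    } else {
        for (int j = 0; j < k; j++) fish[j + k * j] += 1e-6;
        memcpy(lmat, fish, (size_t) k * k * sizeof(double));
        if (chol_k(lmat, k) == 0)
            for (int j = 0; j < k; j++) ldet += 2.0 * log(lmat[j + k * j]);
    }
    po[0] = ll + 0.5 * k * log(2 * M_PI) - 0.5 * ldet;
    po[1] = 1;
    for (int j = 0; j < k; j++) po[2 + j] = eta[j];
    UNPROTECT(1);
    return out;
}
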