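/* Compiled simulation kernels: overdamped Langevin integration of the
 * tethered head under the three neck-linker force laws, coupled to the
 * five-state chemomechanical cycle.  The per-step laws mirror the plain-R
 * reference implementations in R/; the C path exists because production
 * ensembles take ~1e10 SDE steps.
 *
 * RNG: xoshiro256++ seeded by splitmix64, with a 128-layer ziggurat for
 * standard normals (Marsaglia & Tsang).  Self-contained so that runs are
 * reproducible from a single integer seed independently of R's RNG state.
 */

#include <R.h>
#include <Rinternals.h>
#include <math.h>
#include <stdint.h>
#include <stdlib.h>

#if defined(__GNUC__) && !defined(__clang__)
#pragma GCC optimize("O3", "unroll-loops")
#endif

/* ------------------------------------------------------------------ RNG */

typedef struct { uint64_t s[4]; } rng_t;

static inline uint64_t rotl64(const uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
}

static inline uint64_t rng_next(rng_t *r) {
    const uint64_t result = rotl64(r->s[0] + r->s[3], 23) + r->s[0];
    const uint64_t t = r->s[1] << 17;
    r->s[2] ^= r->s[0];
    r->s[3] ^= r->s[1];
    r->s[1] ^= r->s[2];
    r->s[0] ^= r->s[3];
    r->s[2] ^= t;
    r->s[3] = rotl64(r->s[3], 45);
    return result;
}

static void rng_seed(rng_t *r, uint64_t seed) {
    int i;
    for (i = 0; i < 4; i++) {            /* splitmix64 expansion */
        uint64_t z = (seed += 0x9E3779B97F4A7C15ULL);
        z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
        z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
        r->s[i] = z ^ (z >> 31);
    }
}

static inline double runif01(rng_t *r) {
    return (rng_next(r) >> 11) * 0x1.0p-53;   /* in (0,1), never exactly 0 */
}

/* 128-layer ziggurat for N(0,1) */
#define ZIG_R 3.442619855899
static uint32_t zig_kn[128];
static double zig_wn[128], zig_fn[128];
static int zig_ready = 0;

static void zig_setup(void) {
    const double m1 = 2147483648.0;     /* 2^31 */
    double dn = ZIG_R, tn = ZIG_R, vn = 9.91256303526217e-3, q;
    int i;
    q = vn / exp(-0.5 * dn * dn);
    zig_kn[0] = (uint32_t)((dn / q) * m1);
    zig_kn[1] = 0;
    zig_wn[0] = q / m1;
    zig_wn[127] = dn / m1;
    zig_fn[0] = 1.0;
    zig_fn[127] = exp(-0.5 * dn * dn);
    for (i = 126; i >= 1; i--) {
        dn = sqrt(-2.0 * log(vn / dn + exp(-0.5 * dn * dn)));
        zig_kn[i + 1] = (uint32_t)((dn / tn) * m1);
        tn = dn;
        zig_fn[i] = exp(-0.5 * dn * dn);
        zig_wn[i] = dn / m1;
    }
    zig_ready = 1;
}

static inline double rnorm_zig(rng_t *r) {
    for (;;) {
        uint32_t u32 = (uint32_t)(rng_next(r) >> 32);
        int32_t hz = (int32_t)u32;
        uint32_t iz = u32 & 127u;
        uint32_t az = (hz < 0) ? (uint32_t)(-(int64_t)hz) : (uint32_t)hz;
        if (az < zig_kn[iz])
            return hz * zig_wn[iz];
        if (iz == 0) {                   /* tail beyond ZIG_R */
            double x, y;
            do {
                x = -log(runif01(r)) / ZIG_R;
                y = -log(runif01(r));
            } while (y + y < x * x);
            return (hz > 0) ? ZIG_R + x : -(ZIG_R + x);
        } else {
            double x = hz * zig_wn[iz];
            if (zig_fn[iz] + runif01(r) * (zig_fn[iz - 1] - zig_fn[iz]) <
                exp(-0.5 * x * x))
                return x;
        }
    }
}

/* ------------------------------------------------- per-state dynamics */

#define KIND_WLC        0
#define KIND_HOOKEAN    1
#define KIND_REFLECTING 2

static inline double wlc_force_c(double ext, double Lp, double Lc, double kBT) {
    double s = ext / Lc, t = 1.0 - s;
    return (kBT / Lp) * (0.25 / (t * t) - 0.25 + s);
}

typedef struct {
    int kind;
    double center;
    double Lc, Lp;          /* WLC */
    double kappa;           /* Hookean / Reflecting spring */
    double lo, hi;          /* Reflecting barriers */
    /* integrator constants */
    double dt, dtoxi, sig;  /* sig = sqrt(2 D dt) */
    double cap;             /* extension cap fraction for WLC force eval */
    double emk, ousd;       /* exact OU: exp(-k dt/xi), stationary-corrected sd */
    double kBT;
    long cap_hits;
    /* WLC force lookup table on [0, cap*Lc] (engine hot path) */
    double *ftab;
    int ftab_n;
    double ftab_invh;
    /* equilibration clip: SDE blocks longer than eqK steps are truncated
     * to eqK steps.  eqK is ~100-200 relaxation times, so the endpoint of
     * the clipped block and of the full block are both stationary to
     * within exp(-100); no observable is sampled inside a block. */
    double eqK;
} dyn_t;

#define FTAB_N 4096

static void dyn_build_ftab(dyn_t *d) {
    int i;
    double hi = d->cap * d->Lc, h = hi / (FTAB_N - 1);
    d->ftab = (double *)R_alloc(FTAB_N, sizeof(double));
    d->ftab_n = FTAB_N;
    d->ftab_invh = 1.0 / h;
    for (i = 0; i < FTAB_N; i++)
        d->ftab[i] = wlc_force_c(i * h, d->Lp, d->Lc, d->kBT);
}

static void dyn_init(dyn_t *d, double kBT, double xi, double dt) {
    d->dt = dt;
    d->dtoxi = dt / xi;
    d->sig = sqrt(2.0 * (kBT / xi) * dt);
    d->kBT = kBT;
    d->cap_hits = 0;
    d->ftab = NULL;
    d->eqK = 1e18;                       /* no clip unless set below */
    if (d->kind == KIND_HOOKEAN) {
        d->emk = exp(-d->kappa * dt / xi);
        d->ousd = sqrt((kBT / d->kappa) * (1.0 - d->emk * d->emk));
    } else {
        d->emk = 0.0;
        d->ousd = 0.0;
        if (d->kind == KIND_WLC) {
            /* slowest mode: curvature at the centre, k0 = 1.5 kBT/(Lp Lc) */
            double k0 = 1.5 * kBT / (d->Lp * d->Lc);
            d->eqK = ceil(100.0 * (xi / k0) / dt);
        } else {
            /* reflected (near-)Brownian motion: spectral gap pi^2 D / L^2,
             * doubled for the weak spring perturbation */
            double L = d->hi - d->lo, D = kBT / xi;
            d->eqK = ceil(200.0 * (L * L / (9.8696 * D)) / dt);
        }
        if (d->eqK < 256) d->eqK = 256;
    }
}

/* One SDE step for the current chemical state's tether.  For the WLC the
 * force is evaluated with the extension capped at cap*Lc and the drift is
 * limited so it can never carry the head past the potential centre within
 * a single step; positions are kept strictly inside the contour-length
 * support.  For the Hookean spring the exact Gaussian (OU) transition is
 * drawn.  For the Reflecting model a Lepingle-type correction based on the
 * simulated extremum of the underlying Brownian path is applied at the
 * nearer barrier. */
static inline double sde_step(dyn_t *d, double x, rng_t *r) {
    if (d->kind == KIND_HOOKEAN) {
        return d->center + (x - d->center) * d->emk + d->ousd * rnorm_zig(r);
    }
    if (d->kind == KIND_WLC) {
        double dxc = x - d->center;
        double ad = fabs(dxc);
        double ext = ad, f, drift, xn, lim;
        if (ext > d->cap * d->Lc) {
            ext = d->cap * d->Lc;
            d->cap_hits++;
        }
        f = wlc_force_c(ext, d->Lp, d->Lc, d->kBT);
        drift = f * d->dtoxi;
        if (drift > ad) drift = ad;      /* restoring drift stops at centre */
        xn = x - (dxc > 0 ? drift : -drift) + d->sig * rnorm_zig(r);
        lim = 0.999 * d->Lc;
        if (xn > d->center + lim) { xn = d->center + lim; d->cap_hits++; }
        else if (xn < d->center - lim) { xn = d->center - lim; d->cap_hits++; }
        return xn;
    }
    /* reflecting */
    {
        double f, y, s2, u;
        if (x < d->lo) x = d->lo;        /* projection after a centre shift */
        if (x > d->hi) x = d->hi;
        f = -d->kappa * (x - d->center);
        y = x + f * d->dtoxi + d->sig * rnorm_zig(r);
        s2 = d->sig * d->sig;
        u = runif01(r);
        if (x - d->lo <= d->hi - x) {    /* lower barrier is nearer */
            double m = 0.5 * (x + y - sqrt((y - x) * (y - x) - 2.0 * s2 * log(u)));
            if (m < d->lo) y += d->lo - m;
            if (y > d->hi) y = 2.0 * d->hi - y;
            if (y < d->lo) y = d->lo;
        } else {
            double M = 0.5 * (x + y + sqrt((y - x) * (y - x) - 2.0 * s2 * log(u)));
            if (M > d->hi) y -= M - d->hi;
            if (y < d->lo) y = 2.0 * d->lo - y;
            if (y > d->hi) y = d->hi;
        }
        return y;
    }
}

/* Run ni WLC Euler steps using the force lookup table; identical law to
 * sde_step up to the (sub-fN) linear-interpolation error of the table.
 * Specialised block loop: struct fields hoisted to locals, branchless sign
 * handling on the (random-sign) restoring drift. */
static double wlc_run_block(dyn_t *d, double x, long ni, rng_t *r) {
    const double center = d->center, cap = d->cap * d->Lc;
    const double invh = d->ftab_invh, dtoxi = d->dtoxi, sig = d->sig;
    const double lim = 0.999 * d->Lc;
    const double *ftab = d->ftab;
    const int ntab = d->ftab_n;
    long hits = 0, k;
    for (k = 0; k < ni; k++) {
        double dxc = x - center, ad = fabs(dxc);
        double ext = ad, u, f, drift, fr;
        int i;
        if (ext > cap) { ext = cap; hits++; }
        u = ext * invh;
        i = (int)u;
        fr = u - i;
        if (i >= ntab - 1) { i = ntab - 2; fr = 1.0; }
        f = ftab[i] + fr * (ftab[i + 1] - ftab[i]);
        drift = f * dtoxi;
        if (drift > ad) drift = ad;
        x = x - copysign(drift, dxc) + sig * rnorm_zig(r);
        if (x > center + lim) { x = center + lim; hits++; }
        else if (x < center - lim) { x = center - lim; hits++; }
    }
    d->cap_hits += hits;
    return x;
}

/* exact OU transition over n consecutive steps (Hookean tether only):
 * the composition of n Gaussian transitions is itself Gaussian */
static inline double ou_jump(dyn_t *d, double x, double n, rng_t *r) {
    double e = exp(-d->kappa * d->dtoxi * n);
    double sd = sqrt((d->kBT / d->kappa) * (1.0 - e * e));
    return d->center + (x - d->center) * e + sd * rnorm_zig(r);
}

/* number of steps until the next candidate chemical event (>= 1), i.e. a
 * geometric draw at the state's majorant per-step probability.  Together
 * with thinning at the candidate (channel accepted with probability
 * actual/majorant) this reproduces the per-step Bernoulli law exactly
 * while freeing the SDE inner loop of chemistry. */
static inline double geom_steps(double log1mp, rng_t *r) {
    return 1.0 + floor(log(runif01(r)) / log1mp);
}

/* ------------------------------------------------------------ helpers */

static double get_el(SEXP v, int i) { return REAL(v)[i]; }

/* ------------------------------------------------- normal draws (test) */

SEXP C_znorm(SEXP s_n, SEXP s_seed) {
    R_xlen_t n = (R_xlen_t)asReal(s_n);
    rng_t rng;
    SEXP out;
    R_xlen_t i;
    if (!zig_ready) zig_setup();
    rng_seed(&rng, (uint64_t)asReal(s_seed));
    out = PROTECT(allocVector(REALSXP, n));
    for (i = 0; i < n; i++) REAL(out)[i] = rnorm_zig(&rng);
    UNPROTECT(1);
    return out;
}

/* ------------------------------------------- single-state stationary run
 *
 * par = c(kind, center, Lc, Lp, kappa, lo, hi, kBT, xi, dt, cap)
 * Returns histogram counts on a uniform grid, zone-occupancy counters,
 * completed-excursion recurrence statistics and moment accumulators.
 */
SEXP C_stationary(SEXP s_par, SEXP s_nsteps, SEXP s_burn, SEXP s_seed,
                  SEXP s_grid, SEXP s_zone) {
    dyn_t d;
    rng_t rng;
    double glo = get_el(s_grid, 0), ghi = get_el(s_grid, 1);
    int nbins = (int)get_el(s_grid, 2);
    double zlo = get_el(s_zone, 0), zhi = get_el(s_zone, 1);
    double binw, x;
    R_xlen_t nsteps = (R_xlen_t)asReal(s_nsteps);
    R_xlen_t burn = (R_xlen_t)asReal(s_burn);
    R_xlen_t i;
    double *counts;
    double n_in_zone = 0.0, sum_x = 0.0, sum_x2 = 0.0;
    double n_exc = 0.0, exc_steps = 0.0;
    long cur_out = -1;                   /* steps in the open excursion */
    int inz;
    SEXP s_counts, out, nms;

    if (!zig_ready) zig_setup();
    d.kind = (int)get_el(s_par, 0);
    d.center = get_el(s_par, 1);
    d.Lc = get_el(s_par, 2);
    d.Lp = get_el(s_par, 3);
    d.kappa = get_el(s_par, 4);
    d.lo = get_el(s_par, 5);
    d.hi = get_el(s_par, 6);
    d.cap = get_el(s_par, 10);
    dyn_init(&d, get_el(s_par, 7), get_el(s_par, 8), get_el(s_par, 9));
    rng_seed(&rng, (uint64_t)asReal(s_seed));

    binw = (ghi - glo) / nbins;
    s_counts = PROTECT(allocVector(REALSXP, nbins));
    counts = REAL(s_counts);
    for (i = 0; i < nbins; i++) counts[i] = 0.0;

    x = d.center;
    for (i = 0; i < burn; i++) x = sde_step(&d, x, &rng);

    inz = (x >= zlo && x <= zhi);
    for (i = 0; i < nsteps; i++) {
        int j, nowin;
        x = sde_step(&d, x, &rng);
        j = (int)((x - glo) / binw);
        if (j < 0) j = 0;
        if (j >= nbins) j = nbins - 1;
        counts[j] += 1.0;
        sum_x += x;
        sum_x2 += x * x;
        nowin = (x >= zlo && x <= zhi);
        if (inz && !nowin) {
            cur_out = 1;                 /* excursion starts: 1 step outside */
        } else if (!inz && !nowin && cur_out >= 0) {
            cur_out++;
        } else if (!inz && nowin && cur_out >= 0) {
            n_exc += 1.0;                /* completed excursion */
            exc_steps += (double)cur_out;
            cur_out = -1;
        }
        if (nowin) n_in_zone += 1.0;
        inz = nowin;
    }

    out = PROTECT(allocVector(VECSXP, 9));
    nms = PROTECT(allocVector(STRSXP, 9));
    SET_VECTOR_ELT(out, 0, s_counts);
    SET_STRING_ELT(nms, 0, mkChar("counts"));
    SET_VECTOR_ELT(out, 1, ScalarReal(n_in_zone));
    SET_STRING_ELT(nms, 1, mkChar("n_in_zone"));
    SET_VECTOR_ELT(out, 2, ScalarReal((double)nsteps));
    SET_STRING_ELT(nms, 2, mkChar("n_steps"));
    SET_VECTOR_ELT(out, 3, ScalarReal(n_exc));
    SET_STRING_ELT(nms, 3, mkChar("n_excursions"));
    SET_VECTOR_ELT(out, 4, ScalarReal(exc_steps));
    SET_STRING_ELT(nms, 4, mkChar("excursion_steps"));
    SET_VECTOR_ELT(out, 5, ScalarReal(sum_x));
    SET_STRING_ELT(nms, 5, mkChar("sum_x"));
    SET_VECTOR_ELT(out, 6, ScalarReal(sum_x2));
    SET_STRING_ELT(nms, 6, mkChar("sum_x2"));
    SET_VECTOR_ELT(out, 7, ScalarReal((double)d.cap_hits));
    SET_STRING_ELT(nms, 7, mkChar("cap_hits"));
    SET_VECTOR_ELT(out, 8, ScalarReal(x));
    SET_STRING_ELT(nms, 8, mkChar("final_x"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(3);
    return out;
}

/* --------------------------------------------------- full motor cycle
 *
 * par packing (see R/engine.R, pack_engine_par):
 *  0 kind | 1 dt | 2 xi | 3 kBT | 4 cap
 *  5 c2 | 6 c3 | 7 c4
 *  8 Lc1 | 9 Lc2 | 10 Lp
 * 11 kap1 | 12 kap2
 * 13 bhw1 | 14 bhw2   (reflecting barrier half-widths, one/two linkers)
 * 15 k_detach | 16 k_detach_rev | 17 k_atp_eff | 18 k_atp_off
 * 19 k_hyd | 20 k_hyd_rev | 21 k_attach | 22 k_unbind
 * 23 site | 24 zone_half | 25 allow_rear_s4 | 26 max_time | 27 record_events
 */

typedef struct {
    double *t, *x, *st, *step;
    R_xlen_t n, cap;
} elog_t;

static void elog_push(elog_t *e, double t, double st, double x, double step) {
    if (e->n == e->cap) {
        R_xlen_t nc = e->cap * 2;
        e->t = (double *)R_Realloc(e->t, nc, double);
        e->x = (double *)R_Realloc(e->x, nc, double);
        e->st = (double *)R_Realloc(e->st, nc, double);
        e->step = (double *)R_Realloc(e->step, nc, double);
        e->cap = nc;
    }
    e->t[e->n] = t;
    e->st[e->n] = st;
    e->x[e->n] = x;
    e->step[e->n] = step;
    e->n++;
}

SEXP C_run_motor(SEXP s_par, SEXP s_seed) {
    dyn_t d2, d3, d4;
    rng_t rng;
    double dt = get_el(s_par, 1), xi = get_el(s_par, 2), kBT = get_el(s_par, 3);
    double cap = get_el(s_par, 4);
    int kind = (int)get_el(s_par, 0);
    double kd = get_el(s_par, 15), kdr = get_el(s_par, 16);
    double katp = get_el(s_par, 17), katpoff = get_el(s_par, 18);
    double khyd = get_el(s_par, 19), khydr = get_el(s_par, 20);
    double katt = get_el(s_par, 21), kunb = get_el(s_par, 22);
    double site = get_el(s_par, 23), zone = get_el(s_par, 24);
    int allow_rear4 = (int)get_el(s_par, 25);
    double max_time = get_el(s_par, 26);
    int rec = (int)get_el(s_par, 27);
    double t = 0.0, x, pos = 0.0;
    int state = 2;
    double n_fwd = 0.0, n_back = 0.0, n_futile = 0.0, n_dt = 0.0;
    elog_t ev;
    SEXP out, nms, s_ev;

    if (!zig_ready) zig_setup();
    rng_seed(&rng, (uint64_t)asReal(s_seed));

    d2.kind = d3.kind = d4.kind = kind;
    d2.center = get_el(s_par, 5);
    d3.center = get_el(s_par, 6);
    d4.center = get_el(s_par, 7);
    d2.Lc = get_el(s_par, 9);            /* two linkers */
    d3.Lc = d4.Lc = get_el(s_par, 8);    /* one linker */
    d2.Lp = d3.Lp = d4.Lp = get_el(s_par, 10);
    d2.kappa = get_el(s_par, 12);
    d3.kappa = d4.kappa = get_el(s_par, 11);
    d2.lo = d2.center - get_el(s_par, 14);
    d2.hi = d2.center + get_el(s_par, 14);
    d3.lo = d3.center - get_el(s_par, 13);
    d3.hi = d3.center + get_el(s_par, 13);
    d4.lo = d4.center - get_el(s_par, 13);
    d4.hi = d4.center + get_el(s_par, 13);
    d2.cap = d3.cap = d4.cap = cap;
    dyn_init(&d2, kBT, xi, dt);
    dyn_init(&d3, kBT, xi, dt);
    dyn_init(&d4, kBT, xi, dt);

    ev.cap = 256;
    ev.n = 0;
    ev.t = (double *)R_Calloc(ev.cap, double);
    ev.x = (double *)R_Calloc(ev.cap, double);
    ev.st = (double *)R_Calloc(ev.cap, double);
    ev.step = (double *)R_Calloc(ev.cap, double);

    if (kind == KIND_WLC) {
        dyn_build_ftab(&d2);
        dyn_build_ftab(&d3);
        dyn_build_ftab(&d4);
    }

    x = -site;                           /* sketch: start in State 2 at the
                                          * rear binding site */
    if (rec) elog_push(&ev, 0.0, 2.0, x, 0.0);

    {
        /* majorant per-step candidate probabilities by state */
        double pmax2 = (katt + katp) * dt;
        double pmax3 = (katpoff + khyd) * dt;
        double pmax4 = (khydr + kunb + katt) * dt;
        double lg2 = log1p(-pmax2), lg3 = log1p(-pmax3), lg4 = log1p(-pmax4);

        while (t < max_time && state != 5) {
            dyn_t *dd;
            double pmax, lg, n, remain, u;
            int timeout = 0;

            if (state == 1) {
                double rate = kd + kdr;
                t += -log(runif01(&rng)) / rate;
                if (runif01(&rng) < kd / rate) {
                    state = 2;
                    x = -site;           /* rear head frees from its site */
                    if (rec) elog_push(&ev, t, 2.0, x, 0.0);
                } else {
                    state = 4;           /* front head releases (reverse) */
                    x = site;
                    pos -= site;
                    n_back += 1.0;
                    if (rec) elog_push(&ev, t, 4.0, x, -site);
                }
                continue;
            }

            dd = (state == 2) ? &d2 : (state == 3) ? &d3 : &d4;
            pmax = (state == 2) ? pmax2 : (state == 3) ? pmax3 : pmax4;
            lg = (state == 2) ? lg2 : (state == 3) ? lg3 : lg4;

            n = geom_steps(lg, &rng);
            remain = floor((max_time - t) / dt) + 1.0;
            if (n > remain) { n = remain; timeout = 1; }

            if (kind == KIND_HOOKEAN) {
                x = ou_jump(dd, x, n, &rng);
            } else if (kind == KIND_WLC) {
                x = wlc_run_block(dd, x, (long)fmin(n, dd->eqK), &rng);
            } else {
                long i, ni = (long)fmin(n, dd->eqK);
                for (i = 0; i < ni; i++) x = sde_step(dd, x, &rng);
            }
            t += n * dt;
            n_dt += n;
            if (timeout) break;

            /* thinned channel draw at the candidate step; thresholds are
             * the sketch's ordered per-dt Bernoulli probabilities */
            u = runif01(&rng) * pmax;
            if (state == 2) {
                double kx = (fabs(x - site) <= zone ||
                             fabs(x + site) <= zone) ? katt : 0.0;
                if (u <= kx * dt) {
                    int nn = (x > 0.0) ? 1 : -1;
                    if (rec) elog_push(&ev, t, 1.0, x, nn > 0 ? site : 0.0);
                    if (nn > 0) { pos += site; n_fwd += 1.0; }
                    else n_futile += 1.0; /* rebinds its previous site */
                    state = 1;
                    x = nn * site;
                } else if (u <= (kx + katp) * dt) {
                    state = 3;
                    if (rec) elog_push(&ev, t, 3.0, x, 0.0);
                }
            } else if (state == 3) {
                if (u <= katpoff * dt) {
                    state = 2;
                    if (rec) elog_push(&ev, t, 2.0, x, 0.0);
                } else if (u <= (katpoff + khyd) * dt) {
                    state = 4;
                    if (rec) elog_push(&ev, t, 4.0, x, 0.0);
                }
            } else {                     /* state 4 */
                double kx = (fabs(x - site) <= zone) ? katt : 0.0;
                if (allow_rear4 && fabs(x + site) <= zone) kx = katt;
                if (u <= khydr * dt) {
                    state = 3;
                    if (rec) elog_push(&ev, t, 3.0, x, 0.0);
                } else if (u <= (khydr + kunb) * dt) {
                    state = 5;
                    if (rec) elog_push(&ev, t, 5.0, x, 0.0);
                } else if (u <= (khydr + kunb + kx) * dt) {
                    int nn = (x > 0.0) ? 1 : -1;
                    if (rec) elog_push(&ev, t, 1.0, x, nn > 0 ? site : 0.0);
                    if (nn > 0) { pos += site; n_fwd += 1.0; }
                    else n_futile += 1.0;
                    state = 1;
                    x = nn * site;
                }
            }
        }
    }

    out = PROTECT(allocVector(VECSXP, 9));
    nms = PROTECT(allocVector(STRSXP, 9));
    SET_VECTOR_ELT(out, 0, ScalarReal(pos));
    SET_STRING_ELT(nms, 0, mkChar("run_length"));
    SET_VECTOR_ELT(out, 1, ScalarReal(t));
    SET_STRING_ELT(nms, 1, mkChar("total_time"));
    SET_VECTOR_ELT(out, 2, ScalarInteger(state == 5 ? 0 : 1));
    SET_STRING_ELT(nms, 2, mkChar("termination"));
    SET_VECTOR_ELT(out, 3, ScalarReal(n_fwd));
    SET_STRING_ELT(nms, 3, mkChar("n_steps_forward"));
    SET_VECTOR_ELT(out, 4, ScalarReal(n_back));
    SET_STRING_ELT(nms, 4, mkChar("n_steps_backward"));
    SET_VECTOR_ELT(out, 5, ScalarReal(n_futile));
    SET_STRING_ELT(nms, 5, mkChar("n_futile_rebinds"));
    SET_VECTOR_ELT(out, 6, ScalarReal((double)(d2.cap_hits + d3.cap_hits +
                                               d4.cap_hits)));
    SET_STRING_ELT(nms, 6, mkChar("cap_hits"));
    SET_VECTOR_ELT(out, 7, ScalarReal(n_dt));
    SET_STRING_ELT(nms, 7, mkChar("n_sde_steps"));
    {
        SEXP col, enms;
        s_ev = PROTECT(allocVector(VECSXP, 4));
        enms = PROTECT(allocVector(STRSXP, 4));
        col = PROTECT(allocVector(REALSXP, ev.n));
        memcpy(REAL(col), ev.t, ev.n * sizeof(double));
        SET_VECTOR_ELT(s_ev, 0, col);
        UNPROTECT(1);
        SET_STRING_ELT(enms, 0, mkChar("time"));
        col = PROTECT(allocVector(REALSXP, ev.n));
        memcpy(REAL(col), ev.st, ev.n * sizeof(double));
        SET_VECTOR_ELT(s_ev, 1, col);
        UNPROTECT(1);
        SET_STRING_ELT(enms, 1, mkChar("state"));
        col = PROTECT(allocVector(REALSXP, ev.n));
        memcpy(REAL(col), ev.x, ev.n * sizeof(double));
        SET_VECTOR_ELT(s_ev, 2, col);
        UNPROTECT(1);
        SET_STRING_ELT(enms, 2, mkChar("x"));
        col = PROTECT(allocVector(REALSXP, ev.n));
        memcpy(REAL(col), ev.step, ev.n * sizeof(double));
        SET_VECTOR_ELT(s_ev, 3, col);
        UNPROTECT(1);
        SET_STRING_ELT(enms, 3, mkChar("step"));
        setAttrib(s_ev, R_NamesSymbol, enms);
        SET_VECTOR_ELT(out, 8, s_ev);
        SET_STRING_ELT(nms, 8, mkChar("events"));
        UNPROTECT(2);
    }
    setAttrib(out, R_NamesSymbol, nms);
    R_Free(ev.t);
    R_Free(ev.x);
    R_Free(ev.st);
    R_Free(ev.step);
    UNPROTECT(2);
    return out;
}
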