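/* Coupled neuromechanical RHS for deSolve's compiled-code interface.
 *
 * State vector y (length 5N): [alpha | U | E | I | theta], one block per
 * field, co-located on a uniform grid chi_i = i/(N-1), i = 0..N-1.
 *
 * The parameter vector is packed by pack_parms() on the R side and padded
 * with zeros to ESO_MAXPAR; the header layout below must stay in sync with
 * R/simulate.R.
 */

#include <R.h>
#include <math.h>

#define ESO_MAXPAR 6000
#define ESO_NHEAD  24

static double parms[ESO_MAXPAR];

#define N_      ((int) parms[0])
#define MODE_   ((int) parms[1])   /* 0 = coupled, 1 = prescribed distension */
#define PSI_    parms[2]
#define BETA_   parms[3]
#define TAUTH_  parms[4]
#define TAUI_   parms[5]
#define THO_    parms[6]
#define GS_     parms[7]
#define GE_     parms[8]
#define GTH_    parms[9]
#define XS_     parms[10]
#define LAME_   parms[11]
#define LAMI_   parms[12]
#define EHAT_   parms[13]
#define DCHI_   parms[14]
#define BIWIN_  ((int) parms[15])  /* 1 = windowed (local) inhibitory kernel */
#define STAMP_  parms[16]          /* rostral stimulus amplitude (0 = off)   */
#define STXE_   parms[17]          /* stimulus applied for chi <= STXE_      */
#define STT0_   parms[18]
#define STT1_   parms[19]
#define BAGH_   parms[20]          /* prescribed strain-excess level         */
#define BAGX1_  parms[21]
#define BAGX2_  parms[22]
#define BAGTOFF_ parms[23]         /* deflation time (1e30 = never)          */

/* per-node arrays, each of length N, in this order */
#define AHAT_(i) parms[ESO_NHEAD + 0 * N_ + (i)]
#define A_(i)    parms[ESO_NHEAD + 1 * N_ + (i)]
#define B_(i)    parms[ESO_NHEAD + 2 * N_ + (i)]
#define C_(i)    parms[ESO_NHEAD + 3 * N_ + (i)]
#define D_(i)    parms[ESO_NHEAD + 4 * N_ + (i)]
#define E_W(i)   parms[ESO_NHEAD + 5 * N_ + (i)]
#define F_(i)    parms[ESO_NHEAD + 6 * N_ + (i)]
#define WE_(i)   parms[ESO_NHEAD + 7 * N_ + (i)]
#define WI_(i)   parms[ESO_NHEAD + 8 * N_ + (i)]
#define PHIE_(i) parms[ESO_NHEAD + 9 * N_ + (i)]
#define PHII_(i) parms[ESO_NHEAD + 10 * N_ + (i)]

/* sensory kernel 0.5*(1 + tanh(g_E*(x_s - j*dchi))), precomputed at init;
 * kern_len is the first index where it is numerically negligible */
static double kern[1024];
static int kern_len;

static double sat_tanh(double x)
{
    if (x > 20.0) return 1.0;
    if (x < -20.0) return -1.0;
    return tanh(x);
}

void eso_init(void (*odeparms)(int *, double *))
{
    int n = ESO_MAXPAR, j;
    odeparms(&n, parms);
    kern_len = N_;
    for (j = 0; j < N_; j++) {
        kern[j] = 0.5 * (1.0 + sat_tanh(GE_ * (XS_ - j * DCHI_)));
        if (kern[j] < 1e-14) { kern_len = j; break; }
    }
}

/* logistic difference sigmoid, zero at x = 0; overflow-safe */
static double sig_ei(double x, double lam, double phi)
{
    double a = -lam * (x - phi), b = lam * phi;
    if (a > 700.0) a = 700.0;
    if (b > 700.0) b = 700.0;
    return 1.0 / (1.0 + exp(a)) - 1.0 / (1.0 + exp(b));
}

void eso_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip)
{
    const int N = N_;
    const double dchi = DCHI_;
    const double tau = *t;
    const double *alpha = y, *U = y + N, *E = y + 2 * N, *I = y + 3 * N,
                 *theta = y + 4 * N;
    double *dalpha = ydot, *dU = ydot + N, *dE = ydot + 2 * N,
           *dI = ydot + 3 * N, *dtheta = ydot + 4 * N;
    double h[1024], SE[1024], SI[1024];
    int i, k;

    /* strain excess h_k at every node */
    for (k = 0; k < N; k++) {
        if (MODE_ == 0) {
            double s = alpha[k] / theta[k] - AHAT_(k);
            h[k] = s > 0.0 ? s : 0.0;
        } else {
            double chik = k * dchi;
            h[k] = (chik > BAGX1_ && chik < BAGX2_ && tau < BAGTOFF_)
                       ? BAGH_ : 0.0;
        }
    }

    /* mechanosensory source terms: S_E windows receptors at/caudal to i
     * through the precomputed kernel; S_I is a running (prefix) sum over
     * receptors at/rostral to i, windowed only in the BIWIN_ variant. */
    {
        double prefix = 0.0;
        for (i = 0; i < N; i++) {
            double chii = i * dchi, sE = 0.0, sI;
            int kmax = i + kern_len;
            if (kmax > N) kmax = N;
            for (k = i; k < kmax; k++)
                sE += h[k] * kern[k - i] * dchi;
            if (BIWIN_) { /* local (windowed) descending inhibition */
                int kmin = i - kern_len + 1;
                if (kmin < 0) kmin = 0;
                sI = 0.0;
                for (k = kmin; k <= i; k++)
                    sI += h[k] * kern[i - k] * dchi;
            } else {
                prefix += h[i] * dchi;
                sI = prefix;
            }
            SE[i] = WE_(i) * sat_tanh(GS_ * sE);
            SI[i] = WI_(i) * sat_tanh(GS_ * sI);
            if (STAMP_ > 0.0 && tau >= STT0_ && tau < STT1_ && chii <= STXE_)
                SE[i] = STAMP_; /* transient rostral stimulus override */
        }
    }

    /* oscillator chain; node 0 (rostral end) has no upstream neighbour */
    for (i = 0; i < N; i++) {
        double up = (i == 0) ? 0.0 : B_(i) * E[i - 1] - D_(i) * I[i - 1];
        double argE = A_(i) * E[i] + up - E_W(i) * I[i] + SE[i];
        double argI = C_(i) * E[i] - F_(i) * I[i] + SI[i];
        dE[i] = -E[i] + (1.0 - E[i]) * sig_ei(argE, LAME_, PHIE_(i));
        dI[i] = (-I[i] + (1.0 - I[i]) * sig_ei(argI, LAMI_, PHII_(i))) / TAUI_;
        dtheta[i] = (1.0 - theta[i]
                     - 0.5 * (1.0 - THO_)
                           * (1.0 + sat_tanh(GTH_ * (E[i] - EHAT_)))) / TAUTH_;
    }

    if (MODE_ != 0) { /* prescribed distension: fluid frozen */
        for (i = 0; i < N; i++) { dalpha[i] = 0.0; dU[i] = 0.0; }
        return;
    }

    /* 1D tube: mass + momentum, central differences, co-located grid */
    for (i = 1; i < N - 1; i++) {
        double Fp = alpha[i + 1] * U[i + 1], Fm = alpha[i - 1] * U[i - 1];
        double pp = alpha[i + 1] / theta[i + 1] - 1.0;
        double pm = alpha[i - 1] / theta[i - 1] - 1.0;
        dalpha[i] = -(Fp - Fm) / (2.0 * dchi);
        dU[i] = -U[i] * (U[i + 1] - U[i - 1]) / (2.0 * dchi)
                - PSI_ * (pp - pm) / (2.0 * dchi)
                - BETA_ * U[i] / alpha[i];
    }
    /* closed ends: U pinned at 0; continuity closed with mirror ghosts
       consistent with d(alpha/theta)/dchi = 0 at the walls */
    dU[0] = 0.0;
    dU[N - 1] = 0.0;
    dalpha[0] = -(alpha[1] * U[1]) / dchi;
    dalpha[N - 1] = (alpha[N - 2] * U[N - 2]) / dchi;
}
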