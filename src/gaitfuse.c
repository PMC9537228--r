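/* Compiled kernels for the two-stream network.
 *
 * Batch tensors are (T, J, B, C) column-major double arrays.  A
 * temporal kernel-3 convolution is computed as one im2col pack into an
 * N x 3*Cin matrix (N = T2*J*B, K-columns ordered tap-fastest so the
 * (3, Cin, Cout) weight array is already the packed K x Cout matrix)
 * followed by a single dgemm.  The backward pass repacks and runs two
 * dgemms (dW, dX) plus a col2im scatter-add.
 */

#define USE_FC_LEN_T
#include <R.h>
#include <Rinternals.h>
#include <R_ext/BLAS.h>
#include <string.h>
#ifndef FCONE
# define FCONE
#endif

static const double ONE = 1.0, ZERO = 0.0;

/* pack X (T,J,B,Cin) into A (N x 3Cin); pad = 0 (valid) or 1 (same) */
static void im2col3(const double *x, int T, int J, int B, int Cin,
                    int pad, double *a)
{
    const int T2 = pad ? T : T - 2;
    const R_xlen_t N = (R_xlen_t) T2 * J * B;
    for (int c = 0; c < Cin; c++) {
        for (int k = 0; k < 3; k++) {
            double *col = a + (R_xlen_t)(k + 3 * c) * N;
            for (int b = 0; b < B; b++) {
                for (int j = 0; j < J; j++) {
                    const double *src = x +
                        (R_xlen_t) T * (j + (R_xlen_t) J * (b + (R_xlen_t) B * c));
                    double *dst = col + (R_xlen_t) T2 * (j + (R_xlen_t) J * b);
                    int lo = k - pad;           /* input time of t2 = 0 */
                    if (!pad) {
                        memcpy(dst, src + lo, T2 * sizeof(double));
                    } else {
                        int t0 = lo < 0 ? -lo : 0;           /* leading zeros */
                        int t1 = lo + T2 > T ? T - lo : T2;  /* first invalid t2 */
                        for (int t = 0; t < t0; t++) dst[t] = 0.0;
                        memcpy(dst + t0, src + lo + t0,
                               (t1 - t0) * sizeof(double));
                        for (int t = t1; t < T2; t++) dst[t] = 0.0;
                    }
                }
            }
        }
    }
}

/* scatter-add A-shaped gradient back onto dX (zero-initialised) */
static void col2im3(const double *a, int T, int J, int B, int Cin,
                    int pad, double *dx)
{
    const int T2 = pad ? T : T - 2;
    const R_xlen_t N = (R_xlen_t) T2 * J * B;
    for (int c = 0; c < Cin; c++) {
        for (int k = 0; k < 3; k++) {
            const double *col = a + (R_xlen_t)(k + 3 * c) * N;
            for (int b = 0; b < B; b++) {
                for (int j = 0; j < J; j++) {
                    double *dst = dx +
                        (R_xlen_t) T * (j + (R_xlen_t) J * (b + (R_xlen_t) B * c));
                    const double *src = col + (R_xlen_t) T2 * (j + (R_xlen_t) J * b);
                    int lo = k - pad;
                    int t0 = lo < 0 ? -lo : 0;
                    int t1 = lo + T2 > T ? T - lo : T2;
                    for (int t = t0; t < t1; t++) dst[lo + t] += src[t];
                }
            }
        }
    }
}

static void get_dims4(SEXP x, int *d)
{
    SEXP dim = getAttrib(x, R_DimSymbol);
    if (length(dim) != 4) error("expected a 4-d array");
    for (int i = 0; i < 4; i++) d[i] = INTEGER(dim)[i];
}

SEXP C_conv3_fwd(SEXP xs, SEXP ws, SEXP bs, SEXP pads)
{
    int d[4];
    get_dims4(xs, d);
    const int T = d[0], J = d[1], B = d[2], Cin = d[3];
    const int pad = asInteger(pads);
    SEXP wdim = getAttrib(ws, R_DimSymbol);
    if (length(wdim) != 3 || INTEGER(wdim)[0] != 3 ||
        INTEGER(wdim)[1] != Cin)
        error("weight array must be 3 x %d x Cout", Cin);
    const int Cout = INTEGER(wdim)[2];
    const int T2 = pad ? T : T - 2;
    if (T2 < 1) error("temporal extent %d too small for a kernel of 3", T);
    const int K = 3 * Cin;
    const int N = T2 * J * B;

    double *a = (double *) R_alloc((size_t) N * K, sizeof(double));
    im2col3(REAL(xs), T, J, B, Cin, pad, a);

    SEXP ys = PROTECT(allocVector(REALSXP, (R_xlen_t) N * Cout));
    F77_CALL(dgemm)("N", "N", &N, &Cout, &K, &ONE, a, &N, REAL(ws), &K,
                    &ZERO, REAL(ys), &N FCONE FCONE);
    const double *bias = REAL(bs);
    double *y = REAL(ys);
    for (int c = 0; c < Cout; c++) {
        double bc = bias[c];
        double *yc = y + (R_xlen_t) N * c;
        for (int i = 0; i < N; i++) yc[i] += bc;
    }
    SEXP ydim = PROTECT(allocVector(INTSXP, 4));
    INTEGER(ydim)[0] = T2; INTEGER(ydim)[1] = J;
    INTEGER(ydim)[2] = B;  INTEGER(ydim)[3] = Cout;
    setAttrib(ys, R_DimSymbol, ydim);
    UNPROTECT(2);
    return ys;
}

SEXP C_conv3_bwd(SEXP xs, SEXP ws, SEXP dys, SEXP pads, SEXP needdxs)
{
    int d[4];
    get_dims4(xs, d);
    const int T = d[0], J = d[1], B = d[2], Cin = d[3];
    const int pad = asInteger(pads);
    const int need_dx = asInteger(needdxs);
    SEXP wdim = getAttrib(ws, R_DimSymbol);
    const int Cout = INTEGER(wdim)[2];
    const int T2 = pad ? T : T - 2;
    const int K = 3 * Cin;
    const int N = T2 * J * B;

    double *a = (double *) R_alloc((size_t) N * K, sizeof(double));
    im2col3(REAL(xs), T, J, B, Cin, pad, a);

    SEXP dws = PROTECT(allocVector(REALSXP, (R_xlen_t) K * Cout));
    F77_CALL(dgemm)("T", "N", &K, &Cout, &N, &ONE, a, &N, REAL(dys), &N,
                    &ZERO, REAL(dws), &K FCONE FCONE);
    SEXP wddim = PROTECT(allocVector(INTSXP, 3));
    INTEGER(wddim)[0] = 3; INTEGER(wddim)[1] = Cin; INTEGER(wddim)[2] = Cout;
    setAttrib(dws, R_DimSymbol, wddim);

    SEXP dbs = PROTECT(allocVector(REALSXP, Cout));
    const double *dy = REAL(dys);
    for (int c = 0; c < Cout; c++) {
        double s = 0.0;
        const double *col = dy + (R_xlen_t) N * c;
        for (int i = 0; i < N; i++) s += col[i];
        REAL(dbs)[c] = s;
    }

    SEXP dxs = R_NilValue;
    int nprot = 3;
    if (need_dx) {
        double *da = (double *) R_alloc((size_t) N * K, sizeof(double));
        F77_CALL(dgemm)("N", "T", &N, &K, &Cout, &ONE, REAL(dys), &N,
                        REAL(ws), &K, &ZERO, da, &N FCONE FCONE);
        dxs = PROTECT(allocVector(REALSXP, (R_xlen_t) T * J * B * Cin));
        memset(REAL(dxs), 0, sizeof(double) * (size_t) T * J * B * Cin);
        col2im3(da, T, J, B, Cin, pad, REAL(dxs));
        SEXP xdim = PROTECT(allocVector(INTSXP, 4));
        INTEGER(xdim)[0] = T; INTEGER(xdim)[1] = J;
        INTEGER(xdim)[2] = B; INTEGER(xdim)[3] = Cin;
        setAttrib(dxs, R_DimSymbol, xdim);
        nprot += 2;
    }

    SEXP out = PROTECT(allocVector(VECSXP, 3));
    SET_VECTOR_ELT(out, 0, dws);
    SET_VECTOR_ELT(out, 1, dbs);
    SET_VECTOR_ELT(out, 2, dxs);
    SEXP nms = PROTECT(allocVector(STRSXP, 3));
    SET_STRING_ELT(nms, 0, mkChar("dW"));
    SET_STRING_ELT(nms, 1, mkChar("db"));
    SET_STRING_ELT(nms, 2, mkChar("dX"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(nprot + 2);
    return out;
}

SEXP C_relu_fwd(SEXP xs)
{
    R_xlen_t n = xlength(xs);
    SEXP ys = PROTECT(allocVector(REALSXP, n));
    const double *x = REAL(xs);
    double *y = REAL(ys);
    for (R_xlen_t i = 0; i < n; i++) y[i] = x[i] > 0 ? x[i] : 0.0;
    setAttrib(ys, R_DimSymbol, getAttrib(xs, R_DimSymbol));
    UNPROTECT(1);
    return ys;
}

SEXP C_relu_bwd(SEXP xs, SEXP dys)
{
    R_xlen_t n = xlength(xs);
    if (xlength(dys) != n) error("relu gradient shape mismatch");
    SEXP ds = PROTECT(allocVector(REALSXP, n));
    const double *x = REAL(xs), *dy = REAL(dys);
    double *dx = REAL(ds);
    for (R_xlen_t i = 0; i < n; i++) dx[i] = x[i] > 0 ? dy[i] : 0.0;
    setAttrib(ds, R_DimSymbol, getAttrib(xs, R_DimSymbol));
    UNPROTECT(1);
    return ds;
}

/* global max (and argmax) over the leading T2*J spatial block per
 * (b, c) column; X is (T2, J, B, C). */
SEXP C_pool_max_fwd(SEXP xs)
{
    int d[4];
    get_dims4(xs, d);
    const R_xlen_t S = (R_xlen_t) d[0] * d[1];
    const int M = d[2] * d[3];
    SEXP ps = PROTECT(allocVector(REALSXP, M));
    SEXP is = PROTECT(allocVector(INTSXP, M));
    const double *x = REAL(xs);
    for (int m = 0; m < M; m++) {
        const double *col = x + S * m;
        double best = col[0];
        R_xlen_t bi = 0;
        for (R_xlen_t i = 1; i < S; i++)
            if (col[i] > best) { best = col[i]; bi = i; }
        REAL(ps)[m] = best;
        INTEGER(is)[m] = (int)(bi + 1);  /* 1-based within the column */
    }
    SEXP pdim = PROTECT(allocVector(INTSXP, 2));
    INTEGER(pdim)[0] = d[2]; INTEGER(pdim)[1] = d[3];
    setAttrib(ps, R_DimSymbol, pdim);
    SEXP out = PROTECT(allocVector(VECSXP, 2));
    SET_VECTOR_ELT(out, 0, ps);
    SET_VECTOR_ELT(out, 1, is);
    SEXP nms = PROTECT(allocVector(STRSXP, 2));
    SET_STRING_ELT(nms, 0, mkChar("P"));
    SET_STRING_ELT(nms, 1, mkChar("idx"));
    setAttrib(out, R_NamesSymbol, nms);
    UNPROTECT(5);
    return out;
}

SEXP C_pool_max_bwd(SEXP dps, SEXP idxs, SEXP dims)
{
    const int *d = INTEGER(dims);
    const R_xlen_t S = (R_xlen_t) d[0] * d[1];
    const int M = d[2] * d[3];
    SEXP dxs = PROTECT(allocVector(REALSXP, S * M));
    memset(REAL(dxs), 0, sizeof(double) * (size_t)(S * M));
    const double *dp = REAL(dps);
    const int *idx = INTEGER(idxs);
    for (int m = 0; m < M; m++)
        REAL(dxs)[S * m + (idx[m] - 1)] = dp[m];
    SEXP xdim = PROTECT(allocVector(INTSXP, 4));
    for (int i = 0; i < 4; i++) INTEGER(xdim)[i] = d[i];
    setAttrib(dxs, R_DimSymbol, xdim);
    UNPROTECT(2);
    return dxs;
}

/* gather samples `take` (1-based) from (T, J, Ball, C) into
 * (T, J, length(take), C) */
SEXP C_gather_batch(SEXP xs, SEXP takes)
{
    int d[4];
    get_dims4(xs, d);
    const int T = d[0], J = d[1], Ball = d[2], C = d[3];
    const int B = length(takes);
    const int *take = INTEGER(takes);
    const R_xlen_t blk = (R_xlen_t) T * J;
    SEXP ys = PROTECT(allocVector(REALSXP, blk * B * C));
    const double *x = REAL(xs);
    double *y = REAL(ys);
    for (int c = 0; c < C; c++)
        for (int b = 0; b < B; b++)
            memcpy(y + blk * (b + (R_xlen_t) B * c),
                   x + blk * ((take[b] - 1) + (R_xlen_t) Ball * c),
                   blk * sizeof(double));
    SEXP ydim = PROTECT(allocVector(INTSXP, 4));
    INTEGER(ydim)[0] = T; INTEGER(ydim)[1] = J;
    INTEGER(ydim)[2] = B; INTEGER(ydim)[3] = C;
    setAttrib(ys, R_DimSymbol, ydim);
    UNPROTECT(2);
    return ys;
}

static const R_CallMethodDef CallEntries[] = {
    {"C_conv3_fwd",    (DL_FUNC) &C_conv3_fwd,    4},
    {"C_conv3_bwd",    (DL_FUNC) &C_conv3_bwd,    5},
    {"C_relu_fwd",     (DL_FUNC) &C_relu_fwd,     1},
    {"C_relu_bwd",     (DL_FUNC) &C_relu_bwd,     2},
    {"C_pool_max_fwd", (DL_FUNC) &C_pool_max_fwd, 1},
    {"C_pool_max_bwd", (DL_FUNC) &C_pool_max_bwd, 3},
    {"C_gather_batch", (DL_FUNC) &C_gather_batch, 2},
    {NULL, NULL, 0}
};

void R_init_gaitfuse(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    R_forceSymbols(dll, TRUE);
}
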