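#include <Rcpp.h>
using namespace Rcpp;

// Selected inverse of a sparse symmetric positive definite matrix from its
// simplicial Cholesky factor (Takahashi equations).
//
// Input is the lower-triangular factor L of P C P' = L L' in compressed
// column form (slots p, i, x of a dtCMatrix, with the diagonal stored as the
// first entry of each column).  The routine returns values of Z = (P C P')^-1
// at every position in the pattern of L; by the elimination-tree closure
// property this pattern contains the pattern of P C P', so every entry of
// C^-1 at a structural nonzero of C is recovered.
//
// Internally the factor is rescaled to the unit-lower LDL' form
// (d_j = L_jj^2, l_ij = L_ij / L_jj) and the recurrences
//   Z_jj = 1/d_j - sum_{k>j} l_kj Z_kj
//   Z_ij = -sum_{k>j} l_kj Z_ki          (i > j)
// are evaluated column by column from the last column to the first.

// binary search for row 'r' among rows[lo..hi) (sorted ascending)
static inline int find_row(const int *rows, int lo, int hi, int r) {
    while (lo < hi) {
        int mid = (lo + hi) / 2;
        if (rows[mid] < r) lo = mid + 1; else hi = mid;
    }
    return lo;
}

// [[Rcpp::export(name = ".takahashi_inverse")]]
NumericVector takahashi_inverse(IntegerVector Lp, IntegerVector Li,
                                NumericVector Lx, int n) {
    const int *p = INTEGER(Lp);
    const int *ri = INTEGER(Li);
    const double *lx = REAL(Lx);
    int nnz = Lx.size();

    // unit-lower values and column d
    std::vector<double> lu(nnz);
    std::vector<double> d(n);
    int maxcol = 0;
    for (int j = 0; j < n; ++j) {
        double ljj = lx[p[j]];            // diagonal first in each column
        d[j] = ljj * ljj;
        lu[p[j]] = 1.0;
        for (int q = p[j] + 1; q < p[j + 1]; ++q) lu[q] = lx[q] / ljj;
        int cl = p[j + 1] - p[j];
        if (cl > maxcol) maxcol = cl;
    }

    NumericVector Zx(nnz);
    double *zx = REAL(Zx);

    // dense workspace for the submatrix Z[S_j, S_j] of one column's pattern
    std::vector<double> zsub((size_t)maxcol * maxcol, 0.0);
    std::vector<double> zcol(maxcol);

    for (int j = n - 1; j >= 0; --j) {
        int lo = p[j], hi = p[j + 1];
        int m1 = hi - lo - 1;             // off-diagonal count
        if (m1 > 0) {
            const int *S = ri + lo + 1;   // ascending rows > j
            // gather Z[S, S]: column c = S[t2] holds rows >= c; every pair
            // (S[t1], c), t1 >= t2, is in its pattern (elimination-tree
            // closure), so a two-pointer sweep finds them all
            for (int t2 = 0; t2 < m1; ++t2) {
                int c = S[t2];
                int b = p[c], bend = p[c + 1];
                for (int t1 = t2; t1 < m1; ++t1) {
                    int want = S[t1];
                    while (b < bend && ri[b] < want) ++b;
                    double z = (b < bend && ri[b] == want) ? zx[b] : 0.0;
                    zsub[(size_t)t1 * m1 + t2] = z;
                    zsub[(size_t)t2 * m1 + t1] = z;
                }
            }
            // column update: Z[S, j] = -Z[S, S] * l,  l = lu over S
            const double *l = lu.data() + lo + 1;
            for (int t1 = 0; t1 < m1; ++t1) {
                double s = 0.0;
                const double *row = zsub.data() + (size_t)t1 * m1;
                for (int t2 = 0; t2 < m1; ++t2) s += l[t2] * row[t2];
                zcol[t1] = -s;
            }
            for (int t1 = 0; t1 < m1; ++t1) zx[lo + 1 + t1] = zcol[t1];
            double s = 0.0;
            for (int t1 = 0; t1 < m1; ++t1) s += l[t1] * zcol[t1];
            zx[lo] = 1.0 / d[j] - s;
        } else {
            zx[lo] = 1.0 / d[j];
        }
    }
    return Zx;
}

// Per-record quadratic forms h_j = x_j' Z x_j, where the x_j are the rows of
// the model matrix W supplied in transposed compressed form (Wt = t(W), so
// each column of Wt is one record's coefficient clique) and Z is a sparse
// symmetric matrix in general storage.  Every clique pair is a structural
// nonzero of W'W and hence of Z's pattern.
// [[Rcpp::export(name = ".row_quadform")]]
NumericVector row_quadform(IntegerVector Wp, IntegerVector Wi, NumericVector Wx,
                           IntegerVector Zp, IntegerVector Zi, NumericVector Zx) {
    const int *wp = INTEGER(Wp);
    const int *wi = INTEGER(Wi);
    const double *wx = REAL(Wx);
    const int *zp = INTEGER(Zp);
    const int *zi = INTEGER(Zi);
    const double *zxv = REAL(Zx);
    int n = Wp.size() - 1;
    NumericVector out(n);
    for (int j = 0; j < n; ++j) {
        double acc = 0.0;
        for (int t1 = wp[j]; t1 < wp[j + 1]; ++t1) {
            int r1 = wi[t1];
            int lo = zp[r1], hi = zp[r1 + 1];
            for (int t2 = wp[j]; t2 < wp[j + 1]; ++t2) {
                int r2 = wi[t2];
                int pos = find_row(zi, lo, hi, r2);
                if (pos < hi && zi[pos] == r2)
                    acc += wx[t1] * wx[t2] * zxv[pos];
            }
        }
        out[j] = acc;
    }
    return out;
}

// Sum of A_ij * Z[gi + (i-1)*r + a, gj + (j-1)*r + b] over the nonzeros (i,j)
// of a sparse symmetric matrix A (full storage, compressed columns), where Z
// is a sparse symmetric matrix stored as a general dgCMatrix.  Used for the
// trace terms sum_ij Ainv_ij * Cinv-block_ij in the REML gradient; gi is the
// 0-based offset of the random-effect block, r the block size, (a,b) the
// within-block coefficient pair (0-based).
// [[Rcpp::export(name = ".block_trace_sum")]]
double block_trace_sum(IntegerVector Ap, IntegerVector Ai, NumericVector Ax,
                       IntegerVector Zp, IntegerVector Zi, NumericVector Zx,
                       int g0, int r, int a, int b) {
    const int *ap = INTEGER(Ap);
    const int *ai = INTEGER(Ai);
    const double *ax = REAL(Ax);
    const int *zp = INTEGER(Zp);
    const int *zi = INTEGER(Zi);
    const double *zxv = REAL(Zx);
    int q = Ap.size() - 1;
    double acc = 0.0;
    for (int j = 0; j < q; ++j) {
        int zcol = g0 + j * r + b;
        int lo = zp[zcol], hi = zp[zcol + 1];
        for (int t = ap[j]; t < ap[j + 1]; ++t) {
            int i = ai[t];
            int zrow = g0 + i * r + a;
            int pos = find_row(zi, lo, hi, zrow);
            if (pos < hi && zi[pos] == zrow) acc += ax[t] * zxv[pos];
        }
    }
    return acc;
}
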