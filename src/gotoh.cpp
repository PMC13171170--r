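#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Three-state affine-gap global alignment (Gotoh) over a precomputed
// column-score matrix S (nrow = |a|, ncol = |b|). Terminal gaps are
// penalized (true Needleman-Wunsch semantics).
//
// Gap cost convention: a gap of length L costs
//   first + (L-1) * gep
// where first = gop under the default convention (open + (L-1)*ext) and
// first = gop + gep under the alternative (open + L*ext).
//
// Tie-break order everywhere: diagonal (M) > gap-in-b (X, consumes a) >
// gap-in-a (Y, consumes b), which makes the traceback deterministic.
//
// Returns the optimal score and one optimal path as 0-based indices into a
// and b per alignment column, with -1 marking a gap.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".gotoh_core")]]
List gotoh_core(NumericMatrix S, double gop, double gep, bool open_plus_ext) {
    const int n = S.nrow(), m = S.ncol();
    const double first = open_plus_ext ? gop + gep : gop;
    const int W = m + 1;

    // rolling score rows, full pointer matrices (predecessor state per cell)
    std::vector<double> Mprev(W), Xprev(W), Yprev(W), Mcur(W), Xcur(W), Ycur(W);
    std::vector<unsigned char> Mp((size_t)(n + 1) * W), Xp((size_t)(n + 1) * W),
        Yp((size_t)(n + 1) * W);

    Mprev[0] = 0.0; Xprev[0] = NEG_INF; Yprev[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
        Mprev[j] = NEG_INF;
        Xprev[j] = NEG_INF;
        Yprev[j] = -(first + (j - 1) * gep);
        Yp[j] = (j == 1) ? 0 : 2;   // opened from M at origin, then extends
    }

    for (int i = 1; i <= n; ++i) {
        Mcur[0] = NEG_INF;
        Ycur[0] = NEG_INF;
        Xcur[0] = -(first + (i - 1) * gep);
        Xp[(size_t)i * W] = (i == 1) ? 0 : 1;
        for (int j = 1; j <= m; ++j) {
            // M: diagonal step consuming a[i-1], b[j-1]
            double bm = Mprev[j - 1]; unsigned char pm = 0;
            if (Xprev[j - 1] > bm) { bm = Xprev[j - 1]; pm = 1; }
            if (Yprev[j - 1] > bm) { bm = Yprev[j - 1]; pm = 2; }
            Mcur[j] = bm + S(i - 1, j - 1);
            Mp[(size_t)i * W + j] = pm;
            // X: gap in b, consumes a (vertical)
            double bx = Mprev[j] - first; unsigned char px = 0;
            if (Xprev[j] - gep > bx) { bx = Xprev[j] - gep; px = 1; }
            if (Yprev[j] - first > bx) { bx = Yprev[j] - first; px = 2; }
            Xcur[j] = bx;
            Xp[(size_t)i * W + j] = px;
            // Y: gap in a, consumes b (horizontal)
            double by = Mcur[j - 1] - first; unsigned char py = 0;
            if (Xcur[j - 1] - first > by) { by = Xcur[j - 1] - first; py = 1; }
            if (Ycur[j - 1] - gep > by) { by = Ycur[j - 1] - gep; py = 2; }
            Ycur[j] = by;
            Yp[(size_t)i * W + j] = py;
        }
        std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
    }

    double best = Mprev[m]; unsigned char state = 0;
    if (Xprev[m] > best) { best = Xprev[m]; state = 1; }
    if (Yprev[m] > best) { best = Yprev[m]; state = 2; }

    // traceback via pointer matrices
    std::vector<int> pa, pb;
    int i = n, j = m;
    while (i > 0 || j > 0) {
        size_t at = (size_t)i * W + j;
        if (state == 0) {
            pa.push_back(i - 1); pb.push_back(j - 1);
            state = Mp[at]; --i; --j;
        } else if (state == 1) {
            pa.push_back(i - 1); pb.push_back(-1);
            state = Xp[at]; --i;
        } else {
            pa.push_back(-1); pb.push_back(j - 1);
            state = Yp[at]; --j;
        }
    }
    std::reverse(pa.begin(), pa.end());
    std::reverse(pb.begin(), pb.end());

    return List::create(_["score"] = best,
                        _["path_a"] = IntegerVector(pa.begin(), pa.end()),
                        _["path_b"] = IntegerVector(pb.begin(), pb.end()));
}

// Score-only variant without pointer storage, for bulk all-vs-all scoring.
// [[Rcpp::export(name = ".gotoh_score")]]
double gotoh_score(NumericMatrix S, double gop, double gep,
                   bool open_plus_ext) {
    const int n = S.nrow(), m = S.ncol();
    const double first = open_plus_ext ? gop + gep : gop;
    std::vector<double> M(m + 1), X(m + 1), Y(m + 1);
    std::vector<double> M2(m + 1), X2(m + 1), Y2(m + 1);
    M[0] = 0.0; X[0] = NEG_INF; Y[0] = NEG_INF;
    for (int j = 1; j <= m; ++j) {
        M[j] = NEG_INF; X[j] = NEG_INF; Y[j] = -(first + (j - 1) * gep);
    }
    for (int i = 1; i <= n; ++i) {
        M2[0] = NEG_INF; Y2[0] = NEG_INF; X2[0] = -(first + (i - 1) * gep);
        for (int j = 1; j <= m; ++j) {
            double bm = std::max(M[j - 1], std::max(X[j - 1], Y[j - 1]));
            M2[j] = bm + S(i - 1, j - 1);
            X2[j] = std::max(M[j] - first,
                             std::max(X[j] - gep, Y[j] - first));
            Y2[j] = std::max(M2[j - 1] - first,
                             std::max(X2[j - 1] - first, Y2[j - 1] - gep));
        }
        std::swap(M, M2); std::swap(X, X2); std::swap(Y, Y2);
    }
    return std::max(M[m], std::max(X[m], Y[m]));
}
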