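// Exhaustive residual-sum-of-squares enumeration for best-subset search.
// Works on the Gram matrix of [1 X] so each subset costs one small
// symmetric solve instead of a full n x p factorization.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// SSE of the OLS fit (intercept always included) for every subset of the
// columns of X. Subset b (0 .. 2^R - 1) uses column j iff bit j of b is set.
// Returns a vector of length 2^R; entries are NA when the normal equations
// are singular for that subset.
// [[Rcpp::export]]
NumericVector allSubsetSSE(const arma::mat& X, const arma::vec& y) {
    const int R = X.n_cols;
    if (R > 25) stop("allSubsetSSE supports at most 25 columns");
    const arma::uword n = X.n_rows;
    arma::mat Xa(n, R + 1);
    Xa.col(0).ones();
    if (R > 0) Xa.cols(1, R) = X;
    const arma::mat G = Xa.t() * Xa;
    const arma::vec g = Xa.t() * y;
    const double yty = arma::dot(y, y);

    const int nSub = 1 << R;
    NumericVector sse(nSub);
    arma::uvec idx(R + 1);
    for (int b = 0; b < nSub; ++b) {
        arma::uword p = 0;
        idx(p++) = 0;                      // intercept
        for (int j = 0; j < R; ++j)
            if (b & (1 << j)) idx(p++) = j + 1;
        arma::uvec use = idx.head(p);
        arma::mat Gs = G.submat(use, use);
        arma::vec gs = g.elem(use);
        arma::vec beta;
        bool ok = arma::solve(beta, Gs, gs,
                              arma::solve_opts::no_approx);
        if (!ok) {
            sse[b] = NA_REAL;
            continue;
        }
        double s = yty - arma::dot(beta, gs);
        sse[b] = s < 0 ? 0.0 : s;
    }
    return sse;
}
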