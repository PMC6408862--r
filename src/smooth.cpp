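// Local-likelihood smoothing of sparse methylation counts.
//
// For each CpG j the window is the smallest symmetric (in distance)
// neighbourhood containing at least min_cpgs sites and spanning at least
// min_window bp; weights are tricube(distance / halfwidth) * coverage and
// a weighted polynomial of the requested degree (0 or 2) in centred
// position is fitted to the raw proportions. The fitted value at j is the
// intercept, clipped to [0,1]. Zero-coverage sites get weight 0 but still
// receive a fitted value from their neighbours.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
NumericVector smooth_scaffold_cpp(NumericVector pos, NumericVector meth,
                                  NumericVector cov, int min_cpgs,
                                  double min_window, int degree) {
    const int n = pos.size();
    NumericVector out(n);
    if (n == 0) return out;
    const int k = std::min(min_cpgs, n);
    const int p = degree + 1;

    for (int j = 0; j < n; ++j) {
        // expand two pointers symmetrically by distance until k sites
        int lo = j, hi = j;
        while (hi - lo + 1 < k) {
            double dl = (lo > 0) ? pos[j] - pos[lo - 1] : R_PosInf;
            double dr = (hi < n - 1) ? pos[hi + 1] - pos[j] : R_PosInf;
            if (dl <= dr) --lo; else ++hi;
        }
        double h = std::max(std::max(pos[j] - pos[lo], pos[hi] - pos[j]),
                            min_window / 2.0);
        // include every site within h
        while (lo > 0 && pos[j] - pos[lo - 1] <= h) --lo;
        while (hi < n - 1 && pos[hi + 1] - pos[j] <= h) ++hi;

        // accumulate weighted moments; guard h so boundary sites keep a
        // positive tricube weight
        const double hh = h * 1.0000001 + 1e-9;
        arma::mat XtWX(p, p, arma::fill::zeros);
        arma::vec XtWy(p, arma::fill::zeros);
        double swy = 0.0, sw = 0.0;
        int npos = 0;
        for (int i = lo; i <= hi; ++i) {
            if (cov[i] <= 0) continue;
            double d = pos[i] - pos[j];
            double u = std::fabs(d) / hh;
            if (u >= 1.0) continue;
            double tri = 1.0 - u * u * u;
            double w = tri * tri * tri * cov[i];
            if (w <= 0) continue;
            double y = meth[i] / cov[i];
            ++npos;
            sw += w; swy += w * y;
            double xr = 1.0;
            double xp[3] = {1.0, d, d * d};
            for (int a = 0; a < p; ++a)
                for (int b = a; b < p; ++b)
                    XtWX(a, b) += w * xp[a] * xp[b];
            for (int a = 0; a < p; ++a) XtWy(a) += w * xp[a] * y;
            (void)xr;
        }
        double fit;
        if (npos == 0) {
            fit = NA_REAL;
        } else if (degree == 0 || npos < p) {
            fit = swy / sw;                       // weighted mean fallback
        } else {
            for (int a = 1; a < p; ++a)
                for (int b = 0; b < a; ++b) XtWX(a, b) = XtWX(b, a);
            arma::vec beta;
            bool ok = arma::solve(beta, XtWX, XtWy,
                                  arma::solve_opts::no_approx);
            fit = ok ? beta(0) : swy / sw;
        }
        if (!ISNA(fit)) {
            if (fit < 0.0) fit = 0.0;
            if (fit > 1.0) fit = 1.0;
        }
        out[j] = fit;
    }
    return out;
}
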