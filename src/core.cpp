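// Computational cores: local-median smoothing, k-group log-rank over many
// markers, and Newton-Raphson Cox partial-likelihood fits (Breslow/Efron).
// Callers are responsible for complete-case filtering; the Cox and log-rank
// entry points expect times sorted ascending unless noted.
#include <RcppArmadillo.h>
#include <algorithm>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---- local median smoothing -------------------------------------------------

static double median_of(std::vector<double>& v) {
    const size_t n = v.size();
    if (n == 0) return NA_REAL;
    const size_t h = n / 2;
    std::nth_element(v.begin(), v.begin() + h, v.end());
    double m = v[h];
    if (n % 2 == 0) {
        double lo = *std::max_element(v.begin(), v.begin() + h);
        m = 0.5 * (m + lo);
    }
    return m;
}

// values: markers x samples; chrom: integer run label per marker (rows grouped
// by chromosome in genome order); windows are centered with floor((w-1)/2)
// markers to the left, truncated at chromosome boundaries; NA excluded.
// [[Rcpp::export]]
NumericMatrix cpp_smooth(const NumericMatrix& values, const IntegerVector& chrom,
                         int window) {
    const int m = values.nrow(), n = values.ncol();
    if (window < 1) stop("window must be >= 1");
    const int left = (window - 1) / 2, right = window - 1 - left;

    std::vector<int> run_start(m), run_end(m);
    for (int i = 0; i < m; ++i) {
        run_start[i] = (i > 0 && chrom[i] == chrom[i - 1]) ? run_start[i - 1] : i;
    }
    for (int i = m - 1; i >= 0; --i) {
        run_end[i] = (i < m - 1 && chrom[i] == chrom[i + 1]) ? run_end[i + 1] : i;
    }

    NumericMatrix out(m, n);
    std::vector<double> buf;
    buf.reserve(window);
    for (int j = 0; j < n; ++j) {
        for (int i = 0; i < m; ++i) {
            const int lo = std::max(i - left, run_start[i]);
            const int hi = std::min(i + right, run_end[i]);
            buf.clear();
            for (int t = lo; t <= hi; ++t) {
                const double v = values(t, j);
                if (!ISNAN(v)) buf.push_back(v);
            }
            out(i, j) = median_of(buf);
        }
    }
    return out;
}

// ---- k-group log-rank -------------------------------------------------------

// groups: markers x samples, entries in 0..k (0 = excluded for that marker);
// time/event: per sample (complete cases only, any order). Returns per-marker
// chi-square (NA if fewer than 2 nonempty groups), df, and per-group
// n / observed / expected event counts.
// [[Rcpp::export]]
List cpp_logrank_scan(const IntegerMatrix& groups, const NumericVector& time,
                      const IntegerVector& event, int k) {
    const int m = groups.nrow(), n = groups.ncol();
    if (time.size() != n || event.size() != n)
        stop("time/event length must match the number of samples");

    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;
    std::stable_sort(ord.begin(), ord.end(),
                     [&](int a, int b) { return time[a] < time[b]; });

    NumericVector stat(m), df(m);
    NumericMatrix obs(m, k), expd(m, k);
    IntegerMatrix ngrp(m, k);

    std::vector<double> atrisk(k), O(k), E(k);
    std::vector<int> dg(k), cg(k);
    arma::mat V(k, k);

    for (int r = 0; r < m; ++r) {
        std::fill(atrisk.begin(), atrisk.end(), 0.0);
        std::fill(O.begin(), O.end(), 0.0);
        std::fill(E.begin(), E.end(), 0.0);
        V.zeros();
        int ns = 0;
        for (int j = 0; j < n; ++j) {
            const int g = groups(r, j);
            if (g > 0) { atrisk[g - 1] += 1.0; ++ns; }
        }
        int nonempty = 0;
        for (int g = 0; g < k; ++g) {
            ngrp(r, g) = (int) atrisk[g];
            if (atrisk[g] > 0) ++nonempty;
        }
        if (ns == 0 || nonempty == 0) {
            stat[r] = NA_REAL; df[r] = 0;
            for (int g = 0; g < k; ++g) { obs(r, g) = NA_REAL; expd(r, g) = NA_REAL; }
            continue;
        }

        // walk pooled distinct times ascending
        int i = 0;
        while (i < n) {
            // advance to next included sample
            if (groups(r, ord[i]) == 0) { ++i; continue; }
            const double t = time[ord[i]];
            std::fill(dg.begin(), dg.end(), 0);
            std::fill(cg.begin(), cg.end(), 0);
            int j = i;
            while (j < n && time[ord[j]] == t) {
                const int g = groups(r, ord[j]);
                if (g > 0) {
                    if (event[ord[j]] == 1) ++dg[g - 1]; else ++cg[g - 1];
                }
                ++j;
            }
            double N = 0.0; int d = 0;
            for (int g = 0; g < k; ++g) { N += atrisk[g]; d += dg[g]; }
            if (d > 0) {
                for (int g = 0; g < k; ++g) {
                    E[g] += d * atrisk[g] / N;
                    O[g] += dg[g];
                }
                if (N > 1.0) {
                    const double mult = d * (N - d) / (N * N * (N - 1.0));
                    for (int g = 0; g < k; ++g) {
                        for (int h = 0; h < k; ++h) {
                            V(g, h) += mult * (g == h
                                ? atrisk[g] * (N - atrisk[g])
                                : -atrisk[g] * atrisk[h]);
                        }
                    }
                }
            }
            for (int g = 0; g < k; ++g) atrisk[g] -= (dg[g] + cg[g]);
            i = j;
        }

        for (int g = 0; g < k; ++g) { obs(r, g) = O[g]; expd(r, g) = E[g]; }

        if (nonempty < 2) { stat[r] = NA_REAL; df[r] = 0; continue; }

        // statistic on nonempty groups, dropping the last one
        arma::uvec keep(nonempty);
        int p = 0;
        for (int g = 0; g < k; ++g) if (ngrp(r, g) > 0) keep[p++] = g;
        arma::uvec sub = keep.head(nonempty - 1);
        arma::vec u(nonempty - 1);
        for (int g = 0; g < nonempty - 1; ++g) u[g] = O[keep[g]] - E[keep[g]];
        arma::mat Vsub = V.submat(sub, sub);
        arma::vec x;
        bool ok = arma::solve(x, Vsub, u, arma::solve_opts::no_approx);
        if (!ok) {
            arma::mat Vg = arma::pinv(Vsub);
            x = Vg * u;
        }
        double chisq = arma::dot(u, x);
        if (chisq < 0) chisq = 0.0;
        stat[r] = chisq;
        df[r] = nonempty - 1;
    }

    return List::create(_["statistic"] = stat, _["df"] = df, _["obs"] = obs,
                        _["exp"] = expd, _["n"] = ngrp);
}

// ---- Cox proportional hazards ----------------------------------------------

struct CoxEval {
    double ll;
    arma::vec U;
    arma::mat I;
};

// X sorted by time ascending; risk sets accumulated from the largest time
// down. Plain accumulation loops (p is 1-3 in scans; avoid per-sample
// temporaries).
static CoxEval cox_eval(const arma::mat& X, const arma::vec& time,
                        const arma::ivec& event, const arma::vec& beta,
                        bool efron) {
    const int n = X.n_rows, p = X.n_cols;
    CoxEval ev;
    ev.ll = 0.0;
    ev.U = arma::zeros(p);
    ev.I = arma::zeros(p, p);

    std::vector<double> S1(p, 0.0), S2(p * p, 0.0);
    std::vector<double> S1e(p), S2e(p * p), s(p), r1(p);
    double S0 = 0.0;

    int i = n - 1;
    while (i >= 0) {
        const double t = time[i];
        int bstart = i;
        while (bstart > 0 && time[bstart - 1] == t) --bstart;

        double S0e = 0.0, etasum = 0.0;
        std::fill(S1e.begin(), S1e.end(), 0.0);
        std::fill(S2e.begin(), S2e.end(), 0.0);
        std::fill(s.begin(), s.end(), 0.0);
        int d = 0;
        for (int r = bstart; r <= i; ++r) {
            double eta = 0.0;
            for (int j = 0; j < p; ++j) eta += X(r, j) * beta[j];
            const double w = std::exp(eta);
            S0 += w;
            for (int j = 0; j < p; ++j) {
                const double xj = X(r, j);
                S1[j] += w * xj;
                for (int k = 0; k <= j; ++k) S2[j * p + k] += w * xj * X(r, k);
            }
            if (event[r] == 1) {
                ++d;
                etasum += eta;
                for (int j = 0; j < p; ++j) s[j] += X(r, j);
                if (efron) {
                    S0e += w;
                    for (int j = 0; j < p; ++j) {
                        const double xj = X(r, j);
                        S1e[j] += w * xj;
                        for (int k = 0; k <= j; ++k)
                            S2e[j * p + k] += w * xj * X(r, k);
                    }
                }
            }
        }
        if (d > 0) {
            if (!efron) {
                ev.ll += etasum - d * std::log(S0);
                for (int j = 0; j < p; ++j) r1[j] = S1[j] / S0;
                for (int j = 0; j < p; ++j) {
                    ev.U[j] += s[j] - d * r1[j];
                    for (int k = 0; k <= j; ++k)
                        ev.I(j, k) += d * (S2[j * p + k] / S0 - r1[j] * r1[k]);
                }
            } else {
                ev.ll += etasum;
                for (int j = 0; j < p; ++j) ev.U[j] += s[j];
                for (int l = 0; l < d; ++l) {
                    const double f = (double) l / d;
                    const double S0l = S0 - f * S0e;
                    ev.ll -= std::log(S0l);
                    for (int j = 0; j < p; ++j)
                        r1[j] = (S1[j] - f * S1e[j]) / S0l;
                    for (int j = 0; j < p; ++j) {
                        ev.U[j] -= r1[j];
                        for (int k = 0; k <= j; ++k)
                            ev.I(j, k) += (S2[j * p + k] - f * S2e[j * p + k]) / S0l
                                - r1[j] * r1[k];
                    }
                }
            }
        }
        i = bstart - 1;
    }
    for (int j = 0; j < p; ++j)
        for (int k = j + 1; k < p; ++k) ev.I(j, k) = ev.I(k, j);
    return ev;
}

// Newton-Raphson with step halving; returns estimates plus convergence state.
// [[Rcpp::export]]
List cpp_cox(const arma::mat& X, const arma::vec& time, const arma::ivec& event,
             bool efron, double tol, int maxit) {
    const int p = X.n_cols;
    arma::vec beta = arma::zeros(p);

    CoxEval ev = cox_eval(X, time, event, beta, efron);
    const double ll0 = ev.ll;
    bool converged = false;
    int iter = 0;

    for (iter = 1; iter <= maxit; ++iter) {
        arma::vec step;
        bool ok = arma::solve(step, ev.I, ev.U, arma::solve_opts::no_approx);
        if (!ok) step = arma::pinv(ev.I) * ev.U;
        arma::vec newbeta = beta + step;
        CoxEval nev = cox_eval(X, time, event, newbeta, efron);
        int halve = 0;
        while ((!std::isfinite(nev.ll) || nev.ll < ev.ll) && halve < 25) {
            newbeta = 0.5 * (beta + newbeta);
            nev = cox_eval(X, time, event, newbeta, efron);
            ++halve;
        }
        const double delta = std::fabs(nev.ll - ev.ll);
        beta = newbeta;
        ev = nev;
        if (std::isfinite(ev.ll) && delta < tol) { converged = true; break; }
    }

    // monotone-likelihood guard: coefficient drifting to +/- infinity
    if (converged) {
        for (int j = 0; j < p; ++j) {
            const double sdx = arma::stddev(X.col(j));
            if (sdx > 0 && std::fabs(beta[j]) * sdx > 23.0) converged = false;
        }
    }

    arma::mat var(p, p);
    arma::vec se(p);
    bool okv = arma::inv(var, ev.I);
    if (!okv) {
        var = arma::pinv(ev.I);
    }
    for (int j = 0; j < p; ++j) {
        const double v = var(j, j);
        se[j] = (v > 0 && std::isfinite(v)) ? std::sqrt(v) : NA_REAL;
    }

    return List::create(_["beta"] = beta, _["se"] = se, _["var"] = var,
                        _["loglik0"] = ll0, _["loglik"] = ev.ll,
                        _["iter"] = iter, _["converged"] = converged);
}

// Per-marker univariate (plus shared extra covariates) Cox fits.
// cov: markers x samples (NA allowed, sample dropped for that marker);
// extra: samples x q, complete; time ascending. Returns the first
// coefficient's estimate per marker.
// [[Rcpp::export]]
List cpp_cox_scan(const NumericMatrix& cov, const arma::mat& extra,
                  const NumericVector& time, const IntegerVector& event,
                  bool efron, double tol, int maxit) {
    const int m = cov.nrow(), n = cov.ncol();
    const int q = extra.n_cols;
    NumericVector beta(m), se(m), z(m);
    LogicalVector conv(m);
    IntegerVector nused(m);

    std::vector<int> idx;
    idx.reserve(n);
    for (int r = 0; r < m; ++r) {
        idx.clear();
        for (int j = 0; j < n; ++j) {
            if (!ISNAN(cov(r, j))) idx.push_back(j);
        }
        const int ns = (int) idx.size();
        int nev = 0;
        double mu = 0.0;
        for (int t = 0; t < ns; ++t) {
            mu += cov(r, idx[t]);
            nev += event[idx[t]];
        }
        bool degenerate = (ns < 2 || nev < 1);
        if (!degenerate) {
            mu /= ns;
            double ssq = 0.0;
            for (int t = 0; t < ns; ++t) {
                const double dv = cov(r, idx[t]) - mu;
                ssq += dv * dv;
            }
            if (ssq <= 0.0) degenerate = true;
        }
        if (degenerate) {
            beta[r] = NA_REAL; se[r] = NA_REAL; z[r] = NA_REAL;
            conv[r] = false; nused[r] = ns;
            continue;
        }
        arma::mat X(ns, 1 + q);
        arma::vec tt(ns);
        arma::ivec ee(ns);
        for (int t = 0; t < ns; ++t) {
            const int j = idx[t];
            X(t, 0) = cov(r, j);
            for (int c = 0; c < q; ++c) X(t, 1 + c) = extra(j, c);
            tt[t] = time[j];
            ee[t] = event[j];
        }
        List fit = cpp_cox(X, tt, ee, efron, tol, maxit);
        arma::vec b = fit["beta"], s = fit["se"];
        const bool cv = fit["converged"];
        beta[r] = b[0];
        se[r] = s[0];
        z[r] = (std::isfinite(s[0]) && s[0] > 0) ? b[0] / s[0] : NA_REAL;
        conv[r] = cv;
        nused[r] = ns;
    }
    return List::create(_["beta"] = beta, _["se"] = se, _["z"] = z,
                        _["converged"] = conv, _["n"] = nused);
}
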