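// Steady-state firing rates of the autoencoder network:
//   r* = argmin_{r >= 0}  ||y - D r||^2 + 2 T' r
// solved by cyclic coordinate descent with a periodic exact active-set
// polish. CD makes fast global progress and identifies the support; the
// polish solves the equality-constrained KKT system on the current support
// (Lawson-Hanson style inner loop) to drive the residual to machine
// precision even in ill-conditioned or nearly degenerate geometries.
// Deterministic: fixed cyclic order, cold start at r = 0.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// KKT residual at the scale of the gradient g = D'(Dr - y) + T:
//   r_i > 0 : |g_i| ;  r_i = 0 : max(0, -g_i)
static double kkt_residual(const vec& r, const vec& g) {
    double res = 0.0;
    for (uword i = 0; i < r.n_elem; ++i) {
        double v = (r[i] > 0.0) ? std::fabs(g[i]) : std::max(0.0, -g[i]);
        if (v > res) res = v;
    }
    return res;
}

// Solve the restricted problem on support S exactly (inner NNLS loop):
// returns false if a linear solve fails (e.g. exactly singular support).
static bool polish_support(const mat& D, const vec& q, uvec S, vec& r) {
    const uword N = D.n_cols;
    for (int guard = 0; guard < 2 * (int)N + 2; ++guard) {
        if (S.n_elem == 0) { r.zeros(); return true; }
        mat H = D.cols(S).t() * D.cols(S);
        vec rhs = q.elem(S);
        vec rS;
        if (!solve(rS, H, rhs, solve_opts::likely_sympd + solve_opts::no_approx))
            return false;
        if (rS.min() >= 0.0) {
            r.zeros();
            r.elem(S) = rS;
            return true;
        }
        // Lawson-Hanson step: move from current feasible point toward rS
        // until the first coordinate hits zero, then drop it from S
        vec rcur = r.elem(S);
        double alpha = 1.0;
        uword drop = 0;
        for (uword k = 0; k < S.n_elem; ++k) {
            if (rS[k] < 0.0) {
                double denom = rcur[k] - rS[k];
                double a = (denom > 0.0) ? rcur[k] / denom : 0.0;
                if (a < alpha) { alpha = a; drop = k; }
            }
        }
        vec rnew = rcur + alpha * (rS - rcur);
        rnew[drop] = 0.0;
        r.zeros();
        r.elem(S) = clamp(rnew, 0.0, datum::inf);
        S.shed_row(drop);
    }
    return false;
}

// [[Rcpp::export(name = ".nnqpSolve")]]
Rcpp::List nnqp_solve(const arma::mat& D, const arma::mat& Y,
                      const arma::vec& T, double tol = 1e-9,
                      int maxSweeps = 100000) {
    const uword N = D.n_cols, P = Y.n_cols;
    if (D.n_rows != Y.n_rows)
        Rcpp::stop("dimension mismatch between decoder and embedding input");
    if (T.n_elem != N)
        Rcpp::stop("threshold vector length must equal the number of neurons");

    vec h(N);                        // diagonal of D'D
    for (uword i = 0; i < N; ++i) h[i] = dot(D.col(i), D.col(i));

    mat R(N, P, fill::zeros);
    vec objective(P), kkt(P);
    ivec sweeps(P), converged(P);

    for (uword p = 0; p < P; ++p) {
        const vec y = Y.col(p);
        const vec q = D.t() * y - T;    // gradient g = D'(D r) - q
        vec r(N, fill::zeros);
        vec u(D.n_rows, fill::zeros);   // u = D r, kept incrementally

        int s = 0;
        double res = datum::inf;
        for (; s < maxSweeps; ++s) {
            double maxDelta = 0.0;
            for (uword i = 0; i < N; ++i) {
                if (h[i] <= 0.0) continue;     // zero column: r_i stays 0
                double g = dot(D.col(i), u) - q[i];
                double rn = r[i] - g / h[i];
                if (rn < 0.0) rn = 0.0;
                double d = rn - r[i];
                if (d != 0.0) {
                    u += d * D.col(i);
                    r[i] = rn;
                    double ad = std::fabs(d);
                    if (ad > maxDelta) maxDelta = ad;
                }
            }
            vec g = D.t() * u - q;
            res = kkt_residual(r, g);
            if (res <= tol) { ++s; break; }

            // periodic exact polish once CD has identified a support
            if (s >= 10 && (s % 25 == 0 || maxDelta == 0.0)) {
                uvec S0 = find(r > 0.0);
                vec rbest; double resbest = datum::inf;
                // candidate supports: the CD support, and (for
                // ill-conditioned/degenerate supports where the exact
                // solve fails to reach stationarity) each drop-one subset
                std::vector<uvec> cands;
                cands.push_back(S0);
                for (uword k = 0; k < S0.n_elem; ++k) {
                    uvec Sk = S0; Sk.shed_row(k);
                    cands.push_back(Sk);
                }
                for (size_t c = 0; c < cands.size(); ++c) {
                    vec rp = r;
                    if (!polish_support(D, q, cands[c], rp)) continue;
                    vec gp = D.t() * (D * rp) - q;
                    // grow the support if a silent neuron wants in
                    int grow = 0;
                    while (grow++ < (int)N) {
                        double worst = -tol; sword add = -1;
                        for (uword i = 0; i < N; ++i)
                            if (rp[i] == 0.0 && h[i] > 0.0 &&
                                gp[i] < worst) { worst = gp[i]; add = i; }
                        if (add < 0) break;
                        uvec S2 = find(rp > 0.0);
                        S2.insert_rows(S2.n_elem, 1);
                        S2[S2.n_elem - 1] = (uword)add;
                        if (!polish_support(D, q, sort(S2), rp)) break;
                        gp = D.t() * (D * rp) - q;
                    }
                    double resp = kkt_residual(rp, gp);
                    if (resp < resbest) { resbest = resp; rbest = rp; }
                    if (resbest <= tol) break;
                    // before a long stall, settle for progress on the CD
                    // support; afterwards, also try drop-one subsets
                    if (c == 0 && s < 200 && resbest <= res) break;
                }
                if (resbest < res) {
                    r = rbest; u = D * r; res = resbest;
                    if (res <= tol) { ++s; break; }
                }
                if (maxDelta == 0.0) { ++s; break; }  // true CD fixed point
            }
        }

        const vec resid = y - u;
        R.col(p) = r;
        objective[p] = dot(resid, resid) + 2.0 * dot(T, r);
        kkt[p] = res;
        sweeps[p] = s;
        converged[p] = (res <= tol) ? 1 : 0;
    }

    return Rcpp::List::create(
        Rcpp::Named("rates") = R,
        Rcpp::Named("objective") = objective,
        Rcpp::Named("kkt") = kkt,
        Rcpp::Named("sweeps") = sweeps,
        Rcpp::Named("converged") = converged);
}
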