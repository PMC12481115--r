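#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Multiplicative-update NMF minimising squared Frobenius error
// (Lee-Seung updates). `eps` is a floor inside the update ratios that
// prevents division by zero when a factor row/column collapses.
// Stops when the relative decrease of the Frobenius error falls below
// `tol`, or after `max_iter` iterations.
// [[Rcpp::export]]
Rcpp::List nmf_mu_cpp(const arma::mat& V, arma::mat W, arma::mat H,
                      int max_iter, double tol, double eps) {
    std::vector<double> err;
    err.reserve(static_cast<size_t>(max_iter) + 1);
    double prev = norm(V - W * H, "fro");
    err.push_back(prev);
    int it;
    for (it = 1; it <= max_iter; ++it) {
        H %= (W.t() * V) / (W.t() * W * H + eps);
        W %= (V * H.t()) / (W * H * H.t() + eps);
        double e = norm(V - W * H, "fro");
        err.push_back(e);
        if (prev > 0.0 && (prev - e) / prev < tol) { prev = e; break; }
        prev = e;
    }
    return Rcpp::List::create(
        Rcpp::Named("W") = W,
        Rcpp::Named("H") = H,
        Rcpp::Named("error") = prev,
        Rcpp::Named("error_trace") = err,
        Rcpp::Named("iterations") = std::min(it, max_iter));
}
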