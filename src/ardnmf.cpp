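// Multiplicative MAP updates for ARD-NMF with Poisson likelihood,
// exponential (L1) prior on W, half-normal (L2) prior on H, and
// per-component relevance weights lambda.
//
// Block updates (all exact minimisers of the KL majoriser, so the MAP
// objective is non-increasing):
//   H: root of  h^2/lambda + (sum_g w) h - (sum_g w v/vhat) h_old = 0
//   W: w_old * (sum_c h v/vhat) / (sum_c h + 1/lambda)
//   lambda_k: (sum_g w + sum_c h^2/2 + b) / (G + C/2 + a + 1)

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static double kl_div(const mat& V, const mat& Vhat, double eps) {
  double acc = 0.0;
  const double* v = V.memptr();
  const double* vh = Vhat.memptr();
  const uword n = V.n_elem;
  for (uword i = 0; i < n; ++i) {
    if (v[i] > 0) acc += v[i] * std::log(v[i] / (vh[i] + eps));
    acc += vh[i] - v[i];
  }
  return acc;
}

static double map_objective(const mat& V, const mat& W, const mat& H,
                            const vec& lambda, double b, double M,
                            double eps) {
  mat Vhat = W * H;
  vec S = sum(W, 0).t() + 0.5 * sum(H % H, 1);
  return kl_div(V, Vhat, eps) +
    accu((S + b) / lambda + M * log(lambda));
}

// [[Rcpp::export(name = ".ardnmf_iterate")]]
Rcpp::List ardnmf_iterate(const arma::mat& V, arma::mat W, arma::mat H,
                          arma::vec lambda, double b, double a,
                          int max_iter, double tol, int trace_every,
                          bool update_W, bool update_lambda) {
  const double eps = 1e-10;
  const uword G = V.n_rows, C = V.n_cols, K = W.n_cols;
  const double M = (double)G + (double)C / 2.0 + a + 1.0;

  std::vector<double> trace;
  bool converged = false;
  int it = 0;

  mat Vhat(G, C), R(G, C), B(K, C), num(G, K);
  vec colw(K), rowh(K);

  const uword n_elem = V.n_elem;
  const double* vptr = V.memptr();
  // fused r = v / (vhat + eps): much cheaper than expression temporaries
  auto fill_ratio = [&](const mat& Vh, mat& out) {
    const double* vh = Vh.memptr();
    double* o = out.memptr();
    for (uword i = 0; i < n_elem; ++i) o[i] = vptr[i] / (vh[i] + eps);
  };

  mat H_old;
  while (it < max_iter) {
    ++it;
    vec lambda_old = lambda;
    if (!update_lambda) H_old = H;

    // ---- H block ----
    Vhat = W * H;
    fill_ratio(Vhat, R);
    B = W.t() * R;                 // K x C
    colw = sum(W, 0).t();          // A_k
    for (uword c = 0; c < C; ++c) {
      for (uword k = 0; k < K; ++k) {
        const double A = colw(k), l = lambda(k);
        const double bh = B(k, c) * H(k, c);
        H(k, c) = 0.5 * l * (std::sqrt(A * A + 4.0 * bh / l) - A);
      }
    }

    // ---- W block ----
    if (update_W) {
      Vhat = W * H;
      fill_ratio(Vhat, R);
      num = R * H.t();             // G x K
      rowh = sum(H, 1);
      for (uword k = 0; k < K; ++k) {
        const double den = rowh(k) + 1.0 / lambda(k);
        for (uword g = 0; g < G; ++g) {
          W(g, k) = W(g, k) * num(g, k) / den;
        }
      }
    }

    // ---- lambda block ----
    if (update_lambda) {
      lambda = (sum(W, 0).t() + 0.5 * sum(H % H, 1) + b) / M;
    }

    if (trace_every > 0 && (it % trace_every == 0 || it == 1)) {
      trace.push_back(map_objective(V, W, H, lambda, b, M, eps));
    }

    // lambda drives convergence for full fits; H for fixed-W projections
    double dl = update_lambda
      ? norm(lambda - lambda_old, 2) / (norm(lambda_old, 2) + eps)
      : norm(H - H_old, "fro") / (norm(H_old, "fro") + eps);
    if (dl < tol) { converged = true; break; }
  }

  return Rcpp::List::create(
    Rcpp::Named("W") = W, Rcpp::Named("H") = H,
    Rcpp::Named("lambda") = lambda,
    Rcpp::Named("objective_trace") = trace,
    Rcpp::Named("iterations") = it,
    Rcpp::Named("converged") = converged);
}

// [[Rcpp::export(name = ".kl_divergence_cpp")]]
double kl_divergence_cpp(const arma::mat& V, const arma::mat& Vhat) {
  return kl_div(V, Vhat, 1e-10);
}
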