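#include <Rcpp.h>
using namespace Rcpp;

// Penalized negative Poisson log-likelihood of the LN model and its
// gradient, in one pass.
//
// Parameter layout: par[0] = bias (log expected count per bin), followed by
// each variable's weight vector in the order of `indices`. The model's
// expected count at frame t is exp(bias + sum_v w_v[idx_v[t]]); the rate in
// spikes/s is that divided by dt (dt only shifts the bias, so it does not
// enter the objective).
//
// Penalty: beta * sum over adjacent-bin pairs of (w_a - w_b)^2 for smooth
// topologies, or lambda * sum sqrt(w^2 + eps) (smoothed lasso) for discrete
// variables. The constant log(n!) term of the likelihood is dropped.
//
// [[Rcpp::export]]
List ln_nll_grad_cpp(NumericVector par, List indices, IntegerVector nbins,
                     IntegerVector counts, List pen_pairs,
                     LogicalVector is_discrete, double beta, double lambda) {
  const int T = counts.size();
  const int V = indices.size();
  const int P = par.size();
  NumericVector grad(P);
  std::vector<IntegerVector> keep(V);  // keep SEXPs alive for raw pointers
  std::vector<int*> idx(V);
  std::vector<int> off(V);
  int pos = 1;
  for (int v = 0; v < V; ++v) {
    keep[v] = indices[v];
    if (keep[v].size() != T) stop("index/count length mismatch");
    idx[v] = INTEGER(keep[v]);
    off[v] = pos;
    pos += nbins[v];
  }
  if (pos != P) stop("parameter length does not match bin counts");

  double nll = 0.0;
  double gbias = 0.0;
  const double bias = par[0];
  for (int t = 0; t < T; ++t) {
    double lp = bias;
    for (int v = 0; v < V; ++v) lp += par[off[v] + idx[v][t] - 1];
    const double mu = std::exp(lp);
    const double n = counts[t];
    nll += mu - n * lp;
    const double resid = mu - n;
    gbias += resid;
    for (int v = 0; v < V; ++v) grad[off[v] + idx[v][t] - 1] += resid;
  }
  grad[0] = gbias;

  double pen = 0.0;
  const double eps = 1e-8;
  for (int v = 0; v < V; ++v) {
    if (is_discrete[v]) {
      for (int b = 0; b < nbins[v]; ++b) {
        const double w = par[off[v] + b];
        const double s = std::sqrt(w * w + eps);
        pen += lambda * s;
        grad[off[v] + b] += lambda * w / s;
      }
    } else {
      IntegerMatrix pp = pen_pairs[v];
      const int np = pp.nrow();
      for (int k = 0; k < np; ++k) {
        const int a = off[v] + pp(k, 0) - 1;
        const int b = off[v] + pp(k, 1) - 1;
        const double d = par[a] - par[b];
        pen += beta * d * d;
        grad[a] += 2.0 * beta * d;
        grad[b] -= 2.0 * beta * d;
      }
    }
  }

  return List::create(_["value"] = nll + pen, _["gradient"] = grad,
                      _["nll"] = nll, _["penalty"] = pen);
}

// Unpenalized Poisson log-likelihood (log n! dropped) of fixed parameters
// on a subset of frames (1-based `rows`).
// [[Rcpp::export]]
double ln_loglik_cpp(NumericVector par, List indices, IntegerVector nbins,
                     IntegerVector counts, IntegerVector rows) {
  const int V = indices.size();
  std::vector<IntegerVector> keep(V);
  std::vector<int*> idx(V);
  std::vector<int> off(V);
  int pos = 1;
  for (int v = 0; v < V; ++v) {
    keep[v] = indices[v];
    idx[v] = INTEGER(keep[v]);
    off[v] = pos;
    pos += nbins[v];
  }
  const double bias = par[0];
  double ll = 0.0;
  for (int r = 0; r < rows.size(); ++r) {
    const int t = rows[r] - 1;
    double lp = bias;
    for (int v = 0; v < V; ++v) lp += par[off[v] + idx[v][t] - 1];
    ll += counts[t] * lp - std::exp(lp);
  }
  return ll;
}
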