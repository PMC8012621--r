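# LN-Poisson model: penalized likelihood, fitting, cross-validation, and
# forward model selection.

# Concatenated parameter layout: bias, then each variable's weights in the
# order of `variables`.
par_layout <- function(blocks, variables) {
  nbins <- vapply(variables, function(v) blocks[[v]]$spec$bin_count, integer(1))
  list(variables = variables, nbins = nbins, length = 1L + sum(nbins))
}

pack_par <- function(bias, weights, variables) {
  c(bias, unlist(weights[variables], use.names = FALSE))
}

unpack_par <- function(par, layout) {
  w <- vector("list", length(layout$variables))
  names(w) <- layout$variables
  pos <- 2L
  for (i in seq_along(layout$variables)) {
    w[[i]] <- par[pos:(pos + layout$nbins[i] - 1L)]
    pos <- pos + layout$nbins[i]
  }
  list(bias = par[1], weights = w)
}

#' Penalized negative log-likelihood of the LN model
#'
#' The objective minimized by [fit_ln()]: the negative Poisson
#' log-likelihood `sum_t [mu_t - n_t log mu_t]` (with `mu_t` the expected
#' count `exp(bias + sum_i w_i[bin_it])` and the constant `log n!` dropped),
#' plus a smoothness penalty `beta * sum (w_a - w_b)^2` over adjacent bins
#' (rows and columns separately for position grids, wrapped for circular
#' variables) and a lasso penalty `lambda * sum |w|` for discrete variables
#' (smoothed with eps = 1e-8 so the objective stays differentiable).
#'
#' @param bias Scalar log expected count per bin.
#' @param weights Named list of per-variable weight vectors.
#' @param blocks Named list of `design_block`s covering `names(weights)`.
#' @param counts Integer spike counts, one per frame.
#' @param beta Smoothness penalty weight.
#' @param lambda Lasso penalty weight (discrete variables only).
#' @param rows Optional frame subset (1-based).
#' @return `list(value, gradient, nll, penalty)`; the gradient is ordered
#'   (bias, weights in `names(weights)` order).
#' @export
penalized_nll <- function(bias, weights, blocks, counts, beta = 20,
                          lambda = 1, rows = NULL) {
  variables <- names(weights)
  stopifnot(all(variables %in% names(blocks)))
  for (v in variables)
    if (length(weights[[v]]) != blocks[[v]]$spec$bin_count)
      stop(sprintf("weight length of '%s' does not match its bin count", v))
  if (length(blocks) > 0 && length(counts) != length(blocks[[1]]$index))
    stop("counts and design blocks must share the frame axis")
  idx <- lapply(variables, function(v) blocks[[v]]$index)
  if (!is.null(rows)) {
    idx <- lapply(idx, `[`, rows)
    counts <- counts[rows]
  }
  layout <- par_layout(blocks, variables)
  ln_nll_grad_cpp(pack_par(bias, weights, variables), idx,
                  as.integer(layout$nbins), as.integer(counts),
                  lapply(variables, function(v) penalty_pairs(blocks[[v]]$spec)),
                  vapply(variables, function(v)
                    blocks[[v]]$spec$kind == "discrete", logical(1)),
                  beta, lambda)
}

#' Fit the LN-Poisson model
#'
#' Maximizes the penalized Poisson log-likelihood by quasi-Newton descent
#' (L-BFGS-B with the analytic gradient). The objective is convex, so the
#' zero-initialized fit is deterministic; non-convergence within the
#' iteration cap is flagged in `$convergence`, never silent. An empty
#' variable set gives the closed-form mean-firing-rate (null) model.
#'
#' @param blocks Named list of `design_block`s.
#' @param counts Spike counts per frame.
#' @param dt Time bin, seconds.
#' @param variables Variables to include (default all blocks).
#' @param beta,lambda Penalty weights (see [penalized_nll()]).
#' @param rows Optional training-frame subset.
#' @param init Optional warm-start parameter vector (bias, weights).
#' @param maxit Iteration cap.
#' @return A `fitted_model`: bias, per-variable `weights`, specs, penalized
#'   and unpenalized objective values, and convergence diagnostics.
#' @export
fit_ln <- function(blocks, counts, dt, variables = names(blocks),
                   beta = 20, lambda = 1, rows = NULL, init = NULL,
                   maxit = 500) {
  counts_fit <- if (is.null(rows)) counts else counts[rows]
  if (length(variables) == 0) {
    bias <- log(max(mean(counts_fit), 1e-12))
    m <- list(variables = character(0), bias = bias, weights = list(),
              specs = list(), dt = dt, beta = beta, lambda = lambda,
              par = bias, nll = length(counts_fit) * exp(bias) -
                sum(counts_fit) * bias,
              penalty = 0, convergence = 0L, message = "closed form")
    class(m) <- "fitted_model"
    return(m)
  }
  stopifnot(all(variables %in% names(blocks)))
  idx <- lapply(variables, function(v) {
    i <- blocks[[v]]$index
    if (is.null(rows)) i else i[rows]
  })
  layout <- par_layout(blocks, variables)
  pp <- lapply(variables, function(v) penalty_pairs(blocks[[v]]$spec))
  disc <- vapply(variables, function(v)
    blocks[[v]]$spec$kind == "discrete", logical(1))
  counts_i <- as.integer(counts_fit)
  nb <- as.integer(layout$nbins)

  par0 <- if (!is.null(init) && length(init) == layout$length) init else
    c(log(max(mean(counts_fit), 1e-12)), rep(0, layout$length - 1L))

  cache <- new.env(parent = emptyenv())
  evalp <- function(p) {
    if (is.null(cache$par) || !identical(p, cache$par)) {
      r <- ln_nll_grad_cpp(p, idx, nb, counts_i, pp, disc, beta, lambda)
      cache$par <- p; cache$value <- r$value; cache$grad <- r$gradient
      cache$nll <- r$nll; cache$pen <- r$penalty
    }
  }
  opt <- stats::optim(par0,
                      fn = function(p) { evalp(p); cache$value },
                      gr = function(p) { evalp(p); cache$grad },
                      method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e7))
  u <- unpack_par(opt$par, layout)
  final <- ln_nll_grad_cpp(opt$par, idx, nb, counts_i, pp, disc, beta, lambda)
  m <- list(variables = variables, bias = u$bias, weights = u$weights,
            specs = lapply(variables, function(v) blocks[[v]]$spec),
            dt = dt, beta = beta, lambda = lambda, par = opt$par,
            value = final$value, nll = final$nll, penalty = final$penalty,
            convergence = opt$convergence, message = opt$message)
  names(m$specs) <- variables
  class(m) <- "fitted_model"
  if (opt$convergence == 1L)
    warning("fit_ln: iteration cap reached before convergence")
  m
}

# Unpenalized Poisson log-likelihood of a fitted model on a frame subset.
model_loglik <- function(model, blocks, counts, rows = NULL) {
  if (is.null(rows)) rows <- seq_along(counts)
  if (length(model$variables) == 0)
    return(sum(counts[rows]) * model$bias - length(rows) * exp(model$bias))
  ln_loglik_cpp(model$par,
                lapply(model$variables, function(v) blocks[[v]]$index),
                as.integer(vapply(model$variables, function(v)
                  blocks[[v]]$spec$bin_count, integer(1))),
                as.integer(counts), as.integer(rows))
}

#' Contiguous-chunk cross-validation folds
#'
#' Partitions `n` frames into `n_chunks` contiguous chunks assigned
#' round-robin to `n_folds` folds -- a pure function of `n`, so fold
#' boundaries are reproducible. Chunking balances fold occupancy against
#' leakage from the strong temporal autocorrelation of the task state.
#'
#' @param n Number of frames.
#' @param n_folds,n_chunks Fold and chunk counts.
#' @return List of `n_folds` integer index vectors.
#' @export
make_folds <- function(n, n_folds = 10, n_chunks = 50) {
  stopifnot(n >= n_chunks, n_chunks %% n_folds == 0)
  bounds <- floor(seq(0, n, length.out = n_chunks + 1))
  lapply(seq_len(n_folds), function(f) {
    chunks <- seq(f, n_chunks, by = n_folds)
    unlist(lapply(chunks, function(ch) (bounds[ch] + 1L):bounds[ch + 1L]))
  })
}

#' Cross-validated log-likelihood increase (LLi) of a variable set
#'
#' Ten-fold cross-validation of the LN model: for each fold the model and
#' the mean-firing-rate null are trained on the remaining folds and the
#' spike-normalized held-out log-likelihood difference
#' `(LL_model - LL_null) / n_spikes` is recorded. The empty variable set is
#' the null model itself and returns exactly zero in every fold.
#'
#' @inheritParams fit_ln
#' @param n_folds,n_chunks See [make_folds()].
#' @param init Optional warm start (defaults to the full-data fit, which is
#'   also returned).
#' @return `list(lli = <n_folds values>, model = <full-data fit>)`.
#' @export
cross_validate <- function(blocks, counts, dt, variables,
                           beta = 20, lambda = 1,
                           n_folds = 10, n_chunks = 50, init = NULL) {
  n <- length(counts)
  folds <- make_folds(n, n_folds, n_chunks)
  if (length(variables) == 0) {
    return(list(lli = rep(0, n_folds),
                model = fit_ln(blocks, counts, dt, character(0))))
  }
  full <- fit_ln(blocks, counts, dt, variables, beta, lambda, init = init)
  lli <- vapply(folds, function(test) {
    nsp <- sum(counts[test])
    if (nsp == 0)
      stop("a cross-validation fold contains no spikes; use a longer session")
    train <- setdiff(seq_len(n), test)
    m <- fit_ln(blocks, counts, dt, variables, beta, lambda,
                rows = train, init = full$par)
    null <- fit_ln(blocks, counts, dt, character(0), rows = train)
    (model_loglik(m, blocks, counts, test) -
        model_loglik(null, blocks, counts, test)) / nsp
  }, numeric(1))
  list(lli = lli, model = full)
}

#' Forward model selection over task variables
#'
#' Greedy forward search: at each step every remaining candidate is added to
#' the current model, the ten-fold held-out LLi is computed, and the
#' candidate with the largest median LLi is kept only if it significantly
#' improves on the current model (one-sided Wilcoxon signed-rank test on the
#' paired fold LLi values, alpha = 0.05) and strictly increases the median.
#' A neuron whose best single model already fails the test is returned as
#' tuned to nothing (empty selection).
#'
#' @inheritParams cross_validate
#' @param candidates Candidate variable names (default all blocks).
#' @param alpha Acceptance level of the signed-rank test.
#' @return A `selection_result`: `selected` (ordered), `steps` (one row per
#'   accepted step with p-value and median LLi), `fold_lli` of the final
#'   model, `single_lli` (per-candidate fold LLi of the single-variable
#'   models, for population analyses), and `model`, the final full-data fit.
#' @export
forward_select <- function(blocks, counts, dt, candidates = names(blocks),
                           beta = 20, lambda = 1, alpha = 0.05,
                           n_folds = 10, n_chunks = 50) {
  stopifnot(length(candidates) >= 1)
  selected <- character(0)
  cur_lli <- rep(0, n_folds)
  cur_model <- fit_ln(blocks, counts, dt, character(0))
  steps <- list()
  single_lli <- NULL
  repeat {
    rem <- setdiff(candidates, selected)
    if (length(rem) == 0) break
    cvs <- lapply(rem, function(v)
      cross_validate(blocks, counts, dt, c(selected, v), beta, lambda,
                     n_folds, n_chunks))
    names(cvs) <- rem
    med <- vapply(cvs, function(cv) stats::median(cv$lli), numeric(1))
    if (length(selected) == 0)
      single_lli <- lapply(cvs, `[[`, "lli")
    best <- rem[which.max(med)]
    d <- cvs[[best]]$lli - cur_lli
    p <- if (all(d == 0)) 1 else
      stats::wilcox.test(d, alternative = "greater")$p.value
    if (p < alpha && stats::median(cvs[[best]]$lli) > stats::median(cur_lli)) {
      selected <- c(selected, best)
      cur_lli <- cvs[[best]]$lli
      cur_model <- cvs[[best]]$model
      steps[[length(steps) + 1L]] <-
        data.frame(variable = best, p = p,
                   median_lli = stats::median(cur_lli),
                   stringsAsFactors = FALSE)
    } else break
  }
  res <- list(selected = selected,
              steps = if (length(steps) > 0) do.call(rbind, steps) else
                data.frame(variable = character(0), p = numeric(0),
                           median_lli = numeric(0)),
              fold_lli = cur_lli, single_lli = single_lli,
              model = cur_model)
  class(res) <- "selection_result"
  res
}

#' @export
print.selection_result <- function(x, ...) {
  if (length(x$selected) == 0) {
    cat("LN forward selection: not tuned to any candidate variable\n")
  } else {
    cat("LN forward selection:", paste(x$selected, collapse = " + "), "\n")
    print(x$steps, row.names = FALSE)
  }
  invisible(x)
}
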