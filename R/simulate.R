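#' Monte Carlo scenario configuration
#'
#' Describes one benchmark cell of the simulation study: `n` samples whose
#' modulators are drawn from U(-1, 1), `n_genes` genes (one target,
#' `n_genes - 1` regulators with AR(1) correlation `rho`), a random
#' `nonzero_fraction` of regulators carrying signal, and per-sample varying
#' coefficients drawn from a scenario-specific uniform range:
#' Scenario 1: U(0.1, 1); 2: U(0.9, 1); 3: U(-1, -0.1); 4: U(-1, -0.9).
#' Within a signal column the draws are ordered against the modulator
#' (descending for `type = 1`, ascending for `type = 2`), and the
#' `zero_sample_fraction` of samples with the largest modulator values get
#' zero coefficients. Targets are generated as
#' \eqn{y_i = r_i^\top \beta(m_i) + \epsilon_i}, \eqn{\epsilon_i \sim
#' N(0, \mathrm{noise\_sd}^2)}.
#'
#' @param n samples (default 300).
#' @param n_genes network size p + 1 (default 50).
#' @param scenario 1-4.
#' @param type 1 (descending in the modulator) or 2 (ascending).
#' @param rho regulator AR(1) autocorrelation (default 0.5).
#' @param nonzero_fraction fraction of regulators with signal (default 0.10).
#' @param zero_sample_fraction fraction of samples with all-zero
#'   coefficients (default 0.05).
#' @param noise_sd residual standard deviation (default 1).
#' @param n_targets number of target samples per iteration (default 40).
#' @param iterations Monte Carlo iterations (default 20).
#' @param seed integer seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n = 300L, n_genes = 50L, scenario = 1L,
                            type = 1L, rho = 0.5, nonzero_fraction = 0.10,
                            zero_sample_fraction = 0.05, noise_sd = 1,
                            n_targets = 40L, iterations = 20L, seed = 0L) {
  stopifnot(scenario %in% 1:4, type %in% 1:2, abs(rho) < 1,
            nonzero_fraction > 0, nonzero_fraction < 1,
            zero_sample_fraction > 0, zero_sample_fraction < 1,
            n_targets <= n, n_genes >= 3)
  structure(as.list(environment()), class = "scenario_config")
}

scenario_range <- function(scenario) {
  switch(scenario,
         c(0.1, 1), c(0.9, 1), c(-1, -0.1), c(-1, -0.9))
}

#' Generate AR(1)-correlated regulator expression
#'
#' Rows are i.i.d. N(0, Sigma) with \eqn{\Sigma_{jk} = \rho^{|j-k|}},
#' generated by the sequential AR recursion.
#'
#' @param n samples.
#' @param p regulators.
#' @param rho autocorrelation, |rho| < 1.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return An n x p matrix.
#' @export
generate_regulators <- function(n, p, rho = 0.5, seed = NULL) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  with_seed(seed, {
    R <- matrix(0, n, p)
    R[, 1] <- rnorm(n)
    if (p > 1) {
      s <- sqrt(1 - rho^2)
      for (j in 2:p) R[, j] <- rho * R[, j - 1] + s * rnorm(n)
    }
    R
  })
}

#' Generate the true varying coefficients
#'
#' @param cfg a [scenario_config()].
#' @param m modulator vector of length `cfg$n`.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return An n x p matrix of true coefficients (row i is \eqn{\beta(m_i)}),
#'   with attribute `"signal_columns"`.
#' @export
generate_varying_coefficients <- function(cfg, m, seed = NULL) {
  p <- cfg$n_genes - 1L
  n <- cfg$n
  stopifnot(length(m) == n, all(is.finite(m)))
  n_sig <- round(cfg$nonzero_fraction * p)
  if (n_sig < 1) stop("fewer than 1 signal column at this size")
  n_zero <- round(cfg$zero_sample_fraction * n)
  rg <- scenario_range(cfg$scenario)
  with_seed(seed, {
    sig <- sort(sample.int(p, n_sig))
    beta <- matrix(0, n, p)
    ord <- order(m)                      # samples by increasing modulator
    nz <- ord[seq_len(n - n_zero)]       # zeros go to the largest modulators
    for (j in sig) {
      v <- sort(runif(n - n_zero, rg[1], rg[2]),
                decreasing = (cfg$type == 1L))
      beta[nz, j] <- v
    }
    attr(beta, "signal_columns") <- sig
    beta
  })
}

#' Generate target-gene expression from the varying-coefficient model
#'
#' @param R n x p regulator matrix.
#' @param beta_true n x p true coefficient matrix.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed (`NULL` to use the current RNG stream).
#' @return Numeric response vector of length n.
#' @export
generate_targets <- function(R, beta_true, noise_sd = 1, seed = NULL) {
  stopifnot(identical(dim(R), dim(beta_true)))
  with_seed(seed, rowSums(R * beta_true) + rnorm(nrow(R), sd = noise_sd))
}

#' Simulate one complete benchmark dataset
#'
#' @param cfg a [scenario_config()].
#' @param seed integer seed; defaults to `cfg$seed`.
#' @return A `simulated_dataset`: `R`, `beta_true`, `y`, `m`,
#'   `target_indices`, `signal_columns`, `cfg`.
#' @export
simulate_dataset <- function(cfg, seed = cfg$seed) {
  with_seed(seed, {
    m <- runif(cfg$n, -1, 1)
    R <- generate_regulators(cfg$n, cfg$n_genes - 1L, cfg$rho, seed = NULL)
    beta_true <- generate_varying_coefficients(cfg, m, seed = NULL)
    y <- generate_targets(R, beta_true, cfg$noise_sd, seed = NULL)
    targets <- sort(sample.int(cfg$n, cfg$n_targets))
    structure(
      list(R = R, beta_true = beta_true, y = y, m = m,
           target_indices = targets,
           signal_columns = attr(beta_true, "signal_columns"), cfg = cfg),
      class = "simulated_dataset")
  })
}

#' Edge-selection accuracy (TNR, TPR, balanced)
#'
#' Pools all (regulator, target sample) entries: TPR is the fraction of truly
#' nonzero coefficients estimated nonzero, TNR the fraction of truly zero
#' coefficients estimated zero, and `balanced` their unweighted mean.
#'
#' @param beta_true_at_targets,beta_est matrices of the same shape
#'   (target samples x regulators).
#' @return Named numeric vector `tnr`, `tpr`, `balanced`.
#' @export
evaluate_selection <- function(beta_true_at_targets, beta_est) {
  stopifnot(identical(dim(beta_true_at_targets), dim(beta_est)))
  tz <- beta_true_at_targets == 0
  if (!any(tz) || all(tz))
    stop("undefined rate: pool has no true zeros or no true nonzeros")
  ez <- beta_est == 0
  tnr <- sum(tz & ez) / sum(tz)
  tpr <- sum(!tz & !ez) / sum(!tz)
  c(tnr = tnr, tpr = tpr, balanced = (tnr + tpr) / 2)
}

#' Mean absolute error of edge-weight estimation
#'
#' \deqn{\mathrm{MAE} = \frac{1}{\omega} \sum_{\alpha=1}^{\omega}
#'   \sum_{j=1}^{p} |\beta_{j\alpha} - \hat\beta_{j\alpha}|}
#' (summed, not averaged, over regulators).
#'
#' @inheritParams evaluate_selection
#' @return A single number.
#' @export
evaluate_mae <- function(beta_true_at_targets, beta_est) {
  stopifnot(identical(dim(beta_true_at_targets), dim(beta_est)))
  mean(rowSums(abs(beta_true_at_targets - beta_est)))
}

#' Mean squared prediction error at the target samples
#'
#' Mean over (target gene, target sample) of
#' \eqn{(y_{\alpha} - r_\alpha^\top \hat\beta_{\alpha})^2}.
#'
#' @param y observed responses at the target samples.
#' @param R regulator rows at the target samples.
#' @param beta_est estimated coefficients (target samples x regulators).
#' @return A single number.
#' @export
evaluate_mse_prediction <- function(y, R, beta_est) {
  stopifnot(length(y) == nrow(R), identical(dim(R), dim(beta_est)))
  mean((y - rowSums(R * beta_est))^2)
}

#' Run the edge-selection / weight-estimation benchmark
#'
#' For each iteration: simulate a dataset under `cfg`, select (lambda, pi, h)
#' for every target sample under every requested criterion, and accumulate
#' TNR/TPR (pooled over entries), MAE and prediction MSE. Fits are shared
#' across criteria: the grid is evaluated once per target sample and each
#' criterion picks its own minimizer.
#'
#' @param cfg a [scenario_config()].
#' @param criteria character vector of criteria (see
#'   [select_hyperparameters()]).
#' @param grid a [search_grid()]; defaults to `search_grid(m)` per iteration.
#' @param verbose print per-iteration progress.
#' @return A `benchmark_report`: data frame `summary` (one row per
#'   criterion: tnr, tpr, balanced, mae, mse) plus `per_iteration` and `cfg`.
#' @export
run_benchmark <- function(cfg, criteria = "gic", grid = NULL,
                          verbose = FALSE, scale_y = TRUE, ...) {
  stopifnot(inherits(cfg, "scenario_config"))
  criteria <- match.arg(criteria, criterion_names(), several.ok = TRUE)
  iter_seeds <- with_seed(cfg$seed,
                          sample.int(2^31 - 2, cfg$iterations))
  acc <- lapply(criteria, function(cn)
    list(tp = 0, fn = 0, tn = 0, fp = 0, mae = numeric(0), mse = numeric(0)))
  names(acc) <- criteria
  per_iter <- list()
  for (it in seq_len(cfg$iterations)) {
    ds <- simulate_dataset(cfg, seed = iter_seeds[it])
    # fit on centered/scaled columns; report coefficients on the data scale
    ys <- as.numeric(scale(ds$y, scale = scale_y))
    sy <- if (scale_y) sd(ds$y) else 1
    Rs <- scale(ds$R)
    sR <- attr(Rs, "scaled:scale")
    g <- if (is.null(grid)) search_grid(ds$m) else grid
    est <- lapply(criteria, function(cn)
      matrix(0, cfg$n_targets, cfg$n_genes - 1L))
    names(est) <- criteria
    for (ti in seq_along(ds$target_indices)) {
      a <- ds$target_indices[ti]
      res <- evaluate_search(ys, Rs, ds$m, ds$m[a], g, criteria = criteria,
                             seed = child_seed(iter_seeds[it], ti), ...)
      for (cn in criteria)
        est[[cn]][ti, ] <- res$best[[cn]]$beta * sy / sR
    }
    truth <- ds$beta_true[ds$target_indices, , drop = FALSE]
    yt <- ds$y[ds$target_indices]
    Rt <- ds$R[ds$target_indices, , drop = FALSE]
    for (cn in criteria) {
      tz <- truth == 0
      ez <- est[[cn]] == 0
      acc[[cn]]$tn <- acc[[cn]]$tn + sum(tz & ez)
      acc[[cn]]$fp <- acc[[cn]]$fp + sum(tz & !ez)
      acc[[cn]]$tp <- acc[[cn]]$tp + sum(!tz & !ez)
      acc[[cn]]$fn <- acc[[cn]]$fn + sum(!tz & ez)
      acc[[cn]]$mae <- c(acc[[cn]]$mae, evaluate_mae(truth, est[[cn]]))
      acc[[cn]]$mse <- c(acc[[cn]]$mse,
                         evaluate_mse_prediction(yt, Rt, est[[cn]]))
      per_iter[[length(per_iter) + 1L]] <- data.frame(
        iteration = it, criterion = cn,
        tnr = sum(tz & ez) / sum(tz), tpr = sum(!tz & !ez) / sum(!tz),
        mae = acc[[cn]]$mae[it], mse = acc[[cn]]$mse[it])
    }
    if (verbose) message("iteration ", it, "/", cfg$iterations, " done")
  }
  summary <- do.call(rbind, lapply(criteria, function(cn) {
    a <- acc[[cn]]
    tnr <- a$tn / (a$tn + a$fp)
    tpr <- a$tp / (a$tp + a$fn)
    data.frame(criterion = cn, tnr = tnr, tpr = tpr,
               balanced = (tnr + tpr) / 2,
               mae = mean(a$mae), mse = mean(a$mse))
  }))
  structure(list(summary = summary,
                 per_iteration = do.call(rbind, per_iter), cfg = cfg),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  cat("Benchmark: scenario", x$cfg$scenario, "type", x$cfg$type, "|",
      x$cfg$n_genes, "genes,", x$cfg$iterations, "iterations,",
      x$cfg$n_targets, "target samples\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
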