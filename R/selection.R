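#' Hyperparameter search grid
#'
#' Defines the grid over which (lambda, pi, h) are selected. The lambda path
#' is recomputed per (pi, h): 'n_lambda' values log-spaced from
#' \eqn{\lambda_{max} = \max_j |R^{*\top}y^*|_j / \max(\pi, 0.001)} (the
#' smallest lambda at which all coefficients are zero) down to
#' `lambda_min_ratio` times it. Bandwidths default to `n_bandwidths`
#' log-spaced values spanning `bandwidth_range` times the modulator standard
#' deviation.
#'
#' @param m modulator values, used for the default bandwidths; optional if
#'   `bandwidths` is supplied.
#' @param n_lambda number of lambda values per (pi, h).
#' @param lambda_min_ratio ratio of the smallest to the largest lambda.
#' @param lambdas optional explicit lambda values (overrides the path rule).
#' @param pis mixing-parameter values in (0, 1].
#' @param bandwidths optional explicit bandwidth values.
#' @param n_bandwidths,bandwidth_range default-bandwidth controls.
#' @return A `search_grid` object.
#' @export
search_grid <- function(m = NULL, n_lambda = 50L, lambda_min_ratio = 1e-3,
                        lambdas = NULL,
                        pis = c(0.1, 0.3, 0.5, 0.7, 0.9, 1.0),
                        bandwidths = NULL, n_bandwidths = 8L,
                        bandwidth_range = c(0.05, 2)) {
  if (is.null(bandwidths)) {
    if (is.null(m))
      stop("supply either modulator values m or explicit bandwidths")
    s <- stats::sd(m)
    if (!is.finite(s) || s <= 0) stop("modulator has zero spread")
    bandwidths <- exp(seq(log(bandwidth_range[1] * s),
                          log(bandwidth_range[2] * s),
                          length.out = n_bandwidths))
  }
  if (any(bandwidths <= 0) || any(pis <= 0) || any(pis > 1))
    stop("bandwidths must be positive and pis in (0, 1]")
  if (!is.null(lambdas)) {
    if (any(lambdas < 0)) stop("lambdas must be >= 0")
    lambdas <- sort(lambdas, decreasing = TRUE)
  }
  structure(list(n_lambda = as.integer(n_lambda),
                 lambda_min_ratio = lambda_min_ratio,
                 lambdas = lambdas, pis = pis,
                 bandwidths = sort(bandwidths, decreasing = TRUE)),
            class = "search_grid")
}

lambda_path <- function(grid, cmax, pi) {
  if (!is.null(grid$lambdas)) return(grid$lambdas)
  lam_max <- max(cmax, 1e-8) / max(pi, 1e-3)
  exp(seq(log(lam_max), log(lam_max * grid$lambda_min_ratio),
          length.out = grid$n_lambda))
}

criterion_names <- function() c("gic", "aic", "aicc", "bic", "hqc",
                                "ebic", "bicp", "cv")

# Candidate-vs-incumbent comparison with the tie-break order:
# smaller value, then larger lambda, then larger h, then larger pi.
cand_beats <- function(value, lambda, h, pi, inc) {
  if (is.null(inc) || value < inc$value) return(value < Inf)
  if (value > inc$value) return(FALSE)
  if (lambda != inc$lambda) return(lambda > inc$lambda)
  if (h != inc$h) return(h > inc$h)
  pi > inc$pi
}

# Exhaustive grid evaluation for one target sample on raw (transformed-scale)
# y, R. Returns the best point per requested criterion plus the full trace.
evaluate_search <- function(y, R, m, m_alpha, grid, criteria = "gic",
                            seed = 0L, cv_k = 10L, tol = 1e-7, maxit = 1e5,
                            cv_tol = 1e-4, path_sweep_cap = 100L,
                            gic_sigma = c("mle", "unbiased"),
                            gic_ll = c("hetero", "homo"),
                            gic_scale_penalty = FALSE,
                            keep_trace = FALSE, floor = 1e-8) {
  gic_sigma <- match.arg(gic_sigma)
  gic_ll <- match.arg(gic_ll)
  criteria <- match.arg(criteria, criterion_names(), several.ok = TRUE)
  p <- ncol(R)
  best <- setNames(vector("list", length(criteria)), criteria)
  trace <- if (keep_trace) vector("list", 0) else NULL
  n_ok <- 0L
  for (hi in seq_along(grid$bandwidths)) {
    h <- grid$bandwidths[hi]
    w <- tryCatch(gaussian_kernel_weights(m, m_alpha, h, floor = floor),
                  error = function(e) NULL)
    if (is.null(w)) next
    d <- build_weighted_design(y, R, w)
    # classical criteria use the homoskedastic Gaussian MLE likelihood
    # (sigma2 = RSS*/n') on the weighted design, as glmnet-era information
    # criteria do
    n_full <- d$n
    G <- crossprod(d$R_star)
    cc <- crossprod(d$R_star, d$y_star)[, 1]
    foldid <- NULL
    if ("cv" %in% criteria) {
      if (d$n < cv_k) next
      foldid <- with_seed(child_seed(seed, hi),
                          sample(rep(seq_len(cv_k), length.out = d$n)))
    }
    for (pi_mix in grid$pis) {
      lams <- lambda_path(grid, max(abs(cc)), pi_mix)
      # grid points are solved under a sweep cap; the winning point is
      # re-solved to full tolerance below if it hit the cap
      path <- cpp_enet_path(G, cc, lams, pi_mix, tol,
                            as.integer(path_sweep_cap))
      gic_thresh <- if (keep_trace || is.null(best[["gic"]])) Inf else
        best[["gic"]]$value + 20
      crit <- cpp_path_criteria(d$R_star, d$y_star, d$weights, G, path$beta,
                                lams, pi_mix, 1e-10, "gic" %in% criteria,
                                gic_sigma == "mle", gic_ll == "homo",
                                gic_scale_penalty, gic_thresh)
      df <- as.numeric(crit$df)
      m2l <- -2 * as.numeric(crit$loglik)
      gic_bias <- as.numeric(crit$gic_bias)
      m2l_c <- n_full * (log(2 * base::pi * as.numeric(crit$rss) / n_full) + 1)
      vals <- list()
      for (cn in criteria) {
        v <- switch(cn,
          gic = m2l + 2 * gic_bias,
          aic = m2l_c + 2 * df,
          aicc = ifelse(df < n_full - 1,
                        m2l_c + 2 * df + 2 * df * (df + 1) / (n_full - df - 1),
                        Inf),
          bic = m2l_c + df * log(n_full),
          hqc = m2l_c + 2 * df * log(log(n_full)),
          ebic = m2l_c + df * log(n_full) + 2 * 0.5 * lchoose(p, df),
          bicp = m2l_c + df * (log(n_full) + 2 * log(p)),
          cv = as.numeric(cpp_cv_error(d$R_star, d$y_star, d$weights, G, cc,
                                       as.integer(foldid), as.integer(cv_k),
                                       lams, pi_mix, cv_tol,
                                       as.integer(path_sweep_cap)))
        )
        v[!is.finite(v)] <- Inf
        vals[[cn]] <- v
        vmin <- min(v)
        if (is.finite(vmin)) {
          # within a block lambda is the only varying tie-break and the path
          # is descending, so the first minimizer has the largest lambda
          l <- which(v == vmin)[1]
          if (cand_beats(vmin, lams[l], h, pi_mix, best[[cn]])) {
            best[[cn]] <- list(beta = path$beta[, l], lambda = lams[l],
                               pi = pi_mix, h = h, value = vmin,
                               df = df[l], n_retained = d$n,
                               capped = path$iterations[l] < 0)
          }
        }
      }
      n_ok <- n_ok + length(lams)
      if (keep_trace) {
        block <- data.frame(h = h, pi = pi_mix, lambda = lams, df = df,
                            loglik = crit$loglik)
        for (cn in criteria) block[[cn]] <- vals[[cn]]
        trace[[length(trace) + 1L]] <- block
      }
    }
  }
  if (n_ok == 0L || all(vapply(best, is.null, logical(1))))
    stop("selection failed: all grid points degenerate")
  for (cn in criteria) {
    b <- best[[cn]]
    if (!is.null(b) && isTRUE(b$capped)) {
      w <- gaussian_kernel_weights(m, m_alpha, b$h, floor = floor)
      d <- build_weighted_design(y, R, w)
      G <- crossprod(d$R_star)
      cc <- crossprod(d$R_star, d$y_star)[, 1]
      rs <- cpp_enet_path(G, cc, b$lambda, b$pi, tol, as.integer(maxit),
                          b$beta)
      best[[cn]]$beta <- rs$beta[, 1]
      best[[cn]]$capped <- FALSE
    }
  }
  list(best = best,
       trace = if (keep_trace) do.call(rbind, trace) else NULL)
}

#' Select hyperparameters for one (target gene, target sample) pair
#'
#' Exhaustively evaluates the search grid and returns the fit minimizing the
#' chosen criterion; ties are broken toward larger lambda, then larger
#' bandwidth, then larger pi. Coefficients are reported on the original
#' expression scale (the fit itself runs on centered/scaled columns).
#'
#' @param data an [expression_dataset()].
#' @param mod a [modulator_profile()].
#' @param target_gene gene id to use as target (all other genes are
#'   candidate regulators).
#' @param target_sample sample id whose network is estimated.
#' @param grid a [search_grid()]; defaults to `search_grid(mod$m)`.
#' @param criterion `"gic"`, `"aic"`, `"aicc"`, `"bic"`, `"hqc"`, `"ebic"`,
#'   `"bicp"` or `"cv"`.
#' @param seed integer seed (used by the CV fold draw).
#' @param keep_trace keep the full per-grid-point criterion trace.
#' @param ... further options passed to the grid evaluator, e.g.
#'   `gic_sigma` (`"mle"` or `"unbiased"` residual-variance estimator) and
#'   `gic_scale_penalty` (`TRUE` scales the penalty-curvature matrix by
#'   1/n' inside the GIC bias term; see the methods vignette).
#' @return A `netgic_fit`: `beta` (original scale, named by regulator),
#'   `beta_std` (fit scale), `hyper` (lambda, pi, h), `criterion`,
#'   `target_gene`, `target_sample`, and optionally `trace`.
#' @export
select_hyperparameters <- function(data, mod, target_gene, target_sample,
                                   grid = NULL, criterion = "gic",
                                   seed = 0L, keep_trace = TRUE, ...) {
  stopifnot(inherits(data, "expression_dataset"),
            inherits(mod, "modulator_profile"))
  criterion <- match.arg(criterion, criterion_names())
  si <- match(target_sample, data$sample_ids)
  if (is.na(si)) stop("unknown target sample: ", target_sample)
  if (!setequal(mod$sample_ids, data$sample_ids))
    stop("modulator and expression sample ids differ")
  m <- mod$m[data$sample_ids]
  if (is.null(grid)) grid <- search_grid(m)
  td <- target_design(data, target_gene)
  res <- evaluate_search(td$y, td$R, m, m[si], grid, criteria = criterion,
                         seed = seed, keep_trace = keep_trace, ...)
  b <- res$best[[criterion]]
  gi <- td$target_index
  beta_orig <- b$beta * data$scales[gi] / data$scales[-gi]
  structure(
    list(beta = setNames(beta_orig, td$regulators),
         beta_std = setNames(b$beta, td$regulators),
         hyper = list(lambda = b$lambda, pi = b$pi, h = b$h),
         criterion = new_criterion_report(criterion, b$value, b$df,
                                          list(n_retained = b$n_retained)),
         target_gene = target_gene, target_sample = target_sample,
         trace = res$trace),
    class = "netgic_fit"
  )
}

#' @export
print.netgic_fit <- function(x, ...) {
  cat("Personalized fit for gene", x$target_gene, "at sample",
      x$target_sample, "\n  ", toupper(x$criterion$name), "=",
      format(x$criterion$value), "| lambda =", format(x$hyper$lambda),
      "pi =", x$hyper$pi, "h =", format(x$hyper$h), "| df =",
      x$criterion$df, "\n")
  invisible(x)
}

#' Fit personalized networks for a set of target samples
#'
#' Runs [select_hyperparameters()] for every gene as target (all remaining
#' genes as regulators; no self-edges) and every target sample, returning the
#' coefficient tensor indexed (target gene, regulator, target sample).
#' Per-(gene, sample) failures are recorded and skipped, not fatal.
#'
#' @inheritParams select_hyperparameters
#' @param target_samples sample ids whose networks to estimate (default all).
#' @param ... passed on to [select_hyperparameters()].
#' @param verbose print per-fit progress to stderr.
#' @return A `personalized_network`: `coef` (q x q x n_targets array with
#'   `NA` on the self-edge diagonal), `gene_ids`, `target_samples`,
#'   `modulator` (values at the targets), `hyper` (per-fit data frame),
#'   `failures`.
#' @export
fit_personalized_network <- function(data, mod, target_samples = NULL,
                                     grid = NULL, criterion = "gic",
                                     seed = 0L, verbose = FALSE, ...) {
  stopifnot(inherits(data, "expression_dataset"))
  if (is.null(target_samples)) target_samples <- data$sample_ids
  if (length(target_samples) < 1) stop("need at least one target sample")
  q <- length(data$gene_ids)
  if (is.null(grid)) grid <- search_grid(mod$m[data$sample_ids])
  coef <- array(NA_real_,
                dim = c(q, q, length(target_samples)),
                dimnames = list(target = data$gene_ids,
                                regulator = data$gene_ids,
                                sample = target_samples))
  hyper <- list()
  failures <- list()
  for (g in data$gene_ids) {
    for (a in target_samples) {
      fit <- tryCatch(
        select_hyperparameters(data, mod, g, a, grid = grid,
                               criterion = criterion,
                               seed = child_seed(seed, match(g, data$gene_ids),
                                                 match(a, target_samples)),
                               keep_trace = FALSE, ...),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[length(failures) + 1L]] <-
          list(gene = g, sample = a, message = conditionMessage(fit))
        if (verbose) message("failed: ", g, " @ ", a, ": ",
                             conditionMessage(fit))
        next
      }
      coef[g, names(fit$beta), a] <- fit$beta
      hyper[[length(hyper) + 1L]] <-
        data.frame(target = g, sample = a, lambda = fit$hyper$lambda,
                   pi = fit$hyper$pi, h = fit$hyper$h,
                   value = fit$criterion$value, df = fit$criterion$df)
      if (verbose) message("fitted: ", g, " @ ", a)
    }
  }
  structure(
    list(coef = coef, gene_ids = data$gene_ids,
         target_samples = target_samples,
         modulator = mod$m[target_samples],
         criterion = criterion,
         hyper = if (length(hyper)) do.call(rbind, hyper) else NULL,
         failures = failures),
    class = "personalized_network"
  )
}

#' @export
print.personalized_network <- function(x, ...) {
  cat("Personalized network:", length(x$gene_ids), "genes x",
      length(x$target_samples), "target samples (criterion:",
      x$criterion, ")\n")
  if (length(x$failures))
    cat("  ", length(x$failures), "failed fits\n")
  invisible(x)
}
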