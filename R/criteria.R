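#' Curvature of the elastic-net penalty at the fitted coefficients
#'
#' The local-quadratic-approximation curvature
#' \eqn{P'(|\hat\beta_j|)/|\hat\beta_j| = \lambda\{(1-\pi) + \pi/|\hat\beta_j|\}}
#' over the active set; it forms the diagonal matrix
#' \eqn{\Sigma_\lambda(\hat\beta)} in the GIC bias term. Zero coefficients are
#' excluded (the LQA argument fixes them at zero), never divided by.
#'
#' @param fit an `enet_fit`.
#' @param pen a [penalty_config()]; defaults to the penalty stored in `fit`.
#' @return A `penalty_curvature` object: `diag` (named by active index) and
#'   `active_set`.
#' @export
penalty_curvature <- function(fit, pen = fit$penalty) {
  stopifnot(inherits(fit, "enet_fit"))
  pen <- as_penalty(pen)
  act <- fit$active_set
  d <- pen$lambda * ((1 - pen$pi) + pen$pi / abs(fit$beta[act]))
  structure(list(diag = d, active_set = act), class = "penalty_curvature")
}

new_criterion_report <- function(name, value, df, details = list()) {
  structure(list(name = name, value = value, df = df, details = details),
            class = "criterion_report")
}

# Gaussian log-likelihood of the weighted fit on the starred scale,
# Var(y*_i) = w_i * sigma2.
model_loglik <- function(design, fit, noise) {
  resid <- as.numeric(design$y_star - design$R_star %*% fit$beta)
  vs <- noise$per_sample
  -0.5 * (design$n * log(2 * pi) + sum(log(vs)) + sum(resid^2 / vs))
}

#' Sample-specific generalized information criterion (GIC)
#'
#' Evaluates the penalized, kernel-weighted fit by
#' \deqn{\mathrm{GIC} = -2\sum_i \log f(y^*_i \mid r^*_i, \hat\beta)
#'   + 2\,\mathrm{tr}\{R(\hat G)^{-1} Q(\hat G)\},}
#' where, restricted to the active set \eqn{A},
#' \deqn{R(\hat G) = \tfrac1{n'} R^{*\top}_A R^*_A + \Sigma_\lambda, \qquad
#'  Q(\hat G) = \tfrac1{n'}\{ R^{*\top}_A \hat\Lambda^2 R^*_A
#'   - \Sigma_\lambda \hat\beta_A \mathbf{1}^\top \hat\Lambda R^*_A \},}
#' \eqn{\hat\Lambda = \mathrm{diag}\{(y^*_i - r^{*\top}_i\hat\beta)/\sigma^{*2}_i\}}
#' and \eqn{\Sigma_\lambda} the [penalty_curvature()] diagonal. The density is
#' Gaussian with per-sample variance \eqn{\sigma^{*2}_i = w_i\hat\sigma^2}.
#' The bias term generalizes the AIC penalty to estimators that are not
#' maximum likelihood (here: penalized, kernel-weighted least squares).
#'
#' @param design a [build_weighted_design()] object.
#' @param fit an `enet_fit`.
#' @param noise an [estimate_noise_scale()] object.
#' @param pen penalty; defaults to the one stored in `fit`.
#' @param jitter ridge added to \eqn{R(\hat G)} if it is numerically singular.
#' @return A `criterion_report` with `value`, `df` and a `details` list
#'   (`loglik`, `bias`, `R_hat`, `Q_hat`).
#' @export
compute_gic <- function(design, fit, noise, pen = fit$penalty,
                        jitter = 1e-10) {
  stopifnot(inherits(design, "weighted_design"),
            inherits(fit, "enet_fit"), inherits(noise, "noise_scale"))
  pen <- as_penalty(pen)
  if (noise$sigma2 <= 0) stop("degenerate noise scale")
  ll <- model_loglik(design, fit, noise)
  act <- fit$active_set
  if (length(act) == 0L) {
    return(new_criterion_report("gic", -2 * ll, 0L,
                                list(loglik = ll, bias = 0,
                                     empty_active_set = TRUE)))
  }
  n <- design$n
  XA <- design$R_star[, act, drop = FALSE]
  resid <- as.numeric(design$y_star - design$R_star %*% fit$beta)
  lam_d <- resid / noise$per_sample
  sl <- penalty_curvature(fit, pen)$diag
  R_hat <- crossprod(XA) / n + diag(sl, length(act))
  Q_hat <- (crossprod(XA * lam_d^2, XA) -
              (sl * fit$beta[act]) %*% t(crossprod(XA, lam_d))) / n
  inv <- tryCatch(solve(R_hat), error = function(e) {
    warning("near-singular R(G-hat); jitter applied")
    solve(R_hat + diag(jitter, length(act)))
  })
  bias <- sum(diag(inv %*% Q_hat))
  new_criterion_report("gic", -2 * ll + 2 * bias, length(act),
                       list(loglik = ll, bias = bias,
                            R_hat = R_hat, Q_hat = Q_hat))
}

#' Classical information criteria for a fitted model
#'
#' Comparator criteria computed from the (weighted) log-likelihood and the
#' number of nonzero coefficients `df`:
#' AIC \eqn{= -2\ell + 2\,df}; BIC \eqn{= -2\ell + df\log n};
#' AICc \eqn{= \mathrm{AIC} + 2df(df+1)/(n-df-1)};
#' HQC \eqn{= -2\ell + 2\,df\log\log n};
#' EBIC \eqn{= \mathrm{BIC} + 2\gamma\log\binom{p}{df}} (default
#' \eqn{\gamma = 0.5}); BIC-p \eqn{= -2\ell + df(\log n + 2\log p)}.
#'
#' @param name one of `"aic"`, `"aicc"`, `"bic"`, `"hqc"`, `"ebic"`, `"bicp"`.
#' @param loglik model log-likelihood.
#' @param df number of nonzero coefficients.
#' @param n number of (retained) samples.
#' @param p number of candidate predictors (used by EBIC and BIC-p).
#' @param gamma EBIC weight in `[0, 1]`.
#' @return A `criterion_report`.
#' @export
compute_classical_criterion <- function(name, loglik, df, n, p = NULL,
                                        gamma = 0.5) {
  name <- match.arg(name, c("aic", "aicc", "bic", "hqc", "ebic", "bicp"))
  if (name %in% c("ebic", "bicp") && is.null(p))
    stop(name, " requires the number of candidate predictors p")
  if (!is.null(p) && df > p) stop("df cannot exceed p")
  m2l <- -2 * loglik
  value <- switch(name,
    aic = m2l + 2 * df,
    aicc = {
      if (df >= n - 1)
        stop("undefined criterion: AICc requires df < n - 1")
      m2l + 2 * df + 2 * df * (df + 1) / (n - df - 1)
    },
    bic = m2l + df * log(n),
    hqc = m2l + 2 * df * log(log(n)),
    ebic = m2l + df * log(n) + 2 * gamma * lchoose(p, df),
    bicp = m2l + df * (log(n) + 2 * log(p))
  )
  new_criterion_report(name, value, df, list(loglik = loglik, n = n, p = p))
}

#' k-fold cross-validation error for the kernel-weighted elastic net
#'
#' Folds are drawn (seeded) on the retained samples of the weighted design.
#' For each fold the model is fitted on the training portion of the weighted
#' design at the given penalty, and scored on the held-out portion by the
#' kernel-weighted squared error
#' \eqn{\sum_{i \in \mathrm{test}} w_i (y_i - r_i^\top\hat\beta)^2 /
#'  \sum_{i \in \mathrm{test}} w_i}; the mean over folds is returned.
#'
#' @param y response vector (all n samples).
#' @param R regulator matrix (all n samples).
#' @param w a [gaussian_kernel_weights()] object (or `NULL` for unit weights).
#' @param pen a [penalty_config()].
#' @param k number of folds (>= 2).
#' @param seed integer seed for the fold assignment.
#' @param tol,maxit coordinate-descent control.
#' @return The mean weighted CV error (a single number).
#' @export
kfold_cv_error <- function(y, R, w = NULL, pen, k = 10L, seed = 0L,
                           tol = 1e-7, maxit = 1e5) {
  pen <- as_penalty(pen)
  if (k < 2) stop("k must be >= 2")
  d <- build_weighted_design(y, R, w)
  if (d$n < k) stop("fewer retained samples than folds")
  foldid <- with_seed(seed, sample(rep(seq_len(k), length.out = d$n)))
  G <- crossprod(d$R_star)
  cc <- crossprod(d$R_star, d$y_star)[, 1]
  err <- cpp_cv_error(d$R_star, d$y_star, d$weights, G, cc,
                      as.integer(foldid), as.integer(k), pen$lambda, pen$pi,
                      tol, as.integer(maxit))
  as.numeric(err)
}

#' @export
print.criterion_report <- function(x, ...) {
  cat(toupper(x$name), "=", format(x$value), "(df =", x$df, ")\n")
  invisible(x)
}
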