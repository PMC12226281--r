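test_that("penalty curvature matches P'(|b|)/|b|", {
  fit <- structure(list(beta = c(0.5, 0, -2), active_set = c(1L, 3L),
                        penalty = penalty_config(2, 1)),
                   class = "enet_fit")
  pc <- penalty_curvature(fit)
  expect_equal(unname(pc$diag), c(2 / 0.5, 2 / 2))   # lambda*pi/|b|
  # pure ridge: curvature is lambda regardless of the coefficient
  pc0 <- penalty_curvature(fit, penalty_config(3, 0))
  expect_equal(unname(pc0$diag), c(3, 3))
  # no penalty
  pc_null <- penalty_curvature(fit, penalty_config(0, 0.5))
  expect_equal(unname(pc_null$diag), c(0, 0))
})

test_that("compute_gic equals the step-by-step matrix oracle", {
  worst <- 0
  for (r in 1:100) {
    set.seed(r)
    n <- sample(10:20, 1); p <- sample(2:5, 1)
    inst <- make_instance(n = n, p = p, h = runif(1, 0.3, 2), seed = r,
                          n_signal = min(2, p))
    d <- inst$design
    pen <- penalty_config(runif(1, 0.1, 2), sample(c(0.3, 0.7, 1), 1))
    fit <- fit_weighted_elastic_net(d, pen)
    if (length(fit$active_set) == 0 || d$n - length(fit$active_set) < 1) next
    ns <- estimate_noise_scale(d, fit)
    got <- compute_gic(d, fit, ns, pen)$value
    want <- oracle_gic(d, fit, ns, pen$lambda, pen$pi)
    worst <- max(worst, abs(got - want) / max(abs(want), 1))
  }
  expect_lt(worst, 1e-8)
})

test_that("classical criteria follow their closed forms", {
  r <- compute_classical_criterion("aic", loglik = -100, df = 3, n = 300)
  expect_equal(r$value, 206)
  r <- compute_classical_criterion("bic", -100, 3, 300)
  expect_equal(r$value, 200 + 3 * log(300))
  r <- compute_classical_criterion("aicc", -100, 3, 300)
  expect_equal(r$value, 206 + 2 * 3 * 4 / (300 - 3 - 1))
  r <- compute_classical_criterion("hqc", -100, 3, 300)
  expect_equal(r$value, 200 + 6 * log(log(300)))
  r <- compute_classical_criterion("ebic", -100, 3, 300, p = 40)
  expect_equal(r$value, 200 + 3 * log(300) + lchoose(40, 3))
  r <- compute_classical_criterion("bicp", -100, 3, 300, p = 40)
  expect_equal(r$value, 200 + 3 * (log(300) + 2 * log(40)))
})

test_that("null models and reductions behave correctly", {
  for (nm in c("aic", "aicc", "bic", "hqc", "ebic", "bicp")) {
    r <- compute_classical_criterion(nm, -50, 0, 100, p = 20)
    expect_equal(r$value, 100, info = nm)    # df = 0: all equal -2*loglik
  }
  # EBIC with gamma = 0 reduces to BIC
  expect_equal(compute_classical_criterion("ebic", -80, 4, 200, p = 30,
                                           gamma = 0)$value,
               compute_classical_criterion("bic", -80, 4, 200)$value)
  expect_error(compute_classical_criterion("aicc", -10, 9, 10), "undefined")
})

test_that("scaling sigma2 shifts -2*loglik by the closed-form amount", {
  inst <- make_instance(n = 40, p = 4, seed = 8)
  d <- inst$design
  fit <- fit_weighted_elastic_net(d, penalty_config(1, 0.5))
  ns <- estimate_noise_scale(d, fit)
  resid <- as.numeric(d$y_star - d$R_star %*% fit$beta)
  for (cc in c(2, 5)) {
    ns2 <- ns
    ns2$sigma2 <- cc * ns$sigma2
    ns2$per_sample <- cc * ns$per_sample
    shift <- -2 * netgic:::model_loglik(d, fit, ns2) -
      (-2 * netgic:::model_loglik(d, fit, ns))
    want <- d$n * log(cc) + (1 / cc - 1) * sum(resid^2 / ns$per_sample)
    expect_equal(shift, want, tolerance = 1e-9)
  }
})

test_that("unweighted small-penalty GIC bias approaches the classical penalty", {
  # TIC-style sandwich: with unit weights, lambda -> 0 and Gaussian noise,
  # the bias term should concentrate near |active| + 1
  set.seed(99)
  n <- 500; p <- 3
  biases <- replicate(200, {
    R <- matrix(rnorm(n * p), n, p)
    y <- as.numeric(R %*% c(1, 0.5, -1) + rnorm(n))
    d <- build_weighted_design(y, R)
    pen <- penalty_config(1e-8, 0.5)
    fit <- fit_weighted_elastic_net(d, pen)
    ns <- estimate_noise_scale(d, fit, method = "mle")
    compute_gic(d, fit, ns, pen)$details$bias
  })
  expect_lt(abs(mean(biases) - (p + 1)) / (p + 1), 0.25)
})

test_that("cross-validation error is deterministic and exact on noiseless data", {
  set.seed(6)
  n <- 30
  x <- rnorm(n)
  y <- 1.7 * x                      # exact linear, single predictor
  e_loo <- kfold_cv_error(y, matrix(x, ncol = 1), w = NULL,
                          pen = penalty_config(0, 1), k = n, seed = 0)
  expect_equal(e_loo, 0, tolerance = 1e-12)

  inst <- make_instance(n = 60, p = 4, seed = 10)
  e1 <- kfold_cv_error(inst$y, inst$R, inst$w, penalty_config(1, 0.5),
                       k = 5, seed = 3)
  e2 <- kfold_cv_error(inst$y, inst$R, inst$w, penalty_config(1, 0.5),
                       k = 5, seed = 3)
  expect_identical(e1, e2)
  expect_error(kfold_cv_error(inst$y, inst$R, inst$w, penalty_config(1, 1),
                              k = 1), "k must be")
})

test_that("two-fold CV matches a hand-computed univariate oracle", {
  set.seed(13)
  n <- 12
  x <- rnorm(n)
  y <- 0.8 * x + rnorm(n, sd = 0.3)
  k <- 2; seed <- 5
  got <- kfold_cv_error(y, matrix(x, ncol = 1), w = NULL,
                        pen = penalty_config(0, 1), k = k, seed = seed)
  foldid <- netgic:::with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  errs <- vapply(1:k, function(f) {
    tr <- foldid != f
    b <- sum(x[tr] * y[tr]) / sum(x[tr]^2)        # univariate OLS
    mean((y[!tr] - b * x[!tr])^2)                 # unit weights
  }, numeric(1))
  expect_equal(got, mean(errs), tolerance = 1e-8)
})

test_that("criteria are invariant to sample and predictor order", {
  inst <- make_instance(n = 50, p = 5, seed = 17)
  pen <- penalty_config(2, 0.7)
  d <- inst$design
  fit <- fit_weighted_elastic_net(d, pen)
  ns <- estimate_noise_scale(d, fit)
  g0 <- compute_gic(d, fit, ns, pen)$value
  a0 <- compute_classical_criterion("aic", model_loglik_of(d, fit, ns),
                                    length(fit$active_set), d$n)$value

  set.seed(18)
  ps <- sample(length(inst$y))      # permute samples
  pj <- sample(ncol(inst$R))        # permute predictors
  w2 <- gaussian_kernel_weights(inst$m[ps], inst$m[1], inst$w$h)
  d2 <- build_weighted_design(inst$y[ps], inst$R[ps, pj], w2)
  fit2 <- fit_weighted_elastic_net(d2, pen)
  expect_equal(sort(abs(fit2$beta[fit2$beta != 0])),
               sort(abs(fit$beta[fit$beta != 0])), tolerance = 1e-6)
  ns2 <- estimate_noise_scale(d2, fit2)
  expect_equal(compute_gic(d2, fit2, ns2, pen)$value, g0, tolerance = 1e-6)
  a2 <- compute_classical_criterion("aic", model_loglik_of(d2, fit2, ns2),
                                    length(fit2$active_set), d2$n)$value
  expect_equal(a2, a0, tolerance = 1e-6)
})
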