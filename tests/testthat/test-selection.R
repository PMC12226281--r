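sel_data <- local({
  set.seed(41)
  n <- 60; q <- 7
  m <- runif(n, -1, 1)
  x <- matrix(rnorm(n * q), n, q)
  x[, 1] <- 0.9 * x[, 2] - 0.6 * x[, 3] + rnorm(n, sd = 0.5)
  dimnames(x) <- list(paste0("s", 1:n), paste0("g", 1:q))
  list(data = expression_dataset(x),
       mod = modulator_profile(m, paste0("s", 1:n)))
})

test_that("a singleton grid returns that grid point", {
  g <- search_grid(lambdas = 2.5, pis = 0.8, bandwidths = 0.7)
  fit <- select_hyperparameters(sel_data$data, sel_data$mod, "g1", "s5",
                                grid = g)
  expect_equal(fit$hyper, list(lambda = 2.5, pi = 0.8, h = 0.7))
  expect_equal(nrow(fit$trace), 1L)
})

test_that("the winner equals the independently recomputed trace minimum", {
  g <- search_grid(sel_data$mod$m, n_lambda = 8, pis = c(0.5, 1),
                   n_bandwidths = 3)
  for (crit in c("gic", "bic")) {
    fit <- select_hyperparameters(sel_data$data, sel_data$mod, "g1", "s5",
                                  grid = g, criterion = crit)
    tr <- fit$trace
    expect_equal(fit$criterion$value, min(tr[[crit]]))
    # re-fit the winning point through the modular route and compare
    td <- netgic:::target_design(sel_data$data, "g1")
    m <- sel_data$mod$m
    w <- gaussian_kernel_weights(m, m["s5"], fit$hyper$h)
    d <- build_weighted_design(td$y, td$R, w)
    pen <- penalty_config(fit$hyper$lambda, fit$hyper$pi)
    refit <- fit_weighted_elastic_net(d, pen)
    expect_equal(unname(fit$beta_std), refit$beta, tolerance = 1e-5)
    if (crit == "gic") {
      ns <- estimate_noise_scale(d, refit, method = "mle")
      expect_equal(fit$criterion$value, compute_gic(d, refit, ns, pen)$value,
                   tolerance = 1e-5)
    }
  }
})

test_that("every trace row matches the modular single-fit route", {
  g <- search_grid(lambdas = c(6, 2, 0.5), pis = c(0.5, 1),
                   bandwidths = c(0.4, 1.2))
  fit <- select_hyperparameters(sel_data$data, sel_data$mod, "g2", "s10",
                                grid = g, criterion = "gic")
  td <- netgic:::target_design(sel_data$data, "g2")
  m <- sel_data$mod$m
  for (i in seq_len(nrow(fit$trace))) {
    row <- fit$trace[i, ]
    w <- gaussian_kernel_weights(m, m["s10"], row$h)
    d <- build_weighted_design(td$y, td$R, w)
    pen <- penalty_config(row$lambda, row$pi)
    f <- fit_weighted_elastic_net(d, pen)
    expect_equal(row$df, length(f$active_set))
    if (row$df > 0) {
      ns <- estimate_noise_scale(d, f, method = "mle")
      expect_equal(row$gic, compute_gic(d, f, ns, pen)$value,
                   tolerance = 1e-6)
    }
  }
})

test_that("duplicated grid points do not change the winner", {
  g1 <- search_grid(lambdas = c(4, 1, 0.2), pis = c(0.6),
                    bandwidths = c(0.5, 1))
  g2 <- search_grid(lambdas = c(4, 4, 1, 0.2), pis = c(0.6, 0.6),
                    bandwidths = c(0.5, 1, 1))
  f1 <- select_hyperparameters(sel_data$data, sel_data$mod, "g3", "s2",
                               grid = g1)
  f2 <- select_hyperparameters(sel_data$data, sel_data$mod, "g3", "s2",
                               grid = g2)
  expect_equal(f1$hyper, f2$hyper)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-6)
})

test_that("grid refinement can only improve the selected criterion", {
  lams <- c(5, 1, 0.3)
  g1 <- search_grid(lambdas = lams, pis = c(0.5, 1), bandwidths = c(0.5, 1))
  g2 <- search_grid(lambdas = c(lams, 2.3, 0.1), pis = c(0.5, 1, 0.8),
                    bandwidths = c(0.5, 1, 0.25))
  for (crit in c("gic", "aic")) {
    v1 <- select_hyperparameters(sel_data$data, sel_data$mod, "g1", "s8",
                                 grid = g1, criterion = crit)$criterion$value
    v2 <- select_hyperparameters(sel_data$data, sel_data$mod, "g1", "s8",
                                 grid = g2, criterion = crit)$criterion$value
    expect_lte(v2, v1)
  }
})

test_that("smallest network: two genes, one target sample", {
  set.seed(50)
  x <- matrix(rnorm(40), 20, 2, dimnames = list(paste0("s", 1:20),
                                                c("gA", "gB")))
  data <- expression_dataset(x)
  mod <- modulator_profile(runif(20, -1, 1), paste0("s", 1:20))
  g <- search_grid(mod$m, n_lambda = 5, pis = 1, n_bandwidths = 2)
  net <- fit_personalized_network(data, mod, target_samples = "s3", grid = g)
  expect_equal(dim(net$coef), c(2, 2, 1))
  expect_true(all(is.na(diag(net$coef[, , 1]))))
  expect_equal(length(net$failures), 0)
})

test_that("network fitting is deterministic and order-invariant", {
  g <- search_grid(sel_data$mod$m, n_lambda = 6, pis = c(0.5, 1),
                   n_bandwidths = 2)
  n1 <- fit_personalized_network(sel_data$data, sel_data$mod,
                                 target_samples = c("s2", "s9"),
                                 grid = g, seed = 4)
  n2 <- fit_personalized_network(sel_data$data, sel_data$mod,
                                 target_samples = c("s2", "s9"),
                                 grid = g, seed = 4)
  expect_identical(n1$coef, n2$coef)

  # permuting the sample rows leaves every fit unchanged
  set.seed(51)
  perm <- sample(length(sel_data$mod$m))
  xp <- sel_data$data$values[perm, ]
  datap <- expression_dataset(xp)
  modp <- modulator_profile(sel_data$mod$m[perm], rownames(xp))
  n3 <- fit_personalized_network(datap, modp,
                                 target_samples = c("s2", "s9"),
                                 grid = g, seed = 4)
  expect_equal(n3$coef, n1$coef, tolerance = 1e-6)
})

test_that("strong simulated signals are recovered at high TPR", {
  cfg <- scenario_config(n_genes = 50, scenario = 2, type = 1,
                         iterations = 2, n_targets = 10, seed = 3)
  r <- run_benchmark(cfg, "gic")
  expect_gte(r$summary$tpr, 0.9)
})
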