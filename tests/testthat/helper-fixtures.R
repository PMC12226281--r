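# Shared fixture builders and independent oracles for the test suite.

# Small random regression instance with kernel weighting.
make_instance <- function(n = 40, p = 4, h = 0.5, seed = 1,
                          n_signal = min(2, p), coef = 0.8) {
  set.seed(seed)
  m <- runif(n, -1, 1)
  R <- matrix(rnorm(n * p), n, p)
  beta <- c(rep(coef, n_signal), rep(0, p - n_signal))
  y <- as.numeric(R %*% beta + rnorm(n))
  w <- gaussian_kernel_weights(m, m[1], h)
  list(y = y, R = R, m = m, w = w, beta = beta,
       design = build_weighted_design(y, R, w))
}

# Step-by-step GIC oracle: builds every matrix of the criterion explicitly
# (full diagonal matrices, no shortcuts) independently of compute_gic.
oracle_gic <- function(design, fit, noise, lambda, pi) {
  ys <- design$y_star
  Xs <- design$R_star
  n <- design$n
  act <- which(fit$beta != 0)
  sig_star <- noise$per_sample
  resid <- as.numeric(ys - Xs %*% fit$beta)
  ll <- sum(dnorm(ys, mean = as.numeric(Xs %*% fit$beta),
                  sd = sqrt(sig_star), log = TRUE))
  if (length(act) == 0) return(-2 * ll)
  Lam <- diag(resid / sig_star, n)
  XA <- Xs[, act, drop = FALSE]
  Sl <- diag(lambda * ((1 - pi) + pi / abs(fit$beta[act])), length(act))
  Rhat <- t(XA) %*% XA / n + Sl
  ones <- rep(1, n)
  Qhat <- (t(XA) %*% Lam %*% Lam %*% XA -
             Sl %*% fit$beta[act] %*% t(ones) %*% Lam %*% XA) / n
  -2 * ll + 2 * sum(diag(solve(Rhat) %*% Qhat))
}

# Univariate elastic-net closed form for ||x||^2 = 1:
# beta = sign(z) max(|z| - lambda*pi, 0) / (1 + lambda*(1-pi)), z = x'y.
oracle_univariate <- function(z, lambda, pi) {
  sign(z) * max(abs(z) - lambda * pi, 0) / (1 + lambda * (1 - pi))
}

# Tiny personalized-network object with a known coefficient tensor.
make_network <- function(coef, genes = dimnames(coef)[[1]],
                         samples = dimnames(coef)[[3]]) {
  structure(
    list(coef = coef, gene_ids = genes, target_samples = samples,
         modulator = setNames(seq_along(samples), samples),
         criterion = "gic", hyper = NULL, failures = list()),
    class = "personalized_network")
}

model_loglik_of <- function(d, fit, ns) netgic:::model_loglik(d, fit, ns)
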