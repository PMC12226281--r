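#' Gaussian kernel sample weights for a target sample
#'
#' Computes the per-sample weights used in the local (sample-specific) fit:
#' \deqn{k_{i\alpha} = \exp\{-(m_i - m_\alpha)^2 / h\},}
#' where \eqn{m_i} is sample \eqn{i}'s modulator value, \eqn{m_\alpha} the
#' target sample's value and \eqn{h > 0} the bandwidth (in squared modulator
#' units). Samples whose raw weight falls below `floor` are dropped from the
#' local fit; the retained weights are rescaled to sum to the number of
#' retained samples, which keeps the likelihood scale comparable across
#' bandwidths.
#'
#' @param m numeric vector of modulator values, one per sample.
#' @param m_alpha modulator value of the target sample.
#' @param h positive kernel bandwidth.
#' @param floor raw-weight threshold below which a sample is dropped.
#' @param min_retained minimum number of retained samples before the
#'   weighting is declared degenerate.
#' @return An object of class `kernel_weighting`: a list with `raw_weights`
#'   (all n samples), `retained` (indices kept), `weights` (normalized weights
#'   over retained samples, summing to their count), `h`, `m_alpha`, `floor`.
#' @examples
#' w <- gaussian_kernel_weights(seq(-1, 1, length.out = 11), 0, h = 0.5)
#' sum(w$weights)  # number of retained samples
#' @export
gaussian_kernel_weights <- function(m, m_alpha, h, floor = 1e-8,
                                    min_retained = 2L) {
  if (!is.numeric(h) || length(h) != 1L || !is.finite(h) || h <= 0)
    stop("invalid bandwidth: h must be a single positive number")
  if (!all(is.finite(m)))
    stop("modulator values must be finite")
  if (!is.finite(m_alpha))
    stop("target modulator value must be finite")
  raw <- exp(-(m - m_alpha)^2 / h)
  retained <- which(raw >= floor)
  if (length(retained) < min_retained)
    stop("degenerate weighting: fewer than ", min_retained,
         " samples retained at h = ", format(h))
  wr <- raw[retained]
  wr <- wr * (length(retained) / sum(wr))
  structure(
    list(raw_weights = raw, retained = retained, weights = wr,
         h = h, m_alpha = m_alpha, floor = floor),
    class = "kernel_weighting"
  )
}

#' Build the kernel-free weighted design
#'
#' Reformulates the kernel-weighted least-squares problem without the kernel:
#' each retained row of `(y, R)` is scaled by the square root of its
#' normalized kernel weight, so that for any coefficient vector \eqn{\beta}
#' \deqn{(y^* - R^*\beta)^\top(y^* - R^*\beta)
#'   = \sum_i w_i (y_i - r_i^\top \beta)^2.}
#'
#' @param y numeric response vector (target-gene expression), length n.
#' @param R numeric n x p regulator matrix.
#' @param w a [gaussian_kernel_weights()] object (or `NULL` for the
#'   unweighted design with unit weights).
#' @return An object of class `weighted_design`: list with `y_star`, `R_star`
#'   (retained rows, weight-scaled), `y`, `R` (retained rows, original scale),
#'   `weights` (normalized weights), `n` (retained count) and `kernel`.
#' @export
build_weighted_design <- function(y, R, w = NULL) {
  R <- as.matrix(R)
  if (length(y) != nrow(R))
    stop("shape error: length(y) = ", length(y), " but nrow(R) = ", nrow(R))
  if (is.null(w)) {
    keep <- seq_along(y)
    wts <- rep(1, length(y))
  } else {
    stopifnot(inherits(w, "kernel_weighting"))
    if (length(w$raw_weights) != length(y))
      stop("shape error: kernel weighting is for ", length(w$raw_weights),
           " samples but y has ", length(y))
    keep <- w$retained
    wts <- w$weights
  }
  if (length(keep) < 2L)
    stop("weighted design needs at least 2 retained samples")
  sw <- sqrt(wts)
  structure(
    list(y_star = sw * y[keep],
         R_star = sw * R[keep, , drop = FALSE],
         y = y[keep], R = R[keep, , drop = FALSE],
         weights = wts, n = length(keep), kernel = w),
    class = "weighted_design"
  )
}

#' @export
print.kernel_weighting <- function(x, ...) {
  cat("Gaussian kernel weighting: h =", format(x$h),
      "| retained", length(x$retained), "of", length(x$raw_weights),
      "samples\n")
  invisible(x)
}

#' @export
print.weighted_design <- function(x, ...) {
  cat("Weighted design: n' =", x$n, "samples x p =", ncol(x$R_star),
      "regulators\n")
  invisible(x)
}
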