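# Downstream operations on fitted personalized networks: group aggregation,
# cross-condition consensus, top-fraction filtering, drug-sensitivity
# modules and regulate-effect-change scoring.

# weights is t(M) flattened column-major, M indexed [target, regulator]:
# the regulator index varies fastest
net_edge_frame <- function(net, weights) {
  q <- length(net$gene_ids)
  reg <- rep(net$gene_ids, times = q)
  tgt <- rep(net$gene_ids, each = q)
  keep <- reg != tgt
  edge_table(reg[keep], tgt[keep], weights[keep])
}

#' Median network over a group of target samples
#'
#' Per-edge medians of the varying coefficients over the given group, e.g.
#' the drug-resistant cell lines; used to summarize one condition's networks
#' into a single edge table.
#'
#' @param net a `personalized_network`.
#' @param group sample ids or indices into `net$target_samples`.
#' @return An [edge_table()] (all edges, including zero-weight ones).
#' @export
aggregate_group_median <- function(net, group) {
  stopifnot(inherits(net, "personalized_network"))
  if (length(group) == 0) stop("empty group")
  if (is.character(group)) group <- match(group, net$target_samples)
  if (anyNA(group) || any(group < 1 | group > length(net$target_samples)))
    stop("group contains unknown target samples")
  med <- apply(net$coef[, , group, drop = FALSE], c(1, 2), median)
  # med is target x regulator; edge weight(j -> l) = coef[l, j, .]
  net_edge_frame(net, as.numeric(t(med)))
}

#' Consensus network across conditions
#'
#' Keeps only edges whose weight is nonzero in every input table (e.g. the
#' median networks of several drugs) and averages the weights across tables.
#'
#' @param tables list of [edge_table()]s over the same gene universe.
#' @return An [edge_table()] restricted to the common nonzero support.
#' @export
consensus_mean <- function(tables) {
  if (length(tables) < 1) stop("need at least one edge table")
  key <- function(t) paste(t$regulator, t$target, sep = "\r")
  k0 <- sort(key(tables[[1]]))
  for (t in tables[-1]) {
    if (!identical(sort(key(t)), k0))
      stop("edge tables have inconsistent gene universes")
  }
  acc <- tables[[1]][order(key(tables[[1]])), , drop = FALSE]
  wmat <- sapply(tables, function(t) t$weight[order(key(t))])
  wmat <- matrix(wmat, nrow = nrow(acc))
  keep <- rowSums(wmat != 0) == ncol(wmat)
  edge_table(acc$regulator[keep], acc$target[keep],
             rowMeans(wmat[keep, , drop = FALSE]))
}

#' Keep the top fraction of edges by absolute weight
#'
#' Retains the ceiling of `fraction` times the number of nonzero-weight edges,
#' ranked by absolute weight; ties at the cutoff are all retained (so the
#' result may exceed the nominal count, with a message).
#'
#' @param t an [edge_table()].
#' @param fraction in (0, 1].
#' @return The filtered [edge_table()].
#' @export
top_fraction_edges <- function(t, fraction) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  t <- t[t$weight != 0, , drop = FALSE]
  if (nrow(t) == 0) return(edge_table())
  n_keep <- ceiling(fraction * nrow(t))
  aw <- abs(t$weight)
  cut <- sort(aw, decreasing = TRUE)[n_keep]
  keep <- aw >= cut
  if (sum(keep) > n_keep)
    message("ties at the cutoff: retaining ", sum(keep),
            " edges instead of ", n_keep)
  out <- t[keep, , drop = FALSE]
  class(out) <- c("edge_table", "data.frame")
  sort_edges(out)
}

#' First-principal-component module of drug sensitivities
#'
#' Summarizes several drugs' sensitivity profiles into one module score per
#' sample: the first principal component of the column-centered sensitivity
#' matrix. The sign is fixed so that the largest-magnitude loading is
#' positive, making the score direction reproducible.
#'
#' @param sens numeric matrix, samples x drugs (>= 2 drugs, no missing
#'   values).
#' @return Numeric vector of module scores (zero mean), with the loading
#'   vector as attribute `"loading"`.
#' @export
drug_sensitivity_module <- function(sens) {
  sens <- as.matrix(sens)
  if (ncol(sens) < 2) stop("need at least 2 drugs")
  if (!all(is.finite(sens))) stop("sensitivity matrix has missing values")
  if (all(apply(sens, 2, stats::sd) == 0)) stop("rank-0 sensitivity matrix")
  pc <- stats::prcomp(sens, center = TRUE, scale. = FALSE)
  load <- pc$rotation[, 1]
  s <- sign(load[which.max(abs(load))])
  scores <- pc$x[, 1] * s
  attr(scores, "loading") <- load * s
  scores
}

#' Regulate-effect change across target samples
#'
#' For each edge, the range (max minus min) of its varying coefficient over
#' the target samples; edges with large ranges are modulator-specific
#' regulations. Per regulator, the ranges are summed over target genes to a
#' total effect-change score.
#'
#' @param net a `personalized_network` with >= 2 target samples.
#' @return A list with `edges` (an [edge_table()] of per-edge ranges) and
#'   `regulators` (data frame `regulator`, `total`, sorted by `total`
#'   descending).
#' @export
regulate_effect_change <- function(net) {
  stopifnot(inherits(net, "personalized_network"))
  if (length(net$target_samples) < 2)
    stop("need at least 2 target samples to compute a range")
  rng <- apply(net$coef, c(1, 2), function(v) max(v) - min(v))
  edges <- net_edge_frame(net, as.numeric(t(rng)))
  tot <- tapply(edges$weight, edges$regulator, sum)
  reg <- data.frame(regulator = names(tot), total = as.numeric(tot),
                    stringsAsFactors = FALSE)
  reg <- reg[order(-reg$total, reg$regulator), , drop = FALSE]
  rownames(reg) <- NULL
  list(edges = edges, regulators = reg)
}
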