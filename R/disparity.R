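# Disparity metrics, disparity-through-time curves with Brownian null
# envelopes, and divergence-scatter tables.

#' Average pairwise disparity of a set of species
#'
#' `euclidean` mode is the mean over all unordered pairs of the squared
#' Euclidean distance (set `squared = FALSE` for plain Euclidean);
#' `manhattan` mode is the mean absolute-difference sum (used for
#' diet-rank profiles).  A single species has disparity 0.
#'
#' @param data species x traits matrix (a vector is treated as one
#'   trait).
#' @param metric `"euclidean"` or `"manhattan"`.
#' @param squared square the Euclidean distances (default TRUE).
#' @return non-negative scalar.
#' @export
disparity <- function(data, metric = c("euclidean", "manhattan"),
                      squared = TRUE) {
  metric <- match.arg(metric)
  X <- as.matrix(data)
  if (nrow(X) == 0L) stop_invalid("empty species set")
  if (nrow(X) == 1L) return(0)
  d <- stats::dist(X, method = metric)
  if (metric == "euclidean" && squared) d <- d^2
  mean(d)
}

# descendant tip indices per node (list over all nodes)
descendant_tips <- function(tree) {
  n <- ape::Ntip(tree)
  nn <- n + tree$Nnode
  desc <- vector("list", nn)
  for (i in seq_len(n)) desc[[i]] <- i
  po <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(po$edge))) {
    par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[[par]] <- c(desc[[par]], desc[[ch]])
  }
  desc
}

#' Observed disparity-through-time curve
#'
#' At each divergence event (internal node, ordered by time from the
#' root) the lineages present immediately after the event are the
#' branches crossing that time; each contributes the relative disparity
#' (clade disparity over whole-tree disparity) of the clade it subtends,
#' singletons contributing 0, and the event value is their mean.
#'
#' @param tree ultrametric `phylo` object.
#' @param data species x traits matrix, rownames = tip labels.
#' @param metric,squared passed to [disparity()].
#' @return data frame with `node`, `time` (absolute), `rel_time`
#'   (node time / tree depth) and `observed`.
#' @export
dtt_curve <- function(tree, data, metric = "euclidean", squared = TRUE) {
  X <- as.matrix(data)
  if (is.null(rownames(X))) stop_invalid("data must have species rownames")
  X <- X[tree$tip.label, , drop = FALSE]
  total <- disparity(X, metric, squared)
  if (total <= 0) stop_invalid("zero total disparity: curve undefined")
  n <- ape::Ntip(tree)
  nt <- node_times(tree)
  depth <- tree_depth(tree)
  desc <- descendant_tips(tree)
  rel <- vapply(desc, function(tips)
    disparity(X[tips, , drop = FALSE], metric, squared) / total, 0)
  internal <- n + seq_len(tree$Nnode)
  ord <- internal[order(nt[internal])]
  eps <- 1e-9 * depth
  obs <- vapply(ord, function(v) {
    t_v <- nt[v]
    crossing <- which(nt[tree$edge[, 1L]] <= t_v + eps &
                        nt[tree$edge[, 2L]] > t_v + eps)
    mean(rel[tree$edge[crossing, 2L]])
  }, 0)
  data.frame(node = ord, time = nt[ord], rel_time = nt[ord] / depth,
             observed = obs)
}

# one multivariate BM draw on the tree: X (n x p) with Cov = C (x) Sigma
simulate_bm_tips <- function(Ctree_chol, Sigma_chol, p) {
  n <- nrow(Ctree_chol)
  Z <- matrix(stats::rnorm(n * p), n, p)
  t(Ctree_chol) %*% Z %*% Sigma_chol
}

#' Brownian-motion null envelope for a DTT curve
#'
#' The evolutionary rate matrix is estimated from the observed
#' phylogenetic independent contrasts; `n_sim` Brownian datasets are
#' then simulated on the tree with that rate, their DTT curves computed,
#' and the per-event median and central 95% interval returned together
#' with the observed curve.
#'
#' @param tree ultrametric `phylo` object.
#' @param data species x traits matrix.
#' @param n_sim number of simulations (>= 100).
#' @param seed integer seed.
#' @param metric,squared passed to [disparity()].
#' @param level envelope coverage (default 0.95).
#' @return object of class `"dtt_result"`: the [dtt_curve()] columns
#'   plus `null_median`, `null_lower`, `null_upper`, `n_simulations`.
#' @export
bm_null_envelope <- function(tree, data, n_sim = 1000L, seed = NULL,
                             metric = "euclidean", squared = TRUE,
                             level = 0.95) {
  if (n_sim < 100L) stop_invalid("n_sim must be >= 100")
  X <- as.matrix(data)
  X <- X[tree$tip.label, , drop = FALSE]
  obs <- dtt_curve(tree, X, metric, squared)
  rate <- independent_contrasts(tree, X)$rate
  ev <- eigen(rate, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    warning("rate matrix is rank-deficient; adding a small ridge")
    rate <- rate + diag(1e-8 * max(ev), ncol(X))
  }
  Ctree <- mrca_times(tree)
  Rtree <- chol(Ctree)
  Rsig <- chol(rate)
  p <- ncol(X)
  with_seed(seed, {
    sims <- matrix(NA_real_, n_sim, nrow(obs))
    for (s in seq_len(n_sim)) {
      Y <- simulate_bm_tips(Rtree, Rsig, p)
      rownames(Y) <- tree$tip.label
      sims[s, ] <- dtt_curve(tree, Y, metric, squared)$observed
    }
    a <- (1 - level) / 2
    out <- obs
    out$null_median <- apply(sims, 2L, stats::median)
    out$null_lower <- apply(sims, 2L, stats::quantile, probs = a)
    out$null_upper <- apply(sims, 2L, stats::quantile, probs = 1 - a)
    structure(list(curve = out, n_simulations = n_sim, level = level),
              class = "dtt_result")
  })
}

#' @export
print.dtt_result <- function(x, ...) {
  cat("Disparity-through-time:", nrow(x$curve), "events,",
      x$n_simulations, "BM simulations,",
      sprintf("%.0f%%", 100 * x$level), "envelope\n")
  inside <- with(x$curve, observed >= null_lower & observed <= null_upper)
  cat(sprintf("observed inside envelope at %d/%d events\n",
              sum(inside), length(inside)))
  invisible(x)
}

#' @export
plot.dtt_result <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$rel_time, cv$observed, type = "s", ylim =
                   range(cv[c("observed", "null_lower", "null_upper")]),
                 xlab = "relative time", ylab = "relative disparity", ...)
  graphics::lines(cv$rel_time, cv$null_median, type = "s", lty = 2)
  graphics::lines(cv$rel_time, cv$null_lower, type = "s", lty = 3)
  graphics::lines(cv$rel_time, cv$null_upper, type = "s", lty = 3)
  invisible(x)
}

#' Pairwise divergence scatter table
#'
#' One row per unordered species pair with the two distances (e.g.
#' Procrustes shape distance vs genetic distance or time since
#' divergence); a qualitative tool, no statistics are computed.
#'
#' @param shape_dist,other_dist symmetric matrices sharing a species
#'   set (dimnames required).
#' @return data frame with `species_a`, `species_b`, `shape`, `other`.
#' @export
divergence_scatter <- function(shape_dist, other_dist) {
  a <- as.matrix(shape_dist); b <- as.matrix(other_dist)
  if (is.null(rownames(a)) || is.null(rownames(b)))
    stop_invalid("distance matrices need species dimnames")
  if (!setequal(rownames(a), rownames(b)))
    stop_invalid("species sets differ between the two matrices")
  sp <- sort(rownames(a))
  a <- a[sp, sp]; b <- b[sp, sp]
  idx <- which(upper.tri(a), arr.ind = TRUE)
  data.frame(species_a = sp[idx[, 1L]], species_b = sp[idx[, 2L]],
             shape = a[idx], other = b[idx])
}
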