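# Simulators for trees, regime histories and multivariate OU traits.
# These define the generative conditions the downstream estimators are
# tested against: an ultrametric pure-birth tree, a symmetric Markov
# jump process for dietary regimes, and exact branch-wise sampling from
# the Ornstein-Uhlenbeck transition distribution.

#' Simulate an ultrametric pure-birth tree
#'
#' Pure-birth (Yule) topology with branch lengths rescaled so that every
#' tip sits exactly at `depth` time units from the root.
#'
#' @param n_tips number of tips (>= 2).
#' @param depth root-to-tip depth, My.
#' @param seed integer seed; same seed gives an identical tree.
#' @return a `phylo` object with tip labels `t1 ... tN`.
#' @export
simulate_tree <- function(n_tips, depth = 30, seed = NULL) {
  if (n_tips < 2) stop_invalid("n_tips must be >= 2")
  if (depth <= 0) stop_invalid("depth must be positive")
  with_seed(seed, {
    tr <- ape::rphylo(n_tips, birth = 1, death = 0)
    tr$edge.length <- tr$edge.length * (depth / tree_depth(tr))
    tr$tip.label <- paste0("t", seq_len(n_tips))
    tr
  })
}

#' Simulate a regime history along a tree
#'
#' A symmetric Markov jump process: switching events arrive at rate
#' `switch_rate` per My along every branch and move the lineage to a
#' uniformly chosen different regime.  Each branch is painted with the
#' regime at its child end (the regime the branch evolves toward); the
#' total number of jump events per branch is recorded so that expected
#' switch counts can be audited.
#'
#' @param tree a `phylo` object.
#' @param n_regimes number of regimes (>= 1).
#' @param switch_rate events per My (>= 0).
#' @param seed integer seed.
#' @param labels optional regime labels; default `R1 ... Rk`.
#' @param root_regime optional root regime label; default drawn
#'   uniformly.
#' @return an object of class `"regime_painting"` (with an
#'   `events_per_edge` field).
#' @export
simulate_regime_history <- function(tree, n_regimes, switch_rate,
                                    seed = NULL, labels = NULL,
                                    root_regime = NULL) {
  if (n_regimes < 1) stop_invalid("n_regimes must be >= 1")
  if (switch_rate < 0) stop_invalid("switch_rate must be >= 0")
  labels <- labels %||% paste0("R", seq_len(n_regimes))
  stopifnot(length(labels) == n_regimes)
  n <- ape::Ntip(tree)
  with_seed(seed, {
    root_regime <- if (is.null(root_regime)) sample.int(n_regimes, 1L)
      else match(root_regime, labels)
    if (is.na(root_regime)) stop_invalid("unknown root_regime label")
    state <- integer(n + tree$Nnode)
    state[n + 1L] <- root_regime
    events <- integer(nrow(tree$edge))
    po <- ape::reorder.phylo(tree, "postorder")
    ord <- rev(seq_len(nrow(po$edge)))   # preorder over edges
    edge_id <- match(paste(po$edge[, 1L], po$edge[, 2L]),
                     paste(tree$edge[, 1L], tree$edge[, 2L]))
    for (e in ord) {
      par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]; len <- po$edge.length[e]
      s <- state[par]
      k <- stats::rpois(1L, switch_rate * len)
      if (k > 0L && n_regimes > 1L) {
        for (j in seq_len(k)) {
          cand <- setdiff(seq_len(n_regimes), s)
          s <- cand[sample.int(length(cand), 1L)]
        }
        events[edge_id[e]] <- k
      }
      state[ch] <- s
    }
    node_states <- stats::setNames(labels[state[n + seq_len(tree$Nnode)]],
                                   as.character(n + seq_len(tree$Nnode)))
    tip_states <- stats::setNames(labels[state[seq_len(n)]], tree$tip.label)
    new_regime_painting(tree, node_states, tip_states, labels,
                        events_per_edge = events)
  })
}

# Per-tip root-to-tip segment table: tip index, t_a, t_b (node times of
# the segment ends) and regime index of the covering branch.
path_segments <- function(tree, painting) {
  n <- ape::Ntip(tree)
  nt <- node_times(tree)
  parent_of <- integer(n + tree$Nnode)
  edge_of <- integer(n + tree$Nnode)
  parent_of[tree$edge[, 2L]] <- tree$edge[, 1L]
  edge_of[tree$edge[, 2L]] <- seq_len(nrow(tree$edge))
  reg_idx <- match(painting$edge_regime, painting$regime_labels)
  tip <- ta <- tb <- reg <- list()
  for (i in seq_len(n)) {
    v <- i
    segs_a <- segs_b <- segs_r <- numeric(0)
    while (v != n + 1L) {
      e <- edge_of[v]
      segs_a <- c(segs_a, nt[parent_of[v]])
      segs_b <- c(segs_b, nt[v])
      segs_r <- c(segs_r, reg_idx[e])
      v <- parent_of[v]
    }
    tip[[i]] <- rep.int(i, length(segs_a))
    ta[[i]] <- segs_a; tb[[i]] <- segs_b; reg[[i]] <- segs_r
  }
  list(tip = unlist(tip), ta = unlist(ta), tb = unlist(tb),
       regime = unlist(reg),
       depth = nt[seq_len(n)])
}

# OU transition covariance over time t, in the eigenbasis of A:
# entry (k,l) = D_kl * (1 - exp(-(lk+ll) t)) / (lk+ll), limit D_kl * t.
ou_seg_cov <- function(D, lam, t) {
  p <- length(lam)
  Ls <- outer(lam, lam, `+`)
  phi <- ifelse(Ls > 1e-12, -expm1(-Ls * t) / Ls, t)
  D * phi
}

#' Simulate multivariate traits under a multi-peak OU process
#'
#' Exact branch-by-branch sampling from the Ornstein-Uhlenbeck
#' transition distribution `dX = A (theta - X) dt + S dB`: along a branch
#' of length `t` painted regime `r`, the child value is Gaussian with
#' mean `theta_r + exp(-A t) (x_parent - theta_r)` and covariance
#' `int_0^t exp(-A s) S S' exp(-A s) ds` (computed in the eigenbasis of
#' `A`).  `A = 0` reduces to Brownian motion with rate `S S'`.
#'
#' @param tree a `phylo` object.
#' @param painting a `"regime_painting"`.
#' @param A p x p symmetric positive-semidefinite selection matrix
#'   (zero allowed: BM).
#' @param S p x p diffusion factor (Sigma = S S').
#' @param theta n_regimes x p matrix of optima, rows named (or ordered)
#'   by `painting$regime_labels`.
#' @param root_state length-p root value; defaults to the root regime's
#'   optimum.
#' @param seed integer seed.
#' @return species-by-trait numeric matrix, rownames the tip labels.
#' @export
simulate_ou_traits <- function(tree, painting, A, S, theta,
                               root_state = NULL, seed = NULL) {
  A <- as.matrix(A); S <- as.matrix(S); theta <- as.matrix(theta)
  p <- nrow(A)
  if (!isSymmetric(unname(A), tol = 1e-8))
    stop_invalid("A must be symmetric")
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (any(eig$values < -1e-10))
    stop_invalid("A must be positive semi-definite")
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  if (nrow(theta) != length(painting$regime_labels))
    stop_invalid("theta must have one row per regime")
  if (!is.null(rownames(theta)))
    theta <- theta[painting$regime_labels, , drop = FALSE]
  Sigma <- S %*% t(S)
  D <- t(U) %*% Sigma %*% U
  n <- ape::Ntip(tree)
  root_regime <- match(painting$root_state, painting$regime_labels)
  if (is.null(root_state)) root_state <- theta[root_regime, ]
  reg_idx <- match(painting$edge_regime, painting$regime_labels)
  with_seed(seed, {
    x <- matrix(NA_real_, n + tree$Nnode, p)
    x[n + 1L, ] <- root_state
    po <- ape::reorder.phylo(tree, "postorder")
    ord <- rev(seq_len(nrow(po$edge)))
    edge_id <- match(paste(po$edge[, 1L], po$edge[, 2L]),
                     paste(tree$edge[, 1L], tree$edge[, 2L]))
    for (e in ord) {
      par <- po$edge[e, 1L]; ch <- po$edge[e, 2L]; t_e <- po$edge.length[e]
      th <- theta[reg_idx[edge_id[e]], ]
      # mean in eigen coords
      zp <- as.vector(t(U) %*% (x[par, ] - th))
      mz <- exp(-lam * t_e) * zp
      Vz <- ou_seg_cov(D, lam, t_e)
      ev <- eigen((Vz + t(Vz)) / 2, symmetric = TRUE)
      half <- ev$vectors %*% (sqrt(pmax(ev$values, 0)) * t(ev$vectors))
      z <- mz + as.vector(half %*% stats::rnorm(p))
      x[ch, ] <- th + as.vector(U %*% z)
    }
    out <- x[seq_len(n), , drop = FALSE]
    rownames(out) <- tree$tip.label
    colnames(out) <- paste0("trait", seq_len(p))
    out
  })
}
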