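# Independent oracle implementations used to cross-check the package's
# own code paths.  These deliberately use naive algorithms (grid search,
# exhaustive enumeration, explicit path traversal) and never call the
# functions they verify.

# full Procrustes distance by brute-force search over a rotation grid
# (optimal scale in closed form per angle)
grid_procrustes <- function(a, b, n_angles = 20000L) {
  ctr <- function(p) sweep(p, 2L, colMeans(p))
  a <- ctr(a); a <- a / sqrt(sum(a^2))
  b <- ctr(b); b <- b / sqrt(sum(b^2))
  best <- Inf
  for (th in seq(0, 2 * pi, length.out = n_angles)) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
    rb <- b %*% R
    beta <- sum(a * rb)            # optimal scale given |a| = |rb| = 1
    d2 <- sum((a - beta * rb)^2)
    if (d2 < best) best <- d2
  }
  sqrt(best)
}

# patristic distances by explicit root-to-tip path traversal
path_patristic <- function(tree) {
  n <- ape::Ntip(tree)
  parent_of <- integer(n + tree$Nnode)
  len_of <- numeric(n + tree$Nnode)
  parent_of[tree$edge[, 2]] <- tree$edge[, 1]
  len_of[tree$edge[, 2]] <- tree$edge.length
  path_to_root <- function(v) {
    out <- integer(0)
    while (v != n + 1L) { out <- c(out, v); v <- parent_of[v] }
    out
  }
  D <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  paths <- lapply(seq_len(n), path_to_root)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    shared <- intersect(paths[[i]], paths[[j]])
    D[i, j] <- sum(len_of[setdiff(paths[[i]], shared)]) +
      sum(len_of[setdiff(paths[[j]], shared)])
  }
  D
}

# naive disparity-through-time by explicit clade enumeration
naive_dtt <- function(tree, X, metric = "euclidean", squared = TRUE) {
  n <- ape::Ntip(tree)
  X <- as.matrix(X)[tree$tip.label, , drop = FALSE]
  pair_disp <- function(tips) {
    if (length(tips) < 2) return(0)
    M <- X[tips, , drop = FALSE]
    tot <- 0; np <- 0
    for (i in seq_along(tips)) for (j in seq_along(tips)) {
      if (j <= i) next
      d <- if (metric == "euclidean") {
        dd <- sqrt(sum((M[i, ] - M[j, ])^2))
        if (squared) dd^2 else dd
      } else sum(abs(M[i, ] - M[j, ]))
      tot <- tot + d; np <- np + 1
    }
    tot / np
  }
  clade_tips <- function(v) {
    if (v <= n) return(tree$tip.label[v])
    kids <- tree$edge[tree$edge[, 1] == v, 2]
    unlist(lapply(kids, clade_tips))
  }
  nt <- ape::node.depth.edgelength(tree)
  total <- pair_disp(tree$tip.label)
  internal <- (n + 1):(n + tree$Nnode)
  internal <- internal[order(nt[internal])]
  obs <- sapply(internal, function(v) {
    tv <- nt[v] + 1e-9 * max(nt)
    live <- which(nt[tree$edge[, 1]] <= tv & nt[tree$edge[, 2]] > tv)
    mean(sapply(tree$edge[live, 2],
                function(w) pair_disp(clade_tips(w)) / total))
  })
  data.frame(node = internal, time = nt[internal], observed = obs)
}

# exhaustive-enumeration marginals for the ER Mk model at a given rate
enumerate_mk_marginals <- function(tree, tip_states, levels, q) {
  k <- length(levels)
  n <- ape::Ntip(tree)
  tipidx <- match(tip_states[tree$tip.label], levels)
  P <- function(t) {
    e <- exp(-k * q * t)
    M <- matrix((1 - e) / k, k, k); diag(M) <- (1 + (k - 1) * e) / k
    M
  }
  grid <- expand.grid(rep(list(seq_len(k)), tree$Nnode))
  jp <- apply(grid, 1L, function(g) {
    st <- c(tipidx, as.integer(g))
    pr <- 1 / k
    for (e in seq_len(nrow(tree$edge)))
      pr <- pr * P(tree$edge.length[e])[st[tree$edge[e, 1]],
                                        st[tree$edge[e, 2]]]
    pr
  })
  marg <- sapply(seq_len(tree$Nnode), function(i)
    sapply(seq_len(k), function(s) sum(jp[grid[, i] == s])) / sum(jp))
  list(marginals = t(marg), loglik = log(sum(jp)))
}

# Euler-Maruyama simulation of a single-regime OU process on a 3-tip
# tree ((A:t1,B:t1):t1,C:2*t1), theta = 0, root at 0; returns tip
# states as a reps x (3 p) matrix (A, B, C blocks, trait-major columns)
em_three_tip <- function(A, S, t1, reps, dt = 1e-3) {
  p <- nrow(A)
  step_seg <- function(X, tlen) {
    nsteps <- round(tlen / dt)
    for (s in seq_len(nsteps)) {
      X <- X - (X %*% t(A)) * dt +
        matrix(rnorm(nrow(X) * p), ncol = p) %*% t(S) * sqrt(dt)
    }
    X
  }
  root <- matrix(0, reps, p)
  anc <- step_seg(root, t1)      # root -> mrca(A,B)
  tipA <- step_seg(anc, t1)
  tipB <- step_seg(anc, t1)
  tipC <- step_seg(root, 2 * t1)
  cbind(tipA, tipB, tipC)
}

# small utility: RMS per-point deviation after optimal similarity
# alignment of shape `est` onto `ref`
aligned_rms <- function(est, ref) {
  ctr <- function(p) sweep(p, 2L, colMeans(p))
  est <- ctr(est); ref <- ctr(ref)
  sv <- svd(crossprod(est, ref))
  R <- sv$u %*% diag(c(1, sign(det(sv$u %*% t(sv$v))))) %*% t(sv$v)
  est <- est %*% R
  beta <- sum(est * ref) / sum(est^2)
  sqrt(mean(rowSums((beta * est - ref)^2)))
}

# simulate a regime history conditioned on every regime appearing on at
# least one branch
painting_with_all_regimes <- function(tree, n_regimes, rate, seed,
                                      labels = NULL, root_regime = NULL) {
  for (try in 0:50) {
    p <- simulate_regime_history(tree, n_regimes, rate, seed = seed + 1000 * try,
                                 labels = labels, root_regime = root_regime)
    if (length(unique(p$edge_regime)) == n_regimes) return(p)
  }
  stop("could not realize all regimes")
}
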