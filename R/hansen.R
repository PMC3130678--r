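# Multi-peak multivariate Ornstein-Uhlenbeck (Hansen) models on a
# painted phylogeny:  dX = A (theta_r - X) dt + S dB, with one symmetric
# positive-definite selection matrix A and one diffusion factor S shared
# by all regimes, and one optimum theta_r per regime.  The optima are
# concentrated out of the likelihood by GLS given (A, S); (A, S) are
# maximized over a log-Cholesky parameterization by a quasi-Newton
# search (with a simplex fallback).  All covariance algebra is done in the eigenbasis of
# A, where the regime-weight design is diagonal and the tip covariance
# has the closed form used by tip_covariance().

# ---- parameter counting and information criteria ---------------------

#' Free-parameter count of a BM or multi-peak OU model
#'
#' OU: `2 p(p+1)/2 + p n_theta` (the A and S matrices plus one optimum
#' per regime); BM: `p(p+1)/2 + p` (rate matrix plus root mean).  The
#' univariate OU case reduces to `2 + n_theta`.
#'
#' @param p trait count.
#' @param n_theta number of optima (OU only).
#' @param model_class `"OU"` or `"BM"`.
#' @return integer.
#' @export
count_dof <- function(p, n_theta = NULL, model_class = c("OU", "BM")) {
  model_class <- match.arg(model_class)
  if (p < 1) stop_invalid("p must be >= 1")
  if (model_class == "BM") return(as.integer(p * (p + 1) / 2 + p))
  if (is.null(n_theta) || n_theta < 1) stop_invalid("n_theta must be >= 1")
  as.integer(p * (p + 1) + p * n_theta)
}

#' Sample-size-corrected AIC and Schwarz criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`; `SIC = -2 lnL + k ln(n)`.
#'
#' @param log_likelihood maximized log-likelihood.
#' @param k free-parameter count.
#' @param n effective sample size (must exceed k + 1 for the AICc).
#' @return list with `AICc` and `SIC`.
#' @export
information_criteria <- function(log_likelihood, k, n) {
  if (n <= k + 1)
    stop_invalid("AICc undefined: n = ", n, " <= k + 1 = ", k + 1)
  list(AICc = -2 * log_likelihood + 2 * k + 2 * k * (k + 1) / (n - k - 1),
       SIC = -2 * log_likelihood + k * log(n))
}

#' Information-criterion deltas and Akaike-type weights
#'
#' `delta_i = value_i - min(value)`;
#' `w_i = exp(-delta_i / 2) / sum_j exp(-delta_j / 2)`.
#'
#' @param values criterion values (AICc or SIC) across a model set.
#' @return list with `delta` and `weights` (summing to 1).
#' @export
ic_weights <- function(values) {
  if (length(values) < 2) stop_invalid("need >= 2 models")
  delta <- values - min(values)
  w <- exp(-delta / 2)
  list(delta = delta, weights = w / sum(w))
}

# criteria for a fitted model; AICc becomes NA (with a warning) when the
# effective sample size cannot support it
safe_ic <- function(log_likelihood, k, n) {
  if (n <= k + 1) {
    warning("AICc undefined at n = ", n, ", k = ", k, "; reporting NA")
    return(list(AICc = NA_real_, SIC = -2 * log_likelihood + k * log(n)))
  }
  information_criteria(log_likelihood, k, n)
}

# ---- shared precomputation -------------------------------------------

hansen_pre <- function(tree, painting, data = NULL) {
  n <- ape::Ntip(tree)
  if (anyNA(painting$edge_regime))
    stop_invalid("painting incomplete: unpainted branch")
  segs <- path_segments(tree, painting)
  X <- NULL
  if (!is.null(data)) {
    X <- as.matrix(data)
    if (is.null(rownames(X))) stop_invalid("data must have species rownames")
    if (!all(tree$tip.label %in% rownames(X)))
      stop_invalid("missing species in data")
    X <- X[tree$tip.label, , drop = FALSE]
    if (anyNA(X)) stop_invalid("missing trait values")
  }
  Smat <- mrca_times(tree)
  depth <- segs$depth
  TiM <- matrix(depth, n, n)
  list(n = n, segs = segs, Smat = Smat, depth = depth,
       TiM = TiM, TjM = t(TiM), Dif = TiM - Smat,
       nr = length(painting$regime_labels),
       root_regime = match(painting$root_state, painting$regime_labels),
       labels = painting$regime_labels, X = X,
       tip_labels = tree$tip.label)
}

# flat list handed to the compiled likelihood
cpp_pre <- function(pre) {
  list(X = unname(pre$X), Smat = pre$Smat, Dif = pre$Dif,
       depth = pre$depth,
       seg_tip = as.integer(pre$segs$tip), seg_ta = pre$segs$ta,
       seg_tb = pre$segs$tb, seg_regime = as.integer(pre$segs$regime),
       nr = as.integer(pre$nr), root_regime = as.integer(pre$root_regime))
}

# scalar regime-weight design for one eigenvalue: n x nr matrix, with
# the root weight folded into the root regime's column
eigen_design <- function(pre, lam_k) {
  segs <- pre$segs
  val <- exp(-lam_k * (pre$depth[segs$tip] - segs$tb)) -
    exp(-lam_k * (pre$depth[segs$tip] - segs$ta))
  W <- matrix(0, pre$n, pre$nr)
  lin <- (segs$regime - 1L) * pre$n + segs$tip
  rs <- rowsum(val, lin)
  W[as.integer(rownames(rs))] <- rs
  W[, pre$root_regime] <- W[, pre$root_regime] + exp(-lam_k * pre$depth)
  W
}

# np x np tip covariance in the eigenbasis of A (trait-major blocks)
vtilde_blocks <- function(pre, D, lam) {
  p <- length(lam)
  n <- pre$n
  V <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) for (l in seq_len(k)) {
    ls <- lam[k] + lam[l]
    phi <- if (ls > 1e-12) -expm1(-ls * pre$Smat) / ls else pre$Smat
    M <- D[k, l] * exp(-lam[k] * (pre$TiM - pre$Smat) -
                         lam[l] * (pre$TjM - pre$Smat)) * phi
    V[(k - 1L) * n + seq_len(n), (l - 1L) * n + seq_len(n)] <- M
    if (l != k)
      V[(l - 1L) * n + seq_len(n), (k - 1L) * n + seq_len(n)] <- t(M)
  }
  V
}

# log-likelihood with theta concentrated out by GLS; returns pieces
hansen_eval <- function(pre, A, S) {
  p <- nrow(A)
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  lam <- eig$values
  if (any(lam <= 0)) return(list(loglik = -Inf))
  U <- eig$vectors
  Sigma <- S %*% t(S)
  D <- t(U) %*% Sigma %*% U
  V <- vtilde_blocks(pre, D, lam)
  R <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(R)) return(list(loglik = -Inf))
  n <- pre$n; nr <- pre$nr
  W <- matrix(0, n * p, nr * p)
  for (k in seq_len(p))
    W[(k - 1L) * n + seq_len(n), (k - 1L) * nr + seq_len(nr)] <-
      eigen_design(pre, lam[k])
  Z <- pre$X %*% U
  z <- as.vector(Z)
  Wt <- backsolve(R, W, transpose = TRUE)
  zt <- backsolve(R, z, transpose = TRUE)
  G <- crossprod(Wt)
  th <- tryCatch(solve(G, crossprod(Wt, zt)), error = function(e) NULL)
  if (is.null(th)) return(list(loglik = -Inf))
  resid <- zt - Wt %*% th
  quad <- sum(resid^2)
  logdet <- 2 * sum(log(diag(R)))
  ll <- -0.5 * (n * p * log(2 * pi) + logdet + quad)
  theta_tilde <- matrix(th, nr, p)
  theta <- theta_tilde %*% t(U)
  dimnames(theta) <- list(pre$labels, colnames(pre$X))
  list(loglik = ll, theta = theta, U = U, lam = lam, R = R, W = W,
       Wt = Wt, G = G)
}

par_to_AS <- function(par, p) {
  nL <- p * (p + 1) / 2
  L <- matrix(0, p, p)
  L[lower.tri(L, diag = TRUE)] <- par[seq_len(nL)]
  diag(L) <- exp(diag(L))
  A <- L %*% t(L)
  Ls <- matrix(0, p, p)
  Ls[lower.tri(Ls, diag = TRUE)] <- par[nL + seq_len(nL)]
  diag(Ls) <- exp(diag(Ls))
  list(A = A, S = Ls)
}

# ---- public operations ------------------------------------------------

#' Regime weight blocks for every tip
#'
#' For tip `i` with root-to-tip segments `(t_a, t_b]` painted regime
#' `r`, the weight block is the sum over r's segments of
#' `exp(-A (T_i - t_b)) - exp(-A (T_i - t_a))`; the root block is
#' `exp(-A T_i)`.  Root block plus all regime blocks sum to the
#' identity for every tip.
#'
#' @param tree a `phylo` object.
#' @param painting a `"regime_painting"`.
#' @param A p x p symmetric positive-definite selection matrix.
#' @return list with `regime` (array n x n_regimes x p x p) and `root`
#'   (array n x p x p).
#' @export
regime_weights <- function(tree, painting, A) {
  A <- as.matrix(A)
  p <- nrow(A)
  if (!isSymmetric(unname(A), tol = 1e-8)) stop_invalid("A must be symmetric")
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (any(eig$values <= 0)) stop_invalid("A must be positive definite")
  pre <- hansen_pre(tree, painting)
  n <- pre$n; nr <- pre$nr
  U <- eig$vectors
  # scalar designs per eigenvalue, root weight NOT folded here
  segs <- pre$segs
  reg <- array(0, c(n, nr, p, p),
               dimnames = list(pre$tip_labels, pre$labels, NULL, NULL))
  root <- array(0, c(n, p, p), dimnames = list(pre$tip_labels, NULL, NULL))
  Wk <- vector("list", p)
  for (k in seq_len(p)) {
    val <- exp(-eig$values[k] * (pre$depth[segs$tip] - segs$tb)) -
      exp(-eig$values[k] * (pre$depth[segs$tip] - segs$ta))
    W <- matrix(0, n, nr)
    rs <- rowsum(val, (segs$regime - 1L) * n + segs$tip)
    W[as.integer(rownames(rs))] <- rs
    Wk[[k]] <- W
  }
  for (i in seq_len(n)) {
    for (r in seq_len(nr)) {
      w <- vapply(Wk, function(W) W[i, r], 0)
      reg[i, r, , ] <- U %*% (w * t(U))
    }
    root[i, , ] <- U %*% (exp(-eig$values * pre$depth[i]) * t(U))
  }
  list(regime = reg, root = root)
}

#' Tip covariance matrix of a multivariate OU process on a tree
#'
#' Covariance conditional on a fixed root.  With `A = U L U'` and
#' `D = U' Sigma U`, the covariance between tips i and j (shared time
#' `s_ij`, depths `T_i`, `T_j`) in the eigenbasis is
#' `D_kl exp(-l_k (T_i - s)) exp(-l_l (T_j - s)) (1 - exp(-(l_k+l_l) s))
#' / (l_k + l_l)` (the `l_k + l_l -> 0` limit replaces the bracket with
#' `s`, the Brownian case), back-transformed by `U`.
#'
#' @param tree a `phylo` object.
#' @param A p x p symmetric positive-semidefinite selection matrix.
#' @param Sigma p x p symmetric positive-semidefinite diffusion
#'   covariance (`S S'`).
#' @param trait_major if TRUE (default) the (n p) x (n p) matrix is
#'   organized as p x p blocks of n x n; otherwise species-major.
#' @return an (n p) x (n p) covariance matrix.
#' @export
tip_covariance <- function(tree, A, Sigma, trait_major = TRUE) {
  A <- as.matrix(A); Sigma <- as.matrix(Sigma)
  if (!isSymmetric(unname(A), tol = 1e-8)) stop_invalid("A must be symmetric")
  eig <- eigen((A + t(A)) / 2, symmetric = TRUE)
  if (any(eig$values < -1e-10)) stop_invalid("A must be positive semi-definite")
  lam <- pmax(eig$values, 0)
  U <- eig$vectors
  p <- nrow(A)
  n <- ape::Ntip(tree)
  painting <- constant_painting(tree)
  pre <- hansen_pre(tree, painting)
  D <- t(U) %*% Sigma %*% U
  Vt <- vtilde_blocks(pre, D, lam)
  # back-transform: V = (U (x) I_n) Vt (U' (x) I_n)
  K <- kronecker(U, diag(n))
  V <- K %*% Vt %*% t(K)
  if (!trait_major) {
    perm <- as.vector(t(matrix(seq_len(n * p), n, p)))
    V <- V[perm, perm]
  }
  V
}

# trivial single-regime painting (used where only tree times matter)
constant_painting <- function(tree, label = "R1") {
  n <- ape::Ntip(tree)
  node_states <- stats::setNames(rep(label, tree$Nnode),
                                 as.character(n + seq_len(tree$Nnode)))
  tip_states <- stats::setNames(rep(label, n), tree$tip.label)
  new_regime_painting(tree, node_states, tip_states, label)
}

#' Fit a multi-peak multivariate OU (Hansen) model
#'
#' Inner step: given (A, S) the optima are the GLS solution
#' `theta = (W' V^-1 W)^-1 W' V^-1 y` with W the stacked regime-weight
#' design (the root weight folded into the root regime's column, i.e.
#' the root state is tied to the root-regime optimum) and V the OU tip
#' covariance.  Outer step: the multivariate normal log-likelihood is
#' maximized over A (log-Cholesky, symmetric positive definite) and S
#' (lower triangular, positive diagonal) by Nelder-Mead from identity
#' starts.
#'
#' @param tree a `phylo` object.
#' @param data species x p trait matrix (rownames = tip labels).
#' @param painting a `"regime_painting"` covering every branch.
#' @param start optional start values: list with `A` and `S`.
#' @param max_eval maximum likelihood evaluations.
#' @param tol relative convergence tolerance on the log-likelihood.
#' @param use_compiled use the compiled likelihood kernel (the pure-R
#'   evaluator is retained as a reference and for this switch).
#' @param method outer optimizer: `"nlminb"` (quasi-Newton with
#'   finite-difference gradients; default) or `"nelder-mead"`; the
#'   quasi-Newton run falls back to the simplex if it fails to improve
#'   on the identity start.
#' @return object of class `"hansen"`.
#' @export
fit_hansen <- function(tree, data, painting, start = NULL,
                       max_eval = 5000L, tol = 1e-8,
                       use_compiled = TRUE,
                       method = c("nlminb", "nelder-mead")) {
  unused <- setdiff(painting$regime_labels,
                    c(painting$edge_regime, painting$root_state))
  if (length(unused))
    stop_invalid("optimum unidentifiable: regime(s) on no branch: ",
                 paste(unused, collapse = ", "))
  pre <- hansen_pre(tree, painting, data)
  p <- ncol(pre$X)
  if (pre$n < 3) stop_invalid("need >= 3 species")
  nL <- p * (p + 1) / 2
  par0 <- numeric(2 * nL)
  if (!is.null(start)) {
    LA <- chol(start$A); LA <- t(LA)
    v <- LA; diag(v) <- log(diag(v))
    par0[seq_len(nL)] <- v[lower.tri(v, diag = TRUE)]
    LS <- as.matrix(start$S)
    v <- LS; diag(v) <- log(diag(v))
    par0[nL + seq_len(nL)] <- v[lower.tri(v, diag = TRUE)]
  }
  if (use_compiled) {
    cp <- cpp_pre(pre)
    nll <- function(par) hansen_nll_cpp(par, cp)
  } else {
    nll <- function(par) {
      m <- par_to_AS(par, p)
      ll <- hansen_eval(pre, m$A, m$S)$loglik
      if (!is.finite(ll)) 1e10 else -ll
    }
  }
  method <- match.arg(method)
  if (method == "nlminb") {
    o <- stats::nlminb(par0, nll,
                       control = list(eval.max = max_eval,
                                      iter.max = max_eval, rel.tol = tol))
    opt <- list(par = o$par, value = o$objective,
                convergence = o$convergence,
                counts = c(`function` = unname(o$evaluations[1])))
    # guard against quasi-Newton stalls: fall back to the simplex
    if (o$objective > nll(par0) - 1e-8) {
      o2 <- stats::optim(par0, nll, method = "Nelder-Mead",
                         control = list(maxit = max_eval, reltol = tol))
      if (o2$value < opt$value)
        opt <- o2
    }
  } else {
    opt <- stats::optim(par0, nll, method = "Nelder-Mead",
                        control = list(maxit = max_eval, reltol = tol))
  }
  if (opt$convergence != 0 && method == "nelder-mead")
    warning("optimizer did not converge (code ", opt$convergence,
            "); returning best-found fit")
  m <- par_to_AS(opt$par, p)
  ev <- hansen_eval(pre, m$A, m$S)
  k <- count_dof(p, pre$nr, "OU")
  n_eff <- pre$n * p
  ic <- safe_ic(ev$loglik, k, n_eff)
  structure(list(A = m$A, S = m$S, Sigma = m$S %*% t(m$S),
                 theta = ev$theta,
                 root_state = ev$theta[pre$root_regime, ],
                 painting = painting, tree = tree, data = pre$X,
                 log_likelihood = ev$loglik, k = k, n = pre$n,
                 n_eff = n_eff, p = p,
                 AICc = ic$AICc, SIC = ic$SIC,
                 optim = opt[c("convergence", "counts", "value")],
                 start_loglik = -nll(par0)),
            class = "hansen")
}

#' Fit multivariate Brownian motion on a tree
#'
#' ML root mean (GLS) and rate matrix (ML denominator n).
#'
#' @param tree a `phylo` object.
#' @param data species x p trait matrix.
#' @return object of class `"bm_fit"`.
#' @export
fit_bm <- function(tree, data) {
  X <- as.matrix(data)
  if (is.null(rownames(X))) stop_invalid("data must have species rownames")
  X <- X[tree$tip.label, , drop = FALSE]
  if (anyNA(X)) stop_invalid("missing trait values")
  n <- nrow(X); p <- ncol(X)
  if (n < 2) stop_invalid("need >= 2 species")
  C <- mrca_times(tree)
  R <- chol(C)
  Xw <- backsolve(R, X, transpose = TRUE)
  ow <- backsolve(R, matrix(1, n, 1), transpose = TRUE)
  mu <- solve(crossprod(ow), crossprod(ow, Xw))
  resid <- Xw - ow %*% mu
  Sigma <- crossprod(resid) / n
  ld_sigma <- as.numeric(determinant(Sigma, logarithm = TRUE)$modulus)
  ll <- -0.5 * (n * p * log(2 * pi) + p * 2 * sum(log(diag(R))) +
                  n * ld_sigma + n * p)
  k <- count_dof(p, model_class = "BM")
  n_eff <- n * p
  ic <- safe_ic(ll, k, n_eff)
  structure(list(root_state = drop(mu), Sigma = Sigma,
                 tree = tree, data = X,
                 log_likelihood = ll, k = k, n = n, n_eff = n_eff, p = p,
                 AICc = ic$AICc, SIC = ic$SIC),
            class = "bm_fit")
}

# ---- S3 methods -------------------------------------------------------

#' @export
print.hansen <- function(x, ...) {
  cat(sprintf("Multi-peak OU (Hansen) model: %d regimes, %d traits, %d species\n",
              nrow(x$theta), x$p, x$n))
  cat(sprintf("logLik = %.3f  k = %d  AICc = %.2f  SIC = %.2f\n",
              x$log_likelihood, x$k, x$AICc, x$SIC))
  cat("\nOptima (theta):\n"); print(round(x$theta, 4))
  cat("\nSelection matrix A (eigenvalues ",
      paste(sprintf("%.3g", eigen(x$A, symmetric = TRUE,
                                  only.values = TRUE)$values),
            collapse = ", "), "):\n", sep = "")
  print(round(x$A, 4))
  invisible(x)
}

#' @export
summary.hansen <- function(object, ...) {
  print(object)
  cat("\nDiffusion Sigma = S S':\n"); print(round(object$Sigma, 4))
  cat("\nPhylogenetic half-life per A eigenvalue (My):\n")
  print(round(log(2) / eigen(object$A, symmetric = TRUE,
                             only.values = TRUE)$values, 3))
  invisible(object)
}

#' @export
coef.hansen <- function(object, ...) object$theta

#' @export
logLik.hansen <- function(object, ...) {
  structure(object$log_likelihood, df = object$k, nobs = object$n_eff,
            class = "logLik")
}

#' @export
fitted.hansen <- function(object, ...) {
  w <- regime_weights(object$tree, object$painting, object$A)
  n <- object$n; p <- object$p
  nr <- nrow(object$theta)
  rr <- match(object$painting$root_state, object$painting$regime_labels)
  out <- matrix(0, n, p, dimnames = dimnames(object$data))
  for (i in seq_len(n)) {
    mu <- as.vector(matrix(w$root[i, , ], p, p) %*% object$theta[rr, ])
    for (r in seq_len(nr))
      mu <- mu + as.vector(matrix(w$regime[i, r, , ], p, p) %*%
                             object$theta[r, ])
    out[i, ] <- mu
  }
  out
}

#' @export
residuals.hansen <- function(object, ...) object$data - fitted(object)

#' @export
simulate.hansen <- function(object, nsim = 1, seed = NULL, ...) {
  with_seed(seed, {
    lapply(seq_len(nsim), function(b)
      simulate_ou_traits(object$tree, object$painting, object$A, object$S,
                         object$theta, object$root_state))
  })
}

#' @export
plot.hansen <- function(x, dims = c(1, 2), ...) {
  if (x$p < 2) {
    graphics::plot(x$data[, 1], rep(0, x$n), xlab = colnames(x$data)[1],
                   ylab = "", yaxt = "n", ...)
    graphics::abline(v = x$theta[, 1], col = seq_len(nrow(x$theta)) + 1)
  } else {
    cols <- match(x$painting$tip_states, x$painting$regime_labels) + 1
    graphics::plot(x$data[, dims], col = cols, pch = 16, ...)
    graphics::points(x$theta[, dims], pch = 8, cex = 2,
                     col = seq_len(nrow(x$theta)) + 1)
  }
  invisible(x)
}

#' @export
print.bm_fit <- function(x, ...) {
  cat(sprintf("Brownian motion: %d traits, %d species\n", x$p, x$n))
  cat(sprintf("logLik = %.3f  k = %d  AICc = %.2f  SIC = %.2f\n",
              x$log_likelihood, x$k, x$AICc, x$SIC))
  cat("\nRoot state:\n"); print(round(x$root_state, 4))
  cat("\nRate matrix:\n"); print(round(x$Sigma, 5))
  invisible(x)
}

#' @export
logLik.bm_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$k, nobs = object$n_eff,
            class = "logLik")
}

#' @export
coef.bm_fit <- function(object, ...) object$root_state

# ---- model comparison -------------------------------------------------

#' Merge regime labels of a painting into coarser regimes
#'
#' @param painting a `"regime_painting"`.
#' @param groups named list: new label -> character vector of old labels.
#' @return a `"regime_painting"` over the new labels.
#' @export
merge_regimes <- function(painting, groups) {
  old <- unlist(groups)
  if (!setequal(old, painting$regime_labels))
    stop_invalid("groups must partition the existing regime labels")
  map <- stats::setNames(rep(names(groups), lengths(groups)), old)
  node_states <- stats::setNames(map[painting$node_states],
                                 names(painting$node_states))
  tip_states <- stats::setNames(map[painting$tip_states],
                                names(painting$tip_states))
  out <- painting
  out$edge_regime <- unname(map[painting$edge_regime])
  out$node_states <- node_states
  out$tip_states <- tip_states
  out$regime_labels <- names(groups)
  out$root_state <- unname(map[painting$root_state])
  out$events_per_edge <- NULL
  out
}

#' Fit and compare BM and multi-peak OU models
#'
#' Fits Brownian motion plus one Hansen model per supplied painting,
#' computes AICc and SIC with deltas and weights within the set, and
#' flags the best model per criterion.
#'
#' @param tree a `phylo` object.
#' @param data species x p trait matrix.
#' @param paintings named list of `"regime_painting"` objects (e.g.
#'   OU.2 ... OU.5).
#' @param ... passed to [fit_hansen()].
#' @return object of class `"model_comparison"`: a `table` data frame
#'   and the list of `fits`.
#' @export
compare_models <- function(tree, data, paintings, ...) {
  fits <- list(BM = fit_bm(tree, data))
  for (nm in names(paintings))
    fits[[nm]] <- fit_hansen(tree, data, paintings[[nm]], ...)
  aicc <- vapply(fits, `[[`, 0, "AICc")
  sic <- vapply(fits, `[[`, 0, "SIC")
  wa <- ic_weights(aicc); ws <- ic_weights(sic)
  tab <- data.frame(model = names(fits),
                    logLik = vapply(fits, `[[`, 0, "log_likelihood"),
                    DOF = vapply(fits, `[[`, 0L, "k"),
                    AICc = aicc, dAICc = wa$delta, wAICc = wa$weights,
                    SIC = sic, dSIC = ws$delta, wSIC = ws$weights,
                    row.names = NULL)
  structure(list(table = tab, fits = fits,
                 n_eff = fits[[1]]$n_eff,
                 best_AICc = tab$model[which.min(aicc)],
                 best_SIC = tab$model[which.min(sic)]),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, digits = 4, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  cat(sprintf("\nbest by AICc: %s   best by SIC: %s   (n_eff = %d)\n",
              x$best_AICc, x$best_SIC, x$n_eff))
  invisible(x)
}

# ---- parametric bootstrap of optima ----------------------------------

#' Parametric bootstrap confidence regions for adaptive optima
#'
#' Simulates `n_boot` datasets from the fitted model and refits the
#' optima; `refit = "full"` re-estimates (A, S) per replicate,
#' `refit = "theta"` holds them at the fitted values (the conditional
#' GLS bootstrap).  95% regions are percentile intervals for univariate
#' fits and mean + sample-covariance ellipsoids at the chi-square
#' quantile for multivariate fits.
#'
#' @param fitted a `"hansen"` fit.
#' @param n_boot number of replicates (default 5000).
#' @param seed integer seed.
#' @param refit `"full"` or `"theta"`.
#' @param level coverage level (default 0.95).
#' @param max_dropped maximum tolerated fraction of non-converged
#'   replicates before failing.
#' @return object of class `"optima_bootstrap"`.
#' @export
bootstrap_optima <- function(fitted, n_boot = 5000L, seed = NULL,
                             refit = c("full", "theta"), level = 0.95,
                             max_dropped = 0.1) {
  refit <- match.arg(refit)
  stopifnot(inherits(fitted, "hansen"))
  tree <- fitted$tree; painting <- fitted$painting
  pre <- hansen_pre(tree, painting, fitted$data)
  p <- fitted$p; nr <- nrow(fitted$theta)
  samples <- array(NA_real_, c(n_boot, nr, p),
                   dimnames = list(NULL, rownames(fitted$theta),
                                   colnames(fitted$theta)))
  dropped <- 0L
  if (refit == "theta") {
    # with (A, S) held fixed the refitted optima are exactly Gaussian:
    # theta* = theta_hat + (W'V^-1 W)^-1 W'V^-1 eps, so replicates are
    # drawn from that conditional distribution directly
    ev <- hansen_eval(pre, fitted$A, fitted$S)
    P <- solve(ev$G, t(ev$Wt))        # maps whitened noise to theta~
    th_tilde <- as.vector(fitted$theta %*% ev$U)
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        zeta <- stats::rnorm(pre$n * p)
        samples[b, , ] <- matrix(th_tilde + P %*% zeta, nr, p) %*% t(ev$U)
      }
    })
  } else {
    with_seed(seed, {
      for (b in seq_len(n_boot)) {
        Xb <- simulate_ou_traits(tree, painting, fitted$A, fitted$S,
                                 fitted$theta, fitted$root_state)
        fb <- tryCatch(fit_hansen(tree, Xb, painting,
                                  start = list(A = fitted$A, S = fitted$S)),
                       error = function(e) NULL, warning = function(w) NULL)
        if (is.null(fb)) { dropped <- dropped + 1L; next }
        samples[b, , ] <- fb$theta
      }
    })
  }
  if (dropped / n_boot > max_dropped)
    stop_invalid(dropped, " of ", n_boot, " bootstrap replicates failed")
  keep <- !is.na(samples[, 1L, 1L])
  samples <- samples[keep, , , drop = FALSE]
  a <- (1 - level) / 2
  regions <- vector("list", nr)
  names(regions) <- rownames(fitted$theta)
  for (r in seq_len(nr)) {
    th_s <- samples[, r, , drop = FALSE]
    dim(th_s) <- c(sum(keep), p)
    if (p == 1) {
      regions[[r]] <- list(interval = stats::quantile(th_s[, 1],
                                                      c(a, 1 - a)),
                           center = mean(th_s[, 1]))
    } else {
      regions[[r]] <- list(center = colMeans(th_s),
                           cov = stats::cov(th_s),
                           radius2 = stats::qchisq(level, p))
    }
  }
  structure(list(theta_samples = samples, regions = regions,
                 point_estimate = fitted$theta,
                 n_boot = n_boot, n_used = sum(keep), dropped = dropped,
                 level = level, refit = refit, seed = seed, p = p),
            class = "optima_bootstrap")
}

#' Test whether points fall inside the bootstrap confidence regions
#'
#' @param boot an `"optima_bootstrap"`.
#' @param theta n_regimes x p matrix of points (default the fit's own
#'   point estimates).
#' @return named logical vector per regime.
#' @export
optima_in_regions <- function(boot, theta = boot$point_estimate) {
  theta <- as.matrix(theta)
  out <- logical(length(boot$regions))
  names(out) <- names(boot$regions)
  for (r in seq_along(boot$regions)) {
    rg <- boot$regions[[r]]
    if (boot$p == 1) {
      out[r] <- theta[r, 1] >= rg$interval[1] && theta[r, 1] <= rg$interval[2]
    } else {
      d <- theta[r, ] - rg$center
      md2 <- tryCatch(as.numeric(t(d) %*% solve(rg$cov, d)),
                      error = function(e) Inf)
      out[r] <- md2 <= rg$radius2
    }
  }
  out
}

#' @export
print.optima_bootstrap <- function(x, ...) {
  cat(sprintf("Parametric bootstrap of optima: %d replicates (%s refit), %.0f%% regions\n",
              x$n_used, x$refit, 100 * x$level))
  if (x$dropped > 0) cat(x$dropped, "replicates dropped\n")
  for (r in names(x$regions)) {
    rg <- x$regions[[r]]
    if (x$p == 1)
      cat(sprintf("  %s: %.4f  [%.4f, %.4f]\n", r, x$point_estimate[r, 1],
                  rg$interval[1], rg$interval[2]))
    else
      cat(sprintf("  %s: center (%s)\n", r,
                  paste(sprintf("%.4f", rg$center), collapse = ", ")))
  }
  invisible(x)
}
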