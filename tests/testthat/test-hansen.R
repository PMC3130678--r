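# Hansen model machinery: weights, covariances, likelihoods, fits,
# criteria, bootstrap, model comparison.

test_that("information criteria and weights follow their formulas", {
  ic <- information_criteria(0, 1, 11)
  expect_equal(ic$AICc, 2 + 4 / 9)
  ic2 <- information_criteria(0, 2, exp(2))
  expect_equal(ic2$SIC, 4)
  # AICc -> AIC for large n
  ic3 <- information_criteria(-10, 3, 1e9)
  expect_lt(abs(ic3$AICc - (20 + 6)), 1e-6)
  expect_error(information_criteria(0, 5, 6), "AICc undefined")

  w <- ic_weights(c(0, 2))
  expect_equal(unname(w$weights), c(1 / (1 + exp(-1)), exp(-1) / (1 + exp(-1))))
  expect_equal(round(unname(w$weights), 4), c(0.7311, 0.2689))
  set.seed(61)
  for (r in 1:5) {
    w <- ic_weights(rnorm(5, sd = 20))
    expect_equal(sum(w$weights), 1, tolerance = 1e-12)
    expect_equal(min(w$delta), 0)
  }
})

test_that("regime weights: closed form, saturation, identity sum, quadrature", {
  t2 <- read_newick("(A:1,B:1):0;")
  p1 <- simulate_regime_history(t2, 1, 0, seed = 1)
  a <- 0.7
  w <- regime_weights(t2, p1, matrix(a))
  expect_equal(w$regime[1, 1, 1, 1], 1 - exp(-a), tolerance = 1e-12)
  expect_equal(unname(w$root[1, 1, 1]), exp(-a), tolerance = 1e-12)

  wbig <- regime_weights(t2, p1, matrix(50))
  expect_equal(wbig$regime[1, 1, 1, 1], 1, tolerance = 1e-10)

  # root + regime blocks sum to the identity on random painted trees
  for (s in 1:3) {
    tr <- simulate_tree(10, 8, seed = 100 + s)
    pt <- simulate_regime_history(tr, 3, 0.1, seed = 110 + s)
    A <- crossprod(matrix(rnorm(4), 2)) + diag(0.1, 2)
    ww <- regime_weights(tr, pt, A)
    for (i in 1:10) {
      M <- matrix(ww$root[i, , ], 2, 2)
      for (r in 1:3) M <- M + matrix(ww$regime[i, r, , ], 2, 2)
      expect_lt(max(abs(M - diag(2))), 1e-10)
    }
  }

  # quadrature oracle: the weight of a regime along tip A's path is
  # int_seg A exp(-A (T - s)) ds summed over that regime's segments
  t3seg <- read_newick("((A:1,B:1):2,C:3):0;")
  pt3 <- simulate_regime_history(t3seg, 2, 0.8, seed = 7)
  A2 <- matrix(c(0.9, 0.2, 0.2, 0.3), 2, 2)     # distinct eigenvalues
  ww <- regime_weights(t3seg, pt3, A2)
  eig <- eigen(A2, symmetric = TRUE)
  expAt <- function(t) eig$vectors %*% (exp(-eig$values * t) * t(eig$vectors))
  segs <- list(c(0, 2), c(2, 3))                # (root->5], (5->A]
  reg_of_seg <- c(pt3$edge_regime[t3seg$edge[, 2] == 5],
                  pt3$edge_regime[t3seg$edge[, 2] == 1])
  Tdep <- 3
  expected <- lapply(pt3$regime_labels, function(r) matrix(0, 2, 2))
  names(expected) <- pt3$regime_labels
  for (g in 1:2) {
    grid <- seq(segs[[g]][1], segs[[g]][2], length.out = 4001)
    h <- diff(grid[1:2])
    vals <- lapply(grid, function(s) A2 %*% expAt(Tdep - s))
    wts <- rep(c(2, 4), length.out = length(grid))
    wts[1] <- 1; wts[length(grid)] <- 1
    quad <- Reduce(`+`, Map(`*`, vals, wts)) * h / 3
    expected[[reg_of_seg[g]]] <- expected[[reg_of_seg[g]]] + quad
  }
  for (r in seq_along(pt3$regime_labels))
    expect_lt(max(abs(matrix(ww$regime[1, r, , ], 2, 2) -
                        expected[[pt3$regime_labels[r]]])), 1e-8)
})

test_that("tip covariance: closed forms and the Brownian limit", {
  t3 <- read_newick("((A:1,B:1):1,C:2):0;")
  a <- 0.7; s2 <- 0.09
  V <- tip_covariance(t3, matrix(a), matrix(s2))
  expect_equal(V[1, 1], s2 * (1 - exp(-2 * a * 2)) / (2 * a),
               tolerance = 1e-12)
  expect_equal(V[1, 2], s2 * exp(-2 * a) * (1 - exp(-2 * a)) / (2 * a),
               tolerance = 1e-12)
  expect_equal(V[1, 3], 0)

  Sg <- matrix(c(0.2, 0.05, 0.05, 0.5), 2, 2)
  Vbm <- tip_covariance(t3, matrix(0, 2, 2), Sg)
  expect_equal(Vbm, kronecker(Sg, mrca_times(t3)), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(tip_covariance(t3, matrix(c(1, 2, 0, 1), 2), Sg),
               "symmetric")
})

test_that("compiled and reference likelihoods agree", {
  tr <- simulate_tree(12, 10, seed = 62)
  pt <- painting_with_all_regimes(tr, 3, 0.15, seed = 63)
  set.seed(64)
  X <- matrix(rnorm(24), 12, 2, dimnames = list(tr$tip.label, NULL))
  pre <- peakshift:::hansen_pre(tr, pt, X)
  cp <- peakshift:::cpp_pre(pre)
  for (r in 1:5) {
    par <- rnorm(6, sd = 0.5)
    m <- peakshift:::par_to_AS(par, 2)
    expect_equal(hansen_nll_cpp(par, cp),
                 -peakshift:::hansen_eval(pre, m$A, m$S)$loglik,
                 tolerance = 1e-9)
  }
})

test_that("parameter counts cover BM, multivariate and univariate OU", {
  expect_equal(count_dof(3, model_class = "BM"), 9L)
  expect_equal(count_dof(5, model_class = "BM"), 20L)
  expect_equal(count_dof(5, 5, "OU"), 55L)
  expect_equal(count_dof(3, 4, "OU"), 24L)
  expect_equal(count_dof(1, 5, "OU"), 7L)
  expect_error(count_dof(2, model_class = "OU"), "n_theta")
})

test_that("BM fit: closed forms and rate recovery", {
  t2 <- read_newick("(A:1,B:1):0;")
  x <- matrix(c(0, 2), dimnames = list(c("A", "B"), "x"))
  bm <- suppressWarnings(fit_bm(t2, x))
  expect_equal(unname(bm$root_state), 1)
  expect_equal(unname(bm$Sigma[1, 1]), 1)

  tr <- simulate_tree(128, 10, seed = 65)
  Rt <- chol(mrca_times(tr))
  sig <- 0.4
  set.seed(66)
  est <- vapply(1:30, function(r) {
    X <- t(Rt) %*% matrix(rnorm(128)) * sqrt(sig)
    rownames(X) <- tr$tip.label
    fit_bm(tr, X)$Sigma[1, 1]
  }, 0)
  expect_lt(abs(mean(est) / sig - 1), 0.1)
})

test_that("Hansen fit improves on its start and matches BM in the weak-selection limit", {
  tr <- simulate_tree(24, 12, seed = 67)
  pt1 <- simulate_regime_history(tr, 1, 0, seed = 68)
  set.seed(69)
  Rt <- chol(mrca_times(tr))
  X <- t(Rt) %*% matrix(rnorm(48), 24, 2) %*% chol(diag(c(0.3, 0.6)))
  rownames(X) <- tr$tip.label

  bm <- fit_bm(tr, X)
  pre <- peakshift:::hansen_pre(tr, pt1, X)
  Sbm <- t(chol(bm$Sigma))
  ou_at_zero <- peakshift:::hansen_eval(pre, diag(1e-8, 2), Sbm)
  expect_lt(abs(ou_at_zero$loglik - bm$log_likelihood), 0.1)

  pt3 <- simulate_regime_history(tr, 3, 0.1, seed = 70)
  th <- rbind(R1 = c(0, 0), R2 = c(1.5, -1), R3 = c(-1, 1))
  Xou <- simulate_ou_traits(tr, pt3, diag(0.6, 2), diag(0.3, 2), th,
                            seed = 71)
  f <- fit_hansen(tr, Xou, pt3)
  expect_gte(f$log_likelihood, f$start_loglik - 1e-8)
  expect_true(all(eigen(f$A, symmetric = TRUE, only.values = TRUE)$values > 0))
  # methods are coherent
  expect_equal(f$data, fitted(f) + residuals(f), tolerance = 1e-12)
  expect_equal(unname(coef(f)), unname(f$theta))
  expect_equal(as.numeric(logLik(f)), f$log_likelihood)
  sim <- simulate(f, nsim = 2, seed = 5)
  expect_length(sim, 2)
  expect_equal(dim(sim[[1]]), dim(f$data))
})

test_that("optima bootstrap is reproducible and consistent with its point estimates", {
  tr <- simulate_tree(32, 12, seed = 72)
  pt <- simulate_regime_history(tr, 2, 0.08, seed = 73)
  th <- rbind(R1 = c(0, 0), R2 = c(2, -1))
  X <- simulate_ou_traits(tr, pt, diag(0.5, 2), diag(0.25, 2), th, seed = 74)
  f <- fit_hansen(tr, X, pt)

  b1 <- bootstrap_optima(f, n_boot = 150, seed = 11, refit = "theta")
  b2 <- bootstrap_optima(f, n_boot = 150, seed = 11, refit = "theta")
  expect_identical(b1$theta_samples, b2$theta_samples)
  expect_true(all(optima_in_regions(b1)))

  # full-refit replicates distribute around the fitted optima too
  b3 <- bootstrap_optima(f, n_boot = 12, seed = 12, refit = "full")
  expect_equal(b3$n_used, 12)
  centers <- t(sapply(b3$regions, `[[`, "center"))
  expect_lt(max(abs(centers - f$theta)), 0.5)

  # univariate fits get percentile intervals
  X1 <- X[, 1, drop = FALSE]
  f1 <- fit_hansen(tr, X1, pt)
  b4 <- bootstrap_optima(f1, n_boot = 200, seed = 13, refit = "theta")
  expect_true(all(sapply(b4$regions, function(r) length(r$interval) == 2)))
  expect_true(all(optima_in_regions(b4)))
})

test_that("model comparison table is coherent and regime merging is a partition", {
  fx <- phyllostomid_like_fixture(seed = 21, n_specimens = 1)
  X <- fx$traits[, 1:2]
  grp <- diet_model_groupings()
  paintings <- lapply(grp[c("OU.2", "OU.5")],
                      function(g) merge_regimes(fx$painting, g))
  cm <- compare_models(fx$tree, X, paintings)
  expect_equal(sum(cm$table$wAICc), 1, tolerance = 1e-12)
  expect_equal(sum(cm$table$wSIC), 1, tolerance = 1e-12)
  expect_equal(cm$table$model, c("BM", "OU.2", "OU.5"))
  expect_equal(cm$table$DOF, c(count_dof(2, model_class = "BM"),
                               count_dof(2, 2), count_dof(2, 5)))
  expect_true(all(diff(order(cm$table$AICc)) != 0))

  m2 <- merge_regimes(fx$painting, grp$OU.2)
  expect_setequal(m2$regime_labels, c("mastication", "low_mastication"))
  expect_equal(length(m2$edge_regime), length(fx$painting$edge_regime))
  expect_error(merge_regimes(fx$painting,
                             list(a = c("insectivory", "carnivory"))),
               "partition")
})
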