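# Tree parsing, patristic distances, contrasts, ancestral states,
# regime painting.

test_that("Newick parsing validates and round-trips", {
  t2 <- read_newick("(A:1,B:1):0;")
  expect_equal(ape::Ntip(t2), 2)
  expect_equal(unname(node_times(t2)[1:2]), c(1, 1))

  t3 <- read_newick("((A:1,B:1):1,C:2):0;")
  expect_equal(unname(node_times(t3)[1:3]), c(2, 2, 2))

  fx <- simulate_tree(49, 30, seed = 17)
  rt <- read_newick(ape::write.tree(fx))
  lbl <- sort(fx$tip.label)
  expect_equal(patristic_distances(rt)[lbl, lbl],
               patristic_distances(fx)[lbl, lbl], tolerance = 1e-8)
  expect_error(read_newick("((A:1,B:1:2;"), "malformed")
  expect_error(read_newick("(A,B);"), "branch lengths")
})

test_that("patristic distances match a path-traversal oracle and are a metric", {
  t3 <- read_newick("((A:1,B:1):1,C:2):0;")
  D <- patristic_distances(t3)
  expect_equal(D["A", "B"], 2)
  expect_equal(D["A", "C"], 4)
  expect_equal(D["B", "C"], 4)

  for (s in 1:4) {
    tr <- simulate_tree(10, 7, seed = 60 + s)
    D <- patristic_distances(tr)
    expect_equal(D, path_patristic(tr)[rownames(D), colnames(D)],
                 tolerance = 1e-10)
    # triangle inequality
    n <- nrow(D)
    for (i in 1:n) for (j in 1:n) for (k in 1:n)
      expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
  }
})

test_that("independent contrasts: closed forms and rate recovery", {
  t2 <- read_newick("(A:1,B:1):0;")
  x <- matrix(c(0, 2), dimnames = list(c("A", "B"), "x"))
  ic <- independent_contrasts(t2, x)
  expect_equal(unname(abs(ic$contrasts[1, 1])), 2 / sqrt(2))

  tr <- simulate_tree(16, 10, seed = 19)
  const <- matrix(1, 16, 1, dimnames = list(tr$tip.label, "c"))
  icc <- independent_contrasts(tr, const)
  expect_true(all(abs(icc$contrasts) < 1e-12))
  expect_equal(icc$rate[1, 1], 0)

  # BM rate recovery at n = 128: relative bias below 10%
  tr128 <- simulate_tree(128, 10, seed = 20)
  Ct <- chol(mrca_times(tr128))
  sig <- 0.7
  set.seed(21)
  rates <- vapply(1:40, function(r) {
    X <- t(Ct) %*% matrix(rnorm(128), 128, 1) * sqrt(sig)
    rownames(X) <- tr128$tip.label
    independent_contrasts(tr128, X)$rate[1, 1]
  }, 0)
  expect_lt(abs(mean(rates) / sig - 1), 0.1)

  expect_error(independent_contrasts(tr, const[1:10, , drop = FALSE]),
               "species rownames|missing")
})

test_that("continuous ancestral ML equals the GLS mean at the root and a grid oracle", {
  star <- read_newick("(A:1,B:1,C:1):0;")
  vals <- c(A = 0, B = 2, C = 7)
  est <- ancestral_continuous_ml(star, vals)
  expect_equal(unname(est$node_values["4"]), 3, tolerance = 1e-6)

  t3 <- read_newick("((A:1,B:1):1,C:2):0;")
  v3 <- c(A = 0, B = 2, C = 3)
  est3 <- ancestral_continuous_ml(t3, v3)
  # brute-force BM likelihood maximization over (root, internal) grid
  ll <- function(r, a) {
    dnorm(a, r, sqrt(1), log = TRUE) + dnorm(3, r, sqrt(2), log = TRUE) +
      dnorm(0, a, sqrt(1), log = TRUE) + dnorm(2, a, sqrt(1), log = TRUE)
  }
  grid <- expand.grid(r = seq(0, 3, 5e-4), a = seq(0, 3, 5e-4))
  best <- grid[which.max(ll(grid$r, grid$a)), ]
  expect_equal(unname(est3$node_values["4"]), best$r, tolerance = 1e-3)
  expect_equal(unname(est3$node_values["5"]), best$a, tolerance = 1e-3)

  # root equals GLS grand mean 1'C^-1 x / 1'C^-1 1
  tr <- simulate_tree(12, 8, seed = 22)
  set.seed(23)
  x <- setNames(rnorm(12), tr$tip.label)
  C <- mrca_times(tr)
  w <- solve(C, rep(1, 12))
  gls_mean <- sum(w * x[rownames(C)]) / sum(w)
  est2 <- ancestral_continuous_ml(tr, x)
  expect_equal(unname(est2$node_values["13"]), gls_mean, tolerance = 1e-4)
})

test_that("discrete ancestral marginals match exhaustive enumeration", {
  t2 <- read_newick("(A:1,B:1):0;")
  est2 <- ancestral_discrete_ml(t2, c(A = "X", B = "Y"))
  expect_equal(unname(est2$node_state_probabilities[1, ]), c(0.5, 0.5),
               tolerance = 1e-9)

  tr <- simulate_tree(6, 5, seed = 24)
  same <- setNames(rep("X", 6), tr$tip.label)
  estx <- ancestral_discrete_ml(tr, same, levels = c("X", "Y"))
  expect_true(all(estx$node_state_probabilities[, "X"] > 0.99))
  expect_equal(estx$rate, 0)

  for (s in 1:4) {
    trs <- simulate_tree(5 + (s %% 2), 5, seed = 70 + s)
    k <- 2 + (s %% 2)
    lv <- LETTERS[1:k]
    set.seed(80 + s)
    st <- setNames(sample(lv, ape::Ntip(trs), replace = TRUE),
                   trs$tip.label)
    if (length(unique(st)) == 1) st[1] <- setdiff(lv, st[1])[1]
    est <- ancestral_discrete_ml(trs, st, levels = lv)
    orc <- enumerate_mk_marginals(trs, st, lv, est$rate)
    expect_equal(unname(est$node_state_probabilities),
                 unname(orc$marginals), tolerance = 1e-6)
    expect_equal(est$log_likelihood, orc$loglik, tolerance = 1e-8)
    expect_true(all(abs(rowSums(est$node_state_probabilities) - 1) < 1e-9))
  }
})

test_that("regime painting recovers a low-switch-rate history and breaks ties to the parent", {
  tr <- simulate_tree(49, 30, seed = 25)
  truth <- simulate_regime_history(tr, 3, 0.01, seed = 26)
  est <- ancestral_discrete_ml(tr, truth$tip_states,
                               levels = truth$regime_labels)
  painted <- paint_regimes(tr, est, truth$tip_states)
  agreement <- mean(painted$edge_regime == truth$edge_regime)
  expect_gte(agreement, 0.9)

  # all tips one diet: every branch painted that diet
  mono <- setNames(rep("frugivory", 49), tr$tip.label)
  estm <- ancestral_discrete_ml(tr, mono, levels = c("frugivory",
                                                     "insectivory"))
  pm <- paint_regimes(tr, estm, mono)
  expect_true(all(pm$edge_regime == "frugivory"))

  # a tied node resolves toward its parent's state
  t4 <- read_newick("(((A:1,B:1):1,C:2):1,D:3):0;")
  est_t <- list(node_state_probabilities =
                  rbind(`5` = c(X = 1, Y = 0),
                        `6` = c(X = 0.5, Y = 0.5),
                        `7` = c(X = 0.2, Y = 0.8)),
                levels = c("X", "Y"))
  tied <- paint_regimes(t4, est_t,
                        c(A = "Y", B = "Y", C = "X", D = "X"))
  expect_equal(unname(tied$node_states["6"]), "X")
})
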