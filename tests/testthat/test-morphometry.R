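# GPA, sliding, Procrustes distances, shape PCA, parallel analysis.

eq_triangle <- function() rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
iso_triangle <- function() rbind(c(0, 0), c(1, 0), c(0, 1))

test_that("centroid size: value, scaling and translation invariance", {
  sq <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  expect_equal(centroid_size(sq), 2 * sqrt(2))
  expect_equal(centroid_size(sq * 3), 3 * centroid_size(sq))
  expect_equal(centroid_size(sweep(sq, 2, c(5, -7), `+`)),
               centroid_size(sq))
  expect_error(centroid_size(matrix(1, 4, 2)), "degenerate")
})

test_that("GPA aligns similarity copies exactly and normalizes the consensus", {
  tri <- eq_triangle()
  rot <- matrix(c(0, 1, -1, 0), 2, 2)   # 90 degrees
  al <- gpa(list(tri, tri %*% rot))
  expect_lt(sqrt(sum((al$coordinates[1, ] - al$coordinates[2, ])^2)), 1e-10)
  expect_lt(max(abs(colMeans(al$consensus))), 1e-10)
  expect_equal(sqrt(sum(al$consensus^2)), 1, tolerance = 1e-10)
  expect_error(gpa(list(tri, rbind(tri, c(2, 2)))), "point count")
})

test_that("GPA is invariant to similarity transforms of its inputs", {
  set.seed(41)
  shapes <- lapply(1:6, function(i) eq_triangle() +
                     matrix(rnorm(6, sd = 0.05), 3, 2))
  al1 <- gpa(shapes)
  jitter <- lapply(shapes, function(s) {
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    sweep(exp(runif(1, -1, 1)) * s %*% R, 2, runif(2, -5, 5), `+`)
  })
  al2 <- gpa(jitter)
  # consensus agrees up to rotation: compare via Procrustes distance
  expect_lt(procrustes_distance(al1$consensus, al2$consensus), 1e-8)
})

test_that("Procrustes distance matches the rotation-grid oracle and its axioms", {
  d_pkg <- procrustes_distance(eq_triangle(), iso_triangle())
  d_grid <- grid_procrustes(eq_triangle(), iso_triangle())
  expect_equal(d_pkg, d_grid, tolerance = 1e-4)

  rot <- matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2, 2)
  expect_lt(procrustes_distance(eq_triangle(),
                                2.5 * eq_triangle() %*% rot + 3), 1e-10)

  set.seed(42)
  for (i in 1:5) {
    a <- matrix(rnorm(10), 5, 2)
    b <- matrix(rnorm(10), 5, 2)
    expect_equal(procrustes_distance(a, b), procrustes_distance(b, a),
                 tolerance = 1e-12)
    expect_equal(procrustes_distance(a, b), grid_procrustes(a, b),
                 tolerance = 1e-4)
  }
  expect_error(procrustes_distance(eq_triangle(), matrix(rnorm(8), 4, 2)),
               "point counts")
})

test_that("semilandmark sliding removes tangent displacement and never increases SS", {
  base <- fixture_base_shape()
  roles <- fixture_roles()

  # a pure tangent displacement of one semilandmark is slid away
  j <- 7
  u <- base[j + 1, ] - base[j - 1, ]; u <- u / sqrt(sum(u^2))
  displaced <- base
  displaced[j, ] <- displaced[j, ] + 0.08 * u
  al <- gpa(list(base, base, base, displaced), by_species = FALSE)
  slid <- slide_semilandmarks(al, roles = roles)
  resid <- sapply(seq_len(4), function(i)
    sum((slid$coordinates[i, ] - as.vector(slid$consensus))^2))
  expect_lt(max(resid), 1e-6)

  # fixed point: configurations already at the consensus stay put
  al0 <- gpa(list(base, base, base), by_species = FALSE)
  slid0 <- slide_semilandmarks(al0, roles = roles)
  expect_equal(slid0$coordinates, al0$coordinates, tolerance = 1e-9)

  # total Procrustes SS is non-increasing over random datasets
  set.seed(43)
  for (r in 1:20) {
    shapes <- lapply(1:5, function(i) base + matrix(rnorm(40, sd = 0.03),
                                                    20, 2))
    alr <- gpa(shapes, by_species = FALSE)
    ss_before <- sum(vapply(seq_len(5), function(i)
      sum((matrix(alr$coordinates[i, ], ncol = 2) - alr$consensus)^2), 0))
    slr <- slide_semilandmarks(alr, roles = roles)
    expect_lte(slr$procrustes_ss, ss_before + 1e-10)
  }

  # a semilandmark at a curve end has no two neighbours
  bad_roles <- roles; bad_roles[1] <- "semilandmark"
  expect_error(slide_semilandmarks(al0, roles = bad_roles), "neighbours")
})

test_that("shape PCA conserves variance and reconstructs the data", {
  set.seed(44)
  X <- matrix(rnorm(49 * 12, sd = 0.1), 49, 12,
              dimnames = list(paste0("t", 1:49), NULL))
  pc <- shape_pca(X)
  expect_equal(sum(pc$eigenvalues), sum(apply(X, 2, var)),
               tolerance = 1e-10)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  recon <- pc$scores %*% t(pc$eigenvectors) +
    matrix(pc$center, 49, 12, byrow = TRUE)
  expect_lt(max(abs(recon - X)), 1e-8)

  two <- shape_pca(X[1:2, ])
  expect_equal(sum(two$eigenvalues > 1e-12), 1)
  expect_error(shape_pca(X[1, , drop = FALSE]), "at least 2")
})

test_that("parallel analysis: null false-retention and planted-factor recovery", {
  null_hits <- vapply(1:20, function(r) {
    X <- matrix(rnorm(60 * 8), 60, 8)
    parallel_analysis(X, n_reps = 150, seed = r)$n_retained
  }, 0L)
  expect_gte(mean(null_hits == 0L), 0.9)

  planted_hits <- vapply(1:20, function(r) {
    set.seed(500 + r)
    n <- 200
    F2 <- matrix(rnorm(n * 2, sd = 10), n, 2)
    L <- matrix(rnorm(2 * 8), 2, 8)
    X <- F2 %*% L + matrix(rnorm(n * 8), n, 8)
    parallel_analysis(X, n_reps = 150, seed = r)$n_retained
  }, 0L)
  expect_gte(mean(planted_hits == 2L), 0.95)

  X <- matrix(rnorm(50 * 5), 50, 5)
  expect_identical(parallel_analysis(X, n_reps = 120, seed = 9)$n_retained,
                   parallel_analysis(X, n_reps = 120, seed = 9)$n_retained)
  expect_error(parallel_analysis(X, n_reps = 120, percentile = 1.2),
               "percentile")
  expect_error(parallel_analysis(X, n_reps = 10), "n_reps")
})

test_that("TPS files round-trip", {
  fx_lms <- simulate_landmarks(fixture_mean_shapes(),
                               setNames(c("insectivory", "carnivory"),
                                        c("sp1", "sp2")),
                               n_specimens = 2, noise_sd = 0.01,
                               roles = fixture_roles(), seed = 5)
  path <- withr::local_tempfile(fileext = ".tps")
  write_tps(fx_lms, path)
  back <- read_tps(path, roles = fixture_roles())
  expect_equal(length(back), length(fx_lms))
  expect_equal(back[[3]]$points, fx_lms[[3]]$points, tolerance = 1e-8)
  expect_equal(back[[3]]$species_id, "sp2")
})
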