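# Generalized Procrustes analysis, semilandmark sliding, Procrustes
# distances, shape PCA and Horn's parallel analysis.
#
# Conventions: configurations are k x 2 matrices; aligned sets store a
# species x 2k matrix with columns (x1..xk, y1..yk); GPA scales every
# configuration to unit centroid size (partial / least-squares
# Procrustes), so shape distances live on the unit-size preshape space.

centre_pts <- function(pts) sweep(pts, 2L, colMeans(pts))

config_points <- function(x) {
  if (inherits(x, "landmark_config")) x$points else as.matrix(x)
}

flatten_pts <- function(pts) c(pts[, 1L], pts[, 2L])
unflatten_pts <- function(v) {
  k <- length(v) / 2L
  cbind(v[seq_len(k)], v[k + seq_len(k)])
}

# optimal proper rotation R minimizing ||Z - X R||_F; returns X R
rotate_onto <- function(X, Z) {
  M <- crossprod(X, Z)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, d)) %*% t(sv$v)
  X %*% R
}

#' Centroid size of a configuration
#'
#' Square root of the summed squared distances of all points from their
#' centroid.  Invariant to translation and rotation; scales linearly
#' under uniform scaling.
#'
#' @param config a `landmark_config` or k x 2 matrix.
#' @return positive scalar.
#' @export
centroid_size <- function(config) {
  pts <- centre_pts(config_points(config))
  cs <- sqrt(sum(pts^2))
  if (cs < 1e-12) stop_invalid("degenerate shape: all points coincide")
  cs
}

# Core GPA on a list of k x 2 matrices (already any shapes).
# Returns list(aligned = list of k x 2, consensus, iterations).
gpa_core <- function(shapes, tol = 1e-10, max_iter = 200L) {
  shapes <- lapply(shapes, function(p) {
    p <- centre_pts(p)
    p / sqrt(sum(p^2))
  })
  consensus <- shapes[[1L]]
  for (it in seq_len(max_iter)) {
    shapes <- lapply(shapes, rotate_onto, Z = consensus)
    newc <- Reduce(`+`, shapes) / length(shapes)
    newc <- centre_pts(newc)
    newc <- newc / sqrt(sum(newc^2))
    delta <- sqrt(sum((newc - consensus)^2))
    consensus <- newc
    if (delta < tol) break
  }
  shapes <- lapply(shapes, rotate_onto, Z = consensus)
  list(aligned = shapes, consensus = consensus, iterations = it)
}

#' Generalized Procrustes analysis
#'
#' Iterative least-squares superimposition: configurations are centred,
#' scaled to unit centroid size, and rotated to the evolving consensus
#' until the consensus stabilizes.  When species identifiers are present
#' (and `by_species = TRUE`) a preliminary within-species superimposition
#' produces species mean shapes, which are then superimposed to the
#' grand mean — the two-stage averaging appropriate when several
#' specimens represent each species.
#'
#' @param configs list of `landmark_config` objects (or k x 2 matrices).
#' @param by_species average specimens into species means first.
#' @param tol convergence tolerance on the consensus change.
#' @param max_iter maximum superimposition iterations.
#' @return object of class `"aligned_shapes"`: `coordinates`
#'   (units x 2k), `consensus` (k x 2), `centroid_sizes` (raw CS before
#'   scaling; species values are specimen means), `roles`, `labels`.
#' @export
gpa <- function(configs, by_species = TRUE, tol = 1e-10, max_iter = 200L) {
  if (length(configs) < 2L) stop_invalid("need at least 2 configurations")
  pts <- lapply(configs, config_points)
  ks <- vapply(pts, nrow, 0L)
  if (length(unique(ks)) != 1L)
    stop_invalid("configurations differ in point count: ",
                 paste(sort(unique(ks)), collapse = " vs "))
  roles <- if (inherits(configs[[1L]], "landmark_config"))
    configs[[1L]]$roles else rep("landmark", ks[[1L]])
  species <- vapply(configs, function(cf)
    if (inherits(cf, "landmark_config")) cf$species_id else NA_character_, "")
  cs_all <- vapply(pts, centroid_size, 0)

  if (by_species && !anyNA(species) && anyDuplicated(species) > 0L) {
    usp <- unique(species)
    means <- vector("list", length(usp))
    cs_sp <- numeric(length(usp))
    for (i in seq_along(usp)) {
      grp <- which(species == usp[i])
      if (length(grp) == 1L) {
        m <- centre_pts(pts[[grp]])
        m <- m / sqrt(sum(m^2))
      } else {
        g <- gpa_core(pts[grp], tol = tol, max_iter = max_iter)
        m <- Reduce(`+`, g$aligned) / length(grp)
      }
      means[[i]] <- m
      cs_sp[i] <- mean(cs_all[grp])
    }
    shapes <- means
    labels <- usp
    cs_out <- stats::setNames(cs_sp, usp)
  } else {
    shapes <- pts
    labels <- vapply(seq_along(configs), function(i) {
      cf <- configs[[i]]
      if (inherits(cf, "landmark_config") && !is.na(cf$specimen_id))
        cf$specimen_id else paste0("s", i)
    }, "")
    cs_out <- stats::setNames(cs_all, labels)
  }

  g <- gpa_core(shapes, tol = tol, max_iter = max_iter)
  coords <- t(vapply(g$aligned, flatten_pts, numeric(2L * ks[[1L]])))
  rownames(coords) <- labels
  k <- ks[[1L]]
  colnames(coords) <- c(paste0("x", seq_len(k)), paste0("y", seq_len(k)))
  structure(list(coordinates = coords, consensus = g$consensus,
                 centroid_sizes = cs_out, roles = roles, labels = labels,
                 iterations = g$iterations),
            class = "aligned_shapes")
}

#' @export
print.aligned_shapes <- function(x, ...) {
  cat("Aligned shape set:", nrow(x$coordinates), "configurations,",
      nrow(x$consensus), "points (",
      sum(x$roles == "semilandmark"), "semilandmarks )\n")
  invisible(x)
}

#' Slide semilandmarks along their curve tangents
#'
#' Each semilandmark is moved along the chord between its two curve
#' neighbours (point order defines the curve) to the position minimizing
#' its squared distance to the consensus; sliding alternates with GPA
#' re-superimposition until the total Procrustes sum of squares
#' stabilizes.
#'
#' @param aligned an `"aligned_shapes"` object.
#' @param roles optional role flags overriding those stored in `aligned`.
#' @param max_iter maximum slide/superimpose cycles.
#' @param tol convergence tolerance on the total sum of squares.
#' @return an updated `"aligned_shapes"` object.
#' @export
slide_semilandmarks <- function(aligned, roles = NULL, max_iter = 50L,
                                tol = 1e-8) {
  roles <- roles %||% aligned$roles
  k <- nrow(aligned$consensus)
  semi <- which(roles == "semilandmark")
  if (length(semi) == 0L) stop_invalid("no semilandmarks to slide")
  if (any(semi == 1L | semi == k))
    stop_invalid("semilandmark without two curve neighbours (position 1 or ",
                 k, ")")
  shapes <- lapply(seq_len(nrow(aligned$coordinates)),
                   function(i) unflatten_pts(aligned$coordinates[i, ]))
  consensus <- aligned$consensus
  ss_tot <- sum(vapply(shapes, function(s) sum((s - consensus)^2), 0))
  for (it in seq_len(max_iter)) {
    slid <- lapply(shapes, function(s) {
      for (j in semi) {
        u <- s[j + 1L, ] - s[j - 1L, ]
        nu <- sqrt(sum(u^2))
        if (nu < 1e-12) next
        u <- u / nu
        s[j, ] <- s[j, ] + sum((consensus[j, ] - s[j, ]) * u) * u
      }
      s
    })
    g <- gpa_core(slid)
    shapes <- g$aligned
    consensus <- g$consensus
    ss_new <- sum(vapply(shapes, function(s) sum((s - consensus)^2), 0))
    if (abs(ss_tot - ss_new) < tol) { ss_tot <- ss_new; break }
    ss_tot <- ss_new
  }
  coords <- t(vapply(shapes, flatten_pts, numeric(2L * k)))
  dimnames(coords) <- dimnames(aligned$coordinates)
  out <- aligned
  out$coordinates <- coords
  out$consensus <- consensus
  out$procrustes_ss <- ss_tot
  out
}

#' Procrustes distance between two configurations
#'
#' Full Procrustes distance: both configurations are centred and scaled
#' to unit centroid size, then the summed squared difference is
#' minimized over rotation and residual scaling.  Symmetric, zero iff
#' the shapes are identical up to a similarity transform.
#'
#' @param shape_a,shape_b `landmark_config` objects or k x 2 matrices
#'   with equal point counts.
#' @return non-negative scalar.
#' @export
procrustes_distance <- function(shape_a, shape_b) {
  a <- centre_pts(config_points(shape_a))
  b <- centre_pts(config_points(shape_b))
  if (nrow(a) != nrow(b))
    stop_invalid("point counts differ: ", nrow(a), " vs ", nrow(b))
  a <- a / sqrt(sum(a^2))
  b <- b / sqrt(sum(b^2))
  sv <- svd(crossprod(b, a))
  lam <- sum(sv$d[-length(sv$d)]) +
    sign(det(sv$u %*% t(sv$v))) * sv$d[length(sv$d)]
  sqrt(max(0, 1 - min(1, lam)^2))
}

#' Principal components of aligned shape coordinates
#'
#' Covariance-matrix PCA of the species mean aligned coordinates (the
#' variables share units, so no rescaling).
#'
#' @param aligned an `"aligned_shapes"` object or a species x variables
#'   matrix.
#' @return object of class `"shape_pca"`: `eigenvalues`, `eigenvectors`,
#'   `scores`, `center`, `n_retained` (NA until set).
#' @export
shape_pca <- function(aligned) {
  X <- if (inherits(aligned, "aligned_shapes")) aligned$coordinates
       else as.matrix(aligned)
  if (nrow(X) < 2L) stop_invalid("need at least 2 species for a PCA")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  structure(list(eigenvalues = pc$sdev^2,
                 eigenvectors = pc$rotation,
                 scores = pc$x,
                 center = pc$center,
                 n_retained = NA_integer_),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  ev <- x$eigenvalues
  cat("Shape PCA:", nrow(x$scores), "species,", length(ev), "components\n")
  cat("proportion of variance (first 5):",
      paste(sprintf("%.3f", utils::head(ev / sum(ev), 5)), collapse = " "),
      "\n")
  invisible(x)
}

#' Horn's parallel analysis
#'
#' Retains the leading principal components whose observed eigenvalues
#' exceed a percentile of eigenvalues obtained from PCAs of standard
#' normal data of the same dimensions.  The comparison is made on the
#' correlation scale (variables standardized), which makes the rule
#' free of the measurement scale; retention stops at the first failing
#' component.  Constant variables are dropped.
#'
#' @param data species x variables matrix.
#' @param n_reps number of random datasets (>= 100).
#' @param percentile comparison percentile in (0, 1); default 0.95.
#' @param seed integer seed.
#' @return list with `n_retained`, `observed` eigenvalues (correlation
#'   scale), `thresholds`.
#' @export
parallel_analysis <- function(data, n_reps = 1000L, percentile = 0.95,
                              seed = NULL) {
  if (n_reps < 100L) stop_invalid("n_reps must be >= 100")
  if (percentile <= 0 || percentile >= 1)
    stop_invalid("percentile must be in (0, 1)")
  X <- as.matrix(data)
  X <- X[, apply(X, 2L, stats::sd) > 0, drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  obs <- stats::prcomp(X, center = TRUE, scale. = TRUE)$sdev^2
  with_seed(seed, {
    m <- length(obs)
    rand <- matrix(NA_real_, n_reps, m)
    for (r in seq_len(n_reps)) {
      R <- matrix(stats::rnorm(n * p), n, p)
      ev <- stats::prcomp(R, center = TRUE, scale. = TRUE)$sdev^2
      rand[r, ] <- ev[seq_len(m)]
    }
    thresholds <- apply(rand, 2L, stats::quantile, probs = percentile,
                        na.rm = TRUE)
    keep <- obs > thresholds
    n_retained <- if (!keep[1L]) 0L else which.min(c(keep, FALSE)) - 1L
    list(n_retained = as.integer(n_retained), observed = obs,
         thresholds = thresholds)
  })
}
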