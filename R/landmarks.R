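# Landmark configurations, their simulation, and TPS file I/O.

#' Construct a landmark configuration
#'
#' @param points k x 2 numeric matrix of (x, y) coordinates.
#' @param roles character vector of length k, each `"landmark"` or
#'   `"semilandmark"`.
#' @param specimen_id,species_id labels.
#' @return object of class `"landmark_config"`.
#' @export
landmark_config <- function(points, roles = NULL, specimen_id = NA_character_,
                            species_id = NA_character_) {
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop_invalid("points must be a k x 2 matrix")
  k <- nrow(points)
  if (k < 3L) stop_invalid("need at least 3 points")
  roles <- roles %||% rep("landmark", k)
  if (length(roles) != k) stop_invalid("roles length must equal point count")
  if (!all(roles %in% c("landmark", "semilandmark")))
    stop_invalid("roles must be 'landmark' or 'semilandmark'")
  if (anyDuplicated(points) > 0L)
    stop_invalid("configuration has coincident points")
  structure(list(points = unname(points), roles = roles,
                 specimen_id = specimen_id, species_id = species_id),
            class = "landmark_config")
}

#' @export
print.landmark_config <- function(x, ...) {
  cat("Landmark configuration:", nrow(x$points), "points (",
      sum(x$roles == "semilandmark"), "semilandmarks ), specimen",
      x$specimen_id, "species", x$species_id, "\n")
  invisible(x)
}

#' Simulate noisy landmark configurations around regime mean shapes
#'
#' Each specimen is its species' regime mean plus isotropic Gaussian
#' point noise, then a random rotation, scaling and translation are
#' applied so superimposition is non-trivial.
#'
#' @param mean_shapes named list of k x 2 matrices, one per regime.
#' @param species_regimes named character vector: regime per species.
#' @param n_specimens specimens per species.
#' @param noise_sd isotropic landmark noise SD, in the units of the mean
#'   shapes (>= 0).
#' @param roles per-point roles shared by all configurations.
#' @param seed integer seed.
#' @return list of `landmark_config` objects.
#' @export
simulate_landmarks <- function(mean_shapes, species_regimes, n_specimens = 5,
                               noise_sd = 0.02, roles = NULL, seed = NULL) {
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  ks <- vapply(mean_shapes, nrow, 0L)
  if (length(unique(ks)) != 1L)
    stop_invalid("mean shapes must share point count")
  k <- ks[[1L]]
  roles <- roles %||% rep("landmark", k)
  if (!all(species_regimes %in% names(mean_shapes)))
    stop_invalid("species regime without a mean shape")
  with_seed(seed, {
    out <- vector("list", length(species_regimes) * n_specimens)
    idx <- 0L
    for (sp in names(species_regimes)) {
      mu <- as.matrix(mean_shapes[[species_regimes[[sp]]]])
      for (j in seq_len(n_specimens)) {
        pts <- mu + matrix(stats::rnorm(2L * k, sd = noise_sd), k, 2L)
        th <- stats::runif(1L, 0, 2 * pi)
        R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
        sc <- exp(stats::runif(1L, -0.4, 0.4))
        tr <- stats::runif(2L, -3, 3)
        pts <- sweep(sc * pts %*% t(R), 2L, tr, `+`)
        idx <- idx + 1L
        out[[idx]] <- landmark_config(pts, roles,
                                      specimen_id = sprintf("%s_%02d", sp, j),
                                      species_id = sp)
      }
    }
    out
  })
}

#' Read a TPS landmark file
#'
#' Supports the common record fields: `LM=`, coordinate lines,
#' `IMAGE=`, `ID=`.  Point roles are not encoded in TPS; supply them via
#' `roles` (recycled over specimens).  Species are taken as the part of
#' the ID before the last underscore, unless `species_from_id = FALSE`.
#'
#' @param path file path.
#' @param roles optional roles vector applied to every configuration.
#' @param species_from_id derive `species_id` by stripping a trailing
#'   `_nn` suffix from the ID.
#' @return list of `landmark_config` objects.
#' @export
read_tps <- function(path, roles = NULL, species_from_id = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!grepl("^LM\\s*=", lines[i]))
      stop_invalid("TPS parse error at line ", i, ": expected LM=")
    k <- as.integer(sub("^LM\\s*=\\s*", "", lines[i]))
    if (is.na(k) || k < 1L) stop_invalid("TPS parse error: bad LM count")
    coords <- matrix(NA_real_, k, 2L)
    for (j in seq_len(k)) {
      xy <- suppressWarnings(as.numeric(strsplit(lines[i + j], "\\s+")[[1L]]))
      if (length(xy) != 2L || anyNA(xy))
        stop_invalid("TPS parse error at line ", i + j, ": bad coordinates")
      coords[j, ] <- xy
    }
    i <- i + k + 1L
    id <- image <- NA_character_
    while (i <= length(lines) && !grepl("^LM\\s*=", lines[i])) {
      if (grepl("^IMAGE\\s*=", lines[i]))
        image <- sub("^IMAGE\\s*=\\s*", "", lines[i])
      else if (grepl("^ID\\s*=", lines[i]))
        id <- sub("^ID\\s*=\\s*", "", lines[i])
      i <- i + 1L
    }
    spec <- if (!is.na(id)) id else image
    species <- if (species_from_id && !is.na(spec))
      sub("_[^_]*$", "", spec) else NA_character_
    out[[length(out) + 1L]] <-
      landmark_config(coords, roles, specimen_id = spec, species_id = species)
  }
  out
}

#' Write landmark configurations to a TPS file
#'
#' @param configs list of `landmark_config` objects.
#' @param path output file path.
#' @export
write_tps <- function(configs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cf in configs) {
    writeLines(sprintf("LM=%d", nrow(cf$points)), con)
    writeLines(sprintf("%.10g %.10g", cf$points[, 1L], cf$points[, 2L]), con)
    writeLines(sprintf("ID=%s", cf$specimen_id), con)
  }
  invisible(path)
}
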