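# End-to-end orchestration: morphometrics -> PCA / parallel analysis ->
# diet PCA -> PGLS -> disparity-through-time -> ancestral estimation and
# regime painting -> BM/OU.2-OU.5 fitting -> weights -> bootstrap of the
# best model.  Every stage writes plain CSV/JSON so it can be re-run in
# isolation; a manifest records seeds, parameters and file checksums.

#' Regime groupings for the nested OU.2-OU.5 model set
#'
#' OU.2 separates high- from low-mastication diets; OU.3 splits
#' sanguivory from nectarivory; OU.4 lumps insectivory and carnivory as
#' animalivory; OU.5 keeps all five dietary regimes.
#'
#' @return named list of grouping lists usable with [merge_regimes()].
#' @export
diet_model_groupings <- function() {
  list(
    OU.2 = list(mastication = c("insectivory", "carnivory", "frugivory"),
                low_mastication = c("nectarivory", "sanguivory")),
    OU.3 = list(mastication = c("insectivory", "carnivory", "frugivory"),
                nectarivory = "nectarivory",
                sanguivory = "sanguivory"),
    OU.4 = list(animalivory = c("insectivory", "carnivory"),
                frugivory = "frugivory",
                nectarivory = "nectarivory",
                sanguivory = "sanguivory"),
    OU.5 = list(insectivory = "insectivory",
                carnivory = "carnivory",
                frugivory = "frugivory",
                nectarivory = "nectarivory",
                sanguivory = "sanguivory"))
}

#' Predominant diet category per species
#'
#' The item with the highest rank (ties resolved in [diet_items()]
#' order).
#'
#' @param diet species x items rank matrix.
#' @return named character vector.
#' @export
predominant_diet <- function(diet) {
  diet <- as.matrix(diet)
  stats::setNames(colnames(diet)[apply(diet, 1L, which.max)],
                  rownames(diet))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' Run the full comparative analysis
#'
#' @param config a named list (or path to a YAML file) with entries:
#'   `tree` (Newick path or `phylo`), one of `landmarks` (TPS path or
#'   list of configurations, with optional `roles`) or `traits` (CSV
#'   path or matrix of precomputed trait/PC scores), `diet` (CSV path or
#'   rank matrix), optional `cl` (CSV path or named vector), optional
#'   `genetic_distances`; options `n_pcs` (integer or `"auto"` for
#'   parallel analysis), `dtt_nsim` (default 1000), `n_boot` (default
#'   200), `seed`, `slide` (default TRUE), `out_dir`.
#' @return invisibly, a list with every stage's results; files are
#'   written under `out_dir` when given.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_invalid("reading a YAML config requires the yaml package")
    config <- yaml::read_yaml(config)
  }
  seed <- config$seed %||% 1L
  out_dir <- config$out_dir
  dtt_nsim <- config$dtt_nsim %||% 1000L
  n_boot <- config$n_boot %||% 200L
  res <- list(config_echo = config[setdiff(names(config),
                                           c("landmarks", "tree"))])
  t0 <- Sys.time()

  tree <- run_stage("tree", {
    if (inherits(config$tree, "phylo")) config$tree
    else read_newick(paste(readLines(config$tree, warn = FALSE),
                           collapse = ""))
  })
  res$tree <- tree

  # morphometry (skipped when traits are supplied directly)
  if (!is.null(config$traits)) {
    scores_all <- run_stage("traits", {
      x <- config$traits
      if (is.character(x)) x <- utils::read.csv(x, row.names = 1L)
      as.matrix(x)
    })
    res$morphometry <- NULL
  } else {
    res$morphometry <- run_stage("morphometry", {
      lms <- config$landmarks
      if (is.character(lms)) lms <- read_tps(lms, roles = config$roles)
      aligned <- gpa(lms)
      if (isTRUE(config$slide %||% TRUE) &&
          any(aligned$roles == "semilandmark"))
        aligned <- slide_semilandmarks(aligned)
      pca <- shape_pca(aligned)
      list(aligned = aligned, pca = pca)
    })
    scores_all <- res$morphometry$pca$scores
  }

  np <- config$n_pcs %||% "auto"
  if (identical(np, "auto")) {
    res$parallel_analysis <- run_stage("parallel_analysis",
      parallel_analysis(scores_all, n_reps = 500L, seed = seed))
    n_pcs <- max(res$parallel_analysis$n_retained, 2L)
  } else n_pcs <- as.integer(np)
  shape_pcs <- scores_all[, seq_len(min(n_pcs, ncol(scores_all))),
                          drop = FALSE]
  res$n_pcs <- ncol(shape_pcs)

  diet <- run_stage("diet", {
    x <- config$diet
    if (is.character(x)) x <- utils::read.csv(x, row.names = 1L)
    as.matrix(x)
  })
  res$diet_pca <- run_stage("diet_pca", diet_pca(diet))

  cl <- NULL
  if (!is.null(config$cl)) {
    cl <- run_stage("cl", {
      x <- config$cl
      if (is.character(x)) {
        tab <- utils::read.csv(x, row.names = 1L)
        stats::setNames(tab[[1L]], rownames(tab))
      } else if (is.matrix(x)) stats::setNames(x[, 1L], rownames(x))
      else x
    })
  }

  res$pgls <- run_stage("pgls", {
    preds <- res$diet_pca$scores[, seq_len(min(3L,
                                               ncol(res$diet_pca$scores))),
                                 drop = FALSE]
    colnames(preds) <- paste0("dietPC", seq_len(ncol(preds)))
    if (!is.null(cl)) preds <- cbind(preds, CL = cl[rownames(preds)])
    pgls_fit(shape_pcs, preds, tree)
  })

  res$dtt <- run_stage("dtt", {
    out <- list(shape = bm_null_envelope(tree, scores_all,
                                         n_sim = dtt_nsim, seed = seed))
    if (!is.null(cl))
      out$size <- bm_null_envelope(tree, matrix(cl, ncol = 1,
                                                dimnames = list(names(cl),
                                                                "CL")),
                                   n_sim = dtt_nsim, seed = seed + 1L)
    out$diet <- bm_null_envelope(tree, diet, n_sim = dtt_nsim,
                                 seed = seed + 2L, metric = "manhattan")
    out
  })

  if (!is.null(config$genetic_distances)) {
    res$divergence_scatter <- run_stage("divergence_scatter", {
      gd <- config$genetic_distances
      if (is.character(gd)) gd <- as.matrix(utils::read.csv(gd,
                                                            row.names = 1L))
      sd_mat <- as.matrix(stats::dist(scores_all))
      list(genetic = divergence_scatter(sd_mat, gd),
           time = divergence_scatter(sd_mat, patristic_distances(tree) / 2))
    })
  }

  res$painting <- run_stage("ancestral_states", {
    tip_diet <- predominant_diet(diet)
    est <- ancestral_discrete_ml(tree, tip_diet,
                                 levels = intersect(diet_items(),
                                                    unique(tip_diet)))
    paint_regimes(tree, est, tip_diet)
  })

  paintings <- run_stage("model_paintings", {
    grp <- diet_model_groupings()
    present <- res$painting$regime_labels
    lapply(grp, function(g) {
      g <- lapply(g, intersect, present)
      g <- g[lengths(g) > 0]
      merge_regimes(res$painting, g)
    })
  })
  # drop model variants that collapse to an already-present optima count
  paintings <- paintings[!duplicated(vapply(paintings, function(p)
    length(p$regime_labels), 0L))]

  res$models_shape <- run_stage("hansen_shape",
                                compare_models(tree, shape_pcs, paintings))
  if (!is.null(cl)) {
    clm <- matrix(cl, ncol = 1, dimnames = list(names(cl), "CL"))
    res$models_cl <- run_stage("hansen_cl",
                               compare_models(tree, clm, paintings))
  }

  res$bootstrap <- run_stage("bootstrap", {
    best <- res$models_shape$best_AICc
    if (best == "BM") NULL
    else bootstrap_optima(res$models_shape$fits[[best]], n_boot = n_boot,
                          seed = seed, refit = "theta")
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wcsv <- function(x, f) {
      utils::write.csv(x, file.path(out_dir, f))
      f
    }
    files <- character(0)
    if (!is.null(res$morphometry)) {
      al <- res$morphometry$aligned
      files <- c(files, wcsv(as.data.frame(al$coordinates),
                             "aligned_coordinates.csv"))
      files <- c(files, wcsv(data.frame(species = names(al$centroid_sizes),
                                        CS = unname(al$centroid_sizes)),
                             "centroid_sizes.csv"))
    }
    files <- c(files, wcsv(as.data.frame(shape_pcs), "shape_pcs.csv"))
    files <- c(files, wcsv(as.data.frame(res$diet_pca$scores),
                           "diet_pcs.csv"))
    files <- c(files, wcsv(res$models_shape$table, "model_table_shape.csv"))
    if (!is.null(res$models_cl))
      files <- c(files, wcsv(res$models_cl$table, "model_table_cl.csv"))
    for (nm in names(res$dtt))
      files <- c(files, wcsv(res$dtt[[nm]]$curve,
                             paste0("dtt_", nm, ".csv")))
    best <- res$models_shape$fits[[res$models_shape$best_AICc]]
    fit_record <- list(model = res$models_shape$best_AICc,
                       log_likelihood = best$log_likelihood,
                       k = best$k, AICc = best$AICc, SIC = best$SIC,
                       Sigma = unname(best$Sigma))
    if (inherits(best, "hansen")) {
      fit_record$A <- unname(best$A)
      fit_record$S <- unname(best$S)
      fit_record$theta <- as.data.frame(best$theta)
    } else fit_record$root_state <- unname(best$root_state)
    jsonlite::write_json(fit_record, file.path(out_dir, "best_fit.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    files <- c(files, "best_fit.json")
    pg <- res$pgls
    files <- c(files, wcsv(data.frame(
      predictor = rep(pg$predictor_names, times = length(pg$response_names)),
      response = rep(pg$response_names, each = length(pg$predictor_names)),
      b = as.vector(pg$coefficients),
      r = as.vector(pg$partial_correlations),
      P = as.vector(pg$p_values)), "pgls_table.csv"))
    manifest <- list(
      seed = seed, n_pcs = res$n_pcs, dtt_nsim = dtt_nsim, n_boot = n_boot,
      n_models = length(res$models_shape$fits),
      best_AICc = res$models_shape$best_AICc,
      best_SIC = res$models_shape$best_SIC,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      files = as.list(stats::setNames(
        unname(tools::md5sum(file.path(out_dir, files))), files)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    res$manifest <- manifest
  }
  invisible(res)
}
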