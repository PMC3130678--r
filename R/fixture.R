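# A desk-scale synthetic bundle with the statistical structure of a
# phyllostomid-like radiation: 49 tips over 30 My, five dietary regimes
# painted from an insectivorous root, five traits under multi-peak OU,
# rank-valued diet profiles, noisy landmark sets, and a univariate
# skull-length trait.  True parameters travel with the data so recovery
# tests never re-derive them.

# a smooth open outline standing in for a mandible profile: 5 fixed
# landmarks and 15 sliding semilandmarks on the curve between them
fixture_base_shape <- function() {
  s <- seq(0, 1, length.out = 20)
  cbind(x = s, y = 0.25 * sin(pi * s) + 0.05 * s)
}

fixture_roles <- function() {
  roles <- rep("semilandmark", 20)
  roles[c(1, 5, 10, 15, 20)] <- "landmark"
  roles
}

# per-regime deformations of the base outline (elongation, arc height)
fixture_mean_shapes <- function() {
  base <- fixture_base_shape()
  deform <- function(stretch, arc) {
    m <- base
    m[, 1] <- m[, 1] * stretch
    m[, 2] <- m[, 2] * arc
    m
  }
  list(insectivory = deform(1.00, 1.00),
       carnivory   = deform(1.05, 1.25),
       frugivory   = deform(0.90, 1.40),
       nectarivory = deform(1.30, 0.70),
       sanguivory  = deform(0.80, 0.90))
}

# true multivariate OU parameters for the 5-trait fixture
fixture_truth <- function() {
  p <- 5
  A <- diag(0.30, p)
  A[abs(row(A) - col(A)) == 1] <- 0.04
  S <- diag(0.15, p)
  S[2, 1] <- 0.03
  theta <- rbind(insectivory = c( 0,    0,    0,   0,    0),
                 carnivory   = c( 0.6,  0.8, -0.3, 0.2,  0.4),
                 frugivory   = c(-0.9,  0.7,  0.5, -0.4, 0.1),
                 nectarivory = c( 1.1, -0.6,  0.4, 0.6, -0.3),
                 sanguivory  = c(-0.7, -0.9, -0.6, 0.5,  0.5))
  colnames(theta) <- paste0("trait", 1:p)
  list(A_true = A, S_true = S, theta_true = theta,
       alpha_cl = 0.25, sigma_cl = 0.9,
       theta_cl = c(insectivory = 20, carnivory = 27, frugivory = 18,
                    nectarivory = 22, sanguivory = 16),
       switch_rate = 0.04, n_species = 49, tree_depth = 30)
}

#' Phyllostomid-like synthetic scenario bundle
#'
#' A 49-tip ultrametric tree of depth 30 My, five dietary regimes
#' painted from an insectivorous root by a symmetric jump process,
#' five traits evolved under a five-peak OU process with recorded true
#' parameters, a univariate skull-length (CL) trait under its own OU
#' process, diet-rank profiles consistent with the tip regimes, noisy
#' landmark configurations around per-regime mean outlines, and a
#' genetic-distance stand-in proportional to patristic distance.
#'
#' @param seed integer seed; the whole bundle is reproducible from it.
#' @param n_specimens landmark specimens per species.
#' @param noise_sd landmark noise SD.
#' @return list with `tree`, `painting`, `traits`, `cl`, `diet`,
#'   `landmarks`, `roles`, `mean_shapes`, `genetic_distances`, `truth`.
#' @export
phyllostomid_like_fixture <- function(seed = 1L, n_specimens = 5L,
                                      noise_sd = 0.01) {
  truth <- fixture_truth()
  labels <- diet_items()
  tree <- simulate_tree(truth$n_species, truth$tree_depth, seed = seed)
  painting <- simulate_regime_history(tree, 5, truth$switch_rate,
                                      seed = seed + 1L, labels = labels,
                                      root_regime = "insectivory")
  traits <- simulate_ou_traits(tree, painting, truth$A_true, truth$S_true,
                               truth$theta_true, seed = seed + 2L)
  cl <- simulate_ou_traits(tree, painting,
                           matrix(truth$alpha_cl), matrix(truth$sigma_cl),
                           matrix(truth$theta_cl[labels], ncol = 1,
                                  dimnames = list(labels, "CL")),
                           seed = seed + 3L)
  diet <- simulate_diet_ranks(painting$tip_states, seed = seed + 4L)
  landmarks <- simulate_landmarks(fixture_mean_shapes(),
                                  painting$tip_states,
                                  n_specimens = n_specimens,
                                  noise_sd = noise_sd,
                                  roles = fixture_roles(),
                                  seed = seed + 5L)
  gd <- patristic_distances(tree) * 0.006   # ~ percent divergence scale
  list(tree = tree, painting = painting, traits = traits,
       cl = cl, diet = diet, landmarks = landmarks,
       roles = fixture_roles(), mean_shapes = fixture_mean_shapes(),
       genetic_distances = gd, truth = c(truth, seed = seed))
}

#' Write a synthetic scenario bundle to plain-text files
#'
#' Newick tree, TPS landmarks, CSV traits / CL / diet ranks / tip
#' regimes / genetic distances, and a JSON truth record.
#'
#' @param bundle result of [phyllostomid_like_fixture()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths.
#' @export
write_scenario <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             landmarks = file.path(dir, "landmarks.tps"),
             traits = file.path(dir, "traits.csv"),
             cl = file.path(dir, "cl.csv"),
             diet = file.path(dir, "diet_ranks.csv"),
             regimes = file.path(dir, "tip_regimes.csv"),
             genetic = file.path(dir, "genetic_distances.csv"),
             truth = file.path(dir, "truth.json"))
  ape::write.tree(bundle$tree, paths["tree"])
  write_tps(bundle$landmarks, paths["landmarks"])
  utils::write.csv(as.data.frame(bundle$traits), paths["traits"])
  utils::write.csv(as.data.frame(bundle$cl), paths["cl"])
  utils::write.csv(as.data.frame(bundle$diet), paths["diet"])
  utils::write.csv(data.frame(species = names(bundle$painting$tip_states),
                              regime = unname(bundle$painting$tip_states)),
                   paths["regimes"], row.names = FALSE)
  utils::write.csv(as.data.frame(bundle$genetic_distances), paths["genetic"])
  tr <- bundle$truth
  tr$theta_true <- as.data.frame(tr$theta_true)
  jsonlite::write_json(tr, paths["truth"], digits = NA, auto_unbox = TRUE,
                       dataframe = "rows")
  invisible(paths)
}
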