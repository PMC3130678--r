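# Diet-rank tables and their correlation-matrix PCA.
# Ranks follow the 0-3 usage scale: 0 absent, 1 complementary,
# 2 predominant, 3 strict.

#' Canonical dietary regime labels
#' @export
diet_items <- function() {
  c("insectivory", "carnivory", "frugivory", "nectarivory", "sanguivory")
}

# P(rank 1) on non-focal items, by focal regime.  Insectivory and
# carnivory co-occur often (animalivores take both), and both are rare
# in frugivore/nectarivore diets, which planted the insectivory-carnivory
# vs frugivory axis the diet PCA is expected to recover.
diet_side_probs <- function() {
  out <- rbind(
    insectivory = c(NA,  0.7, 0.15, 0.10, 0),
    carnivory   = c(0.9, NA,  0.10, 0.05, 0),
    frugivory   = c(0.25, 0.05, NA, 0.40, 0),
    nectarivory = c(0.25, 0.02, 0.40, NA,  0),
    sanguivory  = c(0,   0,   0,    0,   NA))
  colnames(out) <- diet_items()
  out
}

#' Simulate a diet-rank table from tip regimes
#'
#' Each species' focal item (its regime) receives rank 2 or 3;
#' sanguivores are strict (their only nonzero item, rank 3); other items
#' receive rank 0 or 1 with regime-dependent probabilities that build in
#' the insectivory-carnivory association.
#'
#' @param tip_regimes named character vector, one dietary regime per
#'   species; labels must be among [diet_items()].
#' @param seed integer seed.
#' @return integer species x 5 matrix with columns [diet_items()].
#' @export
simulate_diet_ranks <- function(tip_regimes, seed = NULL) {
  items <- diet_items()
  if (!all(tip_regimes %in% items))
    stop_invalid("unknown regime label(s): ",
                 paste(setdiff(tip_regimes, items), collapse = ", "))
  side <- diet_side_probs()
  n <- length(tip_regimes)
  with_seed(seed, {
    out <- matrix(0L, n, 5L, dimnames = list(names(tip_regimes), items))
    for (i in seq_len(n)) {
      r <- tip_regimes[[i]]
      if (r == "sanguivory") {
        out[i, "sanguivory"] <- 3L
        next
      }
      out[i, r] <- sample(2:3, 1L)
      for (j in setdiff(items, r)) {
        pr <- side[r, j]
        if (!is.na(pr) && pr > 0) out[i, j] <- stats::rbinom(1L, 1L, pr)
      }
    }
    out
  })
}

#' Principal components of the diet-rank correlation matrix
#'
#' Variables are standardized to unit variance, so eigenvalues sum to
#' the number of (retained) variables; zero-variance columns are dropped
#' with a warning.
#'
#' @param diet species x items rank matrix (or data frame).
#' @return list with `scores`, `loadings`, `eigenvalues`, `dropped`.
#' @export
diet_pca <- function(diet) {
  diet <- as.matrix(diet)
  if (nrow(diet) < 2 || ncol(diet) < 2)
    stop_invalid("need >= 2 species and >= 2 diet variables")
  v <- apply(diet, 2L, stats::var)
  dropped <- colnames(diet)[v == 0]
  if (length(dropped)) {
    warning("dropping zero-variance diet column(s): ",
            paste(dropped, collapse = ", "))
    diet <- diet[, v > 0, drop = FALSE]
  }
  pc <- stats::prcomp(diet, center = TRUE, scale. = TRUE)
  list(scores = pc$x,
       loadings = pc$rotation,
       eigenvalues = pc$sdev^2,
       dropped = dropped)
}
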