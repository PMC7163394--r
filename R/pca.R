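## PCA of the goat x period trait means, score ANOVA and per-goat
## barycentres.

#' PCA of the trait mean table
#'
#' Principal component analysis of the eleven goat x period trait means on
#' the correlation scale: traits are centred and standardized to unit
#' variance before the eigendecomposition, since they mix intakes
#' (g DM/kg BW), dimensionless ratios and rates. Incomplete rows are
#' dropped with a warning; a constant trait column is an error naming the
#' trait. Component signs follow a deterministic convention (the
#' largest-magnitude loading of each component is positive) so results
#' are reproducible across runs.
#'
#' @param mean_table goat x period mean table from [goat_period_means()].
#' @param traits trait columns to include (default: the eleven traits).
#' @return object of class `intake_pca`: list with `loadings`
#'   (traits x components), `scores` (data.frame with metadata and
#'   `PC1..PCk` columns, zero column means), `explained_pct` (summing to
#'   100 over all components) and `trait_order`.
#' @export
run_pca <- function(mean_table, traits = trait_names()) {
  need_cols(mean_table, traits, "mean table")
  complete <- stats::complete.cases(mean_table[traits])
  if (!all(complete))
    warning(sum(!complete), " incomplete row(s) dropped from the PCA")
  tab <- mean_table[complete, , drop = FALSE]
  if (nrow(tab) < 3) stop_domain("run_pca: need at least 3 complete rows")
  X <- as.matrix(tab[traits])
  sds <- apply(X, 2, stats::sd)
  if (any(sds < 1e-12))
    stop_domain("constant trait column(s): ",
                paste(traits[sds < 1e-12], collapse = ", "))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  rot <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  explained <- 100 * pc$sdev^2 / sum(pc$sdev^2)
  meta <- tab[intersect(c("goat_id", "breed", "period"), names(tab))]
  structure(list(loadings = rot,
                 scores = cbind(meta, as.data.frame(scores)),
                 explained_pct = explained,
                 trait_order = traits,
                 center = pc$center, scale = pc$scale),
            class = "intake_pca")
}

#' @export
print.intake_pca <- function(x, ...) {
  cat(sprintf("PCA of %d traits on %d rows; PC1 %.1f%%, PC2 %.1f%% (first two: %.1f%%)\n",
              length(x$trait_order), nrow(x$scores), x$explained_pct[1],
              x$explained_pct[2], sum(x$explained_pct[1:2])))
  invisible(x)
}

#' Simplified ANOVA of PCA scores
#'
#' Runs the simplified nested model (breed tested on goat-within-breed;
#' period and breed x period on the residual) on each requested component
#' of the score table, mirroring the trait-level analysis on the
#' condensed axes.
#'
#' @param pca an `intake_pca`.
#' @param components integer vector of component indices (default 1:2).
#' @return named list of `intake_anova` objects (`PC1`, `PC2`, ...).
#' @export
score_anova <- function(pca, components = 1:2) {
  stopifnot(inherits(pca, "intake_pca"))
  need_cols(pca$scores, c("goat_id", "breed", "period"), "score table")
  out <- lapply(components, function(k)
    fit_simplified_anova(pca$scores, paste0("PC", k)))
  names(out) <- paste0("PC", components)
  out
}

#' Per-goat barycentres of the period scores
#'
#' Arithmetic mean, per goat and component, of its period-level scores:
#' the animal's average position on the score plot across physiological
#' stages.
#'
#' @param pca an `intake_pca`.
#' @param components integer vector of component indices.
#' @return data.frame with `goat_id`, `breed` and one mean-score column
#'   per component.
#' @export
goat_barycentres <- function(pca, components = 1:2) {
  stopifnot(inherits(pca, "intake_pca"))
  sc <- pca$scores
  cols <- paste0("PC", components)
  need_cols(sc, c("goat_id", cols), "score table")
  rows <- lapply(split(sc, sc$goat_id), function(s) {
    cbind(data.frame(goat_id = s$goat_id[1],
                     breed = if ("breed" %in% names(s)) s$breed[1] else NA,
                     n_periods = nrow(s), stringsAsFactors = FALSE),
          as.data.frame(as.list(colMeans(s[cols]))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
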