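## End-to-end pipeline: simulate (or read) -> profiles -> fits and
## segmentation -> traits -> statistics -> report directory.

#' Default pipeline configuration
#'
#' All constants default to the standard protocol: 90/180/900-min windows
#' inside a 22-h (1320 min) recording at 2-min sampling, 8 slope
#' clusters, 30-min minimum pause, 0.95 within-period repeatability
#' threshold.
#'
#' @param seed integer seed for the whole run.
#' @return nested configuration list.
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    design = list(n_goats = 35, n_periods = 4, n_days = 4,
                  interval = 2, window = 1320, resolution = 5),
    variances = list(),          # overrides of variance_spec() defaults
    missing = "none",            # "none", "pattern", or a data.frame
    inputs = NULL,               # named CSV paths to analyse real data
    day_window = 900,
    k_clusters = 8,
    min_pause = 30,
    repeatability_threshold = 0.95,
    penalty = NULL               # NULL = BIC over the default grid
  )
}

#' Read a pipeline configuration from YAML
#'
#' Unspecified fields fall back to [default_run_config()].
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  utils::modifyList(default_run_config(), yaml::read_yaml(path))
}

#' Validate input tables
#'
#' Schema and key-consistency checks across the trough, feed, refusal and
#' body-weight tables: grid regularity, duplicated timestamps, negative
#' weights, missing BW or feed rows for recorded goat-days, refusals
#' exceeding offers, fractions outside (0, 1).
#'
#' @param trough,feed,refusal,bw data.frames (or `NULL` to skip a table).
#' @return data.frame of violations (`table`, `cell`, `issue`); zero rows
#'   when everything is consistent.
#' @export
validate_inputs <- function(trough, feed = NULL, refusal = NULL, bw = NULL) {
  v <- list()
  add <- function(table, cell, issue) v[[length(v) + 1]] <<-
    data.frame(table = table, cell = cell, issue = issue, stringsAsFactors = FALSE)
  tp <- validate_trough(trough)
  if (nrow(tp)) for (r in seq_len(nrow(tp))) add("trough", tp$cell[r], tp$issue[r])
  cells <- unique(trough[c("goat_id", "period", "day")])
  if (!is.null(bw)) {
    need_cols(bw, c("goat_id", "period", "bw"), "bw table")
    for (r in seq_len(nrow(cells))) {
      hit <- bw$bw[bw$goat_id == cells$goat_id[r] & bw$period == cells$period[r]]
      if (length(hit) != 1 || is.na(hit))
        add("bw", sprintf("goat %s period %s", cells$goat_id[r], cells$period[r]),
            "missing or ambiguous body weight")
      else if (hit <= 0)
        add("bw", sprintf("goat %s period %s", cells$goat_id[r], cells$period[r]),
            "non-positive body weight")
    }
  }
  if (!is.null(feed)) {
    need_cols(feed, c("goat_id", "period", "day", "offered_dm_g"), "feed table")
    bad <- which(feed$offered_dm_g <= 0)
    for (r in bad) add("feed", sprintf("goat %s period %s day %s",
                                       feed$goat_id[r], feed$period[r], feed$day[r]),
                       "non-positive offered mass")
    if ("offered_ndf" %in% names(feed)) {
      bad <- which(!is.na(feed$offered_ndf) &
                     (feed$offered_ndf <= 0 | feed$offered_ndf >= 1))
      for (r in bad) add("feed", sprintf("goat %s period %s day %s",
                                         feed$goat_id[r], feed$period[r], feed$day[r]),
                         "offered NDF fraction outside (0, 1)")
    }
  }
  if (!is.null(refusal) && !is.null(feed)) {
    need_cols(refusal, c("goat_id", "period", "day", "refusal_dm_g"), "refusal table")
    key <- function(d) paste(d$goat_id, d$period, d$day)
    m <- match(key(refusal), key(feed))
    for (r in which(!is.na(m))) {
      if (!is.na(refusal$refusal_dm_g[r]) &&
          refusal$refusal_dm_g[r] > feed$offered_dm_g[m[r]] + 1e-9)
        add("refusal", sprintf("goat %s period %s day %s", refusal$goat_id[r],
                               refusal$period[r], refusal$day[r]),
            "refusal mass exceeds offered mass")
    }
  }
  if (length(v)) do.call(rbind, v)
  else data.frame(table = character(0), cell = character(0), issue = character(0),
                  stringsAsFactors = FALSE)
}

## Tiny FNV-style hash of the resolved configuration, for the manifest.
config_hash <- function(config) {
  s <- paste(utils::capture.output(utils::str(config)), collapse = "\n")
  h <- 2166136261
  for (code in utf8ToInt(s)) h <- mul32(xor32(h, code), 16777619)
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Run the full phenotyping pipeline
#'
#' Wires all stages end to end: simulate a herd (or read recordings from
#' `config$inputs`), build profiles, fit the exponential model and the
#' segmentation, compute the eleven traits and their goat x period means,
#' run the statistical layer (full and simplified ANOVA per trait,
#' between-period correlations, repeatability ratios, PCA with score
#' ANOVA and barycentres) and write every table to `out_dir` as CSV plus
#' a `manifest.json` recording the seed, resolved configuration and its
#' hash. Deterministic given the seed.
#'
#' @param config configuration list (see [default_run_config()] /
#'   [read_run_config()]).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory results (`traits`,
#'   `means`, `screen`, `correlations`, `pca`, ...) and `files`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = tempfile("run")) {
  config <- utils::modifyList(default_run_config(), config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  seed <- config$seed

  if (is.null(config$inputs)) {
    design <- do.call(herd_design, config$design)
    variances <- do.call(variance_spec, config$variances)
    missing <- config$missing
    if (is.character(missing))
      missing <- switch(missing, none = NULL,
                        pattern = missing_cells_pattern(design, seed),
                        stop_domain("unknown missing spec: ", missing))
    message("stage simulate: ", design$n_goats, " goats x ", design$n_periods,
            " periods x ", design$n_days, " days")
    herd <- simulate_herd(design, variances, seed = seed, missing = missing)
    trough <- herd$trough; bw <- herd$bw_table
    feed <- herd$feed_table; refusal <- herd$refusal_table
  } else {
    message("stage read: ", config$inputs$trough)
    trough <- read_trough_series(config$inputs$trough)
    bw <- utils::read.csv(config$inputs$bw, stringsAsFactors = FALSE)
    feed <- if (!is.null(config$inputs$feed))
      utils::read.csv(config$inputs$feed, stringsAsFactors = FALSE) else NULL
    refusal <- if (!is.null(config$inputs$refusal))
      utils::read.csv(config$inputs$refusal, stringsAsFactors = FALSE) else NULL
  }
  viol <- validate_inputs(trough, feed, refusal, bw)
  if (nrow(viol))
    stop_domain("stage validate: ", nrow(viol), " violation(s); first: ",
                viol$table[1], " ", viol$cell[1], " - ", viol$issue[1])

  message("stage traits: ", nrow(unique(trough[c("goat_id", "period", "day")])),
          " goat-days")
  records <- compute_trait_table(trough, bw, feed, refusal,
                                 day_window = config$day_window,
                                 k_clusters = config$k_clusters,
                                 min_pause = config$min_pause,
                                 seed = seed, penalty = config$penalty)
  means <- goat_period_means(records)

  message("stage stats")
  screen <- repeatability_screen(records, means,
                                 threshold = config$repeatability_threshold)
  full_tabs <- lapply(trait_names(), function(tr)
    tryCatch(cbind(trait = tr, as.data.frame(fit_full_anova(records, tr))),
             error = function(e) NULL))
  simple_tabs <- lapply(trait_names(), function(tr)
    tryCatch(cbind(trait = tr, as.data.frame(fit_simplified_anova(means, tr))),
             error = function(e) NULL))
  cors <- lapply(trait_names(), function(tr)
    tryCatch(between_period_correlations(means, tr), error = function(e) NULL))
  names(cors) <- trait_names()
  cor_rows <- do.call(rbind, lapply(trait_names(), function(tr) {
    cc <- cors[[tr]]
    if (is.null(cc)) return(NULL)
    idx <- which(upper.tri(cc$r), arr.ind = TRUE)
    data.frame(trait = tr,
               period_a = rownames(cc$r)[idx[, 1]],
               period_b = colnames(cc$r)[idx[, 2]],
               r = cc$r[idx], p = cc$p[idx], n = cc$n[idx],
               stringsAsFactors = FALSE)
  }))

  message("stage pca")
  pca <- run_pca(means)
  sanova <- score_anova(pca)
  bary <- goat_barycentres(pca)
  score_rr <- data.frame(
    component = c("PC1", "PC2"),
    ratio = c(repeatability_ratio(pca$scores, "PC1")$ratio,
              repeatability_ratio(pca$scores, "PC2")$ratio))

  out <- list(traits = records, means = means, screen = screen,
              correlations = cor_rows, pca = pca, score_anova = sanova,
              barycentres = bary, score_repeatability = score_rr)
  files <- c(
    traits = "traits.csv", trait_means = "trait_means.csv",
    repeatability = "repeatability.csv", anova_full = "anova_full.csv",
    anova_simplified = "anova_simplified.csv", correlations = "correlations.csv",
    pca_loadings = "pca_loadings.csv", pca_scores = "pca_scores.csv",
    barycentres = "barycentres.csv", score_repeatability = "score_repeatability.csv")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  utils::write.csv(records, paths["traits"], row.names = FALSE)
  utils::write.csv(means, paths["trait_means"], row.names = FALSE)
  utils::write.csv(screen, paths["repeatability"], row.names = FALSE)
  utils::write.csv(do.call(rbind, full_tabs), paths["anova_full"], row.names = FALSE)
  utils::write.csv(do.call(rbind, simple_tabs), paths["anova_simplified"],
                   row.names = FALSE)
  utils::write.csv(cor_rows, paths["correlations"], row.names = FALSE)
  utils::write.csv(cbind(trait = rownames(pca$loadings),
                         as.data.frame(pca$loadings)),
                   paths["pca_loadings"], row.names = FALSE)
  utils::write.csv(pca$scores, paths["pca_scores"], row.names = FALSE)
  utils::write.csv(bary, paths["barycentres"], row.names = FALSE)
  utils::write.csv(score_rr, paths["score_repeatability"], row.names = FALSE)
  manifest <- list(package = "caprifeed",
                   version = as.character(utils::packageVersion("caprifeed")),
                   seed = seed, config = config, config_hash = config_hash(config),
                   n_records = nrow(records), n_means = nrow(means),
                   explained_pct_pc12 = sum(pca$explained_pct[1:2]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out$files <- c(paths, manifest = file.path(out_dir, "manifest.json"))
  invisible(out)
}
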