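## Nested fixed-effect ANOVA with custom error terms, within-period
## repeatability, between-period correlations and the between/(between +
## within) repeatability ratio.

## Sequential (type-I) sums of squares for an ordered list of terms, by
## incremental least squares; handles unbalanced data via QR rank.
seq_anova <- function(data, response, terms, effect_names = terms) {
  y <- data[[response]]
  keep <- !is.na(y)
  if (!all(keep)) {
    data <- data[keep, , drop = FALSE]
    y <- y[keep]
  }
  n <- length(y)
  if (n < 3) stop_domain("ANOVA: too few observations")
  X <- matrix(1, n, 1)
  rss_prev <- sum((y - mean(y))^2)
  rank_prev <- 1L
  df <- ss <- numeric(length(terms))
  for (k in seq_along(terms)) {
    mm <- stats::model.matrix(stats::reformulate(terms[k], intercept = FALSE), data)
    X <- cbind(X, mm)
    fit <- stats::lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    ss[k] <- max(0, rss_prev - rss)
    df[k] <- fit$rank - rank_prev
    rss_prev <- rss
    rank_prev <- fit$rank
  }
  res_df <- n - rank_prev
  list(table = data.frame(effect = effect_names, df = df, ss = ss,
                          stringsAsFactors = FALSE),
       res_df = res_df, res_ss = rss_prev, n = n)
}

finish_anova <- function(sq, error_map, response, model) {
  tab <- sq$table
  if (any(tab$df == 0))
    stop_domain("ANOVA: effect(s) ", paste(tab$effect[tab$df == 0], collapse = ", "),
                " are confounded (zero degrees of freedom)")
  if (sq$res_df <= 0)
    stop_domain("ANOVA: no residual degrees of freedom; the design is saturated")
  tab$ms <- tab$ss / tab$df
  res_ms <- sq$res_ss / sq$res_df
  tab$error_term <- vapply(tab$effect, function(e)
    error_map[[e]] %||% "residual", character(1))
  tab$f <- tab$p <- NA_real_
  for (r in seq_len(nrow(tab))) {
    if (tab$error_term[r] == "residual") {
      den <- res_ms; dendf <- sq$res_df
    } else {
      hit <- match(tab$error_term[r], tab$effect)
      if (is.na(hit)) stop_domain("ANOVA: unknown error term ", tab$error_term[r])
      den <- tab$ms[hit]; dendf <- tab$df[hit]
    }
    tab$f[r] <- tab$ms[r] / den
    tab$p[r] <- stats::pf(tab$f[r], tab$df[r], dendf, lower.tail = FALSE)
  }
  tab <- rbind(tab, data.frame(effect = "residual", df = sq$res_df,
                               ss = sq$res_ss, ms = res_ms,
                               error_term = NA, f = NA_real_, p = NA_real_))
  structure(tab, class = c("intake_anova", "data.frame"),
            response = response, model = model, n = sq$n)
}

#' Full nested ANOVA of day-level trait records
#'
#' Fits the fixed-effect model with breed, goat nested in breed, day
#' nested in breed and goat, period, and the breed x period interaction,
#' by sequential (type-I) sums of squares in that order. Error terms
#' follow the nested design: the breed mean square is tested against the
#' goat-within-breed mean square, everything else against the residual.
#' The day-within-goat F-test against the residual is the within-period
#' repeatability test: a large p-value (no day effect) means the trait is
#' repeatable across days for a given goat.
#'
#' Adding a constant to all observations leaves every F statistic
#' unchanged; mild unbalance (missing goat-days) is handled by least
#' squares.
#'
#' @param records trait-record data.frame with `goat_id`, `breed`,
#'   `period`, `day` and the response column.
#' @param response name of the trait column to analyse.
#' @param error_map named list mapping effect names to the effect used as
#'   their error term (`"residual"` for the residual mean square).
#' @return an `intake_anova` data.frame: per-effect `df`, `ss`, `ms`,
#'   `error_term`, `f`, `p`, plus a residual row.
#' @export
fit_full_anova <- function(records, response,
                           error_map = list(breed = "goat(breed)")) {
  need_cols(records, c("goat_id", "breed", "period", "day", response),
            "trait records")
  d <- data.frame(y = records[[response]],
                  breed = factor(records$breed),
                  goat = factor(records$goat_id),
                  day = factor(records$day),
                  period = factor(records$period))
  sq <- seq_anova(d, "y", c("breed", "goat", "goat:day", "period", "breed:period"),
                  c("breed", "goat(breed)", "day(goat)", "period", "breed:period"))
  finish_anova(sq, error_map, response, "full")
}

#' Within-period repeatability decision
#'
#' Reads the day-within-goat p-value off a full-model ANOVA and declares
#' the trait repeatable within period when that p-value exceeds the
#' threshold (default 0.95): a p-value that large is strong evidence that
#' days differ only by residual noise for a given goat.
#'
#' @param anova an `intake_anova` from [fit_full_anova()].
#' @param threshold repeatability threshold on the day-effect p-value.
#' @return list with `response`, `p_value`, `threshold`, `repeatable`.
#' @export
within_period_repeatability <- function(anova, threshold = 0.95) {
  stopifnot(inherits(anova, "intake_anova"))
  r <- match("day(goat)", anova$effect)
  if (is.na(r)) stop_domain("ANOVA has no day(goat) effect; fit the full model")
  p <- anova$p[r]
  list(response = attr(anova, "response"), p_value = p,
       threshold = threshold, repeatable = p > threshold)
}

#' Simplified ANOVA of goat x period means
#'
#' The day effect is dropped: breed, goat within breed, period and
#' breed x period are fitted on the per-goat per-period means, with the
#' breed effect tested on the goat-within-breed mean square and the rest
#' on the residual. Per-breed and per-period means with pairwise grouping
#' letters (alpha = 0.05, each family tested against its effect's error
#' term) are attached as attribute `"group_means"`.
#'
#' @param mean_table goat x period mean table from [goat_period_means()]
#'   (any data.frame with `goat_id`, `breed`, `period` and the response).
#' @param response trait column name.
#' @param error_map named list of error-term overrides.
#' @param alpha significance level for the grouping letters.
#' @return an `intake_anova` data.frame.
#' @export
fit_simplified_anova <- function(mean_table, response,
                                 error_map = list(breed = "goat(breed)"),
                                 alpha = 0.05) {
  need_cols(mean_table, c("goat_id", "breed", "period", response), "mean table")
  d <- data.frame(y = mean_table[[response]],
                  breed = factor(mean_table$breed),
                  goat = factor(mean_table$goat_id),
                  period = factor(mean_table$period))
  sq <- seq_anova(d, "y", c("breed", "goat", "period", "breed:period"),
                  c("breed", "goat(breed)", "period", "breed:period"))
  out <- finish_anova(sq, error_map, response, "simplified")
  res_row <- nrow(out)
  gm <- list(
    period = group_means(d, "period", out$ms[res_row], out$df[res_row], alpha),
    breed = group_means(d, "breed",
                        out$ms[match("goat(breed)", out$effect)],
                        out$df[match("goat(breed)", out$effect)], alpha))
  attr(out, "group_means") <- gm
  out
}

## Factor-level means with pairwise grouping letters against a given
## error mean square.
group_means <- function(d, fac, err_ms, err_df, alpha = 0.05) {
  keep <- !is.na(d$y)
  lv <- levels(d[[fac]])
  m <- vapply(lv, function(l) mean(d$y[keep & d[[fac]] == l]), numeric(1))
  n <- vapply(lv, function(l) sum(keep & d[[fac]] == l), numeric(1))
  k <- length(lv)
  p <- matrix(1, k, k, dimnames = list(lv, lv))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    se <- sqrt(err_ms * (1 / n[i] + 1 / n[j]))
    tstat <- if (se > 0) (m[i] - m[j]) / se else 0
    p[i, j] <- p[j, i] <- 2 * stats::pt(abs(tstat), err_df, lower.tail = FALSE)
  }
  data.frame(level = lv, mean = m, n = n,
             letters = cld_letters(m, p, alpha), row.names = NULL,
             stringsAsFactors = FALSE)
}

## Compact letter display: levels sharing a letter do not differ at alpha.
cld_letters <- function(means, pmat, alpha = 0.05) {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  groups <- list()
  for (i in ord) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (all(pmat[i, groups[[g]]] > alpha)) {
        groups[[g]] <- c(groups[[g]], i)
        placed <- TRUE
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- i
  }
  out <- character(k)
  for (g in seq_along(groups))
    for (i in groups[[g]]) out[i] <- paste0(out[i], letters[g])
  out
}

#' Between-period correlations of goat means
#'
#' Pearson correlations, per pair of periods, between the mean values per
#' goat of a trait, with two-sided p-values and pairwise-complete handling
#' of missing cells. Pairs with fewer than 3 complete goats are left `NA`
#' and flagged.
#'
#' @param mean_table goat x period mean table.
#' @param response trait column name.
#' @return object of class `period_correlations`: list of matrices `r`,
#'   `p`, `n` and a star-annotated character matrix `stars`
#'   (`*` p < 0.05, `**` p < 0.01).
#' @export
between_period_correlations <- function(mean_table, response) {
  need_cols(mean_table, c("goat_id", "period", response), "mean table")
  periods <- sort(unique(mean_table$period))
  k <- length(periods)
  wide <- stats::reshape(
    mean_table[c("goat_id", "period", response)],
    idvar = "goat_id", timevar = "period", direction = "wide")
  vals <- as.matrix(wide[, -1, drop = FALSE])
  colnames(vals) <- periods
  r <- p <- nmat <- matrix(NA_real_, k, k, dimnames = list(periods, periods))
  diag(r) <- 1; diag(p) <- 0
  diag(nmat) <- colSums(!is.na(vals))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- stats::complete.cases(vals[, c(i, j)])
    nmat[i, j] <- nmat[j, i] <- sum(ok)
    if (sum(ok) < 3) next
    ct <- stats::cor.test(vals[ok, i], vals[ok, j])
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  stars <- matrix("", k, k, dimnames = dimnames(r))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, n = nmat, stars = stars, response = response),
            class = "period_correlations")
}

#' @export
print.period_correlations <- function(x, ...) {
  cat("Between-period correlations of", x$response, "\n")
  shown <- matrix(paste0(formatC(x$r, digits = 3, format = "f"), x$stars),
                  nrow(x$r), dimnames = dimnames(x$r))
  print(shown, quote = FALSE)
  invisible(x)
}

#' Between-period repeatability ratio
#'
#' One-way decomposition of the goat x period means by goat: the
#' between-animal variance component is estimated by method of moments
#' from the between- and within-goat mean squares (negative estimates
#' truncated to zero) and the repeatability is
#' `sigma2_between / (sigma2_between + sigma2_within)` -- the proportion of
#' the variance between animals on the sum of the between- and
#' within-animal variances, i.e. the squared correlation expected between
#' repeated measures of the same animal in different periods. Invariant
#' to affine transformation of the trait.
#'
#' @param mean_table goat x period mean table.
#' @param response trait column name.
#' @return object of class `repeatability_result`: list with `response`,
#'   `sigma2_between`, `sigma2_within`, `ratio`, `n_goats`, `n_cells`.
#' @export
repeatability_ratio <- function(mean_table, response) {
  need_cols(mean_table, c("goat_id", "period", response), "mean table")
  x <- mean_table[[response]]
  g <- factor(mean_table$goat_id)
  keep <- !is.na(x)
  x <- x[keep]; g <- droplevels(g[keep])
  ni <- table(g)
  if (any(ni < 2)) {
    drop <- names(ni)[ni < 2]
    warning("dropping goat(s) with a single period: ", paste(drop, collapse = ", "))
    keep <- !(as.character(g) %in% drop)
    x <- x[keep]; g <- droplevels(g[keep])
    ni <- table(g)
  }
  a <- nlevels(g)
  if (a < 2) stop_domain("repeatability_ratio: need at least two goats with >= 2 periods")
  N <- length(x)
  gm <- mean(x)
  mi <- tapply(x, g, mean)
  msb <- sum(ni * (mi - gm)^2) / (a - 1)
  msw <- sum((x - mi[g])^2) / (N - a)
  k0 <- (N - sum(ni^2) / N) / (a - 1)
  s2b <- max(0, (msb - msw) / k0)
  s2w <- msw
  ratio <- if (s2b + s2w <= 0) 0 else s2b / (s2b + s2w)
  structure(list(response = response, sigma2_between = s2b,
                 sigma2_within = s2w, ratio = ratio,
                 n_goats = a, n_cells = N),
            class = "repeatability_result")
}

#' @export
print.repeatability_result <- function(x, ...) {
  cat(sprintf("Repeatability of %s: %.3f (between %.4g, within %.4g; %d goats)\n",
              x$response, x$ratio, x$sigma2_between, x$sigma2_within, x$n_goats))
  invisible(x)
}

#' Repeatability screen across traits
#'
#' Convenience wrapper: for each trait, the full-model day-effect p-value,
#' the within-period repeatability decision and the between-period
#' repeatability ratio of the goat x period means.
#'
#' @param records day-level trait records.
#' @param mean_table goat x period mean table.
#' @param responses trait columns (default: the eleven traits).
#' @param threshold within-period repeatability threshold.
#' @return data.frame, one row per trait.
#' @export
repeatability_screen <- function(records, mean_table,
                                 responses = trait_names(), threshold = 0.95) {
  rows <- lapply(responses, function(tr) {
    day_p <- tryCatch(
      within_period_repeatability(fit_full_anova(records, tr), threshold)$p_value,
      error = function(e) NA_real_)
    rr <- tryCatch(repeatability_ratio(mean_table, tr),
                   error = function(e) list(ratio = NA_real_))
    data.frame(trait = tr, day_p = day_p,
               repeatable_within = !is.na(day_p) & day_p > threshold,
               ratio_between_periods = rr$ratio, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
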