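# Two-group comparison statistics and run reports.

#' Compare two treatment groups parameter by parameter
#'
#' For each morphological parameter: two-sided Mann-Whitney U test (exact
#' for small samples without ties), effect size r = Z / sqrt(N) from the
#' normal approximation of U, the Hodges-Lehmann estimate and 95% confidence
#' interval of the median difference, and the two-sample Kolmogorov-Smirnov
#' statistic. Statistics are computed at the individual-cell level, which
#' inflates the apparent sample size relative to the number of animals and
#' can overstate significance; the returned object carries this caveat and
#' per-animal cell counts so pseudoreplication is visible.
#'
#' @param records data.frame of per-cell records.
#' @param group_column column holding exactly two group labels.
#' @param parameters feature columns; default [morph_features].
#' @param conf_level confidence level for the median-difference CI.
#' @return data.frame with one row per parameter: `parameter`, `n1`, `n2`,
#'   `mw_U`, `mw_p`, `effect_size_r`, `hl_estimate`, `ci_low`, `ci_high`,
#'   `ks_D`, `ks_p`. Attributes: `groups` (level order: differences are
#'   group1 - group2), `caveat`, `cells_per_animal`.
#' @export
compare_groups <- function(records, group_column = "group",
                           parameters = morph_features(),
                           conf_level = 0.95) {
  g <- factor(records[[group_column]])
  if (nlevels(g) != 2L)
    stop("compare_groups needs exactly two groups; for per-cluster ",
         "comparisons use cluster_comparisons()")
  if (any(table(g) < 3L)) stop("each group needs at least 3 cells")
  lv <- levels(g)
  rows <- lapply(parameters, function(p) {
    x <- records[[p]][g == lv[1]]
    y <- records[[p]][g == lv[2]]
    n1 <- length(x); n2 <- length(y); N <- n1 + n2
    wt <- suppressWarnings(wilcox.test(x, y, conf.int = TRUE,
                                       conf.level = conf_level))
    U <- unname(wt$statistic)
    # normal approximation with tie correction, for the signed effect size
    r <- rank(c(x, y))
    ties <- table(r)
    mu_u <- n1 * n2 / 2
    sig_u <- sqrt(n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1))))
    zval <- if (sig_u > 0) (U - mu_u) / sig_u else 0
    ks <- suppressWarnings(ks.test(x, y))
    data.frame(parameter = p, n1 = n1, n2 = n2,
               mw_U = U, mw_p = wt$p.value,
               effect_size_r = zval / sqrt(N),
               hl_estimate = unname(wt$estimate),
               ci_low = wt$conf.int[1], ci_high = wt$conf.int[2],
               ks_D = unname(ks$statistic), ks_p = ks$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lv
  attr(out, "caveat") <- paste(
    "Statistics are computed at the individual-cell level, which increases",
    "the apparent sample size and may overstate statistical significance.")
  if ("animal_id" %in% names(records))
    attr(out, "cells_per_animal") <-
      as.data.frame(table(animal = records$animal_id, group = g))
  out
}

#' Assemble a run report
#'
#' Collects the pipeline outputs into a single reproducible report: cell
#' counts per exclusion reason, per-group parameter medians and quartiles,
#' group statistics, cluster frequencies, and the full configuration echo.
#' Written as JSON plus a short human-readable markdown summary when `path`
#' is given.
#'
#' @param audit audit table from [audit_table] (segmentation stage).
#' @param records morphometric records from [measure_cells] or a feature
#'   table (morphometry stage).
#' @param comparisons optional output of [compare_groups].
#' @param frequency optional output of [frequency_test].
#' @param config configuration list echoed for reproducibility.
#' @param path optional output stem; writes `<path>.json` and `<path>.md`.
#' @return The report as a list, invisibly when writing.
#' @export
run_report <- function(audit, records, comparisons = NULL, frequency = NULL,
                       config = default_config(), path = NULL) {
  if (is.null(audit)) stop("missing input from stage: segmentation (audit table)")
  if (is.null(records)) stop("missing input from stage: morphometry (records)")
  excl <- table(factor(audit$exclusion_reason,
                       levels = c("none", "too_small", "too_large",
                                  "incomplete", "manual")))
  params <- intersect(morph_features(), names(records))
  by_group <- NULL
  if ("group" %in% names(records) && length(unique(records$group)) >= 1L) {
    by_group <- lapply(split(records, records$group), function(df) {
      lapply(setNames(params, params), function(p) {
        q <- unname(quantile(df[[p]], c(0.25, 0.5, 0.75), na.rm = TRUE))
        list(q1 = q[1], median = q[2], q3 = q[3], n = sum(is.finite(df[[p]])))
      })
    })
  }
  rep_list <- list(
    n_objects = nrow(audit),
    n_included = sum(audit$included),
    exclusions = as.list(excl),
    parameter_summaries = by_group,
    group_comparisons = if (!is.null(comparisons)) {
      lst <- as.list(comparisons)
      lst$caveat <- attr(comparisons, "caveat")
      lst
    },
    cluster_frequency = if (!is.null(frequency)) list(
      chi2 = frequency$chi2, df = frequency$df, p = frequency$p,
      observed = as.data.frame(frequency$table),
      expected = as.data.frame(frequency$expected),
      any_low_expected = any(frequency$low_expected)),
    config = config)
  if (is.null(path)) return(rep_list)
  jsonlite::write_json(rep_list, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  md <- c(
    "# gliamorph run report", "",
    sprintf("- objects labeled: %d", rep_list$n_objects),
    sprintf("- cells included: %d", rep_list$n_included),
    sprintf("- exclusions: %s",
            paste(names(excl), as.integer(excl), sep = "=", collapse = ", ")),
    if (!is.null(frequency))
      sprintf("- cluster frequency chi-square: chi2 = %.3f, df = %d, p = %.4g",
              frequency$chi2, frequency$df, frequency$p),
    "",
    "Note: statistics are computed at the individual-cell level, which",
    "increases the apparent sample size; per-animal cell counts are in the",
    "JSON report.")
  writeLines(md, paste0(path, ".md"))
  invisible(rep_list)
}
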