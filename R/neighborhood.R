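#' Classify zip neighborhoods into sensitivity quartiles
#'
#' Cut points are the empirical 25th/50th/75th percentiles of the zip-level
#' SDS scores (linear interpolation between closest ranks, i.e.
#' [stats::quantile()] type 7). A zip is labelled `"low"` when its score is at
#' or below the first cut; bins above are half-open upward, so ties at a cut
#' fall in the lower group. Labels are ordered
#' low < medium-low < medium-high < high.
#'
#' @param zip_scores data frame with `zip` and `SDS_z` (e.g.
#'   `fit$zip_scores`).
#' @return list of class `sds_quartiles`: `groups` (data frame `zip`,
#'   `SDS_z`, `quartile`), `cuts` (the three percentiles) and `group_means`.
#' @export
classify_quartiles <- function(zip_scores) {
  stopifnot(all(c("zip", "SDS_z") %in% names(zip_scores)))
  x <- zip_scores$SDS_z
  if (length(x) < 4) stop("quartile classification needs at least 4 zips")
  if (max(x) == min(x))
    stop("degenerate score distribution: all zip scores equal")
  cuts <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  labels <- c("low", "medium-low", "medium-high", "high")
  lab <- ifelse(x <= cuts[1], labels[1],
         ifelse(x <= cuts[2], labels[2],
         ifelse(x <= cuts[3], labels[3], labels[4])))
  groups <- data.frame(zip = zip_scores$zip, SDS_z = x,
                       quartile = factor(lab, levels = labels, ordered = TRUE),
                       stringsAsFactors = FALSE)
  structure(list(
    groups = groups,
    cuts = stats::setNames(cuts, c("q25", "q50", "q75")),
    group_means = tapply(groups$SDS_z, groups$quartile, mean)
  ), class = "sds_quartiles")
}

#' @export
print.sds_quartiles <- function(x, ...) {
  cat("Zip sensitivity quartiles (cuts at",
      paste(round(x$cuts, 2), collapse = " / "), ")\n")
  print(table(x$groups$quartile))
  invisible(x)
}

#' Compare covariates across sensitivity quartiles
#'
#' For each requested covariate: group means and standard deviations by
#' quartile, a one-way ANOVA F test, and Tukey's HSD post-hoc table over all
#' six group pairs. Missing covariate values are dropped per covariate
#' (pairwise deletion) with the analysis n reported; a covariate constant
#' within all groups is flagged rather than crashed on. No cross-covariate
#' multiplicity correction is applied.
#'
#' @param grouping an [classify_quartiles()] object.
#' @param covariate_table data frame with `zip` and covariate columns.
#' @param covariates character vector of columns to test; default all
#'   non-`zip` numeric columns.
#' @return list of class `sds_group_comparison`: `anova` (one row per
#'   covariate: group means/sds, F, p, n) and `tukey` (named list of pairwise
#'   tables).
#' @export
compare_groups <- function(grouping, covariate_table, covariates = NULL) {
  stopifnot(inherits(grouping, "sds_quartiles"), "zip" %in% names(covariate_table))
  if (is.null(covariates)) {
    covariates <- setdiff(names(covariate_table)[vapply(covariate_table, is.numeric, TRUE)],
                          "zip")
  }
  g <- grouping$groups
  merged <- merge(g, covariate_table, by = "zip")
  merged$quartile <- factor(merged$quartile, ordered = FALSE)  # aov wants nominal

  rows <- list(); tukey <- list()
  for (cv in covariates) {
    d <- merged[!is.na(merged[[cv]]), c("quartile", cv)]
    names(d)[2] <- "y"
    means <- tapply(d$y, d$quartile, mean)
    sds <- tapply(d$y, d$quartile, stats::sd)
    constant <- length(unique(d$y)) == 1L
    small <- any(table(d$quartile) < 2L)
    if (constant || small || nlevels(droplevels(d$quartile)) < 2L) {
      rows[[cv]] <- data.frame(covariate = cv, t(means), F = NA_real_, p = NA_real_,
                               n = nrow(d), flag = if (constant) "constant" else "insufficient groups",
                               stringsAsFactors = FALSE)
      next
    }
    d$grp <- droplevels(d$quartile)
    fit <- stats::aov(y ~ grp, data = d)
    an <- summary(fit)[[1]]
    rows[[cv]] <- data.frame(covariate = cv, t(means),
                             F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
                             n = nrow(d), flag = "", stringsAsFactors = FALSE)
    tukey[[cv]] <- stats::TukeyHSD(fit)$grp
  }
  anova_tab <- do.call(rbind, rows)
  rownames(anova_tab) <- NULL
  structure(list(anova = anova_tab, tukey = tukey,
                 group_sd = NULL), class = "sds_group_comparison")
}

#' @export
print.sds_group_comparison <- function(x, ...) {
  cat("Covariate comparison across sensitivity quartiles (one-way ANOVA):\n")
  tab <- x$anova
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Correlate zip sensitivity with health indicators
#'
#' Pearson correlation (with two-sided test) between the zip-level SDS score
#' and each requested indicator. An indicator with zero variance over the
#' paired observations is flagged rather than tested.
#'
#' @param zip_scores data frame with `zip` and `SDS_z`.
#' @param covariate_table data frame with `zip` and indicator columns.
#' @param indicators character vector of indicator column names.
#' @return data frame `indicator`, `r`, `p`, `n`, `flag`.
#' @export
correlate_indicators <- function(zip_scores, covariate_table, indicators) {
  merged <- merge(zip_scores, covariate_table, by = "zip")
  out <- lapply(indicators, function(ind) {
    if (!ind %in% names(merged)) stop("unknown indicator: ", ind)
    d <- merged[!is.na(merged[[ind]]) & !is.na(merged$SDS_z), ]
    n <- nrow(d)
    if (n < 3)
      return(data.frame(indicator = ind, r = NA_real_, p = NA_real_, n = n,
                        flag = "fewer than 3 pairs", stringsAsFactors = FALSE))
    if (stats::sd(d[[ind]]) == 0 || stats::sd(d$SDS_z) == 0)
      return(data.frame(indicator = ind, r = NA_real_, p = NA_real_, n = n,
                        flag = "zero variance", stringsAsFactors = FALSE))
    ct <- stats::cor.test(d$SDS_z, d[[ind]], method = "pearson")
    data.frame(indicator = ind, r = unname(ct$estimate), p = ct$p.value, n = n,
               flag = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-zip police action rates
#'
#' The fraction of a zip's complaints whose record indicates a police
#' response. Zips with no complaints are omitted.
#'
#' @param complaint_table complaints with `zip` (or resolvable via `units`)
#'   and a logical `police_action` column.
#' @param units optional unit table to map `building_id` to `zip` when the
#'   complaint table has no `zip` column.
#' @return data frame `zip`, `action_rate`, `n_complaints`.
#' @export
police_action_rates <- function(complaint_table, units = NULL) {
  ct <- complaint_table
  if (!"zip" %in% names(ct)) {
    if (is.null(units)) stop("complaints carry no zip and no unit table supplied")
    ct$zip <- units$zip[match(ct$building_id, units$unit_id)]
  }
  if (!"police_action" %in% names(ct))
    stop("complaint table has no police_action flag")
  ct <- ct[!is.na(ct$zip), , drop = FALSE]
  sp <- split(ct$police_action, ct$zip)
  data.frame(zip = names(sp),
             action_rate = vapply(sp, mean, 0),
             n_complaints = vapply(sp, length, 0L),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare demographics by police-action rate within sensitivity quartiles
#'
#' Within each SDS quartile, zips are split into a low-response stratum
#' (action rate below `low`) and a high-response stratum (rate above `high`);
#' zips in between are excluded. The demographic share (default: non-Hispanic
#' White percentage) is compared between strata with a Welch two-sample
#' t-test. A quartile in which either stratum has fewer than 2 zips is
#' flagged and its test skipped.
#'
#' @param rates per-zip rates from [police_action_rates()].
#' @param grouping an [classify_quartiles()] object.
#' @param covariate_table data frame with `zip` and the share column.
#' @param share_col name of the demographic share column.
#' @param low,high rate thresholds, `0 < low < high < 1` (defaults 0.3 and
#'   0.6).
#' @return data frame, one row per quartile: stratum means, zip counts, `t`,
#'   `p`, `flag`.
#' @export
compare_police_by_group <- function(rates, grouping, covariate_table,
                                    share_col = "nonhispanic_white_pct",
                                    low = 0.3, high = 0.6) {
  stopifnot(inherits(grouping, "sds_quartiles"))
  if (!(low > 0 && low < high && high < 1))
    stop("thresholds must satisfy 0 < low < high < 1")
  if (!share_col %in% names(covariate_table))
    stop("unknown share column: ", share_col)

  d <- merge(merge(rates, grouping$groups, by = "zip"),
             covariate_table[, c("zip", share_col)], by = "zip")
  names(d)[names(d) == share_col] <- "share"

  out <- lapply(levels(grouping$groups$quartile), function(q) {
    g <- d[d$quartile == q, ]
    lo <- g$share[g$action_rate < low]
    hi <- g$share[g$action_rate > high]
    row <- data.frame(quartile = q,
                      mean_low = if (length(lo)) mean(lo) else NA_real_,
                      mean_high = if (length(hi)) mean(hi) else NA_real_,
                      n_low = length(lo), n_high = length(hi),
                      t = NA_real_, p = NA_real_, flag = "",
                      stringsAsFactors = FALSE)
    if (length(lo) < 2 || length(hi) < 2) {
      row$flag <- "stratum too small; test skipped"
      return(row)
    }
    tt <- stats::t.test(lo, hi)   # Welch by default
    row$t <- unname(tt$statistic); row$p <- tt$p.value
    row
  })
  do.call(rbind, out)
}
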