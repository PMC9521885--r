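#' POI activity intensity
#'
#' Visit density: visits per 10,000 square feet of floor area per time unit.
#' The 10,000 sq ft scale is deliberate and pinned: the sensation value
#' `D * log(A)` is not invariant to the intensity unit (the min-max
#' normalisation removes a common log-base factor but not a per-unit additive
#' shift interacting with heterogeneous `D`), so intensities must be expressed
#' on this scale throughout a run.
#'
#' @param visits visit count(s), >= 0.
#' @param floor_area floor area(s) in square feet, > 0.
#' @return numeric intensity, visits per 10,000 sq ft.
#' @export
#' @examples
#' activity_intensity(20, 10000)  # 20
#' activity_intensity(4, 5000)    # 8
activity_intensity <- function(visits, floor_area) {
  if (any(is.na(floor_area)) || any(floor_area <= 0))
    stop("floor_area must be > 0")
  visits / floor_area * 1e4
}

#' Absolute threshold
#'
#' The mean activity intensity over a unit's open intervals in which a
#' complaint was reported: the average stimulus level that produced a
#' response.
#'
#' @param complaint_intensities intensities of complaint-flagged open
#'   intervals (nonempty).
#' @return numeric mean intensity `A`.
#' @export
absolute_threshold <- function(complaint_intensities) {
  if (length(complaint_intensities) == 0)
    stop("no complaint intervals: unit cannot be scored")
  mean(complaint_intensities)
}

#' Difference threshold (Weber fraction)
#'
#' The fractional excess of the absolute threshold over the unit's baseline
#' mean intensity, `D = (A - B) / B` with `B` the mean intensity of open,
#' complaint-free intervals. A negative value (complaint-time density below
#' baseline) is kept as computed, not floored at zero.
#'
#' @param A absolute threshold from [absolute_threshold()].
#' @param baseline_intensities intensities of open, complaint-free intervals
#'   (nonempty, positive mean).
#' @return numeric Weber fraction `D`.
#' @export
#' @examples
#' difference_threshold(20, rep(4, 10))  # 4.0, i.e. 400%
#' difference_threshold(6, rep(4, 10))   # 0.5, i.e. 50%
difference_threshold <- function(A, baseline_intensities) {
  if (length(baseline_intensities) == 0)
    stop("no baseline intervals: unit cannot be scored")
  B <- mean(baseline_intensities)
  if (B <= 0) stop("baseline mean intensity must be > 0")
  (A - B) / B
}

#' Subjective sensation
#'
#' Fechner's law: sensation grows as the logarithm of the stimulus, scaled
#' here by the Weber fraction: `SS = D * log(A)`. Base-10 logarithm by
#' default; the final SDS score is provably invariant to the log base (a
#' positive rescaling of all `SS` values), so the choice is cosmetic.
#'
#' @param D Weber fraction.
#' @param A absolute threshold, > 0.
#' @param log_base base of the logarithm (default 10).
#' @return numeric sensation value.
#' @export
#' @examples
#' subjective_sensation(4, 20)  # 4 * log10(20) = 5.20412
subjective_sensation <- function(D, A, log_base = 10) {
  if (any(is.na(A)) || any(A <= 0)) stop("absolute threshold A must be > 0")
  D * log(A, base = log_base)
}

#' SDS scores from sensation values
#'
#' Inverse min-max normalisation to a 0-100 score:
#' `SDS = |1 - (SS - min SS) / (max SS - min SS)| * 100`.
#' The unit with the largest sensation value (most tolerant) scores 0, the
#' smallest (most sensitive) scores 100. Normalisation is over all scored
#' units in the run; ties at an extreme all receive the extreme score.
#'
#' @param ss numeric sensation values for at least two units, not all equal.
#' @return numeric scores in `[0, 100]`.
#' @export
#' @examples
#' sds_scores(c(0, 1, 2))  # 100 50 0
sds_scores <- function(ss) {
  if (length(ss) < 2)
    stop("min-max normalization undefined: need at least two scored units")
  rng <- range(ss)
  if (rng[1] == rng[2])
    stop("min-max normalization undefined: all sensation values equal; ",
         "check that complaint and baseline intensities vary across units")
  abs(1 - (ss - rng[1]) / (rng[2] - rng[1])) * 100
}

#' Fit social distancing sensitivity scores
#'
#' The estimator core: from a flagged six-hour interval table and its unit
#' table, computes for every scorable unit the absolute threshold `A` (mean
#' complaint-interval intensity), the difference threshold `D` (Weber
#' fraction over the unit's baseline), the subjective sensation
#' `SS = D * log A`, and the inverse min-max normalised SDS score in
#' `[0, 100]`, then aggregates scores to zip-code neighborhoods.
#'
#' Only open intervals enter either side of the computation. A unit is
#' scorable when it has at least one complaint-flagged open interval, at
#' least `min_baseline` open complaint-free intervals, a positive baseline
#' mean, and `A > 0`; units failing these gates are recorded in the ledger,
#' not silently dropped. With `stratified_baseline = TRUE` each complaint
#' interval is referenced against the baseline mean of its own time-of-day
#' slot rather than the whole-study baseline.
#'
#' @param intervals interval table from [bin_six_hour()] +
#'   [flag_complaints()]: `unit_id`, `interval_start`, `visits`, `open`,
#'   `intensity`, `complaint`.
#' @param units unit table from [pool_to_buildings()]: `unit_id`, `zip`,
#'   `poi_type`, `floor_area`.
#' @param min_baseline minimum number of open complaint-free intervals
#'   required to score a unit (default 4, about one day of baseline).
#' @param log_base log base for the sensation value (default 10; SDS is
#'   invariant to this choice).
#' @param stratified_baseline match complaint intervals to baselines from the
#'   same six-hour slot of the day (default `FALSE`: whole-study baseline).
#' @param ledger optional [new_ledger()].
#' @return An object of class `sds_fit`: list with
#'   \describe{
#'     \item{estimates}{per-unit data frame: `unit_id`, `zip`, `poi_type`,
#'       `A`, `D`, `SS`, `SDS`, `n_complaint_intervals`,
#'       `n_baseline_intervals`.}
#'     \item{zip_scores}{per-zip data frame: `zip`, `SDS_z`, `n_units`.}
#'     \item{intervals}{the open intervals of scored units (used by
#'       [citywide_complaint_curves()] and [plot.sds_fit()]).}
#'     \item{settings, ledger, call}{fit metadata.}
#'   }
#' @seealso [coef.sds_fit()], [summary.sds_fit()], [plot.sds_fit()],
#'   [type_summary()]
#' @export
sds_fit <- function(intervals, units, min_baseline = 4L, log_base = 10,
                    stratified_baseline = FALSE, ledger = NULL) {
  if (is.null(ledger)) ledger <- new_ledger()
  needed <- c("unit_id", "interval_start", "open", "intensity", "complaint")
  stopifnot(all(needed %in% names(intervals)),
            all(c("unit_id", "zip") %in% names(units)))

  n0 <- nrow(intervals)
  open_iv <- intervals[intervals$open, , drop = FALSE]
  ledger_add(ledger, "score_drop_closed_intervals", n0, nrow(open_iv))

  split_iv <- split(open_iv, open_iv$unit_id)
  all_units <- units$unit_id
  ledger_add(ledger, "score_units_without_complaints",
             length(all_units),
             sum(vapply(split_iv, function(g) any(g$complaint), TRUE)))

  est <- lapply(split_iv, function(g) {
    ci <- g$intensity[g$complaint]
    bi <- g$intensity[!g$complaint]
    if (length(ci) < 1L || length(bi) < min_baseline) return(NULL)
    A <- absolute_threshold(ci)
    B <- if (stratified_baseline) {
      slot <- format(g$interval_start, "%H")
      bmeans <- tapply(g$intensity[!g$complaint], slot[!g$complaint], mean)
      ref <- bmeans[slot[g$complaint]]
      if (anyNA(ref)) return(NULL)   # a complaint slot with no baseline history
      mean(ref)
    } else {
      mean(bi)
    }
    if (is.na(B) || B <= 0 || A <= 0) return(NULL)
    D <- (A - B) / B
    data.frame(unit_id = g$unit_id[1], A = A, D = D,
               SS = subjective_sensation(D, A, log_base),
               n_complaint_intervals = length(ci),
               n_baseline_intervals = length(bi),
               stringsAsFactors = FALSE)
  })
  scored <- do.call(rbind, est)
  ledger_add(ledger, "score_units_below_min_baseline_or_degenerate",
             length(split_iv), if (is.null(scored)) 0L else nrow(scored))
  if (is.null(scored) || nrow(scored) == 0L)
    stop("no scoreable units: every unit lacks complaints or baseline history")
  rownames(scored) <- NULL

  scored$SDS <- sds_scores(scored$SS)
  m <- match(scored$unit_id, units$unit_id)
  scored$zip <- units$zip[m]
  scored$poi_type <- if ("poi_type" %in% names(units)) units$poi_type[m] else NA_character_
  scored <- scored[, c("unit_id", "zip", "poi_type", "A", "D", "SS", "SDS",
                       "n_complaint_intervals", "n_baseline_intervals")]

  zip_scores <- aggregate_zip(scored, ledger = ledger)

  structure(list(
    estimates = scored,
    zip_scores = zip_scores,
    intervals = open_iv[open_iv$unit_id %in% scored$unit_id, , drop = FALSE],
    settings = list(min_baseline = min_baseline, log_base = log_base,
                    stratified_baseline = stratified_baseline),
    n_units_in = length(all_units),
    ledger = ledger,
    call = match.call()
  ), class = "sds_fit")
}

#' Aggregate unit SDS scores to zip-code neighborhoods
#'
#' The neighborhood score is the arithmetic mean of member unit SDS scores.
#' Zips contributing no scored unit are simply absent (and counted in the
#' ledger when one is supplied).
#'
#' @param estimates per-unit estimates with `unit_id`, `zip`, `SDS`.
#' @param ledger optional [new_ledger()].
#' @return data frame `zip`, `SDS_z`, `n_units`.
#' @export
aggregate_zip <- function(estimates, ledger = NULL) {
  stopifnot(all(c("zip", "SDS") %in% names(estimates)))
  sp <- split(estimates$SDS, estimates$zip)
  out <- data.frame(zip = names(sp),
                    SDS_z = vapply(sp, mean, 0),
                    n_units = vapply(sp, length, 0L),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(ledger))
    ledger_add(ledger, "zip_aggregation", nrow(estimates), nrow(estimates),
               detail = sprintf("%d zips scored", nrow(out)))
  out
}

#' Citywide complaint versus baseline intensity curves
#'
#' For each six-hour slot of the study period, the mean intensity over
#' complaint-flagged open intervals and over complaint-free open intervals.
#' Slots with no contributing intervals are `NA`, not zero.
#'
#' @param intervals flagged open-interval table (e.g. `fit$intervals`).
#' @return data frame `interval_start`, `baseline_mean`, `complaint_mean`.
#' @export
citywide_complaint_curves <- function(intervals) {
  iv <- intervals[intervals$open, , drop = FALSE]
  slots <- sort(unique(iv$interval_start))
  mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)
  key <- match(iv$interval_start, slots)
  base <- tapply(iv$intensity[!iv$complaint], key[!iv$complaint], mean)
  comp <- tapply(iv$intensity[iv$complaint], key[iv$complaint], mean)
  out <- data.frame(interval_start = slots,
                    baseline_mean = NA_real_, complaint_mean = NA_real_)
  out$baseline_mean[as.integer(names(base))] <- as.numeric(base)
  out$complaint_mean[as.integer(names(comp))] <- as.numeric(comp)
  out
}

#' Per-establishment-type summary of sensitivity estimates
#'
#' For each establishment type among scored units: the number of complaints
#' at units of that type, the share of scored units of that type, the modal
#' complaint hour, and mean and standard deviation of `A`, `D` and `SDS`.
#' Per-type means are of the globally normalised scores; no per-type
#' re-normalisation is done.
#'
#' @param object an [sds_fit()] object.
#' @param complaint_table complaint table (for counts and modal hours).
#' @param units unit table.
#' @return data frame, one row per type, sorted by mean SDS descending.
#' @export
type_summary <- function(object, complaint_table, units) {
  stopifnot(inherits(object, "sds_fit"))
  est <- object$estimates
  scored_units <- est$unit_id
  comp <- complaint_table[complaint_table$building_id %in% scored_units, , drop = FALSE]
  mh <- mode_complaint_hour(comp, units)

  sp <- split(est, est$poi_type)
  out <- do.call(rbind, lapply(names(sp), function(ty) {
    g <- sp[[ty]]
    n_c <- sum(comp$building_id %in% g$unit_id)
    data.frame(poi_type = ty,
               complaint_volume = n_c,
               unit_share_pct = nrow(g) / nrow(est) * 100,
               mode_hour = if (ty %in% mh$poi_type) mh$mode_hour[mh$poi_type == ty] else NA_integer_,
               A_mean = mean(g$A), A_sd = stats::sd(g$A),
               D_mean = mean(g$D), D_sd = stats::sd(g$D),
               SDS_mean = mean(g$SDS), SDS_sd = stats::sd(g$SDS),
               n_units = nrow(g),
               stringsAsFactors = FALSE)
  }))
  out[order(-out$SDS_mean), , drop = FALSE]
}

# ---- methods ---------------------------------------------------------------

#' @export
print.sds_fit <- function(x, ...) {
  cat("Social distancing sensitivity fit\n")
  cat(sprintf("  %d scored units (of %d) in %d zips\n",
              nrow(x$estimates), x$n_units_in, nrow(x$zip_scores)))
  cat(sprintf("  mean A = %.2f visits / 10,000 sq ft / 6 h; mean D = %.2f; mean SDS = %.2f\n",
              mean(x$estimates$A), mean(x$estimates$D), mean(x$estimates$SDS)))
  invisible(x)
}

#' Extract per-unit threshold estimates
#'
#' @param object an [sds_fit()] object.
#' @param ... unused.
#' @return numeric matrix with one row per scored unit and columns `A`, `D`,
#'   `SS`, `SDS`.
#' @export
coef.sds_fit <- function(object, ...) {
  m <- as.matrix(object$estimates[, c("A", "D", "SS", "SDS")])
  rownames(m) <- object$estimates$unit_id
  m
}

#' Summarise a sensitivity fit
#'
#' @param object an [sds_fit()] object.
#' @param ... unused.
#' @return list of class `summary.sds_fit` with citywide means and 95%
#'   confidence intervals for `A` and `D`, score quantiles, and the zip table.
#' @export
summary.sds_fit <- function(object, ...) {
  est <- object$estimates
  ci <- function(x) {
    se <- stats::sd(x) / sqrt(length(x))
    mean(x) + c(-1, 1) * stats::qt(0.975, length(x) - 1) * se
  }
  out <- list(
    n_units = nrow(est), n_zips = nrow(object$zip_scores),
    A_mean = mean(est$A), A_ci = ci(est$A),
    D_mean = mean(est$D), D_ci = ci(est$D),
    SDS_quantiles = stats::quantile(est$SDS, c(0, 0.25, 0.5, 0.75, 1)),
    zip_scores = object$zip_scores,
    settings = object$settings
  )
  class(out) <- "summary.sds_fit"
  out
}

#' @export
print.summary.sds_fit <- function(x, ...) {
  cat("Social distancing sensitivity fit:", x$n_units, "units,", x$n_zips, "zips\n")
  cat(sprintf("  absolute threshold A: mean %.2f [95%% CI %.2f-%.2f]\n",
              x$A_mean, x$A_ci[1], x$A_ci[2]))
  cat(sprintf("  difference threshold D: mean %.2f [95%% CI %.2f-%.2f]\n",
              x$D_mean, x$D_ci[1], x$D_ci[2]))
  cat("  SDS quantiles:\n")
  print(round(x$SDS_quantiles, 2))
  invisible(x)
}

#' Plot complaint versus baseline intensity curves
#'
#' Citywide mean visit intensity per six-hour slot, separately for
#' complaint-flagged and complaint-free open intervals.
#'
#' @param x an [sds_fit()] object.
#' @param ... passed to [graphics::plot()].
#' @return the curve data frame, invisibly.
#' @export
plot.sds_fit <- function(x, ...) {
  cv <- citywide_complaint_curves(x$intervals)
  ylim <- range(c(cv$baseline_mean, cv$complaint_mean), na.rm = TRUE)
  graphics::plot(cv$interval_start, cv$baseline_mean, type = "l", col = "steelblue",
                 ylim = ylim, xlab = "interval start",
                 ylab = "mean visits per 10,000 sq ft", ...)
  graphics::lines(cv$interval_start, cv$complaint_mean, col = "firebrick")
  graphics::legend("topleft", legend = c("baseline", "complaint reported"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(cv)
}
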