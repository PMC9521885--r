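#' Configuration for the synthetic city generator
#'
#' Builds and validates the parameter set for [generate_city()]. The synthetic
#' city plants a known per-neighborhood reporting threshold `theta` so that the
#' full scoring pipeline can be exercised and its recovered sensitivity scores
#' compared against ground truth.
#'
#' The generative model: each POI receives Poisson hourly visits with mean
#' `base_rate * diurnal_profile[hour]` while open, zero while closed. In each
#' six-hour interval a POI may experience a crowding burst (probability
#' `crowding_burst_prob`) that inflates its visits by a multiplier drawn
#' uniformly from `burst_multiplier_range`. A complaint is emitted with
#' probability `report_prob` whenever the interval's visit intensity exceeds
#' `(1 + theta_z)` times that POI's running baseline mean intensity, where
#' `theta_z` is the planted threshold of the POI's zip: the minimum fractional
#' excess over baseline that residents of that neighborhood will report. Small
#' `theta_z` means a sensitive neighborhood (small excursions get reported);
#' `Inf` is a sentinel for "never reports".
#'
#' @param n_zips number of zip-code neighborhoods (>= 2).
#' @param pois_per_zip POIs per zip (>= 1).
#' @param study_start,study_end study period bounds (midnight-aligned,
#'   `study_end` exclusive), as `POSIXct` or parseable `"YYYY-MM-DD"` /
#'   `"YYYY-MM-DD HH:MM:SS"` strings. Timestamps are local clock time; no
#'   timezone arithmetic is performed.
#' @param base_rate mean visits per open hour per POI before diurnal modulation.
#' @param diurnal_profile 24 non-negative multipliers, one per clock hour.
#' @param poi_types named list mapping establishment type to its inclusive
#'   open-hour range `c(first_hour, last_hour)`.
#' @param floor_area_meanlog,floor_area_sdlog log-normal parameters for POI
#'   floor area in square feet.
#' @param crowding_burst_prob per-interval probability of a crowding burst.
#' @param burst_multiplier_range length-2 numeric, both entries > 1.
#' @param planted_theta per-zip reporting thresholds theta_z (>= 0, `Inf`
#'   allowed); a single value is recycled, `NULL` gives an even spread from
#'   0.05 to 1.5 across zips.
#' @param report_prob probability that a threshold-exceeding interval yields a
#'   complaint.
#' @param police_action_prob per-zip probability that a complaint is marked
#'   with a police response; recycled like `planted_theta`; `NULL` gives an
#'   even spread from 0.15 to 0.75.
#' @param covariate_spec named list of per-covariate specs, each a list with
#'   `direction` (`"+"` or `"-"`: sign of association with theta_z) and
#'   `noise_sd` (noise scale on the standardised covariate). Custom covariate
#'   names must also supply `center` and `scale` for the output units.
#' @param warmup_days days at the start of the study during which no
#'   complaints are emitted (the running baseline needs history).
#' @param pois_per_building `NULL` for one POI per building, or an integer
#'   range such as `c(2, 3)` to pool several POIs per building (a stress test
#'   for the building-pooling path).
#' @param seed master integer seed; all child random streams derive from it.
#'
#' @return A validated list of class `city_config`.
#' @export
#' @examples
#' cfg <- city_config(n_zips = 2, pois_per_zip = 3, study_end = "2020-04-04")
#' cfg$planted_theta
city_config <- function(n_zips = 20L,
                        pois_per_zip = 30L,
                        study_start = "2020-03-28",
                        study_end = "2020-05-27",
                        base_rate = 1.0,
                        diurnal_profile = default_diurnal_profile(),
                        poi_types = default_poi_types(),
                        floor_area_meanlog = log(4000),
                        floor_area_sdlog = 0.4,
                        crowding_burst_prob = 0.05,
                        burst_multiplier_range = c(1.5, 6),
                        planted_theta = NULL,
                        report_prob = 0.5,
                        police_action_prob = NULL,
                        covariate_spec = default_covariate_spec(),
                        warmup_days = 2L,
                        pois_per_building = NULL,
                        seed = 1L) {
  n_zips <- as.integer(n_zips)
  pois_per_zip <- as.integer(pois_per_zip)
  if (is.na(n_zips) || n_zips < 2L) stop("n_zips must be >= 2")
  if (is.na(pois_per_zip) || pois_per_zip < 1L) stop("pois_per_zip must be >= 1")

  study_start <- .parse_ts(study_start)
  study_end <- .parse_ts(study_end)
  if (is.na(study_start) || is.na(study_end)) stop("unparseable study bounds")
  if (study_end <= study_start) stop("degenerate date range: study_end <= study_start")
  hrs <- as.numeric(difftime(study_end, study_start, units = "hours"))
  if (hrs %% 24 != 0 || format(study_start, "%H%M%S") != "000000")
    stop("study bounds must be midnight-aligned whole days")

  if (length(diurnal_profile) == 0L) stop("empty diurnal profile")
  if (length(diurnal_profile) != 24L || any(diurnal_profile < 0) ||
      all(diurnal_profile == 0))
    stop("diurnal_profile must be 24 non-negative multipliers, not all zero")

  for (p in c(crowding_burst_prob, report_prob)) {
    if (is.na(p) || p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (length(burst_multiplier_range) != 2L || any(burst_multiplier_range <= 1) ||
      diff(burst_multiplier_range) < 0)
    stop("burst_multiplier_range must be an increasing pair with both entries > 1")

  zips <- sprintf("Z%03d", seq_len(n_zips))
  if (is.null(planted_theta)) planted_theta <- seq(0.05, 1.5, length.out = n_zips)
  if (length(planted_theta) == 1L) planted_theta <- rep(planted_theta, n_zips)
  if (length(planted_theta) != n_zips) stop("planted_theta must have one value per zip")
  if (any(is.na(planted_theta)) || any(planted_theta < 0))
    stop("planted thresholds theta_z must be >= 0 (Inf allowed)")
  names(planted_theta) <- zips

  if (is.null(police_action_prob)) police_action_prob <- seq(0.15, 0.75, length.out = n_zips)
  if (length(police_action_prob) == 1L) police_action_prob <- rep(police_action_prob, n_zips)
  if (length(police_action_prob) != n_zips || any(police_action_prob < 0) ||
      any(police_action_prob > 1))
    stop("police_action_prob must be per-zip probabilities in [0, 1]")
  names(police_action_prob) <- zips

  if (is.null(names(poi_types)) || any(names(poi_types) == ""))
    stop("poi_types must be a named list")
  for (rng in poi_types) {
    if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 0 || rng[2] > 23)
      stop("each poi_types entry must be an inclusive hour range within 0..23")
  }

  .validate_covariate_spec(covariate_spec)

  if (!is.null(pois_per_building)) {
    pois_per_building <- as.integer(pois_per_building)
    if (length(pois_per_building) == 1L) pois_per_building <- rep(pois_per_building, 2L)
    if (any(pois_per_building < 1L) || pois_per_building[1] > pois_per_building[2])
      stop("pois_per_building must be a non-decreasing positive integer range")
  }

  cfg <- list(
    n_zips = n_zips, pois_per_zip = pois_per_zip, zips = zips,
    study_start = study_start, study_end = study_end,
    base_rate = base_rate, diurnal_profile = as.numeric(diurnal_profile),
    poi_types = poi_types,
    floor_area_meanlog = floor_area_meanlog, floor_area_sdlog = floor_area_sdlog,
    crowding_burst_prob = crowding_burst_prob,
    burst_multiplier_range = as.numeric(burst_multiplier_range),
    planted_theta = planted_theta, report_prob = report_prob,
    police_action_prob = police_action_prob,
    covariate_spec = covariate_spec,
    warmup_days = as.integer(warmup_days),
    pois_per_building = pois_per_building,
    seed = as.integer(seed)
  )
  class(cfg) <- "city_config"
  cfg
}

#' Default diurnal visit profile
#'
#' Hourly multipliers with a quiet night, a midday plateau and an early-evening
#' peak, roughly matching urban retail foot-traffic rhythms.
#'
#' @return Numeric vector of length 24.
#' @export
default_diurnal_profile <- function() {
  c(0.20, 0.10, 0.10, 0.10, 0.10, 0.20, 0.40, 0.70, 0.90, 1.10, 1.30, 1.50,
    1.60, 1.50, 1.40, 1.30, 1.40, 1.60, 1.80, 1.60, 1.20, 0.90, 0.60, 0.40)
}

#' Default establishment types and opening hours
#'
#' @return Named list of inclusive hour ranges.
#' @export
default_poi_types <- function() {
  list(
    food_and_drink = c(8L, 23L),
    grocery        = c(7L, 21L),
    store          = c(9L, 19L),
    gym            = c(6L, 21L),
    clinic         = c(8L, 17L)
  )
}

#' Default synthetic neighborhood covariate roster
#'
#' Five covariates mirroring the attributes typically joined to neighborhood
#' sensitivity scores: income, racial composition, political affiliation and
#' two health indicators. `direction` is the sign of the association with the
#' planted threshold `theta_z` (larger theta = more tolerant neighborhood), so
#' e.g. case rates rise with theta while vaccination falls.
#'
#' @return Named list of covariate specs for [city_config()].
#' @export
default_covariate_spec <- function() {
  list(
    median_income          = list(direction = "-", noise_sd = 0.5),
    nonhispanic_white_pct  = list(direction = "-", noise_sd = 0.5),
    republican_voters_pct  = list(direction = "+", noise_sd = 0.5),
    covid_case_rate        = list(direction = "+", noise_sd = 0.5),
    vaccination_rate       = list(direction = "-", noise_sd = 0.5)
  )
}

# output units (center, scale) for the covariates shipped by default
.covariate_units <- list(
  median_income         = c(75000, 15000),
  nonhispanic_white_pct = c(0.45, 0.15),
  republican_voters_pct = c(0.45, 0.15),
  covid_case_rate       = c(2300, 350),
  vaccination_rate      = c(0.65, 0.08)
)

.validate_covariate_spec <- function(spec) {
  if (length(spec) == 0L) return(invisible(TRUE))
  if (is.null(names(spec)) || any(names(spec) == ""))
    stop("covariate_spec must be a named list")
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (!is.list(s) || is.null(s$direction) || !(s$direction %in% c("+", "-")))
      stop("covariate '", nm, "': direction must be \"+\" or \"-\"")
    if (is.null(s$noise_sd) || s$noise_sd < 0)
      stop("covariate '", nm, "': noise_sd must be >= 0")
    if (!nm %in% names(.covariate_units) &&
        (is.null(s$center) || is.null(s$scale)))
      stop("unknown covariate name '", nm,
           "': supply center and scale for custom covariates")
  }
  invisible(TRUE)
}

# Local clock time, no timezone arithmetic: everything is parsed and held in UTC
# so that arithmetic on timestamps never crosses a DST boundary.
.parse_ts <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(format(x, "%Y-%m-%d %H:%M:%S"), tz = "UTC"))
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%S", "%Y-%m-%dT%H:%M:%S", "%Y-%m-%d"))
  out
}

#' @export
print.city_config <- function(x, ...) {
  days <- as.numeric(difftime(x$study_end, x$study_start, units = "days"))
  cat("Synthetic city configuration\n")
  cat(sprintf("  %d zips x %d POIs, %g days (%s to %s)\n", x$n_zips, x$pois_per_zip,
              days, format(x$study_start, "%Y-%m-%d"), format(x$study_end, "%Y-%m-%d")))
  cat(sprintf("  planted theta range: [%g, %g]; report_prob %g; burst prob %g x [%g, %g]\n",
              min(x$planted_theta), max(x$planted_theta), x$report_prob,
              x$crowding_burst_prob, x$burst_multiplier_range[1], x$burst_multiplier_range[2]))
  cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
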