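# Child seeds: one master seed, deterministic derived streams per component,
# so regenerating with a different theta reuses identical visit/burst/report
# randomness (monotone-design property) and identical configs reproduce
# byte-identical tables.
.child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647) * 1009 + k) %% 2147483647L
}

#' Generate a synthetic city
#'
#' Simulates POIs, hourly visit streams, complaint events and neighborhood
#' covariates under the generative model described in [city_config()], and
#' returns the latent ground truth (planted thresholds, burst /
#' threshold-exceeded / complaint flags per interval) so that downstream
#' estimates can be validated against what was planted.
#'
#' Complaint logic: for each POI, the running baseline at interval `t` is the
#' mean intensity of its earlier open, non-burst intervals. An open interval
#' after the warm-up period exceeds threshold when its intensity is greater
#' than `(1 + theta_z)` times the running baseline; each exceeding interval
#' emits a complaint with probability `report_prob`, timestamped uniformly
#' within the interval. Every random draw (visits, bursts, multipliers,
#' reporting, timestamps, police flags) comes from a stream independent of
#' `theta`, so lowering `theta_z` for a zip can only add complaints.
#'
#' @param config a [city_config()].
#' @return An object of class `sds_city`: a list with elements
#'   \describe{
#'     \item{poi}{POI table: `poi_id`, `building_id`, `zip`, `poi_type`,
#'       `floor_area`.}
#'     \item{visits}{long hourly table: `poi_id`, `timestamp`, `visits`,
#'       `open`.}
#'     \item{complaints}{`complaint_id`, `timestamp`, `building_id`, `zip`,
#'       `descriptor`, `police_action`, `resolution`.}
#'     \item{covariates}{per-zip covariate table from [generate_covariates()].}
#'     \item{ground_truth}{list: `theta` (per zip), `intervals` (per POI x
#'       interval latent flags), and the config used.}
#'   }
#' @export
#' @examples
#' cfg <- city_config(n_zips = 2, pois_per_zip = 3, study_end = "2020-04-08",
#'                    seed = 42)
#' city <- generate_city(cfg)
#' nrow(city$visits)  # 6 POIs x 11 days x 24 h
generate_city <- function(config) {
  stopifnot(inherits(config, "city_config"))
  cfg <- config

  n_poi <- cfg$n_zips * cfg$pois_per_zip
  n_hours <- as.integer(as.numeric(difftime(cfg$study_end, cfg$study_start, units = "hours")))
  n_int <- n_hours %/% 6L
  hod <- rep(0:23, length.out = n_hours)            # hour of day per hour slot
  int_of_hour <- rep(seq_len(n_int), each = 6L)     # interval index per hour slot
  hour_ts <- cfg$study_start + (seq_len(n_hours) - 1L) * 3600
  int_start_ts <- cfg$study_start + (seq_len(n_int) - 1L) * 21600

  # --- POI attributes -------------------------------------------------------
  set.seed(.child_seed(cfg$seed, 1L))
  poi_id <- sprintf("P%05d", seq_len(n_poi))
  zip <- rep(cfg$zips, each = cfg$pois_per_zip)
  type_names <- names(cfg$poi_types)
  poi_type <- sample(type_names, n_poi, replace = TRUE)
  floor_area <- round(stats::rlnorm(n_poi, cfg$floor_area_meanlog, cfg$floor_area_sdlog))
  floor_area <- pmax(floor_area, 100)

  building_id <- if (is.null(cfg$pois_per_building)) {
    sprintf("B%05d", seq_len(n_poi))
  } else {
    .assign_buildings(n_poi, zip, cfg$pois_per_building)
  }

  poi_table <- data.frame(poi_id = poi_id, building_id = building_id, zip = zip,
                          poi_type = poi_type, floor_area = as.numeric(floor_area),
                          stringsAsFactors = FALSE)

  # --- open/closed and hourly visits ---------------------------------------
  open_rng <- do.call(rbind, cfg$poi_types)[poi_type, , drop = FALSE]
  # n_poi x n_hours logical: open when hour of day within the type's range
  open_h <- outer(open_rng[, 1], hod, "<=") & outer(open_rng[, 2], hod, ">=")

  lambda <- matrix(rep(cfg$base_rate * cfg$diurnal_profile[hod + 1L], each = n_poi),
                   nrow = n_poi)
  lambda[!open_h] <- 0
  set.seed(.child_seed(cfg$seed, 2L))
  visits_h <- matrix(stats::rpois(n_poi * n_hours, lambda), nrow = n_poi)

  # --- bursts ---------------------------------------------------------------
  open_i <- t(rowsum(t(open_h) + 0, int_of_hour) > 0)       # n_poi x n_int
  set.seed(.child_seed(cfg$seed, 3L))
  burst <- matrix(stats::runif(n_poi * n_int) < cfg$crowding_burst_prob,
                  nrow = n_poi) & open_i
  set.seed(.child_seed(cfg$seed, 4L))
  mult <- matrix(stats::runif(n_poi * n_int, cfg$burst_multiplier_range[1],
                              cfg$burst_multiplier_range[2]), nrow = n_poi)
  burst_h <- burst[, int_of_hour, drop = FALSE]
  mult_h <- mult[, int_of_hour, drop = FALSE]
  visits_h[burst_h] <- round(visits_h[burst_h] * mult_h[burst_h])

  # --- interval intensities and running baselines --------------------------
  visits_i <- t(rowsum(t(visits_h), int_of_hour))            # n_poi x n_int
  intensity <- visits_i / floor_area * 1e4

  elig <- open_i & !burst                                    # baseline-eligible
  cs <- t(apply(intensity * elig, 1, cumsum))
  cn <- t(apply(elig, 1, cumsum))
  # running mean over *prior* eligible intervals
  prev_mean <- cbind(NA_real_, cs[, -n_int, drop = FALSE] /
                                 ifelse(cn[, -n_int, drop = FALSE] > 0,
                                        cn[, -n_int, drop = FALSE], NA_real_))

  theta_poi <- cfg$planted_theta[zip]
  warmup_int <- cfg$warmup_days * 4L
  after_warmup <- matrix(rep(seq_len(n_int) > warmup_int, each = n_poi), nrow = n_poi)
  exceeded <- intensity > (1 + theta_poi) * prev_mean        # NA where undefined
  exceeded[is.na(exceeded)] <- FALSE
  exceeded <- exceeded & open_i & after_warmup

  set.seed(.child_seed(cfg$seed, 5L))
  u_report <- matrix(stats::runif(n_poi * n_int), nrow = n_poi)
  complaint <- exceeded & u_report < cfg$report_prob

  set.seed(.child_seed(cfg$seed, 6L))
  u_time <- matrix(stats::runif(n_poi * n_int), nrow = n_poi)
  set.seed(.child_seed(cfg$seed, 7L))
  u_police <- matrix(stats::runif(n_poi * n_int), nrow = n_poi)

  # --- assemble tables ------------------------------------------------------
  visit_table <- data.frame(
    poi_id = rep(poi_id, times = n_hours),
    timestamp = rep(hour_ts, each = n_poi),
    visits = as.integer(visits_h),
    open = as.logical(open_h),
    stringsAsFactors = FALSE
  )

  idx <- which(complaint, arr.ind = TRUE)
  idx <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE]
  if (nrow(idx) > 0) {
    c_ts <- int_start_ts[idx[, 2]] + floor(u_time[idx] * 21600)
    c_police <- u_police[idx] < cfg$police_action_prob[zip[idx[, 1]]]
    complaint_table <- data.frame(
      complaint_id = sprintf("C%06d", seq_len(nrow(idx))),
      timestamp = c_ts,
      building_id = building_id[idx[, 1]],
      zip = zip[idx[, 1]],
      descriptor = "social distancing",
      police_action = as.logical(c_police),
      resolution = ifelse(c_police, "police action taken", "no action necessary"),
      stringsAsFactors = FALSE
    )
  } else {
    complaint_table <- data.frame(
      complaint_id = character(),
      timestamp = as.POSIXct(character(), tz = "UTC"),
      building_id = character(), zip = character(), descriptor = character(),
      police_action = logical(), resolution = character(),
      stringsAsFactors = FALSE
    )
  }

  gt_intervals <- data.frame(
    poi_id = rep(poi_id, times = n_int),
    interval_start = rep(int_start_ts, each = n_poi),
    open = as.logical(open_i),
    burst = as.logical(burst),
    exceeded = as.logical(exceeded),
    complaint = as.logical(complaint),
    stringsAsFactors = FALSE
  )
  ground_truth <- list(
    theta = data.frame(zip = cfg$zips, theta = as.numeric(cfg$planted_theta),
                       stringsAsFactors = FALSE),
    intervals = gt_intervals,
    config = cfg
  )

  covariates <- generate_covariates(cfg, ground_truth)

  structure(list(poi = poi_table, visits = visit_table,
                 complaints = complaint_table, covariates = covariates,
                 ground_truth = ground_truth, config = cfg),
            class = "sds_city")
}

# group consecutive POIs within a zip into buildings of size lo..hi
.assign_buildings <- function(n_poi, zip, rng) {
  sizes <- sample(seq(rng[1], rng[2]), n_poi, replace = TRUE)
  building <- character(n_poi)
  b <- 0L
  for (z in unique(zip)) {
    members <- which(zip == z)
    i <- 1L
    while (i <= length(members)) {
      b <- b + 1L
      k <- min(sizes[members[i]], length(members) - i + 1L)
      building[members[i:(i + k - 1L)]] <- sprintf("B%05d", b)
      i <- i + k
    }
  }
  building
}

#' Generate neighborhood covariates tied to the planted thresholds
#'
#' Each covariate is a monotone transform of the planted per-zip threshold
#' `theta_z` (sign given by the covariate's `direction`), plus Gaussian noise
#' of the configured scale, mapped affinely to plausible output units. With
#' `noise_sd = 0` the covariate is an exactly monotone function of `theta_z`.
#' The monotone transform is the standardised rank of `theta_z`, which keeps
#' the construction well defined when some thresholds are infinite.
#'
#' @param config a [city_config()].
#' @param ground_truth the `ground_truth` element of a generated city (only
#'   the `theta` table is used).
#' @return data frame with one row per zip: `zip`, then one column per
#'   configured covariate.
#' @export
generate_covariates <- function(config, ground_truth) {
  stopifnot(inherits(config, "city_config"))
  .validate_covariate_spec(config$covariate_spec)
  theta <- ground_truth$theta
  n <- nrow(theta)
  r <- rank(theta$theta, ties.method = "average")
  z <- if (stats::sd(r) > 0) (r - mean(r)) / stats::sd(r) else rep(0, n)

  set.seed(.child_seed(config$seed, 8L))
  out <- data.frame(zip = theta$zip, stringsAsFactors = FALSE)
  for (nm in names(config$covariate_spec)) {
    s <- config$covariate_spec[[nm]]
    sign <- if (s$direction == "+") 1 else -1
    units <- if (nm %in% names(.covariate_units)) .covariate_units[[nm]] else c(s$center, s$scale)
    val <- sign * z + stats::rnorm(n, 0, s$noise_sd)
    out[[nm]] <- units[1] + units[2] * val
  }
  out
}

#' @export
print.sds_city <- function(x, ...) {
  cat("Synthetic city:", nrow(x$poi), "POIs in", x$config$n_zips, "zips;",
      nrow(x$visits), "hourly visit rows;", nrow(x$complaints), "complaints\n")
  invisible(x)
}
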