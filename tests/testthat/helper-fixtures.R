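# Small in-code fixture builders shared across the suite.

ts0 <- as.POSIXct("2020-03-28 00:00:00", tz = "UTC")

make_units <- function(ids, zip = "Z001", poi_type = "store", floor_area = 10000) {
  data.frame(unit_id = ids, zip = zip, poi_type = poi_type,
             floor_area = floor_area,
             n_pois_pooled = 1L, stringsAsFactors = FALSE)
}

# one row per element of `intensity`; interval_start advances in 6 h steps
make_intervals <- function(unit_id, intensity, complaint,
                           open = TRUE, start = ts0) {
  n <- length(intensity)
  data.frame(unit_id = unit_id,
             interval_start = start + (seq_len(n) - 1L) * 21600,
             visits = intensity,  # areas of 10,000 sq ft make these equal
             open = rep_len(open, n),
             intensity = intensity,
             complaint = rep_len(complaint, n),
             stringsAsFactors = FALSE)
}

# a two-unit city reproducing the textbook worked example: both units share a
# baseline mean density of 4; unit B's complaint interval has density 20,
# unit C's has density 6
fig1_city <- function() {
  iv <- rbind(
    make_intervals("caseB", c(rep(4, 8), 20), c(rep(FALSE, 8), TRUE)),
    make_intervals("caseC", c(rep(4, 8), 6), c(rep(FALSE, 8), TRUE))
  )
  units <- make_units(c("caseB", "caseC"))
  list(intervals = iv, units = units)
}

# memoised default-scale synthetic city (the shipped default config):
# 20 zips x 30 POIs x 60 days, seed 1
.city_cache <- new.env(parent = emptyenv())
default_city <- function(seed = 1L) {
  key <- paste0("city", seed)
  if (is.null(.city_cache[[key]])) {
    cfg <- city_config(seed = seed)
    city <- generate_city(cfg)
    pooled <- pool_to_buildings(city$poi, city$visits)
    iv <- flag_complaints(bin_six_hour(pooled$visits, pooled$units),
                          city$complaints)
    fit <- sds_fit(iv, pooled$units)
    .city_cache[[key]] <- list(city = city, units = pooled$units,
                               intervals = iv, fit = fit)
  }
  .city_cache[[key]]
}

# small quick city for structural tests
small_city <- function(seed = 5L, ...) {
  cfg <- city_config(n_zips = 3, pois_per_zip = 4, study_end = "2020-04-11",
                     seed = seed, ...)
  generate_city(cfg)
}
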