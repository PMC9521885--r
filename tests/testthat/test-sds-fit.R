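test_that("activity intensity is visits per 10,000 sq ft", {
  expect_equal(activity_intensity(0, 3000), 0)
  expect_equal(activity_intensity(20, 10000), 20)
  expect_equal(activity_intensity(6, 10000), 6)
  expect_equal(activity_intensity(4, 5000), 8)
  expect_error(activity_intensity(1, 0), "floor_area")
  expect_error(activity_intensity(1, -5), "floor_area")
})

test_that("absolute threshold is the mean complaint-interval intensity", {
  expect_equal(absolute_threshold(20), 20)
  expect_equal(absolute_threshold(rep(7.3, 3)), 7.3)
  set.seed(1)
  x <- runif(50, 0, 30)
  expect_equal(absolute_threshold(x), sum(x) / length(x))
  expect_error(absolute_threshold(numeric(0)), "no complaint intervals")
})

test_that("difference threshold reproduces the 400% / 50% worked example", {
  expect_equal(difference_threshold(20, rep(4, 5)), 4.0)
  expect_equal(difference_threshold(6, rep(4, 5)), 0.5)
  expect_equal(difference_threshold(5, rep(5, 8)), 0)
  expect_lt(difference_threshold(3, rep(4, 5)), 0)  # kept, not floored
  expect_error(difference_threshold(5, numeric(0)), "no baseline")
  expect_error(difference_threshold(5, rep(0, 5)), "> 0")
})

test_that("subjective sensation follows Fechner's law", {
  expect_equal(subjective_sensation(0, 17), 0)
  expect_equal(subjective_sensation(2.5, 1), 0)
  expect_equal(subjective_sensation(4, 20), 4 * log10(20))
  expect_equal(subjective_sensation(4, 20), 5.20411998265592, tolerance = 1e-12)
  expect_equal(subjective_sensation(2, 8, log_base = 2), 6)
  expect_error(subjective_sensation(1, 0), "A must be > 0")
})

test_that("SDS scores are an inverse min-max rescale with exact endpoints", {
  expect_equal(sds_scores(c(0, 1, 2)), c(100, 50, 0))
  set.seed(3)
  ss <- rnorm(40)
  s <- sds_scores(ss)
  expect_true(all(s >= 0 & s <= 100))
  expect_equal(s[which.max(ss)], 0)
  expect_equal(s[which.min(ss)], 100)
  # tied extremes all get the extreme score
  s <- sds_scores(c(1, 1, 2, 3, 3))
  expect_equal(s, c(100, 100, 50, 0, 0))
  expect_error(sds_scores(c(2, 2, 2)), "all sensation values equal")
  expect_error(sds_scores(5), "at least two")
})

test_that("the two-unit worked-example city ranks Case C as more sensitive", {
  fx <- fig1_city()
  fit <- sds_fit(fx$intervals, fx$units)
  est <- fit$estimates
  expect_equal(est$A[est$unit_id == "caseB"], 20)
  expect_equal(est$A[est$unit_id == "caseC"], 6)
  expect_equal(est$D[est$unit_id == "caseB"], 4.0)
  expect_equal(est$D[est$unit_id == "caseC"], 0.5)
  expect_equal(est$SDS[est$unit_id == "caseC"], 100)
  expect_equal(est$SDS[est$unit_id == "caseB"], 0)
})

test_that("closed intervals never enter threshold or baseline statistics", {
  iv <- rbind(
    make_intervals("U1", c(4, 4, 4, 4, 999, 20), c(rep(FALSE, 5), TRUE),
                   open = c(rep(TRUE, 4), FALSE, TRUE)),
    make_intervals("U2", c(rep(4, 5), 8), c(rep(FALSE, 5), TRUE))
  )
  fit <- sds_fit(iv, make_units(c("U1", "U2")))
  expect_equal(fit$estimates$A[fit$estimates$unit_id == "U1"], 20)
  expect_equal(fit$estimates$D[fit$estimates$unit_id == "U1"], 4)
})

test_that("units without complaints or baseline history are excluded via the ledger", {
  iv <- rbind(
    make_intervals("scored1", c(rep(4, 6), 20), c(rep(FALSE, 6), TRUE)),
    make_intervals("scored2", c(rep(4, 6), 8), c(rep(FALSE, 6), TRUE)),
    make_intervals("nocomplaint", rep(5, 7), FALSE),
    make_intervals("thin", c(4, 4, 12), c(FALSE, FALSE, TRUE))  # < min_baseline
  )
  led <- new_ledger()
  fit <- sds_fit(iv, make_units(unique(iv$unit_id)), ledger = led)
  expect_setequal(fit$estimates$unit_id, c("scored1", "scored2"))
  df <- as.data.frame(led)
  expect_true("score_units_below_min_baseline_or_degenerate" %in% df$rule)
  expect_true(all(df$rows_in - df$rows_dropped == df$rows_out))
  # nothing scoreable at all is a hard error
  expect_error(sds_fit(make_intervals("only", rep(4, 8), FALSE),
                       make_units("only")),
               "no scoreable units")
})

test_that("fit matches the straight-loop oracle to 1e-12 on random small fixtures", {
  for (seed in 1:3) {
    set.seed(seed)
    n_units <- sample(5:20, 1)
    units <- make_units(sprintf("U%02d", 1:n_units),
                        zip = sample(c("Z1", "Z2", "Z3"), n_units, replace = TRUE),
                        floor_area = sample(c(2000, 5000, 10000), n_units, TRUE))
    iv <- do.call(rbind, lapply(seq_len(n_units), function(i) {
      n <- sample(10:30, 1)
      visits <- rpois(n, 8) + 1
      complaint <- runif(n) < 0.2
      if (!any(complaint)) complaint[n] <- TRUE
      data.frame(unit_id = units$unit_id[i],
                 interval_start = ts0 + (seq_len(n) - 1) * 21600,
                 visits = visits, open = TRUE,
                 intensity = visits / units$floor_area[i] * 1e4,
                 complaint = complaint, stringsAsFactors = FALSE)
    }))
    fit <- sds_fit(iv, units)
    orc <- oracle_scores(iv, units)
    m <- match(orc$unit_id, fit$estimates$unit_id)
    expect_equal(fit$estimates$A[m], orc$A, tolerance = 1e-12)
    expect_equal(fit$estimates$D[m], orc$D, tolerance = 1e-12)
    expect_equal(fit$estimates$SS[m], orc$SS, tolerance = 1e-12)
    expect_equal(fit$estimates$SDS[m], orc$SDS, tolerance = 1e-12)
    zo <- oracle_zip_means(orc)
    zm <- match(zo$zip, fit$zip_scores$zip)
    expect_equal(fit$zip_scores$SDS_z[zm], zo$SDS_z, tolerance = 1e-12)
    expect_equal(fit$zip_scores$n_units[zm], zo$n_units)
  }
})

test_that("SDS is invariant to the log base but not to the intensity unit", {
  fx <- small_city(seed = 8)
  pooled <- pool_to_buildings(fx$poi, fx$visits)
  iv <- flag_complaints(bin_six_hour(pooled$visits, pooled$units), fx$complaints)
  f10 <- sds_fit(iv, pooled$units, min_baseline = 2, log_base = 10)
  fe <- sds_fit(iv, pooled$units, min_baseline = 2, log_base = exp(1))
  expect_equal(f10$estimates$SDS, fe$estimates$SDS, tolerance = 1e-9)
  # SS itself scales by ln(10)
  expect_equal(fe$estimates$SS, f10$estimates$SS * log(10), tolerance = 1e-9)

  # intensity unit is NOT neutral: rescaling to per-sq-ft changes scores
  # whenever D varies across units
  iv2 <- iv; iv2$intensity <- iv$intensity / 1e4
  f_rescaled <- sds_fit(iv2, pooled$units, min_baseline = 2)
  expect_gt(max(abs(f_rescaled$estimates$SDS - f10$estimates$SDS)), 1e-6)
})

test_that("score ordering follows the thresholds", {
  # equal D, larger A => larger SS => lower SDS
  iv <- rbind(
    make_intervals("bigA", c(rep(10, 5), 20), c(rep(FALSE, 5), TRUE)),
    make_intervals("smallA", c(rep(2, 5), 4), c(rep(FALSE, 5), TRUE)),
    make_intervals("ref", c(rep(3, 5), 4.5), c(rep(FALSE, 5), TRUE))
  )
  fit <- sds_fit(iv, make_units(unique(iv$unit_id)))
  est <- fit$estimates
  expect_equal(est$D[est$unit_id == "bigA"], est$D[est$unit_id == "smallA"])
  expect_lt(est$SDS[est$unit_id == "bigA"], est$SDS[est$unit_id == "smallA"])

  # equal A > 1, larger D => lower SDS
  iv <- rbind(
    make_intervals("bigD", c(rep(2, 5), 10), c(rep(FALSE, 5), TRUE)),
    make_intervals("smallD", c(rep(8, 5), 10), c(rep(FALSE, 5), TRUE)),
    make_intervals("ref", c(rep(5, 5), 10), c(rep(FALSE, 5), TRUE))
  )
  fit <- sds_fit(iv, make_units(unique(iv$unit_id)))
  est <- fit$estimates
  expect_equal(est$A[est$unit_id == "bigD"], est$A[est$unit_id == "smallD"])
  expect_lt(est$SDS[est$unit_id == "bigD"], est$SDS[est$unit_id == "smallD"])
})

test_that("stratified baselines reference the complaint interval's own slot", {
  # unit with a strong diurnal split: slot 00 baseline 2, slot 12 baseline 10
  n_days <- 6
  iv <- do.call(rbind, lapply(seq_len(n_days), function(d) {
    start <- ts0 + (d - 1) * 86400
    data.frame(unit_id = "U1",
               interval_start = start + c(0, 12) * 3600,
               visits = c(2, 10), open = TRUE, intensity = c(2, 10),
               complaint = FALSE, stringsAsFactors = FALSE)
  }))
  iv$complaint[nrow(iv)] <- TRUE   # complaint in a 12:00 slot, intensity 10
  iv2 <- rbind(iv, make_intervals("U2", c(rep(4, 6), 8), c(rep(FALSE, 6), TRUE)))
  units <- make_units(c("U1", "U2"))

  whole <- sds_fit(iv2, units)
  strat <- sds_fit(iv2, units, stratified_baseline = TRUE)
  # whole-study baseline mixes slots: mean of (5x2 + 6x10)/11
  expect_equal(whole$estimates$D[whole$estimates$unit_id == "U1"],
               (10 - mean(c(rep(2, 6), rep(10, 5)))) / mean(c(rep(2, 6), rep(10, 5))))
  # slot-matched baseline: the five remaining 12:00 intervals, mean 10 => D = 0
  expect_equal(strat$estimates$D[strat$estimates$unit_id == "U1"], 0)
})

test_that("zip aggregation is the member mean", {
  est <- data.frame(unit_id = c("a", "b", "c"), zip = c("Z1", "Z2", "Z2"),
                    SDS = c(70, 40, 60), stringsAsFactors = FALSE)
  zs <- aggregate_zip(est)
  expect_equal(zs$SDS_z[zs$zip == "Z1"], 70)
  expect_equal(zs$SDS_z[zs$zip == "Z2"], 50)
  expect_equal(zs$n_units, c(1L, 2L))
})

test_that("citywide curves stratify complaint and baseline means per slot", {
  # construction: complaint intervals have exactly twice the baseline intensity
  n <- 12
  iv <- rbind(
    make_intervals("U1", rep(c(3, 6), n / 2), rep(c(FALSE, TRUE), n / 2)),
    make_intervals("U2", rep(c(5, 10), n / 2), rep(c(FALSE, TRUE), n / 2))
  )
  cv <- citywide_complaint_curves(iv)
  pop <- !is.na(cv$baseline_mean) & !is.na(cv$complaint_mean)
  expect_false(any(pop))  # alternating: each slot is all-baseline or all-complaint
  expect_equal(cv$complaint_mean[!is.na(cv$complaint_mean)],
               2 * cv$baseline_mean[!is.na(cv$baseline_mean)])

  # no complaints anywhere => complaint curve entirely missing
  iv0 <- make_intervals("U1", rep(4, 6), FALSE)
  cv0 <- citywide_complaint_curves(iv0)
  expect_true(all(is.na(cv0$complaint_mean)))
  expect_false(any(is.na(cv0$baseline_mean)))

  # random fixture equals brute-force stratified means
  set.seed(9)
  ivr <- do.call(rbind, lapply(c("A", "B", "C"), function(u)
    make_intervals(u, runif(20, 1, 10), runif(20) < 0.3)))
  cvr <- citywide_complaint_curves(ivr)
  for (i in seq_len(nrow(cvr))) {
    rows <- ivr[ivr$interval_start == cvr$interval_start[i], ]
    bm <- mean(rows$intensity[!rows$complaint])
    cm <- mean(rows$intensity[rows$complaint])
    expect_equal(cvr$baseline_mean[i], if (is.nan(bm)) NA_real_ else bm)
    expect_equal(cvr$complaint_mean[i], if (is.nan(cm)) NA_real_ else cm)
  }
})

test_that("type summary matches hand computation on a 4-unit fixture", {
  iv <- rbind(
    make_intervals("U1", c(rep(4, 5), 20), c(rep(FALSE, 5), TRUE)),
    make_intervals("U2", c(rep(4, 5), 6), c(rep(FALSE, 5), TRUE)),
    make_intervals("U3", c(rep(2, 5), 8), c(rep(FALSE, 5), TRUE)),
    make_intervals("U4", c(rep(5, 5), 10), c(rep(FALSE, 5), TRUE))
  )
  units <- make_units(c("U1", "U2", "U3", "U4"),
                      poi_type = c("cafe", "cafe", "store", "store"))
  fit <- sds_fit(iv, units)
  comp <- data.frame(
    complaint_id = c("C1", "C2", "C3"),
    timestamp = ts0 + 5 * 21600 + c(0, 60, 120),
    building_id = c("U1", "U2", "U2"), stringsAsFactors = FALSE)
  ts <- type_summary(fit, comp, units)

  cafe <- ts[ts$poi_type == "cafe", ]
  expect_equal(cafe$complaint_volume, 3L)
  expect_equal(cafe$unit_share_pct, 50)
  est <- fit$estimates
  expect_equal(cafe$A_mean, mean(est$A[est$poi_type == "cafe"]))
  expect_equal(cafe$D_mean, mean(c(4, 0.5)))
  expect_equal(cafe$SDS_mean, mean(est$SDS[est$poi_type == "cafe"]))
  expect_equal(cafe$SDS_sd, sd(est$SDS[est$poi_type == "cafe"]))
  expect_equal(cafe$mode_hour, 6L)  # 5th interval starts at 06:00 on day 2

  # single-type city: share is 100%
  fit2 <- sds_fit(iv[iv$unit_id %in% c("U1", "U2"), ], units[1:2, ])
  ts2 <- type_summary(fit2, comp, units)
  expect_equal(ts2$unit_share_pct, 100)
})

test_that("fit methods expose estimates coherently", {
  fx <- fig1_city()
  fit <- sds_fit(fx$intervals, fx$units)
  cf <- coef(fit)
  expect_identical(rownames(cf), fit$estimates$unit_id)
  expect_identical(colnames(cf), c("A", "D", "SS", "SDS"))
  sm <- summary(fit)
  expect_equal(sm$A_mean, mean(fit$estimates$A))
  expect_output(print(fit), "scored units")
  expect_output(print(sm), "absolute threshold")
})
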