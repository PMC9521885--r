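#' Load the POI, visit and complaint tables
#'
#' Reads the three core CSV inputs, checks required columns, coerces types,
#' and routes malformed rows (unparseable timestamps, negative visit counts,
#' non-positive floor areas, missing building ids) to the filter ledger
#' instead of dropping them silently.
#'
#' Expected columns: POI table `poi_id`, `building_id`, `zip`, `poi_type`,
#' `floor_area`; visit table `poi_id`, `timestamp`, `visits`, `open`;
#' complaint table `complaint_id`, `timestamp`, `building_id` (any further
#' columns, e.g. `police_action` or `resolution`, are carried through).
#'
#' @param poi,visits,complaints paths to CSV files.
#' @param ledger a [new_ledger()]; created if `NULL`.
#' @return list with `poi`, `visits`, `complaints` data frames and the
#'   `ledger`.
#' @export
load_tables <- function(poi, visits, complaints, ledger = NULL) {
  if (is.null(ledger)) ledger <- new_ledger()
  for (p in c(poi, visits, complaints)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }

  poi_tab <- utils::read.csv(poi, stringsAsFactors = FALSE)
  .require_cols(poi_tab, c("poi_id", "building_id", "zip", "poi_type", "floor_area"), "poi")
  n0 <- nrow(poi_tab)
  poi_tab$floor_area <- suppressWarnings(as.numeric(poi_tab$floor_area))
  bad <- is.na(poi_tab$floor_area) | poi_tab$floor_area <= 0
  ledger_add(ledger, "poi_invalid_floor_area", n0, n0 - sum(bad))
  poi_tab <- poi_tab[!bad, , drop = FALSE]
  n0 <- nrow(poi_tab)
  bad <- is.na(poi_tab$building_id) | poi_tab$building_id == ""
  ledger_add(ledger, "poi_missing_building_id", n0, n0 - sum(bad))
  poi_tab <- poi_tab[!bad, , drop = FALSE]

  vis_tab <- utils::read.csv(visits, stringsAsFactors = FALSE)
  .require_cols(vis_tab, c("poi_id", "timestamp", "visits", "open"), "visits")
  n0 <- nrow(vis_tab)
  ts <- .parse_ts_vec(vis_tab$timestamp)
  bad <- is.na(ts)
  ledger_add(ledger, "visits_unparseable_timestamp", n0, n0 - sum(bad))
  vis_tab <- vis_tab[!bad, , drop = FALSE]
  ts <- ts[!bad]
  n0 <- nrow(vis_tab)
  vis_tab$visits <- suppressWarnings(as.numeric(vis_tab$visits))
  bad <- is.na(vis_tab$visits) | vis_tab$visits < 0
  ledger_add(ledger, "visits_negative_or_missing_count", n0, n0 - sum(bad))
  vis_tab <- vis_tab[!bad, , drop = FALSE]
  vis_tab$timestamp <- ts[!bad]
  vis_tab$open <- .as_flag(vis_tab$open)

  comp_tab <- utils::read.csv(complaints, stringsAsFactors = FALSE,
                              colClasses = c(timestamp = "character"))
  .require_cols(comp_tab, c("complaint_id", "timestamp", "building_id"), "complaints")
  n0 <- nrow(comp_tab)
  if (n0 > 0) {
    ts <- .parse_ts_vec(comp_tab$timestamp)
    bad <- is.na(ts)
    ledger_add(ledger, "complaints_unparseable_timestamp", n0, n0 - sum(bad))
    comp_tab <- comp_tab[!bad, , drop = FALSE]
    comp_tab$timestamp <- ts[!bad]
  } else {
    comp_tab$timestamp <- as.POSIXct(character(), tz = "UTC")
    ledger_add(ledger, "complaints_unparseable_timestamp", 0L, 0L)
  }
  if ("police_action" %in% names(comp_tab)) {
    comp_tab$police_action <- .as_flag(comp_tab$police_action)
  }

  list(poi = poi_tab, visits = vis_tab, complaints = comp_tab, ledger = ledger)
}

.require_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop(sprintf("%s table is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")))
  invisible(TRUE)
}

.parse_ts_vec <- function(x) {
  if (inherits(x, "POSIXct")) return(.parse_ts(x))
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), tz = "UTC", origin = "1970-01-01")
  for (fmt in c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S", "%Y-%m-%d")) {
    todo <- is.na(out)
    if (!any(todo)) break
    out[todo] <- as.POSIXct(x[todo], tz = "UTC", format = fmt)
  }
  out
}

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(as.character(x)) %in% c("true", "t", "1", "yes")
}

#' Pool POIs to building-level scoring units
#'
#' POIs sharing a building id are merged into one scoring unit: floor areas
#' add, same-hour visits add, a unit is open in an hour when any member is
#' open, the unit's establishment type is the modal member type (ties broken
#' towards the lexicographically smallest), and the zip is the modal member
#' zip.
#'
#' @param poi_table POI table from [load_tables()].
#' @param visit_table hourly visit table from [load_tables()].
#' @param ledger optional [new_ledger()].
#' @return list with `units` (unit_id, zip, poi_type, floor_area,
#'   n_pois_pooled) and `visits` (unit_id, timestamp, visits, open).
#' @export
pool_to_buildings <- function(poi_table, visit_table, ledger = NULL) {
  if (is.null(ledger)) ledger <- new_ledger()
  stopifnot(all(c("poi_id", "building_id", "zip", "poi_type", "floor_area") %in%
                  names(poi_table)))

  # modal value, ties to the lexicographically smallest
  modal <- function(x) {
    tab <- sort(table(x), decreasing = TRUE)
    cand <- names(tab)[tab == tab[1]]
    sort(cand)[1]
  }

  units <- do.call(rbind, lapply(split(poi_table, poi_table$building_id), function(g) {
    data.frame(unit_id = g$building_id[1],
               zip = modal(g$zip),
               poi_type = modal(g$poi_type),
               floor_area = sum(g$floor_area),
               n_pois_pooled = nrow(g),
               stringsAsFactors = FALSE)
  }))
  rownames(units) <- NULL

  n0 <- nrow(visit_table)
  bmap <- poi_table$building_id[match(visit_table$poi_id, poi_table$poi_id)]
  known <- !is.na(bmap)
  ledger_add(ledger, "visits_unknown_poi", n0, sum(known))
  vt <- visit_table[known, , drop = FALSE]
  bmap <- bmap[known]

  # fast path: every building holds a single POI, so pooling is a relabelling
  if (!anyDuplicated(poi_table$building_id)) {
    unit_visits <- data.frame(unit_id = bmap, timestamp = vt$timestamp,
                              visits = as.numeric(vt$visits),
                              open = as.logical(vt$open), stringsAsFactors = FALSE)
    unit_visits <- unit_visits[order(unit_visits$unit_id, unit_visits$timestamp), ]
    rownames(unit_visits) <- NULL
    return(list(units = units, visits = unit_visits, ledger = ledger))
  }

  secs <- as.numeric(vt$timestamp)
  key <- paste(bmap, secs, sep = "|")
  vis <- rowsum(as.numeric(vt$visits), key)
  opn <- rowsum(as.numeric(vt$open), key) > 0
  rn <- rownames(vis)
  unit_visits <- data.frame(
    unit_id = sub("\\|.*$", "", rn),
    timestamp = as.POSIXct(as.numeric(sub("^.*\\|", "", rn)), tz = "UTC",
                           origin = "1970-01-01"),
    visits = as.numeric(vis[, 1]),
    open = as.logical(opn[, 1]),
    stringsAsFactors = FALSE
  )
  unit_visits <- unit_visits[order(unit_visits$unit_id, unit_visits$timestamp), ]
  rownames(unit_visits) <- NULL

  list(units = units, visits = unit_visits, ledger = ledger)
}

#' Bin hourly unit visits to six-hour intervals
#'
#' Intervals are half-open `[t, t + 6h)` in local clock time, anchored at
#' hours 0, 6, 12 and 18. Visits are summed within the interval and a unit is
#' open in an interval when it is open in any member hour. Intensity (visits
#' per 10,000 sq ft per interval) is attached from the unit table.
#'
#' @param unit_visits hourly table from [pool_to_buildings()].
#' @param units unit table (for floor areas).
#' @return interval table: `unit_id`, `interval_start`, `visits`, `open`,
#'   `intensity`.
#' @export
bin_six_hour <- function(unit_visits, units) {
  secs <- as.numeric(unit_visits$timestamp)
  key <- paste(unit_visits$unit_id, secs)
  if (anyDuplicated(key))
    stop("duplicate (unit, hour) rows in visit table: ambiguous source")

  int_secs <- floor(secs / 21600) * 21600
  gkey <- paste(unit_visits$unit_id, int_secs, sep = "|")
  vis <- rowsum(as.numeric(unit_visits$visits), gkey)
  opn <- rowsum(as.numeric(unit_visits$open), gkey) > 0
  rn <- rownames(vis)
  out <- data.frame(
    unit_id = sub("\\|.*$", "", rn),
    interval_start = as.POSIXct(as.numeric(sub("^.*\\|", "", rn)), tz = "UTC",
                                origin = "1970-01-01"),
    visits = as.numeric(vis[, 1]),
    open = as.logical(opn[, 1]),
    stringsAsFactors = FALSE
  )
  area <- units$floor_area[match(out$unit_id, units$unit_id)]
  out$intensity <- activity_intensity(out$visits, area)
  out <- out[order(out$unit_id, out$interval_start), ]
  rownames(out) <- NULL
  out
}

#' Flag intervals in which a complaint was reported
#'
#' Sets `complaint = TRUE` for an interval when at least one complaint
#' timestamp for that unit falls in `[interval_start, interval_start + 6h)`.
#' The flag is boolean, not a count: several complaints in one interval flag
#' it once. Complaints whose building id matches no unit, or whose timestamp
#' falls outside the binned study period, go to the ledger. Re-running on an
#' already flagged table recomputes the same flags (idempotent).
#'
#' @param interval_table from [bin_six_hour()].
#' @param complaint_table from [load_tables()].
#' @param ledger optional [new_ledger()].
#' @return `interval_table` with a logical `complaint` column.
#' @export
flag_complaints <- function(interval_table, complaint_table, ledger = NULL) {
  if (is.null(ledger)) ledger <- new_ledger()
  n0 <- nrow(complaint_table)
  if (n0 == 0) {
    interval_table$complaint <- FALSE
    ledger_add(ledger, "complaints_unmatched_to_interval", 0L, 0L)
    return(interval_table)
  }
  c_int <- floor(as.numeric(complaint_table$timestamp) / 21600) * 21600
  ckey <- paste(complaint_table$building_id, c_int)
  ikey <- paste(interval_table$unit_id, as.numeric(interval_table$interval_start))
  matched <- ckey %in% ikey
  ledger_add(ledger, "complaints_unmatched_to_interval", n0, sum(matched))
  interval_table$complaint <- ikey %in% ckey
  interval_table
}

#' Modal complaint hour by establishment type
#'
#' For each establishment type with at least one complaint, the most frequent
#' clock hour (0-23) of its complaint timestamps; ties go to the earliest
#' hour. Types with no complaints are omitted.
#'
#' @param complaint_table complaints with `building_id` and `timestamp`.
#' @param units unit table with `unit_id` and `poi_type`.
#' @return data frame `poi_type`, `mode_hour`, `n_complaints`.
#' @export
mode_complaint_hour <- function(complaint_table, units) {
  type <- units$poi_type[match(complaint_table$building_id, units$unit_id)]
  keep <- !is.na(type)
  if (!any(keep)) {
    return(data.frame(poi_type = character(), mode_hour = integer(),
                      n_complaints = integer(), stringsAsFactors = FALSE))
  }
  hr <- as.integer(format(complaint_table$timestamp[keep], "%H"))
  type <- type[keep]
  out <- do.call(rbind, lapply(split(hr, type), function(h) {
    tab <- table(factor(h, levels = 0:23))
    data.frame(mode_hour = as.integer(names(tab)[which.max(tab)]),
               n_complaints = length(h))
  }))
  data.frame(poi_type = rownames(out), mode_hour = out$mode_hour,
             n_complaints = out$n_complaints, row.names = NULL,
             stringsAsFactors = FALSE)
}
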