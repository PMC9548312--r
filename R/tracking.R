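#' Breeding phase windows
#'
#' The three phenological phases of the breeding season used to split
#' tracking data: late incubation (31 May - 15 Jun), early nestling rearing
#' (16 Jun - 6 Jul) and late nestling rearing (7 - 25 Jul). End dates are
#' inclusive; a boundary day belongs to the later phase because each window
#' starts the day after the previous one ends.
#'
#' @param year Calendar year the windows fall in.
#' @return `data.frame` with columns `phase`, `start`, `end` (class `Date`).
#' @export
breeding_phases <- function(year = 2019) {
  data.frame(
    phase = phase_names(),
    start = as.Date(sprintf(c("%d-05-31", "%d-06-16", "%d-07-07"), year)),
    end   = as.Date(sprintf(c("%d-06-15", "%d-07-06", "%d-07-25"), year)),
    stringsAsFactors = FALSE
  )
}

#' Fix-filtering configuration
#'
#' Bundles the retention rules applied to raw GPS fixes before habitat use is
#' counted: a night window that removes roosting locations, a colony
#' exclusion buffer (padded by the GPS location error) that removes fixes at
#' the colony itself, the foraging radius that bounds availability, and the
#' per-individual quality thresholds.
#'
#' @param night_start,night_end Local clock times (`"HH:MM"`) bounding the
#'   night window; fixes at or between them are removed (default 20:00-06:00,
#'   boundary instants removed).
#' @param exclusion_radius_m Default colony exclusion radius in metres.
#' @param colony_overrides Named numeric vector of per-colony exclusion radii
#'   (e.g. `c(PR = 80)` where observation showed no foraging within 80 m).
#' @param gps_error_pad_m Extra pad added to the exclusion radius for GPS
#'   location error (default 40).
#' @param foraging_radius_m Maximum distance from the colony for a fix to
#'   count as available-for-use (default 3000).
#' @param min_fixes Minimum retained fixes per individual (default 100).
#' @param min_days Minimum distinct local calendar dates with at least one
#'   retained fix (default 10).
#' @return List of class `filter_config`.
#' @export
filter_config <- function(night_start = "20:00", night_end = "06:00",
                          exclusion_radius_m = 50, colony_overrides = NULL,
                          gps_error_pad_m = 40, foraging_radius_m = 3000,
                          min_fixes = 100, min_days = 10) {
  stopifnot(exclusion_radius_m >= 0, gps_error_pad_m >= 0,
            foraging_radius_m > 0, min_fixes >= 1, min_days >= 1)
  structure(list(night_start = night_start, night_end = night_end,
                 exclusion_radius_m = exclusion_radius_m,
                 colony_overrides = colony_overrides,
                 gps_error_pad_m = gps_error_pad_m,
                 foraging_radius_m = foraging_radius_m,
                 min_fixes = as.integer(min_fixes),
                 min_days = as.integer(min_days)),
            class = "filter_config")
}

hhmm_to_min <- function(s) {
  p <- as.integer(strsplit(s, ":", fixed = TRUE)[[1]])
  p[1] * 60L + p[2]
}

#' Assign breeding phases to dates
#'
#' @param dates `Date` vector (or coercible).
#' @param phases Phase table from [breeding_phases()].
#' @return Character vector of phase names, `NA` outside all windows.
#' @export
assign_phase <- function(dates, phases = breeding_phases()) {
  dates <- as.Date(dates)
  out <- rep(NA_character_, length(dates))
  for (i in seq_len(nrow(phases))) {
    hit <- !is.na(dates) & dates >= phases$start[i] & dates <= phases$end[i]
    out[hit] <- phases$phase[i]
  }
  out
}

#' Filter raw GPS fixes to analysis-ready foraging locations
#'
#' Applies, in order: the night window (roosting fixes), the padded colony
#' exclusion buffer, and the foraging-radius cut. Each fix is annotated with
#' its breeding phase; ordering is preserved. The rules are idempotent:
#' filtering an already-filtered table changes nothing.
#'
#' @param fixes `data.frame` with columns `individual_id`, `colony_id`,
#'   `timestamp` (`POSIXct`, local time), `x`, `y` (metres in the colony
#'   frame).
#' @param colonies `data.frame` with columns `colony_id`, `x`, `y`.
#' @param config A [filter_config()].
#' @param phases Phase table from [breeding_phases()].
#' @return The input with added columns `phase`, `retained` (logical) and
#'   `drop_reason` (`NA`, `"night"`, `"colony_buffer"`, `"out_of_range"`).
#' @export
filter_fixes <- function(fixes, colonies, config = filter_config(),
                         phases = breeding_phases()) {
  if (nrow(fixes) == 0L) stop("empty fix table")
  miss <- setdiff(unique(fixes$colony_id), colonies$colony_id)
  if (length(miss))
    stop("unknown colony id(s): ", paste(miss, collapse = ", "))
  ci <- match(fixes$colony_id, colonies$colony_id)
  d <- sqrt((fixes$x - colonies$x[ci])^2 + (fixes$y - colonies$y[ci])^2)
  excl <- rep(config$exclusion_radius_m, nrow(fixes))
  if (!is.null(config$colony_overrides)) {
    ov <- match(fixes$colony_id, names(config$colony_overrides))
    excl[!is.na(ov)] <- config$colony_overrides[ov[!is.na(ov)]]
  }
  tod <- as.POSIXlt(fixes$timestamp)
  mins <- tod$hour * 60 + tod$min + tod$sec / 60
  ns <- hhmm_to_min(config$night_start); ne <- hhmm_to_min(config$night_end)
  night <- if (ns > ne) mins >= ns | mins <= ne else mins >= ns & mins <= ne
  in_buffer <- d <= excl + config$gps_error_pad_m
  out_range <- d > config$foraging_radius_m
  reason <- rep(NA_character_, nrow(fixes))
  reason[out_range] <- "out_of_range"
  reason[in_buffer] <- "colony_buffer"
  reason[night] <- "night"
  fixes$phase <- assign_phase(as.Date(fixes$timestamp,
                                      tz = attr(tod, "tzone")[1]), phases)
  fixes$retained <- is.na(reason)
  fixes$drop_reason <- reason
  fixes
}

#' Per-individual quality control
#'
#' Drops individuals that did not keep an active nest through tracking, kept
#' fewer than `min_fixes` retained locations, or were tracked on fewer than
#' `min_days` distinct local calendar dates.
#'
#' @param fixes Output of [filter_fixes()].
#' @param config A [filter_config()].
#' @param nest_active Optional named logical vector by individual id
#'   (default: all active).
#' @return List with `fixes` (retained fixes of accepted individuals) and
#'   `report` (`data.frame`: individual_id, n_fixes, n_days, accepted,
#'   reason).
#' @export
qc_individuals <- function(fixes, config = filter_config(),
                           nest_active = NULL) {
  kept <- fixes[fixes$retained, , drop = FALSE]
  ids <- unique(fixes$individual_id)
  n_fixes <- vapply(ids, function(i) sum(kept$individual_id == i), integer(1))
  n_days <- vapply(ids, function(i) {
    length(unique(as.Date(kept$timestamp[kept$individual_id == i])))
  }, integer(1))
  active <- if (is.null(nest_active)) rep(TRUE, length(ids)) else {
    a <- nest_active[match(ids, names(nest_active))]
    a[is.na(a)] <- TRUE
    a
  }
  reason <- rep(NA_character_, length(ids))
  reason[n_days < config$min_days] <- "min_days"
  reason[n_fixes < config$min_fixes] <- "min_fixes"
  reason[!active] <- "nest_failed"
  report <- data.frame(individual_id = ids, n_fixes = n_fixes,
                       n_days = n_days, accepted = is.na(reason),
                       reason = reason, stringsAsFactors = FALSE)
  list(fixes = kept[kept$individual_id %in% ids[is.na(reason)], , drop = FALSE],
       report = report)
}

#' Habitat use counts from retained fixes
#'
#' Counts, per individual, phase and habitat class, the retained fixes whose
#' raster cell carries that class. Fixes outside the raster or on no-data
#' cells are dropped from the totals.
#'
#' @param fixes Retained fixes (e.g. `qc_individuals(...)$fixes`), with a
#'   `phase` column.
#' @param rasters Named list of `habitat_raster` objects, one per phase.
#' @param class_map Optional class-to-group mapping applied before counting.
#' @return `data.frame` with columns `individual`, `colony`, `phase`,
#'   `class`, `u`, `N`.
#' @export
use_table <- function(fixes, rasters, class_map = NULL) {
  fixes <- fixes[!is.na(fixes$phase), , drop = FALSE]
  if (nrow(fixes) == 0L)
    stop("no retained fixes with an assigned phase; nothing to count")
  out <- list()
  for (ph in unique(fixes$phase)) {
    r <- rasters[[ph]]
    if (is.null(r)) stop("no raster supplied for phase ", ph)
    sub <- fixes[fixes$phase == ph, , drop = FALSE]
    cls <- raster_class_at(r, sub$x, sub$y)
    if (!is.null(class_map)) {
      known <- is.na(cls) | cls %in% names(class_map)
      if (!all(known))
        stop("classes missing from class_map: ",
             paste(unique(cls[!known]), collapse = ", "))
      cls <- ifelse(is.na(cls), NA, unname(class_map[cls]))
    }
    ok <- !is.na(cls)
    sub <- sub[ok, , drop = FALSE]; cls <- cls[ok]
    if (!nrow(sub)) next
    agg <- stats::aggregate(list(u = rep(1L, nrow(sub))),
                            by = list(individual = sub$individual_id,
                                      colony = sub$colony_id, class = cls),
                            FUN = sum)
    tot <- stats::aggregate(list(N = agg$u),
                            by = list(individual = agg$individual), FUN = sum)
    agg$N <- tot$N[match(agg$individual, tot$individual)]
    agg$phase <- ph
    out[[ph]] <- agg[, c("individual", "colony", "phase", "class", "u", "N")]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
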