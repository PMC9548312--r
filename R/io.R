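#' Read a matched foraging/control pair table
#'
#' Long CSV with one row per location: `pair_id`, `role` (forage/control,
#' case-insensitive), `colony`, `date`, coordinates, `veg_height_cm`,
#' `structure`, `crop`. Validation is strict: every pair id must appear
#' exactly twice with one member per role, structure and crop labels must be
#' known, and offending rows are reported by line.
#'
#' @param path CSV path.
#' @return Validated `data.frame`.
#' @export
read_pairs <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("pair_id", "role", "veg_height_cm", "structure", "crop")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d$veg_height_cm <- parse_numeric(d$veg_height_cm, "veg_height_cm")
  if (any(d$veg_height_cm < 0, na.rm = TRUE))
    stop("negative vegetation height at line(s) ",
         paste(utils::head(which(d$veg_height_cm < 0) + 1L, 5), collapse = ", "))
  bad_s <- !is.na(d$structure) & !(d$structure %in% c(phenology_states(), ""))
  if (any(bad_s))
    stop("unknown structure label(s): ",
         paste(unique(d$structure[bad_s]), collapse = ", "),
         "; permitted: ", paste(phenology_states(), collapse = ", "))
  bad_c <- !is.na(d$crop) & d$crop != "" & !(d$crop %in% crop_classes())
  if (any(bad_c))
    stop("unknown crop label(s): ",
         paste(unique(d$crop[bad_c]), collapse = ", "),
         "; permitted: ", paste(crop_classes(), collapse = ", "))
  pairs_to_wide(d)   # runs the pairing validation; result discarded
  d
}

# tolerate the unicode minus sign U+2212 that typeset tables often carry
parse_numeric <- function(x, what) {
  if (is.numeric(x)) return(x)
  x <- gsub("−", "-", trimws(x))
  out <- suppressWarnings(as.numeric(x))
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad))
    stop("non-numeric ", what, " at line(s) ",
         paste(utils::head(which(bad) + 1L, 5), collapse = ", "))
  out
}

#' Read a GPS fix table
#'
#' CSV with columns `individual_id`, `colony_id`, `timestamp` (ISO-8601) and
#' either `x`,`y` (metres, local frame) or `lon`,`lat` (decimal degrees,
#' projected with a local azimuthal-equidistant frame centred on `origin`).
#'
#' @param path CSV path.
#' @param origin `c(lon, lat)` of the local frame origin; required for
#'   lon/lat input.
#' @param tz Timezone of the timestamps (default UTC).
#' @return `data.frame` with metric coordinates and `POSIXct` timestamps.
#' @export
read_tracks <- function(path, origin = NULL, tz = "UTC") {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("individual_id", "colony_id", "timestamp")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  ts <- as.POSIXct(strptime(d$timestamp, "%Y-%m-%dT%H:%M:%S", tz = tz))
  alt <- as.POSIXct(strptime(d$timestamp, "%Y-%m-%d %H:%M:%S", tz = tz))
  ts[is.na(ts)] <- alt[is.na(ts)]
  if (anyNA(ts))
    stop("unparseable timestamp at line(s) ",
         paste(utils::head(which(is.na(ts)) + 1L, 5), collapse = ", "))
  d$timestamp <- ts
  if (all(c("x", "y") %in% names(d))) {
    d$x <- parse_numeric(d$x, "x"); d$y <- parse_numeric(d$y, "y")
  } else if (all(c("lon", "lat") %in% names(d))) {
    if (is.null(origin)) stop("lon/lat input requires a projection origin")
    xy <- project_local(parse_numeric(d$lon, "lon"),
                        parse_numeric(d$lat, "lat"), origin[1], origin[2])
    d$x <- xy$x; d$y <- xy$y
  } else stop("need either x/y or lon/lat columns")
  if (any(!is.finite(d$x) | !is.finite(d$y)))
    stop("non-finite coordinates")
  d
}

#' Read a habitat map from GeoJSON
#'
#' RFC 7946 FeatureCollection of polygons with properties `class`,
#' `pheno_p1`, `pheno_p2`, `pheno_p3`. Coordinates must either be in a local
#' metric frame (`crs` property `"local_metres"`) or lon/lat, in which case
#' `origin` fixes the local azimuthal-equidistant frame.
#'
#' @param path GeoJSON path.
#' @param origin `c(lon, lat)` origin for lon/lat input.
#' @return A [parcel_table()].
#' @export
read_habitat_map <- function(path, origin = NULL) {
  g <- jsonlite::read_json(path)
  if (is.null(g$type) || g$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  local <- identical(g$crs, "local_metres") ||
    identical(g$crs$properties$name, "local_metres")
  feats <- g$features
  if (!length(feats)) stop("empty FeatureCollection")
  getp <- function(f, k) {
    v <- f$properties[[k]]
    if (is.null(v)) NA_character_ else as.character(v)
  }
  geom <- lapply(feats, function(f) {
    if (f$geometry$type != "Polygon")
      stop("only Polygon geometries are supported")
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(pt) c(pt[[1]], pt[[2]])))
    if (!local) {
      if (is.null(origin)) stop("lon/lat GeoJSON requires a projection origin")
      xy <- project_local(m[, 1], m[, 2], origin[1], origin[2])
      m <- cbind(xy$x, xy$y)
    }
    m
  })
  parcel_table(id = seq_along(feats),
               class = vapply(feats, getp, character(1), k = "class"),
               geometry = geom,
               pheno_p1 = vapply(feats, getp, character(1), k = "pheno_p1"),
               pheno_p2 = vapply(feats, getp, character(1), k = "pheno_p2"),
               pheno_p3 = vapply(feats, getp, character(1), k = "pheno_p3"))
}

#' Write a habitat raster as an ESRI ASCII grid
#'
#' @param raster A `habitat_raster`.
#' @param path Output path.
#' @param codes Optional named integer codes per class; defaults to the
#'   alphabetical index of the classes present.
#' @return Invisibly, the code table used.
#' @export
write_ascii_grid <- function(raster, path, codes = NULL) {
  cls <- sort(unique(raster$class[!is.na(raster$class)]))
  if (is.null(codes)) codes <- stats::setNames(seq_along(cls), cls)
  m <- matrix(-9999L, nrow(raster$class), ncol(raster$class))
  known <- !is.na(raster$class)
  m[known] <- codes[raster$class[known]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(m)), sprintf("nrows %d", nrow(m)),
    sprintf("xllcorner %g", raster$origin[1]),
    sprintf("yllcorner %g", raster$origin[2]),
    sprintf("cellsize %g", raster$cell_size),
    "NODATA_value -9999"), con)
  for (i in rev(seq_len(nrow(m))))   # ascii grids run north to south
    writeLines(paste(m[i, ], collapse = " "), con)
  invisible(codes)
}

#' Run the full habitat-selection pipeline on simulated or supplied data
#'
#' simulate (optional) -> filter fixes -> QC -> use counts -> selection
#' ratios with Koopman intervals -> per-phase weighted gamma GLMM -> the
#' three matched-pair conditional logistic models. Writes tidy CSV outputs
#' and a JSON run log (row tallies, config hash) when `out_dir` is given.
#'
#' @param sim A `sim_output` from [simulate_study()]; or supply `tracks`,
#'   `rasters`, `colonies`, `pairs` yourself via this list interface.
#' @param config A [filter_config()].
#' @param min_use Minimum used locations per class (default 5).
#' @param out_dir Optional output directory.
#' @return List with `ratios`, `glmm` (per phase: fit, wald, r2), `clogit`
#'   (per model), `qc_report`.
#' @export
run_pipeline <- function(sim, config = filter_config(), min_use = 5,
                         out_dir = NULL) {
  filtered <- filter_fixes(sim$tracks, sim$colonies, config)
  qc <- qc_individuals(filtered, config)
  use <- use_table(qc$fixes, sim$rasters)
  avail <- do.call(rbind, lapply(names(sim$rasters), function(ph) {
    do.call(rbind, lapply(seq_len(nrow(sim$colonies)), function(i)
      availability(sim$rasters[[ph]],
                   unlist(sim$colonies[i, c("x", "y")]),
                   radius_m = config$foraging_radius_m,
                   colony = sim$colonies$colony_id[i])))
  }))
  ratios <- selection_ratio_table(use, avail, min_use = min_use)
  glmm <- lapply(split(as.data.frame(ratios), ratios$phase), function(d) {
    if (length(unique(d$class[d$min_use_ok])) < 2) return(NULL)
    fit <- fit_ratio_glmm(d)
    list(fit = fit, wald = wald_chisq(fit), marginal_r2 = nakagawa_r2(fit))
  })
  clogit <- lapply(c(height = "height", structure = "structure",
                     crop = "crop"),
                   function(m) fit_pair_clogit(sim$pairs, model = m))
  res <- list(ratios = ratios, glmm = glmm, clogit = clogit,
              qc_report = qc$report,
              tallies = table(filtered$drop_reason, useNA = "ifany"))
  if (!is.null(out_dir)) write_pipeline_outputs(res, sim, out_dir)
  res
}

write_pipeline_outputs <- function(res, sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(res$ratios),
                   file.path(out_dir, "selection_ratios.csv"),
                   row.names = FALSE)
  tests <- do.call(rbind, lapply(names(res$glmm), function(ph) {
    g <- res$glmm[[ph]]
    if (is.null(g)) return(NULL)
    data.frame(phase = ph, chi2 = g$wald$chi2, df = g$wald$df,
               p = g$wald$p, marginal_r2 = g$marginal_r2)
  }))
  if (!is.null(tests))
    utils::write.csv(tests, file.path(out_dir, "glmm_tests.csv"),
                     row.names = FALSE)
  tab1 <- do.call(rbind, lapply(names(res$clogit), function(m) {
    f <- res$clogit[[m]]
    if (is.null(f$levels)) {
      se <- sqrt(diag(f$vcov))
      data.frame(model = m, contrast = names(coef(f)),
                 estimate = unname(coef(f)), se = unname(se),
                 z = unname(coef(f) / se),
                 p = unname(2 * stats::pnorm(-abs(coef(f) / se))),
                 pseudo_r2 = f$pseudo_r2, stringsAsFactors = FALSE)
    } else {
      ct <- pairwise_contrasts(f)
      ct$model <- m; ct$pseudo_r2 <- f$pseudo_r2
      ct[, c("model", "contrast", "estimate", "se", "z", "p", "pseudo_r2")]
    }
  }))
  utils::write.csv(tab1, file.path(out_dir, "clogit_models.csv"),
                   row.names = FALSE)
  log <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              package_version = as.character(utils::packageVersion("habsel")),
              dropped = as.list(res$tallies),
              qc = res$qc_report,
              config_hash = config_hash(sim$config))
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(out_dir)
}

#' Hash of a configuration object
#'
#' MD5 of the canonical JSON serialisation; lets a run log prove which
#' configuration produced it.
#'
#' @param config Any serialisable list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, force = TRUE,
                       digits = NA)
  unname(tools::md5sum(tmp))
}
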