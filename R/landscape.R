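#' Analysis habitat groups
#'
#' The eight habitat levels used in the population-level selection models.
#' Field maps typically carry many more classes; [default_class_map()] folds
#' them onto these eight groups before any availability computation.
#'
#' @return Character vector of the eight group labels.
#' @export
habitat_groups <- function() {
  c("alfalfa", "winter_cereals", "other_non_irrigated", "maize",
    "other_irrigated", "urbanized", "water", "other_seminatural")
}

#' Crop classes entering the third-order crop-type model
#'
#' @return Character vector of the five crop labels.
#' @export
crop_classes <- function() {
  c("alfalfa", "winter_cereals", "other_non_irrigated", "maize",
    "other_irrigated")
}

#' Vegetation structure states
#'
#' Phenological states of a cultivated parcel: standing crop before harvest,
#' stubble after harvest, or bare ploughed soil. Non-crop classes carry the
#' `"not_applicable"` state.
#'
#' @return Character vector of the three states.
#' @export
phenology_states <- function() c("vegetated", "harvested", "ploughed")

#' Default mapping from mapped habitat classes to analysis groups
#'
#' Identity on the eight group labels plus a few common field-map synonyms.
#' Supply your own named character vector (`names` = mapped class, `value` =
#' analysis group) to [availability()] when the field map uses a richer
#' legend.
#'
#' @return Named character vector mapping class codes to the eight groups.
#' @export
default_class_map <- function() {
  groups <- habitat_groups()
  map <- stats::setNames(groups, groups)
  extra <- c(
    wheat = "winter_cereals", barley = "winter_cereals",
    rye = "winter_cereals", triticale = "winter_cereals",
    soybean = "other_irrigated", horticultural = "other_irrigated",
    urban = "urbanized", road = "urbanized", farmstead = "urbanized",
    canal = "water", wetland = "water",
    hedgerow = "other_seminatural", grassland = "other_seminatural",
    orchard = "other_seminatural"
  )
  c(map, extra)
}

#' Build a parcel table
#'
#' A parcel is a simple polygon in a local metric frame carrying a habitat
#' class and, for crop classes, a phenological state per breeding phase.
#'
#' @param id Integer parcel ids (unique).
#' @param class Character habitat class per parcel.
#' @param geometry List of two-column numeric matrices (x, y vertices in
#'   metres; the ring may be open or closed).
#' @param pheno_p1,pheno_p2,pheno_p3 Phenological state per phase
#'   (`"vegetated"`, `"harvested"`, `"ploughed"`), or `NA` for non-crop
#'   classes.
#' @return A `data.frame` of class `parcel_table` with a `geometry` list
#'   column.
#' @export
parcel_table <- function(id, class, geometry,
                         pheno_p1 = NA_character_,
                         pheno_p2 = NA_character_,
                         pheno_p3 = NA_character_) {
  id <- as.integer(id)
  if (anyDuplicated(id)) stop("parcel ids must be unique")
  if (!is.list(geometry)) stop("geometry must be a list of coordinate matrices")
  ok <- vapply(geometry, function(g) is.matrix(g) && ncol(g) == 2 && nrow(g) >= 3,
               logical(1))
  if (!all(ok)) stop("each geometry must be a matrix with >= 3 rows and 2 columns")
  df <- data.frame(id = id, class = as.character(class),
                   pheno_p1 = rep_len(as.character(pheno_p1), length(id)),
                   pheno_p2 = rep_len(as.character(pheno_p2), length(id)),
                   pheno_p3 = rep_len(as.character(pheno_p3), length(id)),
                   stringsAsFactors = FALSE)
  df$geometry <- geometry
  crop <- df$class %in% crop_classes()
  states <- c(phenology_states(), NA)
  for (p in c("pheno_p1", "pheno_p2", "pheno_p3")) {
    if (!all(df[[p]] %in% states)) stop("unknown phenology state in ", p)
    if (any(crop & is.na(df[[p]])))
      stop("crop parcels must carry a phenology state for every phase")
  }
  class(df) <- c("parcel_table", "data.frame")
  df
}

# Even-odd ray casting, vectorised over query points. Points exactly on an
# edge are resolved by the half-open crossing rule; rasterization additionally
# breaks ties deterministically by processing parcels in increasing id order.
point_in_polygon <- function(px, py, poly) {
  if (!isTRUE(all.equal(poly[1, ], poly[nrow(poly), ], check.attributes = FALSE)))
    poly <- rbind(poly, poly[1, , drop = FALSE])
  n <- nrow(poly) - 1L
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[i + 1L, 1]; yj <- poly[i + 1L, 2]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py - yi) * (xj - xi) / (yj - yi)
      hit <- crosses & (px < xint)
      inside <- xor(inside, hit)
    }
  }
  inside
}

phase_names <- function() c("late_incubation", "early_rearing", "late_rearing")

pheno_column <- function(phase) {
  idx <- match(phase, phase_names())
  if (is.na(idx)) stop("unknown phase: ", phase)
  paste0("pheno_p", idx)
}

#' Rasterize a parcel map
#'
#' Burns parcels onto a regular square grid: each cell takes the class of the
#' parcel containing its centre (lowest parcel id wins when centres fall on a
#' shared edge), or no-data where no parcel contains the centre. The default
#' 40 m resolution matches the GPS location error of the tracking devices, so
#' a fix and the cell it falls in are commensurate.
#'
#' @param parcels A [parcel_table()].
#' @param phase Phase name (`"late_incubation"`, `"early_rearing"`,
#'   `"late_rearing"`); selects which phenology column travels with the
#'   raster.
#' @param cell_size Cell edge in metres (default 40).
#' @param bounds Numeric `c(xmin, ymin, xmax, ymax)`; defaults to the parcel
#'   bounding box.
#' @return An object of class `habitat_raster`: list with `class`, `pheno`
#'   and `parcel` matrices (rows index y from the bottom), `origin`,
#'   `cell_size` and `phase`.
#' @export
rasterize_parcels <- function(parcels, phase = "late_incubation",
                              cell_size = 40, bounds = NULL) {
  if (nrow(parcels) == 0L) stop("empty parcel list")
  if (!is.numeric(cell_size) || cell_size <= 0) stop("cell_size must be > 0")
  pcol <- pheno_column(phase)
  if (is.null(bounds)) {
    xs <- unlist(lapply(parcels$geometry, function(g) g[, 1]))
    ys <- unlist(lapply(parcels$geometry, function(g) g[, 2]))
    bounds <- c(min(xs), min(ys), max(xs), max(ys))
  }
  nx <- max(1L, as.integer(round((bounds[3] - bounds[1]) / cell_size)))
  ny <- max(1L, as.integer(round((bounds[4] - bounds[2]) / cell_size)))
  cx <- bounds[1] + (seq_len(nx) - 0.5) * cell_size
  cy <- bounds[2] + (seq_len(ny) - 0.5) * cell_size
  cls <- matrix(NA_character_, nrow = ny, ncol = nx)
  pid <- matrix(NA_integer_, nrow = ny, ncol = nx)
  phn <- matrix(NA_character_, nrow = ny, ncol = nx)
  ord <- order(parcels$id)
  for (k in ord) {
    g <- parcels$geometry[[k]]
    jx <- which(cx >= min(g[, 1]) - cell_size & cx <= max(g[, 1]) + cell_size)
    iy <- which(cy >= min(g[, 2]) - cell_size & cy <= max(g[, 2]) + cell_size)
    if (!length(jx) || !length(iy)) next
    qx <- rep(cx[jx], times = length(iy))
    qy <- rep(cy[iy], each = length(jx))
    hit <- point_in_polygon(qx, qy, g)
    if (!any(hit)) next
    rows <- rep(iy, each = length(jx))[hit]
    cols <- rep(jx, times = length(iy))[hit]
    free <- is.na(pid[cbind(rows, cols)])
    if (!any(free)) next
    idx <- cbind(rows[free], cols[free])
    pid[idx] <- parcels$id[k]
    cls[idx] <- parcels$class[k]
    phn[idx] <- if (parcels$class[k] %in% crop_classes())
      parcels[[pcol]][k] else "not_applicable"
  }
  structure(list(class = cls, pheno = phn, parcel = pid,
                 origin = bounds[1:2], cell_size = cell_size, phase = phase),
            class = "habitat_raster")
}

#' @export
print.habitat_raster <- function(x, ...) {
  cat(sprintf("habitat_raster: %d x %d cells of %g m (phase %s)\n",
              nrow(x$class), ncol(x$class), x$cell_size, x$phase))
  tab <- table(x$class, useNA = "ifany")
  print(tab)
  invisible(x)
}

raster_cell_centres <- function(raster) {
  nx <- ncol(raster$class); ny <- nrow(raster$class)
  cs <- raster$cell_size
  list(x = raster$origin[1] + (seq_len(nx) - 0.5) * cs,
       y = raster$origin[2] + (seq_len(ny) - 0.5) * cs)
}

# Row/col of the cell containing each point; NA outside the grid.
raster_cell_index <- function(raster, x, y) {
  cs <- raster$cell_size
  col <- floor((x - raster$origin[1]) / cs) + 1L
  row <- floor((y - raster$origin[2]) / cs) + 1L
  bad <- col < 1L | col > ncol(raster$class) | row < 1L | row > nrow(raster$class)
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Class of the raster cell containing each point
#'
#' @param raster A `habitat_raster`.
#' @param x,y Point coordinates in metres.
#' @return Character vector of class codes (`NA` outside the grid or on
#'   no-data cells).
#' @export
raster_class_at <- function(raster, x, y) {
  idx <- raster_cell_index(raster, x, y)
  out <- rep(NA_character_, length(x))
  ok <- !is.na(idx$row)
  out[ok] <- raster$class[cbind(idx$row[ok], idx$col[ok])]
  out
}

#' Habitat availability within a colony foraging buffer
#'
#' Counts raster cells per habitat class among cells whose centre lies within
#' `radius_m` of the colony; no-data cells are excluded from the total. Cell
#' counts, rather than vector areas, keep availability on the same integer
#' footing as use counts, which is what the Koopman score interval for the
#' use:availability ratio requires. Hectares are recoverable as
#' `cells * cell_size^2 / 1e4`.
#'
#' @param raster A `habitat_raster`.
#' @param colony_xy Numeric `c(x, y)` of the colony in metres.
#' @param radius_m Buffer radius in metres (default 3000, the species'
#'   foraging range around the colony).
#' @param class_map Optional named vector folding raster classes onto
#'   analysis groups before counting (see [default_class_map()]).
#' @param colony Optional colony id label carried into the output.
#' @return `data.frame` of class `availability_table` with columns `colony`,
#'   `phase`, `class`, `cells`, `proportion`; attribute `total_cells`.
#' @export
availability <- function(raster, colony_xy, radius_m = 3000,
                         class_map = NULL, colony = "colony") {
  if (radius_m <= 0) stop("radius_m must be > 0")
  cc <- raster_cell_centres(raster)
  xr <- range(cc$x); yr <- range(cc$y)
  if (colony_xy[1] < xr[1] - raster$cell_size / 2 ||
      colony_xy[1] > xr[2] + raster$cell_size / 2 ||
      colony_xy[2] < yr[1] - raster$cell_size / 2 ||
      colony_xy[2] > yr[2] + raster$cell_size / 2)
    stop("colony lies outside the raster bounds")
  if (colony_xy[1] - radius_m < xr[1] || colony_xy[1] + radius_m > xr[2] ||
      colony_xy[2] - radius_m < yr[1] || colony_xy[2] + radius_m > yr[2])
    warning("buffer extends beyond the raster; availability is clipped")
  dx <- outer(rep(1, nrow(raster$class)), cc$x - colony_xy[1])
  dy <- outer(cc$y - colony_xy[2], rep(1, ncol(raster$class)))
  inside <- (dx^2 + dy^2) <= radius_m^2
  cls <- raster$class[inside]
  cls <- cls[!is.na(cls)]
  if (!length(cls)) stop("no habitat cells within the buffer")
  if (!is.null(class_map)) {
    unknown <- setdiff(unique(cls), names(class_map))
    if (length(unknown))
      stop("classes missing from class_map: ", paste(unknown, collapse = ", "))
    cls <- unname(class_map[cls])
  }
  tab <- table(cls)
  out <- data.frame(colony = colony, phase = raster$phase,
                    class = names(tab), cells = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$proportion <- out$cells / sum(out$cells)
  attr(out, "total_cells") <- sum(out$cells)
  class(out) <- c("availability_table", "data.frame")
  out
}

#' Phenological state of parcels in a given phase
#'
#' @param parcels A [parcel_table()].
#' @param phase Phase name.
#' @return Character vector: the recorded state for crop parcels,
#'   `"not_applicable"` for non-crop classes.
#' @export
phenology_state <- function(parcels, phase) {
  state <- parcels[[pheno_column(phase)]]
  state[!(parcels$class %in% crop_classes())] <- "not_applicable"
  state
}

#' Local azimuthal-equidistant projection
#'
#' Projects longitude/latitude onto a planar metric frame centred on a colony.
#' Over the few kilometres of a foraging buffer the distortion of the
#' spherical formula is negligible, and buffers and fixed offsets stay exact
#' in metres.
#'
#' @param lon,lat Coordinates in decimal degrees.
#' @param lon0,lat0 Projection centre in decimal degrees.
#' @param R Earth radius in metres.
#' @return `data.frame` with columns `x`, `y` in metres.
#' @export
project_local <- function(lon, lat, lon0, lat0, R = 6371008.8) {
  to_rad <- pi / 180
  lam <- lon * to_rad; phi <- lat * to_rad
  lam0 <- lon0 * to_rad; phi0 <- lat0 * to_rad
  cosc <- sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam - lam0)
  cosc <- pmin(1, pmax(-1, cosc))
  c_ang <- acos(cosc)
  k <- ifelse(c_ang < 1e-12, 1, c_ang / sin(c_ang))
  x <- R * k * cos(phi) * sin(lam - lam0)
  y <- R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam - lam0))
  data.frame(x = x, y = y)
}
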