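#' Default per-phase phenology transition table
#'
#' Probability that a parcel of each crop is vegetated / harvested / ploughed
#' in each breeding phase, emulating the seasonal dynamics of an intensively
#' cultivated plain: alfalfa is cut repeatedly so it alternates vegetated and
#' harvested all season; winter cereals (and the other autumn-sown,
#' non-irrigated crops) stand in late incubation and are fully harvested or
#' ploughed by late rearing; maize and other irrigated summer crops stay
#' vegetated throughout, growing taller as the season advances.
#'
#' @return Named list of 3x3 matrices (rows = phases, cols = states).
#' @export
default_phenology <- function() {
  mk <- function(...) {
    m <- matrix(c(...), nrow = 3, byrow = TRUE,
                dimnames = list(phase_names(), phenology_states()))
    stopifnot(all(abs(rowSums(m) - 1) < 1e-9))
    m
  }
  list(
    alfalfa             = mk(0.60, 0.40, 0.00,
                             0.50, 0.50, 0.00,
                             0.50, 0.50, 0.00),
    winter_cereals      = mk(0.90, 0.10, 0.00,
                             0.30, 0.50, 0.20,
                             0.00, 0.60, 0.40),
    other_non_irrigated = mk(0.90, 0.10, 0.00,
                             0.30, 0.50, 0.20,
                             0.00, 0.60, 0.40),
    maize               = mk(1, 0, 0,  1, 0, 0,  1, 0, 0),
    other_irrigated     = mk(1, 0, 0,  1, 0, 0,  1, 0, 0)
  )
}

#' Default true selection weights per phase
#'
#' Relative preference of the simulated forager for each habitat group, per
#' phase. The pattern follows the seasonal shift the analyses are designed to
#' detect: alfalfa and freshly sown maize early, winter cereals and other
#' non-irrigated crops after their harvest, urbanized areas and water always
#' avoided. Weights are relative; only ratios matter.
#'
#' @return 3 x 8 numeric matrix (phases x habitat groups).
#' @export
default_sel_weights <- function() {
  m <- rbind(
    late_incubation = c(2.0, 1.0, 1.0, 1.8, 0.8, 0.2, 0.5, 1.0),
    early_rearing   = c(2.0, 1.8, 1.8, 0.4, 0.5, 0.2, 0.3, 1.0),
    late_rearing    = c(0.5, 2.0, 2.0, 0.3, 0.5, 0.2, 0.3, 1.0)
  )
  colnames(m) <- habitat_groups()
  m
}

#' Default vegetation-height model
#'
#' Mean and standard deviation (cm) of a zero-truncated normal height per
#' crop, state and phase. The numbers are invented but respect the field
#' constraints: harvested stubble is always shorter than the standing crop of
#' the same type, ploughed ground is near zero, and maize grows from seedling
#' height early in the season to well above 2 m by late rearing.
#'
#' @return `data.frame` with columns `crop`, `state`, `phase`, `mean`, `sd`.
#' @export
default_height_model <- function() {
  phs <- phase_names()
  rows <- list()
  add <- function(crop, state, means, sds) {
    rows[[length(rows) + 1L]] <<- data.frame(
      crop = crop, state = state, phase = phs, mean = means, sd = sds,
      stringsAsFactors = FALSE)
  }
  for (cr in crop_classes()) {
    add(cr, "harvested", c(12, 12, 12), c(6, 6, 6))
    add(cr, "ploughed", c(2, 2, 2), c(2, 2, 2))
  }
  add("alfalfa", "vegetated", c(45, 45, 45), c(15, 15, 15))
  add("winter_cereals", "vegetated", c(75, 85, 90), c(15, 15, 15))
  add("other_non_irrigated", "vegetated", c(75, 85, 90), c(15, 15, 15))
  add("maize", "vegetated", c(30, 120, 220), c(15, 30, 30))
  add("other_irrigated", "vegetated", c(40, 70, 90), c(20, 25, 30))
  out <- do.call(rbind, rows)
  # overwrite crop-generic rows set above for states that only exist once
  out[!duplicated(out[c("crop", "state", "phase")], fromLast = TRUE), ]
}

#' Simulation configuration
#'
#' The stated world for the synthetic landscape, tracks and matched pairs:
#' ~10 ha rectangular fields tiling an 8 x 8 km scene, crop cover
#' proportions of an intensive agricultural plain (alfalfa 18%, winter
#' cereals 33%, other non-irrigated 3%, maize 8%, other irrigated 20%, the
#' remainder urbanized/water/semi-natural), per-phase phenology, GPS fixes at
#' 15-min cadence within a 3-km colony radius plus deliberate night roost
#' fixes, and 500-m random-angle paired controls whose foraging/control
#' labelling follows a conditional logistic law in vegetation height with
#' slope `beta_height` per cm.
#'
#' @param seed Integer master seed; every stream derives from it.
#' @param scene_size_m Square scene edge (default 8000).
#' @param field_dims_m Field width and height in metres (default
#'   `c(400, 250)`, i.e. 10 ha).
#' @param cell_size_m Raster resolution (default 40).
#' @param crop_mix Named proportions over the eight habitat groups.
#' @param phenology Transition table, see [default_phenology()].
#' @param sel_weights True selection weights, see [default_sel_weights()].
#' @param beta_height True conditional log-odds per cm of vegetation height
#'   (default -0.06: shorter vegetation preferred).
#' @param height_model See [default_height_model()].
#' @param start_date First tracking day (default `"2019-05-31"`).
#' @param n_days Tracking days (default 56, spanning all three phases).
#' @param cadence_min GPS cadence in minutes (default 15).
#' @param day_start,day_end First and last daytime fix times.
#' @param roost_times Night fix times (exercise the roost filter).
#' @param n_individuals Number of tracked birds (default 9).
#' @param colony_split Named number of individuals per colony (default
#'   `c(PR = 2, BA = 7)`).
#' @param n_pairs Matched pairs to draw (default 411).
#' @param control_distance_m Offset of the control point (default 500).
#' @param pair_phase Phase(s) whose landscapes the pairs are read from; each
#'   pair draws a date uniformly within one of these windows (default the
#'   first two phases, matching a May-June observation season).
#' @param foraging_radius_m Colony foraging radius (default 3000).
#' @param movement `"iid"` (memoryless, matching the estimators'
#'   assumptions) or `"markov"` (first-order distance kernel, for robustness
#'   experiments only).
#' @param movement_scale_m Step-length scale of the markov kernel.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       scene_size_m = 8000,
                       field_dims_m = c(400, 250),
                       cell_size_m = 40,
                       crop_mix = c(alfalfa = 0.18, winter_cereals = 0.33,
                                    other_non_irrigated = 0.03, maize = 0.08,
                                    other_irrigated = 0.20, urbanized = 0.10,
                                    water = 0.03, other_seminatural = 0.05),
                       phenology = default_phenology(),
                       sel_weights = default_sel_weights(),
                       beta_height = -0.06,
                       height_model = default_height_model(),
                       start_date = "2019-05-31",
                       n_days = 56,
                       cadence_min = 15,
                       day_start = "06:15",
                       day_end = "19:45",
                       roost_times = c("20:30", "22:00", "03:00", "05:30"),
                       n_individuals = 9,
                       colony_split = c(PR = 2, BA = 7),
                       n_pairs = 411,
                       control_distance_m = 500,
                       pair_phase = c("late_incubation", "early_rearing"),
                       foraging_radius_m = 3000,
                       movement = c("iid", "markov"),
                       movement_scale_m = 800) {
  stopifnot(abs(sum(crop_mix) - 1) < 1e-9,
            all(names(crop_mix) %in% habitat_groups()))
  movement <- match.arg(movement)
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# run expr under a derived RNG stream, restoring global state afterwards
with_sim_seed <- function(seed, offset, expr) {
  stopifnot(seed + offset < 2^31)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed + offset))
  force(expr)
}

#' Default colony table for a simulated scene
#'
#' Two colonies near the scene centre, far enough from the edges that their
#' 3-km buffers stay inside the scene.
#'
#' @param config A [sim_config()].
#' @return `data.frame` with `colony_id`, `x`, `y`.
#' @export
sim_colonies <- function(config) {
  c0 <- config$scene_size_m / 2
  data.frame(colony_id = names(config$colony_split),
             x = c0 + c(-500, 500)[seq_along(config$colony_split)],
             y = c0, stringsAsFactors = FALSE)
}

#' Simulate the parcel mosaic
#'
#' Rectangular fields of the configured size tile the scene; crop types are
#' drawn i.i.d. from the crop mix and a phenological state per phase from the
#' crop's transition row.
#'
#' @param config A [sim_config()].
#' @return A [parcel_table()] with phenology for all three phases.
#' @export
simulate_landscape <- function(config = sim_config()) {
  s <- config$scene_size_m
  if (s < 2 * config$foraging_radius_m)
    stop("scene too small to contain the foraging buffer")
  fw <- config$field_dims_m[1]; fh <- config$field_dims_m[2]
  nx <- ceiling(s / fw); ny <- ceiling(s / fh)
  with_sim_seed(config$seed, 0, {
    n <- nx * ny
    cls <- sample(names(config$crop_mix), n, replace = TRUE,
                  prob = config$crop_mix)
    pheno <- matrix(NA_character_, n, 3)
    for (cr in names(config$phenology)) {
      idx <- which(cls == cr)
      if (!length(idx)) next
      for (p in 1:3) {
        pheno[idx, p] <- sample(phenology_states(), length(idx),
                                replace = TRUE,
                                prob = config$phenology[[cr]][p, ])
      }
    }
    geom <- vector("list", n)
    k <- 0L
    for (iy in seq_len(ny)) for (ix in seq_len(nx)) {
      k <- k + 1L
      x0 <- (ix - 1) * fw; y0 <- (iy - 1) * fh
      geom[[k]] <- cbind(c(x0, x0 + fw, x0 + fw, x0),
                         c(y0, y0, y0 + fh, y0 + fh))
    }
    parcel_table(seq_len(n), cls, geom,
                 pheno_p1 = pheno[, 1], pheno_p2 = pheno[, 2],
                 pheno_p3 = pheno[, 3])
  })
}

#' Rasterize a simulated landscape for every phase
#'
#' @param parcels A [parcel_table()].
#' @param config A [sim_config()].
#' @return Named list of `habitat_raster` objects, one per phase.
#' @export
phase_rasters <- function(parcels, config = sim_config()) {
  bounds <- c(0, 0, config$scene_size_m, config$scene_size_m)
  out <- lapply(phase_names(), function(ph)
    rasterize_parcels(parcels, ph, config$cell_size_m, bounds))
  names(out) <- phase_names()
  out
}

#' Simulate GPS tracks of central-place foragers
#'
#' For each individual and each daytime slot a fix is placed in a raster cell
#' drawn with probability proportional to the phase's true selection weight
#' of the cell's habitat, among cells within the foraging radius of the
#' bird's colony; position within the cell is uniform. Night slots emit
#' roost fixes within 30 m of the colony, which the preparation filters must
#' remove. Daytime sampling is memoryless by default so the use counts are
#' independent draws, matching what the selection-ratio machinery assumes.
#'
#' @param rasters Output of [phase_rasters()].
#' @param config A [sim_config()].
#' @param colonies Colony table (default [sim_colonies()]).
#' @return `data.frame` of fixes: `individual_id`, `colony_id`, `timestamp`,
#'   `x`, `y`.
#' @export
simulate_tracks <- function(rasters, config = sim_config(),
                            colonies = sim_colonies(config)) {
  split <- config$colony_split
  ids <- sprintf("bird_%02d", seq_len(config$n_individuals))
  col_of <- rep(names(split), split)[seq_len(config$n_individuals)]
  dates <- as.Date(config$start_date) + seq_len(config$n_days) - 1
  phases <- assign_phase(dates)
  slots <- seq(hhmm_to_min(config$day_start), hhmm_to_min(config$day_end),
               by = config$cadence_min)
  roost_min <- vapply(config$roost_times, hhmm_to_min, numeric(1))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    cxy <- unlist(colonies[match(col_of[i], colonies$colony_id), c("x", "y")])
    fixes_i <- with_sim_seed(config$seed, 1000 + i, {
      per_phase <- lapply(phase_names(), function(ph) {
        nd <- sum(phases == ph, na.rm = TRUE)
        if (nd == 0) return(NULL)
        r <- rasters[[ph]]
        cc <- raster_cell_centres(r)
        dx <- outer(rep(1, nrow(r$class)), cc$x - cxy[1])
        dy <- outer(cc$y - cxy[2], rep(1, ncol(r$class)))
        ok <- which((dx^2 + dy^2) <= config$foraging_radius_m^2 &
                      !is.na(r$class))
        wts <- config$sel_weights[ph, r$class[ok]]
        if (all(wts == 0)) stop("all selection weights zero in phase ", ph)
        nfix <- nd * length(slots)
        cell <- if (config$movement == "iid") {
          sample(seq_along(ok), nfix, replace = TRUE, prob = wts)
        } else {
          markov_cells(ok, wts, r, nfix, config$movement_scale_m)
        }
        rows <- (ok[cell] - 1) %% nrow(r$class) + 1
        cols <- (ok[cell] - 1) %/% nrow(r$class) + 1
        cs <- r$cell_size
        x <- r$origin[1] + (cols - 1) * cs + stats::runif(nfix, 0, cs)
        y <- r$origin[2] + (rows - 1) * cs + stats::runif(nfix, 0, cs)
        day <- rep(dates[which(phases == ph)], each = length(slots))
        tod <- rep(slots, times = nd)
        data.frame(day = day, minute = tod, x = x, y = y)
      })
      day_fixes <- do.call(rbind, per_phase)
      nro <- length(dates) * length(roost_min)
      ang <- stats::runif(nro, 0, 2 * pi)
      rad <- stats::runif(nro, 0, 30)
      roost <- data.frame(day = rep(dates, each = length(roost_min)),
                          minute = rep(roost_min, times = length(dates)),
                          x = cxy[1] + rad * cos(ang),
                          y = cxy[2] + rad * sin(ang))
      rbind(day_fixes, roost)
    })
    fixes_i$individual_id <- ids[i]
    fixes_i$colony_id <- col_of[i]
    out[[i]] <- fixes_i
  }
  all <- do.call(rbind, out)
  all$timestamp <- as.POSIXct(all$day, tz = "UTC") + all$minute * 60
  all <- all[order(all$individual_id, all$timestamp), ]
  rownames(all) <- NULL
  all[, c("individual_id", "colony_id", "timestamp", "x", "y")]
}

# first-order kernel: next cell weighted by habitat weight times a
# distance decay from the previous cell
markov_cells <- function(ok, wts, r, nfix, scale_m) {
  nr <- nrow(r$class)
  cs <- r$cell_size
  cx <- ((ok - 1) %/% nr + 0.5) * cs
  cy <- ((ok - 1) %% nr + 0.5) * cs
  cell <- integer(nfix)
  cell[1] <- sample(seq_along(ok), 1, prob = wts)
  for (t in 2:nfix) {
    d <- sqrt((cx - cx[cell[t - 1]])^2 + (cy - cy[cell[t - 1]])^2)
    cell[t] <- sample(seq_along(ok), 1, prob = wts * exp(-d / scale_m))
  }
  cell
}

rtrunc_norm <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

#' Simulate matched foraging/control pairs
#'
#' Draws a candidate point uniformly within the foraging radius of a colony
#' and a second point 500 m away at a uniform random angle, keeps the draw
#' only if both points fall on one of the five crop classes (the field
#' protocol avoided urban areas, roads and orchards), reads vegetation
#' structure from the parcel's phenology and vegetation height from the
#' crop-by-state truncated-normal model, then labels one member "forage"
#' with probability `exp(b*h1) / (exp(b*h1) + exp(b*h2))` where `b` is
#' `beta_height`. That labelling law is the exact generative dual of the 1:1
#' conditional logistic likelihood, so the fitted slope is consistent for
#' `beta_height` by construction.
#'
#' @param rasters Output of [phase_rasters()].
#' @param config A [sim_config()].
#' @param colonies Colony table (default [sim_colonies()]).
#' @param n_pairs Number of pairs (default `config$n_pairs`).
#' @return Long `data.frame`: `pair_id`, `role`, `colony`, `date`, `x`, `y`,
#'   `veg_height_cm`, `structure`, `crop`.
#' @export
simulate_pairs <- function(rasters, config = sim_config(),
                           colonies = sim_colonies(config),
                           n_pairs = config$n_pairs) {
  phs <- config$pair_phase
  if (any(!phs %in% names(rasters)))
    stop("no raster for phase(s) ",
         paste(setdiff(phs, names(rasters)), collapse = ", "))
  hm <- config$height_model
  hkey <- paste(hm$crop, hm$state, hm$phase)
  phase_tab <- breeding_phases()
  with_sim_seed(config$seed, 2000, {
    acc <- list(); n_acc <- 0L
    guard <- 0L
    while (n_acc < n_pairs) {
      guard <- guard + 1L
      if (guard > 200L) stop("pair acceptance rate too low; check landscape")
      m <- 4L * (n_pairs - n_acc) + 20L
      ph_i <- sample(phs, m, replace = TRUE)
      ci <- sample(nrow(colonies), m, replace = TRUE)
      ang0 <- stats::runif(m, 0, 2 * pi)
      rad <- config$foraging_radius_m * sqrt(stats::runif(m))
      x1 <- colonies$x[ci] + rad * cos(ang0)
      y1 <- colonies$y[ci] + rad * sin(ang0)
      ang <- stats::runif(m, 0, 2 * pi)
      x2 <- x1 + config$control_distance_m * sin(ang)   # north = 0 deg
      y2 <- y1 + config$control_distance_m * cos(ang)
      c1 <- s1 <- c2 <- s2 <- rep(NA_character_, m)
      for (ph in unique(ph_i)) {
        r <- rasters[[ph]]
        sel <- ph_i == ph
        c1[sel] <- raster_class_at(r, x1[sel], y1[sel])
        c2[sel] <- raster_class_at(r, x2[sel], y2[sel])
        i1 <- raster_cell_index(r, x1[sel], y1[sel])
        i2 <- raster_cell_index(r, x2[sel], y2[sel])
        ok1 <- !is.na(i1$row); ok2 <- !is.na(i2$row)
        s1[sel][ok1] <- r$pheno[cbind(i1$row[ok1], i1$col[ok1])]
        s2[sel][ok2] <- r$pheno[cbind(i2$row[ok2], i2$col[ok2])]
      }
      keep <- c1 %in% crop_classes() & c2 %in% crop_classes()
      if (!any(keep)) next
      k1 <- match(paste(c1[keep], s1[keep], ph_i[keep]), hkey)
      k2 <- match(paste(c2[keep], s2[keep], ph_i[keep]), hkey)
      h1 <- rtrunc_norm(sum(keep), hm$mean[k1], hm$sd[k1])
      h2 <- rtrunc_norm(sum(keep), hm$mean[k2], hm$sd[k2])
      p1_forage <- stats::plogis(config$beta_height * (h1 - h2))
      first_is_forage <- stats::runif(sum(keep)) < p1_forage
      batch <- data.frame(colony = colonies$colony_id[ci[keep]],
                          phase = ph_i[keep],
                          x1 = x1[keep], y1 = y1[keep],
                          x2 = x2[keep], y2 = y2[keep],
                          c1 = c1[keep], c2 = c2[keep],
                          s1 = s1[keep], s2 = s2[keep],
                          h1 = h1, h2 = h2, fwd = first_is_forage,
                          stringsAsFactors = FALSE)
      acc[[length(acc) + 1L]] <- batch
      n_acc <- n_acc + nrow(batch)
    }
    w <- do.call(rbind, acc)[seq_len(n_pairs), ]
    pr <- phase_tab[match(w$phase, phase_tab$phase), ]
    span <- as.integer(pr$end - pr$start) + 1L
    dates <- pr$start +
      floor(stats::runif(n_pairs) * span)
    long <- function(role_first) {
      pick <- function(a, b) ifelse(w$fwd == role_first, a, b)
      data.frame(pair_id = sprintf("pair_%04d", seq_len(n_pairs)),
                 role = if (role_first) "forage" else "control",
                 colony = w$colony, date = dates,
                 x = pick(w$x1, w$x2), y = pick(w$y1, w$y2),
                 veg_height_cm = round(pick(w$h1, w$h2), 1),
                 structure = pick(w$s1, w$s2),
                 crop = pick(w$c1, w$c2), stringsAsFactors = FALSE)
    }
    out <- rbind(long(TRUE), long(FALSE))
    out <- out[order(out$pair_id, out$role == "control"), ]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a complete study
#'
#' Landscape, per-phase rasters, GPS tracks and matched pairs from one
#' configuration, together with the truth record (the generating parameters)
#' needed to verify recovery.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_output`: `parcels`, `rasters`, `colonies`,
#'   `tracks`, `pairs`, `truth`.
#' @export
simulate_study <- function(config = sim_config()) {
  parcels <- simulate_landscape(config)
  rasters <- phase_rasters(parcels, config)
  colonies <- sim_colonies(config)
  tracks <- simulate_tracks(rasters, config, colonies)
  pairs <- simulate_pairs(rasters, config, colonies)
  truth <- list(sel_weights = config$sel_weights,
                beta_height = config$beta_height,
                crop_mix = config$crop_mix,
                phenology = config$phenology,
                height_model = config$height_model,
                seed = config$seed)
  structure(list(parcels = parcels, rasters = rasters, colonies = colonies,
                 tracks = tracks, pairs = pairs, truth = truth,
                 config = config),
            class = "sim_output")
}

#' True population selection ratio implied by preference weights
#'
#' Under cell sampling with probability proportional to `w*_k`, the expected
#' used proportion of class k is `w*_k a_k / sum_j w*_j a_j`, so the
#' selection ratio converges to `w*_k / sum_j w*_j (a_j / A)`: the weight
#' renormalised by the availability-weighted mean weight.
#'
#' @param weights Named true weights over habitat groups.
#' @param avail An [availability()] table.
#' @return Named numeric vector of expected selection ratios per class.
#' @export
true_selection_ratio <- function(weights, avail) {
  w <- weights[avail$class]
  denom <- sum(w * avail$proportion)
  stats::setNames(w / denom, avail$class)
}
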