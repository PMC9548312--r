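# Independent oracles used across test files. Each deliberately takes a
# different computational route from the package implementation.

# Angle-summation (winding) point-in-polygon: independent of the package's
# even-odd ray casting.
pip_winding <- function(px, py, poly) {
  if (isTRUE(all.equal(poly[1, ], poly[nrow(poly), ], check.attributes = FALSE)))
    poly <- poly[-nrow(poly), , drop = FALSE]
  vapply(seq_along(px), function(i) {
    vx <- poly[, 1] - px[i]
    vy <- poly[, 2] - py[i]
    ang <- atan2(vy, vx)
    d <- diff(c(ang, ang[1]))
    d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
    abs(sum(d)) > pi
  }, logical(1))
}

# Koopman CI by brute-force grid: single-term bracket form of the score
# statistic (different algebra from the package's two-term form), scanned on
# a 1e-4 log-scale grid for sign changes against the chi-square quantile.
koopman_ci_grid <- function(x1, n1, x2, n2, conf = 0.95, span = 8) {
  crit <- qchisq(conf, df = 1)
  stat <- function(phi) {
    b <- phi * (n1 + x2) + x1 + n2
    p1 <- (b - sqrt(pmax(b^2 - 4 * phi * (n1 + n2) * (x1 + x2), 0))) /
      (2 * (n1 + n2))
    p1 <- pmin(pmax(p1, 1e-12), 1 - 1e-12)
    (x1 - n1 * p1)^2 / (n1 * p1 * (1 - p1)) *
      (1 + (n1 * (phi - p1)) / (n2 * (1 - p1)))
  }
  centre <- if (x1 > 0) log((x1 / n1) / (x2 / n2)) else
    log(((x1 + 0.5) / (n1 + 1)) / (x2 / n2))
  lphi <- seq(centre - span, centre + span, by = 1e-4)
  above <- stat(exp(lphi)) > crit
  flips <- which(diff(above) != 0)
  roots <- exp((lphi[flips] + lphi[flips + 1L]) / 2)
  lo <- if (x1 == 0) 0 else min(roots)
  hi <- if (length(roots) >= (if (x1 == 0) 1 else 2)) max(roots) else Inf
  c(lo = lo, hi = hi)
}

# Dense grid-search maximiser of the matched-pair conditional likelihood for
# a single continuous predictor.
clogit_grid <- function(d, lo = -1, hi = 1, step = 1e-5) {
  beta <- seq(lo, hi, by = step)
  eta <- outer(beta, d)
  ll <- rowSums(eta - log1p(exp(eta)))
  list(beta = beta[which.max(ll)], loglik = max(ll))
}

# Shared small simulated study (built once per test run).
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 42, n_days = 14, n_individuals = 3,
                        n_pairs = 150)
      cache <<- simulate_study(cfg)
    }
    cache
  }
})

# Random matched-pair difference fixtures for equivalence checks.
random_pairs <- function(n, beta = -0.05, seed = 1) {
  set.seed(seed)
  h_c <- rgamma(n, shape = 4, scale = 15)
  h_f <- rgamma(n, shape = 4, scale = 6)
  swap <- runif(n) > plogis(beta * (h_f - h_c))
  hf <- ifelse(swap, h_c, h_f); hc <- ifelse(swap, h_f, h_c)
  data.frame(pair_id = rep(sprintf("p%03d", seq_len(n)), 2),
             role = rep(c("forage", "control"), each = n),
             veg_height_cm = c(hf, hc), stringsAsFactors = FALSE)
}

# Parcel fixture helper: crops get a constant vegetated phenology.
mk_parcels <- function(ids, classes, geoms) {
  crop <- classes %in% crop_classes()
  st <- ifelse(crop, "vegetated", NA)
  parcel_table(ids, classes, geoms, st, st, st)
}
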