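#' Manly selection ratio
#'
#' Ratio of the used proportion of a habitat class to its available
#' proportion: `w = (u/N) / (a/A)`. Values above 1 indicate preference,
#' below 1 avoidance, 1 use proportional to availability.
#'
#' @param u Used locations in the class.
#' @param N Total used locations.
#' @param a Available cells of the class.
#' @param A Total available cells.
#' @return Numeric selection ratio.
#' @export
selection_ratio <- function(u, N, a, A) {
  stopifnot(N > 0, A > 0)
  if (any(a == 0 & u > 0))
    stop("used class with zero availability: ratio undefined")
  (u / N) / (a / A)
}

# Koopman's constrained MLE of p1 under p1 = phi * p2, and the score
# statistic for H0: p1/p2 = phi. The statistic is asymptotically
# chi-square(1); the CI inverts it at the conf-level quantile.
koopman_p1_tilde <- function(phi, x1, n1, x2, n2) {
  b <- phi * (n1 + x2) + x1 + n2
  disc <- b^2 - 4 * phi * (n1 + n2) * (x1 + x2)
  disc <- pmax(disc, 0)
  (b - sqrt(disc)) / (2 * (n1 + n2))
}

#' Koopman score statistic for a ratio of binomial proportions
#'
#' @param phi Hypothesised ratio `p1/p2` (> 0).
#' @param x1,n1 Successes and trials of the numerator proportion.
#' @param x2,n2 Successes and trials of the denominator proportion.
#' @return The score chi-square statistic (1 df) at `phi`.
#' @export
koopman_score_stat <- function(phi, x1, n1, x2, n2) {
  p1t <- koopman_p1_tilde(phi, x1, n1, x2, n2)
  p1t <- pmin(pmax(p1t, 1e-12), 1 - 1e-12)
  p2t <- pmin(pmax(p1t / phi, 1e-12), 1 - 1e-12)
  (x1 - n1 * p1t)^2 / (n1 * p1t * (1 - p1t)) +
    (x2 - n2 * p2t)^2 / (n2 * p2t * (1 - p2t))
}

#' Koopman score confidence interval for p1/p2
#'
#' Score-method interval for the ratio of two binomial proportions, found by
#' locating the values of the ratio where the score statistic (with
#' constrained maximum-likelihood nuisance estimates) crosses the
#' chi-square(1) quantile. `x1 = 0` gives a lower bound of 0; a bound the
#' root search cannot bracket within a very wide range is reported as `Inf`.
#'
#' @param x1,n1,x2,n2 Binomial counts, `0 <= x1 <= n1`, `0 <= x2 <= n2`.
#' @param conf Confidence level in (0, 1), default 0.95.
#' @return Numeric `c(lo, hi)` with attribute `estimate` (the point ratio).
#' @export
koopman_ci <- function(x1, n1, x2, n2, conf = 0.95) {
  stopifnot(n1 > 0, n2 > 0, x1 >= 0, x1 <= n1, x2 >= 0, x2 <= n2,
            conf > 0, conf < 1)
  crit <- stats::qchisq(conf, df = 1)
  f <- function(lphi) koopman_score_stat(exp(lphi), x1, n1, x2, n2) - crit
  est <- if (x2 > 0) (x1 / n1) / (x2 / n2) else Inf
  # anchor the search at a ratio where the statistic is at its minimum
  anchor <- if (x1 > 0 && x2 > 0) log(est) else
    log(((x1 + 0.5) / (n1 + 1)) / ((x2 + 0.5) / (n2 + 1)))
  search_out <- function(dir) {
    step <- 0.5
    repeat {
      hi <- anchor + dir * step
      if (f(hi) > 0)
        return(stats::uniroot(f, sort(c(anchor, hi)), tol = 1e-10)$root)
      step <- step * 2
      if (step > 60) return(dir * Inf)
    }
  }
  lo <- if (x1 == 0) 0 else exp(search_out(-1))
  hi <- if (x1 == n1 && x2 == 0) Inf else {
    h <- search_out(+1)
    if (is.finite(h)) exp(h) else Inf
  }
  structure(c(lo = lo, hi = hi), estimate = est, conf = conf)
}

#' Per-individual selection ratios with score intervals and weights
#'
#' Joins use counts to availability, computes the Manly selection ratio per
#' individual x phase x class, attaches the Koopman score interval comparing
#' the binomial use count (`u` of `N`) with the pseudo-binomial availability
#' count (`a` of `A` raster cells), and the precision weight
#' `1 / (hi - lo)` used by the population model. Classes with fewer than
#' `min_use` used locations are flagged (`min_use_ok = FALSE`) and excluded
#' from model input downstream; an unbounded interval gets a capped length of
#' `cap_factor` times the point estimate so its weight stays finite.
#'
#' @param use Use counts from [use_table()].
#' @param avail An [availability()] table or a row-bound set of them covering
#'   every colony x phase in `use`.
#' @param min_use Minimum used locations per class (default 5).
#' @param conf Confidence level (default 0.95).
#' @param cap_factor Cap on the CI length, in units of the point estimate,
#'   applied when a bound is infinite (default 10).
#' @return `data.frame` of class `selection_ratio_table` with columns
#'   `individual`, `colony`, `phase`, `class`, `u`, `N`, `a`, `A`, `ratio`,
#'   `lo`, `hi`, `weight`, `min_use_ok`.
#' @export
selection_ratio_table <- function(use, avail, min_use = 5, conf = 0.95,
                                  cap_factor = 10) {
  totals <- stats::aggregate(list(A = avail$cells),
                             by = list(colony = avail$colony,
                                       phase = avail$phase), FUN = sum)
  key <- function(d) paste(d$colony, d$phase, d$class, sep = "\r")
  ai <- match(key(use), key(avail))
  if (anyNA(ai)) {
    bad <- unique(use$class[is.na(ai)])
    stop("no availability for used class(es): ", paste(bad, collapse = ", "))
  }
  out <- use
  out$a <- avail$cells[ai]
  ti <- match(paste(use$colony, use$phase), paste(totals$colony, totals$phase))
  out$A <- totals$A[ti]
  out$ratio <- selection_ratio(out$u, out$N, out$a, out$A)
  cis <- t(vapply(seq_len(nrow(out)), function(i)
    as.numeric(koopman_ci(out$u[i], out$N[i], out$a[i], out$A[i], conf)),
    numeric(2)))
  out$lo <- cis[, 1]; out$hi <- cis[, 2]
  len <- out$hi - out$lo
  capped <- !is.finite(len)
  len[capped] <- cap_factor * out$ratio[capped]
  out$weight <- 1 / len
  out$min_use_ok <- out$u >= min_use
  if (any(capped))
    message(sum(capped), " interval(s) unbounded; weight from capped length")
  class(out) <- c("selection_ratio_table", "data.frame")
  out
}

#' @export
print.selection_ratio_table <- function(x, ...) {
  cat(sprintf("selection ratios: %d rows, %d individuals, %d phase(s)\n",
              nrow(x), length(unique(x$individual)),
              length(unique(x$phase))))
  print.data.frame(utils::head(as.data.frame(x), 10), digits = 3)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
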