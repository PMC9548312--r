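#' Conditional logistic regression for 1:1 matched pairs
#'
#' Third-order selection compares each observed foraging location with a
#' control location 500 m away in a random direction, pair by pair. With 1:1
#' matching the conditional likelihood depends only on within-pair covariate
#' differences: it equals a no-intercept binary logistic regression on
#' `x_forage - x_control` with every outcome set to 1. The fit maximises
#'
#'   sum_i [ beta' d_i - log(1 + exp(beta' d_i)) ]
#'
#' by Newton-Raphson with step-halving. Pairs with tied covariates contribute
#' `log(1/2)` each and carry no information about `beta`; the null
#' log-likelihood is `n_pairs * log(1/2)`.
#'
#' Three separate models are supported, mirroring the field covariates:
#' vegetation height (continuous, cm), vegetation structure (3-level factor)
#' and crop type (5-level factor). They are never combined: height is not
#' independent of structure or crop, so each model answers its own question.
#'
#' @param pairs Long-format pair table: columns `pair_id`, `role`
#'   (`"forage"`/`"control"`, case-insensitive), `veg_height_cm`,
#'   `structure`, `crop` (see [read_pairs()]); extra columns are ignored.
#' @param model `"height"`, `"structure"` or `"crop"`.
#' @param reference Reference level for categorical models (default
#'   `"vegetated"` for structure, `"alfalfa"` for crop).
#' @param crop_subset For the crop model: `"all"` (default) keeps every pair
#'   where both members carry a valid crop label; `"vegetated"` additionally
#'   requires both members vegetated.
#' @return Object of class `pair_clogit` with coefficients, covariance,
#'   log-likelihoods, pseudo R-squared and flags.
#' @export
fit_pair_clogit <- function(pairs, model = c("height", "structure", "crop"),
                            reference = NULL,
                            crop_subset = c("all", "vegetated")) {
  model <- match.arg(model)
  crop_subset <- match.arg(crop_subset)
  w <- pairs_to_wide(pairs)
  if (model == "height") {
    keep <- !is.na(w$h_f) & !is.na(w$h_c)
    D <- cbind(veg_height_cm = w$h_f[keep] - w$h_c[keep])
    levels_used <- NULL
  } else if (model == "structure") {
    if (is.null(reference)) reference <- "vegetated"
    keep <- w$s_f %in% phenology_states() & w$s_c %in% phenology_states()
    levs <- c(reference, setdiff(phenology_states(), reference))
    D <- dummy_diff(w$s_f[keep], w$s_c[keep], levs)
    levels_used <- levs
  } else {
    if (is.null(reference)) reference <- "alfalfa"
    keep <- w$c_f %in% crop_classes() & w$c_c %in% crop_classes()
    if (crop_subset == "vegetated")
      keep <- keep & w$s_f == "vegetated" & w$s_c == "vegetated"
    levs <- c(reference, setdiff(crop_classes(), reference))
    D <- dummy_diff(w$c_f[keep], w$c_c[keep], levs)
    levels_used <- levs
  }
  if (!any(keep)) stop("no usable pairs for model '", model, "'")
  empty <- colSums(D != 0) == 0L
  dropped_levels <- colnames(D)[empty]
  if (any(empty)) {
    if (all(empty)) dropped_levels <- character(0)   # zero-information fit
    else D <- D[, !empty, drop = FALSE]
  }
  if (!is.null(levels_used)) levels_used <- c(reference, colnames(D))
  nr <- clogit_newton(D)
  n_pairs <- nrow(D)
  ll_null <- n_pairs * log(0.5)
  r2 <- max(0, min(1 - nr$loglik / ll_null, 1 - 1e-12))
  structure(list(model = model, coefficients = nr$beta, vcov = nr$vcov,
                 loglik = nr$loglik, loglik_null = ll_null,
                 pseudo_r2 = r2, n_pairs = n_pairs,
                 n_informative = nr$n_informative,
                 converged = nr$converged, separation = nr$separation,
                 zero_information = nr$zero_information,
                 levels = levels_used, reference = reference,
                 dropped_levels = if (model == "height") NULL else
                   dropped_levels,
                 differences = D),
            class = "pair_clogit")
}

# long (pair_id, role, ...) -> one row per pair with forage/control columns
pairs_to_wide <- function(pairs) {
  role <- tolower(trimws(pairs$role))
  role[role %in% c("forage", "foraging", "f")] <- "forage"
  role[role %in% c("control", "c")] <- "control"
  if (!all(role %in% c("forage", "control")))
    stop("unrecognised role labels: ",
         paste(unique(pairs$role[!role %in% c("forage", "control")]),
               collapse = ", "))
  ids <- unique(pairs$pair_id)
  fi <- match(paste(ids, "forage"), paste(pairs$pair_id, role))
  ci <- match(paste(ids, "control"), paste(pairs$pair_id, role))
  bad <- ids[is.na(fi) | is.na(ci)]
  if (length(bad))
    stop("pair id(s) without exactly one forage and one control member: ",
         paste(utils::head(bad, 5), collapse = ", "))
  counts <- table(pairs$pair_id)
  if (any(counts != 2L))
    stop("pair id(s) appearing other than twice: ",
         paste(utils::head(names(counts)[counts != 2L], 5), collapse = ", "))
  hc <- function(col, idx) if (col %in% names(pairs)) pairs[[col]][idx] else NA
  data.frame(pair_id = ids,
             h_f = hc("veg_height_cm", fi), h_c = hc("veg_height_cm", ci),
             s_f = as.character(hc("structure", fi)),
             s_c = as.character(hc("structure", ci)),
             c_f = as.character(hc("crop", fi)),
             c_c = as.character(hc("crop", ci)),
             stringsAsFactors = FALSE)
}

dummy_diff <- function(f_lab, c_lab, levels) {
  mk <- function(lab) {
    m <- matrix(0, length(lab), length(levels) - 1L,
                dimnames = list(NULL, levels[-1]))
    for (j in seq_along(levels[-1])) m[, j] <- as.numeric(lab == levels[j + 1L])
    m
  }
  mk(f_lab) - mk(c_lab)
}

# Newton-Raphson for the no-intercept difference-logistic likelihood.
clogit_newton <- function(D, tol = 1e-10, max_iter = 50, sep_bound = 15) {
  D <- as.matrix(D)
  p <- ncol(D)
  informative <- rowSums(D != 0) > 0
  n_inf <- sum(informative)
  if (n_inf == 0L) {
    return(list(beta = stats::setNames(rep(0, p), colnames(D)),
                vcov = matrix(NA_real_, p, p, dimnames = list(colnames(D),
                                                              colnames(D))),
                loglik = nrow(D) * log(0.5), converged = TRUE,
                separation = FALSE, zero_information = TRUE,
                n_informative = 0L))
  }
  beta <- rep(0, p)
  ll <- function(b) {
    eta <- drop(D %*% b)
    sum(eta - log1p(exp(eta)))
  }
  ll_old <- ll(beta)
  converged <- FALSE
  separation <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(D %*% beta)
    mu <- stats::plogis(eta)
    grad <- drop(crossprod(D, 1 - mu))
    W <- mu * (1 - mu)
    H <- crossprod(D * sqrt(W))
    step <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(step)) { separation <- TRUE; break }
    new_beta <- beta + step
    ll_new <- ll(new_beta)
    halvings <- 0L
    while (ll_new < ll_old && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      ll_new <- ll(new_beta)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    if (max(abs(beta)) > sep_bound) { separation <- TRUE; break }
    if (abs(ll_new - ll_old) < tol) { ll_old <- ll_new; converged <- TRUE; break }
    ll_old <- ll_new
  }
  eta <- drop(D %*% beta)
  mu <- stats::plogis(eta)
  # complete separation: the conditional likelihood approaches its supremum
  # (every informative pair fitted with probability ~1) while the maximiser
  # runs to infinity
  if (!separation && min(mu[informative]) > 0.999)
    separation <- TRUE
  H <- crossprod(D * sqrt(mu * (1 - mu)))
  V <- tryCatch(solve(H), error = function(e)
    matrix(NA_real_, p, p))
  dimnames(V) <- list(colnames(D), colnames(D))
  list(beta = stats::setNames(beta, colnames(D)), vcov = V,
       loglik = ll_old, converged = converged && !separation,
       separation = separation, zero_information = FALSE,
       n_informative = n_inf)
}

#' @export
coef.pair_clogit <- function(object, ...) object$coefficients

#' @export
vcov.pair_clogit <- function(object, ...) object$vcov

#' @export
logLik.pair_clogit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients),
            nobs = object$n_pairs, class = "logLik")
}

#' @export
print.pair_clogit <- function(x, ...) {
  cat(sprintf("Matched-pair conditional logistic model (%s)\n", x$model))
  cat(sprintf("  pairs: %d (informative: %d)\n", x$n_pairs, x$n_informative))
  se <- sqrt(diag(x$vcov))
  tab <- data.frame(estimate = x$coefficients, se = se,
                    z = x$coefficients / se)
  print(round(tab, 4))
  cat(sprintf("  logLik: %.3f (null %.3f), McFadden pseudo-R2: %.3f\n",
              x$loglik, x$loglik_null, x$pseudo_r2))
  if (x$separation)
    cat("  WARNING: separation detected; estimates diverge to infinity\n")
  if (x$zero_information)
    cat("  note: no informative pairs; coefficients fixed at 0\n")
  invisible(x)
}

#' @export
summary.pair_clogit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  z <- object$coefficients / se
  tab <- data.frame(estimate = object$coefficients, se = se, z = z,
                    p = 2 * stats::pnorm(-abs(z)))
  out <- list(model = object$model, coefficients = tab,
              pseudo_r2 = object$pseudo_r2, n_pairs = object$n_pairs)
  if (!is.null(object$levels)) out$wald <- factor_wald(object)
  out
}

#' Joint Wald chi-square test of a categorical predictor
#'
#' Tests that all dummy coefficients of the factor are zero; df = number of
#' levels minus one.
#'
#' @param object A categorical `pair_clogit` fit.
#' @return List with `chi2`, `df`, `p`.
#' @export
factor_wald <- function(object) {
  if (is.null(object$levels))
    stop("factor test requires a categorical model")
  b <- object$coefficients
  V <- object$vcov
  chi2 <- drop(t(b) %*% solve(V, b))
  df <- length(b)
  list(chi2 = chi2, df = df, p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' All pairwise level contrasts of a categorical matched-pair model
#'
#' For every pair of factor levels reports the log-odds of the second level
#' relative to the first ("A vs. B" is the coefficient B would get with A as
#' the reference), with delta-rule standard errors from the coefficient
#' covariance. Equivalent to refitting with each level as reference.
#'
#' @param object A categorical `pair_clogit` fit.
#' @return `data.frame`: `contrast`, `estimate`, `se`, `z`, `p`.
#' @export
pairwise_contrasts <- function(object) {
  if (is.null(object$levels))
    stop("contrasts require a categorical model")
  levs <- object$levels
  b <- c(0, object$coefficients)          # reference coefficient is 0
  V <- matrix(0, length(levs), length(levs),
              dimnames = list(levs, levs))
  V[-1, -1] <- object$vcov
  rows <- list()
  for (i in seq_along(levs)) for (j in seq_along(levs)) {
    if (i >= j) next
    est <- b[j] - b[i]
    se <- sqrt(V[i, i] + V[j, j] - 2 * V[i, j])
    z <- est / se
    rows[[length(rows) + 1L]] <- data.frame(
      contrast = paste(levs[i], "vs.", levs[j]),
      estimate = est, se = se, z = z, p = 2 * stats::pnorm(-abs(z)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' McFadden pseudo R-squared
#'
#' `1 - logLik(model) / logLik(null)`: the proportional reduction in
#' log-likelihood relative to the intercept-free null in which each pair is
#' a coin flip. Comparable across models fitted to the same pairs.
#'
#' @param object A `pair_clogit` fit.
#' @return Pseudo R-squared in `[0, 1)`.
#' @export
mcfadden_r2 <- function(object) object$pseudo_r2
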