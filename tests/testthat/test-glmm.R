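# Gamma ratio data with known fixed effects, random intercepts and prior
# weights. Weights enter as precision: observation i has shape w_i * shape0.
sim_ratio_data <- function(n_ind = 12, n_col = 2, beta = c(0, 0.7, -1.6),
                           classes = c("alfalfa", "winter_cereals", "maize"),
                           sd_ind = 0, sd_col = 0, shape0 = 20,
                           weights = NULL, seed = 1) {
  set.seed(seed)
  d <- expand.grid(individual = sprintf("i%02d", seq_len(n_ind)),
                   class = classes, stringsAsFactors = FALSE)
  d$colony <- rep(sprintf("c%d", seq_len(n_col)),
                  length.out = n_ind)[match(d$individual,
                                            unique(d$individual))]
  re_i <- rnorm(n_ind, 0, sd_ind)
  re_c <- rnorm(n_col, 0, sd_col)
  eta <- beta[match(d$class, classes)] +
    re_i[match(d$individual, unique(d$individual))] +
    re_c[match(d$colony, unique(d$colony))]
  d$weight <- if (is.null(weights)) rep(1, nrow(d)) else weights
  shape <- shape0 * d$weight
  d$ratio <- rgamma(nrow(d), shape = shape, rate = shape / exp(eta))
  d$min_use_ok <- TRUE
  d
}

test_that("with no random variance the mixed fit matches the weighted GLM oracle", {
  set.seed(21)
  d <- sim_ratio_data(n_ind = 30, shape0 = 50, seed = 21,
                      weights = runif(90, 0.5, 4))
  # constrained at the zero-variance boundary: exact reduction to IRLS
  mixed0 <- fit_ratio_glmm(d, fix_zero_variance = TRUE)
  glm_o <- fit_ratio_glmm(d, random = "none")
  expect_equal(unname(coef(mixed0)), unname(coef(glm_o)), tolerance = 1e-4)
  expect_equal(unname(sqrt(diag(vcov(mixed0)))),
               unname(sqrt(diag(vcov(glm_o)))), tolerance = 1e-6)
  # the free fit estimates near-zero variances and lands close by
  mixed <- fit_ratio_glmm(d)
  expect_lt(sum(mixed$varcorr), 0.02)
  expect_equal(unname(coef(mixed)), unname(coef(glm_o)), tolerance = 0.05)
})

test_that("constant ratios give intercept log c and null contrasts", {
  d <- sim_ratio_data(seed = 2)
  d$ratio <- 3.5
  # constant response: glm's AIC arithmetic warns (zero deviance), harmless
  fit <- suppressWarnings(fit_ratio_glmm(d, random = "none"))
  expect_equal(unname(coef(fit)[1]), log(3.5), tolerance = 1e-8)
  expect_equal(unname(coef(fit)[-1]), rep(0, 2), tolerance = 1e-8)
})

test_that("doubling all weights leaves the point estimates unchanged", {
  set.seed(5)
  d <- sim_ratio_data(n_ind = 16, sd_ind = 0.3, seed = 5,
                      weights = runif(48, 0.5, 3))
  d2 <- d; d2$weight <- 2 * d$weight
  # exact invariance on the fixed-effects-only route
  g1 <- fit_ratio_glmm(d, random = "none")
  g2 <- fit_ratio_glmm(d2, random = "none")
  expect_equal(coef(g2), coef(g1), tolerance = 1e-10)
  # mixed route: invariant up to optimizer tolerance
  f1 <- fit_ratio_glmm(d)
  f2 <- fit_ratio_glmm(d2)
  expect_equal(coef(f2), coef(f1), tolerance = 5e-3)
})

test_that("scaling ratios by c shifts only the intercept by log c", {
  d <- sim_ratio_data(n_ind = 16, sd_ind = 0.3, seed = 6)
  f1 <- fit_ratio_glmm(d)
  d2 <- d; d2$ratio <- d$ratio * 4
  f2 <- fit_ratio_glmm(d2)
  expect_equal(unname(coef(f2)[1] - coef(f1)[1]), log(4), tolerance = 1e-4)
  expect_equal(coef(f2)[-1], coef(f1)[-1], tolerance = 1e-4)
})

test_that("refitting after permuting rows reproduces the estimates", {
  d <- sim_ratio_data(n_ind = 12, sd_ind = 0.4, seed = 7)
  f1 <- fit_ratio_glmm(d)
  set.seed(8)
  f2 <- fit_ratio_glmm(d[sample(nrow(d)), ])
  expect_equal(coef(f2), coef(f1), tolerance = 1e-8)
  expect_equal(f2$varcorr, f1$varcorr, tolerance = 1e-8)
})

test_that("Wald factor test: single-contrast identity and manual quadratic form", {
  d2 <- sim_ratio_data(classes = c("alfalfa", "maize"), beta = c(0, 0.5),
                       n_ind = 20, seed = 9)
  fit <- fit_ratio_glmm(d2, random = "none")
  se <- sqrt(diag(vcov(fit)))
  z <- coef(fit)[2] / se[2]
  w <- wald_chisq(fit)
  expect_equal(w$df, 1)
  expect_equal(w$chi2, unname(z^2), tolerance = 1e-10)
  d3 <- sim_ratio_data(n_ind = 15, sd_ind = 0.2, seed = 10)
  f3 <- fit_ratio_glmm(d3)
  idx <- grep("^habitat", names(coef(f3)))
  manual <- drop(t(coef(f3)[idx]) %*%
                   solve(vcov(f3)[idx, idx], coef(f3)[idx]))
  expect_equal(wald_chisq(f3)$chi2, manual)
})

test_that("marginal R2 equals its variance-ratio definition", {
  d <- sim_ratio_data(n_ind = 15, sd_ind = 0.4, seed = 11)
  fit <- fit_ratio_glmm(d)
  X <- model.matrix(~habitat, fit$data)
  vf <- var(drop(X %*% coef(fit)))
  expected <- vf / (vf + sum(fit$varcorr) + trigamma(1 / fit$dispersion))
  expect_equal(nakagawa_r2(fit), expected)
  ln <- vf / (vf + sum(fit$varcorr) + log1p(fit$dispersion))
  expect_equal(nakagawa_r2(fit, obs_var = "lognormal"), ln)
  # null fixed effects push R2 towards zero
  d0 <- sim_ratio_data(beta = c(0, 0, 0), n_ind = 20, sd_ind = 0.5, seed = 12)
  expect_lt(nakagawa_r2(fit_ratio_glmm(d0)), 0.2)
  expect_gt(nakagawa_r2(fit), 0.5)
})

test_that("fixed effects are recovered within 2 SE in most replicates", {
  truth <- c(alfalfa = 0, winter_cereals = 0.7, maize = -1.6)
  hits <- 0L; total <- 0L
  for (rep in 1:60) {
    d <- sim_ratio_data(n_ind = 9, sd_ind = 0.25, shape0 = 15,
                        beta = unname(truth), seed = 100 + rep)
    fit <- suppressWarnings(fit_ratio_glmm(d))
    b <- coef(fit)[-1]; se <- sqrt(diag(suppressWarnings(vcov(fit))))[-1]
    tr <- truth[sub("^habitat", "", names(b))] - truth[["alfalfa"]]
    hits <- hits + sum(abs(b - tr) <= 2 * se)
    total <- total + length(b)
  }
  expect_gte(hits / total, 0.90)
})

test_that("marginal R2 is calibrated on a known variance partition", {
  # fixed variance 2.0 across classes, individual variance 1.0, latent
  # residual 1.0 (gamma shape chosen so trigamma(shape) = 1)
  shape <- uniroot(function(s) trigamma(s) - 1, c(0.5, 5))$root
  b <- c(-1, 1) * sqrt(2)   # two balanced classes, var = 2 exactly
  r2s <- vapply(1:60, function(rep) {
    d <- sim_ratio_data(n_ind = 40, classes = c("a", "b"), beta = b,
                        sd_ind = 1, shape0 = shape, seed = 300 + rep)
    nakagawa_r2(suppressWarnings(fit_ratio_glmm(d, reference = "a")))
  }, numeric(1))
  expect_lt(abs(mean(r2s) - 0.5), 0.05)
})

test_that("Wald p-values are uniform under the null habitat model", {
  ps <- vapply(1:200, function(r) {
    d <- sim_ratio_data(n_ind = 20, classes = c("a", "b", "c", "d"),
                        beta = rep(0, 4), sd_ind = 0.3, shape0 = 30,
                        seed = 600 + r)
    suppressWarnings(wald_chisq(fit_ratio_glmm(d, reference = "a")))$p
  }, numeric(1))
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate inputs are rejected", {
  d <- sim_ratio_data(seed = 13)
  d1 <- d[d$class == "alfalfa", ]
  expect_error(fit_ratio_glmm(d1), "two habitat levels")
  d$ratio[1] <- -1
  expect_error(fit_ratio_glmm(d), "strictly positive")
})
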