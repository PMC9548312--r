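three_pairs <- data.frame(
  pair_id = rep(c("p1", "p2", "p3"), 2),
  role = rep(c("forage", "control"), each = 3),
  veg_height_cm = c(10, 5, 25, 20, 25, 20),  # differences -10, -20, +5
  stringsAsFactors = FALSE)

test_that("three-pair fit matches the dense grid-search oracle", {
  fit <- fit_pair_clogit(three_pairs, "height")
  oracle <- clogit_grid(c(-10, -20, 5))
  expect_equal(unname(coef(fit)), oracle$beta, tolerance = 1e-4)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  expect_equal(fit$loglik_null, 3 * log(0.5))
  expect_equal(mcfadden_r2(fit), 1 - fit$loglik / (3 * log(0.5)))
})

test_that("matched-pair fit equals the difference-logistic and survival oracles", {
  pr <- random_pairs(120, beta = -0.05, seed = 11)
  fit <- fit_pair_clogit(pr, "height")
  d <- pr$veg_height_cm[pr$role == "forage"] -
    pr$veg_height_cm[pr$role == "control"]
  glm_fit <- glm(rep(1, length(d)) ~ d - 1, family = binomial,
                 control = glm.control(epsilon = 1e-12))
  expect_equal(unname(coef(fit)), unname(coef(glm_fit)), tolerance = 1e-8)
  skip_if_not_installed("survival")
  pr$y <- as.integer(pr$role == "forage")
  sf <- survival::coxph(
    survival::Surv(rep(1, nrow(pr)), y) ~ veg_height_cm +
      survival::strata(pair_id),
    data = pr, method = "exact")
  expect_equal(unname(coef(fit)), unname(coef(sf)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(vcov(fit)))), unname(sqrt(diag(vcov(sf)))),
               tolerance = 1e-6)
})

test_that("swapping roles negates the slope; level shifts leave it unchanged", {
  pr <- random_pairs(80, seed = 3)
  fit <- fit_pair_clogit(pr, "height")
  swapped <- pr
  swapped$role <- ifelse(pr$role == "forage", "control", "forage")
  expect_equal(unname(coef(fit_pair_clogit(swapped, "height"))),
               -unname(coef(fit)), tolerance = 1e-9)
  shifted <- pr
  shifted$veg_height_cm <- pr$veg_height_cm + 100
  expect_equal(coef(fit_pair_clogit(shifted, "height")), coef(fit),
               tolerance = 1e-9)
})

test_that("tied pairs carry no information and do not move the estimate", {
  pr <- random_pairs(60, seed = 5)
  ties <- data.frame(pair_id = rep(sprintf("t%02d", 1:10), 2),
                     role = rep(c("forage", "control"), each = 10),
                     veg_height_cm = rep(30, 20), stringsAsFactors = FALSE)
  f1 <- fit_pair_clogit(pr, "height")
  f2 <- fit_pair_clogit(rbind(pr, ties), "height")
  expect_equal(coef(f2), coef(f1), tolerance = 1e-9)
  expect_equal(f2$loglik, f1$loglik + 10 * log(0.5), tolerance = 1e-9)
  all_tied <- fit_pair_clogit(ties, "height")
  expect_true(all_tied$zero_information)
  expect_equal(unname(coef(all_tied)), 0)
  expect_equal(mcfadden_r2(all_tied), 0)
})

test_that("complete separation is flagged, not returned as a finite estimate", {
  pr <- data.frame(pair_id = rep(sprintf("p%02d", 1:20), 2),
                   role = rep(c("forage", "control"), each = 20),
                   veg_height_cm = c(rep(5, 20), rep(50, 20)),
                   stringsAsFactors = FALSE)
  fit <- fit_pair_clogit(pr, "height")
  expect_true(fit$separation)
  expect_false(fit$converged)
})

test_that("role labels are normalised and pairing is validated", {
  pr <- random_pairs(10, seed = 2)
  pr$role <- ifelse(pr$role == "forage", "Foraging", "CONTROL")
  expect_s3_class(fit_pair_clogit(pr, "height"), "pair_clogit")
  broken <- random_pairs(10, seed = 2)[-1, ]
  expect_error(fit_pair_clogit(broken, "height"), "p001")
})

sim_struct_pairs <- function(n, beta = c(harvested = 2, ploughed = -0.5),
                             seed = 1) {
  set.seed(seed)
  states <- phenology_states()
  s1 <- sample(states, n, replace = TRUE)
  s2 <- sample(states, n, replace = TRUE)
  eta <- function(s) ifelse(s == "harvested", beta[["harvested"]],
                            ifelse(s == "ploughed", beta[["ploughed"]], 0))
  p1 <- plogis(eta(s1) - eta(s2))
  fwd <- runif(n) < p1
  data.frame(pair_id = rep(sprintf("s%03d", 1:n), 2),
             role = rep(c("forage", "control"), each = n),
             structure = c(ifelse(fwd, s1, s2), ifelse(fwd, s2, s1)),
             stringsAsFactors = FALSE)
}

test_that("categorical fit recovers structure effects and the Wald identity", {
  pr <- sim_struct_pairs(400, seed = 9)
  fit <- fit_pair_clogit(pr, "structure")
  expect_equal(fit$levels[1], "vegetated")
  b <- coef(fit); se <- sqrt(diag(vcov(fit)))
  expect_lt(abs(b[["harvested"]] - 2), 2 * se[["harvested"]])
  w <- factor_wald(fit)
  expect_equal(w$df, 2)
  manual <- drop(t(b) %*% solve(vcov(fit), b))
  expect_equal(w$chi2, manual)
  # two-level reduction: drop ploughed pairs -> chi2 equals z^2
  sub <- pr[rep(!(pr$structure[1:400] == "ploughed" |
                    pr$structure[401:800] == "ploughed"), 2), ]
  f2 <- fit_pair_clogit(sub, "structure")
  z <- coef(f2) / sqrt(diag(vcov(f2)))
  expect_equal(factor_wald(f2)$chi2, unname(z^2), tolerance = 1e-10)
})

test_that("pairwise contrasts are transitive and reparameterisation-invariant", {
  sim <- small_sim()
  fit <- fit_pair_clogit(sim$pairs, "crop")
  ct <- pairwise_contrasts(fit)
  est <- function(a, b) {
    row <- ct$contrast == paste(a, "vs.", b)
    if (any(row)) ct$estimate[row] else -ct$estimate[ct$contrast == paste(b, "vs.", a)]
  }
  levs <- fit$levels
  expect_equal(est(levs[1], levs[3]),
               est(levs[1], levs[2]) + est(levs[2], levs[3]),
               tolerance = 1e-12)
  refit <- fit_pair_clogit(sim$pairs, "crop", reference = levs[2])
  ct2 <- pairwise_contrasts(refit)
  shared <- intersect(ct$contrast, ct2$contrast)
  expect_gt(length(shared), 0)
  expect_equal(ct$estimate[match(shared, ct$contrast)],
               ct2$estimate[match(shared, ct2$contrast)], tolerance = 1e-8)
  expect_equal(ct$se[match(shared, ct$contrast)],
               ct2$se[match(shared, ct2$contrast)], tolerance = 1e-6)
})

test_that("contrast standard errors follow the delta rule on a hand-built covariance", {
  fake <- structure(list(model = "structure",
                         coefficients = c(harvested = 1.2, ploughed = -0.4),
                         vcov = matrix(c(0.04, 0.01, 0.01, 0.09), 2, 2,
                                       dimnames = list(c("harvested", "ploughed"),
                                                       c("harvested", "ploughed"))),
                         levels = c("vegetated", "harvested", "ploughed"),
                         loglik = -10, loglik_null = -20, pseudo_r2 = 0.5,
                         n_pairs = 30, n_informative = 30),
                    class = "pair_clogit")
  ct <- pairwise_contrasts(fake)
  expect_equal(ct$se[ct$contrast == "vegetated vs. harvested"], sqrt(0.04))
  expect_equal(ct$estimate[ct$contrast == "harvested vs. ploughed"], -1.6)
  expect_equal(ct$se[ct$contrast == "harvested vs. ploughed"],
               sqrt(0.04 + 0.09 - 2 * 0.01))
})

test_that("crop model restricts to valid crop pairs and optional vegetated subset", {
  sim <- small_sim()
  fit_all <- fit_pair_clogit(sim$pairs, "crop")
  fit_veg <- fit_pair_clogit(sim$pairs, "crop", crop_subset = "vegetated")
  expect_lte(fit_veg$n_pairs, fit_all$n_pairs)
  expect_equal(fit_all$reference, "alfalfa")
})
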