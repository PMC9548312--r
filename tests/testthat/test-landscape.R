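test_that("single-parcel cover rasterizes to a uniform grid", {
  p <- parcel_table(1, "alfalfa",
                    list(cbind(c(0, 400, 400, 0), c(0, 0, 400, 400))),
                    "vegetated", "vegetated", "harvested")
  r <- rasterize_parcels(p, "late_incubation", 40, c(0, 0, 400, 400))
  expect_equal(dim(r$class), c(10L, 10L))
  expect_true(all(r$class == "alfalfa"))
  expect_true(all(r$pheno == "vegetated"))
})

test_that("abutting parcels split cells by centre membership", {
  p <- mk_parcels(1:2, c("maize", "water"),
                  list(cbind(c(0, 200, 200, 0), c(0, 0, 400, 400)),
                       cbind(c(200, 400, 400, 200), c(0, 0, 400, 400))))
  r <- rasterize_parcels(p, cell_size = 40, bounds = c(0, 0, 400, 400))
  expect_equal(as.integer(table(r$class)[c("maize", "water")]), c(50L, 50L))
  expect_true(all(r$class[, 1:5] == "maize"))
})

test_that("irregular parcels match the winding-number oracle cell by cell", {
  tri <- cbind(c(0, 360, 40), c(20, 80, 380))
  pent <- cbind(c(201, 401, 401, 323, 221), c(181, 121, 401, 401, 301))
  quad <- cbind(c(0, 160, 120, -40), c(-40, 0, 200, 160))
  p <- mk_parcels(1:3, c("alfalfa", "maize", "water"),
                  list(tri, pent, quad))
  r <- rasterize_parcels(p, cell_size = 40, bounds = c(0, 0, 400, 400))
  cx <- 0 + (seq_len(10) - 0.5) * 40
  gx <- rep(cx, times = 10); gy <- rep(cx, each = 10)
  oracle <- rep(NA_character_, 100)
  for (k in 1:3) {  # lowest id wins ties
    hit <- pip_winding(gx, gy, p$geometry[[k]]) & is.na(oracle)
    oracle[hit] <- p$class[k]
  }
  got <- as.vector(t(r$class))  # row i = y band i, column j = x band j
  expect_equal(got, oracle)
})

test_that("rasterize rejects degenerate input", {
  p <- parcel_table(1, "water", list(cbind(c(0, 1, 1), c(0, 0, 1))))
  expect_error(rasterize_parcels(p, cell_size = 0), "cell_size")
  expect_error(rasterize_parcels(p[0, ], cell_size = 40), "empty")
  expect_error(rasterize_parcels(p, phase = "brooding"), "unknown phase")
})

test_that("availability matches exhaustive distance filtering and conserves cells", {
  sim <- small_sim()
  r <- sim$rasters$late_incubation
  colony <- unlist(sim$colonies[1, c("x", "y")])
  av <- availability(r, colony, 3000)
  expect_equal(sum(av$cells), attr(av, "total_cells"))
  expect_equal(sum(av$proportion), 1, tolerance = 1e-9)
  # brute force: enumerate every centre, filter by distance, tabulate
  cs <- r$cell_size
  cx <- r$origin[1] + (seq_len(ncol(r$class)) - 0.5) * cs
  cy <- r$origin[2] + (seq_len(nrow(r$class)) - 0.5) * cs
  g <- expand.grid(y = cy, x = cx)
  cls <- as.vector(r$class)
  ok <- (g$x - colony[1])^2 + (g$y - colony[2])^2 <= 3000^2 & !is.na(cls)
  oracle <- table(cls[ok])
  expect_equal(av$cells, as.integer(oracle[av$class]))
})

test_that("availability handles degenerate and uniform cases", {
  p <- mk_parcels(1, "alfalfa",
                  list(cbind(c(0, 400, 400, 0), c(0, 0, 400, 400))))
  r <- rasterize_parcels(p, cell_size = 40, bounds = c(0, 0, 400, 400))
  av <- suppressWarnings(availability(r, c(200, 200), 3000))
  expect_equal(av$proportion, 1.0)
  tiny <- availability(r, c(60, 60), 25)  # only the centre at (60,60)
  expect_equal(sum(tiny$cells), 1L)
  expect_error(availability(r, c(5000, 5000), 100), "outside")
  expect_warning(availability(r, c(200, 200), 10000), "clipped")
})

test_that("availability is invariant under scene translation", {
  p <- mk_parcels(1:2, c("maize", "water"),
                  list(cbind(c(0, 200, 200, 0), c(0, 0, 400, 400)),
                       cbind(c(200, 400, 400, 200), c(0, 0, 400, 400))))
  shift <- function(g, dx, dy) cbind(g[, 1] + dx, g[, 2] + dy)
  p2 <- mk_parcels(1:2, p$class, lapply(p$geometry, shift, dx = 1e4, dy = -3e3))
  r1 <- rasterize_parcels(p, cell_size = 40, bounds = c(0, 0, 400, 400))
  r2 <- rasterize_parcels(p2, cell_size = 40,
                          bounds = c(1e4, -3e3, 1e4 + 400, -3e3 + 400))
  a1 <- suppressWarnings(availability(r1, c(200, 200), 150))
  a2 <- suppressWarnings(availability(r2, c(1e4 + 200, -3e3 + 200), 150))
  expect_equal(a1$proportion, a2$proportion)
})

test_that("halving the cell size barely changes convex-parcel proportions", {
  poly1 <- cbind(c(0, 2000, 2000, 0), c(0, 0, 900, 2000))
  poly2 <- cbind(c(2000, 0, 2000), c(900, 2000, 2000))
  p <- mk_parcels(1:2, c("alfalfa", "maize"), list(poly1, poly2))
  props <- function(cs) {
    r <- rasterize_parcels(p, cell_size = cs, bounds = c(0, 0, 2000, 2000))
    av <- suppressWarnings(availability(r, c(1000, 1000), 5000))
    setNames(av$proportion, av$class)
  }
  p40 <- props(40); p20 <- props(20)
  expect_lt(max(abs(p40 - p20[names(p40)])), 0.02)
})

test_that("phenology lookup distinguishes crops from fixed classes", {
  p <- parcel_table(1:2, c("alfalfa", "water"),
                    list(cbind(c(0, 1, 1), c(0, 0, 1)) * 100,
                         cbind(c(2, 3, 3), c(0, 0, 1)) * 100),
                    pheno_p1 = c("harvested", NA),
                    pheno_p2 = c("vegetated", NA),
                    pheno_p3 = c("vegetated", NA))
  expect_equal(phenology_state(p, "late_incubation"),
               c("harvested", "not_applicable"))
  expect_equal(phenology_state(p, "early_rearing")[1], "vegetated")
  expect_error(phenology_state(p, "phase_4"), "unknown phase")
})

test_that("local projection preserves short distances", {
  # 500 m due east of a Po Plain colony
  xy <- project_local(c(11.10, 11.10634), c(44.96, 44.96), 11.10, 44.96)
  d <- sqrt(diff(xy$x)^2 + diff(xy$y)^2)
  expect_equal(d, 500, tolerance = 1)
  expect_equal(xy$x[1], 0); expect_equal(xy$y[1], 0)
})
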