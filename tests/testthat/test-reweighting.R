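test_that("two-bin histogram PMF matches the closed form", {
  rc <- rc_series("d", c(rep(0.5, 100), rep(1.5, 37)))
  g <- histogram_pmf(rc, bins = 2, temperature = 300)
  expect_equal(as.vector(g$counts), c(100, 37))
  # delta PMF = -kB T log(37/100) = 0.593 kcal/mol at 300 K
  expect_equal(diff(range(g$pmf)), -0.0019872 * 300 * log(37 / 100),
               tolerance = 1e-9)
  expect_equal(min(g$pmf), 0)
})

test_that("degenerate and uniform histograms behave", {
  one <- histogram_pmf(rc_series("d", rep(1, 50)), bins = 5)
  expect_equal(sum(!is.na(one$pmf)), 1)
  expect_equal(min(one$pmf, na.rm = TRUE), 0)
  set.seed(1)
  u <- histogram_pmf(rc_series("d", runif(10000)), bins = 10)
  expect_true(all(abs(u$pmf) < 0.1))
  expect_error(histogram_pmf(rc_series("d", numeric(0))), "no frames")
})

test_that("zero and constant boosts leave the PMF unchanged", {
  set.seed(3)
  x <- rnorm(2000)
  g <- histogram_pmf(rc_series("x", x), bins = 20)
  zero <- boost_record(rep(0, 2000), rep(0, 2000))
  rw0 <- cumulant_reweight(g, zero)
  expect_identical(rw0$pmf, g$pmf)
  const <- boost_record(rep(0, 2000), rep(3.7, 2000))
  rwc <- cumulant_reweight(g, const)
  expect_equal(rwc$pmf, g$pmf, tolerance = 1e-12)
})

test_that("order 1 and order 2 agree when the boost variance is zero", {
  set.seed(4)
  x <- rnorm(1000)
  g <- histogram_pmf(rc_series("x", x), bins = 10)
  # dV constant within each bin: proportional to the bin index
  bins <- g$frame_bins
  dv <- as.numeric(bins) * 0.5
  b <- boost_record(rep(0, 1000), dv)
  r1 <- cumulant_reweight(g, b, order = 1)
  r2 <- cumulant_reweight(g, b, order = 2)
  expect_equal(r1$pmf, r2$pmf, tolerance = 1e-9)
  expect_true(all(r2$c2[r2$counts > 0] < 1e-18))
})

test_that("anchoring holds over reliable bins before and after reweighting", {
  set.seed(5)
  x <- c(rnorm(1000), rnorm(5, 10)) # a tiny unreliable far cluster
  g <- histogram_pmf(rc_series("x", x), bins = 30)
  expect_equal(min(g$pmf, na.rm = TRUE), 0)
  b <- boost_record(rep(0, length(x)), abs(rnorm(length(x))))
  rw <- cumulant_reweight(g, b, min_frames = 10)
  expect_equal(min(rw$pmf[rw$reliable], na.rm = TRUE), 0)
  # unreliable bins are flagged, not dropped
  expect_true(any(!rw$reliable & rw$counts > 0))
})

test_that("periodic coordinates are invariant under 360-degree rotation", {
  set.seed(6)
  ang <- runif(3000, -180, 180)
  g1 <- histogram_pmf(rc_series("phi", ang, periodic = TRUE), bins = 36)
  g2 <- histogram_pmf(rc_series("phi", ang + 360, periodic = TRUE),
                      bins = 36)
  expect_equal(g1$pmf, g2$pmf)
  expect_equal(g1$counts, g2$counts)
})

test_that("2D grids bin jointly and export to CSV with metadata", {
  set.seed(7)
  rc1 <- rc_series("d1", rnorm(4000, 5))
  rc2 <- rc_series("d2", rnorm(4000, 8))
  g <- histogram_pmf(list(rc1, rc2), bins = c(10, 12))
  expect_equal(dim(g$pmf), c(10, 12))
  expect_equal(sum(g$counts), 4000)
  f <- tempfile(fileext = ".csv")
  write_fel_csv(g, f)
  df <- read.csv(f)
  expect_equal(nrow(df), 120)
  expect_true(all(c("d1", "d2", "pmf", "count") %in% names(df)))
  meta <- jsonlite::read_json(paste0(f, ".json"))
  expect_equal(meta$temperature, 300)
})

test_that("reweighted double-well PMF matches a 10x longer unbiased run", {
  pot <- double_well_potential(3.6, 1.5)
  g <- gamd_simulate(pot, n_equil = 20000, n_prod = 200000, sigma0 = 6,
                     stride = 10, seed = 5)
  unb <- run_langevin(pot, NULL, n_steps = 2000000, stride = 10, seed = 6)
  gb <- histogram_pmf(rc_series("x", g$production$coords[, 1]), bins = 40)
  rw <- cumulant_reweight(gb, g$production$boost)
  gu <- histogram_pmf(rc_series("x", unb$coords[, 1]), bins = 40)
  pu <- approx(gu$axes[[1]]$centers, gu$pmf, xout = gb$axes[[1]]$centers)$y
  sel <- which(as.vector(gb$counts) >= 500 & !is.na(pu))
  expect_gt(length(sel), 5)
  expect_lt(max(abs(rw$pmf[sel] - pu[sel])), 0.5)
  # the reweighted barrier recovers the analytic 3.6 kcal/mol within 10%
  centers <- gb$axes[[1]]$centers
  barrier <- max(rw$pmf[abs(centers) < 0.5], na.rm = TRUE)
  expect_lt(abs(barrier - 3.6) / 3.6, 0.10)
})

test_that("misaligned boost records are rejected", {
  g <- histogram_pmf(rc_series("x", rnorm(100)), bins = 5)
  b <- boost_record(rep(0, 99), rep(0, 99))
  expect_error(cumulant_reweight(g, b), "99 frames")
})
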