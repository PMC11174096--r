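test_that("potential statistics are exact for closed-form inputs", {
  s <- collect_stats(c(1, 2, 3))
  expect_equal(s$v_max, 3)
  expect_equal(s$v_min, 1)
  expect_equal(s$v_avg, 2)
  expect_equal(s$sigma_v, sqrt(2 / 3), tolerance = 1e-12) # 0.8165
  s0 <- collect_stats(c(5, 5, 5))
  expect_equal(s0$sigma_v, 0)
  expect_error(collect_stats(numeric(0)), "empty")
})

test_that("population sd estimate converges on a Normal stream", {
  set.seed(42)
  s <- collect_stats(rnorm(10000, sd = 2))
  expect_lt(abs(s$sigma_v - 2), 0.06)
})

test_that("k0 worked examples and degenerate input", {
  st <- structure(list(v_max = 100, v_min = 0, v_avg = 80, sigma_v = 5),
                  class = "potential_stats")
  expect_equal(compute_k0(st, sigma0 = 10)$k0, 1.0)
  p <- compute_k0(st, sigma0 = 0.5)
  expect_equal(p$k0, 0.5)
  expect_equal(p$k, 0.5 / 100)
  expect_equal(p$E, 100)
  expect_error(compute_k0(collect_stats(c(5, 5, 5))), "degenerate")
})

test_that("k0 stays in [0, 1] for randomized statistics in both modes", {
  set.seed(11)
  for (i in 1:200) {
    v <- rnorm(50, sd = runif(1, 0.1, 20))
    st <- collect_stats(v)
    for (mode in c("lower", "upper")) {
      p <- suppressWarnings(
        compute_k0(st, sigma0 = runif(1, 0.01, 10), bound_mode = mode))
      expect_gte(p$k0, 0)
      expect_lte(p$k0, 1)
      # reference energy within its admissible range [Vmax, Vmin + 1/k]
      expect_gte(p$E, st$v_max - 1e-9)
      expect_lte(p$E, st$v_min + 1 / p$k + 1e-9)
    }
  }
})

test_that("upper bound mode falls back to lower when sigma0 >= sigmaV", {
  st <- structure(list(v_max = 10, v_min = 0, v_avg = 5, sigma_v = 1),
                  class = "potential_stats")
  expect_warning(p <- compute_k0(st, sigma0 = 6, bound_mode = "upper"),
                 "falling back")
  expect_true(p$fallback)
  expect_equal(p$bound_mode, "lower")
})

test_that("boost branch behaviour matches hand evaluation", {
  expect_equal(gamd_boost(10, list(E = 5, k = 1)), 0)
  expect_equal(gamd_boost(5, list(E = 5, k = 1)), 0)  # V >= E branch at V = E
  expect_equal(gamd_boost(3, list(E = 5, k = 0.5)), 1.0)
  # V* ordering and compression for the worked pair
  p <- list(E = 5, k = 0.1)
  v1s <- 1 + gamd_boost(1, p); v2s <- 2 + gamd_boost(2, p)
  expect_equal(v1s, 1.8)
  expect_equal(v2s, 2.45)
  expect_lt(v1s, v2s)
  expect_lt(v2s - v1s, 1)
})

test_that("ordering and gap compression hold for admissible random inputs", {
  set.seed(5)
  for (i in 1:500) {
    v <- sort(runif(2, -10, 10))
    v1 <- v[1]; v2 <- v[2]
    k <- runif(1, 1e-3, 1 / (v2 - v1)) # ensures Vmax <= Vmin + 1/k
    E <- runif(1, v2, v1 + 1 / k)
    p <- list(E = E, k = k)
    v1s <- v1 + gamd_boost(v1, p)
    v2s <- v2 + gamd_boost(v2, p)
    expect_lt(v1s, v2s)                 # ordering preserved
    expect_lte(v2s - v1s, v2 - v1)      # gap never widened
    if (E > v2) expect_lt(v2s - v1s, v2 - v1) # strict compression below E
  }
})

test_that("boost is non-negative and monotone decreasing below E", {
  p <- list(E = 2, k = 0.3)
  v <- seq(-10, 4, length.out = 200)
  dv <- gamd_boost(v, p)
  expect_true(all(dv >= 0))
  below <- v < 2
  expect_true(all(diff(dv[below]) < 0))
  expect_true(all(dv[!below] == 0))
})

test_that("unbiased harmonic run satisfies equipartition", {
  r <- run_langevin(harmonic_potential(2), n_steps = 1e6, timestep = 0.02,
                    friction = 1, seed = 3)
  expect_equal(var(r$coords[, 1]), 0.0019872 * 300 / 2, tolerance = 0.05)
  expect_true(all(r$boost$dV == 0)) # params = NULL means no boost
})

test_that("zero-friction integration conserves energy", {
  r <- run_langevin(harmonic_potential(1), temperature = 0, n_steps = 10000,
                    timestep = 0.01, friction = 0, x0 = 1, seed = 1)
  expect_lt(abs(r$final_energy - 0.5), 1e-4) # initial energy 0.5*1*1^2
})

test_that("langevin runs are seed-deterministic and flag divergence", {
  r1 <- run_langevin(harmonic_potential(1), n_steps = 500, seed = 9)
  r2 <- run_langevin(harmonic_potential(1), n_steps = 500, seed = 9)
  expect_identical(r1$coords, r2$coords)
  expect_error(
    run_langevin(harmonic_potential(-5), n_steps = 5000, seed = 1),
    "diverged at step")
})

test_that("boosting multiplies barrier crossings on a 6 kT double well", {
  pot <- double_well_potential(3.6, 1.5) # ~6 kT barrier at 300 K
  crossings <- function(x) sum(diff(sign(x)) != 0)
  boosted <- 0; unbiased <- 0
  for (seed in 1:5) {
    g <- gamd_simulate(pot, n_equil = 10000, n_prod = 50000, sigma0 = 6,
                       stride = 10, seed = seed)
    u <- run_langevin(pot, NULL, n_steps = 50000, stride = 10,
                      seed = seed + 100)
    boosted <- boosted + crossings(g$production$coords[, 1])
    unbiased <- unbiased + crossings(u$coords[, 1])
  }
  expect_gte(boosted, unbiased)
})

test_that("analytic gradients agree with finite differences", {
  for (pot in list(harmonic_potential(c(1.5, 3)), double_well_potential(4, 1.2),
                   double_well_2d(3, 1, 2))) {
    set.seed(2)
    X <- matrix(runif(10 * pot$dim, -2, 2), ncol = pot$dim)
    g <- potential_gradient(pot, X)
    h <- 1e-6
    for (d in seq_len(pot$dim)) {
      Xp <- X; Xp[, d] <- Xp[, d] + h
      Xm <- X; Xm[, d] <- Xm[, d] - h
      fd <- (potential_energy(pot, Xp) - potential_energy(pot, Xm)) / (2 * h)
      expect_equal(g[, d], fd, tolerance = 1e-5)
    }
  }
})

test_that("boost records round-trip through CSV", {
  rec <- boost_record(c(1, 2, 3), c(0.5, 0, 0.1), temperature = 310)
  f <- tempfile(fileext = ".csv")
  write_boost_csv(rec, f)
  back <- read_boost_csv(f, temperature = 310)
  expect_equal(back$V, rec$V)
  expect_equal(back$dV, rec$dV)
  expect_error(boost_record(1:3, c(-0.1, 0, 0)), "non-negative")
})
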