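test_that("superposition recovers rigidly moved copies exactly", {
  set.seed(10)
  xyz <- matrix(rnorm(15 * 3, sd = 3), ncol = 3)
  fit0 <- superpose(xyz, xyz)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-10)
  th <- pi / 2
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- xyz %*% R + matrix(c(3, -7, 2), 15, 3, byrow = TRUE)
  fit <- superpose(moved, xyz)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_equal(fit$fitted, xyz, tolerance = 1e-9)
})

test_that("superposition RMSD matches a numeric-minimization oracle", {
  # 4-point toy with one atom displaced by 1 Angstrom
  ref <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  mob <- ref; mob[4, 3] <- mob[4, 3] + 1
  got <- superpose(mob, ref)$rmsd
  # oracle: direct minimization over Euler angles + translation
  obj <- function(par) {
    ca <- cos(par[1]); sa <- sin(par[1])
    cb <- cos(par[2]); sb <- sin(par[2])
    cg <- cos(par[3]); sg <- sin(par[3])
    R <- rbind(c(cb * cg, sa * sb * cg - ca * sg, ca * sb * cg + sa * sg),
               c(cb * sg, sa * sb * sg + ca * cg, ca * sb * sg - sa * cg),
               c(-sb, sa * cb, ca * cb))
    moved <- mob %*% t(R) + matrix(par[4:6], 4, 3, byrow = TRUE)
    sqrt(mean(rowSums((moved - ref)^2)))
  }
  oracle <- optim(rep(0, 6), obj, method = "BFGS",
                  control = list(reltol = 1e-14, maxit = 2000))$value
  expect_equal(got, oracle, tolerance = 1e-6)
  expect_error(superpose(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)),
                         rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))),
               "collinear")
})

test_that("RMSD series is zero for a static trajectory and normalized", {
  base <- matrix(rnorm(10 * 3), ncol = 3)
  tr <- trajectory_ensemble(array(rep(t(base), 6),
                                  c(3, 10, 6))[, , , drop = FALSE] |>
                              aperm(c(3, 2, 1)))
  rs <- rmsd_series(tr)
  expect_true(all(rs$rmsd < 1e-9))
  expect_equal(sum(rs$distribution$density) * 0.1, 1, tolerance = 1e-9)
})

test_that("a planted two-state ligand series yields a bimodal histogram", {
  set.seed(12)
  base <- matrix(rnorm(20 * 3, sd = 4), ncol = 3)
  shift <- c(2.0, 0, 0) # displaces half the frames by a 2 A internal move
  nf <- 200
  coords <- array(NA_real_, c(nf, 20, 3))
  state <- rep(c(0, 1), each = nf / 2)
  for (f in seq_len(nf)) {
    x <- base
    if (state[f] == 1) x[1:5, ] <- x[1:5, ] +
        matrix(shift, 5, 3, byrow = TRUE)
    coords[f, , ] <- x + rnorm(60, sd = 0.03)
  }
  tr <- trajectory_ensemble(coords)
  rs <- rmsd_series(tr, reference = 1L, selection = "all")
  d <- rs$distribution
  modes <- d$center[d$density > 0.5 * max(d$density)]
  expect_gt(diff(range(modes)), 0.5) # two separated populations
})

test_that("RMSF matches the closed form for a single oscillating atom", {
  # moving atom at the centroid of a static cage so the fit stays put
  set.seed(13)
  cage <- matrix(rnorm(40 * 3, sd = 6), ncol = 3)
  cage <- sweep(cage, 2, colMeans(cage))
  base <- rbind(c(0, 0, 0), cage)
  d <- 0.5
  nf <- 40
  coords <- array(NA_real_, c(nf, 41, 3))
  for (f in seq_len(nf)) {
    x <- base
    x[1, 1] <- if (f %% 2 == 0) d else -d
    coords[f, , ] <- x
  }
  tr <- trajectory_ensemble(coords)
  out <- rmsf(tr, selection = "all")
  expect_equal(out$rmsf[1], d, tolerance = 0.03)
  expect_true(all(out$rmsf[-1] < 0.05))
  expect_error(rmsf(trajectory_ensemble(array(0, c(1, 5, 3)))), "single")
})

test_that("RMSF agrees with an independent bio3d-based evaluation", {
  set.seed(14)
  nf <- 30; na <- 12
  coords <- array(rnorm(nf * na * 3, sd = 1), c(nf, na, 3))
  base <- matrix(rnorm(na * 3, sd = 5), ncol = 3)
  for (f in seq_len(nf)) coords[f, , ] <- coords[f, , ] + base
  tr <- trajectory_ensemble(coords)
  got <- rmsf(tr)$rmsf
  # oracle: bio3d fit to frame-1, mean, re-fit to mean, two-pass formula
  xyz <- matrix(aperm(coords, c(3, 2, 1)), nrow = nf, byrow = TRUE)
  fitted <- suppressWarnings(bio3d::fit.xyz(xyz[1, ], xyz))
  mean1 <- colMeans(fitted)
  fitted <- suppressWarnings(bio3d::fit.xyz(mean1, fitted))
  mu <- colMeans(fitted)
  dev2 <- sweep(fitted, 2, mu)^2
  oracle <- sqrt(colMeans(dev2[, seq(1, 3 * na, 3)]) +
                   colMeans(dev2[, seq(2, 3 * na, 3)]) +
                   colMeans(dev2[, seq(3, 3 * na, 3)]))
  expect_equal(got, oracle, tolerance = 1e-6)
})

test_that("PCA recovers a planted single mode and its variance", {
  set.seed(15)
  base <- matrix(rnorm(30 * 3, sd = 5), ncol = 3)
  base <- sweep(base, 2, colMeans(base))
  # antisymmetric stretch of atoms 1 and 2 placed on the x axis: no net
  # translation or torque, so superposition cannot absorb it
  base[1, ] <- c(8, 0, 0); base[2, ] <- c(-8, 0, 0)
  nf <- 60
  amp <- rnorm(nf, sd = 0.7)
  coords <- array(NA_real_, c(nf, 30, 3))
  for (f in seq_len(nf)) {
    x <- base
    x[1, 1] <- x[1, 1] + amp[f]
    x[2, 1] <- x[2, 1] - amp[f]
    coords[f, , ] <- x
  }
  tr <- trajectory_ensemble(coords)
  p <- pca_ca(tr, selection = "all")
  mode <- rep(0, 90); mode[1] <- 1 / sqrt(2); mode[4] <- -1 / sqrt(2)
  expect_gt(abs(sum(p$eigenvectors[, 1] * mode)), 0.999)
  pop_var <- mean(amp^2) - mean(amp)^2
  expect_equal(p$eigenvalues[1], 2 * pop_var, tolerance = 1e-6)
  # trace identity and orthonormality
  expect_equal(sum(p$eigenvalues), p$trace, tolerance = 1e-6 * p$trace)
  expect_equal(crossprod(p$eigenvectors), diag(90), tolerance = 1e-8)
})

test_that("distance RCs are exact, symmetric, and rigid-motion invariant", {
  coords <- array(NA_real_, c(2, 3, 3))
  coords[1, , ] <- rbind(c(0, 0, 0), c(3, 4, 0), c(1, 1, 1))
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  coords[2, , ] <- coords[1, , ] %*% R + matrix(c(1, 2, 3), 3, 3,
                                                byrow = TRUE)
  tr <- trajectory_ensemble(coords)
  d12 <- rc_distance(tr, 1, 2)
  expect_equal(d12$values, c(5, 5), tolerance = 1e-9)
  expect_equal(rc_distance(tr, 2, 1)$values, d12$values)
  expect_error(rc_distance(tr, 1, 9), "not present")
})

test_that("dihedrals follow the IUPAC convention and match an oracle", {
  # planar trans and cis arrangements
  trans <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, -1, 0))
  cis <- rbind(c(0, 1, 0), c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  mk <- function(xyz) trajectory_ensemble(array(xyz, c(1, 4, 3)))
  tr_t <- mk(array(rep(trans, each = 1), c(4, 3)))
  tr_c <- mk(cis)
  expect_equal(abs(rc_dihedral(tr_t, 1:4)$values), 180, tolerance = 1e-9)
  expect_equal(rc_dihedral(tr_c, 1:4)$values, 0, tolerance = 1e-9)
  # randomized configurations vs an independent vector-algebra oracle
  set.seed(16)
  for (i in 1:25) {
    xyz <- matrix(rnorm(12), 4, 3)
    tr <- mk(xyz)
    got <- rc_dihedral(tr, 1:4)$values
    b1 <- xyz[2, ] - xyz[1, ]; b2 <- xyz[3, ] - xyz[2, ]
    b3 <- xyz[4, ] - xyz[3, ]
    cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])
    n1 <- cr(b1, b2); n2 <- cr(b2, b3)
    cosphi <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
    phi <- acos(pmin(pmax(cosphi, -1), 1)) * 180 / pi
    if (sum(n1 * b3) < 0) phi <- -phi
    expect_equal(got, phi, tolerance = 1e-9)
  }
  col <- mk(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 1, 0)))
  expect_error(rc_dihedral(col, 1:4), "collinear")
})

test_that("hydrogen-bond criterion uses strict inequalities", {
  mk <- function(D, H, A) {
    coords <- array(NA_real_, c(1, 3, 3))
    coords[1, , ] <- rbind(D, H, A)
    trajectory_ensemble(coords)
  }
  # donor-acceptor distance exactly 3.5 A (angle 180): NOT bound
  at_dist <- mk(c(0, 0, 0), c(1, 0, 0), c(3.5, 0, 0))
  expect_equal(hbond_occupancy(at_dist, 1, 2, 3)$occupancy, 0)
  # angle below 120 at short distance: NOT bound
  low_ang <- mk(c(0, 0, 0), c(1, 0, 0), c(0.3, 0.4, 0)) # ~30 degrees
  expect_equal(hbond_occupancy(low_ang, 1, 2, 3)$occupancy, 0)
  # just inside both thresholds: bound
  b3 <- generate_hbond_series(hbond_series_spec(1, 1,
                                                bound_geometry = c(3.49, 120.5)))
  expect_equal(hbond_occupancy(b3, 1, 2, 3)$occupancy, 100)
  # criterion thresholds are strict parameters of the implementation
  at <- hbond_occupancy(at_dist, 1, 2, 3)
  expect_false(at$distance < 3.5 && at$angle > 120)
  expect_error(hbond_occupancy(b3, 1, 9, 3), "not present")
})
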