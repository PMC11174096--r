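#' Analytic model potentials
#'
#' Small library of 1D/2D potentials used to exercise the GaMD boost
#' mathematics with a Langevin integrator.  Each potential carries a
#' closed-form energy and gradient; the built-in forms also have a fast
#' compiled path inside the integrator.  Units: energy kcal/mol, length
#' Angstrom, mass amu (AKMA-like time unit, ~48.9 fs).
#'
#' * `harmonic_potential(ks)`: sum of `0.5 * ks[d] * x[d]^2` (ks per
#'   dimension, kcal/mol/A^2).
#' * `double_well_potential(height, half_sep)`: quartic double well
#'   `height * ((x/half_sep)^2 - 1)^2` with minima at `±half_sep` and a
#'   barrier of `height` kcal/mol at the origin.
#' * `double_well_2d(height, half_sep, ky)`: the same double well in x
#'   plus an independent harmonic well in y.
#'
#' @param ks spring constant(s), kcal/mol/A^2.
#' @param height barrier height, kcal/mol.
#' @param half_sep half the minima separation, Angstrom.
#' @param ky spring constant of the transverse harmonic well.
#' @return an object of class `analytic_potential`.
#' @export
harmonic_potential <- function(ks = 1) {
  structure(list(name = "harmonic", id = 1L, par = as.numeric(ks),
                 dim = length(ks)), class = "analytic_potential")
}

#' @rdname harmonic_potential
#' @export
double_well_potential <- function(height = 4, half_sep = 1) {
  structure(list(name = "double_well", id = 2L,
                 par = c(height, half_sep), dim = 1L),
            class = "analytic_potential")
}

#' @rdname harmonic_potential
#' @export
double_well_2d <- function(height = 4, half_sep = 1, ky = 2) {
  structure(list(name = "double_well_2d", id = 3L,
                 par = c(height, half_sep, ky), dim = 2L),
            class = "analytic_potential")
}

#' Evaluate an analytic potential
#'
#' @param potential an `analytic_potential`.
#' @param x numeric matrix of configurations (rows) or a vector for a
#'   single configuration.
#' @return `potential_energy`: numeric vector of energies;
#'   `potential_gradient`: matrix of gradients (rows match `x`).
#' @export
potential_energy <- function(potential, x) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = potential$dim)
  as.numeric(.pot_eval_cpp(potential$id, potential$par, x)$energy)
}

#' @rdname potential_energy
#' @export
potential_gradient <- function(potential, x) {
  x <- if (is.matrix(x)) x else matrix(x, ncol = potential$dim)
  .pot_eval_cpp(potential$id, potential$par, x)$gradient
}

#' Summary statistics of a potential-energy series
#'
#' Computed over an unbiased (conventional MD) segment and then frozen;
#' these statistics parameterize the GaMD boost.  The standard deviation
#' is the population (divide-by-N) form.
#'
#' @param v numeric vector of per-frame potential energies (kcal/mol).
#' @return object of class `potential_stats` with fields `v_max`, `v_min`,
#'   `v_avg`, `sigma_v`.
#' @examples
#' collect_stats(c(1, 2, 3))  # sigma_v = 0.8165
#' @export
collect_stats <- function(v) {
  if (length(v) == 0L) stop("empty potential-energy series")
  if (any(!is.finite(v))) stop("non-finite values in potential series")
  structure(list(v_max = max(v), v_min = min(v), v_avg = mean(v),
                 sigma_v = sqrt(mean((v - mean(v))^2))),
            class = "potential_stats")
}

#' @export
print.potential_stats <- function(x, ...) {
  cat(sprintf("potential_stats: Vmax %.4g  Vmin %.4g  Vavg %.4g  sigmaV %.4g\n",
              x$v_max, x$v_min, x$v_avg, x$sigma_v))
  invisible(x)
}

#' GaMD boost parameters from potential statistics
#'
#' Computes the effective harmonic constant `k0`, the force constant
#' `k = k0 / (Vmax - Vmin)`, and the reference energy `E`.  In the
#' lower-bound mode `E = Vmax` and
#' `k0 = min(1, (sigma0/sigmaV) * (Vmax - Vmin)/(Vmax - Vavg))`;
#' in the upper-bound mode `E = Vmin + 1/k` and
#' `k0 = (1 - sigma0/sigmaV) * (Vmax - Vmin)/(Vavg - Vmin)` clamped to
#' (0, 1].  The upper bound requires `sigma0 < sigmaV`; otherwise the
#' function falls back to the lower bound and flags it.
#'
#' @param stats a [collect_stats()] result.
#' @param sigma0 user limit on the boost-potential standard deviation
#'   (kcal/mol); 6.0 is the customary default at 300 K.
#' @param bound_mode `"lower"` (default) or `"upper"`.
#' @return object of class `gamd_params` with `E`, `k0`, `k`, `sigma0`,
#'   `bound_mode`, and `fallback` (TRUE when upper mode was demoted).
#' @export
compute_k0 <- function(stats, sigma0 = 6.0, bound_mode = c("lower", "upper")) {
  bound_mode <- match.arg(bound_mode)
  stopifnot(inherits(stats, "potential_stats"))
  spread <- stats$v_max - stats$v_min
  if (spread <= 0)
    stop("degenerate potential statistics: Vmax == Vmin")
  if (stats$sigma_v <= 0)
    stop("degenerate potential statistics: sigmaV == 0")
  fallback <- FALSE
  if (bound_mode == "upper" && sigma0 >= stats$sigma_v) {
    warning("upper bound requires sigma0 < sigmaV; falling back to lower")
    bound_mode <- "lower"
    fallback <- TRUE
  }
  if (bound_mode == "lower") {
    k0 <- min(1, (sigma0 / stats$sigma_v) * spread /
                   (stats$v_max - stats$v_avg))
    k <- k0 / spread
    E <- stats$v_max
  } else {
    k0 <- (1 - sigma0 / stats$sigma_v) * spread /
      (stats$v_avg - stats$v_min)
    k0 <- min(1, k0)
    k <- k0 / spread
    E <- stats$v_min + 1 / k
  }
  structure(list(E = E, k0 = k0, k = k, sigma0 = sigma0,
                 bound_mode = bound_mode, fallback = fallback),
            class = "gamd_params")
}

#' @export
print.gamd_params <- function(x, ...) {
  cat(sprintf("gamd_params: E %.4g  k0 %.4g  k %.4g  (%s bound%s)\n",
              x$E, x$k0, x$k, x$bound_mode,
              if (x$fallback) ", fallback" else ""))
  invisible(x)
}

#' GaMD boost potential
#'
#' `dV = 0` when `V >= E`, otherwise `dV = 0.5 * k * (E - V)^2`.  The
#' boosted surface `V* = V + dV` preserves the energy ordering of any two
#' states and compresses their gap whenever `E` lies in its admissible
#' range `[Vmax, Vmin + 1/k]`.
#'
#' @param V numeric vector of potential energies (kcal/mol).
#' @param params a [compute_k0()] result (or any list with `E` and `k`).
#' @return numeric vector of boost energies `dV >= 0`.
#' @examples
#' p <- list(E = 5, k = 0.5)
#' gamd_boost(3, p)   # 0.5 * 0.5 * 2^2 = 1
#' gamd_boost(10, p)  # 0: above the reference energy
#' @export
gamd_boost <- function(V, params) {
  ifelse(V >= params$E, 0, 0.5 * params$k * (params$E - V)^2)
}

#' Per-frame boost record of a (possibly boosted) run
#'
#' @param V per-frame total potential (kcal/mol).
#' @param dV per-frame boost (kcal/mol, all >= 0).
#' @param temperature simulation temperature (K).
#' @param timestep integration step (AKMA-like units).
#' @param seed integer seed of the run.
#' @return object of class `boost_record`: a data frame `frame, V, dV`
#'   with run metadata attributes.
#' @export
boost_record <- function(V, dV, temperature = 300, timestep = NA,
                         seed = NA) {
  if (length(V) != length(dV)) stop("V and dV lengths differ")
  if (any(dV < 0)) stop("boost energies must be non-negative")
  rec <- data.frame(frame = seq_along(V), V = V, dV = dV)
  attr(rec, "temperature") <- temperature
  attr(rec, "timestep") <- timestep
  attr(rec, "seed") <- seed
  class(rec) <- c("boost_record", "data.frame")
  rec
}

#' Write / read a boost record as CSV (columns frame, V, dV)
#' @param record a [boost_record()].
#' @param file path.
#' @param temperature temperature to attach on read (K).
#' @return `file` (write) or a `boost_record` (read).
#' @export
write_boost_csv <- function(record, file) {
  write.csv(as.data.frame(record)[, c("frame", "V", "dV")], file,
            row.names = FALSE)
  invisible(file)
}

#' @rdname write_boost_csv
#' @export
read_boost_csv <- function(file, temperature = 300) {
  df <- read.csv(file)
  boost_record(df$V, df$dV, temperature = temperature)
}

#' Langevin dynamics on an analytic potential, optionally GaMD-boosted
#'
#' BAOAB-split Langevin integration; with `friction = 0` the scheme
#' reduces to velocity Verlet and conserves energy, which is how the
#' integrator is validated.  With `params` supplied, forces include the
#' boost gradient `-d(dV)/dx`, i.e. the unboosted force scaled by
#' `1 - k (E - V)` wherever `V < E`; with `params = NULL` the run is plain
#' (unbiased) dynamics and `dV` is identically zero.
#'
#' The timestep must resolve the stiffest well: for a harmonic frequency
#' `omega = sqrt(ks / m)` the stability limit is `dt < 2 / omega`, and
#' `dt <= 0.1 / omega` is used in the package defaults.
#'
#' @param potential an `analytic_potential`.
#' @param params optional [compute_k0()] result enabling the boost.
#' @param temperature bath temperature (K); 300 by default.
#' @param n_steps integration steps.
#' @param timestep step size (AKMA-like time units).
#' @param friction collision frequency (inverse time units).
#' @param mass particle mass (amu).
#' @param x0 initial configuration (defaults to the origin or a well
#'   minimum for the double wells).
#' @param stride record every `stride`-th step.
#' @param seed integer seed (all stochasticity in the run flows from it).
#' @param domain_limit abort when `|x|` exceeds this bound (divergence
#'   guard).
#' @return list with `coords` (matrix n_rec x dim), `boost` (a
#'   [boost_record()]), and `final_energy` (kinetic + potential, for
#'   conservation checks).
#' @export
run_langevin <- function(potential, params = NULL, temperature = 300,
                         n_steps = 10000, timestep = 0.02, friction = 1,
                         mass = 1, x0 = NULL, stride = 1, seed = 1,
                         domain_limit = 1e3) {
  stopifnot(inherits(potential, "analytic_potential"))
  if (is.null(x0)) {
    x0 <- rep(0, potential$dim)
    if (potential$name %in% c("double_well", "double_well_2d"))
      x0[1] <- -potential$par[2]
  }
  boosted <- !is.null(params)
  res <- .langevin_cpp(potential$id, potential$par, as.numeric(x0),
                       mass, temperature, friction, timestep,
                       as.integer(n_steps), as.integer(stride),
                       boosted,
                       if (boosted) params$E else 0,
                       if (boosted) params$k else 0,
                       as.integer(seed), domain_limit)
  list(coords = res$coords,
       boost = boost_record(as.numeric(res$V), as.numeric(res$dV),
                            temperature = temperature, timestep = timestep,
                            seed = seed),
       final_energy = res$final_energy)
}

#' Staged GaMD run on a model potential
#'
#' Mirrors the staged protocol of a production GaMD study at toy scale:
#' an unbiased segment collects the potential statistics, the statistics
#' are frozen into boost parameters, and a boosted production run records
#' the per-frame boost for reweighting.
#'
#' @param potential an `analytic_potential`.
#' @param n_equil unbiased (statistics-collection) steps.
#' @param n_prod boosted production steps.
#' @param sigma0,bound_mode passed to [compute_k0()].
#' @param verbose print the run parameters (E, k0, k and the statistics).
#' @inheritParams run_langevin
#' @return list with `stats`, `params`, `equil` and `production` run
#'   results (each as returned by [run_langevin()]).
#' @export
gamd_simulate <- function(potential, n_equil = 20000, n_prod = 100000,
                          sigma0 = 6.0, bound_mode = "lower",
                          temperature = 300, timestep = 0.02, friction = 1,
                          mass = 1, stride = 1, seed = 1, verbose = FALSE) {
  equil <- run_langevin(potential, NULL, temperature, n_equil, timestep,
                        friction, mass, stride = stride, seed = seed)
  stats <- collect_stats(equil$boost$V)
  params <- compute_k0(stats, sigma0 = sigma0, bound_mode = bound_mode)
  if (verbose)
    message(sprintf(
      "GaMD run: E = %.4g, k0 = %.4g, k = %.4g (Vmax %.4g Vmin %.4g Vavg %.4g sigmaV %.4g)",
      params$E, params$k0, params$k, stats$v_max, stats$v_min, stats$v_avg,
      stats$sigma_v))
  prod <- run_langevin(potential, params, temperature, n_prod, timestep,
                       friction, mass,
                       x0 = equil$coords[nrow(equil$coords), ],
                       stride = stride, seed = seed + 1L)
  list(stats = stats, params = params, equil = equil, production = prod)
}
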