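#' Binding free energy component set (MM-GBSA-style bookkeeping)
#'
#' Holds the five enthalpy components of an end-state binding free energy
#' calculation - gas-phase electrostatics `dEele` and van der Waals
#' `dEvdw`, generalized-Born polar solvation `dGgb`, nonpolar surface
#' term `dGsurf`, and the self-consistent-field correction `dGscf` of the
#' QM region - plus the entropy penalty stored as the `-T dS` value
#' (positive when binding is entropically unfavourable, matching how such
#' tables are printed).  All energies in kcal/mol.
#'
#' @param dEele,dEvdw,dGgb,dGsurf,dGscf enthalpy components (kcal/mol).
#' @param minus_TdS entropy contribution as the `-T dS` value (kcal/mol).
#' @param system optional system label.
#' @return object of class `energy_components`.
#' @export
energy_components <- function(dEele, dEvdw, dGgb, dGsurf, dGscf,
                              minus_TdS, system = NA_character_) {
  vals <- list(dEele = dEele, dEvdw = dEvdw, dGgb = dGgb, dGsurf = dGsurf,
               dGscf = dGscf, minus_TdS = minus_TdS)
  missing <- names(vals)[vapply(vals, function(v)
    is.null(v) || length(v) != 1L || is.na(v), TRUE)]
  if (length(missing) > 0)
    stop("missing energy component(s): ", paste(missing, collapse = ", "))
  structure(c(vals, list(system = system)), class = "energy_components")
}

#' Aggregate components into binding enthalpy and free energy
#'
#' `dH = dEele + dEvdw + dGgb + dGsurf + dGscf` and
#' `dGbind = dH + (-T dS)` (exact sums of the stored values).
#'
#' @param components an [energy_components()] object.
#' @return the object with `dH` and `dGbind` fields added.
#' @examples
#' x <- energy_components(0.09, -52.14, 30.43, -5.90, -10.72, 17.20)
#' aggregate_energy(x)$dGbind
#' @export
aggregate_energy <- function(components) {
  stopifnot(inherits(components, "energy_components"))
  components$dH <- components$dEele + components$dEvdw + components$dGgb +
    components$dGsurf + components$dGscf
  components$dGbind <- components$dH + components$minus_TdS
  components
}

#' @export
print.energy_components <- function(x, ...) {
  cat("energy_components", if (!is.na(x$system)) paste0("[", x$system, "]"),
      "\n")
  for (f in c("dEele", "dEvdw", "dGgb", "dGsurf", "dGscf", "minus_TdS",
              "dH", "dGbind"))
    if (!is.null(x[[f]])) cat(sprintf("  %-10s %8.2f kcal/mol\n", f, x[[f]]))
  invisible(x)
}

#' Binding strengthening caused by a partner protein
#'
#' `ddG = dGbind(without partner) - dGbind(with partner)`; positive means
#' the partner strengthens inhibitor binding.
#'
#' @param dGbind_with binding free energy of the complex with the partner
#'   protein bound (kcal/mol).
#' @param dGbind_without binding free energy without the partner.
#' @return `ddG` in kcal/mol.
#' @export
vcyclin_effect <- function(dGbind_with, dGbind_without) {
  dGbind_without - dGbind_with
}

#' Nonpolar solvation term from a buried surface area
#'
#' `dGsurf = gamma * dSASA + beta` with the customary coefficients
#' `gamma = 0.0072 kcal/mol/A^2` and `beta = 0`.
#'
#' @param delta_sasa buried solvent-accessible surface area (A^2,
#'   negative on binding).
#' @param gamma surface tension coefficient (kcal/mol/A^2).
#' @param beta_const constant offset (kcal/mol).
#' @return `dGsurf` in kcal/mol.
#' @export
nonpolar_term <- function(delta_sasa, gamma = 0.0072, beta_const = 0) {
  if (!all(is.finite(delta_sasa))) stop("`delta_sasa` must be finite")
  gamma * delta_sasa + beta_const
}

#' Experimental binding free energy from an IC50
#'
#' `dGexp = R T log(IC50 / 1 M)` with
#' `R = 0.0019872 kcal/mol/K` - negative (favourable) for sub-molar
#' IC50, zero at 1 M.  This is the binding-free-energy convention of
#' the usual `dG = -RT log(1/IC50)` relation.
#'
#' @param ic50 half-maximal inhibitory concentration in molar.
#' @param temperature temperature in K.
#' @return `dGexp` in kcal/mol.
#' @examples
#' dg_from_ic50(15e-9, 298)   # a 15 nM inhibitor: about -10.7 kcal/mol
#' @export
dg_from_ic50 <- function(ic50, temperature = 300) {
  if (any(ic50 <= 0)) stop("IC50 must be positive")
  .kB * temperature * log(ic50)
}

#' Consistency check of a side-chain/backbone decomposition row
#'
#' Verifies the three identities `TvdW = SvdW + BvdW`,
#' `Tele = Sele + Bele`, `Tgb = Sgb + Bgb` at a rounding tolerance, and
#' reports the residual of `dG` against `TvdW + Tele + Tgb` (expected
#' nonzero: the nonpolar surface part of a per-residue free energy is not
#' tabulated in such decompositions).
#'
#' @param row named list / one-row data frame with `SvdW`, `BvdW`,
#'   `TvdW`, `Sele`, `Bele`, `Tele`, `Sgb`, `Bgb`, `Tgb`, `dG`.
#' @param tol identity tolerance in kcal/mol (default 0.02, the rounding
#'   drift of a two-decimal table).
#' @return list with per-term logical `ok`, `residuals`, the overall
#'   `passed` flag and `dg_residual`.
#' @export
check_decomposition <- function(row, tol = 0.02) {
  res <- c(vdw = row$TvdW - (row$SvdW + row$BvdW),
           ele = row$Tele - (row$Sele + row$Bele),
           gb = row$Tgb - (row$Sgb + row$Bgb))
  ok <- abs(res) <= tol + 1e-9
  list(ok = ok, residuals = res, passed = all(ok),
       dg_residual = row$dG - (row$TvdW + row$Tele + row$Tgb))
}

#' Load a binding energy component table
#'
#' Reads a CSV with one row per system and columns `system`, `dEele`,
#' `dEvdw`, `dGgb`, `dGsurf`, `dGscf`, `minus_TdS` (extra columns such as
#' printed `dH` / `dGbind` are carried through).  The packaged reference
#' table for the four inhibitor-bound CDK6 systems (LQQ and AP9, each
#' with and without the Vcyclin partner protein) is returned when `file`
#' is omitted.
#'
#' @param file CSV path (default: the packaged reference table).
#' @return data frame of components.
#' @export
load_energy_table <- function(file = system.file("extdata",
                                                 "cdk6_energy_components.csv",
                                                 package = "gamdl")) {
  df <- read.csv(file, check.names = FALSE, comment.char = "#")
  need <- c("system", "dEele", "dEvdw", "dGgb", "dGsurf", "dGscf",
            "minus_TdS")
  if (!all(need %in% names(df)))
    stop("component table must have columns ", paste(need, collapse = ", "))
  df
}

#' Load a per-residue side-chain/backbone decomposition table
#'
#' Columns `system`, `residue`, `SvdW`, `BvdW`, `TvdW`, `Sele`, `Bele`,
#' `Tele`, `Sgb`, `Bgb`, `Tgb`, `dG`.  The packaged reference table for
#' the inhibitor-contacting residues of the four CDK6 systems is returned
#' when `file` is omitted.
#'
#' @param file CSV path (default: the packaged reference table).
#' @return data frame with one row per residue and system.
#' @export
load_decomposition_table <- function(file = system.file(
  "extdata", "cdk6_decomposition.csv", package = "gamdl")) {
  read.csv(file, check.names = FALSE, comment.char = "#")
}

#' Aggregate every row of a component table
#'
#' @param table a [load_energy_table()] data frame.
#' @return the table with computed `dH_sum` and `dGbind_sum` columns
#'   appended (sums of the stored components, independent of any printed
#'   `dH` / `dGbind` columns carried in the file).
#' @export
aggregate_energy_table <- function(table) {
  out <- table
  out$dH_sum <- with(table, dEele + dEvdw + dGgb + dGsurf + dGscf)
  # dGbind is referenced to the printed enthalpy when present so the
  # stored-value identity dGbind = dH + (-T dS) holds exactly
  dh <- if ("dH" %in% names(table)) table$dH else out$dH_sum
  out$dGbind_sum <- dh + table$minus_TdS
  out
}
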