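#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' mobile selection onto the reference.  The rotation determinant is +1
#' (no reflection).
#'
#' @param mobile n x 3 coordinate matrix (or a `trajectory_ensemble` with
#'   `frame`).
#' @param reference n x 3 coordinate matrix aligned atom-by-atom with
#'   `mobile`.
#' @param selection optional atom indices used for the fit (default all).
#' @param frame frame index when `mobile` is a trajectory.
#' @return object of class `superposition`: `rotation` (3 x 3),
#'   `translation` (length 3), `rmsd` (Angstrom), and `fitted`
#'   (transformed full mobile coordinates).
#' @export
superpose <- function(mobile, reference, selection = NULL, frame = 1L) {
  if (inherits(mobile, "trajectory_ensemble"))
    mobile <- frame_coords(mobile, frame)
  if (inherits(reference, "trajectory_ensemble"))
    reference <- frame_coords(reference, frame)
  if (!is.null(selection)) {
    msel <- mobile[selection, , drop = FALSE]
    rsel <- reference[selection, , drop = FALSE]
  } else {
    msel <- mobile; rsel <- reference
  }
  if (nrow(msel) < 3L) stop("at least 3 atoms are required for a rigid fit")
  cm <- colMeans(msel); cr <- colMeans(rsel)
  X <- sweep(msel, 2, cm); Y <- sweep(rsel, 2, cr)
  sv_ref <- svd(Y)$d
  if (sv_ref[2] < 1e-8 * max(sv_ref[1], 1))
    stop("degenerate (collinear) selection: rigid fit is ill-defined")
  s <- svd(crossprod(X, Y))
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  fitted_sel <- X %*% R
  rmsd <- sqrt(mean(rowSums((fitted_sel - Y)^2)))
  translation <- cr - as.vector(cm %*% R)
  fitted <- sweep(mobile %*% R, 2, translation, `+`)
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 fitted = fitted), class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: RMSD %.4f A\n", x$rmsd))
  invisible(x)
}

#' Per-frame RMSD series and its probability distribution
#'
#' Each frame is rigidly fitted to the reference over the selection, then
#' the RMSD over that selection is reported.  The distribution is a
#' normalized density histogram with a fixed bin width.
#'
#' @param traj a `trajectory_ensemble`.
#' @param reference reference frame index or an n x 3 matrix (default the
#'   first frame, i.e. RMSD relative to the initial structure).
#' @param selection `"calpha"`, `"all"`, or atom indices.
#' @param fit superpose each frame before measuring (default TRUE).
#' @param bin_width histogram bin width in Angstrom (default 0.1).
#' @return list with `rmsd` (per frame, Angstrom) and `distribution`
#'   (data frame `center`, `density`; integrates to 1).
#' @export
rmsd_series <- function(traj, reference = 1L, selection = "calpha",
                        fit = TRUE, bin_width = 0.1) {
  sel <- .resolve_selection(traj, selection)
  ref <- if (is.matrix(reference)) reference else frame_coords(traj, reference)
  nf <- n_frames(traj)
  out <- numeric(nf)
  refsel <- ref[sel, , drop = FALSE]
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)[sel, , drop = FALSE]
    out[f] <- if (fit) superpose(xyz, refsel)$rmsd
    else sqrt(mean(rowSums((xyz - refsel)^2)))
  }
  edges <- seq(0, max(out) + bin_width, by = bin_width)
  h <- tabulate(findInterval(out, edges, rightmost.closed = TRUE),
                nbins = length(edges) - 1L)
  dens <- h / (sum(h) * bin_width)
  list(rmsd = out,
       distribution = data.frame(center = (edges[-1] + edges[-length(edges)]) / 2,
                                 density = dens))
}

# superpose every frame onto a reference over a selection; returns the
# n_frames x (3 * n_sel) matrix of fitted selected coordinates
.fit_frames <- function(traj, sel, ref_sel) {
  nf <- n_frames(traj)
  F <- matrix(NA_real_, nf, 3L * length(sel))
  for (f in seq_len(nf)) {
    xyz <- frame_coords(traj, f)[sel, , drop = FALSE]
    F[f, ] <- as.vector(t(superpose(xyz, ref_sel)$fitted))
  }
  F
}

#' Per-residue root-mean-square fluctuation
#'
#' Frames are superposed onto the first frame, the time-mean structure is
#' computed, and all frames are re-fitted to that mean (one iteration);
#' the RMSF of atom `i` is the root-mean-square displacement from its
#' mean position.
#'
#' @param traj a `trajectory_ensemble` with at least 2 frames.
#' @param selection `"calpha"` (default) or atom indices.
#' @return data frame `atom`, `resno`, `rmsf` (Angstrom).
#' @export
rmsf <- function(traj, selection = "calpha") {
  if (n_frames(traj) < 2L) stop("RMSF is undefined for a single frame")
  sel <- .resolve_selection(traj, selection)
  ref <- frame_coords(traj, 1L)[sel, , drop = FALSE]
  F <- .fit_frames(traj, sel, ref)
  mean1 <- matrix(colMeans(F), ncol = 3L, byrow = TRUE)
  F <- .fit_frames(traj, sel, mean1)
  mu <- colMeans(F)
  dev2 <- sweep(F, 2, mu)^2
  per_atom <- sqrt(rowSums(matrix(colMeans(dev2), ncol = 3L, byrow = TRUE)))
  data.frame(atom = sel, resno = traj$atoms$resno[sel], rmsf = per_atom)
}

#' Principal component analysis of positional covariance
#'
#' Diagonalizes the 3N x 3N covariance matrix of the superposed selected
#' coordinates (population covariance about the time mean).  Eigenvalues
#' are sorted descending; their sum equals the total positional variance
#' (the covariance trace).
#'
#' @param traj a `trajectory_ensemble` with at least 2 frames.
#' @param selection `"calpha"` (default) or atom indices.
#' @param max_atoms guard for the dense eigendecomposition (default 1000
#'   atoms, i.e. a 3000 x 3000 covariance).
#' @return object of class `pca_result`: `eigenvalues` (A^2),
#'   `eigenvectors` (columns, orthonormal), `mean` (3N vector),
#'   `trace`.
#' @export
pca_ca <- function(traj, selection = "calpha", max_atoms = 1000L) {
  if (n_frames(traj) < 2L) stop("PCA requires at least 2 frames")
  sel <- .resolve_selection(traj, selection)
  if (length(sel) > max_atoms)
    stop("selection of ", length(sel), " atoms exceeds the dense ",
         "eigendecomposition limit (", max_atoms, " atoms)")
  ref <- frame_coords(traj, 1L)[sel, , drop = FALSE]
  F <- .fit_frames(traj, sel, ref)
  mean1 <- matrix(colMeans(F), ncol = 3L, byrow = TRUE)
  F <- .fit_frames(traj, sel, mean1)
  mu <- colMeans(F)
  Xc <- sweep(F, 2, mu)
  C <- crossprod(Xc) / nrow(Xc)
  e <- eigen(C, symmetric = TRUE)
  structure(list(eigenvalues = pmax(e$values, 0),
                 eigenvectors = e$vectors, mean = mu,
                 trace = sum(diag(C))), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("pca_result:", length(x$eigenvalues), "modes; top eigenvalues",
      paste(sprintf("%.3g", utils::head(x$eigenvalues, 3)), collapse = ", "),
      "A^2\n")
  invisible(x)
}

#' Distance reaction coordinate between two atoms
#'
#' @param traj a `trajectory_ensemble`.
#' @param atom_a,atom_b atom indices (1-based).
#' @param name axis name (default "Ra-Rb").
#' @return an [rc_series()] of per-frame Euclidean distances (Angstrom).
#' @export
rc_distance <- function(traj, atom_a, atom_b,
                        name = paste0("d", atom_a, "-", atom_b)) {
  na <- n_atoms(traj)
  for (a in c(atom_a, atom_b))
    if (a < 1L || a > na) stop("atom index ", a, " not present (1..", na, ")")
  d <- sqrt(rowSums((traj$coords[, atom_a, , drop = FALSE] -
                       traj$coords[, atom_b, , drop = FALSE])^2))
  rc_series(name, as.numeric(d), periodic = FALSE)
}

#' Dihedral-angle reaction coordinate over four atoms
#'
#' Signed torsion in degrees, IUPAC convention (cis = 0, trans = 180,
#' positive for clockwise rotation viewed from atom 2 towards atom 3),
#' reported in (-180, 180].
#'
#' @param traj a `trajectory_ensemble`.
#' @param atoms integer vector of four distinct atom indices.
#' @param name axis name.
#' @return an [rc_series()] with `periodic = TRUE`.
#' @export
rc_dihedral <- function(traj, atoms,
                        name = paste0("chi", paste(atoms, collapse = "-"))) {
  if (length(atoms) != 4L || anyDuplicated(atoms))
    stop("`atoms` must be four distinct atom indices")
  na <- n_atoms(traj)
  if (any(atoms < 1L | atoms > na)) stop("atom index out of range")
  p <- lapply(1:4, function(i) traj$coords[, atoms[i], , drop = TRUE])
  p <- lapply(p, function(m) if (is.null(dim(m))) matrix(m, 1) else m)
  b1 <- p[[2]] - p[[1]]; b2 <- p[[3]] - p[[2]]; b3 <- p[[4]] - p[[3]]
  cross <- function(a, b)
    cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
          a[, 3] * b[, 1] - a[, 1] * b[, 3],
          a[, 1] * b[, 2] - a[, 2] * b[, 1])
  n1 <- cross(b1, b2); n2 <- cross(b2, b3)
  n1n <- sqrt(rowSums(n1^2)); n2n <- sqrt(rowSums(n2^2))
  if (any(n1n < 1e-10) || any(n2n < 1e-10))
    stop("undefined dihedral: three consecutive atoms are collinear")
  x <- rowSums(n1 * n2)
  y <- rowSums(n1 * b3) * sqrt(rowSums(b2^2))
  ang <- .wrap180(atan2(y, x) * 180 / pi)
  rc_series(name, ang, periodic = TRUE)
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' A frame counts as bound when the donor-acceptor distance is strictly
#' below 3.5 Angstrom AND the donor-hydrogen-acceptor angle is strictly
#' above 120 degrees (boundary values are not bound).  Mean distance and
#' angle are reported over the bound frames, matching how hydrogen-bond
#' tables are customarily tabulated.
#'
#' @param traj a `trajectory_ensemble`.
#' @param donor,hydrogen,acceptor atom indices of the D-H...A triple.
#' @param dist_cut,angle_cut criterion thresholds (default 3.5 A, 120
#'   degrees, both strict).
#' @return object of class `hbond_result`: `occupancy` (percent),
#'   `mean_distance`, `mean_angle`, `bound` (per-frame flag), `distance`
#'   and `angle` series.
#' @export
hbond_occupancy <- function(traj, donor, hydrogen, acceptor,
                            dist_cut = 3.5, angle_cut = 120) {
  na <- n_atoms(traj)
  for (a in c(donor, hydrogen, acceptor))
    if (is.na(a) || a < 1L || a > na)
      stop("hydrogen-bond atom index ", a, " not present")
  D <- matrix(traj$coords[, donor, ], ncol = 3)
  H <- matrix(traj$coords[, hydrogen, ], ncol = 3)
  A <- matrix(traj$coords[, acceptor, ], ncol = 3)
  dist <- sqrt(rowSums((D - A)^2))
  v1 <- D - H; v2 <- A - H
  cosang <- rowSums(v1 * v2) /
    (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  bound <- dist < dist_cut & ang > angle_cut
  structure(list(occupancy = 100 * mean(bound),
                 mean_distance = if (any(bound)) mean(dist[bound]) else
                   NA_real_,
                 mean_angle = if (any(bound)) mean(ang[bound]) else NA_real_,
                 bound = bound, distance = dist, angle = ang),
            class = "hbond_result")
}

#' @export
print.hbond_result <- function(x, ...) {
  cat(sprintf("hbond_result: occupancy %.1f%% (mean %.2f A / %.1f deg)\n",
              x$occupancy, x$mean_distance, x$mean_angle))
  invisible(x)
}
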