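#' Conformational trajectory ensembles
#'
#' A `trajectory_ensemble` is the common currency of the package: an ordered
#' set of frames of 3D coordinates with per-atom metadata.  Coordinates are
#' stored as an `n_frames x n_atoms x 3` array in Angstrom; atom metadata
#' follows PDB conventions (`elety` atom name, `resno` 1-based residue
#' number, `resid` residue type, `chain`).
#'
#' @param coords numeric array `n_frames x n_atoms x 3` (Angstrom).
#' @param atoms data frame with one row per atom; columns `elety`, `resno`,
#'   `resid`, `chain` (missing columns are filled with C-alpha defaults).
#' @param label optional class label attached to the whole ensemble.
#' @return an object of class `trajectory_ensemble`.
#' @examples
#' coords <- array(rnorm(2 * 3 * 3), c(2, 3, 3))
#' traj <- trajectory_ensemble(coords)
#' n_frames(traj)
#' @export
trajectory_ensemble <- function(coords, atoms = NULL, label = NULL) {
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("`coords` must be an n_frames x n_atoms x 3 array")
  n_at <- dim(coords)[2]
  if (is.null(atoms)) {
    atoms <- data.frame(elety = "CA", resno = seq_len(n_at),
                        resid = "ALA", chain = "A",
                        stringsAsFactors = FALSE)
  }
  if (nrow(atoms) != n_at)
    stop("`atoms` has ", nrow(atoms), " rows but coords has ", n_at, " atoms")
  for (col in c("elety", "resno", "resid", "chain")) {
    if (is.null(atoms[[col]]))
      atoms[[col]] <- switch(col, elety = "CA", resno = seq_len(n_at),
                             resid = "ALA", chain = "A")
  }
  structure(list(coords = coords, atoms = atoms, label = label),
            class = "trajectory_ensemble")
}

#' @export
print.trajectory_ensemble <- function(x, ...) {
  cat("trajectory_ensemble:", n_frames(x), "frames x", n_atoms(x), "atoms")
  if (!is.null(x$label)) cat("  [", x$label, "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param traj a `trajectory_ensemble`.
#' @return integer count.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame as an n_atoms x 3 coordinate matrix
#' @param traj a `trajectory_ensemble`.
#' @param i frame index (1-based).
#' @return numeric matrix `n_atoms x 3`.
#' @export
frame_coords <- function(traj, i) {
  if (i < 1L || i > n_frames(traj)) stop("frame index out of range")
  matrix(traj$coords[i, , ], ncol = 3L)
}

#' Indices of C-alpha atoms
#' @param traj a `trajectory_ensemble`.
#' @return integer vector of atom indices with atom name "CA".
#' @export
ca_indices <- function(traj) which(traj$atoms$elety == "CA")

# resolve a selection argument into atom indices
.resolve_selection <- function(traj, selection) {
  if (is.null(selection) || identical(selection, "all"))
    return(seq_len(n_atoms(traj)))
  if (identical(selection, "calpha")) {
    idx <- ca_indices(traj)
    if (length(idx) == 0L) stop("no C-alpha atoms in trajectory")
    return(idx)
  }
  idx <- as.integer(selection)
  if (any(idx < 1L | idx > n_atoms(traj)))
    stop("selection indices out of range")
  idx
}

#' Subsample a trajectory at a fixed stride
#'
#' Keeps the first frame and every `stride`-th frame after it, emulating
#' the fixed time interval at which simulation snapshots are retained for
#' featurization.
#'
#' @param traj a `trajectory_ensemble`.
#' @param stride positive integer stride.
#' @return the strided `trajectory_ensemble`.
#' @export
subsample <- function(traj, stride) {
  stride <- as.integer(stride)
  if (is.na(stride) || stride < 1L) stop("`stride` must be a positive integer")
  nf <- n_frames(traj)
  if (stride >= nf)
    warning("stride ", stride, " >= ", nf, " frames; keeping only frame 1")
  keep <- seq(1L, nf, by = stride)
  trajectory_ensemble(traj$coords[keep, , , drop = FALSE], traj$atoms,
                      traj$label)
}

#' Write an ensemble as a multi-model PDB file
#'
#' One `MODEL` block per frame, `ATOM` records only.  A sidecar CSV of
#' per-frame labels can be written alongside with [write_frame_labels()].
#'
#' @param traj a `trajectory_ensemble`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_pdb <- function(traj, file) {
  xyz <- matrix(aperm(traj$coords, c(3, 2, 1)), nrow = n_frames(traj),
                byrow = TRUE)
  bio3d::write.pdb(pdb = NULL, file = file, xyz = xyz,
                   resno = traj$atoms$resno, resid = traj$atoms$resid,
                   eleno = seq_len(n_atoms(traj)), elety = traj$atoms$elety,
                   chain = traj$atoms$chain)
  invisible(file)
}

#' Write an ensemble as a long-format coordinate CSV
#'
#' Columns: `frame`, `atom`, `elety`, `resno`, `x`, `y`, `z`; 1-based
#' indices throughout.
#'
#' @param traj a `trajectory_ensemble`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory_csv <- function(traj, file) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  df <- data.frame(
    frame = rep(seq_len(nf), each = na),
    atom  = rep(seq_len(na), times = nf),
    elety = rep(traj$atoms$elety, times = nf),
    resno = rep(traj$atoms$resno, times = nf),
    x = as.vector(t(traj$coords[, , 1])),
    y = as.vector(t(traj$coords[, , 2])),
    z = as.vector(t(traj$coords[, , 3])))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Read a trajectory from a multi-model PDB or coordinate CSV
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"pdb"`, or `"csv"`.
#' @return a `trajectory_ensemble`.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "pdb"
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty trajectory file: ", path)
  if (format == "pdb") {
    pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                    error = function(e)
                      stop("failed to parse PDB '", path, "': ",
                           conditionMessage(e)))
    nxyz <- ncol(pdb$xyz)
    if (is.null(nxyz) || nxyz < 3L) stop("no coordinates in ", path)
    na <- nxyz / 3L
    nf <- nrow(pdb$xyz)
    coords <- aperm(array(t(pdb$xyz), c(3, na, nf)), c(3, 2, 1))
    atoms <- data.frame(elety = pdb$atom$elety, resno = pdb$atom$resno,
                        resid = pdb$atom$resid, chain = pdb$atom$chain,
                        stringsAsFactors = FALSE)
    return(trajectory_ensemble(coords, atoms))
  }
  df <- read.csv(path)
  need <- c("frame", "atom", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("coordinate CSV must have columns ", paste(need, collapse = ", "))
  frames <- sort(unique(df$frame))
  counts <- table(df$frame)
  if (length(unique(counts)) != 1L)
    stop("inconsistent atom count across frames (frame ",
         names(counts)[which(counts != counts[1])[1]], ")")
  na <- unname(counts[1]); nf <- length(frames)
  df <- df[order(df$frame, df$atom), ]
  coords <- array(NA_real_, c(nf, na, 3))
  coords[, , 1] <- matrix(df$x, nf, na, byrow = TRUE)
  coords[, , 2] <- matrix(df$y, nf, na, byrow = TRUE)
  coords[, , 3] <- matrix(df$z, nf, na, byrow = TRUE)
  first <- df[df$frame == frames[1], ]
  atoms <- data.frame(
    elety = if (!is.null(first$elety)) first$elety else "CA",
    resno = if (!is.null(first$resno)) first$resno else seq_len(na),
    resid = "ALA", chain = "A", stringsAsFactors = FALSE)
  trajectory_ensemble(coords, atoms)
}

#' Write / read a per-frame class label sidecar CSV
#'
#' @param labels character or factor vector, one entry per frame.
#' @param file path of the sidecar CSV (columns `frame`, `label`).
#' @return `file` (write) or a character vector of labels (read).
#' @export
write_frame_labels <- function(labels, file) {
  write.csv(data.frame(frame = seq_along(labels),
                       label = as.character(labels)),
            file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_frame_labels
#' @export
read_frame_labels <- function(file) {
  df <- read.csv(file)
  as.character(df$label[order(df$frame)])
}
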