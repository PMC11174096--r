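#' Residue contact map of a frame
#'
#' Binary symmetric matrix with entry (i, j) = 1 when the C-alpha /
#' C-alpha distance is less than or equal to the cutoff (boundary
#' inclusive).  The diagonal is 1 (zero distance always satisfies the
#' cutoff); no sequence-separation exclusion is applied, so chain
#' neighbours (~3.8 Angstrom apart) are in contact, as in a real protein.
#'
#' @param frame an n x 3 coordinate matrix of the selected atoms, or a
#'   `trajectory_ensemble` (then `frame_index` and `selection` apply).
#' @param cutoff contact cutoff in Angstrom (default 4.5).
#' @param frame_index frame to use when `frame` is a trajectory.
#' @param selection atom selection when `frame` is a trajectory
#'   (default `"calpha"`).
#' @return integer 0/1 matrix of class `contact_map`.
#' @examples
#' xyz <- rbind(c(0, 0, 0), c(4.4, 0, 0), c(10, 0, 0))
#' contact_map(xyz)  # residues 1-2 in contact, 3 isolated
#' @export
contact_map <- function(frame, cutoff = 4.5, frame_index = 1L,
                        selection = "calpha") {
  if (inherits(frame, "trajectory_ensemble")) {
    if (identical(selection, "calpha")) {
      resno <- unique(frame$atoms$resno)
      has_ca <- resno %in% frame$atoms$resno[frame$atoms$elety == "CA"]
      if (!all(has_ca))
        stop("residue ", resno[!has_ca][1], " has no C-alpha atom")
    }
    sel <- .resolve_selection(frame, selection)
    frame <- frame_coords(frame, frame_index)[sel, , drop = FALSE]
  }
  if (nrow(frame) < 2L) stop("a contact map needs at least 2 atoms")
  m <- (as.matrix(stats::dist(frame)) <= cutoff) * 1L
  diag(m) <- 1L
  dimnames(m) <- NULL
  class(m) <- c("contact_map", class(m))
  m
}

#' Contact maps for every (strided) frame of a trajectory
#'
#' @param traj a `trajectory_ensemble`.
#' @param cutoff contact cutoff (Angstrom).
#' @param selection atom selection (default `"calpha"`).
#' @param stride keep every `stride`-th frame (see [subsample()]).
#' @return list of `contact_map` matrices; attribute `frames` records the
#'   source frame index of each map.
#' @export
contact_maps <- function(traj, cutoff = 4.5, selection = "calpha",
                         stride = 1L) {
  keep <- seq(1L, n_frames(traj), by = as.integer(stride))
  sel <- .resolve_selection(traj, selection)
  maps <- lapply(keep, function(f)
    contact_map(frame_coords(traj, f)[sel, , drop = FALSE], cutoff = cutoff))
  attr(maps, "frames") <- keep
  maps
}

#' Grayscale image stack from binary contact maps
#'
#' Maps contact 1 to intensity 255 and 0 to 0; the transform is lossless,
#' so `image_to_map()` inverts it exactly.
#'
#' @param maps list of `contact_map` matrices (homogeneous size).
#' @param labels class label per map (length 1 is recycled).
#' @return object of class `contact_image_set`: `pixels` (H*W x n matrix
#'   of 0/255 intensities, column-major pixels), `height`, `width`,
#'   `labels` (factor), `frames`.
#' @export
to_images <- function(maps, labels) {
  if (length(maps) == 0L) stop("no maps supplied")
  ns <- vapply(maps, nrow, 1L)
  if (length(unique(ns)) != 1L ||
      length(unique(vapply(maps, ncol, 1L))) != 1L)
    stop("contact maps have inconsistent sizes")
  if (length(labels) == 1L) labels <- rep(labels, length(maps))
  if (length(labels) != length(maps))
    stop("label count (", length(labels), ") does not match map count (",
         length(maps), ")")
  px <- vapply(maps, function(m) as.numeric(m) * 255,
               numeric(ns[1] * ncol(maps[[1]])))
  frames <- attr(maps, "frames")
  structure(list(pixels = px, height = ns[1], width = ncol(maps[[1]]),
                 labels = factor(labels),
                 frames = if (is.null(frames)) seq_along(maps) else frames),
            class = "contact_image_set")
}

#' @export
print.contact_image_set <- function(x, ...) {
  cat("contact_image_set:", ncol(x$pixels), "images of", x$height, "x",
      x$width, "pixels;", nlevels(x$labels), "classes\n")
  invisible(x)
}

#' Number of images in a `contact_image_set`
#' @param images a `contact_image_set`.
#' @return integer count.
#' @export
n_images <- function(images) ncol(images$pixels)

#' Recover the binary contact map behind one image
#' @param images a `contact_image_set`.
#' @param i image index.
#' @return a `contact_map` matrix.
#' @export
image_to_map <- function(images, i) {
  m <- matrix(as.integer(images$pixels[, i] > 127), images$height,
              images$width)
  class(m) <- c("contact_map", class(m))
  m
}

#' Combine image sets (same image size) into one labelled stack
#' @param ... `contact_image_set` objects.
#' @return a single `contact_image_set`.
#' @export
combine_images <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "contact_image_set"))
    sets <- sets[[1]]
  h <- unique(vapply(sets, `[[`, 1L, "height"))
  w <- unique(vapply(sets, `[[`, 1L, "width"))
  if (length(h) != 1L || length(w) != 1L)
    stop("image sets have different sizes")
  structure(list(pixels = do.call(cbind, lapply(sets, `[[`, "pixels")),
                 height = h, width = w,
                 labels = factor(unlist(lapply(sets, function(s)
                   as.character(s$labels)))),
                 frames = unlist(lapply(sets, `[[`, "frames"))),
            class = "contact_image_set")
}

#' Write / read a contact map as an 8-bit grayscale PNG
#' @param map a `contact_map` (0/1) matrix.
#' @param file PNG path.
#' @return `file` (write) or a `contact_map` (read).
#' @export
write_contact_png <- function(map, file) {
  png::writePNG(unclass(map) * 1.0, file)
  invisible(file)
}

#' @rdname write_contact_png
#' @export
read_contact_png <- function(file) {
  m <- png::readPNG(file)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m <- (m > 0.5) * 1L
  class(m) <- c("contact_map", class(m))
  m
}

#' Write a contact map as CSV (1-based residue indices in the header)
#' @param map a `contact_map`.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_contact_csv <- function(map, file) {
  m <- as.data.frame(unclass(map))
  names(m) <- paste0("res", seq_len(ncol(m)))
  write.csv(m, file, row.names = FALSE)
  invisible(file)
}

#' Write an image manifest (path, label, frame) for an image set
#' @param images a `contact_image_set`.
#' @param file CSV path.
#' @param paths optional vector of per-image file paths.
#' @return `file`, invisibly.
#' @export
write_image_manifest <- function(images, file, paths = NA_character_) {
  write.csv(data.frame(path = paths, label = as.character(images$labels),
                       frame = images$frames),
            file, row.names = FALSE)
  invisible(file)
}
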