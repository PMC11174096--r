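#' Reaction coordinate series
#'
#' A named per-frame scalar observable used as a free-energy-landscape
#' axis.  Periodic series (dihedrals) are wrapped into (-180, 180].
#'
#' @param name axis name.
#' @param values numeric per-frame values (Angstrom or degrees).
#' @param periodic TRUE for dihedral angles (period 360 degrees).
#' @return object of class `rc_series`.
#' @export
rc_series <- function(name, values, periodic = FALSE) {
  if (periodic) values <- .wrap180(values)
  structure(list(name = name, values = as.numeric(values),
                 periodic = periodic), class = "rc_series")
}

# wrap angles into (-180, 180]
.wrap180 <- function(x) {
  y <- x - 360 * floor((x + 180) / 360)
  y[y == -180] <- 180
  y
}

# bin edges for one axis
.axis_edges <- function(values, bins, periodic) {
  if (periodic) return(seq(-180, 180, length.out = bins + 1L))
  r <- range(values)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  pad <- diff(r) * 1e-8
  seq(r[1] - pad, r[2] + pad, length.out = bins + 1L)
}

#' Unreweighted potential of mean force over 1 or 2 reaction coordinates
#'
#' Histograms the frames and converts bin probabilities to a free energy
#' `F* = -kB T log(count / total)`, anchored so the minimum over occupied
#' bins is exactly 0.  Empty bins are `NA` (missing), never a finite cap.
#'
#' @param rc an [rc_series()] or list of two aligned `rc_series`.
#' @param bins bin count per axis (scalar or length-2); dihedral axes span
#'   (-180, 180] exactly.
#' @param temperature temperature (K) used for kB T.
#' @return object of class `fel_grid`: axes, per-bin `pmf`, `counts`,
#'   `frame_bins` (linear bin index per frame), `temperature`.
#' @examples
#' rc <- rc_series("d", c(rep(1, 100), rep(2, 37)))
#' g <- histogram_pmf(rc, bins = 2, temperature = 300)
#' diff(range(g$pmf))  # -kB T log(37/100) = 0.593 kcal/mol
#' @export
histogram_pmf <- function(rc, bins = 50, temperature = 300) {
  if (inherits(rc, "rc_series")) rc <- list(rc)
  if (!length(rc) %in% 1:2) stop("1 or 2 reaction coordinates required")
  n <- length(rc[[1]]$values)
  if (n == 0L) stop("no frames to histogram")
  if (length(rc) == 2L && length(rc[[2]]$values) != n)
    stop("reaction coordinate series are not aligned")
  bins <- rep(as.integer(bins), length.out = length(rc))
  axes <- vector("list", length(rc))
  idx <- vector("list", length(rc))
  for (a in seq_along(rc)) {
    edges <- .axis_edges(rc[[a]]$values, bins[a], rc[[a]]$periodic)
    i <- findInterval(rc[[a]]$values, edges, rightmost.closed = TRUE)
    i[i < 1L | i > bins[a]] <- NA_integer_
    axes[[a]] <- list(name = rc[[a]]$name, edges = edges,
                      centers = (edges[-1] + edges[-length(edges)]) / 2,
                      periodic = rc[[a]]$periodic)
    idx[[a]] <- i
  }
  nb <- prod(bins)
  lin <- if (length(rc) == 1L) idx[[1]] else
    idx[[1]] + (idx[[2]] - 1L) * bins[1]
  counts_v <- tabulate(lin, nbins = nb)
  kT <- .kB * temperature
  pmf_v <- ifelse(counts_v > 0, -kT * log(counts_v / sum(counts_v)), NA_real_)
  pmf_v <- pmf_v - min(pmf_v, na.rm = TRUE)
  shape <- function(v) if (length(rc) == 1L) v else matrix(v, bins[1], bins[2])
  structure(list(axes = axes, counts = shape(counts_v),
                 pmf = shape(pmf_v), c1 = NULL, c2 = NULL,
                 reliable = shape(counts_v > 0), frame_bins = lin,
                 temperature = temperature, order = 0L,
                 reweighted = FALSE),
            class = "fel_grid")
}

#' @export
print.fel_grid <- function(x, ...) {
  dims <- paste(vapply(x$axes, function(a) length(a$centers), 1L),
                collapse = " x ")
  cat("fel_grid:", dims, "bins over",
      paste(vapply(x$axes, `[[`, "", "name"), collapse = ", "),
      if (x$reweighted) sprintf("(reweighted, order %d)", x$order)
      else "(unreweighted)", "\n")
  invisible(x)
}

#' Cumulant-expansion reweighting of a boosted free energy profile
#'
#' Recovers the canonical potential of mean force from a GaMD run.  Per
#' occupied bin the boost cumulants `C1 = mean(dV)` and `C2 = var(dV)`
#' (population variance) are accumulated over that bin's frames and the
#' modified free energy is corrected by the cumulant expansion of
#' `-kB T log < exp(beta dV) >`:
#' `F = F* - (C1 + beta/2 * C2)` at order 2 (`F = F* - C1` at order 1),
#' with `beta = 1/(kB T)`, then re-anchored so the minimum over reliable
#' bins is 0.  Bins with fewer frames than `min_frames` are flagged
#' unreliable and excluded from anchoring.
#'
#' @param grid a [histogram_pmf()] result.
#' @param boost a [boost_record()] aligned to the frames that built the
#'   grid (`dV` identically zero reproduces the input profile).
#' @param order cumulant expansion order, 1 or 2 (default 2).
#' @param min_frames reliability floor per bin (default 10).
#' @return the reweighted `fel_grid` (with `c1`, `c2`, `reliable` filled).
#' @export
cumulant_reweight <- function(grid, boost, order = 2L, min_frames = 10L) {
  stopifnot(inherits(grid, "fel_grid"))
  if (!order %in% 1:2) stop("`order` must be 1 or 2")
  dV <- boost$dV
  if (length(dV) != length(grid$frame_bins))
    stop("boost record has ", length(dV), " frames but the grid was built ",
         "from ", length(grid$frame_bins))
  nb <- length(grid$counts)
  lin <- grid$frame_bins
  ok <- !is.na(lin)
  s1 <- rowsum(dV[ok], lin[ok])
  s2 <- rowsum(dV[ok]^2, lin[ok])
  bins_seen <- as.integer(rownames(s1))
  c1 <- c2 <- rep(NA_real_, nb)
  counts_v <- as.vector(grid$counts)
  c1[bins_seen] <- s1 / counts_v[bins_seen]
  c2[bins_seen] <- s2 / counts_v[bins_seen] - (s1 / counts_v[bins_seen])^2
  c2 <- pmax(c2, 0) # clip negative rounding residue of the variance
  kT <- .kB * grid$temperature
  beta <- 1 / kT
  fstar <- as.vector(grid$pmf)
  corr <- if (order == 1L) c1 else c1 + beta / 2 * c2
  f <- fstar - corr
  reliable_v <- counts_v >= min_frames
  if (!any(reliable_v)) stop("no bin reaches the reliability floor")
  f <- f - min(f[reliable_v], na.rm = TRUE)
  shape <- function(v) if (is.matrix(grid$counts))
    matrix(v, nrow(grid$counts), ncol(grid$counts)) else v
  out <- grid
  out$pmf <- shape(f)
  out$c1 <- shape(c1)
  out$c2 <- shape(c2)
  out$reliable <- shape(reliable_v)
  out$order <- as.integer(order)
  out$reweighted <- TRUE
  out
}

#' Export a free energy landscape as long-format CSV plus JSON metadata
#'
#' CSV columns: bin centers (one per axis), `pmf`, `count`, `c1`, `c2`,
#' `reliable`; the sidecar records temperature, expansion order and bin
#' edges.
#'
#' @param grid an `fel_grid`.
#' @param file CSV path; metadata goes to `<file>.json` unless
#'   `meta_file` is given.
#' @param meta_file optional JSON sidecar path.
#' @return `file`, invisibly.
#' @export
write_fel_csv <- function(grid, file, meta_file = paste0(file, ".json")) {
  stopifnot(inherits(grid, "fel_grid"))
  dims <- vapply(grid$axes, function(a) length(a$centers), 1L)
  centers <- lapply(grid$axes, `[[`, "centers")
  df <- if (length(dims) == 1L)
    data.frame(x = centers[[1]]) else
    expand.grid(x = centers[[1]], y = centers[[2]])
  names(df) <- vapply(grid$axes, `[[`, "", "name")
  df$pmf <- as.vector(grid$pmf)
  df$count <- as.vector(grid$counts)
  df$c1 <- if (is.null(grid$c1)) NA_real_ else as.vector(grid$c1)
  df$c2 <- if (is.null(grid$c2)) NA_real_ else as.vector(grid$c2)
  df$reliable <- as.vector(grid$reliable)
  write.csv(df, file, row.names = FALSE)
  meta <- list(temperature = grid$temperature, order = grid$order,
               reweighted = grid$reweighted,
               axes = lapply(grid$axes, function(a)
                 list(name = a$name, periodic = a$periodic,
                      edges = a$edges)))
  jsonlite::write_json(meta, meta_file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}
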