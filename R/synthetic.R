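#' Specification of a multi-state synthetic conformational ensemble
#'
#' Defines a set of labelled pseudo-protein ensembles whose classes differ
#' only in which inter-domain block pairs are in contact, emulating (at
#' contact-pattern level) four kinase systems whose glycine-rich loop,
#' activation loop, and regulatory-helix contacts differ.  Residues are
#' single C-alpha points; each named domain block is laid out on its own
#' chain segment with ~3.8 Angstrom consecutive spacing, and a contact
#' rule moves residues of its second block within the 4.5 Angstrom contact
#' cutoff of their partners in the first, independently per frame and per
#' matched residue pair.  Gaussian coordinate noise is applied after
#' contact placement so contacts near the cutoff flip stochastically.
#'
#' @param n_classes number of conformational classes (>= 2).
#' @param n_residues number of residues per frame.
#' @param n_frames_per_class frames generated for each class.
#' @param domain_blocks named list of integer vectors of residue indices
#'   (1-based, disjoint, within `1:n_residues`), e.g.
#'   `list("G-loop" = 1:8, "T-loop" = 20:31, "alphaC" = 40:47)`.
#' @param class_contact_rules list with one element per class; each element
#'   is a list of rules `list(block_a, block_b, p)` giving the probability
#'   `p` that the two named blocks are in contact in a frame of that class.
#' @param coordinate_noise_sd Gaussian noise, per coordinate, in Angstrom.
#' @param seed master integer seed; class `c` draws from an independent
#'   stream seeded with `seed + 7919 * c` so classes can be generated in
#'   any order (or in parallel) reproducibly.
#' @return an object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n_classes, n_residues, n_frames_per_class,
                          domain_blocks, class_contact_rules,
                          coordinate_noise_sd = 0.3, seed = 1L) {
  if (n_classes < 2L) stop("`n_classes` must be >= 2")
  if (length(class_contact_rules) != n_classes)
    stop("`class_contact_rules` must have one element per class")
  if (is.null(names(domain_blocks)) || any(names(domain_blocks) == ""))
    stop("`domain_blocks` must be a named list")
  all_idx <- unlist(domain_blocks)
  if (any(all_idx < 1L | all_idx > n_residues))
    stop("domain block indices outside [1, n_residues]")
  if (anyDuplicated(all_idx))
    stop("domain blocks overlap")
  for (cls in seq_len(n_classes)) {
    for (rule in class_contact_rules[[cls]]) {
      if (length(rule) < 3L)
        stop("each rule must be list(block_a, block_b, p)")
      ba <- rule[[1]]; bb <- rule[[2]]; p <- rule[[3]]
      if (!ba %in% names(domain_blocks) || !bb %in% names(domain_blocks))
        stop("rule references unknown block: ", ba, " / ", bb)
      if (ba == bb) stop("a rule must pair two distinct blocks")
      if (p < 0 || p > 1) stop("contact probability must be in [0, 1]")
    }
    moved <- vapply(class_contact_rules[[cls]], function(r) r[[2]], "")
    if (anyDuplicated(moved))
      stop("class ", cls, ": a block may be the moved partner of at most ",
           "one rule")
    anchors <- vapply(class_contact_rules[[cls]], function(r) r[[1]], "")
    if (any(table(anchors) > 2L))
      stop("class ", cls, ": at most two rules may share an anchor block")
  }
  structure(list(n_classes = as.integer(n_classes),
                 n_residues = as.integer(n_residues),
                 n_frames_per_class = as.integer(n_frames_per_class),
                 domain_blocks = domain_blocks,
                 class_contact_rules = class_contact_rules,
                 coordinate_noise_sd = coordinate_noise_sd,
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

# Base layout: every domain block occupies its own straight segment at
# y = 20 * (block index), x = 3.8 * k; linker residues sit on a baseline row
# at y = -20.  Rows are >= 20 Angstrom apart, far outside the 4.5 Angstrom
# contact cutoff, so only within-segment neighbours touch by construction.
.base_layout <- function(n_residues, domain_blocks) {
  xyz <- matrix(0, n_residues, 3)
  linker <- setdiff(seq_len(n_residues), unlist(domain_blocks))
  if (length(linker) > 0)
    xyz[linker, ] <- cbind(3.8 * seq_along(linker), -20, 0)
  for (j in seq_along(domain_blocks)) {
    idx <- domain_blocks[[j]]
    xyz[idx, ] <- cbind(3.8 * (seq_along(idx) - 1), 20 * j, 0)
  }
  xyz
}

#' Generate labelled multi-state conformational ensembles
#'
#' For each class, frame, and matched residue pair of a rule's two blocks,
#' the contact is switched on with the rule's stated probability; an "on"
#' residue of the second block is docked 3.4 Angstrom from its partner in
#' the first (inside the 4.5 Angstrom cutoff), an "off" residue stays on
#' its own distant segment.  The realized inter-block contact band is thus
#' a per-frame binomial pixel pattern: its density is the class signature,
#' while individual contacts near the cutoff still flip under the
#' coordinate noise (added last).  With the same spec (and seed) the
#' output is bit-identical.
#'
#' @param spec an [ensemble_spec()].
#' @return named list of `trajectory_ensemble` objects, one per class
#'   (`class1`, `class2`, ...), each carrying its label.
#' @export
generate_state_ensemble <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  base <- .base_layout(spec$n_residues, spec$domain_blocks)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  out <- list()
  for (cls in seq_len(spec$n_classes)) {
    set.seed(spec$seed + 7919L * cls)
    rules <- spec$class_contact_rules[[cls]]
    nf <- spec$n_frames_per_class
    coords <- array(NA_real_, c(nf, spec$n_residues, 3))
    # per frame and per matched residue pair, draw the contact state; the
    # realized inter-block band is then a binomial pixel pattern whose
    # density carries the class signature
    states <- lapply(rules, function(r) {
      L <- length(spec$domain_blocks[[r[[2]]]])
      matrix(runif(nf * L) < r[[3]], nf, L)
    })
    # alternate the side on which moved blocks dock onto a shared anchor
    anchor_names <- vapply(rules, function(r) r[[1]], "")
    side <- ave(seq_along(rules), anchor_names,
                FUN = function(v) seq_along(v))
    for (f in seq_len(nf)) {
      xyz <- base
      for (ri in seq_along(rules)) {
        on <- states[[ri]][f, ]
        if (!any(on)) next
        a_idx <- spec$domain_blocks[[rules[[ri]][[1]]]]
        b_idx <- spec$domain_blocks[[rules[[ri]][[2]]]]
        offset <- c(0, if (side[ri] == 1L) 3.4 else -3.4, 0)
        k <- pmin(seq_along(b_idx), length(a_idx))
        xyz[b_idx[on], ] <- xyz[a_idx[k][on], , drop = FALSE] +
          matrix(offset, sum(on), 3, byrow = TRUE)
      }
      coords[f, , ] <- xyz
    }
    coords <- coords + array(rnorm(length(coords),
                                   sd = spec$coordinate_noise_sd),
                             dim(coords))
    out[[paste0("class", cls)]] <-
      trajectory_ensemble(coords, label = paste0("class", cls))
  }
  out
}

#' Specification of a synthetic hydrogen-bond geometry series
#'
#' Four atoms per frame: donor `D`, donor hydrogen `H`, acceptor `A`, and a
#' static anchor.  Each frame is in the bound geometry with probability
#' `target_occupancy` and in the unbound geometry otherwise.  The bound
#' geometry must satisfy the hydrogen-bond criterion (donor-acceptor
#' distance < 3.5 Angstrom and D-H...A angle > 120 degrees); the unbound
#' geometry must violate at least one of the two.
#'
#' @param n_frames number of frames.
#' @param target_occupancy fraction of frames in the bound geometry.
#' @param bound_geometry numeric `c(distance, angle)` (Angstrom, degrees).
#' @param unbound_geometry numeric `c(distance, angle)`.
#' @param jitter_sd Gaussian positional jitter (Angstrom); default 0 keeps
#'   the stated geometries exact.
#' @param seed integer seed.
#' @return an object of class `hbond_series_spec`.
#' @export
hbond_series_spec <- function(n_frames, target_occupancy,
                              bound_geometry = c(2.9, 155),
                              unbound_geometry = c(4.5, 100),
                              jitter_sd = 0, seed = 1L) {
  if (target_occupancy < 0 || target_occupancy > 1)
    stop("`target_occupancy` must be in [0, 1]")
  if (!(bound_geometry[1] < 3.5 && bound_geometry[2] > 120))
    stop("bound geometry must satisfy distance < 3.5 and angle > 120")
  if (unbound_geometry[1] < 3.5 && unbound_geometry[2] > 120)
    stop("unbound geometry must violate the hydrogen-bond criterion")
  structure(list(n_frames = as.integer(n_frames),
                 target_occupancy = target_occupancy,
                 bound_geometry = bound_geometry,
                 unbound_geometry = unbound_geometry,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "hbond_series_spec")
}

# place D at origin, H at (1,0,0), and A at distance `d` from D forming a
# D-H-A angle of `theta` degrees at the hydrogen (law of cosines)
.hbond_frame <- function(d, theta_deg) {
  theta <- theta_deg * pi / 180
  disc <- d^2 - sin(theta)^2
  if (disc < 0) stop("geometry (", d, " A, ", theta_deg,
                     " deg) is unreachable with a 1 A D-H bond")
  rho <- cos(theta) + sqrt(disc)
  H <- c(1, 0, 0)
  A <- H + rho * c(-cos(theta), sin(theta), 0)
  rbind(c(0, 0, 0), H, A, c(10, 0, 0))
}

#' Generate a hydrogen-bond geometry trajectory
#'
#' @param spec an [hbond_series_spec()].
#' @return a `trajectory_ensemble` with atoms `D`, `H`, `A`, `X` (anchor);
#'   attribute `bound` records the per-frame bound state drawn.
#' @export
generate_hbond_series <- function(spec) {
  stopifnot(inherits(spec, "hbond_series_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)
  bound <- runif(spec$n_frames) < spec$target_occupancy
  fb <- .hbond_frame(spec$bound_geometry[1], spec$bound_geometry[2])
  fu <- .hbond_frame(spec$unbound_geometry[1], spec$unbound_geometry[2])
  coords <- array(NA_real_, c(spec$n_frames, 4, 3))
  for (f in seq_len(spec$n_frames))
    coords[f, , ] <- if (bound[f]) fb else fu
  if (spec$jitter_sd > 0)
    coords <- coords + array(rnorm(length(coords), sd = spec$jitter_sd),
                             dim(coords))
  atoms <- data.frame(elety = c("D", "H", "A", "X"), resno = c(1, 1, 2, 3),
                      resid = c("DON", "DON", "ACC", "ANC"), chain = "A",
                      stringsAsFactors = FALSE)
  traj <- trajectory_ensemble(coords, atoms)
  attr(traj, "bound") <- bound
  traj
}
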