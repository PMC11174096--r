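#' Pipeline configuration
#'
#' One configuration object drives the whole workflow: simulate synthetic
#' ensembles and a toy GaMD run, featurize into contact-map images, train
#' the classifier, compute saliency and key contacts, select reaction
#' coordinates, build free energy landscapes, and run the structural and
#' energetic reports.  Can be built in code or loaded from YAML.
#'
#' Recognized blocks (all optional except `synthetic` when downstream
#' stages are enabled): `seed`, `stages` (character vector of stage
#' names), `synthetic` (fields of [ensemble_spec()]), `gamd` (`barrier`,
#' `half_sep`, `sigma0`, `n_equil`, `n_prod`, `temperature`, `timestep`,
#' `friction`, `stride`), `featurization` (`cutoff`, `stride`),
#' `deep_learning` (fields of [cnn_config()] except the image size),
#' `fel` (`bins`, `bins_dihedral`, `temperature`, `min_frames`),
#' `energetics` (`components_csv`), `saliency_threshold`,
#' `rc_threshold`.
#'
#' @param config a named list or path to a YAML file.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("seed", "stages", "synthetic", "gamd", "featurization",
             "deep_learning", "fel", "energetics", "saliency_threshold",
             "rc_threshold")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    seed = 1L,
    stages = c("simulate", "featurize", "train", "saliency", "rcs", "fel",
               "analyze", "energetics"),
    synthetic = NULL,
    gamd = list(barrier = 3.6, half_sep = 1.5, sigma0 = 6, n_equil = 20000,
                n_prod = 200000, temperature = 300, timestep = 0.02,
                friction = 1, stride = 10),
    featurization = list(cutoff = 4.5, stride = 1L),
    deep_learning = list(),
    fel = list(bins = 50L, bins_dihedral = 60L, temperature = 300,
               min_frames = 10L),
    energetics = list(components_csv = NULL),
    saliency_threshold = 0.7,
    rc_threshold = 0.9)
  for (k in names(defaults)) {
    if (is.null(config[[k]])) {
      config[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && k != "synthetic") {
      miss <- setdiff(names(defaults[[k]]), names(config[[k]]))
      config[[k]][miss] <- defaults[[k]][miss]
    }
  }
  dl_stages <- c("featurize", "train", "saliency", "rcs", "fel", "analyze")
  if (any(dl_stages %in% config$stages) && is.null(config$synthetic))
    stop("the `synthetic` block is required when stages ",
         paste(intersect(dl_stages, config$stages), collapse = "/"),
         " are enabled")
  class(config) <- "pipeline_config"
  config
}

# default 4-class configuration: two block-pair contact rules per system
# family (glycine-rich-loop/activation-loop vs regulatory-helix/
# activation-loop analogs), high vs low contact probability
#' Default synthetic four-state pipeline configuration
#'
#' A compact, fully specified configuration for the end-to-end synthetic
#' workflow: 4 classes whose G-loop/T-loop and alphaC/T-loop analog
#' contacts differ (contact probability 0.9 vs 0.1), 64 residues.
#'
#' @param n_frames_per_class frames per class (default 200).
#' @param seed master seed.
#' @return a [pipeline_config()].
#' @export
default_pipeline_config <- function(n_frames_per_class = 200L, seed = 1L) {
  pipeline_config(list(
    seed = as.integer(seed),
    synthetic = list(
      n_classes = 4L, n_residues = 64L,
      n_frames_per_class = as.integer(n_frames_per_class),
      domain_blocks = list("G-loop" = 1:16, "T-loop" = 25:40,
                           "alphaC" = 49:64),
      class_contact_rules = list(
        list(list("T-loop", "G-loop", 0.9), list("T-loop", "alphaC", 0.1)),
        list(list("T-loop", "G-loop", 0.9), list("T-loop", "alphaC", 0.9)),
        list(list("T-loop", "G-loop", 0.1), list("T-loop", "alphaC", 0.9)),
        list(list("T-loop", "G-loop", 0.1), list("T-loop", "alphaC", 0.1))),
      coordinate_noise_sd = 0.3)))
}

#' Run the integrated workflow
#'
#' Executes the enabled stages in dependency order and writes every
#' product under `outdir`, together with a JSON run manifest recording
#' per-stage parameters, seeds, outputs and their MD5 hashes.  With an
#' identical configuration and seed the CSV outputs are reproducible
#' hash-for-hash (the deep-learning stage is reproducible given its
#' recorded seed and checkpoint).
#'
#' @param config a [pipeline_config()] (or list / YAML path accepted by
#'   it).
#' @param outdir output directory (created if absent).
#' @param verbose print stage progress.
#' @return the run manifest, invisibly (also written to
#'   `manifest.json`).
#' @export
run_pipeline <- function(config, outdir = "gamdl_run", verbose = TRUE) {
  config <- pipeline_config(unclass(config))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  say <- function(...) if (verbose) message(...)
  note_stage <- function(name, params, outputs) {
    manifest$stages[[name]] <<- list(
      parameters = params, outputs = as.list(outputs),
      md5 = as.list(tools::md5sum(outputs)), status = "ok")
    .write_manifest(manifest, outdir)
  }
  ensembles <- NULL
  images <- NULL
  model <- NULL
  contacts_by_class <- NULL

  if ("simulate" %in% config$stages) {
    say("stage simulate: synthetic ensembles + toy GaMD run")
    spec <- do.call(ensemble_spec, c(config$synthetic,
                                     list(seed = config$seed)))
    ensembles <- generate_state_ensemble(spec)
    files <- character(0)
    for (nm in names(ensembles)) {
      f <- file.path(outdir, paste0("ensemble_", nm, ".pdb"))
      write_trajectory_pdb(ensembles[[nm]], f)
      files <- c(files, f)
    }
    lab_file <- file.path(outdir, "ensemble_labels.csv")
    write_frame_labels(rep(names(ensembles),
                           each = spec$n_frames_per_class), lab_file)
    g <- config$gamd
    gamd <- gamd_simulate(double_well_potential(g$barrier, g$half_sep),
                          n_equil = g$n_equil, n_prod = g$n_prod,
                          sigma0 = g$sigma0, temperature = g$temperature,
                          timestep = g$timestep, friction = g$friction,
                          stride = g$stride, seed = config$seed,
                          verbose = verbose)
    boost_file <- file.path(outdir, "gamd_boost.csv")
    write_boost_csv(gamd$production$boost, boost_file)
    saveRDS(gamd, file.path(outdir, "gamd_run.rds"))
    note_stage("simulate",
               list(synthetic = config$synthetic, gamd = g,
                    seed = config$seed,
                    gamd_params = gamd$params[c("E", "k0", "k")]),
               c(files, lab_file, boost_file))
  }

  if ("featurize" %in% config$stages) {
    say("stage featurize: contact maps -> grayscale images")
    if (is.null(ensembles)) stop("featurize requires the simulate stage")
    fz <- config$featurization
    sets <- lapply(names(ensembles), function(nm) {
      maps <- contact_maps(ensembles[[nm]], cutoff = fz$cutoff,
                           stride = fz$stride)
      to_images(maps, nm)
    })
    images <- combine_images(sets)
    f <- file.path(outdir, "image_manifest.csv")
    write_image_manifest(images, f)
    note_stage("featurize", fz, f)
  }

  if ("train" %in% config$stages) {
    say("stage train: contact-map CNN")
    if (is.null(images)) stop("train requires the featurize stage")
    dl <- config$deep_learning
    dl$height <- images$height; dl$width <- images$width
    dl$n_classes <- nlevels(images$labels)
    if (is.null(dl$seed)) dl$seed <- config$seed
    cfg <- do.call(cnn_config, dl)
    model <- cnn_train(images, cfg, verbose = verbose)
    hist_file <- file.path(outdir, "training_history.csv")
    write.csv(model$history, hist_file, row.names = FALSE)
    ckpt <- file.path(outdir, "cnn_checkpoint.rds")
    save_cnn(model, ckpt)
    val <- cnn_evaluate(model, images, model$split$validation)
    say(sprintf("  validation accuracy %.4f over %d images", val$accuracy,
                length(model$split$validation)))
    note_stage("train",
               list(config = unclass(cfg), epochs_run = model$epochs_run,
                    val_accuracy = val$accuracy),
               c(hist_file, ckpt))
  }

  if ("saliency" %in% config$stages) {
    say("stage saliency: per-class key residue contacts")
    if (is.null(model)) stop("saliency requires the train stage")
    fz <- config$featurization
    contacts_by_class <- list()
    files <- character(0)
    for (nm in names(ensembles)) {
      maps <- contact_maps(ensembles[[nm]], cutoff = fz$cutoff,
                           stride = fz$stride)
      rep_map <- most_populated_map(maps)
      sal <- saliency(model, rep_map, nm)
      kc <- extract_key_contacts(sal, config$saliency_threshold)
      contacts_by_class[[nm]] <- kc
      f <- file.path(outdir, paste0("key_contacts_", nm, ".csv"))
      write_key_contacts(kc, f)
      files <- c(files, f)
    }
    note_stage("saliency", list(threshold = config$saliency_threshold),
               files)
  }

  rcs <- NULL
  if ("rcs" %in% config$stages) {
    say("stage rcs: reaction coordinates from key contacts")
    if (is.null(contacts_by_class)) stop("rcs requires the saliency stage")
    all_traj <- .concat_ensembles(ensembles)
    strict <- lapply(contacts_by_class, function(kc)
      kc[kc$gradient > config$rc_threshold, , drop = FALSE])
    pooled <- unique(do.call(rbind, strict)[, c("res_i", "res_j")])
    rcs <- select_rcs(pooled, all_traj)
    f <- file.path(outdir, "reaction_coordinates.csv")
    if (length(rcs) > 0) {
      df <- data.frame(frame = seq_along(rcs[[1]]$values))
      for (rc in rcs) df[[rc$name]] <- rc$values
      write.csv(df, f, row.names = FALSE)
      note_stage("rcs", list(threshold = config$rc_threshold), f)
    } else {
      note_stage("rcs", list(threshold = config$rc_threshold), character(0))
    }
  }

  if ("fel" %in% config$stages) {
    say("stage fel: free energy landscapes")
    files <- character(0)
    fel <- config$fel
    # reweighted 1D PMF of the toy GaMD run
    gamd <- readRDS(file.path(outdir, "gamd_run.rds"))
    rc <- rc_series("x", gamd$production$coords[, 1])
    grid <- histogram_pmf(rc, bins = fel$bins,
                          temperature = fel$temperature)
    rw <- cumulant_reweight(grid, gamd$production$boost,
                            min_frames = fel$min_frames)
    f <- file.path(outdir, "fel_gamd_reweighted.csv")
    write_fel_csv(rw, f)
    files <- c(f, paste0(f, ".json"))
    # 2D distance FEL over the first two selected RCs
    if (!is.null(rcs) && length(rcs) >= 2) {
      g2 <- histogram_pmf(rcs[1:2], bins = fel$bins,
                          temperature = fel$temperature)
      f2 <- file.path(outdir, "fel_distance2d.csv")
      write_fel_csv(g2, f2)
      files <- c(files, f2, paste0(f2, ".json"))
    }
    # pseudo-dihedral FEL around the first key-contact residue
    if (!is.null(rcs) && length(rcs) >= 1) {
      all_traj <- .concat_ensembles(ensembles)
      res <- as.integer(sub("^d(\\d+)-.*", "\\1",
                            rcs[[1]]$name))
      if (is.na(res) || res < 2L) res <- 2L
      if (res + 2L > n_atoms(all_traj)) res <- n_atoms(all_traj) - 2L
      phi <- rc_dihedral(all_traj, (res - 1L):(res + 2L),
                         name = paste0("phi", res))
      psi <- rc_dihedral(all_traj, res:(res + 3L),
                         name = paste0("psi", res))
      g3 <- histogram_pmf(list(phi, psi), bins = fel$bins_dihedral,
                          temperature = fel$temperature)
      f3 <- file.path(outdir, "fel_dihedral2d.csv")
      write_fel_csv(g3, f3)
      files <- c(files, f3, paste0(f3, ".json"))
    }
    note_stage("fel", fel, files)
  }

  if ("analyze" %in% config$stages) {
    say("stage analyze: RMSF per class")
    if (is.null(ensembles)) stop("analyze requires the simulate stage")
    tabs <- lapply(names(ensembles), function(nm) {
      df <- rmsf(ensembles[[nm]])
      df$system <- nm
      df
    })
    f <- file.path(outdir, "rmsf.csv")
    write.csv(do.call(rbind, tabs), f, row.names = FALSE)
    note_stage("analyze", list(selection = "calpha"), f)
  }

  if ("energetics" %in% config$stages) {
    say("stage energetics: binding free energy bookkeeping")
    csv <- config$energetics$components_csv
    tab <- if (is.null(csv)) load_energy_table() else load_energy_table(csv)
    agg <- aggregate_energy_table(tab)
    f <- file.path(outdir, "binding_energies.csv")
    write.csv(agg, f, row.names = FALSE)
    note_stage("energetics", list(components_csv = csv), f)
  }

  .write_manifest(manifest, outdir)
  invisible(manifest)
}

.write_manifest <- function(manifest, outdir) {
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
}

# concatenate per-class ensembles (equal-frame concatenation)
.concat_ensembles <- function(ensembles) {
  coords <- do.call(abind3, lapply(ensembles, `[[`, "coords"))
  trajectory_ensemble(coords, ensembles[[1]]$atoms)
}

# minimal 3D array row-binding (avoids an abind dependency)
abind3 <- function(...) {
  arrs <- list(...)
  dims <- dim(arrs[[1]])
  total <- sum(vapply(arrs, function(a) dim(a)[1], 1L))
  out <- array(NA_real_, c(total, dims[2], dims[3]))
  at <- 1L
  for (a in arrs) {
    out[at:(at + dim(a)[1] - 1L), , ] <- a
    at <- at + dim(a)[1]
  }
  out
}

#' Reaction coordinates from key residue contacts
#'
#' For each residue pair a C-alpha/C-alpha distance series is extracted;
#' explicit residues can additionally contribute pseudo-dihedral series
#' (torsion over four consecutive C-alpha atoms centred on the residue).
#'
#' @param key_contacts a [extract_key_contacts()] result or data frame
#'   with `res_i`, `res_j`.
#' @param traj a `trajectory_ensemble` (C-alpha atoms indexed by
#'   residue).
#' @param dihedral_residues optional residue indices for which phi/psi
#'   pseudo-dihedral series are added.
#' @return named list of [rc_series()] (empty, with a warning, when no
#'   contacts are supplied).
#' @export
select_rcs <- function(key_contacts, traj, dihedral_residues = NULL) {
  out <- list()
  kc <- as.data.frame(key_contacts)
  if (nrow(kc) == 0L && is.null(dihedral_residues)) {
    warning("no key contacts supplied; no reaction coordinates selected")
    return(out)
  }
  ca <- ca_indices(traj)
  for (r in seq_len(nrow(kc))) {
    i <- kc$res_i[r]; j <- kc$res_j[r]
    rc <- rc_distance(traj, ca[i], ca[j], name = paste0("d", i, "-", j))
    out[[rc$name]] <- rc
  }
  for (res in dihedral_residues) {
    if (res < 2L || res + 2L > length(ca)) next
    phi <- rc_dihedral(traj, ca[(res - 1L):(res + 2L)],
                       name = paste0("phi", res))
    psi <- rc_dihedral(traj, ca[res:(res + 3L)],
                       name = paste0("psi", res))
    out[[phi$name]] <- phi
    out[[psi$name]] <- psi
  }
  out
}
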