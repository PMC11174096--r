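# shared builders for synthetic fixtures (everything generated in code)

# two-class ensembles with one planted block-pair contact difference;
# block layout shrinks with the residue count
make_two_class_ensembles <- function(n_frames = 120, n_res = 32,
                                     p = c(0.9, 0.1), seed = 3) {
  blocks <- if (n_res >= 20) list(A = 1:8, B = 13:20)
  else list(A = seq_len(n_res %/% 4),
            B = (n_res - n_res %/% 4 + 1):n_res)
  spec <- ensemble_spec(
    2, n_res, n_frames,
    domain_blocks = blocks,
    class_contact_rules = list(list(list("A", "B", p[1])),
                               list(list("A", "B", p[2]))),
    seed = seed)
  generate_state_ensemble(spec)
}

# labelled image set from a list of ensembles
ensembles_to_images <- function(ens, cutoff = 4.5) {
  sets <- lapply(names(ens), function(nm)
    to_images(contact_maps(ens[[nm]], cutoff = cutoff), nm))
  combine_images(sets)
}

# a small config for fast CNN tests (32x32 images)
tiny_cnn_config <- function(height = 32, n_classes = 2, epochs = 4,
                            seed = 1, ...) {
  cnn_config(height, n_classes = n_classes,
             conv_filters = c(8L, 8L, 16L, 16L), dense_units = c(64L, 32L),
             epochs = epochs, learning_rate = 1e-3, seed = seed, ...)
}

# random symmetric matrix in [0,1] with unit max (a fake saliency map)
random_saliency <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n)
  m <- (m + t(m)) / 2
  m / max(m)
}
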