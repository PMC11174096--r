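#' Configuration of the contact-map convolutional network
#'
#' Fixed topology, configurable sizes: four 3 x 3 "same" convolution
#' layers (filter counts `conv_filters`), each followed by ReLU and 2 x 2
#' max pooling, then two ReLU dense layers with dropout, then a linear
#' softmax classification layer.  Images must be at least 16 x 16 with
#' both dimensions divisible by 16 so that four poolings are possible.
#'
#' @param height,width input image size in pixels.
#' @param n_classes number of output classes.
#' @param conv_filters four convolution filter counts
#'   (default `c(32, 32, 64, 64)`).
#' @param dense_units two dense layer sizes (default `c(512, 128)`).
#' @param dropout dropout rate of the dense layers, in `[0, 1)`.
#' @param epochs maximum training epochs.
#' @param train_fraction fraction of images used for training (the rest
#'   validate), in (0, 1).
#' @param batch_size minibatch size.
#' @param learning_rate Adam learning rate.
#' @param seed integer seed controlling weight init, shuffling, dropout.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(height, width = height, n_classes = 4L,
                       conv_filters = c(32L, 32L, 64L, 64L),
                       dense_units = c(512L, 128L), dropout = 0.5,
                       epochs = 25L, train_fraction = 0.8,
                       batch_size = 32L, learning_rate = 1e-4, seed = 1L) {
  if (length(conv_filters) != 4L) stop("`conv_filters` must have length 4")
  if (length(dense_units) != 2L) stop("`dense_units` must have length 2")
  if (dropout < 0 || dropout >= 1) stop("`dropout` must be in [0, 1)")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  if (height < 16L || width < 16L || height %% 16L != 0L ||
      width %% 16L != 0L)
    stop("image size ", height, "x", width, " cannot pass four 2x2 ",
         "poolings; dimensions must be multiples of 16")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_classes = as.integer(n_classes),
                 conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units), dropout = dropout,
                 epochs = as.integer(epochs),
                 train_fraction = train_fraction,
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "cnn_config")
}

#' Layer-by-layer shape report of a network configuration
#'
#' @param config a [cnn_config()].
#' @return data frame `layer`, `output_shape`, `n_params`.
#' @export
layer_shapes <- function(config) {
  h <- config$height; w <- config$width; cin <- 1L
  rows <- list()
  for (l in 1:4) {
    f <- config$conv_filters[l]
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("conv%d (3x3) + relu", l),
                 output_shape = sprintf("%dx%dx%d", h, w, f),
                 n_params = f * (cin * 9L + 1L))
    h <- h %/% 2L; w <- w %/% 2L
    rows[[length(rows) + 1L]] <-
      data.frame(layer = sprintf("maxpool%d (2x2)", l),
                 output_shape = sprintf("%dx%dx%d", h, w, f), n_params = 0L)
    cin <- f
  }
  units <- c(cin * h * w, config$dense_units, config$n_classes)
  nm <- c(sprintf("dense1 (%d) + relu + dropout", units[2]),
          sprintf("dense2 (%d) + relu + dropout", units[3]),
          sprintf("dense3 (%d) + softmax", units[4]))
  for (l in 1:3)
    rows[[length(rows) + 1L]] <-
      data.frame(layer = nm[l], output_shape = as.character(units[l + 1L]),
                 n_params = units[l + 1L] * (units[l] + 1L))
  do.call(rbind, rows)
}

#' Stratified train/validation split of an image set
#'
#' Draws `train_fraction` of each class (rounded) for training; the split
#' is disjoint, exhaustive, and reproducible for a given seed.
#'
#' @param images a `contact_image_set`.
#' @param train_fraction training fraction in (0, 1).
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `validation`.
#' @export
split_dataset <- function(images, train_fraction = 0.8, seed = 1L) {
  labs <- images$labels
  if (any(table(labs) < 2L))
    stop("every class needs at least 2 images to split")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                          globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  train <- integer(0)
  for (cl in levels(labs)) {
    idx <- which(labs == cl)
    n_tr <- round(length(idx) * train_fraction)
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train <- c(train, sample(idx, n_tr))
  }
  train <- sort(train)
  list(train = train, validation = setdiff(seq_along(labs), train))
}

#' Train the contact-map classifier
#'
#' Minimizes softmax cross-entropy with Adam.  Pixels are scaled to
#' `[0, 1]` internally.  Training stops early once the validation
#' accuracy reaches `early_stop_acc` (set above 1 to disable).  The
#' per-epoch history (loss and accuracy on both sets) is recorded.
#'
#' @param images a `contact_image_set`.
#' @param config a [cnn_config()].
#' @param split optional list with `train` / `validation` indices (from
#'   [split_dataset()]); by default a stratified split with the config's
#'   `train_fraction` and `seed` is drawn.
#' @param early_stop_acc validation accuracy at which training stops
#'   (default 1.0, i.e. stop when the validation set is perfectly
#'   classified).
#' @param verbose print one line per epoch.
#' @return object of class `cnn_classifier`: `params`, `config`,
#'   `classes` (label order), `history`, `epochs_run`, `split`.
#' @export
cnn_train <- function(images, config, split = NULL, early_stop_acc = 1.0,
                      verbose = FALSE) {
  stopifnot(inherits(images, "contact_image_set"),
            inherits(config, "cnn_config"))
  if (images$height != config$height || images$width != config$width)
    stop("image size ", images$height, "x", images$width,
         " does not match the configured ", config$height, "x",
         config$width)
  if (nlevels(images$labels) != config$n_classes)
    stop("found ", nlevels(images$labels), " classes but config expects ",
         config$n_classes)
  if (is.null(split))
    split <- split_dataset(images, config$train_fraction, config$seed)
  X <- images$pixels / 255
  y <- as.integer(images$labels) - 1L
  fit <- .cnn_train_cpp(X, y, as.integer(split$train - 1L),
                        as.integer(split$validation - 1L),
                        unclass(config), config$epochs, config$batch_size,
                        config$learning_rate, config$seed, early_stop_acc)
  if (verbose) {
    h <- fit$history
    for (i in seq_len(nrow(h)))
      message(sprintf(
        "epoch %2d  train loss %.4f acc %.4f | val loss %.4f acc %.4f",
        h$epoch[i], h$train_loss[i], h$train_accuracy[i], h$val_loss[i],
        h$val_accuracy[i]))
  }
  structure(list(params = fit$params, config = config,
                 classes = levels(images$labels), history = fit$history,
                 epochs_run = fit$epochs_run, split = split),
            class = "cnn_classifier")
}

#' @export
print.cnn_classifier <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "cnn_classifier: %d classes, %d epochs run, final val accuracy %.4f\n",
    length(x$classes), x$epochs_run, h$val_accuracy[nrow(h)]))
  invisible(x)
}

# pixels matrix (H*W x n, 0..255 or 0..1) from various inputs
.as_pixels <- function(model, newdata) {
  if (inherits(newdata, "contact_image_set")) {
    if (newdata$height != model$config$height ||
        newdata$width != model$config$width)
      stop("image size does not match the trained model")
    return(newdata$pixels / 255)
  }
  if (is.matrix(newdata) &&
      nrow(newdata) == model$config$height &&
      ncol(newdata) == model$config$width)
    return(matrix(as.numeric(newdata), ncol = 1L))
  if (is.matrix(newdata) &&
      nrow(newdata) == model$config$height * model$config$width)
    return(newdata)
  stop("cannot interpret `newdata` as images for this model")
}

#' Class-probability predictions of a trained classifier
#'
#' @param object a `cnn_classifier`.
#' @param newdata a `contact_image_set`, a single contact map, or a
#'   pixel matrix (pixels x images, values in `[0, 1]`).
#' @param ... unused.
#' @return list with `probabilities` (images x classes; rows sum to 1)
#'   and `class` (predicted label per image).
#' @export
predict.cnn_classifier <- function(object, newdata, ...) {
  X <- .as_pixels(object, newdata)
  pr <- t(.cnn_predict_cpp(object$params, X, unclass(object$config)))
  colnames(pr) <- object$classes
  list(probabilities = pr,
       class = factor(object$classes[max.col(pr)], levels = object$classes))
}

#' Evaluate a classifier on labelled images
#'
#' @param model a `cnn_classifier`.
#' @param images a `contact_image_set` with labels.
#' @param indices optional subset of image indices (e.g. the validation
#'   split).
#' @return list with `confusion` (true x predicted counts), `accuracy`,
#'   and `loss` (mean cross-entropy).
#' @export
cnn_evaluate <- function(model, images, indices = NULL) {
  labs <- as.character(images$labels)
  if (!all(unique(labs) %in% model$classes))
    stop("images carry labels unseen at training time: ",
         paste(setdiff(unique(labs), model$classes), collapse = ", "))
  X <- images$pixels / 255
  if (!is.null(indices)) {
    X <- X[, indices, drop = FALSE]
    labs <- labs[indices]
  }
  pr <- t(.cnn_predict_cpp(model$params, X, unclass(model$config)))
  pred <- model$classes[max.col(pr)]
  truth <- factor(labs, levels = model$classes)
  pred <- factor(pred, levels = model$classes)
  confusion <- table(truth = truth, predicted = pred)
  p_true <- pr[cbind(seq_along(labs), as.integer(truth))]
  list(confusion = confusion,
       accuracy = sum(diag(confusion)) / length(labs),
       loss = -mean(log(pmax(p_true, 1e-12))))
}

#' Save / load a classifier checkpoint
#'
#' The checkpoint is self-describing: it embeds the configuration and
#' class label order alongside the parameters.
#'
#' @param model a `cnn_classifier`.
#' @param file checkpoint path.
#' @return `file` (save) or the restored `cnn_classifier` (load).
#' @export
save_cnn <- function(model, file) {
  saveRDS(model, file)
  invisible(file)
}

#' @rdname save_cnn
#' @export
load_cnn <- function(file) {
  model <- readRDS(file)
  if (!inherits(model, "cnn_classifier"))
    stop("file does not contain a cnn_classifier checkpoint")
  model
}

#' Most populated contact map of a stack
#'
#' The representative map of the densest region of contact-map space:
#' maps are clustered by complete linkage under Hamming distance, the
#' tree is cut at a radius of `radius_frac` of the map entry count, and
#' the medoid (minimum summed distance) of the largest cluster is
#' returned.  Stacks larger than `max_maps` are subsampled evenly first
#' (the pairwise distance matrix is quadratic in the stack size).
#'
#' @param maps list of `contact_map` matrices.
#' @param radius_frac cluster radius as a fraction of the number of map
#'   entries (default 0.1).
#' @param max_maps pairwise-distance budget (default 1000 maps).
#' @return the medoid `contact_map`.
#' @export
most_populated_map <- function(maps, radius_frac = 0.1, max_maps = 1000L) {
  if (length(maps) == 0L) stop("empty map stack")
  if (length(maps) == 1L) return(maps[[1]])
  if (length(maps) > max_maps)
    maps <- maps[unique(round(seq(1, length(maps), length.out = max_maps)))]
  M <- t(vapply(maps, as.numeric, numeric(length(maps[[1]]))))
  # Hamming distance of binary rows: a XOR b = a(1-b) + (1-a)b
  D <- M %*% t(1 - M)
  D <- D + t(D)
  cl <- cutree(hclust(as.dist(D), method = "complete"),
               h = radius_frac * ncol(M))
  big <- as.integer(names(which.max(table(cl))))
  members <- which(cl == big)
  medoid <- members[which.min(rowSums(D[members, members, drop = FALSE]))]
  maps[[medoid]]
}

#' Saliency map of a contact map for a target class
#'
#' Backpropagates the pre-softmax class score to the input pixels (the
#' raw probability is avoided so saturated outputs do not null the
#' gradient), takes absolute values, symmetrizes as `(M + t(M)) / 2`,
#' and min-max normalizes to `[0, 1]` (an identically zero gradient stays
#' all-zero).
#'
#' @param model a trained `cnn_classifier`.
#' @param map a `contact_map` of the trained size (values 0/1).
#' @param target_class class label or 1-based class index.
#' @return matrix of class `saliency_map` with attribute `target_class`.
#' @export
saliency <- function(model, map, target_class) {
  cfg <- model$config
  if (nrow(map) != cfg$height || ncol(map) != cfg$width)
    stop("map size ", nrow(map), "x", ncol(map),
         " does not match the trained model")
  if (is.character(target_class))
    target_class <- match(target_class, model$classes)
  if (is.na(target_class) || target_class < 1L ||
      target_class > length(model$classes))
    stop("unknown target class")
  g <- .cnn_input_grad_cpp(model$params, as.numeric(map),
                           as.integer(target_class - 1L), unclass(cfg))
  G <- abs(matrix(g, cfg$height, cfg$width))
  G <- (G + t(G)) / 2
  if (max(G) > 0) G <- G / max(G)
  structure(G, class = c("saliency_map", "matrix", "array"),
            target_class = model$classes[target_class])
}

#' Extract key residue contacts from a saliency map
#'
#' Residue pairs (i < j) whose gradient is strictly greater than the
#' threshold, sorted by descending gradient.  The customary threshold is
#' 0.7 for characteristic contacts; a stricter cut (0.9) selects the
#' contacts used as reaction coordinates.
#'
#' @param sal a [saliency()] result (normalized to `[0, 1]`).
#' @param threshold strict lower bound on the gradient (default 0.7).
#' @return data frame of class `key_contact_set` with columns `res_i`,
#'   `res_j` (1-based, i < j), `gradient`; attribute `threshold`.
#' @export
extract_key_contacts <- function(sal, threshold = 0.7) {
  idx <- which(upper.tri(sal) & sal > threshold, arr.ind = TRUE)
  out <- data.frame(res_i = idx[, 1], res_j = idx[, 2],
                    gradient = sal[idx])
  out <- out[order(-out$gradient), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "threshold") <- threshold
  class(out) <- c("key_contact_set", "data.frame")
  out
}

#' Write a key-contact table as CSV (1-based residue numbering)
#' @param contacts a [extract_key_contacts()] result.
#' @param file CSV path.
#' @return `file`, invisibly.
#' @export
write_key_contacts <- function(contacts, file) {
  write.csv(as.data.frame(contacts), file, row.names = FALSE)
  invisible(file)
}
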