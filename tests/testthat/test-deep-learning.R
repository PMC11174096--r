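test_that("configuration validation and layer introspection", {
  expect_error(cnn_config(60), "multiples of 16")
  expect_error(cnn_config(8), "multiples of 16")
  expect_error(cnn_config(64, conv_filters = c(32, 64)), "length 4")
  expect_error(cnn_config(64, dropout = 1), "dropout")
  cfg <- cnn_config(64, n_classes = 4)
  rep <- layer_shapes(cfg)
  # 4 conv blocks then dense 512, 128, n_classes
  expect_equal(sum(grepl("^conv", rep$layer)), 4)
  expect_equal(rep$output_shape[rep$layer == "conv1 (3x3) + relu"], "64x64x32")
  expect_equal(rep$output_shape[rep$layer == "maxpool4 (2x2)"], "4x4x64")
  expect_equal(rep$output_shape[grepl("^dense", rep$layer)],
               c("512", "128", "4"))
  # dense1 sees the 4*4*64 = 1024 flatten
  expect_equal(rep$n_params[grepl("dense1", rep$layer)], 512 * 1025)
})

test_that("dataset splits are stratified, disjoint, exhaustive, seeded", {
  ens <- make_two_class_ensembles(n_frames = 50, n_res = 16)
  imgs <- ensembles_to_images(ens)
  sp <- split_dataset(imgs, 0.8, seed = 4)
  expect_equal(length(sp$train), 80)
  expect_equal(length(sp$validation), 20)
  expect_equal(intersect(sp$train, sp$validation), integer(0))
  expect_setequal(c(sp$train, sp$validation), seq_len(100))
  # per-class 40/10
  expect_equal(unname(table(imgs$labels[sp$train])), c(40L, 40L),
               ignore_attr = TRUE)
  expect_identical(split_dataset(imgs, 0.8, seed = 4), sp)
  expect_false(identical(split_dataset(imgs, 0.8, seed = 5)$train, sp$train))
  one <- imgs; one$labels <- factor(c("a", rep("b", 99)))
  expect_error(split_dataset(one), "at least 2")
})

test_that("analytic gradients agree with finite differences", {
  # tiny network in single precision; central differences at loose tol
  set.seed(17)
  cfg <- cnn_config(16, n_classes = 2, conv_filters = c(2L, 2L, 3L, 3L),
                    dense_units = c(8L, 6L), dropout = 0, seed = 1)
  X <- matrix(runif(256 * 3), 256, 3)
  y <- c(0L, 1L, 0L)
  fit <- gamdl:::.cnn_train_cpp(X, y, 0:2, 0:2, unclass(cfg), 1L, 3L,
                                1e-9, 1L, 2.0)
  par <- fit$params
  lg <- gamdl:::.cnn_loss_grad_cpp(par, X, y, unclass(cfg), TRUE)
  loss_at <- function(nm, i, h) {
    pp <- par; pp[[nm]][i] <- pp[[nm]][i] + h
    gamdl:::.cnn_loss_grad_cpp(pp, X, y, unclass(cfg), FALSE)$loss
  }
  l0 <- gamdl:::.cnn_loss_grad_cpp(par, X, y, unclass(cfg), FALSE)$loss
  set.seed(18)
  rel_err <- c()
  for (nm in c("Wc1", "Wc3", "Wd1", "Wd3", "bc2", "bd3")) {
    w <- par[[nm]]
    picks <- sample(length(w), min(10, length(w)))
    for (i in picks) {
      g <- lg$grads[[nm]][i]
      if (abs(g) <= 5e-3) next
      # the loss is piecewise linear in any one parameter, and kinks can
      # sit exactly at the evaluation point (tied ReLU/pool states); the
      # analytic gradient is then a one-sided derivative, so accept
      # agreement with the central OR either one-sided difference
      err <- min(vapply(c(1e-3, 2.5e-4), function(h) {
        lp <- loss_at(nm, i, h); lm <- loss_at(nm, i, -h)
        min(abs((lp - lm) / (2 * h) - g), abs((lp - l0) / h - g),
            abs((l0 - lm) / h - g))
      }, 1))
      rel_err <- c(rel_err, err / max(abs(g), 1e-8))
    }
  }
  # the network is piecewise linear: a few probes straddle a ReLU kink or
  # a pool argmax switch, so the check is statistical
  expect_gt(length(rel_err), 10)
  expect_lt(median(rel_err), 0.01)
  expect_gte(mean(rel_err < 0.05), 0.85)
})

test_that("training separates a clean two-rule synthetic set", {
  ens <- make_two_class_ensembles(n_frames = 120, n_res = 32, seed = 21)
  imgs <- ensembles_to_images(ens)
  accs <- vapply(1:3, function(s) {
    m <- cnn_train(imgs, tiny_cnn_config(32, epochs = 6, seed = s))
    cnn_evaluate(m, imgs, m$split$validation)$accuracy
  }, 1)
  expect_gte(max(accs), 0.999)
})

test_that("permuted labels train to chance level", {
  ens <- make_two_class_ensembles(n_frames = 100, n_res = 32, seed = 22)
  imgs <- ensembles_to_images(ens)
  set.seed(23)
  imgs$labels <- sample(imgs$labels)
  m <- cnn_train(imgs, tiny_cnn_config(32, epochs = 3, seed = 1),
                 early_stop_acc = 2)
  acc <- cnn_evaluate(m, imgs, m$split$validation)$accuracy
  expect_lt(abs(acc - 0.5), 0.2)
})

test_that("training is seed-deterministic and ignores validation pixels", {
  ens <- make_two_class_ensembles(n_frames = 30, n_res = 16, seed = 24)
  imgs <- ensembles_to_images(ens)
  cfg <- tiny_cnn_config(16, epochs = 2, seed = 7)
  sp <- split_dataset(imgs, 0.8, seed = 7)
  m1 <- cnn_train(imgs, cfg, split = sp, early_stop_acc = 2)
  m2 <- cnn_train(imgs, cfg, split = sp, early_stop_acc = 2)
  expect_identical(m1$params, m2$params)
  # scrambling the validation images must not change the learned weights
  imgs3 <- imgs
  set.seed(25)
  imgs3$pixels[, sp$validation] <-
    255 * (matrix(runif(length(imgs3$pixels[, sp$validation])) < 0.5, 256))
  m3 <- cnn_train(imgs3, cfg, split = sp, early_stop_acc = 2)
  expect_identical(m1$params, m3$params)
})

test_that("probability outputs are normalized and evaluation is consistent", {
  ens <- make_two_class_ensembles(n_frames = 30, n_res = 16, seed = 26)
  imgs <- ensembles_to_images(ens)
  m <- cnn_train(imgs, tiny_cnn_config(16, epochs = 2, seed = 1),
                 early_stop_acc = 2)
  pr <- predict(m, imgs)$probabilities
  expect_true(all(abs(rowSums(pr) - 1) < 1e-6))
  expect_true(all(pr >= 0))
  ev <- cnn_evaluate(m, imgs)
  expect_equal(sum(ev$confusion), n_images(imgs))
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  bad <- imgs; bad$labels <- factor(rep("mystery", n_images(imgs)))
  expect_error(cnn_evaluate(m, bad), "unseen")
})

test_that("checkpoints restore a model that predicts identically", {
  ens <- make_two_class_ensembles(n_frames = 20, n_res = 16, seed = 27)
  imgs <- ensembles_to_images(ens)
  m <- cnn_train(imgs, tiny_cnn_config(16, epochs = 1, seed = 1),
                 early_stop_acc = 2)
  f <- tempfile(fileext = ".rds")
  save_cnn(m, f)
  m2 <- load_cnn(f)
  expect_identical(predict(m, imgs)$probabilities,
                   predict(m2, imgs)$probabilities)
})

test_that("most populated map finds modes and cluster medoids", {
  n <- 8
  a <- contact_map(matrix(c(0, 0, 0, 2, 0, 0, 10, 0, 0, 12, 0, 0,
                            20, 0, 0, 22, 0, 0, 30, 0, 0, 32, 0, 0),
                          ncol = 3, byrow = TRUE))
  b <- a; b[1, 3] <- b[3, 1] <- 1L
  # one exact map repeated 60% of the time wins
  stack <- c(replicate(6, a, simplify = FALSE),
             replicate(4, b, simplify = FALSE))
  expect_equal(most_populated_map(stack), a)
  expect_equal(most_populated_map(list(b)), b)
  # all-distinct maps with one tight cluster: medoid found by an
  # exhaustive pairwise-distance oracle
  set.seed(28)
  flip <- function(m, k) {
    idx <- which(upper.tri(m))
    for (q in sample(idx, k)) {
      i <- row(m)[q]; j <- col(m)[q]
      m[i, j] <- m[j, i] <- 1L - m[i, j]
    }
    m
  }
  tight <- lapply(c(1, 1, 2, 1, 2), function(k) flip(a, k))
  far <- lapply(c(20, 22, 24), function(k) flip(a, k))
  stack2 <- c(tight, far)
  got <- most_populated_map(stack2)
  D <- matrix(0, 8, 8)
  for (i in 1:8) for (j in 1:8)
    D[i, j] <- sum(stack2[[i]] != stack2[[j]])
  cl <- cutree(hclust(as.dist(D), method = "complete"), h = 0.1 * n * n)
  big <- as.integer(names(which.max(table(cl))))
  members <- which(cl == big)
  medoid <- members[which.min(rowSums(D[members, members]))]
  expect_equal(got, stack2[[medoid]])
})

test_that("saliency is symmetric, normalized, and finds a planted pixel", {
  # classes differ only in the single contact (5, 12)
  spec <- ensemble_spec(
    2, 16, 80,
    domain_blocks = list(A = 5, B = 12),
    class_contact_rules = list(list(list("A", "B", 1.0)),
                               list(list("A", "B", 0.0))),
    seed = 31)
  ens <- generate_state_ensemble(spec)
  imgs <- ensembles_to_images(ens)
  hits <- 0
  for (s in 1:3) {
    m <- cnn_train(imgs, tiny_cnn_config(16, epochs = 8, seed = s),
                   early_stop_acc = 2)
    rep_map <- most_populated_map(contact_maps(ens$class1))
    sal <- saliency(m, rep_map, "class1")
    expect_true(isSymmetric(unclass(sal)))
    expect_equal(max(sal), 1)
    expect_true(all(sal >= 0 & sal <= 1))
    top <- which(sal == max(sal), arr.ind = TRUE)
    if (any(top[, 1] == 5 & top[, 2] == 12)) hits <- hits + 1
  }
  expect_gte(hits, 2) # planted feature recovered in most seeds
})

test_that("key contact extraction equals an exhaustive scan", {
  sal <- random_saliency(12, seed = 32)
  sal[3, 7] <- sal[7, 3] <- 0.70 # exactly at threshold: excluded
  kc <- extract_key_contacts(sal, 0.7)
  oracle <- list()
  for (i in 1:11) for (j in (i + 1):12)
    if (sal[i, j] > 0.7) oracle[[length(oracle) + 1]] <- c(i, j)
  oracle <- do.call(rbind, oracle)
  expect_equal(nrow(kc), nrow(oracle))
  expect_setequal(paste(kc$res_i, kc$res_j),
                  paste(oracle[, 1], oracle[, 2]))
  expect_false(any(kc$res_i == 3 & kc$res_j == 7)) # strict inequality
  expect_true(all(diff(kc$gradient) <= 0)) # sorted descending
  # single clear pixel
  one <- matrix(0, 10, 10); one[3, 7] <- one[7, 3] <- 0.9
  k1 <- extract_key_contacts(one, 0.7)
  expect_equal(unname(as.matrix(k1[, 1:2])), matrix(c(3L, 7L), 1))
  # 0.9-threshold set is a subset of the 0.7 set
  k07 <- extract_key_contacts(sal, 0.7)
  k09 <- extract_key_contacts(sal, 0.9)
  expect_true(all(paste(k09$res_i, k09$res_j) %in%
                    paste(k07$res_i, k07$res_j)))
})
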