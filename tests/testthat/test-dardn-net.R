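encode_batch <- function(seqs) encode_sequences(seqs)

test_that("model builds are deterministic and length-agnostic", {
  cfg <- model_config(seed = 12)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)

  # shape contract: batch of 8 sequences -> 8 x 2 logits
  set.seed(13)
  x <- encode_batch(vapply(1:8, function(i) random_seq(100), ""))
  o <- dardn:::cpp_forward_logits(m1$params, x)
  expect_equal(dim(o), c(8L, 2L))

  # same parameter count regardless of input length (global pooling head)
  expect_identical(sum(lengths(m1$params)), sum(lengths(build_model(cfg)$params)))
  x_long <- encode_batch(vapply(1:2, function(i) random_seq(1200), ""))
  expect_silent(dardn:::cpp_forward_logits(m1$params, x_long))

  expect_error(predict(m1, encode_batch("ACGTA")), "kernel")
  expect_error(model_config(kernel_a = 4, kernel_b = 4), "kernel_a")
})

test_that("bce_loss matches closed forms", {
  expect_equal(bce_loss(0.5, 1), log(2), tolerance = 1e-12)
  expect_lt(bce_loss(c(1 - 1e-7, 1e-7), c(1, 0)), 1e-6)
  expect_equal(bce_loss(c(0.9, 0.2, 0.8), c(1, 0, 1)),
               -(log(0.9) + log(0.8) + log(0.8)) / 3, tolerance = 1e-12)
  expect_error(bce_loss(c(0.5, 0.5), 1), "equal length")
})

test_that("predict maps logits through softmax with a 0.5 threshold", {
  cfg <- model_config(channels = 6L, fc_hidden = 8L, seed = 14)
  mod <- build_model(cfg)
  set.seed(15)
  x <- encode_batch(vapply(1:5, function(i) random_seq(60), ""))
  pr <- predict(mod, x)
  expect_equal(pr$p, 1 / (1 + exp(pr$o1 - pr$o2)), tolerance = 1e-12)
  expect_equal(pr$predicted_label, as.integer(pr$p >= 0.5))
  expect_true(all(pr$p >= 0 & pr$p <= 1))

  # batch vs one-by-one
  single <- vapply(1:5, function(i) predict(mod, x[, , i])$p, 1)
  expect_equal(pr$p, single, tolerance = 1e-6)
})

test_that("confusion counts match a brute-force tally", {
  expect_equal(unclass(confusion_counts(c(1, 0, 1), c(1, 0, 1)))[1:4],
               list(TP = 2L, TN = 1L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  truth <- c(1, 0, 1, 0)
  inv <- confusion_counts(1 - truth, truth)
  expect_equal(inv$TP + inv$TN, 0)

  set.seed(16)
  p <- sample(0:1, 100, TRUE)
  y <- sample(0:1, 100, TRUE)
  cc <- confusion_counts(p, y)
  tally <- c(TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in 1:100) {
    k <- if (p[i] == 1 && y[i] == 1) "TP" else if (p[i] == 0 && y[i] == 0)
      "TN" else if (p[i] == 1) "FP" else "FN"
    tally[k] <- tally[k] + 1
  }
  expect_equal(unlist(cc[1:4]), tally)
  expect_equal(cc$TP + cc$TN + cc$FP + cc$FN, 100)
  expect_error(confusion_counts(c(1, 0), 1), "equal length")
})

test_that("mcc matches its definition, bounds and conventions", {
  expect_equal(round(mcc(76, 5108, 2, 21), 2), 0.87)
  expect_equal(round(mcc(47, 5067, 31, 62), 2), 0.50)
  expect_equal(mcc(10, 10, 0, 0), 1)
  expect_equal(mcc(0, 0, 10, 10), -1)
  expect_equal(mcc(0, 50, 0, 5), 0)  # zero marginal -> 0 by convention
  expect_equal(mcc(confusion_counts(c(1, 0), c(1, 0))), 1)

  # antisymmetry under prediction flip when marginals permit
  set.seed(17)
  for (i in 1:20) {
    p <- sample(0:1, 50, TRUE)
    y <- sample(0:1, 50, TRUE)
    m1 <- mcc(confusion_counts(p, y))
    m2 <- mcc(confusion_counts(1 - p, y))
    expect_true(abs(m1) <= 1 && abs(m2) <= 1)
    expect_equal(m1, -m2, tolerance = 1e-12)
  }
})

test_that("gradients agree with central finite differences", {
  cfg <- model_config(kernel_a = 3L, kernel_b = 5L, channels = 5L,
                      fc_hidden = 7L, seed = 18)
  mod <- build_model(cfg)
  set.seed(19)
  n <- 6
  x <- encode_batch(vapply(1:n, function(i) random_seq(24), ""))
  y <- rep(c(1, 0), 3)
  w <- c(1, 2, 1, 1, 0.5, 1)
  res <- dardn:::cpp_loss_grads(mod$params, x, y, w)
  h <- 1e-6
  worst <- 0
  for (nm in names(mod$params)) {
    idx <- sample(length(mod$params[[nm]]), min(5, length(mod$params[[nm]])))
    for (ii in idx) {
      p2 <- mod$params
      p2[[nm]][ii] <- p2[[nm]][ii] + h
      lp <- dardn:::cpp_loss_grads(p2, x, y, w)$loss
      p2[[nm]][ii] <- p2[[nm]][ii] - 2 * h
      lm <- dardn:::cpp_loss_grads(p2, x, y, w)$loss
      g_num <- (lp - lm) / (2 * h)
      g_ana <- res$grads[[nm]][ii]
      worst <- max(worst, abs(g_num - g_ana) /
                            (abs(g_num) + abs(g_ana) + 1e-8))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("training separates a toy motif-insertion set", {
  fit <- toy_sim_fit()
  hist <- fit$model$history
  # loss decreases over the first epochs on the separable set
  expect_lt(hist$train_loss[3], hist$train_loss[1])
  expect_equal(max(hist$val_mcc, na.rm = TRUE), 1)
  expect_lte(which(hist$val_mcc == 1)[1], 20L)
})

test_that("zero training epochs leave the model unchanged", {
  cfg <- model_config(channels = 4L, fc_hidden = 4L, seed = 20)
  mod <- build_model(cfg)
  set.seed(21)
  x <- encode_batch(vapply(1:4, function(i) random_seq(30), ""))
  y <- c(1, 0, 1, 0)
  fit <- dardn_train(mod, x, y, config = train_config(max_epochs = 0L))
  expect_identical(fit$params, mod$params)
  expect_null(fit$history)
})

test_that("weighted balancing avoids collapse under heavy imbalance", {
  set.seed(22)
  motif <- "CCTGGGAA"
  n_pos <- 4
  n_neg <- 100
  pos <- vapply(seq_len(n_pos), function(i) {
    s <- scrub_motif(random_seq(80), motif)
    insert_motif(s, motif, 6)$sequence
  }, "")
  neg <- vapply(seq_len(n_neg), function(i) {
    scrub_motif(random_seq(80), motif)
  }, "")
  x <- encode_batch(c(pos, neg))
  y <- c(rep(1, n_pos), rep(0, n_neg))
  mod <- build_model(model_config(channels = 8L, fc_hidden = 8L, seed = 23))
  fit <- dardn_train(mod, x, y,
                     config = train_config(learning_rate = 3e-3,
                                           batch_size = 16L,
                                           max_epochs = 40L,
                                           lr_decay_every = 15L,
                                           class_balance = "weighted",
                                           seed = 24))
  pr <- predict(fit, x)
  expect_true(all(c(0L, 1L) %in% pr$predicted_label))
  expect_true(all(pr$predicted_label[y == 1] == 1))
})

test_that("small motif translations do not flip toy-model predictions", {
  fit <- toy_sim_fit()
  model <- fit$model
  motif <- "CCTGGGAA"
  set.seed(25)
  base <- scrub_motif(random_seq(200), motif)
  starts <- seq(5, 185, by = 20)  # ten insertions, like the training set
  mk <- function(off) {
    s <- base
    for (st in starts + off) substr(s, st + 1, st + 8) <- motif
    s
  }
  p0 <- predict(model, one_hot_encode(mk(0)))$predicted_label
  p3 <- predict(model, one_hot_encode(mk(3)))$predicted_label
  expect_equal(p0, 1L)
  expect_equal(p3, p0)
})

test_that("model checkpoints round-trip through disk", {
  fit <- toy_sim_fit()$model
  path <- tempfile(fileext = ".rds")
  write_model(fit, path)
  back <- read_model(path)
  x <- encode_batch(random_seq(50, seed = 26))
  expect_identical(predict(back, x), predict(fit, x))
  expect_identical(back$history, fit$history)
  bad <- tempfile()
  saveRDS(list(1), bad)
  expect_error(read_model(bad), "checkpoint")
})
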