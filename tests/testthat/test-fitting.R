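# fitting: loss values, scheduler, training-loop contracts, determinism

test_that("cosine_lr follows the closed form and published endpoints", {
  expect_equal(cosine_lr(0, 25, 0.001), 0.001)
  expect_equal(cosine_lr(25, 25, 0.001), 0)
  expect_equal(cosine_lr(12.5, 25, 0.001), 0.0005)
  lrs <- cosine_lr(0:25, 25, 0.001)
  expect_true(all(diff(lrs) <= 0))
  expect_equal(cosine_lr(3, 10, 0.01, lr_min = 0.001),
               0.001 + 0.5 * 0.009 * (1 + cos(pi * 0.3)))
})

test_that("soft Jaccard loss matches scalar arithmetic oracles", {
  # perfect hard match: loss ~ 0
  lab <- array(sample(0:2, 32, TRUE), c(4, 4, 2))
  onehot <- osteoseg:::.one_hot(lab, 3L)
  expect_equal(soft_jaccard_loss(onehot, onehot), 0, tolerance = 1e-6)

  # fully disjoint single-class prediction: loss 1
  t0 <- osteoseg:::.one_hot(array(0L, c(2, 2, 1)), 3L)
  p1 <- osteoseg:::.one_hot(array(1L, c(2, 2, 1)), 3L)
  expect_equal(soft_jaccard_loss(p1, t0), 1, tolerance = 1e-6)

  # toy case evaluated against an independent scalar formula
  p <- array(0, c(2, 2, 3, 1))
  p[, , 1, 1] <- matrix(c(0.5, 0.5, 1, 0), 2, 2)
  p[, , 2, 1] <- 1 - p[, , 1, , drop = FALSE]
  t <- array(0, c(2, 2, 3, 1))
  t[, , 1, 1] <- matrix(c(1, 1, 1, 0), 2, 2)
  t[, , 2, 1] <- 1 - t[, , 1, , drop = FALSE]
  oracle <- function(pv, tv, s = 0, e = 1e-7) {
    I <- sum(pv * tv); U <- sum(pv) + sum(tv) - I
    (I + s) / (U + s + e)
  }
  exp_loss <- 1 - mean(c(
    oracle(p[, , 1, ], t[, , 1, ]),  # I = 2, U = 3 -> 2/3
    oracle(p[, , 2, ], t[, , 2, ]),
    oracle(p[, , 3, ], t[, , 3, ])   # empty class -> 0
  ))
  expect_equal(soft_jaccard_loss(p, t), exp_loss, tolerance = 1e-12)
  expect_equal(oracle(p[, , 1, ], t[, , 1, ]), 2 / 3, tolerance = 1e-6)

  # smoothing parameter is honoured: J_c = (I+1)/(U+1+eps) per class
  expect_equal(soft_jaccard_loss(p, t, smooth = 1),
               1 - mean(c(3 / (4 + 1e-7), 2 / (3 + 1e-7),
                          1 / (1 + 1e-7))), tolerance = 1e-12)
  expect_error(soft_jaccard_loss(p, t[, , 1:2, , drop = FALSE]),
               "identical shapes")
})

test_that("micro-aggregated epoch IoU equals single-mega-batch IoU", {
  ns <- asNamespace("osteoseg")
  set.seed(21)
  acc <- list(I = numeric(3), U = numeric(3))
  all_pred <- integer(0)
  all_lab <- integer(0)
  for (b in 1:7) {
    n <- sample(2:5, 1)
    probs <- array(runif(6 * 6 * 3 * n), c(6, 6, 3, n))
    labels <- array(sample(0:2, 36 * n, TRUE), c(6, 6, n))
    acc <- ns$.iou_accumulate(acc, probs, labels)
    all_pred <- c(all_pred, as.vector(ns$.argmax_labels(probs)))
    all_lab <- c(all_lab, as.vector(labels))
  }
  mega <- ns$.confusion_iu(all_lab, all_pred, 3L)
  expect_identical(acc$I, as.numeric(mega$intersection))
  expect_identical(acc$U, as.numeric(mega$union))
  expect_equal(ns$.miou_from_counts(acc),
               mean(mega$intersection[mega$union > 0] /
                      mega$union[mega$union > 0]))
})

make_small_fit <- function(out_dir = NULL, epochs = 2L) {
  pool <- make_phantom_pool(1:2, shape = c(6L, 24L, 24L),
                            cortex_radius = c(6, 8),
                            cortex_thickness = c(2, 3))
  split <- split_scans(names(pool), 0.5, seed = 7)
  cfg <- fit_config(epochs = epochs, batch_size = 4L,
                    patch = patch_spec(16L, 2L), seed = 7,
                    out_dir = out_dir)
  spec <- model_spec("tiny_unet", base_channels = 8L)
  fit(pool, split, spec, cfg)
}

test_that("fit produces a checkpoint, logs and in-range metrics", {
  td <- withr::local_tempdir()
  res <- make_small_fit(file.path(td, "run"))
  h <- res$history
  expect_equal(nrow(h), 2)
  expect_true(all(h$train_loss >= 0 & h$val_loss >= 0))
  expect_true(all(h$train_miou >= 0 & h$train_miou <= 1))
  expect_true(all(h$val_miou >= 0 & h$val_miou <= 1))
  # logged lr sequence equals the cosine schedule
  expect_equal(h$lr, cosine_lr(0:1, 2, 0.001))
  expect_true(file.exists(res$ckpt_path))
  expect_true(file.exists(res$final_ckpt_path))
  expect_true(file.exists(res$log_path))
  log <- readLines(res$log_path)
  expect_match(log[1], "^# osteoseg .*standalone")
  # validation scans never appear among training ids (leak audit)
  expect_length(intersect(res$split$train_ids, res$split$val_ids), 0)
  # checkpoint metadata is complete enough for prediction
  expect_s3_class(res$checkpoint, "osteoseg_checkpoint")
  expect_identical(res$checkpoint$metadata$patch_px, 16L)
})

test_that("deterministic mode reruns are bitwise identical", {
  td1 <- withr::local_tempdir()
  td2 <- withr::local_tempdir()
  r1 <- make_small_fit(file.path(td1, "run"))
  r2 <- make_small_fit(file.path(td2, "run"))
  expect_identical(r1$history, r2$history)
  expect_identical(r1$final_checkpoint$model$params,
                   r2$final_checkpoint$model$params)
  expect_identical(readBin(r1$log_path, "raw", 1e6),
                   readBin(r2$log_path, "raw", 1e6))
})

test_that("fit rejects invalid splits", {
  pool <- make_phantom_pool(1:2, shape = c(4L, 16L, 16L),
                            cortex_radius = c(4, 5),
                            cortex_thickness = c(1, 2))
  spec <- model_spec("tiny_unet", base_channels = 8L)
  cfg <- fit_config(epochs = 1L, batch_size = 2L,
                    patch = patch_spec(16L, 1L), seed = 1)
  bad <- structure(list(train_ids = names(pool),
                        val_ids = character(0),
                        requested_fraction = 0.5, seed = 1L),
                   class = "split_plan")
  expect_error(fit(pool, bad, spec, cfg), "non-empty")
  other <- structure(list(train_ids = c("nope"), val_ids = names(pool)[1],
                          requested_fraction = 0.5, seed = 1L),
                     class = "split_plan")
  expect_error(fit(pool, other, spec, cfg), "cover")
})
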