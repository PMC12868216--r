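# prediction: chunk grids, probability merging, thresholded labels,
# whole-volume inference with stub models

test_that("plan_chunks covers every pixel with a deterministic grid", {
  # single chunk when tile equals chunk
  g1 <- plan_chunks(c(512L, 512L), 512L, 0.25)
  expect_equal(nrow(g1$origins), 1)
  expect_equal(g1$origins[1, ], c(y = 0L, x = 0L))

  # 768 tile, 512 chunk, 50% overlap: origins {0, 256} per axis
  g2 <- plan_chunks(c(768L, 768L), 512L, 0.5)
  expect_setequal(unique(g2$origins[, "y"]), c(0L, 256L))
  expect_setequal(unique(g2$origins[, "x"]), c(0L, 256L))
  # brute-force pixelwise coverage check
  cov <- matrix(0L, 768, 768)
  for (i in seq_len(nrow(g2$origins))) {
    o <- g2$origins[i, ]
    cov[(o[1] + 1):(o[1] + 512), (o[2] + 1):(o[2] + 512)] <-
      cov[(o[1] + 1):(o[1] + 512), (o[2] + 1):(o[2] + 512)] + 1L
  }
  expect_true(all(cov >= 1))

  # tile smaller than chunk: single padded chunk
  g3 <- plan_chunks(c(500L, 500L), 512L)
  expect_equal(nrow(g3$origins), 1)
  expect_equal(g3$padded_shape, c(512L, 512L))
  expect_equal(g3$tile_shape, c(500L, 500L))

  # coverage with uneven stride: last chunk aligned to far edge
  g4 <- plan_chunks(c(300L, 200L), 128L, 0.25)
  expect_true(max(g4$origins[, "y"]) == 300 - 128)
  expect_true(max(g4$origins[, "x"]) == 200 - 128)
})

test_that("merge_chunks averages probabilities in overlaps", {
  # constant chunks merge to the constant regardless of overlap
  g <- plan_chunks(c(96L, 96L), 64L, 0.5)
  v <- c(0.2, 0.5, 0.3)
  chunks <- lapply(seq_len(nrow(g$origins)), function(i) {
    a <- array(0, c(64, 64, 3))
    for (c in 1:3) a[, , c] <- v[c]
    a
  })
  pm <- merge_chunks(chunks, g)
  for (c in 1:3) expect_equal(range(pm$probs[, , c]), rep(v[c], 2))
  # normalized inputs stay normalized
  expect_equal(range(apply(pm$probs, c(1, 2), sum)), c(1, 1))

  # two chunks overlapping on a strip: 0.2 and 0.6 average to 0.4
  g2 <- plan_chunks(c(4L, 6L), 4L, 0.5)
  expect_equal(nrow(g2$origins), 2)
  mk <- function(p1) {
    a <- array(0, c(4, 4, 3))
    a[, , 1] <- 1 - p1; a[, , 2] <- p1
    a
  }
  pm2 <- merge_chunks(list(mk(0.2), mk(0.6)), g2)
  expect_equal(unique(as.vector(pm2$probs[, 3:4, 2])), 0.4)
  expect_equal(unique(as.vector(pm2$probs[, 1:2, 2])), 0.2)
  expect_equal(unique(as.vector(pm2$probs[, 5:6, 2])), 0.6)
  expect_true(all(pm2$counts[, 3:4] == 2))

  expect_error(merge_chunks(list(mk(0.2)), g2), "expected 2 chunks")
})

test_that("assign_labels applies argmax with confidence reassignment", {
  arr <- array(0, c(1, 3, 3))
  arr[1, 1, ] <- c(0.2, 0.45, 0.35)  # low confidence -> background
  arr[1, 2, ] <- c(0.1, 0.6, 0.3)    # confident bone
  arr[1, 3, ] <- c(1, 0, 0)          # confident background
  lab <- assign_labels(arr, 0.5)
  expect_equal(as.vector(lab), c(0L, 1L, 0L))
  # ties break to the lowest class index
  tie <- array(1 / 3, c(1, 1, 3))
  expect_equal(as.vector(assign_labels(tie, 0)), 0L)
  tie2 <- array(c(0.1, 0.45, 0.45), c(1, 1, 3))
  expect_equal(as.vector(assign_labels(tie2, 0)), 1L)
  # threshold 1 with max prob < 1 blanks everything
  expect_true(all(assign_labels(arr, 1) == 0L))
})

test_that("predict_volume equals the composition oracle for a stub", {
  v <- make_volume(c(2, 16, 16), seed = 3)
  logits <- c(0.3, 1.2, -0.5)
  ck <- osteoseg:::.make_checkpoint(constant_stub(logits), "minmax", 16L)
  pred <- predict_volume(ck, v, chunk_px = 16L, threshold = 0.5)
  expected_class <- which.max(softmax3(logits)) - 1L
  expected <- if (max(softmax3(logits)) < 0.5) 0L else expected_class
  expect_true(all(pred$mask$labels == expected))
  expect_equal(pred$confidence$mean_max_prob, max(softmax3(logits)))
  expect_identical(dim(pred$mask$labels), dim(v$voxels))

  # threshold 1 with an imperfect stub blanks the mask
  pred1 <- predict_volume(ck, v, chunk_px = 16L, threshold = 1)
  expect_true(all(pred1$mask$labels == 0L))
})

test_that("chunked equals unchunked prediction for stub models", {
  v <- make_volume(c(2, 32, 32), seed = 11)
  model <- intensity_stub()
  ck <- osteoseg:::.make_checkpoint(model, "minmax", 32L)
  whole <- predict_volume(ck, v, chunk_px = 32L, overlap_fraction = 0)
  st <- compute_norm_stats(v, "minmax")
  for (ov in c(0, 0.25, 0.5)) {
    chunked <- predict_volume(ck, v, chunk_px = 16L,
                              overlap_fraction = ov)
    expect_identical(chunked$mask$labels, whole$mask$labels)
    # per-voxel probability agreement against a direct forward pass
    x <- array(normalize_patch(v$voxels[1, , ], st), c(32, 32, 1, 1))
    direct <- osteoseg:::.softmax_channels(model$forward(model$params, x))
    g <- plan_chunks(c(32L, 32L), 16L, ov)
    slice <- normalize_patch(v$voxels[1, , ], st)
    chunks <- lapply(seq_len(nrow(g$origins)), function(i) {
      o <- g$origins[i, ]
      xx <- array(slice[(o[1] + 1):(o[1] + 16), (o[2] + 1):(o[2] + 16)],
                  c(16, 16, 1, 1))
      osteoseg:::.softmax_channels(model$forward(model$params, xx))[, , , 1]
    })
    pm <- merge_chunks(chunks, g)
    expect_lt(max(abs(pm$probs - direct[, , , 1])), 1e-5)
  }
})

test_that("predict_volume refuses incomplete metadata", {
  v <- make_volume(c(1, 8, 8))
  ck <- osteoseg:::.make_checkpoint(constant_stub(c(1, 0, 0)), "minmax",
                                    8L)
  ck$metadata$normalization <- NULL
  expect_error(predict_volume(ck, v), "metadata incomplete")
})

test_that("inference batch estimate is a sane pure function", {
  expect_gte(estimate_inference_batch(512L, 1), 1)
  b64 <- estimate_inference_batch(64L, 256)
  b128 <- estimate_inference_batch(128L, 256)
  expect_gt(b64, b128)
  expect_identical(b64, estimate_inference_batch(64L, 256))
})
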