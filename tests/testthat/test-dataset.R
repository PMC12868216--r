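# dataset: splits, folds, patch origins, augmentation, bookkeeping

test_that("split_scans realizes the requested fraction at scan level", {
  ids16 <- sprintf("s%02d", 1:16)
  sp <- split_scans(ids16, 0.8125, seed = 42)
  expect_length(sp$train_ids, 13)
  expect_length(sp$val_ids, 3)
  expect_setequal(c(sp$train_ids, sp$val_ids), ids16)
  expect_length(intersect(sp$train_ids, sp$val_ids), 0)

  sp2 <- split_scans(c("a", "b"), 0.5, seed = 1)
  expect_length(sp2$train_ids, 1)
  expect_length(sp2$val_ids, 1)

  # brute-force oracle: chosen count minimizes |c/N - fraction|
  ids20 <- sprintf("t%02d", 1:20)
  sp3 <- split_scans(ids20, 0.8, seed = 3)
  counts <- 1:19
  best <- counts[which.min(abs(counts / 20 - 0.8))]
  expect_length(sp3$train_ids, best)
  expect_identical(best, 16L)

  expect_error(split_scans("only", 0.5, 1), "at least 2")
  expect_error(split_scans(c("a", "b"), 1.2, 1), "fraction")

  # same seed reproduces the split; no scan ever on both sides
  for (seed in 1:20) {
    s <- split_scans(ids20, 0.7, seed)
    expect_identical(s$train_ids, split_scans(ids20, 0.7, seed)$train_ids)
    expect_length(intersect(s$train_ids, s$val_ids), 0)
  }
})

test_that("build_folds makes consecutive equal blocks with ordered pools", {
  ids <- bone_fold_order()
  fp <- build_folds(ids, 5)
  expect_length(fp$folds, 5)
  expect_true(all(lengths(fp$folds) == 4))
  expect_identical(fp$folds[[1]], ids[1:4])
  # pool 1 = positions 5..20 in sequence order
  expect_identical(fp$pools[[1]], ids[5:20])
  # every scan in exactly one test fold
  expect_setequal(unlist(fp$folds), ids)
  expect_identical(anyDuplicated(unlist(fp$folds)), 0L)
  # fold + pool partition the scans
  for (i in 1:5) {
    expect_setequal(c(fp$folds[[i]], fp$pools[[i]]), ids)
    expect_length(intersect(fp$folds[[i]], fp$pools[[i]]), 0)
  }

  fp3 <- build_folds(sprintf("x%d", 1:9), 3)
  expect_true(all(lengths(fp3$folds) == 3))
  expect_error(build_folds(sprintf("x%d", 1:10), 3), "not divisible")
})

test_that("sample_patch_origins respects overlap and determinism", {
  # forced case: patch equals tile, all origins (0,0)
  sp <- patch_spec(256L, 4L, max_overlap = 0)
  o <- sample_patch_origins(c(256L, 256L), sp, seed = 1)
  expect_true(all(o == 0L))

  # large tile, zero overlap achievable: pairwise intersections are 0
  sp2 <- patch_spec(256L, 4L, max_overlap = 0)
  o2 <- sample_patch_origins(c(1024L, 1024L), sp2, seed = 5)
  for (i in 1:3) for (j in (i + 1):4) {
    dy <- max(0, 256 - abs(o2[i, 1] - o2[j, 1]))
    dx <- max(0, 256 - abs(o2[i, 2] - o2[j, 2]))
    expect_equal(dy * dx, 0)
  }
  # origins keep patches inside the tile
  expect_true(all(o2 >= 0 & o2 <= 1024 - 256))

  # same seed, same origins
  expect_identical(o2, sample_patch_origins(c(1024L, 1024L), sp2,
                                            seed = 5))
})

test_that("geometric augmentation branch frequencies match the policy", {
  set.seed(1701)
  n <- 100000L
  pol <- augmentation_policy()
  sp <- matrix(runif(16), 4, 4)
  branches <- character(n)
  for (i in seq_len(n)) {
    branches[i] <- augment_geometric(sp, sp, pol)$branch
  }
  freq <- table(factor(branches,
                       c("hflip", "vflip", "rot90s", "none"))) / n
  expect_lt(abs(freq[["rot90s"]] - 0.5), 0.005)
  # chi-square goodness of fit not rejected at alpha = 0.01
  p_exp <- c(pol$p_hflip, pol$p_vflip, pol$p_rot90s, pol$p_none)
  cs <- suppressWarnings(stats::chisq.test(as.vector(freq) * n,
                                           p = p_exp))
  expect_gt(cs$p.value, 0.01)
})

test_that("scan and mask patches stay aligned under every augmentation", {
  # coordinate-encoding image: value = y * 1000 + x
  co <- outer(1:16 * 1000, 1:16, `+`)
  set.seed(7)
  for (i in 1:200) {
    g <- augment_geometric(co, co)
    expect_identical(g$scan, g$mask)
  }
  # hflip applied twice is the identity
  h <- function(m) m[, ncol(m):1]
  expect_identical(h(h(co)), co)
})

test_that("intensity augmentation obeys ranges and clipping", {
  pol <- augmentation_policy()
  # identity parameters leave the patch untouched
  p <- matrix(runif(64), 8, 8)
  expect_equal(augment_intensity(p, list(scale = 1, delta = 0),
                                 "minmax"), p)
  # min-max saturation: all-1 patch shifted up stays 1
  ones <- matrix(1, 4, 4)
  expect_equal(augment_intensity(ones, list(scale = 1, delta = 0.15),
                                 "minmax"), ones)
  # drawn parameters always within the declared ranges
  set.seed(42)
  draws <- replicate(100000, unlist(draw_intensity_params(pol)))
  expect_gte(min(draws["scale", ]), 0.75)
  expect_lte(max(draws["scale", ]), 1.25)
  expect_gte(min(draws["delta", ]), -0.15)
  expect_lte(max(draws["delta", ]), 0.15)
  # selection frequencies ~40% each
  expect_lt(abs(mean(draws["scale", ] != 1) - 0.4), 0.01)
  expect_lt(abs(mean(draws["delta", ] != 0) - 0.4), 0.01)
})

test_that("patches_per_epoch reproduces the published bookkeeping", {
  tiles <- bone_tile_counts()
  pool1 <- build_folds(bone_fold_order(), 5)$pools[[1]]
  pp <- patches_per_epoch(pool1, tiles, per_tile = 4L)
  expect_identical(pp$n_total, 142960L)

  # single scan sanity and conservation under any split
  expect_identical(patches_per_epoch("solo", c(solo = 10L), 4L)$n_total,
                   40L)
  sp <- split_scans(pool1, 0.8125, seed = 42)
  pps <- patches_per_epoch(sp, tiles, 4L)
  expect_identical(pps$n_train + pps$n_val, 142960L)
  expect_error(patches_per_epoch(c("nope"), tiles), "unknown scan id")
})
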