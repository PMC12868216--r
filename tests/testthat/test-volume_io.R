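# volume_io: TIFF stack round trips, slice ordering, normalization stats

test_that("read/write round trip is bit-exact for u8, u16 and float", {
  td <- withr::local_tempdir()
  shapes <- c(3, 4, 5)

  v8 <- scan_volume(array(sample(0:255, prod(shapes), TRUE), shapes),
                    "v8", bit_depth = "u8")
  write_tiff_stack(v8, file.path(td, "v8"))
  r8 <- read_tiff_stack(file.path(td, "v8"))
  expect_identical(r8$voxels, v8$voxels + 0)
  expect_identical(r8$bit_depth, "u8")

  v16 <- scan_volume(array(sample(0:65535, prod(shapes), TRUE), shapes),
                     "v16")
  write_tiff_stack(v16, file.path(td, "v16"))
  r16 <- read_tiff_stack(file.path(td, "v16"))
  expect_identical(r16$voxels, v16$voxels + 0)
  expect_identical(r16$bit_depth, "u16")

  # float: quantize through one write/read so values are exactly
  # float32-representable, then the round trip must be bit-exact
  vf0 <- scan_volume(array(rnorm(prod(shapes)), shapes), "vf",
                     bit_depth = "float")
  write_tiff_stack(vf0, file.path(td, "vf0"))
  vf <- read_tiff_stack(file.path(td, "vf0"))
  write_tiff_stack(vf, file.path(td, "vf"))
  rf <- read_tiff_stack(file.path(td, "vf"))
  expect_identical(rf$voxels, vf$voxels)
  expect_identical(rf$bit_depth, "float")
})

test_that("masks round trip as u8 with values preserved", {
  td <- withr::local_tempdir()
  m <- make_mask(c(3, 8, 8), "m1")
  write_tiff_stack(m, file.path(td, "m1_mask"))
  r <- read_label_mask(file.path(td, "m1_mask"))
  expect_identical(r$labels, m$labels)
  expect_identical(r$scan_id, "m1")
})

test_that("slices stack in lexicographic filename order", {
  td <- withr::local_tempdir()
  d <- file.path(td, "scan")
  dir.create(d)
  # names s1, s10, s2: lexicographic order is s1, s10, s2
  for (nm in c("s10", "s2", "s1")) {
    val <- switch(nm, s1 = 1, s10 = 10, s2 = 2)
    osteoseg:::write_tiff_slice(matrix(val, 2, 2), file.path(td, "scan",
                                paste0(nm, ".tif")), bits = 8L)
  }
  v <- read_tiff_stack(d)
  expect_equal(v$voxels[, 1, 1], c(1, 10, 2))
  # zero-padded writer names sort numerically
  w <- scan_volume(array(seq_len(12 * 2 * 2) - 1, c(12, 2, 2)), "w",
                   bit_depth = "u8")
  write_tiff_stack(w, file.path(td, "w"))
  expect_identical(read_tiff_stack(file.path(td, "w"))$voxels,
                   w$voxels + 0)
})

test_that("read errors name the offending condition", {
  td <- withr::local_tempdir()
  dir.create(file.path(td, "empty"))
  expect_error(read_tiff_stack(file.path(td, "empty")), "no TIFF")
  dir.create(file.path(td, "mixed"))
  osteoseg:::write_tiff_slice(matrix(0, 2, 2),
                              file.path(td, "mixed", "a.tif"), bits = 8L)
  osteoseg:::write_tiff_slice(matrix(0, 3, 2),
                              file.path(td, "mixed", "b.tif"), bits = 8L)
  expect_error(read_tiff_stack(file.path(td, "mixed")), "b\\.tif")
})

test_that("TIFF codec interoperates with Python tifffile", {
  td <- withr::local_tempdir()
  v <- scan_volume(array(sample(0:65535, 2 * 6 * 9, TRUE), c(2, 6, 9)),
                   "x")
  write_tiff_stack(v, file.path(td, "x"))
  out <- system2("python", c("-c", shQuote(sprintf(
    "import tifffile; a = tifffile.imread('%s'); print(a.dtype, a.shape[0], a.shape[1], int(a.sum()))",
    file.path(td, "x", "slice_0000.tif")))), stdout = TRUE)
  parts <- strsplit(out, " ")[[1]]
  expect_identical(parts[1], "uint16")
  expect_equal(as.integer(parts[2:3]), c(6L, 9L))
  expect_equal(as.numeric(parts[4]), sum(v$voxels[1, , ]))

  system2("python", c("-c", shQuote(sprintf(
    "import numpy as np, tifffile; rng = np.random.default_rng(5); tifffile.imwrite('%s', rng.integers(0, 255, (4, 7)).astype(np.uint8))",
    file.path(td, "py.tif")))))
  s <- osteoseg:::read_tiff_slice(file.path(td, "py.tif"))
  chk <- system2("python", c("-c", shQuote(sprintf(
    "import tifffile; print(int(tifffile.imread('%s').sum()))",
    file.path(td, "py.tif")))), stdout = TRUE)
  expect_equal(sum(s$pixels), as.numeric(chk))
})

test_that("normalization statistics are population statistics", {
  v <- scan_volume(array(c(0, 2, 4, 6), c(1, 2, 2)), "s")
  st <- compute_norm_stats(v, "zscore")
  expect_equal(st$mean, 3)
  expect_equal(st$std, sqrt(5))  # population: mean((x - 3)^2) = 5
  expect_equal(st$min, 0)
  expect_equal(st$max, 6)
  expect_identical(st$mode, "zscore")
  expect_identical(compute_norm_stats(v, "minmax")$mode, "minmax")

  cv <- scan_volume(array(7, c(2, 2, 2)), "c")
  stc <- compute_norm_stats(cv, "zscore")
  expect_equal(stc$mean, 7)
  expect_equal(stc$std, 0)
  expect_equal(stc$min, stc$max)

  # invariant to slice reordering of identical content
  v2 <- scan_volume(v$voxels[1, , , drop = FALSE], "s2")
  expect_equal(compute_norm_stats(v2, "zscore")$mean, st$mean)
})

test_that("normalize_patch obeys the mode contracts", {
  v <- scan_volume(array(c(0, 2, 4, 6), c(1, 2, 2)), "s")
  stz <- compute_norm_stats(v, "zscore")
  stm <- compute_norm_stats(v, "minmax")

  expect_equal(normalize_patch(matrix(3, 2, 2), stz), matrix(0, 2, 2))
  expect_equal(sort(as.vector(normalize_patch(v$voxels[1, , ], stm))),
               c(0, 1 / 3, 2 / 3, 1))

  # degenerate scan maps to zeros through the epsilon guard
  cst <- compute_norm_stats(scan_volume(array(5, c(1, 2, 2)), "c"),
                            "minmax")
  expect_equal(normalize_patch(matrix(5, 2, 2), cst), matrix(0, 2, 2))

  # z-score of full scan has mean ~0, population sd ~1
  big <- make_volume(c(4, 10, 10), seed = 7)
  stb <- compute_norm_stats(big, "zscore")
  z <- normalize_patch(big$voxels, stb)
  expect_lt(abs(mean(z)), 1e-10)
  expect_lt(abs(sqrt(mean((z - mean(z))^2)) - 1), 1e-5)

  # minmax output always within [0, 1]
  nm <- normalize_patch(big$voxels, compute_norm_stats(big, "minmax"))
  expect_gte(min(nm), 0)
  expect_lte(max(nm), 1)
})
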