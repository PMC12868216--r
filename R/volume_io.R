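#' Construct a scan volume
#'
#' A `scan_volume` is the unit of data handling throughout the toolkit: a 3D
#' grayscale intensity array ordered Z (slices) x Y (rows) x X (columns),
#' together with the voxel size and the scan identity used for leak-free
#' scan-level splitting.
#'
#' @param voxels 3D numeric array, dimensions Z x Y x X.
#' @param scan_id Character scalar naming the scan.
#' @param voxel_size_um Positive isotropic voxel size in micrometers.
#' @param bit_depth One of `"u8"`, `"u16"`, `"float"`. Integer depths bound
#'   the admissible intensity range to `[0, 2^depth - 1]`.
#' @return An object of class `scan_volume`.
#' @export
scan_volume <- function(voxels, scan_id, voxel_size_um = 1,
                        bit_depth = c("u16", "u8", "float")) {
  bit_depth <- match.arg(bit_depth)
  if (!is.array(voxels) || length(dim(voxels)) != 3L) {
    stop("`voxels` must be a 3D array (Z x Y x X)")
  }
  if (any(dim(voxels) < 1L)) stop("all volume dimensions must be >= 1")
  if (!is.character(scan_id) || length(scan_id) != 1L || !nzchar(scan_id)) {
    stop("`scan_id` must be a non-empty character scalar")
  }
  if (!is.numeric(voxel_size_um) || voxel_size_um <= 0) {
    stop("`voxel_size_um` must be positive")
  }
  if (bit_depth != "float") {
    top <- if (bit_depth == "u8") 255 else 65535
    rng <- range(voxels)
    if (rng[1] < 0 || rng[2] > top) {
      stop("intensities out of range [0, ", top, "] for bit depth ",
           bit_depth)
    }
  }
  structure(
    list(scan_id = scan_id, voxels = voxels,
         voxel_size_um = as.numeric(voxel_size_um), bit_depth = bit_depth),
    class = "scan_volume"
  )
}

#' Construct a label mask
#'
#' Integer class array congruent with a paired [scan_volume()]. Class codes:
#' 0 = background (including marrow), 1 = cortical/trabecular bone,
#' 2 = medullary pores.
#'
#' @param labels 3D integer array (Z x Y x X) with values in `{0, 1, 2}`.
#' @param scan_id Character scalar naming the scan the mask belongs to.
#' @return An object of class `label_mask`.
#' @export
label_mask <- function(labels, scan_id) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stop("`labels` must be a 3D array (Z x Y x X)")
  }
  if (!all(labels %in% c(0, 1, 2))) {
    stop("mask values must be within {0, 1, 2}")
  }
  storage.mode(labels) <- "integer"
  structure(
    list(scan_id = scan_id, labels = labels,
         class_codes = c(`0` = "background", `1` = "bone", `2` = "pores")),
    class = "label_mask"
  )
}

#' @export
print.scan_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<scan_volume> %s: %d x %d x %d (Z x Y x X), %s, %.1f um/voxel\n",
              x$scan_id, d[1], d[2], d[3], x$bit_depth, x$voxel_size_um))
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_mask> %s: %d x %d x %d (Z x Y x X), classes {0,1,2}\n",
              x$scan_id, d[1], d[2], d[3]))
  invisible(x)
}

.infer_bit_depth <- function(bits, format) {
  if (format == "float") "float" else if (bits == 8) "u8" else "u16"
}

#' Read a volume from a directory of TIFF slices
#'
#' Stacks all single-page grayscale TIFF files found in `dir_path` into a
#' Z x Y x X volume. Slices are ordered by plain lexicographic (byte-wise)
#' filename order, so zero-padded numeric names sort numerically. The bit
#' depth is inferred from the pixel type of the slices.
#'
#' @param dir_path Directory containing `.tif`/`.tiff` files.
#' @param scan_id Scan identity; defaults to the directory basename.
#' @param voxel_size_um Voxel size to record, micrometers.
#' @return A [scan_volume()].
#' @export
read_tiff_stack <- function(dir_path, scan_id = basename(dir_path),
                            voxel_size_um = 1) {
  if (!dir.exists(dir_path)) stop("directory does not exist: ", dir_path)
  files <- list.files(dir_path, pattern = "\\.tiff?$", ignore.case = TRUE)
  if (length(files) == 0L) stop("no TIFF slices found in ", dir_path)
  files <- sort(files, method = "radix")  # byte-wise, locale-independent
  slices <- vector("list", length(files))
  ref <- NULL
  for (i in seq_along(files)) {
    s <- read_tiff_slice(file.path(dir_path, files[i]))
    if (is.null(ref)) {
      ref <- s
    } else if (!identical(dim(s$pixels), dim(ref$pixels)) ||
               s$bits != ref$bits || s$format != ref$format) {
      stop("slice ", files[i], " differs in shape or pixel type from ",
           files[1])
    }
    slices[[i]] <- s$pixels
  }
  vox <- array(0, dim = c(length(files), nrow(ref$pixels), ncol(ref$pixels)))
  for (i in seq_along(slices)) vox[i, , ] <- slices[[i]]
  scan_volume(vox, scan_id = scan_id, voxel_size_um = voxel_size_um,
              bit_depth = .infer_bit_depth(ref$bits, ref$format))
}

#' Read a label mask from a directory of TIFF slices
#'
#' @inheritParams read_tiff_stack
#' @return A [label_mask()].
#' @export
read_label_mask <- function(dir_path, scan_id = sub("_mask$", "",
                                                    basename(dir_path))) {
  vol <- read_tiff_stack(dir_path, scan_id = scan_id)
  label_mask(vol$voxels, scan_id = scan_id)
}

#' Write a volume or mask as a directory of TIFF slices
#'
#' One single-page grayscale TIFF per Z slice, named `slice_0000.tif`,
#' `slice_0001.tif`, ... so that lexicographic order equals slice order.
#' Volumes keep their bit depth (`u8`/`u16`/32-bit float); masks are stored
#' as 8-bit (three classes).
#'
#' @param vol A [scan_volume()] or [label_mask()].
#' @param dir_path Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_tiff_stack <- function(vol, dir_path) {
  if (inherits(vol, "label_mask")) {
    arr <- vol$labels
    bits <- 8L; float <- FALSE
  } else if (inherits(vol, "scan_volume")) {
    arr <- vol$voxels
    bits <- switch(vol$bit_depth, u8 = 8L, u16 = 16L, float = 32L)
    float <- vol$bit_depth == "float"
  } else {
    stop("`vol` must be a scan_volume or label_mask")
  }
  dir.create(dir_path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir_path)) stop("cannot create directory: ", dir_path)
  nz <- dim(arr)[1]
  for (z in seq_len(nz)) {
    path <- file.path(dir_path, sprintf("slice_%04d.tif", z - 1L))
    write_tiff_slice(arr[z, , ], path, bits = bits, float = float)
  }
  invisible(dir_path)
}

#' Compute per-scan normalization statistics
#'
#' Statistics are computed once over the full scan (never per patch) and
#' reused for every patch cropped from it, so that patch intensities remain
#' comparable within a scan. The standard deviation is the population form
#' (divisor N): this is a normalization constant, not an inferential
#' estimate.
#'
#' @param vol A [scan_volume()].
#' @param mode `"zscore"` or `"minmax"`.
#' @return A `norm_stats` object with fields `scan_id`, `mode`, `mean`,
#'   `std`, `min`, `max`.
#' @export
compute_norm_stats <- function(vol, mode = c("zscore", "minmax")) {
  mode <- match.arg(mode)
  stopifnot(inherits(vol, "scan_volume"))
  x <- as.numeric(vol$voxels)
  m <- mean(x)
  structure(
    list(scan_id = vol$scan_id, mode = mode, mean = m,
         std = sqrt(mean((x - m)^2)), min = min(x), max = max(x)),
    class = "norm_stats"
  )
}

#' Normalize a 2D patch with scan-level statistics
#'
#' Z-score mode maps to `(x - mean) / max(std, eps)`; min-max mode maps to
#' `(x - min) / max(max - min, eps)` and is therefore confined to `[0, 1]`
#' whenever the statistics come from the patch's source scan. Degenerate
#' (constant) scans map to all zeros through the epsilon guard.
#'
#' @param patch 2D numeric matrix (or array) of raw intensities.
#' @param stats A `norm_stats` record from [compute_norm_stats()].
#' @param eps Guard against zero std / zero range; default `1e-8`.
#' @return Numeric matrix of normalized intensities.
#' @export
normalize_patch <- function(patch, stats, eps = 1e-8) {
  stopifnot(inherits(stats, "norm_stats"))
  if (stats$mode == "zscore") {
    (patch - stats$mean) / max(stats$std, eps)
  } else {
    (patch - stats$min) / max(stats$max - stats$min, eps)
  }
}

# admissible dynamic range of normalized intensities, used to clip after
# intensity augmentation
.norm_range <- function(stats_or_mode) {
  mode <- if (is.character(stats_or_mode)) stats_or_mode else stats_or_mode$mode
  if (mode == "minmax") c(0, 1) else c(-Inf, Inf)
}
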