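# Chunked sliding-window inference: overlapping chunks per slice,
# softmax probabilities averaged in overlapping regions, argmax with
# confidence-based background reassignment.

#' Plan the chunk grid for one tile
#'
#' Chunk origins advance by `stride = floor(chunk_px * (1 -
#' overlap_fraction))` (at least 1) along each axis; the final chunk on an
#' axis is aligned to the far edge so every pixel is covered. Tiles
#' smaller than the chunk are handled by reflect-padding up to the chunk
#' size (outputs are cropped back).
#'
#' @param tile_shape Integer `(rows, cols)`.
#' @param chunk_px Square chunk edge in pixels.
#' @param overlap_fraction Fraction of chunk overlap in `[0, 1)`.
#' @return A `chunk_grid` with `origins` (0-based `(y, x)` matrix),
#'   `chunk_px`, `padded_shape`, `tile_shape`, `overlap_fraction`.
#' @export
plan_chunks <- function(tile_shape, chunk_px, overlap_fraction = 0.25) {
  stopifnot(chunk_px >= 1, overlap_fraction >= 0, overlap_fraction < 1)
  padded <- pmax(as.integer(tile_shape), chunk_px)
  stride <- max(1L, as.integer(floor(chunk_px * (1 - overlap_fraction))))
  axis_origins <- function(extent) {
    if (extent <= chunk_px) return(0L)
    o <- seq.int(0L, extent - chunk_px, by = stride)
    if (o[length(o)] != extent - chunk_px) {
      o <- c(o, extent - chunk_px)
    }
    o
  }
  oy <- axis_origins(padded[1])
  ox <- axis_origins(padded[2])
  origins <- cbind(y = rep(oy, times = length(ox)),
                   x = rep(ox, each = length(oy)))
  structure(
    list(origins = origins, chunk_px = as.integer(chunk_px),
         padded_shape = padded, tile_shape = as.integer(tile_shape),
         overlap_fraction = overlap_fraction),
    class = "chunk_grid"
  )
}

#' Merge per-chunk class probabilities into a full-tile probability map
#'
#' Overlap-aware merging: each pixel's class vector is the arithmetic mean
#' over all chunks covering it, which keeps probability vectors normalized
#' (a convex combination of normalized vectors). The map is cropped from
#' the padded grid back to the tile shape.
#'
#' @param chunk_probs List of `(chunk_px, chunk_px, n_classes)` arrays,
#'   one per grid origin, in grid order.
#' @param grid A `chunk_grid` from [plan_chunks()].
#' @return A `probability_map` with `probs` (tile `H x W x n_classes`)
#'   and `counts` (per-pixel coverage).
#' @export
merge_chunks <- function(chunk_probs, grid) {
  stopifnot(inherits(grid, "chunk_grid"))
  if (length(chunk_probs) != nrow(grid$origins)) {
    stop("expected ", nrow(grid$origins), " chunks, got ",
         length(chunk_probs))
  }
  p <- grid$chunk_px
  n_classes <- dim(chunk_probs[[1]])[3]
  acc <- array(0, c(grid$padded_shape, n_classes))
  count <- matrix(0L, grid$padded_shape[1], grid$padded_shape[2])
  for (i in seq_len(nrow(grid$origins))) {
    o <- grid$origins[i, ]
    ys <- (o[1] + 1L):(o[1] + p)
    xs <- (o[2] + 1L):(o[2] + p)
    acc[ys, xs, ] <- acc[ys, xs, , drop = FALSE] + chunk_probs[[i]]
    count[ys, xs] <- count[ys, xs] + 1L
  }
  if (any(count == 0L)) stop("chunk grid does not cover the tile")
  for (c in seq_len(n_classes)) {
    acc[, , c] <- acc[, , c] / count
  }
  ys <- seq_len(grid$tile_shape[1])
  xs <- seq_len(grid$tile_shape[2])
  structure(
    list(probs = acc[ys, xs, , drop = FALSE],
         counts = count[ys, xs, drop = FALSE]),
    class = "probability_map"
  )
}

# argmax over the class dim of (H, W, C[, N]); ties go to the lowest
# class index. Returns integer labels 0..C-1 with the spatial dims.
.argmax_labels <- function(probs) {
  d <- dim(probs)
  if (length(d) == 3L) {
    m <- matrix(probs, d[1] * d[2], d[3])
    out <- max.col(m, ties.method = "first") - 1L
    array(out, d[1:2])
  } else {
    pp <- aperm(probs, c(1, 2, 4, 3))
    m <- matrix(pp, d[1] * d[2] * d[4], d[3])
    out <- max.col(m, ties.method = "first") - 1L
    array(out, c(d[1], d[2], d[4]))
  }
}

#' Assign class labels with confidence-based background reassignment
#'
#' Each pixel takes its maximum-probability class (ties break to the
#' lowest class index, i.e. background wins ties); pixels whose maximum
#' probability falls below the confidence threshold are reassigned to
#' background (class 0).
#'
#' @param pmap A `probability_map`, or a bare `H x W x n_classes` array.
#' @param threshold Confidence threshold in `[0, 1]` (default 0.5).
#' @return Integer label matrix `H x W`.
#' @export
assign_labels <- function(pmap, threshold = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1)
  probs <- if (inherits(pmap, "probability_map")) pmap$probs else pmap
  d <- dim(probs)
  m <- matrix(probs, d[1] * d[2], d[3])
  labels <- max.col(m, ties.method = "first") - 1L
  maxp <- m[cbind(seq_len(nrow(m)), labels + 1L)]
  labels[maxp < threshold] <- 0L
  matrix(labels, d[1], d[2])
}

#' Estimate the inference batch size from a memory budget
#'
#' Pure function of the chunk size and a conservative working-set model
#' (activations of the compact U-Net peak at roughly 40 channel-planes of
#' the chunk in double precision). Keeps CPU inference from thrashing
#' while batching tiles.
#'
#' @param chunk_px Chunk edge in pixels.
#' @param budget_mb Memory budget in MiB (default 256).
#' @return Integer batch size, at least 1.
#' @export
estimate_inference_batch <- function(chunk_px, budget_mb = 256) {
  bytes_per_chunk <- chunk_px^2 * 8 * 40
  max(1L, as.integer(floor(budget_mb * 2^20 / bytes_per_chunk)))
}

#' Predict the segmentation of a whole volume
#'
#' For every Z slice: normalize with statistics computed on the input
#' scan using the normalization mode stored in the checkpoint metadata,
#' extract the chunk grid, run the model over chunks in batches, average
#' softmax probabilities in overlapping regions, and assign labels with
#' confidence thresholding. Slices accumulate into a full label mask.
#'
#' @param ckpt An `osteoseg_checkpoint` (metadata must carry the
#'   normalization mode and patch size).
#' @param vol A [scan_volume()].
#' @param chunk_px Chunk size; defaults to the checkpoint's training
#'   patch size. Rounded up to a multiple of 4 (U-Net downsampling).
#' @param threshold Confidence threshold (default 0.5).
#' @param overlap_fraction Chunk overlap (default 0.25).
#' @param budget_mb Memory budget driving the inference batch size.
#' @return List with `mask` (a [label_mask()]) and `confidence`
#'   (mean and min over voxels of the per-voxel maximum probability).
#' @export
predict_volume <- function(ckpt, vol, chunk_px = NULL, threshold = 0.5,
                           overlap_fraction = 0.25, budget_mb = 256) {
  stopifnot(inherits(ckpt, "osteoseg_checkpoint"),
            inherits(vol, "scan_volume"))
  md <- ckpt$metadata
  required <- c("architecture", "normalization", "patch_px", "fit_mode")
  missing <- required[vapply(required, function(f) {
    is.null(md[[f]]) || (is.atomic(md[[f]]) && anyNA(md[[f]]))
  }, logical(1))]
  if (length(missing)) {
    stop("checkpoint metadata incomplete (missing: ",
         paste(missing, collapse = ", "),
         "); refusing to predict without the fitted configuration")
  }
  if (is.null(chunk_px)) chunk_px <- md$patch_px
  chunk_px <- as.integer(4L * ceiling(chunk_px / 4))
  model <- ckpt$model
  stats <- compute_norm_stats(vol, md$normalization)
  d <- dim(vol$voxels)
  grid <- plan_chunks(d[2:3], chunk_px, overlap_fraction)
  batch_n <- estimate_inference_batch(chunk_px, budget_mb)
  out <- array(0L, d)
  conf_sum <- 0; conf_min <- 1; n_vox <- 0
  for (z in seq_len(d[1])) {
    slice <- normalize_patch(vol$voxels[z, , ], stats)
    slice <- .reflect_pad(slice, grid$padded_shape[1],
                          grid$padded_shape[2])
    n_chunks <- nrow(grid$origins)
    chunk_probs <- vector("list", n_chunks)
    for (start in seq.int(1L, n_chunks, by = batch_n)) {
      idx <- start:min(start + batch_n - 1L, n_chunks)
      x <- array(0, c(chunk_px, chunk_px, 1L, length(idx)))
      for (j in seq_along(idx)) {
        o <- grid$origins[idx[j], ]
        x[, , 1L, j] <- slice[(o[1] + 1L):(o[1] + chunk_px),
                              (o[2] + 1L):(o[2] + chunk_px)]
      }
      probs <- .softmax_channels(model$forward(model$params, x))
      for (j in seq_along(idx)) {
        chunk_probs[[idx[j]]] <- probs[, , , j, drop = TRUE]
      }
    }
    pmap <- merge_chunks(chunk_probs, grid)
    out[z, , ] <- assign_labels(pmap, threshold)
    maxp <- apply(pmap$probs, c(1, 2), max)
    conf_sum <- conf_sum + sum(maxp)
    conf_min <- min(conf_min, min(maxp))
    n_vox <- n_vox + length(maxp)
  }
  list(
    mask = label_mask(out, scan_id = vol$scan_id),
    confidence = list(mean_max_prob = conf_sum / n_vox,
                      min_max_prob = conf_min)
  )
}
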