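# Scan-level data handling: leak-free splits, ordered k-fold partitions,
# patch origin sampling with overlap control, and augmentation.

# run expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards
.with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Scan-level train/validation split
#'
#' Shuffles the scan ids with `seed` and assigns the first
#' `clamp(round(N * fraction), 1, N - 1)` scans to training, the rest to
#' validation. Rounding to the nearest integer count makes the realized
#' training share as close as possible to the requested fraction while
#' keeping whole scans together -- the leak-free guarantee: no scan (and
#' hence no pair of adjacent slices) can appear on both sides.
#'
#' @param ids Character vector of scan ids (length >= 2, unique).
#' @param fraction Requested training fraction in (0, 1).
#' @param seed Integer seed controlling the shuffle.
#' @return A `split_plan` with `train_ids`, `val_ids`,
#'   `requested_fraction`, `seed`.
#' @export
split_scans <- function(ids, fraction, seed) {
  if (length(ids) < 2L) stop("need at least 2 scans to split")
  if (anyDuplicated(ids)) stop("scan ids must be unique")
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  shuffled <- .with_seed(seed, sample(ids))
  n_train <- min(max(round(length(ids) * fraction), 1L),
                 length(ids) - 1L)
  structure(
    list(train_ids = shuffled[seq_len(n_train)],
         val_ids = shuffled[-seq_len(n_train)],
         requested_fraction = fraction, seed = as.integer(seed)),
    class = "split_plan"
  )
}

#' Ordered k-fold partition of scans
#'
#' `ordered_ids` is the fixed (post-shuffle) scan order. Fold `i` is the
#' i-th consecutive block of `N / k` scans; its training/validation pool
#' is the complement, kept in sequence order. `k` must divide the number
#' of scans.
#'
#' @param ordered_ids Character vector of scan ids in fixed order.
#' @param k Number of folds (>= 2).
#' @return A `fold_plan` with `ordered_ids`, `k`, `folds` (list of test-id
#'   vectors) and `pools` (list of complement-id vectors).
#' @export
build_folds <- function(ordered_ids, k) {
  n <- length(ordered_ids)
  if (k < 2L) stop("`k` must be >= 2")
  if (n %% k != 0L) {
    stop("number of scans (", n, ") is not divisible by k = ", k)
  }
  size <- n %/% k
  folds <- lapply(seq_len(k), function(i) {
    ordered_ids[((i - 1L) * size + 1L):(i * size)]
  })
  pools <- lapply(folds, function(f) setdiff(ordered_ids, f))
  structure(list(ordered_ids = ordered_ids, k = as.integer(k),
                 folds = folds, pools = pools),
            class = "fold_plan")
}

#' Patch sampling specification
#'
#' @param patch_px Square patch edge in pixels.
#' @param patches_per_tile Random patches cropped per 2D tile (default 4).
#' @param max_overlap Maximum tolerated pairwise overlap fraction of patch
#'   areas, in `[0, 1]` (best-effort, see [sample_patch_origins()]).
#' @return A `patch_spec`.
#' @export
patch_spec <- function(patch_px, patches_per_tile = 4L, max_overlap = 1) {
  stopifnot(patch_px >= 1, patches_per_tile >= 1,
            max_overlap >= 0, max_overlap <= 1)
  structure(list(patch_px = as.integer(patch_px),
                 patches_per_tile = as.integer(patches_per_tile),
                 max_overlap = max_overlap),
            class = "patch_spec")
}

.rect_overlap_frac <- function(a, b, p) {
  dy <- max(0, p - abs(a[1] - b[1]))
  dx <- max(0, p - abs(a[2] - b[2]))
  (dy * dx) / (p * p)
}

#' Sample random patch origins within a tile
#'
#' Draws `patches_per_tile` top-left origins (0-based `(y, x)`) uniformly
#' within the tile. The pairwise overlap constraint is enforced by
#' rejection sampling with at most 200 retries per patch; when the
#' constraint is unsatisfiable (e.g. patch equals tile) the last candidate
#' is accepted with a warning-free fallback, since identical origins are
#' then forced. The same origins must be applied to the scan and its mask
#' so patches stay voxel-aligned.
#'
#' @param tile_shape Integer `(rows, cols)` of the tile.
#' @param spec A [patch_spec()].
#' @param seed Optional seed; by default draws from the current RNG
#'   stream (so a seeded training loop stays reproducible).
#' @param max_retries Rejection-sampling budget per patch.
#' @return Integer matrix `patches_per_tile x 2` of 0-based `(y, x)`.
#' @export
sample_patch_origins <- function(tile_shape, spec, seed = NULL,
                                 max_retries = 200L) {
  stopifnot(inherits(spec, "patch_spec"))
  draw <- function() {
    p <- spec$patch_px
    # tiles smaller than the patch are reflect-padded downstream; the
    # origin is then forced to 0 on that axis
    ymax <- max(tile_shape[1] - p, 0L)
    xmax <- max(tile_shape[2] - p, 0L)
    origins <- matrix(0L, spec$patches_per_tile, 2L,
                      dimnames = list(NULL, c("y", "x")))
    for (i in seq_len(spec$patches_per_tile)) {
      for (try in seq_len(max_retries)) {
        cand <- c(sample.int(ymax + 1L, 1L) - 1L,
                  sample.int(xmax + 1L, 1L) - 1L)
        ok <- TRUE
        if (i > 1L && spec$max_overlap < 1) {
          for (j in seq_len(i - 1L)) {
            if (.rect_overlap_frac(origins[j, ], cand, p) >
                spec$max_overlap + 1e-12) {
              ok <- FALSE
              break
            }
          }
        }
        if (ok) break
      }
      if (!ok && (ymax > 0L || xmax > 0L)) {
        warning("overlap constraint not satisfied after ", max_retries,
                " retries; accepting last candidate", call. = FALSE)
      }
      origins[i, ] <- cand
    }
    origins
  }
  if (is.null(seed)) draw() else .with_seed(seed, draw())
}

# reflect-pad a matrix on the bottom/right to at least (h, w)
.reflect_pad <- function(m, h, w) {
  if (nrow(m) < h) {
    need <- h - nrow(m)
    idx <- rev(seq_len(nrow(m)))[seq_len(min(need, nrow(m)))]
    while (length(idx) < need) idx <- c(idx, rev(idx))[seq_len(need)]
    m <- rbind(m, m[idx, , drop = FALSE])
  }
  if (ncol(m) < w) {
    need <- w - ncol(m)
    idx <- rev(seq_len(ncol(m)))[seq_len(min(need, ncol(m)))]
    while (length(idx) < need) idx <- c(idx, rev(idx))[seq_len(need)]
    m <- cbind(m, m[, idx, drop = FALSE])
  }
  m
}

.crop_patch <- function(tile, origin, p) {
  tile <- .reflect_pad(tile, origin[1] + p, origin[2] + p)
  tile[(origin[1] + 1L):(origin[1] + p),
       (origin[2] + 1L):(origin[2] + p), drop = FALSE]
}

#' Augmentation policy
#'
#' The geometric branch is a single categorical draw: horizontal flip
#' (16.6%), vertical flip (16.6%), a rotation by 90, 180 or 270 degrees
#' chosen uniformly (50% total), or no transform (16.8%). Rotations are
#' restricted to quarter turns so label masks transform without
#' interpolation artifacts. Intensity augmentation applies, with
#' independent 40% probabilities, a global contrast rescale (factor drawn
#' from `scale_range`) and a brightness shift (drawn from `shift_range`)
#' to already-normalized patches, followed by clipping to the dynamic
#' range of the normalization mode.
#'
#' @param p_hflip,p_vflip,p_rot90s,p_none Geometric branch probabilities;
#'   must sum to 1.
#' @param p_brightness,p_contrast Independent intensity probabilities.
#' @param shift_range,scale_range Uniform sampling ranges.
#' @return An `augmentation_policy`.
#' @export
augmentation_policy <- function(p_hflip = 0.166, p_vflip = 0.166,
                                p_rot90s = 0.5, p_none = 0.168,
                                p_brightness = 0.4, p_contrast = 0.4,
                                shift_range = c(-0.15, 0.15),
                                scale_range = c(0.75, 1.25)) {
  probs <- c(p_hflip, p_vflip, p_rot90s, p_none)
  if (abs(sum(probs) - 1) > 1e-9) {
    stop("geometric branch probabilities must sum to 1 (got ",
         sum(probs), ")")
  }
  structure(list(p_hflip = p_hflip, p_vflip = p_vflip,
                 p_rot90s = p_rot90s, p_none = p_none,
                 p_brightness = p_brightness, p_contrast = p_contrast,
                 shift_range = shift_range, scale_range = scale_range),
            class = "augmentation_policy")
}

.rot90cw <- function(m, k = 1L) {
  for (i in seq_len(k %% 4L)) m <- t(m[nrow(m):1, , drop = FALSE])
  m
}

#' Apply one geometric augmentation draw to a scan/mask tile pair
#'
#' Exactly one branch is drawn per call using cumulative thresholds on a
#' single uniform variate, with the branch probabilities of the policy.
#' The identical transform is applied to scan and mask.
#'
#' @param scan_patch,mask_patch Matrices of equal shape (square for
#'   rotations).
#' @param policy An [augmentation_policy()].
#' @return List with `scan`, `mask`, `branch` (one of `"hflip"`,
#'   `"vflip"`, `"rot90s"`, `"none"`) and `k_rot` (quarter turns, 0 if no
#'   rotation).
#' @export
augment_geometric <- function(scan_patch, mask_patch,
                              policy = augmentation_policy()) {
  u <- stats::runif(1)
  cum <- cumsum(c(policy$p_hflip, policy$p_vflip, policy$p_rot90s))
  if (u < cum[1]) {
    branch <- "hflip"; k <- 0L
    f <- function(m) m[, ncol(m):1, drop = FALSE]
  } else if (u < cum[2]) {
    branch <- "vflip"; k <- 0L
    f <- function(m) m[nrow(m):1, , drop = FALSE]
  } else if (u < cum[3]) {
    branch <- "rot90s"
    k <- sample.int(3L, 1L)
    f <- function(m) .rot90cw(m, k)
  } else {
    branch <- "none"; k <- 0L
    f <- identity
  }
  list(scan = f(scan_patch), mask = f(mask_patch), branch = branch,
       k_rot = k)
}

#' Draw the shared intensity-augmentation parameters for a batch
#'
#' One contrast factor and one brightness shift are drawn per batch and
#' applied to all scan patches in it (masks are never intensity
#' augmented). A branch that is not selected contributes the identity
#' (`scale = 1`, `delta = 0`).
#'
#' @param policy An [augmentation_policy()].
#' @return List with `scale` and `delta`.
#' @export
draw_intensity_params <- function(policy = augmentation_policy()) {
  scale <- if (stats::runif(1) < policy$p_contrast) {
    stats::runif(1, policy$scale_range[1], policy$scale_range[2])
  } else 1
  delta <- if (stats::runif(1) < policy$p_brightness) {
    stats::runif(1, policy$shift_range[1], policy$shift_range[2])
  } else 0
  list(scale = scale, delta = delta)
}

#' Intensity-augment a normalized patch
#'
#' Applies `x -> x * scale` then `x -> x + delta`, clipping the result to
#' the dynamic range implied by the normalization mode (`[0, 1]` for
#' min-max; unbounded for z-score).
#'
#' @param norm_patch Normalized patch matrix.
#' @param params List with `scale` and `delta`, e.g. from
#'   [draw_intensity_params()].
#' @param mode Normalization mode the patch was produced with.
#' @return Augmented patch.
#' @export
augment_intensity <- function(norm_patch, params, mode = "minmax") {
  rng <- .norm_range(mode)
  out <- norm_patch * params$scale + params$delta
  pmin(pmax(out, rng[1]), rng[2])
}

#' Patches per epoch under a split or pool
#'
#' With `patches_per_tile` random patches cropped from every 2D tile of
#' every scan, the per-epoch patch counts are a pure bookkeeping function
#' of the tile counts; the total is independent of how scans are assigned
#' to training and validation.
#'
#' @param plan_or_ids A `split_plan`, or a character vector of scan ids
#'   (a pool) for which only the total is defined.
#' @param tile_counts Named integer vector mapping scan id to tile count.
#' @param per_tile Patches cropped per tile (default 4).
#' @return List with `n_train`, `n_val` (NA for a bare pool) and
#'   `n_total`.
#' @export
patches_per_epoch <- function(plan_or_ids, tile_counts, per_tile = 4L) {
  count_for <- function(ids) {
    missing <- setdiff(ids, names(tile_counts))
    if (length(missing)) {
      stop("unknown scan id(s): ", paste(missing, collapse = ", "))
    }
    if (any(tile_counts[ids] <= 0)) stop("tile counts must be positive")
    per_tile * sum(tile_counts[ids])
  }
  if (inherits(plan_or_ids, "split_plan")) {
    n_train <- count_for(plan_or_ids$train_ids)
    n_val <- count_for(plan_or_ids$val_ids)
    list(n_train = n_train, n_val = n_val, n_total = n_train + n_val)
  } else {
    list(n_train = NA_integer_, n_val = NA_integer_,
         n_total = count_for(plan_or_ids))
  }
}
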