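#' Single-cycle cosine annealing learning rate
#'
#' `lr(t) = lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * t / E))`: one
#' half-cosine from `lr0` at `t = 0` to `lr_min` at `t = E`, without
#' restarts. The schedule is stepped once per epoch; epoch `t`
#' (0-based) trains at `cosine_lr(t, E, lr0)`.
#'
#' @param t Epoch index, `0 <= t <= E`.
#' @param E Total number of epochs.
#' @param lr0 Initial global learning rate.
#' @param lr_min Final learning rate (default 0).
#' @return Learning rate at epoch `t`.
#' @export
cosine_lr <- function(t, E, lr0, lr_min = 0) {
  stopifnot(all(t >= 0), all(t <= E), E >= 1, lr0 > 0)
  lr_min + 0.5 * (lr0 - lr_min) * (1 + cos(pi * t / E))
}

#' Training configuration
#'
#' @param epochs Number of full passes through the training pool.
#' @param batch_size Patches per weight update.
#' @param lr0 Initial global learning rate (default 0.001).
#' @param lr_min Cosine-annealed final learning rate (default 0).
#' @param normalization `"zscore"` or `"minmax"` (scan-level statistics).
#' @param patch A [patch_spec()].
#' @param augment Enable geometric + intensity augmentation of training
#'   patches (validation is never augmented).
#' @param policy An [augmentation_policy()].
#' @param seed Integer seed for all RNG streams of the run.
#' @param deterministic Reproducibility mode: re-seeds at the start of
#'   `fit()` so a rerun on the same machine is bitwise identical.
#'   Cross-platform bitwise identity is not promised.
#' @param mixed_precision Pass-through flag; the CPU backend always
#'   computes in double precision, so this is recorded but has no effect.
#' @param loss_smooth Smoothing constant of the soft Jaccard loss
#'   (default 0; see [soft_jaccard_loss()]).
#' @param adam_eps Adam denominator constant (default 1e-8).
#' @param weight_decay Decoupled (AdamW-style) weight decay applied to
#'   convolution weights only; bounds logit growth so the softmax cannot
#'   saturate away rare classes (default 1e-4).
#' @param out_dir Optional directory for the epoch log (CSV) and
#'   checkpoints; `NULL` keeps everything in memory only.
#' @return A `fit_config`.
#' @export
fit_config <- function(epochs, batch_size = 8L, lr0 = 0.001, lr_min = 0,
                       normalization = c("zscore", "minmax"),
                       patch = patch_spec(64L, 4L), augment = TRUE,
                       policy = augmentation_policy(), seed = 42L,
                       deterministic = TRUE, mixed_precision = FALSE,
                       loss_smooth = 0, adam_eps = 1e-8,
                       weight_decay = 1e-4, out_dir = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(epochs >= 1, batch_size >= 1, lr0 > 0,
            inherits(patch, "patch_spec"))
  structure(
    list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
         lr0 = lr0, lr_min = lr_min, normalization = normalization,
         patch = patch, augment = augment, policy = policy,
         seed = as.integer(seed), deterministic = deterministic,
         mixed_precision = mixed_precision, loss_smooth = loss_smooth,
         adam_eps = adam_eps, weight_decay = weight_decay,
         out_dir = out_dir),
    class = "fit_config"
  )
}

# accumulate hard-prediction intersection/union counts; micro epoch
# aggregation: counts are summed over all batches, divided once at the end
.iou_accumulate <- function(acc, probs, labels, n_classes = 3L) {
  pred <- .argmax_labels(probs)
  cc <- .confusion_iu(labels, pred, n_classes)
  acc$I <- acc$I + cc$intersection
  acc$U <- acc$U + cc$union
  acc
}

.miou_from_counts <- function(acc) {
  present <- acc$U > 0
  if (!any(present)) return(NA_real_)
  mean(acc$I[present] / acc$U[present])
}

# assemble one batch: crop, normalize, (augment), one-hot
.make_batch <- function(items, cfg, stats_by_scan, augment) {
  p <- cfg$patch$patch_px
  n <- length(items)
  x <- array(0, c(p, p, 1L, n))
  labels <- array(0L, c(p, p, n))
  intensity <- if (augment) draw_intensity_params(cfg$policy) else NULL
  for (i in seq_len(n)) {
    it <- items[[i]]
    sp <- .crop_patch(it$scan, it$origin, p)
    mp <- .crop_patch(it$mask, it$origin, p)
    if (augment) {
      g <- augment_geometric(sp, mp, cfg$policy)
      sp <- g$scan; mp <- g$mask
    }
    sp <- normalize_patch(sp, stats_by_scan[[it$scan_id]])
    if (augment) {
      sp <- augment_intensity(sp, intensity, cfg$normalization)
    }
    x[, , 1L, i] <- sp
    labels[, , i] <- mp
  }
  list(x = x, labels = labels)
}

# iterate tiles of the given scans in random order, yielding batches of
# cropped patches; calls process(batch_items)
.epoch_batches <- function(pool, ids, cfg, process) {
  tiles <- do.call(rbind, lapply(ids, function(id) {
    data.frame(scan_id = id, z = seq_len(dim(pool[[id]]$volume$voxels)[1]),
               stringsAsFactors = FALSE)
  }))
  tiles <- tiles[sample.int(nrow(tiles)), , drop = FALSE]
  buffer <- list()
  for (r in seq_len(nrow(tiles))) {
    id <- tiles$scan_id[r]; z <- tiles$z[r]
    scan_tile <- pool[[id]]$volume$voxels[z, , ]
    mask_tile <- pool[[id]]$mask$labels[z, , ]
    origins <- sample_patch_origins(dim(scan_tile), cfg$patch)
    for (i in seq_len(nrow(origins))) {
      buffer[[length(buffer) + 1L]] <- list(
        scan_id = id, scan = scan_tile, mask = mask_tile,
        origin = origins[i, ]
      )
      if (length(buffer) == cfg$batch_size) {
        process(buffer)
        buffer <- list()
      }
    }
  }
  if (length(buffer) > 0L) process(buffer)
  invisible(NULL)
}

#' Fit a segmentation model on a pool of scan/mask pairs
#'
#' One epoch processes every training tile once in random order (sampling
#' without replacement), crops random patches, augments (training only),
#' normalizes with scan-level statistics, and updates the weights with
#' Adam on the soft Jaccard loss. Epoch metrics use micro aggregation:
#' per-class intersection and union counts are accumulated across all
#' batches and divided once, which equals the IoU of the concatenation of
#' all batches. The learning rate follows a single-cycle cosine schedule
#' stepped per epoch. The best checkpoint (by validation mIoU) is
#' rewritten on improvement; final-epoch weights are kept under a
#' distinct name.
#'
#' Validation scans are never touched by training batches: the split is at
#' the scan level and audited before the loop starts.
#'
#' @param pool Named list (by scan id) of `list(volume =, mask =)` pairs.
#' @param split A `split_plan` covering exactly the pool's scan ids.
#' @param spec A [model_spec()].
#' @param cfg A [fit_config()].
#' @return A `fit_result`: `checkpoint` (best), `final_checkpoint`,
#'   `history` (one row per epoch), and when `cfg$out_dir` is set,
#'   `log_path`, `ckpt_path`, `final_ckpt_path`.
#' @export
fit <- function(pool, split, spec, cfg) {
  stopifnot(inherits(split, "split_plan"), inherits(cfg, "fit_config"))
  ids <- names(pool)
  if (!setequal(c(split$train_ids, split$val_ids), ids)) {
    stop("split does not cover exactly the scans in the pool")
  }
  if (length(intersect(split$train_ids, split$val_ids)) > 0L) {
    stop("scan-level leak: id(s) present in both train and validation")
  }
  if (length(split$train_ids) == 0L || length(split$val_ids) == 0L) {
    stop("both training and validation sets must be non-empty")
  }
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  }
  set.seed(cfg$seed)
  stats_by_scan <- lapply(pool, function(p) {
    compute_norm_stats(p$volume, cfg$normalization)
  })
  model <- build_model(spec)
  params <- model$params
  adam <- .adam_init(params)
  hyper <- list(epochs = cfg$epochs, batch_size = cfg$batch_size,
                lr0 = cfg$lr0, seed = cfg$seed)
  history <- vector("list", cfg$epochs)
  best_val <- -Inf
  best_ckpt <- NULL
  for (epoch in seq_len(cfg$epochs)) {
    lr <- cosine_lr(epoch - 1L, cfg$epochs, cfg$lr0, cfg$lr_min)
    tr <- list(I = numeric(spec$n_classes), U = numeric(spec$n_classes))
    tr_loss <- 0; tr_n <- 0
    .epoch_batches(pool, split$train_ids, cfg, function(items) {
      b <- .make_batch(items, cfg, stats_by_scan, augment = cfg$augment)
      fwd <- model$forward_cached(params, b$x, training = TRUE)
      probs <- .softmax_channels(fwd$logits)
      target <- .one_hot(b$labels, spec$n_classes)
      lg <- .jaccard_loss_grad(probs, target, cfg$loss_smooth)
      if (!is.finite(lg$loss)) {
        stop("non-finite training loss at epoch ", epoch,
             "; check input scaling and learning rate")
      }
      dlogits <- .softmax_backward(probs, lg$grad)
      grads <- model$backward(params, fwd$cache, dlogits)
      upd <- .adam_step(params, grads, adam, lr, eps = cfg$adam_eps,
                        weight_decay = cfg$weight_decay)
      params <- upd$params
      # roll the batch-norm running statistics forward
      for (nm in names(params)) {
        if (!is.null(params[[nm]]$rm) &&
            exists(nm, envir = fwd$cache, inherits = FALSE)) {
          layer_cache <- get(nm, envir = fwd$cache)
          params[[nm]]$rm <- layer_cache$rm
          params[[nm]]$rv <- layer_cache$rv
        }
      }
      params <<- params
      adam <<- upd$state
      tr <<- .iou_accumulate(tr, probs, b$labels, spec$n_classes)
      tr_loss <<- tr_loss + lg$loss * length(items)
      tr_n <<- tr_n + length(items)
    })
    va <- list(I = numeric(spec$n_classes), U = numeric(spec$n_classes))
    va_loss <- 0; va_n <- 0
    .epoch_batches(pool, split$val_ids, cfg, function(items) {
      b <- .make_batch(items, cfg, stats_by_scan, augment = FALSE)
      logits <- model$forward(params, b$x)
      probs <- .softmax_channels(logits)
      target <- .one_hot(b$labels, spec$n_classes)
      va_loss <<- va_loss +
        soft_jaccard_loss(probs, target, cfg$loss_smooth) * length(items)
      va_n <<- va_n + length(items)
      va <<- .iou_accumulate(va, probs, b$labels, spec$n_classes)
    })
    val_miou <- .miou_from_counts(va)
    improved <- is.finite(val_miou) && val_miou > best_val
    history[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      train_loss = tr_loss / tr_n, train_miou = .miou_from_counts(tr),
      val_loss = va_loss / va_n, val_miou = val_miou,
      improved = improved
    )
    if (improved) {
      best_val <- val_miou
      m <- model; m$params <- params
      best_ckpt <- .make_checkpoint(m, cfg$normalization,
                                    cfg$patch$patch_px, hyper,
                                    val_miou = val_miou, epoch = epoch)
      if (!is.null(cfg$out_dir)) {
        save_checkpoint(best_ckpt, file.path(cfg$out_dir, "best.ckpt"))
      }
    }
  }
  history <- do.call(rbind, history)
  m <- model; m$params <- params
  final_ckpt <- .make_checkpoint(m, cfg$normalization, cfg$patch$patch_px,
                                 hyper,
                                 val_miou = history$val_miou[cfg$epochs],
                                 epoch = cfg$epochs)
  out <- list(checkpoint = best_ckpt, final_checkpoint = final_ckpt,
              history = history, split = split)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    save_checkpoint(final_ckpt, file.path(cfg$out_dir, "final.ckpt"))
    if (!is.null(best_ckpt)) {
      save_checkpoint(best_ckpt, file.path(cfg$out_dir, "best.ckpt"))
    }
    log_path <- file.path(cfg$out_dir, "fit_log.csv")
    .write_fit_log(log_path, history, split, cfg, spec)
    out$log_path <- log_path
    out$ckpt_path <- file.path(cfg$out_dir, "best.ckpt")
    out$final_ckpt_path <- file.path(cfg$out_dir, "final.ckpt")
  }
  class(out) <- "fit_result"
  out
}

# epoch log: CSV with a comment header carrying the version string and the
# resolved configuration (auditability). No timestamps, so reruns under
# deterministic mode are bitwise identical.
.write_fit_log <- function(path, history, split, cfg, spec) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  header <- c(
    paste0("# osteoseg ", .osteoseg_version()),
    paste0("# architecture=", spec$architecture, " backbone=",
           spec$backbone, " classes=", spec$n_classes),
    paste0("# normalization=", cfg$normalization, " patch_px=",
           cfg$patch$patch_px, " patches_per_tile=",
           cfg$patch$patches_per_tile, " augment=", cfg$augment),
    paste0("# epochs=", cfg$epochs, " batch_size=", cfg$batch_size,
           " lr0=", cfg$lr0, " seed=", cfg$seed, " deterministic=",
           cfg$deterministic),
    paste0("# train=", paste(split$train_ids, collapse = ",")),
    paste0("# val=", paste(split$val_ids, collapse = ","))
  )
  writeLines(header, con)
  utils::write.table(format(history, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result> ", nrow(x$history), " epochs; best val mIoU ",
      sprintf("%.4f", max(x$history$val_miou)), "\n", sep = "")
  invisible(x)
}
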