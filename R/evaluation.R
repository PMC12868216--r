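# Class-wise / mean IoU evaluation, Dice conversion, and k-fold
# cross-validation orchestration.

# fast per-class intersection/union from two integer arrays
.confusion_iu <- function(ref, pred, n_classes = 3L) {
  if (!identical(dim(ref), dim(pred)) &&
      !(length(ref) == length(pred))) {
    stop("reference and prediction shapes differ")
  }
  joint <- tabulate(as.integer(ref) * n_classes + as.integer(pred) + 1L,
                    nbins = n_classes * n_classes)
  cm <- matrix(joint, n_classes, n_classes, byrow = TRUE)  # ref x pred
  I <- diag(cm)
  U <- rowSums(cm) + colSums(cm) - I
  list(intersection = I, union = U)
}

#' Per-class intersection and union counts
#'
#' For each class `c`: `intersection = |ref == c & pred == c|`,
#' `union = |ref == c | pred == c|` -- the building blocks of the Jaccard
#' index.
#'
#' @param ref,pred [label_mask()] objects or integer arrays of equal
#'   shape.
#' @param n_classes Number of classes (default 3).
#' @return Data frame with columns `class`, `intersection`, `union`.
#' @export
confusion_counts <- function(ref, pred, n_classes = 3L) {
  r <- if (inherits(ref, "label_mask")) ref$labels else ref
  p <- if (inherits(pred, "label_mask")) pred$labels else pred
  if (!identical(dim(r), dim(p))) {
    stop("reference and prediction shapes differ: ",
         paste(dim(r), collapse = "x"), " vs ",
         paste(dim(p), collapse = "x"))
  }
  iu <- .confusion_iu(r, p, n_classes)
  data.frame(class = 0:(n_classes - 1L), intersection = iu$intersection,
             union = iu$union)
}

#' Convert an IoU score to a Dice coefficient
#'
#' Uses the exact identity `dice = 2 * iou / (1 + iou)`. By default the
#' result is rounded half-up to 4 decimals, the reporting convention used
#' throughout; pass `digits = NULL` for the unrounded value.
#'
#' @param iou IoU value(s) in `[0, 1]`.
#' @param digits Reporting precision (default 4); `NULL` to disable.
#' @return Dice value(s).
#' @export
iou_to_dice <- function(iou, digits = 4) {
  if (any(iou < 0 | iou > 1, na.rm = TRUE)) {
    stop("IoU values must lie in [0, 1]")
  }
  dice <- 2 * iou / (1 + iou)
  if (is.null(digits)) dice else .round_half_up(dice, digits)
}

.round_half_up <- function(x, digits) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Class-wise and mean IoU report
#'
#' Per-class IoU is `intersection / union`; classes absent from both
#' masks (union 0, an undefined 0/0) are excluded from the mean. The mean
#' is unweighted over `class_set`: `"all_classes"` (background, bone,
#' pores; the default) or `"foreground_only"` (bone, pores). The class
#' set only changes the mean, never the per-class values. Dice values are
#' converted per class and averaged over the same set.
#'
#' @param ref,pred [label_mask()] objects or integer arrays, equal shape.
#' @param class_set `"all_classes"` or `"foreground_only"`.
#' @param n_classes Number of classes (default 3).
#' @return An `iou_report` with `per_class_iou`, `miou`,
#'   `per_class_dice`, `mdice`, `class_set_used`.
#' @export
iou_report <- function(ref, pred,
                       class_set = c("all_classes", "foreground_only"),
                       n_classes = 3L) {
  class_set <- match.arg(class_set)
  cc <- confusion_counts(ref, pred, n_classes)
  iou <- ifelse(cc$union > 0, cc$intersection / cc$union, NA_real_)
  names(iou) <- as.character(cc$class)
  dice <- 2 * iou / (1 + iou)
  names(dice) <- names(iou)
  used <- if (class_set == "foreground_only") {
    seq_len(n_classes - 1L) + 1L  # rows for classes 1..C-1
  } else {
    seq_len(n_classes)
  }
  structure(
    list(per_class_iou = iou, miou = mean(iou[used], na.rm = TRUE),
         per_class_dice = dice, mdice = mean(dice[used], na.rm = TRUE),
         class_set_used = class_set),
    class = "iou_report"
  )
}

#' @export
print.iou_report <- function(x, ...) {
  cat("<iou_report> class set:", x$class_set_used, "\n")
  cls <- names(x$per_class_iou)
  for (i in seq_along(cls)) {
    cat(sprintf("  class %s: IoU %.4f  Dice %.4f\n", cls[i],
                x$per_class_iou[i], x$per_class_dice[i]))
  }
  cat(sprintf("  mIoU %.4f  mDice %.4f\n", x$miou, x$mdice))
  invisible(x)
}

#' Summarize a scan-level mIoU table into fold and grand statistics
#'
#' Input: one row per (fold, seed, scan) with the scan-level mIoU. Fold
#' statistics are mean and SD over the fold's test scans (per seed); the
#' grand statistic is the mean and SD over all fold-by-seed means. Dice
#' columns convert the scan-level values first and then average
#' (mean-of-conversions).
#'
#' @param scan_table Data frame with columns `fold`, `seed`, `scan_id`,
#'   `miou`.
#' @return A `crossval_summary` with `scan_table`, `fold_summary`,
#'   `grand_mean`, `grand_sd`, `grand_mean_dice`, `grand_sd_dice`.
#' @export
summarize_crossval <- function(scan_table) {
  stopifnot(all(c("fold", "seed", "scan_id", "miou") %in%
                  names(scan_table)))
  scan_table$mdice <- iou_to_dice(scan_table$miou, digits = NULL)
  agg <- stats::aggregate(cbind(miou, mdice) ~ fold + seed,
                          data = scan_table, FUN = mean)
  sds <- stats::aggregate(cbind(miou, mdice) ~ fold + seed,
                          data = scan_table,
                          FUN = function(v) {
                            if (length(v) > 1) stats::sd(v) else NA_real_
                          })
  fold_summary <- data.frame(
    fold = agg$fold, seed = agg$seed,
    mean_miou = agg$miou, sd_miou = sds$miou,
    mean_mdice = agg$mdice, sd_mdice = sds$mdice
  )
  fold_summary <- fold_summary[order(fold_summary$fold,
                                     fold_summary$seed), ]
  rownames(fold_summary) <- NULL
  structure(
    list(scan_table = scan_table, fold_summary = fold_summary,
         grand_mean = mean(fold_summary$mean_miou),
         grand_sd = stats::sd(fold_summary$mean_miou),
         grand_mean_dice = mean(fold_summary$mean_mdice),
         grand_sd_dice = stats::sd(fold_summary$mean_mdice)),
    class = "crossval_summary"
  )
}

#' @export
print.crossval_summary <- function(x, ...) {
  cat("<crossval_summary>\n")
  print(x$fold_summary, digits = 4)
  cat(sprintf("grand mIoU %.4f +/- %.4f  [mDice %.4f +/- %.4f]\n",
              x$grand_mean, x$grand_sd, x$grand_mean_dice,
              x$grand_sd_dice))
  invisible(x)
}

#' k-fold cross-validation of the full fit/predict pipeline
#'
#' For every (fold, seed) pair: the fold's training/validation pool is
#' split internally at the scan level, a model is fitted, each test scan
#' of the fold is predicted, and its scan-level mIoU recorded. Summaries
#' follow [summarize_crossval()].
#'
#' @param scans Named list (by scan id) of `list(volume =, mask =)`.
#' @param fold_plan A `fold_plan` over the scan ids.
#' @param seeds Integer vector of fitting seeds (>= 1 seed).
#' @param spec A [model_spec()].
#' @param cfg A [fit_config()]; its `seed` is overridden per run.
#' @param train_fraction Internal pool split fraction (default 0.8125).
#' @param threshold Prediction confidence threshold.
#' @param class_set Class set for scan-level mIoU.
#' @return A `crossval_summary`.
#' @export
cross_validate <- function(scans, fold_plan, seeds, spec, cfg,
                           train_fraction = 0.8125, threshold = 0.5,
                           class_set = "all_classes") {
  stopifnot(inherits(fold_plan, "fold_plan"), length(seeds) >= 1)
  if (!setequal(fold_plan$ordered_ids, names(scans))) {
    stop("fold plan ids do not match the supplied scans")
  }
  rows <- list()
  for (fi in seq_len(fold_plan$k)) {
    for (seed in seeds) {
      res <- tryCatch({
        pool_ids <- fold_plan$pools[[fi]]
        split <- split_scans(pool_ids, train_fraction, seed)
        run_cfg <- cfg
        run_cfg$seed <- as.integer(seed)
        fitres <- fit(scans[pool_ids], split, spec, run_cfg)
        ckpt <- fitres$checkpoint
        if (is.null(ckpt)) ckpt <- fitres$final_checkpoint
        lapply(fold_plan$folds[[fi]], function(id) {
          pred <- predict_volume(ckpt, scans[[id]]$volume,
                                 threshold = threshold)
          rep <- iou_report(scans[[id]]$mask, pred$mask,
                            class_set = class_set)
          data.frame(fold = fi, seed = seed, scan_id = id,
                     miou = rep$miou, stringsAsFactors = FALSE)
        })
      }, error = function(e) {
        stop("cross-validation failed at fold ", fi, ", seed ", seed,
             ": ", conditionMessage(e))
      })
      rows <- c(rows, res)
    }
  }
  summarize_crossval(do.call(rbind, rows))
}
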