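# Normalized performance-efficiency weighted scoring of fitted models.
#
# Seven raw metrics per model: mIoU (predictivity), B batch size, U mean
# GPU utilization %, F forward FLOPs, P parameter count, V peak VRAM, T
# fitting-loop time. Higher is better for mIoU/B/U; lower is better for
# F/P/V/T. Hardware metrics are user-supplied or probe-filled; the
# toolkit never fabricates them.

.metric_names <- c("miou", "B", "U", "F", "P", "V", "T")
.higher_better <- c("miou", "B", "U")

#' Create one performance-efficiency record
#'
#' @param label Model label (e.g. "unet/resnet18/256px").
#' @param miou Mean IoU in `[0, 1]`.
#' @param B Batch size used for fitting.
#' @param U Mean GPU utilization in percent, `[0, 100]`.
#' @param F Floating-point operations of one forward pass on one batch.
#' @param P Parameter count.
#' @param V Peak VRAM (any consistent unit).
#' @param T Time spent in the fitting loop (any consistent unit).
#' @return A one-row data frame.
#' @export
efficiency_record <- function(label, miou, B, U, F, P, V, T) {
  stopifnot(miou >= 0, miou <= 1, U >= 0, U <= 100,
            B > 0, F > 0, P > 0, V > 0, T > 0)
  data.frame(label = label, miou = miou, B = B, U = U, F = F, P = P,
             V = V, T = T, stringsAsFactors = FALSE)
}

#' Min-max normalize efficiency records
#'
#' Higher-is-better metrics (mIoU, B, U) are scaled as
#' `(x - min) / (max - min)`; lower-is-better metrics (F, P, V, T) are
#' scaled the same way and then inverted (`1 - .`), so 1 is always the
#' preferred end. A degenerate column (max equals min) carries no
#' discriminating information and is set to 1 for every record so it
#' penalizes no one. Normalization is over exactly the records supplied.
#'
#' @param records Data frame of [efficiency_record()] rows (>= 2 rows).
#' @return Data frame with `label` and `<metric>_norm` columns.
#' @export
normalize_metrics <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 2,
            all(c("label", .metric_names) %in% names(records)))
  out <- data.frame(label = records$label, stringsAsFactors = FALSE)
  for (m in .metric_names) {
    x <- records[[m]]
    rng <- range(x)
    norm <- if (rng[2] > rng[1]) {
      scaled <- (x - rng[1]) / (rng[2] - rng[1])
      if (m %in% .higher_better) scaled else 1 - scaled
    } else {
      rep(1, length(x))
    }
    out[[paste0(m, "_norm")]] <- norm
  }
  out
}

#' Weighted performance-efficiency score
#'
#' Dot product of the normalized metric vector with the weight vector
#' `(w_miou, w_B, w_U, w_F, w_P, w_V, w_T)`. The default places weight
#' 0.85 on mIoU and 0.025 on each of the six efficiency metrics.
#'
#' @param norm_row One row of [normalize_metrics()] output (or any list
#'   with the `<metric>_norm` fields).
#' @param weights Nonnegative weight vector of length 7 in the metric
#'   order mIoU, B, U, F, P, V, T.
#' @return Scalar score.
#' @export
weighted_score <- function(norm_row, weights = c(0.85, rep(0.025, 6))) {
  if (length(weights) != 7L) stop("`weights` must have length 7")
  if (any(weights < 0)) stop("weights must be nonnegative")
  vals <- vapply(paste0(.metric_names, "_norm"),
                 function(f) as.numeric(norm_row[[f]]), numeric(1))
  sum(vals * weights)
}

#' Rank models by weighted score
#'
#' Scores every record under the given mIoU weight, with the remaining
#' weight split equally over the six efficiency metrics
#' (`(1 - w) / 6` each). Ties are broken by higher raw mIoU, then by
#' label, so reports are deterministic.
#'
#' @param records Data frame of [efficiency_record()] rows.
#' @param miou_weight Weight on mIoU in `[0, 1]` (default 0.85).
#' @return A `weighted_score_table`: records + normalized columns +
#'   `score` + `rank`, sorted by rank, with attributes `weights` and
#'   `miou_weight`.
#' @export
rank_models <- function(records, miou_weight = 0.85) {
  stopifnot(miou_weight >= 0, miou_weight <= 1)
  weights <- c(miou_weight, rep((1 - miou_weight) / 6, 6))
  norm <- normalize_metrics(records)
  score <- vapply(seq_len(nrow(norm)),
                  function(i) weighted_score(norm[i, ], weights),
                  numeric(1))
  out <- cbind(records, norm[, -1, drop = FALSE], score = score)
  ord <- order(-out$score, -out$miou, out$label)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "weights") <- weights
  attr(out, "miou_weight") <- miou_weight
  class(out) <- c("weighted_score_table", "data.frame")
  out
}

#' Sensitivity sweep over the mIoU weight
#'
#' Re-ranks the records for each requested mIoU weight `w`, using
#' per-efficiency-metric weight `(1 - w) / 6`, and extracts the top
#' models.
#'
#' @param records Data frame of [efficiency_record()] rows.
#' @param miou_weights Vector of mIoU weights in `[0, 1]`.
#' @param top_k How many top models to tabulate per weight (default 3).
#' @return List with `tables` (one `weighted_score_table` per weight) and
#'   `top` (data frame of the top-k labels and scores per weight).
#' @export
sensitivity_sweep <- function(records,
                              miou_weights = c(1, 0.95, 0.9, 0.85, 0.8,
                                               0.75, 0.7),
                              top_k = 3L) {
  tables <- lapply(miou_weights, function(w) rank_models(records, w))
  names(tables) <- format(miou_weights)
  top <- do.call(rbind, lapply(seq_along(miou_weights), function(i) {
    t <- tables[[i]]
    k <- min(top_k, nrow(t))
    data.frame(miou_weight = miou_weights[i],
               efficiency_weight = (1 - miou_weights[i]) / 6,
               rank = seq_len(k), label = t$label[seq_len(k)],
               score = t$score[seq_len(k)], stringsAsFactors = FALSE)
  }))
  list(tables = tables, top = top)
}
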