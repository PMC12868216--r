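.architectures <- c("tiny_unet", "unet", "unetpp", "deeplabv3plus",
                    "segformer")
.backbones <- c("none", "resnet18", "resnet50", "efficientnet_b3", "mit_b1")

# admissible architecture/backbone pairings
.valid_pairs <- function() {
  rbind(
    data.frame(architecture = "tiny_unet", backbone = "none"),
    expand.grid(architecture = c("unet", "unetpp", "deeplabv3plus"),
                backbone = c("resnet18", "resnet50", "efficientnet_b3"),
                stringsAsFactors = FALSE),
    data.frame(architecture = "segformer", backbone = "mit_b1")
  )
}

#' Specify a segmentation model
#'
#' Describes an architecture/backbone pairing, its input/output contract
#' and how its weights are initialized. Only `tiny_unet` (a compact
#' dependency-free U-Net) has a runnable backend in this package; the
#' large published architectures are validated here so configurations and
#' checkpoints round-trip, but building them requires an external deep
#' learning backend that is not bundled.
#'
#' @param architecture One of `"tiny_unet"`, `"unet"`, `"unetpp"`,
#'   `"deeplabv3plus"`, `"segformer"`.
#' @param backbone Encoder backbone; `"none"` for `tiny_unet`, else one of
#'   `"resnet18"`, `"resnet50"`, `"efficientnet_b3"`, `"mit_b1"`.
#' @param n_classes Number of output classes (default 3).
#' @param in_channels Number of input channels (default 1, grayscale).
#' @param init `"random"`, `"imagenet"`, or a path to a checkpoint file
#'   whose metadata must match this spec.
#' @param base_channels Width of the first `tiny_unet` level (default 16).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture = "tiny_unet", backbone = "none",
                       n_classes = 3L, in_channels = 1L, init = "random",
                       base_channels = 16L) {
  architecture <- match.arg(architecture, .architectures)
  backbone <- match.arg(backbone, .backbones)
  pairs <- .valid_pairs()
  ok <- any(pairs$architecture == architecture & pairs$backbone == backbone)
  if (!ok) {
    valid <- paste(pairs$architecture[pairs$architecture == architecture],
                   pairs$backbone[pairs$architecture == architecture],
                   sep = "/", collapse = ", ")
    stop("invalid architecture/backbone pair ", architecture, "/", backbone,
         "; valid pairs for this architecture: ",
         if (nzchar(valid)) valid else "(none)")
  }
  structure(
    list(architecture = architecture, backbone = backbone,
         n_classes = as.integer(n_classes),
         in_channels = as.integer(in_channels), init = init,
         base_channels = as.integer(base_channels)),
    class = "model_spec"
  )
}

#' Build a model handle from a specification
#'
#' The returned handle maps a `(H, W, in_channels, N)` batch to per-class
#' logits `(H, W, n_classes, N)`, preserving the spatial dimensions. For
#' `tiny_unet`, weights are drawn from the current R RNG stream when
#' `init = "random"`, or loaded from a checkpoint file when `init` is a
#' path.
#'
#' @param spec A [model_spec()].
#' @return An object of class `osteoseg_model` with elements `spec`,
#'   `params` and a `forward(params, x)` function.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  if (spec$architecture != "tiny_unet") {
    stop("architecture '", spec$architecture, "' requires an external ",
         "pretrained segmentation backend which is not installed; ",
         "'tiny_unet' is the self-contained CPU architecture")
  }
  if (identical(spec$init, "imagenet")) {
    stop("imagenet initialization requires a network download and is not ",
         "available; use init = 'random' or a checkpoint file path")
  }
  params <- if (!identical(spec$init, "random")) {
    ckpt <- load_checkpoint(spec$init)
    md <- ckpt$metadata
    if (!identical(md$architecture, spec$architecture) ||
        !identical(md$backbone, spec$backbone) ||
        !identical(md$n_classes, spec$n_classes)) {
      stop("checkpoint metadata (", md$architecture, "/", md$backbone,
           ", ", md$n_classes, " classes) does not match the requested ",
           "model spec")
    }
    ckpt$model$params
  } else {
    .unet_init(spec$base_channels, spec$in_channels, spec$n_classes)
  }
  structure(
    list(
      spec = spec,
      params = params,
      forward = function(params, x) .unet_forward(params, x)$logits,
      forward_cached = function(params, x, training = FALSE) {
        .unet_forward(params, x, want_cache = TRUE, training = training)
      },
      backward = .unet_backward
    ),
    class = "osteoseg_model"
  )
}

#' Create a stub model for pipeline testing
#'
#' Wraps an arbitrary per-batch function into a model handle, so the
#' chunking, merging and thresholding stages of prediction can be verified
#' against closed-form expectations independently of any trained network.
#'
#' @param fn Function taking a `(H, W, C_in, N)` array and returning a
#'   `(H, W, n_classes, N)` logits array.
#' @param n_classes Number of classes emitted by `fn`.
#' @return An `osteoseg_model` handle with architecture `"stub"`.
#' @export
stub_model <- function(fn, n_classes = 3L) {
  structure(
    list(
      spec = structure(list(architecture = "stub", backbone = "none",
                            n_classes = as.integer(n_classes),
                            in_channels = 1L, init = "none",
                            base_channels = 0L),
                       class = "model_spec"),
      params = list(),
      forward = function(params, x) fn(x)
    ),
    class = "osteoseg_model"
  )
}

#' Profile model complexity
#'
#' Counts learnable parameters and the floating-point operations of one
#' forward pass on `sample_batch` (multiply and add counted separately;
#' convolution and bias terms only, which dominate). These are the F and P
#' inputs of the performance-efficiency ranking.
#'
#' @param model An `osteoseg_model` handle.
#' @param sample_batch A `(H, W, C, N)` array matching the input contract.
#' @return A `complexity_profile` with `flops_forward` and `param_count`.
#' @export
profile_model <- function(model, sample_batch) {
  stopifnot(inherits(model, "osteoseg_model"))
  d <- dim(sample_batch)
  if (length(d) != 4L || d[3] != model$spec$in_channels) {
    stop("sample batch must be (H, W, ", model$spec$in_channels, ", N)")
  }
  param_count <- sum(vapply(model$params, function(l) {
    sum(vapply(intersect(c("w", "b", "gamma", "beta"), names(l)),
               function(f) length(l[[f]]), numeric(1)))
  }, numeric(1)))
  tab <- .unet_layer_table(model$spec$base_channels,
                           model$spec$in_channels, model$spec$n_classes)
  hw <- (d[1] / tab$downsample) * (d[2] / tab$downsample)
  flops <- sum((2 * tab$k^2 * tab$cin + 1) * tab$cout * hw) * d[4]
  structure(list(flops_forward = flops, param_count = param_count),
            class = "complexity_profile")
}

# ---- checkpoints ----

.osteoseg_version <- function() {
  paste0(as.character(utils::packageVersion("osteoseg")), ".standalone")
}

.make_checkpoint <- function(model, normalization, patch_px,
                             hyperparameters = list(), val_miou = NA_real_,
                             epoch = NA_integer_) {
  structure(
    list(
      model = model,
      metadata = list(
        architecture = model$spec$architecture,
        backbone = model$spec$backbone,
        n_classes = model$spec$n_classes,
        fit_mode = "2D",
        normalization = normalization,
        patch_px = as.integer(patch_px),
        hyperparameters = hyperparameters,
        val_miou = val_miou,
        epoch = epoch,
        version = .osteoseg_version()
      )
    ),
    class = "osteoseg_checkpoint"
  )
}

#' Save / load model checkpoints
#'
#' A checkpoint bundles the model handle (weights included) with a
#' metadata block: architecture, backbone, fit mode, normalization mode,
#' patch size, hyperparameters and the toolkit version string. Prediction
#' refuses checkpoints whose metadata is incomplete.
#'
#' @param ckpt An `osteoseg_checkpoint`.
#' @param path File path (conventionally `.ckpt`).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns the checkpoint.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "osteoseg_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint file not found: ", path)
  ckpt <- readRDS(path)
  if (!inherits(ckpt, "osteoseg_checkpoint")) {
    stop("file is not an osteoseg checkpoint: ", path)
  }
  ckpt
}

#' @export
print.osteoseg_checkpoint <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<osteoseg_checkpoint> %s/%s (%s), norm=%s, patch=%dpx, version=%s\n",
    md$architecture, md$backbone, md$fit_mode, md$normalization,
    md$patch_px, md$version))
  if (!is.na(md$val_miou)) {
    cat(sprintf("  best val mIoU %.4f at epoch %d\n", md$val_miou,
                md$epoch))
  }
  invisible(x)
}
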