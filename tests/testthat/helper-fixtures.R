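# Shared fixtures, all generated in code (no binary files in the repo).

# small deterministic u16 volume
make_volume <- function(shape = c(3, 4, 5), seed = 1, scan_id = "vol") {
  withr_seed <- function(expr) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    expr
  }
  vox <- withr_seed(array(sample(0:65535, prod(shape), TRUE), shape))
  scan_volume(vox, scan_id = scan_id)
}

# mask with a centered square of bone containing a pore dot, per slice
make_mask <- function(shape = c(3, 8, 8), scan_id = "vol") {
  lab <- array(0L, shape)
  ys <- 3:(shape[2] - 2)
  xs <- 3:(shape[3] - 2)
  lab[, ys, xs] <- 1L
  lab[, shape[2] %/% 2, shape[3] %/% 2] <- 2L
  label_mask(lab, scan_id = scan_id)
}

# tiny in-memory phantom pool for fit/predict tests
make_phantom_pool <- function(seeds, shape = c(8L, 32L, 32L),
                              cortex_radius = c(7, 9),
                              cortex_thickness = c(2, 3)) {
  pool <- list()
  for (s in seeds) {
    cfg <- phantom_config(shape = shape, cortex_radius_px = cortex_radius,
                          cortex_thickness_px = cortex_thickness,
                          packing_gap_px = 2L, seed = s)
    pair <- generate_phantom(cfg, scan_id = sprintf("ph%03d", s))
    pool[[pair$volume$scan_id]] <- list(volume = pair$volume,
                                        mask = pair$mask)
  }
  pool
}

# deterministic stub model: per-pixel logits as a fixed function of the
# input intensity (translation invariant)
intensity_stub <- function() {
  stub_model(function(x) {
    d <- dim(x)
    logits <- array(0, c(d[1], d[2], 3L, d[4]))
    v <- x[, , 1, , drop = FALSE]
    logits[, , 1, ] <- 1 - v
    logits[, , 2, ] <- 2 * v
    logits[, , 3, ] <- 0.5 * v
    logits
  })
}

# stub emitting constant logits everywhere
constant_stub <- function(logits3) {
  stub_model(function(x) {
    d <- dim(x)
    out <- array(0, c(d[1], d[2], 3L, d[4]))
    for (c in 1:3) out[, , c, ] <- logits3[c]
    out
  })
}

softmax3 <- function(z) exp(z) / sum(exp(z))
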