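# Synthetic long-bone micro-CT phantom generator. Emulates, at reduced
# scale, the difficulty modes catalogued for the real dataset: closely
# packed bones, composite intensity domains, dim low-contrast scans,
# 8-bit depth, drill holes, and growth-plate bands.

#' Phantom generator configuration
#'
#' Geometry is specified in pixels so the phantoms stay small and
#' CPU-fast; a long bone is an elliptical cortical annulus extruded along
#' Z with a marrow cavity containing spherical/ellipsoidal pores.
#' Intensity levels are fractions of the full dynamic range and must be
#' ordered bone > marrow > background before noise; pores image at
#' background level (voids).
#'
#' @param shape Integer `(Z, Y, X)` volume shape.
#' @param n_bones Number of bones per phantom.
#' @param cortex_radius_px Range of the outer cortical radius.
#' @param cortex_thickness_px Range of the cortical thickness.
#' @param pore_density Target pore voxel fraction within marrow, `[0, 1]`.
#' @param pore_radius_px Range of pore radii.
#' @param packing_gap_px Minimum background gap between bones (small
#'   values emulate tightly packed bones).
#' @param growth_plate Add a transverse low-density band (labelled as
#'   pores) across the marrow cavity.
#' @param growth_plate_px Band thickness in slices.
#' @param intensity Named levels `background`, `marrow`, `bone` in
#'   `[0, 1]`.
#' @param noise_sigma Additive Gaussian noise SD (fraction of range).
#' @param n_intensity_domains Number of Z-domains with distinct global
#'   offsets (composite-scan emulation).
#' @param dimming_factor Multiplies all intensities, `(0, 1]`; small
#'   values emulate dim low-contrast scans.
#' @param bit_depth `"u16"` or `"u8"`.
#' @param drill_hole Carve a transverse cylindrical drill hole through
#'   the first bone.
#' @param radial_ramp Add a radial brightness ramp (beam-hardening-like).
#' @param seed Integer seed; phantoms are bit-identical for a fixed
#'   configuration.
#' @return A `phantom_config`.
#' @export
phantom_config <- function(shape = c(16L, 64L, 64L), n_bones = 1L,
                           cortex_radius_px = c(14, 20),
                           cortex_thickness_px = c(3, 6),
                           pore_density = 0.08,
                           pore_radius_px = c(1, 3),
                           packing_gap_px = 4L,
                           growth_plate = FALSE, growth_plate_px = 2L,
                           intensity = c(background = 0.08,
                                         marrow = 0.40, bone = 0.80),
                           noise_sigma = 0.02,
                           n_intensity_domains = 1L,
                           dimming_factor = 1,
                           bit_depth = c("u16", "u8"),
                           drill_hole = FALSE, radial_ramp = FALSE,
                           seed = 1L) {
  bit_depth <- match.arg(bit_depth)
  if (!(intensity[["bone"]] > intensity[["marrow"]] &&
        intensity[["marrow"]] > intensity[["background"]])) {
    stop("intensity levels must be ordered bone > marrow > background")
  }
  stopifnot(length(shape) == 3L, all(shape >= 1),
            pore_density >= 0, pore_density <= 1,
            dimming_factor > 0, dimming_factor <= 1,
            n_intensity_domains >= 1)
  if (2 * (max(cortex_radius_px) + packing_gap_px) > min(shape[2:3])) {
    stop("cortex radius plus packing gap does not fit the field of view")
  }
  structure(
    list(shape = as.integer(shape), n_bones = as.integer(n_bones),
         cortex_radius_px = cortex_radius_px,
         cortex_thickness_px = cortex_thickness_px,
         pore_density = pore_density, pore_radius_px = pore_radius_px,
         packing_gap_px = as.integer(packing_gap_px),
         growth_plate = growth_plate,
         growth_plate_px = as.integer(growth_plate_px),
         intensity = intensity, noise_sigma = noise_sigma,
         n_intensity_domains = as.integer(n_intensity_domains),
         dimming_factor = dimming_factor, bit_depth = bit_depth,
         drill_hole = drill_hole, radial_ramp = radial_ramp,
         seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# place n ellipse centers with no overlap of (radius + gap) disks
.place_bones <- function(cfg) {
  ny <- cfg$shape[2]; nx <- cfg$shape[3]
  bones <- list()
  for (b in seq_len(cfg$n_bones)) {
    placed <- FALSE
    for (try in seq_len(500L)) {
      ry <- stats::runif(1, cfg$cortex_radius_px[1],
                         cfg$cortex_radius_px[2])
      rx <- stats::runif(1, cfg$cortex_radius_px[1],
                         cfg$cortex_radius_px[2])
      th <- stats::runif(1, cfg$cortex_thickness_px[1],
                         cfg$cortex_thickness_px[2])
      r <- max(ry, rx)
      lo_y <- r + 1; hi_y <- ny - r
      lo_x <- r + 1; hi_x <- nx - r
      if (hi_y <= lo_y || hi_x <= lo_x) next
      cy <- stats::runif(1, lo_y, hi_y)
      cx <- stats::runif(1, lo_x, hi_x)
      ok <- TRUE
      for (other in bones) {
        dist <- sqrt((cy - other$cy)^2 + (cx - other$cx)^2)
        if (dist < r + max(other$ry, other$rx) + cfg$packing_gap_px) {
          ok <- FALSE
          break
        }
      }
      if (ok) {
        bones[[b]] <- list(cy = cy, cx = cx, ry = ry, rx = rx, th = th)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", cfg$n_bones, " bones without overlap; ",
           "reduce n_bones, radii, or packing gap")
    }
  }
  bones
}

#' Generate one synthetic scan/mask pair
#'
#' Procedural construction: per bone, an elliptical cortical annulus
#' (class 1) along Z with a marrow cavity (class 0 at marrow intensity)
#' containing randomly placed spherical pores (class 2); optional
#' transverse growth-plate band, drill hole, composite intensity domains,
#' radial brightness ramp, global dimming, Gaussian noise, and
#' quantization to the configured bit depth. The mask is exact by
#' construction.
#'
#' @param cfg A [phantom_config()].
#' @param scan_id Scan identity of the generated pair.
#' @return List with `volume` (a [scan_volume()]) and `mask`
#'   (a [label_mask()]).
#' @export
generate_phantom <- function(cfg, scan_id = "phantom") {
  stopifnot(inherits(cfg, "phantom_config"))
  .with_seed(cfg$seed, {
    nz <- cfg$shape[1]; ny <- cfg$shape[2]; nx <- cfg$shape[3]
    # material codes: 0 background, 1 bone, 2 pore, 3 marrow
    bones <- .place_bones(cfg)
    yy <- matrix(seq_len(ny), ny, nx)
    xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
    section <- matrix(0L, ny, nx)
    for (b in bones) {
      outer <- ((yy - b$cy) / b$ry)^2 + ((xx - b$cx) / b$rx)^2 <= 1
      inner <- ((yy - b$cy) / max(b$ry - b$th, 1))^2 +
        ((xx - b$cx) / max(b$rx - b$th, 1))^2 <= 1
      section[outer & !inner] <- 1L
      section[inner] <- 3L
    }
    material <- array(0L, cfg$shape)
    for (z in seq_len(nz)) material[z, , ] <- section
    # pores: spheres placed at random marrow voxels until the target
    # marrow fraction is reached
    marrow_idx <- which(material == 3L, arr.ind = TRUE)
    n_marrow <- nrow(marrow_idx)
    target <- cfg$pore_density * n_marrow
    if (target > 0 && n_marrow > 0) {
      placed <- 0
      for (iter in seq_len(10000L)) {
        if (placed >= target) break
        ctr <- marrow_idx[sample.int(n_marrow, 1L), ]
        r <- stats::runif(1, cfg$pore_radius_px[1], cfg$pore_radius_px[2])
        rz <- max(1L, floor(r))
        zs <- max(1L, ctr[1] - rz):min(nz, ctr[1] + rz)
        ys <- max(1L, ctr[2] - ceiling(r)):min(ny, ctr[2] + ceiling(r))
        xs <- max(1L, ctr[3] - ceiling(r)):min(nx, ctr[3] + ceiling(r))
        for (z in zs) for (y in ys) for (x in xs) {
          if (material[z, y, x] == 3L &&
              (z - ctr[1])^2 + (y - ctr[2])^2 + (x - ctr[3])^2 <= r^2) {
            material[z, y, x] <- 2L
            placed <- placed + 1
          }
        }
      }
    }
    if (cfg$growth_plate && nz >= cfg$growth_plate_px) {
      z0 <- max(1L, nz %/% 2L - cfg$growth_plate_px %/% 2L)
      zs <- z0:min(nz, z0 + cfg$growth_plate_px - 1L)
      band <- material[zs, , , drop = FALSE]
      band[band == 3L] <- 2L
      material[zs, , ] <- band
    }
    if (cfg$drill_hole && length(bones) >= 1L) {
      b <- bones[[1]]
      zc <- nz / 2; r_d <- max(2, min(4, b$ry / 4))
      for (z in seq_len(nz)) {
        if (abs(z - zc) > r_d) next
        rows <- which(abs(seq_len(ny) - b$cy) <= r_d)
        material[z, rows, ] <- 0L
      }
    }
    # intensity synthesis
    levels <- c(cfg$intensity[["background"]], cfg$intensity[["bone"]],
                cfg$intensity[["background"]], cfg$intensity[["marrow"]])
    vol <- array(levels[material + 1L], cfg$shape)
    if (cfg$n_intensity_domains > 1L) {
      bounds <- floor(seq(0, nz, length.out = cfg$n_intensity_domains + 1))
      offsets <- c(0, stats::runif(cfg$n_intensity_domains - 1L,
                                   -0.08, 0.08))
      for (d in seq_len(cfg$n_intensity_domains)) {
        zs <- (bounds[d] + 1L):bounds[d + 1L]
        vol[zs, , ] <- vol[zs, , ] + offsets[d]
      }
    }
    if (cfg$radial_ramp) {
      rad <- sqrt((yy - (ny + 1) / 2)^2 + (xx - (nx + 1) / 2)^2)
      ramp <- 0.1 * rad / max(rad)
      for (z in seq_len(nz)) vol[z, , ] <- vol[z, , ] + ramp
    }
    vol <- vol * cfg$dimming_factor
    if (cfg$noise_sigma > 0) {
      vol <- vol + stats::rnorm(length(vol), 0, cfg$noise_sigma)
    }
    vol <- pmin(pmax(vol, 0), 1)
    top <- if (cfg$bit_depth == "u8") 255 else 65535
    vol <- array(round(vol * top), cfg$shape)
    labels <- material
    labels[labels == 3L] <- 0L
    list(
      volume = scan_volume(vol, scan_id = scan_id,
                           bit_depth = cfg$bit_depth),
      mask = label_mask(labels, scan_id = scan_id)
    )
  })
}

# difficulty-mode presets layered on a template configuration
.phantom_mode <- function(cfg, mode) {
  switch(mode,
    easy = cfg,
    packed = {
      cfg$n_bones <- 2L
      cfg$cortex_radius_px <- c(9, 12)
      cfg$packing_gap_px <- 2L
      cfg
    },
    dim = { cfg$dimming_factor <- 0.35; cfg },
    composite = { cfg$n_intensity_domains <- 3L; cfg },
    `8bit` = { cfg$bit_depth <- "u8"; cfg },
    drill = { cfg$drill_hole <- TRUE; cfg },
    growth_plate = { cfg$growth_plate <- TRUE; cfg },
    stop("unknown phantom mode: ", mode)
  )
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_scans` scan/mask TIFF-stack folder pairs
#' (`<id>/`, `<id>_mask/`) with varied seeds and difficulty modes, plus a
#' `manifest.csv` listing scan id, tile count, mode, seed and a config
#' digest.
#'
#' @param n_scans Number of scan/mask pairs.
#' @param cfg Template [phantom_config()]; per-scan seeds are derived
#'   from `cfg$seed`.
#' @param out_dir Output directory.
#' @param modes Character vector of difficulty modes recycled over scans
#'   (subset of `"easy"`, `"packed"`, `"dim"`, `"composite"`, `"8bit"`,
#'   `"drill"`, `"growth_plate"`).
#' @return The manifest data frame (also written to
#'   `out_dir/manifest.csv`).
#' @export
generate_dataset <- function(n_scans, cfg = phantom_config(), out_dir,
                             modes = "easy") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create directory: ", out_dir)
  modes <- rep_len(modes, n_scans)
  rows <- vector("list", n_scans)
  for (i in seq_len(n_scans)) {
    cfg_i <- .phantom_mode(cfg, modes[i])
    cfg_i$seed <- cfg$seed + i
    id <- sprintf("phantom_%02d_%s", i, modes[i])
    pair <- generate_phantom(cfg_i, scan_id = id)
    write_tiff_stack(pair$volume, file.path(out_dir, id))
    write_tiff_stack(pair$mask, file.path(out_dir, paste0(id, "_mask")))
    rows[[i]] <- data.frame(
      scan_id = id, tiles = cfg_i$shape[1], mode = modes[i],
      seed = cfg_i$seed, config_digest = .config_digest(cfg_i),
      stringsAsFactors = FALSE
    )
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

# cheap deterministic digest of a configuration (FNV-1a over its
# deparsed form)
.config_digest <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) * 16777619
    h <- h %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
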