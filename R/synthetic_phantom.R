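#' Configuration of the synthetic sonographic phantom
#'
#' Desk-scale stand-in for shoulder ultrasound lesions: 8-bit speckled
#' textures in which tears are darker, more skewed/kurtotic and more uniform
#' than tendinopathies. Each case is a smooth echogenicity field multiplied
#' by Gaussian-smoothed gamma speckle (mean 1), rounded and clipped to
#' \[0, 255\], with a random convex polygon lesion ROI covering 20-60% of
#' the frame.
#'
#' Defaults (chosen once; see the package vignette for rationale):
#' class mean echogenicities 117 (tendinopathy) and 43 (tear); tendinopathy
#' heterogeneity as sinusoidal fibrillar bands (amplitude 25 gray levels,
#' period 24 px) plus random hypoechoic patches; tears carry a focal
#' hypoechoic core (level 15) over 12% of the ROI and a 2 px echogenic
#' margin band (level 100) standing in for adjacent tendon enclosed by the
#' delineation; gamma speckle shape k = 12 smoothed at sigma = 1.5 px;
#' 128 x 128 frames, 50 cases per class.
#'
#' @param dims Frame size in pixels, `c(height, width)`.
#' @param n_per_class Cases per class.
#' @param tendinopathy_mean,tear_mean Target lesion echogenicity in
#'   \[0, 255\].
#' @param echogenicity_sd Case-level standard deviation of the lesion's
#'   expected echogenicity around its class mean (gray levels): patients
#'   vary, so two lesions of the same class differ in overall brightness.
#'   Without it every ROI mean estimates its class mean almost noiselessly
#'   (ROIs average thousands of pixels) and any mean offset separates the
#'   classes perfectly.
#' @param band_amplitude,band_period Fibrillar band amplitude (gray levels)
#'   and period (px) of the tendinopathy field.
#' @param patch_fraction Mean area fraction of each random hypoechoic patch
#'   in tendinopathy lesions (2-4 patches per case; 0 disables them).
#' @param core_fraction,core_level Area fraction and gray level of the
#'   hypoechoic tear core.
#' @param rim_level,rim_width Gray level and width (px) of the brighter
#'   margin band inside the tear ROI boundary, standing in for the adjacent
#'   echogenic tendon tissue that a lesion delineation unavoidably encloses;
#'   it gives tear histograms their bright right tail.
#' @param speckle_shape Gamma shape k of the multiplicative speckle.
#' @param psf_sigma Gaussian smoothing scale of the speckle (px).
#' @param background_level Echogenicity outside the lesion.
#' @param seed Integer seed fixing the full dataset bit-exactly.
#' @return List of class `"phantom_config"`.
#' @export
phantom_config <- function(dims = c(128L, 128L), n_per_class = 50L,
                           tendinopathy_mean = 117, tear_mean = 43,
                           echogenicity_sd = 12,
                           band_amplitude = 25, band_period = 24,
                           patch_fraction = 0.04,
                           core_fraction = 0.12, core_level = 15,
                           rim_level = 100, rim_width = 2L,
                           speckle_shape = 12, psf_sigma = 1.5,
                           background_level = 100, seed = 20190228L) {
  stopifnot(tendinopathy_mean >= 0, tendinopathy_mean <= 255,
            tear_mean >= 0, tear_mean <= 255,
            speckle_shape > 0, core_fraction >= 0, core_fraction < 1,
            n_per_class >= 1, all(dims >= 16))
  structure(
    list(dims = as.integer(dims), n_per_class = as.integer(n_per_class),
         tendinopathy_mean = tendinopathy_mean, tear_mean = tear_mean,
         echogenicity_sd = echogenicity_sd,
         band_amplitude = band_amplitude, band_period = band_period,
         patch_fraction = patch_fraction,
         core_fraction = core_fraction, core_level = core_level,
         rim_level = rim_level, rim_width = as.integer(rim_width),
         speckle_shape = speckle_shape, psf_sigma = psf_sigma,
         background_level = background_level, seed = as.integer(seed)),
    class = "phantom_config"
  )
}

# deterministic per-case substream seed, kept < 2^31
.case_seed <- function(seed, idx) {
  (as.numeric(seed) %% 65536 * 32749 + idx * 257) %% 2147483647
}

# run `expr` under a locally seeded RNG, restoring global RNG state
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Gaussian-smoothed unit-mean gamma speckle field
.speckle_field <- function(dims, shape, sigma) {
  s <- matrix(stats::rgamma(prod(dims), shape = shape, rate = shape),
              dims[1], dims[2])
  if (sigma > 0) {
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    s <- .conv_sep(s, k)
  }
  s / mean(s)
}

# separable 2-D convolution with edge renormalization
.conv_sep <- function(m, k) {
  r <- (length(k) - 1L) / 2L
  ones <- matrix(1, nrow(m), ncol(m))
  conv1 <- function(mm, along) {
    n <- if (along == 1) nrow(mm) else ncol(mm)
    out <- matrix(0, nrow(mm), ncol(mm))
    for (off in -r:r) {
      w <- k[off + r + 1L]
      idx_src <- pmin(pmax(seq_len(n) + off, 1L), n) # clamp replicates edge
      if (along == 1) out <- out + w * mm[idx_src, , drop = FALSE]
      else out <- out + w * mm[, idx_src, drop = FALSE]
    }
    out
  }
  conv1(conv1(m, 1), 2)
}

# random convex polygon ROI covering 20-60% of the frame
.random_roi <- function(dims) {
  for (try in 1:25) {
    ctr <- dims / 2 + stats::runif(2, -0.05, 0.05) * dims
    nv <- 12L
    ang <- sort(stats::runif(nv, 0, 2 * pi))
    aspect <- stats::runif(1, 0.75, 1.3)
    rho <- stats::runif(1, 0.30, 0.42) * min(dims) *
      stats::runif(nv, 0.82, 1.0)
    vr <- ctr[1] + rho * sin(ang) * sqrt(aspect)
    vc <- ctr[2] + rho * cos(ang) / sqrt(aspect)
    vr <- pmin(pmax(vr, 0), dims[1] - 1)
    vc <- pmin(pmax(vc, 0), dims[2] - 1)
    hull <- grDevices::chull(vc, vr)
    verts <- cbind(vr, vc)[hull, ]
    if (nrow(verts) < 3L) next
    mask <- rasterize_polygon(verts, dims)
    frac <- mean(mask)
    if (frac >= 0.2 && frac <= 0.6) return(list(mask = mask, vertices = verts))
  }
  stop("failed to draw a lesion ROI covering 20-60% of the frame",
       call. = FALSE)
}

# in-mask band within `w` pixels (chessboard metric) of the mask boundary
.boundary_band <- function(mask, w) {
  nr <- nrow(mask); nc <- ncol(mask)
  eroded <- mask
  for (dr in -w:w) for (dc in -w:w) {
    if (dr == 0L && dc == 0L) next
    shifted <- matrix(FALSE, nr, nc)
    rs <- max(1L, 1L + dr):min(nr, nr + dr)
    cs <- max(1L, 1L + dc):min(nc, nc + dc)
    shifted[rs, cs] <- mask[rs - dr, cs - dc]
    shifted[setdiff(seq_len(nr), rs), ] <- FALSE
    eroded <- eroded & shifted
  }
  mask & !eroded
}

# elliptical patch mask centered near the ROI centroid
.ellipse_patch <- function(dims, mask, area_frac, aspect, jitter = 0.25) {
  idx <- which(mask, arr.ind = TRUE)
  ctr <- colMeans(idx)
  span <- apply(idx, 2, function(v) diff(range(v))) / 2
  ctr <- ctr + stats::runif(2, -jitter, jitter) * span
  area <- area_frac * nrow(idx)
  a <- sqrt(area / pi * aspect)   # semi-axis (rows)
  b <- sqrt(area / pi / aspect)
  th <- stats::runif(1, 0, pi)
  rr <- row(mask) - ctr[1]; cc <- col(mask) - ctr[2]
  u <- rr * cos(th) + cc * sin(th)
  v <- -rr * sin(th) + cc * cos(th)
  (u / a)^2 + (v / b)^2 <= 1 & mask
}

#' Generate one synthetic lesion case
#'
#' Builds the class-specific echogenicity field (tendinopathy: mean level
#' plus fibrillar sinusoidal bands and hypoechoic patches; tear: darker mean
#' with a focal hypoechoic core), multiplies it by smoothed unit-mean gamma
#' speckle and quantizes to 8 bits.
#'
#' @param label `"tendinopathy"` or `"tear"`.
#' @param cfg A `"phantom_config"`.
#' @param case_seed Integer seed of this case's random substream.
#' @param case_id,patient_id Identifiers for the record.
#' @return A `"case_record"`.
#' @export
generate_case <- function(label, cfg, case_seed,
                          case_id = label, patient_id = case_id) {
  label <- match.arg(label, c("tendinopathy", "tear"))
  stopifnot(inherits(cfg, "phantom_config"))
  .with_seed(case_seed, {
    dims <- cfg$dims
    roi <- .random_roi(dims)
    mask <- roi$mask
    mu <- matrix(cfg$background_level, dims[1], dims[2])
    # patient-to-patient echogenicity variation around the class mean
    class_mean <- if (label == "tendinopathy") cfg$tendinopathy_mean
                  else cfg$tear_mean
    class_mean <- min(max(class_mean +
                            stats::rnorm(1, 0, cfg$echogenicity_sd), 5), 250)
    if (label == "tendinopathy") {
      phase <- stats::runif(1, 0, 2 * pi)
      orient <- stats::runif(1, 0, pi)
      wave <- sin(2 * pi * (row(mu) * cos(orient) + col(mu) * sin(orient)) /
                    cfg$band_period + phase)
      field <- class_mean + cfg$band_amplitude * wave
      if (cfg$patch_fraction > 0) {
        npatch <- sample(2:4, 1)
        for (i in seq_len(npatch)) {
          patch <- .ellipse_patch(
            dims, mask,
            stats::runif(1, 0.5, 1.5) * cfg$patch_fraction,
            stats::runif(1, 0.5, 2))
          field[patch] <- 0.6 * class_mean
        }
      }
      mu[mask] <- field[mask]
    } else {
      field <- matrix(class_mean, dims[1], dims[2])
      if (cfg$core_fraction > 0) {
        core <- .ellipse_patch(dims, mask, cfg$core_fraction,
                               stats::runif(1, 0.5, 2))
        field[core] <- cfg$core_level
      }
      if (cfg$rim_width > 0L) {
        field[.boundary_band(mask, cfg$rim_width)] <- cfg$rim_level
      }
      mu[mask] <- field[mask]
    }
    s <- .speckle_field(dims, cfg$speckle_shape, cfg$psf_sigma)
    img <- pmin(pmax(round(mu * s), 0), 255)
    storage.mode(img) <- "integer"
    case_record(case_id, patient_id, img, mask, label)
  })
}

#' Generate a labelled phantom dataset
#'
#' `n_per_class` cases per class, all randomness flowing from `cfg$seed`
#' through deterministic per-case substreams, so the same configuration
#' always regenerates the identical dataset. When `dir` is given, images and
#' masks are written as 8-bit PNGs together with a
#' `case_id,patient_id,image_file,roi_file,label` manifest readable by
#' [load_manifest()].
#'
#' @param cfg A `"phantom_config"`.
#' @param dir Optional output directory.
#' @return List with `cases` (list of `"case_record"`) and `manifest`
#'   (data.frame).
#' @export
generate_dataset <- function(cfg, dir = NULL) {
  stopifnot(inherits(cfg, "phantom_config"))
  labels <- rep(c("tendinopathy", "tear"), each = cfg$n_per_class)
  ids <- sprintf("%s_%03d", ifelse(labels == "tear", "tear", "tend"),
                 c(seq_len(cfg$n_per_class), seq_len(cfg$n_per_class)))
  cases <- lapply(seq_along(labels), function(i) {
    generate_case(labels[i], cfg, .case_seed(cfg$seed, i),
                  case_id = ids[i], patient_id = sprintf("P%03d", i))
  })
  manifest <- data.frame(
    case_id = ids,
    patient_id = sprintf("P%03d", seq_along(labels)),
    image_file = paste0(ids, ".png"),
    roi_file = paste0(ids, "_mask.png"),
    label = labels
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(cases)) {
      write_gray_image(cases[[i]]$image,
                       file.path(dir, manifest$image_file[i]))
      write_gray_image(ifelse(cases[[i]]$mask, 255L, 0L) * 1L,
                       file.path(dir, manifest$roi_file[i]))
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  list(cases = cases, manifest = manifest)
}
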