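#' Configuration for the synthetic B-scan generator
#'
#' Defines the geometry, optical properties and noise level of a synthetic
#' OCT B-scan: a bright stromal band (the choroid) containing dark elliptical
#' vessels, lying beneath a retina-like layer complex with a foveal pit.
#' The generator is fully determined by `seed`.
#'
#' @param height,width image size in pixels; both must be multiples of 64 so
#'   that generated scans can be fed to the U-Net unchanged.
#' @param scale_x,scale_y lateral/axial pixel size in microns per pixel.
#'   Defaults mirror a 9-mm macular line scan sampled over 768 columns
#'   (9000/768 um/px laterally) and a typical spectral-domain axial sampling
#'   of 3.87 um/px.
#' @param choroid_mean_thickness mean choroidal thickness in microns.
#' @param choroid_thickness_variation fractional amplitude of the smooth
#'   thickness undulation along the scan.
#' @param vessel_count number of vessel ellipses planted in the band.
#' @param vessel_radius_range two-element range of vessel radii in microns.
#' @param vessel_intensity,stroma_intensity rendered intensities in `[0, 1]`.
#' @param fovea_pit_depth depth of the foveal pit in microns.
#' @param speckle_sigma standard deviation of multiplicative log-normal
#'   speckle; 0 disables noise.
#' @param tilt_degrees tilt of the band's centre line, implemented as a shear.
#' @param seed integer seed determining every random choice.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(height = 768, width = 768,
                             scale_x = 9000 / 768, scale_y = 3.87,
                             choroid_mean_thickness = 350,
                             choroid_thickness_variation = 0.1,
                             vessel_count = 150,
                             vessel_radius_range = c(25, 140),
                             vessel_intensity = 0.2,
                             stroma_intensity = 0.8,
                             fovea_pit_depth = 120,
                             speckle_sigma = 0.05,
                             tilt_degrees = 0,
                             seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              scale_x = scale_x, scale_y = scale_y,
              choroid_mean_thickness = choroid_mean_thickness,
              choroid_thickness_variation = choroid_thickness_variation,
              vessel_count = as.integer(vessel_count),
              vessel_radius_range = vessel_radius_range,
              vessel_intensity = vessel_intensity,
              stroma_intensity = stroma_intensity,
              fovea_pit_depth = fovea_pit_depth,
              speckle_sigma = speckle_sigma,
              tilt_degrees = tilt_degrees,
              seed = as.integer(seed))
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$height %% 64 != 0 || cfg$width %% 64 != 0)
    stop("height and width must be multiples of 64", call. = FALSE)
  ints <- c(cfg$vessel_intensity, cfg$stroma_intensity)
  if (any(ints < 0 | ints > 1))
    stop("intensities must lie in [0, 1]", call. = FALSE)
  if (any(cfg$vessel_radius_range <= 0) ||
      length(cfg$vessel_radius_range) != 2)
    stop("vessel_radius_range must be two positive values", call. = FALSE)
  if (cfg$speckle_sigma < 0)
    stop("speckle_sigma must be >= 0", call. = FALSE)
  if (cfg$scale_x <= 0 || cfg$scale_y <= 0)
    stop("pixel scales must be positive", call. = FALSE)
  invisible(cfg)
}

#' Generate one synthetic OCT B-scan with exact ground truth
#'
#' Renders a choroid-like stromal band with planted elliptical vessels under
#' a retina-like complex with a foveal pit, then applies multiplicative
#' log-normal speckle. The returned masks describe the exact rendered
#' geometry before noise; the per-column band thickness used during
#' rendering is retained so that geometric truth can be read back.
#'
#' Vessels with larger radii are preferentially placed toward the scleral
#' side of the band, mimicking the Haller/Sattler stratification of the
#' choroid.
#'
#' @param config a [generator_config()].
#' @return An object of class `synthetic_sample`: a list with `image`
#'   (H x W matrix in `[0, 1]`), logical `region_mask` and `vessel_mask`
#'   (vessels always inside the region), `fovea_col`, `fovea_row` (1-based),
#'   `scale_x`, `scale_y`, the internal per-column `thickness_px` profile,
#'   and `vessel_area_px`, the per-ellipse rasterised area tally accumulated
#'   during generation (before overlap removal).
#' @export
generate_bscan <- function(config) {
  validate_generator_config(config)
  cfg <- config
  H <- cfg$height; W <- cfg$width
  with_seed(cfg$seed, {
    cols <- seq_len(W)

    # fovea column jittered within the central 30% of the scan
    fovea_col <- as.integer(round(W / 2 + runif(1, -0.15, 0.15) * W))
    fovea_col <- max(1L, min(W, fovea_col))

    # upper (RPE-C) boundary: flat base line plus tilt shear of the band
    u0 <- 0.45 * H
    shear <- tan(cfg$tilt_degrees * pi / 180) * cfg$scale_x / cfg$scale_y
    u <- round(u0 + shear * (cols - (W + 1) / 2))

    # smooth per-column thickness profile (integer pixels, the truth record)
    t_um <- cfg$choroid_mean_thickness *
      (1 + cfg$choroid_thickness_variation *
         sin(2 * pi * runif(1, 0.5, 2) * cols / W + runif(1, 0, 2 * pi)))
    t_px <- pmax(1L, as.integer(round(t_um / cfg$scale_y)))

    # keep the band inside the frame
    u <- pmin(pmax(u, 2L), H - max(t_px) - 2L)
    lower <- u + t_px - 1L

    image <- matrix(0.05, H, W)
    region <- matrix(FALSE, H, W)
    for (j in cols) {
      rows <- u[j]:lower[j]
      region[rows, j] <- TRUE
      image[rows, j] <- cfg$stroma_intensity
      if (lower[j] < H) image[(lower[j] + 1):H, j] <- 0.15  # sclera
    }

    # retina-like complex above the band, with a Gaussian foveal pit
    ret_px <- round(250 / cfg$scale_y)
    pit_px <- cfg$fovea_pit_depth / cfg$scale_y
    sigma_pit <- 350 / cfg$scale_x
    pit <- pit_px * exp(-((cols - fovea_col)^2) / (2 * sigma_pit^2))
    r_top <- pmax(1L, as.integer(round(u - ret_px + pit)))
    for (j in cols) {
      if (r_top[j] <= u[j] - 1L) {
        rows <- r_top[j]:(u[j] - 1L)
        # graded inner layers, bright RPE just above the band
        image[rows, j] <- 0.45 + 0.2 * (rows - r_top[j]) / max(1, length(rows))
        rpe <- max(r_top[j], u[j] - 3L):(u[j] - 1L)
        image[rpe, j] <- 0.9
      }
    }
    fovea_row <- r_top[fovea_col]

    # vessels: filled ellipses, larger radii toward the scleral side
    vessel <- matrix(FALSE, H, W)
    r_rng <- cfg$vessel_radius_range
    vessel_area_px <- 0
    if (cfg$vessel_count > 0) {
      for (k in seq_len(cfg$vessel_count)) {
        cx <- runif(1, 1, W)
        depth_frac <- runif(1, 0.08, 0.92)
        jc <- max(1L, min(W, as.integer(round(cx))))
        cy <- u[jc] + depth_frac * (t_px[jc] - 1)
        r_um <- r_rng[1] + (r_rng[2] - r_rng[1]) *
          (0.3 * runif(1) + 0.7 * depth_frac)
        ecc <- runif(1, 0.5, 1)
        theta <- runif(1, 0, pi)
        a <- r_um / cfg$scale_x            # lateral semi-axis, px
        b <- r_um * ecc / cfg$scale_y      # axial semi-axis, px
        m <- max(a, b) + 2
        jr <- max(1L, floor(cx - m)):min(W, ceiling(cx + m))
        ir <- max(1L, floor(cy - m)):min(H, ceiling(cy + m))
        jj <- matrix(jr, length(ir), length(jr), byrow = TRUE)
        ii <- matrix(ir, length(ir), length(jr))
        dx <- jj - cx
        dy <- ii - cy
        inside <- ((dx * cos(theta) + dy * sin(theta)) / a)^2 +
          ((-dx * sin(theta) + dy * cos(theta)) / b)^2 <= 1
        hit <- inside & region[ir, jr, drop = FALSE]
        vessel_area_px <- vessel_area_px + sum(hit)
        vessel[ir, jr] <- vessel[ir, jr] | hit
      }
      image[vessel] <- cfg$vessel_intensity
    }

    # multiplicative log-normal speckle, mean-one, clipped to [0, 1]
    if (cfg$speckle_sigma > 0) {
      s <- cfg$speckle_sigma
      image <- clip01(image * exp(rnorm(H * W, -s^2 / 2, s)))
    }

    structure(list(image = image, region_mask = region, vessel_mask = vessel,
                   fovea_col = fovea_col, fovea_row = fovea_row,
                   scale_x = cfg$scale_x, scale_y = cfg$scale_y,
                   thickness_px = t_px, upper_row = u,
                   vessel_area_px = vessel_area_px,
                   config = cfg),
              class = "synthetic_sample")
  })
}

#' Generate a dataset of synthetic B-scans
#'
#' Per-sample seeds are derived deterministically from `seed`; thickness,
#' vessel count and tilt are jittered around the values in `config` so the
#' dataset spans realistic anatomical variation.
#'
#' @param config a [generator_config()] giving the central parameter values.
#' @param n number of samples (>= 1).
#' @param seed master seed for the dataset.
#' @return list of `synthetic_sample` objects.
#' @export
generate_dataset <- function(config, n, seed = config$seed) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  validate_generator_config(config)
  lapply(seq_len(n), function(i) {
    si <- derive_seed(seed, i)
    jit <- with_seed(si + 1L, runif(3, -1, 1))
    cfg <- config
    cfg$choroid_mean_thickness <- config$choroid_mean_thickness * (1 + 0.2 * jit[1])
    cfg$vessel_count <- max(0L, as.integer(round(
      config$vessel_count * (1 + 0.2 * jit[2]))))
    cfg$tilt_degrees <- config$tilt_degrees * jit[3]
    cfg$seed <- si
    generate_bscan(cfg)
  })
}

#' Degrade exact masks into model-like probability maps
#'
#' Turns a sample's binary ground truth into soft probability maps by
#' Gaussian blurring and additive noise, clipped to `[0, 1]`. The fovea
#' channel is the constructed fovea training target (see
#' [build_fovea_target()]) degraded the same way. With both sigmas zero the
#' maps equal the clean masks/target exactly.
#'
#' @param sample a `synthetic_sample`.
#' @param blur_sigma Gaussian blur standard deviation in pixels.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param seed seed for the noise.
#' @return An object of class `segmentation_output`: list with `region_prob`,
#'   `vessel_prob`, `fovea_prob` matrices in `[0, 1]`.
#' @export
degrade_to_probability_maps <- function(sample, blur_sigma = 0,
                                        noise_sigma = 0, seed = 1L) {
  if (blur_sigma < 0 || noise_sigma < 0)
    stop("sigmas must be >= 0", call. = FALSE)
  fovea <- build_fovea_target(dim(sample$image), sample$fovea_col,
                              sample$fovea_row)
  degrade1 <- function(x, sub_seed) {
    x <- gaussian_blur(x, blur_sigma)
    if (noise_sigma > 0)
      x <- x + with_seed(sub_seed, matrix(rnorm(length(x), 0, noise_sigma),
                                          nrow(x), ncol(x)))
    clip01(x)
  }
  out <- list(region_prob = degrade1(sample$region_mask * 1, derive_seed(seed, 1)),
              vessel_prob = degrade1(sample$vessel_mask * 1, derive_seed(seed, 2)),
              fovea_prob = degrade1(fovea, derive_seed(seed, 3)))
  class(out) <- "segmentation_output"
  out
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat(sprintf("synthetic OCT B-scan %d x %d px (%.2f x %.2f um/px)\n",
              nrow(x$image), ncol(x$image), x$scale_x, x$scale_y))
  cat(sprintf("  fovea at (row %d, col %d); region %d px, vessels %d px\n",
              x$fovea_row, x$fovea_col, sum(x$region_mask), sum(x$vessel_mask)))
  invisible(x)
}
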