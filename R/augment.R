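#' Augmentation configuration
#'
#' The stochastic training augmentations, applied in random order per
#' sample: horizontal flip (p = 0.5), independent brightness and contrast
#' scaling (factors ~ U(0.5, 1.5), p = 0.95 each), random rotation
#' (~ U(-25, 25) degrees) with shear (~ U(-15, 15) degrees) at p = 1/3, and
#' isotropic scaling (~ U(0.8, 1.2)) at p = 1/3. Geometric transforms are
#' applied identically to the image and all target channels (nearest
#' neighbour for the binary region/vessel channels, bilinear for the fovea
#' channel) and to the fovea coordinates; photometric transforms touch the
#' image only.
#'
#' @param hflip_p horizontal flip probability.
#' @param brightness_range,contrast_range factor ranges.
#' @param photometric_p probability of each photometric transform.
#' @param rotation_range,shear_range degree ranges.
#' @param affine_p probability of the rotation+shear transform.
#' @param scale_range scale factor range.
#' @param scale_p probability of the scaling transform.
#' @return An object of class `augmentation_config`.
#' @export
augmentation_config <- function(hflip_p = 0.5,
                                brightness_range = c(0.5, 1.5),
                                contrast_range = c(0.5, 1.5),
                                photometric_p = 0.95,
                                rotation_range = c(-25, 25),
                                shear_range = c(-15, 15),
                                affine_p = 1 / 3,
                                scale_range = c(0.8, 1.2),
                                scale_p = 1 / 3) {
  ps <- c(hflip_p, photometric_p, affine_p, scale_p)
  if (any(ps < 0 | ps > 1)) stop("probabilities must lie in [0, 1]",
                                 call. = FALSE)
  structure(list(hflip_p = hflip_p, brightness_range = brightness_range,
                 contrast_range = contrast_range,
                 photometric_p = photometric_p,
                 rotation_range = rotation_range, shear_range = shear_range,
                 affine_p = affine_p, scale_range = scale_range,
                 scale_p = scale_p),
            class = "augmentation_config")
}

# forward affine map about the image centre in (col, row) coordinates;
# A is 2x2, returns warped image and the point-mapping function
warp_affine <- function(image, A, center, filter) {
  tvec <- center - A %*% center
  m <- t(cbind(A, tvec))
  warped <- EBImage::affine(EBImage::Image(t(image)), m, filter = filter,
                            bg.col = 0, antialias = FALSE)
  t(EBImage::imageData(warped))
}

map_point <- function(A, center, p) as.vector(A %*% (p - center) + center)

#' Augment one training sample
#'
#' @param image H x W numeric matrix in `[0, 1]`.
#' @param targets H x W x 3 array (region, vessel, fovea target).
#' @param fovea_col 1-based fovea column.
#' @param config an [augmentation_config()].
#' @param seed optional seed; `NULL` draws from the current RNG stream.
#' @return list with transformed `image`, `targets`, `fovea_col` and the
#'   applied transform `order`.
#' @export
augment_sample <- function(image, targets, fovea_col,
                           config = augmentation_config(), seed = NULL) {
  run <- function() {
    H <- nrow(image); W <- ncol(image)
    center <- c((W + 1) / 2, (H + 1) / 2)   # (col, row)
    ops <- sample(c("hflip", "brightness", "contrast", "affine", "scale"))
    fcol <- fovea_col
    # fovea row from the target channel, needed to track the column under
    # rotations; falls back to the centre row for a flat channel
    pk <- which(targets[, , 3] == max(targets[, , 3]), arr.ind = TRUE)
    frow <- if (diff(range(targets[, , 3])) > 0) pk[1, 1] else center[2]
    for (op in ops) {
      if (op == "hflip" && runif(1) < config$hflip_p) {
        image <- image[, W:1, drop = FALSE]
        targets <- targets[, W:1, , drop = FALSE]
        fcol <- W + 1 - fcol
      } else if (op == "brightness" && runif(1) < config$photometric_p) {
        f <- runif(1, config$brightness_range[1], config$brightness_range[2])
        image <- clip01(image * f)
      } else if (op == "contrast" && runif(1) < config$photometric_p) {
        f <- runif(1, config$contrast_range[1], config$contrast_range[2])
        image <- adjust_contrast(image, f)
      } else if (op %in% c("affine", "scale")) {
        p <- if (op == "affine") config$affine_p else config$scale_p
        if (runif(1) >= p) next
        A <- if (op == "affine") {
          th <- runif(1, config$rotation_range[1], config$rotation_range[2]) *
            pi / 180
          sh <- tan(runif(1, config$shear_range[1], config$shear_range[2]) *
                      pi / 180)
          R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
          S <- matrix(c(1, 0, sh, 1), 2, 2)
          R %*% S
        } else {
          diag(2) * runif(1, config$scale_range[1], config$scale_range[2])
        }
        image <- clip01(warp_affine(image, A, center, "bilinear"))
        t2 <- targets
        t2[, , 1] <- warp_affine(targets[, , 1], A, center, "none")
        t2[, , 2] <- warp_affine(targets[, , 2], A, center, "none")
        t2[, , 3] <- clip01(warp_affine(targets[, , 3], A, center, "bilinear"))
        targets <- t2
        p <- map_point(A, center, c(fcol, frow))
        fcol <- p[1]; frow <- p[2]
      }
    }
    list(image = image, targets = targets,
         fovea_col = as.integer(max(1, min(W, round(fcol)))), order = ops)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
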