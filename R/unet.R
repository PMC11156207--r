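#' U-Net architecture configuration
#'
#' A depth-7 fully convolutional U-Net with three sigmoid output channels
#' (choroid region, vessels, fovea). Each block is two 3x3 convolutions,
#' each followed by BatchNorm and ReLU; levels are joined by 2x2 max-pooling
#' on the way down and by up-blocks (1x1 channel-reduction convolution plus
#' bilinear x2 interpolation) with concatenated skip connections on the way
#' up. The first three blocks widen the channel dimension from 8 to 64,
#' after which it stays constant; the decoder runs at constant 64 channels.
#'
#' @param depth number of encoder levels.
#' @param encoder_channels channel widths per encoder level
#'   (length = `depth`).
#' @param out_channels output channels (region, vessel, fovea).
#' @return An object of class `unet_config`.
#' @export
unet_config <- function(depth = 7L,
                        encoder_channels = c(8L, 32L, 64L, 64L, 64L, 64L, 64L),
                        out_channels = 3L) {
  if (length(encoder_channels) != depth)
    stop("encoder_channels must have length `depth`", call. = FALSE)
  structure(list(depth = as.integer(depth),
                 encoder_channels = as.integer(encoder_channels),
                 out_channels = as.integer(out_channels)),
            class = "unet_config")
}

#' Training configuration
#'
#' The reference recipe: AdamW (learning rate 5e-4, weight decay 1e-8),
#' per-pixel binary cross-entropy averaged over the three output channels,
#' and the global gradient norm clamped to 3 before each step.
#'
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param weight_decay AdamW decoupled weight decay.
#' @param grad_norm_clip maximum global gradient norm.
#' @param batch_size samples per optimizer step (gradient accumulation).
#' @param seed seed for shuffling and augmentation.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 40L, lr = 5e-4, weight_decay = 1e-8,
                         grad_norm_clip = 3, batch_size = 1L, seed = 1L) {
  if (lr < 0 || weight_decay < 0)
    stop("lr and weight_decay must be >= 0", call. = FALSE)
  if (grad_norm_clip <= 0) stop("grad_norm_clip must be > 0", call. = FALSE)
  structure(list(epochs = as.integer(epochs), lr = lr,
                 weight_decay = weight_decay, grad_norm_clip = grad_norm_clip,
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

#' Build a U-Net model
#'
#' Instantiates the native network with He-initialized weights. The model is
#' fully convolutional: any input whose height and width are divisible by
#' `2^(depth-1)` produces an aligned 3-channel logit map of the same size.
#'
#' @param config a [unet_config()].
#' @param seed weight initialization seed.
#' @return An object of class `unet` holding an external pointer to the
#'   native network.
#' @export
build_unet <- function(config = unet_config(), seed = 1L) {
  ptr <- unet_create(config$encoder_channels, 1L, config$out_channels,
                     as.integer(seed))
  structure(list(ptr = ptr, config = config, seed = as.integer(seed)),
            class = "unet")
}

#' @export
print.unet <- function(x, ...) {
  cat(sprintf("U-Net depth %d, channels [%s], %d output channels, %s parameters\n",
              x$config$depth, paste(x$config$encoder_channels, collapse = ", "),
              x$config$out_channels,
              format(unet_num_params(x$ptr), big.mark = ",")))
  invisible(x)
}

# input shape must be divisible by 2^(depth-1); reflect-pad if not
pad_to_multiple <- function(image, mult) {
  H <- nrow(image); W <- ncol(image)
  ph <- (mult - H %% mult) %% mult
  pw <- (mult - W %% mult) %% mult
  if (ph == 0 && pw == 0) return(list(image = image, ph = 0L, pw = 0L))
  ri <- c(seq_len(H), seq(H - 1, by = -1, length.out = ph))
  ci <- c(seq_len(W), seq(W - 1, by = -1, length.out = pw))
  list(image = image[ri, ci, drop = FALSE], ph = ph, pw = pw)
}

#' Predict segmentation maps for a B-scan
#'
#' Runs the network in evaluation mode (BatchNorm running statistics) and
#' applies the sigmoid, returning three aligned probability maps. Inputs
#' whose size is not divisible by `2^(depth-1)` are reflect-padded and the
#' output cropped back.
#'
#' @param model a [build_unet()] model.
#' @param scan a [bscan()] or a plain numeric matrix in `[0, 1]`.
#' @return A `segmentation_output`: list with `region_prob`, `vessel_prob`,
#'   `fovea_prob`.
#' @export
predict_scan <- function(model, scan) {
  img <- if (inherits(scan, "bscan")) scan$image else scan
  stop_if_not_image(img)
  mult <- 2^(model$config$depth - 1L)
  pad <- pad_to_multiple(img, mult)
  logits <- unet_forward_logits(model$ptr, pad$image)
  probs <- 1 / (1 + exp(-logits))
  H <- nrow(img); W <- ncol(img)
  out <- list(region_prob = probs[1:H, 1:W, 1],
              vessel_prob = probs[1:H, 1:W, 2],
              fovea_prob = probs[1:H, 1:W, 3])
  class(out) <- "segmentation_output"
  out
}

#' @rdname predict_scan
#' @param object,... S3 method arguments (`...` must contain `scan` or a
#'   matrix as the first element).
#' @export
predict.unet <- function(object, ...) {
  predict_scan(object, ..1)
}

# stack the three training target channels for one sample
sample_targets <- function(sample) {
  H <- nrow(sample$image); W <- ncol(sample$image)
  tgt <- array(0, c(H, W, 3))
  tgt[, , 1] <- sample$region_mask
  tgt[, , 2] <- sample$vessel_mask
  tgt[, , 3] <- build_fovea_target(c(H, W), sample$fovea_col, sample$fovea_row)
  tgt
}

#' Train a U-Net on synthetic samples
#'
#' Runs the stated loop: (optionally) augment each sample, forward, mean
#' binary cross-entropy over the three channels, clip the global gradient
#' norm, AdamW step. Peripapillary-sized samples (width = 2 x height) are
#' randomly cropped to height x height at a multiple-of-192 column offset
#' each epoch.
#'
#' @param model a [build_unet()] model (updated in place; also returned).
#' @param dataset list of `synthetic_sample` objects.
#' @param tcfg a [train_config()].
#' @param acfg an [augmentation_config()] or `NULL` for no augmentation.
#' @return list with `model` and `history`, a data frame with per-epoch mean
#'   `loss` and maximum clipped gradient norm `grad_norm`.
#' @export
train_model <- function(model, dataset, tcfg = train_config(), acfg = NULL) {
  if (length(dataset) == 0) stop("dataset is empty", call. = FALSE)
  if (any(vapply(dataset, function(s) is.na(s$fovea_row), logical(1))))
    stop("samples must carry fovea annotations", call. = FALSE)
  targets <- lapply(dataset, sample_targets)
  n <- length(dataset)
  history <- data.frame(epoch = seq_len(tcfg$epochs), loss = NA_real_,
                        grad_norm = NA_real_)
  with_seed(tcfg$seed, {
    for (epoch in seq_len(tcfg$epochs)) {
      ord <- sample.int(n)
      losses <- numeric(0)
      gmax <- 0
      pending <- 0L
      for (i in ord) {
        img <- dataset[[i]]$image
        tgt <- targets[[i]]
        if (!is.null(acfg)) {
          aug <- augment_sample(img, tgt, dataset[[i]]$fovea_col, acfg,
                                seed = NULL)
          img <- aug$image; tgt <- aug$targets
        }
        hh <- nrow(img)
        if (ncol(img) == 2L * hh) {
          off <- sample(seq(0L, ncol(img) - hh, by = 192L), 1)
          img <- img[, (off + 1L):(off + hh), drop = FALSE]
          tgt <- tgt[, (off + 1L):(off + hh), , drop = FALSE]
        }
        losses <- c(losses, unet_accumulate(model$ptr, img, tgt))
        pending <- pending + 1L
        if (pending >= tcfg$batch_size) {
          st <- unet_apply_update(model$ptr, tcfg$lr, tcfg$weight_decay,
                                  tcfg$grad_norm_clip)
          gmax <- max(gmax, st$grad_norm_clipped)
          pending <- 0L
        }
      }
      if (pending > 0) {
        st <- unet_apply_update(model$ptr, tcfg$lr, tcfg$weight_decay,
                                tcfg$grad_norm_clip)
        gmax <- max(gmax, st$grad_norm_clipped)
      }
      if (any(!is.finite(losses)))
        stop("NaN loss at epoch ", epoch, "; aborting training", call. = FALSE)
      history$loss[epoch] <- mean(losses)
      history$grad_norm[epoch] <- gmax
    }
  })
  list(model = model, history = history)
}

#' Save / load a trained model
#'
#' Checkpoints contain the architecture, weights and BatchNorm running
#' statistics (optimizer state is not serialized).
#'
#' @param model a [build_unet()] model.
#' @param path checkpoint file path (`.rds`).
#' @return `load_unet` returns the restored model.
#' @export
save_unet <- function(model, path) {
  saveRDS(list(config = model$config, seed = model$seed,
               state = unet_get_state(model$ptr)), path)
  invisible(path)
}

#' @rdname save_unet
#' @export
load_unet <- function(path) {
  ck <- readRDS(path)
  model <- build_unet(ck$config, ck$seed)
  unet_set_state(model$ptr, ck$state)
  model
}
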