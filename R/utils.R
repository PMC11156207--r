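# internal helpers shared across modules

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# derive a per-item 32-bit seed from a master seed
derive_seed <- function(master, i) {
  as.integer((as.numeric(master) * 48271 + i * 10007) %% 2147483647)
}

stop_if_not_image <- function(image, name = "image") {
  if (!is.matrix(image) || !is.numeric(image))
    stop(sprintf("`%s` must be a numeric matrix", name), call. = FALSE)
}

is_binary <- function(x) all(x %in% c(0, 1, TRUE, FALSE))

as_mask <- function(x) {
  m <- matrix(as.logical(x > 0.5 | x == 1), nrow(x), ncol(x))
  m[is.na(m)] <- FALSE
  m
}

gaussian_blur <- function(image, sigma) {
  if (sigma <= 0) return(image)
  EBImage::gblur(image, sigma = sigma)
}
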