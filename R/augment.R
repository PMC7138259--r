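#' Augmentation configuration
#'
#' Label-consistent augmentation applied jointly to a tile and its target
#' mask: a random quarter-turn rotation, independent horizontal and vertical
#' flips (each Bernoulli(1/2)), and an additive brightness offset applied to
#' the image only. Rotations are restricted to quarter turns so the binary
#' mask is transformed losslessly — arbitrary-angle rotation would require
#' interpolating the mask. An optional gamma transform (off by default) is
#' available for contrast robustness experiments.
#'
#' @param rot90 enable random quarter-turn rotations.
#' @param flips enable random horizontal/vertical flips.
#' @param brightness maximum additive brightness offset as a fraction of the
#'   intensity range (offset drawn uniformly in `[-brightness, +brightness]`);
#'   0 disables.
#' @param gamma optional length-2 range for a random gamma exponent, or
#'   `NULL` to disable.
#' @param seed optional seed consumed by callers that own the draw.
#' @return an object of class `augment_config`.
#' @export
augment_config <- function(rot90 = TRUE, flips = TRUE, brightness = 0.1,
                           gamma = NULL, seed = NULL) {
  if (brightness < 0 || brightness > 1)
    stop("brightness must be in [0, 1]")
  if (!is.null(gamma) && (length(gamma) != 2 || any(gamma <= 0)))
    stop("gamma must be NULL or a positive length-2 range")
  structure(list(rot90 = isTRUE(rot90), flips = isTRUE(flips),
                 brightness = brightness, gamma = gamma, seed = seed),
            class = "augment_config")
}

draw_augment <- function(cfg) {
  list(k = if (cfg$rot90) sample(0:3, 1) else 0L,
       flip_h = if (cfg$flips) runif(1) < 0.5 else FALSE,
       flip_v = if (cfg$flips) runif(1) < 0.5 else FALSE,
       delta = if (cfg$brightness > 0)
         runif(1, -cfg$brightness, cfg$brightness) else 0,
       gamma = if (!is.null(cfg$gamma))
         runif(1, cfg$gamma[1], cfg$gamma[2]) else 1)
}

apply_geom <- function(m, draw) {
  if (draw$k != 0L) m <- rot90_mat(m, draw$k)
  if (draw$flip_h) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
  if (draw$flip_v) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  m
}

#' Augment an image patch together with its mask
#'
#' The geometric transform (rotation + flips) is applied identically to the
#' patch and the mask; the photometric transform (brightness, optional
#' gamma) touches the patch only and is clipped to \[0, 1\]. The mask stays
#' strictly binary and its foreground pixel count is preserved.
#'
#' @param patch `H x W x C` numeric array (or matrix) in \[0, 1\].
#' @param mask 0/1 matrix of matching spatial size.
#' @param cfg an [augment_config()].
#' @param draw optional explicit draw (list with `k`, `flip_h`, `flip_v`,
#'   `delta`, `gamma`); by default drawn from the current RNG state.
#' @return list with `patch` and `mask`.
#' @export
augment_pair <- function(patch, mask, cfg = augment_config(), draw = NULL) {
  pd <- dim(patch)
  if (!identical(pd[1:2], dim(mask)))
    stop("patch and mask spatial dimensions differ")
  if (cfg$rot90 && pd[1] != pd[2])
    stop("quarter-turn rotation requires square tiles")
  draw <- draw %||% draw_augment(cfg)
  if (length(pd) == 3L) {
    out <- array(0, dim = c(dim(apply_geom(patch[, , 1], draw)), pd[3]))
    for (ch in seq_len(pd[3])) out[, , ch] <- apply_geom(patch[, , ch], draw)
  } else {
    out <- apply_geom(patch, draw)
  }
  mask <- as_mask(apply_geom(mask, draw))
  if (draw$gamma != 1) out <- clip01(out)^draw$gamma
  if (draw$delta != 0) out <- out + draw$delta
  list(patch = clip01(out), mask = mask)
}
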