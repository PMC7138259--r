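#' Overlapping inference grid specification
#'
#' Full frames are larger than the network input, and predicting on a plain
#' disjoint grid leaves visible seams at tile borders. Inference therefore
#' uses an overlapping grid: `n_per_axis` linearly spaced tile origins per
#' axis (linspace from 0 to `dimension - tile_size`, rounded to integers),
#' whose Cartesian product covers the frame with heavy overlap. At the
#' full-frame scale (1392 x 1040, 512-px tiles, 30 coordinates per axis)
#' this yields 900 tiles. Duplicate origins after rounding are retained so
#' the tile count is always exactly `n_per_axis^2`.
#'
#' @param n_per_axis linearly spaced origins per axis (default 30).
#' @param tile_size tile side length in pixels.
#' @return an object of class `grid_spec`.
#' @export
grid_spec <- function(n_per_axis = 30L, tile_size = 512L) {
  cfg <- list(n_per_axis = as.integer(n_per_axis),
              tile_size = as.integer(tile_size))
  if (cfg$n_per_axis < 1) stop("n_per_axis must be >= 1")
  if (cfg$tile_size < 1) stop("tile_size must be >= 1")
  structure(cfg, class = "grid_spec")
}

# round half away from zero (origins are non-negative here)
round_half_up <- function(v) floor(v + 0.5)

#' Enumerate the overlapping inference grid
#'
#' @param frame_size `c(width, height)` of the frame in pixels.
#' @param spec a [grid_spec()].
#' @return data.frame of 0-based tile origins (`x`, `y`), the full Cartesian
#'   product in row-major order (y outer), with exactly `n_per_axis^2` rows.
#' @export
linspace_grid <- function(frame_size, spec) {
  W <- frame_size[1]; H <- frame_size[2]; t <- spec$tile_size
  if (t > W || t > H) stop("tile_size exceeds the frame dimensions")
  xs <- round_half_up(seq(0, W - t, length.out = spec$n_per_axis))
  ys <- round_half_up(seq(0, H - t, length.out = spec$n_per_axis))
  data.frame(x = rep(xs, times = length(ys)),
             y = rep(ys, each = length(xs)))
}

#' Average overlapping tile predictions into a full-frame probability map
#'
#' Each pixel's probability is the arithmetic mean of all tile predictions
#' covering it; the per-pixel count of contributing tiles is kept as a
#' coverage channel. Low-coverage border pixels are where stitching
#' artifacts concentrate, so coverage is surfaced rather than corrected.
#' Pixels covered by no tile get probability 0 and are flagged.
#'
#' @param tile_probs list of `tile x tile` probability matrices.
#' @param origins data.frame of 0-based origins (`x`, `y`), same length.
#' @param frame_size `c(width, height)`.
#' @param tile_size tile side length (inferred from the first tile if
#'   missing).
#' @return an object of class `probability_map`: list with `prob` and
#'   `coverage` matrices (H x W) and an `uncovered` flag.
#' @export
stitch_average <- function(tile_probs, origins, frame_size, tile_size = NULL) {
  stopifnot(length(tile_probs) == nrow(origins))
  t <- tile_size %||% nrow(tile_probs[[1]])
  W <- frame_size[1]; H <- frame_size[2]
  acc <- matrix(0, H, W)
  cov <- matrix(0L, H, W)
  for (k in seq_along(tile_probs)) {
    x <- origins$x[k]; y <- origins$y[k]
    if (x < 0 || y < 0 || x + t > W || y + t > H)
      stop("tile origin (", x, ",", y, ") out of bounds")
    rows <- (y + 1):(y + t); cols <- (x + 1):(x + t)
    acc[rows, cols] <- acc[rows, cols] + tile_probs[[k]]
    cov[rows, cols] <- cov[rows, cols] + 1L
  }
  prob <- matrix(0, H, W)
  covered <- cov > 0
  prob[covered] <- acc[covered] / cov[covered]
  structure(list(prob = prob, coverage = cov, uncovered = any(!covered)),
            class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  cat("<probability_map>", paste(dim(x$prob), collapse = "x"),
      "| coverage", min(x$coverage), "-", max(x$coverage),
      if (x$uncovered) "| has uncovered pixels" else "", "\n")
  invisible(x)
}

#' Predict a full frame by overlapping-grid stitching
#'
#' Extracts every grid tile, runs the network on each, and averages the
#' per-tile foreground probabilities pixel-wise. Deterministic given fixed
#' weights.
#'
#' @param params a trained `unet_params`.
#' @param frame an [annotated_image()] or an `H x W x 3` array.
#' @param spec a [grid_spec()]; its `tile_size` must equal the network's
#'   `input_size`.
#' @param batch_size tiles predicted per inner loop (memory knob only; the
#'   result does not depend on it).
#' @return a `probability_map`.
#' @export
predict_frame <- function(params, frame, spec, batch_size = 16L) {
  img <- if (inherits(frame, "annotated_image")) frame$image else frame
  if (spec$tile_size != params$config$input_size)
    stop("grid tile_size must equal the network input_size")
  H <- dim(img)[1]; W <- dim(img)[2]
  origins <- linspace_grid(c(W, H), spec)
  t <- spec$tile_size
  probs <- vector("list", nrow(origins))
  for (start in seq(1L, nrow(origins), by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, nrow(origins))
    for (k in idx) {
      tile <- extract_tile(img, origins$x[k], origins$y[k], t)
      probs[[k]] <- predict_probabilities(params, tile)
    }
  }
  stitch_average(probs, origins, c(W, H), t)
}

#' Threshold a probability map into a binary mask
#'
#' Foreground where probability is strictly greater than the threshold
#' (ties go to background). The default operating point is 0.5.
#'
#' @param map a `probability_map` or a probability matrix.
#' @param threshold scalar in \[0, 1\].
#' @return integer 0/1 matrix with the threshold recorded as attribute
#'   `threshold`.
#' @export
binarize <- function(map, threshold = 0.5) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  p <- if (inherits(map, "probability_map")) map$prob else map
  out <- matrix(as.integer(p > threshold), nrow(p), ncol(p))
  attr(out, "threshold") <- threshold
  out
}
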