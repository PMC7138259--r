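#' Tile sampler configuration
#'
#' Controls how fixed-size training tiles are drawn from annotated frames.
#' For each class, a frame is scanned on a stride grid; tile origins whose
#' footprint contains at least `min_positive_pixels` foreground pixels of
#' the class are positive candidates, the rest negative. From these, at most
#' `max_positive` positives are drawn uniformly without replacement, and the
#' same number of negatives, giving a balanced per-class set. Tiles may
#' overlap freely — overlapping draws create differently aligned views of
#' the same objects.
#'
#' @param tile_size tile side length in pixels (default 512).
#' @param max_positive positive-tile cap per frame per class (default 20).
#' @param stride scan stride in pixels (default 64). The final origin in
#'   each axis is clamped to `dimension - tile_size` so the scan reaches the
#'   frame border.
#' @param min_positive_pixels minimum foreground pixels for a tile to count
#'   as positive (default 1).
#' @param seed integer seed for the per-frame draws.
#' @return an object of class `sampler_config`.
#' @export
sampler_config <- function(tile_size = 512L, max_positive = 20L, stride = 64L,
                           min_positive_pixels = 1L, seed = 1L) {
  cfg <- list(tile_size = as.integer(tile_size),
              max_positive = as.integer(max_positive),
              stride = as.integer(stride),
              min_positive_pixels = as.integer(min_positive_pixels),
              seed = as.integer(seed))
  stopifnot(cfg$tile_size >= 1, cfg$max_positive >= 0, cfg$stride >= 1,
            cfg$min_positive_pixels >= 1)
  structure(cfg, class = "sampler_config")
}

# Scan positions along one axis: stride grid from 0 with the final origin
# clamped to (extent - tile), so the last tile touches the border.
scan_positions <- function(extent, tile, stride) {
  if (tile > extent) stop("tile_size exceeds the frame dimension")
  last <- extent - tile
  g <- seq(0L, last, by = stride)
  g[length(g)] <- last
  unique(g)
}

#' Enumerate positive and negative candidate tile origins
#'
#' Scans the frame row-major (y outer, x inner) at the configured stride.
#' Origins are 0-based; a tile's footprint is the half-open square
#' `[x, x + tile) x [y, y + tile)`.
#'
#' @param annotated an [annotated_image()].
#' @param class_label a schema short label available in the image.
#' @param cfg a [sampler_config()].
#' @return list with data.frames `positives` and `negatives` (columns `x`,
#'   `y`, `pixels` = foreground pixel count in the footprint), in scan order.
#' @export
enumerate_candidates <- function(annotated, class_label, cfg = sampler_config()) {
  if (!class_label %in% annotated$available_classes)
    stop("class ", class_label, " is not available in image ", annotated$id)
  m <- annotated$masks[[class_label]]
  H <- nrow(m); W <- ncol(m); t <- cfg$tile_size
  if (t > min(H, W)) stop("tile_size exceeds the frame dimensions")
  xs <- scan_positions(W, t, cfg$stride)
  ys <- scan_positions(H, t, cfg$stride)
  # summed-area table for O(1) footprint sums
  cs <- apply(apply(m, 2, cumsum), 1, cumsum)   # W x H: cs[j, i] = sum m[1:i, 1:j]
  S <- matrix(0, H + 1L, W + 1L)
  S[2:(H + 1L), 2:(W + 1L)] <- t(cs)
  counts <- outer(ys, xs, function(y, x)
    S[cbind(y + t + 1L, x + t + 1L)] - S[cbind(y + 1L, x + t + 1L)] -
      S[cbind(y + t + 1L, x + 1L)] + S[cbind(y + 1L, x + 1L)])
  grid <- data.frame(x = rep(xs, times = length(ys)),
                     y = rep(ys, each = length(xs)),
                     pixels = as.vector(t(counts)))
  pos <- grid$pixels >= cfg$min_positive_pixels
  list(positives = grid[pos, , drop = FALSE],
       negatives = grid[grid$pixels == 0, , drop = FALSE])
}

extract_tile <- function(arr, x, y, t) {
  if (length(dim(arr)) == 3L) arr[(y + 1):(y + t), (x + 1):(x + t), , drop = FALSE]
  else arr[(y + 1):(y + t), (x + 1):(x + t), drop = FALSE]
}

tile_sample <- function(patch, target, class_label, origin, source_image_id) {
  structure(list(patch = patch, target = as_mask(target),
                 class_label = class_label,
                 is_positive = any(target != 0),
                 origin = c(x = origin[[1]], y = origin[[2]]),
                 source_image_id = source_image_id),
            class = "tile_sample")
}

#' Draw a balanced positive/negative tile set from one frame
#'
#' Selects `min(max_positive, #positive candidates)` positive origins by a
#' seeded uniform draw without replacement, then the same number of negative
#' origins. If fewer negatives exist than selected positives, all negatives
#' are taken and a warning records the imbalance. The per-frame draw seed is
#' derived from `cfg$seed`, the image id and the class, so the draw does not
#' depend on processing order.
#'
#' @inheritParams enumerate_candidates
#' @return list of `tile_sample` objects, positives first.
#' @export
balanced_sample <- function(annotated, class_label, cfg = sampler_config()) {
  cand <- enumerate_candidates(annotated, class_label, cfg)
  npos_avail <- nrow(cand$positives)
  if (npos_avail == 0) return(list())
  npos <- min(cfg$max_positive, npos_avail)
  nneg <- min(npos, nrow(cand$negatives))
  if (nneg < npos)
    warning("image ", annotated$id, ", class ", class_label, ": only ", nneg,
            " negative tiles available for ", npos, " positives")
  draw <- with_seed(derive_seed(cfg$seed, annotated$id, class_label), {
    list(pos = sort(sample.int(npos_avail, npos)),
         neg = if (nneg > 0) sort(sample.int(nrow(cand$negatives), nneg))
               else integer())
  })
  t <- cfg$tile_size
  m <- annotated$masks[[class_label]]
  mk <- function(row) tile_sample(
    extract_tile(annotated$image, row$x, row$y, t),
    extract_tile(m, row$x, row$y, t),
    class_label, c(row$x, row$y), annotated$id)
  c(lapply(draw$pos, function(i) mk(cand$positives[i, ])),
    lapply(draw$neg, function(i) mk(cand$negatives[i, ])))
}

#' Build the full training set for one class across frames
#'
#' Concatenates [balanced_sample()] over every frame where the class is
#' available; frames without the class contribute nothing. Deterministic
#' given the sampler seed and the input frame order.
#'
#' @param images list of [annotated_image()] objects.
#' @param class_label schema short label.
#' @param cfg a [sampler_config()].
#' @return list of `tile_sample` objects.
#' @export
build_class_dataset <- function(images, class_label, cfg = sampler_config()) {
  usable <- Filter(function(im) class_label %in% im$available_classes, images)
  if (!length(usable)) {
    warning("class ", class_label, " is not available in any image; ",
            "empty dataset")
    return(list())
  }
  do.call(c, lapply(usable, balanced_sample, class_label = class_label,
                    cfg = cfg))
}

#' Write a tile dataset to disk with a manifest
#'
#' Saves each tile's image patch and binary target as a PNG pair plus a
#' manifest CSV (`source_image_id`, `x`, `y`, `class`, `is_positive`,
#' `patch`, `target`).
#'
#' @param dataset list of `tile_sample` objects.
#' @param dir output directory.
#' @return path of the manifest CSV, invisibly.
#' @export
write_tile_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(dataset), function(i) {
    s <- dataset[[i]]
    stem <- sprintf("%s_%s_%05d", s$source_image_id, s$class_label, i)
    pp <- file.path(dir, paste0(stem, ".patch.png"))
    tp <- file.path(dir, paste0(stem, ".target.png"))
    write_image(s$patch, pp)
    write_mask(s$target, tp)
    data.frame(source_image_id = s$source_image_id, x = s$origin[["x"]],
               y = s$origin[["y"]], class = s$class_label,
               is_positive = s$is_positive, patch = basename(pp),
               target = basename(tp), stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}
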