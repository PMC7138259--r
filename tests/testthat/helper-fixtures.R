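# Shared fixtures, built in code at test time.

# A tiny annotated image with hand-placed masks: class O is a filled square,
# class P a horizontal bar crossing it (so P and O overlap).
tiny_annotated <- function(side = 32L) {
  img <- array(0.5, dim = c(side, side, 3L))
  O <- matrix(0L, side, side); O[9:20, 9:20] <- 1L
  P <- matrix(0L, side, side); P[14:16, ] <- 1L
  img[, , 1][O == 1] <- 0.7
  img[, , 1][P == 1] <- 0.3
  annotated_image(img, list(O = O, P = P), id = "tiny")
}

random_mask <- function(h = 16L, w = 16L, p = 0.3) {
  matrix(rbinom(h * w, 1L, p), h, w)
}

# Exhaustive pixel-loop metric oracle (independent of the implementation).
oracle_rates <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    p <- pred[i, j] != 0; g <- gt[i, j] != 0
    if (p && g) tp <- tp + 1L
    else if (p && !g) fp <- fp + 1L
    else if (!p && !g) tn <- tn + 1L
    else fn <- fn + 1L
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sens = if (tp + fn > 0) tp / (tp + fn) else 0,
       spec = if (tn + fp > 0) tn / (tn + fp) else 0,
       dsc = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1)
}

# Exhaustive pairwise AUC oracle: P(score+ > score-) + 0.5 P(tie).
oracle_auc <- function(scores, labels) {
  x <- scores[labels != 0]; y <- scores[labels == 0]
  if (!length(x) || !length(y)) return(NA_real_)
  cmp <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

desk_net <- function() network_config(depth = 2L, base_filters = 8L,
                                      input_size = 64L)

# Tiles whose foreground is trivially separable by intensity: bright square
# on dark background, for trainability checks.
separable_tiles <- function(n = 8L, side = 16L, seed = 99L) {
  overlapseg:::with_seed(seed, lapply(seq_len(n), function(i) {
    m <- matrix(0L, side, side)
    x0 <- sample(2:(side - 7), 1); y0 <- sample(2:(side - 7), 1)
    m[y0:(y0 + 5), x0:(x0 + 5)] <- 1L
    img <- array(0.2 + 0.02 * rnorm(side * side * 3), dim = c(side, side, 3))
    for (ch in 1:3) img[, , ch][m == 1] <- 0.8 + 0.02 * rnorm(sum(m))
    img[img < 0] <- 0; img[img > 1] <- 1
    structure(list(patch = img, target = m, class_label = "O",
                   is_positive = TRUE, origin = c(x = 0L, y = 0L),
                   source_image_id = sprintf("sep_%02d", i)),
              class = "tile_sample")
  }))
}
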