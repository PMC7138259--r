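# Small internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Deterministic 31-bit seed derived from a base seed and string context,
# so per-image/per-class draws are independent but reproducible.
derive_seed <- function(seed, ...) {
  ctx <- paste(c(...), collapse = "/")
  h <- 0
  for (v in utf8ToInt(ctx)) h <- (h * 131 + v) %% 2147480017
  as.integer((as.numeric(seed) * 48271 + h) %% 2147480017)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Quarter-turn rotations (counter-clockwise), exact for any matrix.
rot90_mat <- function(m, k = 1L) {
  k <- ((k %% 4L) + 4L) %% 4L
  if (k == 0L) return(m)
  for (i in seq_len(k)) m <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  m
}

# Separable box-ish Gaussian blur with edge replication; small sigmas only.
blur_mat <- function(m, sigma = 1) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(2 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(x, n) rbind(x[rep(1, n), , drop = FALSE], x,
                              x[rep(nrow(x), n), , drop = FALSE])
  conv1 <- function(x) {
    xp <- pad(x, r)
    out <- matrix(0, nrow(x), ncol(x))
    for (i in seq_along(k)) out <- out + k[i] * xp[i:(i + nrow(x) - 1L), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(m))))
}

is_binary_mask <- function(m) is.matrix(m) && all(m %in% c(0L, 1L, 0, 1, TRUE, FALSE))

as_mask <- function(m) {
  out <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  out
}
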