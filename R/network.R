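#' Network architecture configuration
#'
#' Describes one binary encoder-decoder (U-Net style) segmentation network.
#' Each network predicts a single structure class: its last layer emits two
#' per-pixel scores, one for the target class and one for "everything else",
#' which a two-way softmax turns into a foreground probability. Convolutions
#' are 3x3 SAME-padded so the output has the input's spatial size; each
#' encoder level applies two convolutions and a 2x2 max-pool, the decoder
#' mirrors it with 2x2 stride-2 transposed convolutions and skip
#' concatenation along the channel axis.
#'
#' @param depth number of down/up-sampling levels; the tile side must be
#'   divisible by `2^depth`.
#' @param base_filters channel count of the first encoder level; it doubles
#'   at every level below.
#' @param input_size side length (pixels) of the square input tile.
#' @param in_channels input channels (3 for RGB).
#' @return an object of class `network_config`.
#' @export
network_config <- function(depth = 4L, base_filters = 64L, input_size = 512L,
                           in_channels = 3L) {
  cfg <- list(depth = as.integer(depth), base_filters = as.integer(base_filters),
              input_size = as.integer(input_size), in_channels = as.integer(in_channels))
  if (cfg$depth < 1L) stop("depth must be >= 1")
  if (cfg$base_filters < 1L) stop("base_filters must be >= 1")
  if (cfg$input_size %% (2L^cfg$depth) != 0L)
    stop("input_size (", cfg$input_size, ") must be divisible by 2^depth (",
         2L^cfg$depth, ")")
  structure(cfg, class = "network_config")
}

# Ordered weight shapes for a given configuration. Channel plan: level i
# (1-based) carries base_filters * 2^(i-1) channels; the bottleneck doubles
# once more; the 1x1 output conv maps the first level's channels to 2 scores.
unet_weight_spec <- function(cfg) {
  D <- cfg$depth
  ch <- cfg$base_filters * 2L^(0:(D))   # ch[i] = level i, ch[D+1] = bottleneck
  spec <- list()
  cin <- cfg$in_channels
  for (i in seq_len(D)) {
    spec[[paste0("enc", i, "_conv1")]] <- c(3L, 3L, cin, ch[i])
    spec[[paste0("enc", i, "_conv2")]] <- c(3L, 3L, ch[i], ch[i])
    cin <- ch[i]
  }
  spec[["bot_conv1"]] <- c(3L, 3L, ch[D], ch[D + 1L])
  spec[["bot_conv2"]] <- c(3L, 3L, ch[D + 1L], ch[D + 1L])
  for (i in rev(seq_len(D))) {
    above <- if (i == D) ch[D + 1L] else ch[i + 1L]
    spec[[paste0("dec", i, "_up")]]    <- c(2L, 2L, above, ch[i])
    spec[[paste0("dec", i, "_conv1")]] <- c(3L, 3L, 2L * ch[i], ch[i])
    spec[[paste0("dec", i, "_conv2")]] <- c(3L, 3L, ch[i], ch[i])
  }
  spec[["out"]] <- c(1L, 1L, ch[1L], 2L)
  spec
}

#' Build a network with Glorot-initialized weights
#'
#' Weights are drawn from the Glorot (Xavier) uniform distribution,
#' `U(-l, l)` with `l = sqrt(6 / (fan_in + fan_out))` computed over the
#' kernel's receptive field; biases start at zero.
#'
#' @param cfg a [network_config()].
#' @param seed integer seed for the weight draw (reproducible builds).
#' @return an object of class `unet_params`: the configuration, a named list
#'   of weight arrays, and a global step counter.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "network_config"))
  spec <- unet_weight_spec(cfg)
  weights <- with_seed(seed, lapply(spec, function(d) {
    fan_in <- d[1] * d[2] * d[3]
    fan_out <- d[1] * d[2] * d[4]
    lim <- sqrt(6 / (fan_in + fan_out))
    list(W = array(runif(prod(d), -lim, lim), dim = d),
         b = numeric(d[4]))
  }))
  structure(list(config = cfg, weights = weights, step = 0L),
            class = "unet_params")
}

#' @export
print.unet_params <- function(x, ...) {
  np <- sum(vapply(x$weights, function(w) length(w$W) + length(w$b), 0))
  cat("<unet_params> depth", x$config$depth, "base", x$config$base_filters,
      "input", x$config$input_size, "|", length(x$weights), "layers,",
      format(np, big.mark = ","), "parameters, step", x$step, "\n")
  invisible(x)
}

n_parameters <- function(params) {
  sum(vapply(params$weights, function(w) length(w$W) + length(w$b), 0))
}

check_tile <- function(params, x) {
  if (length(dim(x)) != 3L)
    stop("input must be an H x W x channels array")
  if (dim(x)[1] != dim(x)[2])
    stop("input tiles must be square")
  if (dim(x)[3] != params$config$in_channels)
    stop("input has ", dim(x)[3], " channels, network expects ",
         params$config$in_channels)
  if (dim(x)[1] %% (2L^params$config$depth) != 0L)
    stop("tile side must be divisible by 2^depth")
  invisible(TRUE)
}

#' Forward pass: raw two-channel scores
#'
#' Runs the network on one tile or a list of tiles and returns the raw
#' pre-softmax scores; channel 1 is the target class, channel 2 the rest.
#' The output spatial size always equals the input's.
#'
#' @param params a `unet_params` object.
#' @param batch one `H x W x C` array or a list of them.
#' @return an `H x W x 2` score array, or a list of them.
#' @export
net_forward <- function(params, batch) {
  one <- function(x) {
    check_tile(params, x)
    unet_apply_cpp(params$weights, x, params$config$depth)$logits
  }
  if (is.list(batch)) lapply(batch, one) else one(batch)
}

#' Per-pixel foreground probability
#'
#' Two-way softmax over the network's output channels; returns the
#' target-class channel, a value in \[0, 1\] at every pixel.
#'
#' @inheritParams net_forward
#' @return an `H x W` probability matrix, or a list of them.
#' @export
predict_probabilities <- function(params, batch) {
  one <- function(x) {
    lg <- net_forward(params, x)
    softmax_fg(lg)
  }
  if (is.list(batch)) lapply(batch, one) else one(batch)
}

#' @export
predict.unet_params <- function(object, newdata, ...) {
  predict_probabilities(object, newdata)
}

# Numerically stable foreground softmax from an H x W x 2 score array.
softmax_fg <- function(logits) {
  a <- logits[, , 1]
  b <- logits[, , 2]
  m <- pmax(a, b)
  ea <- exp(a - m)
  ea / (ea + exp(b - m))
}

#' Save / load a network checkpoint
#'
#' A checkpoint directory holds the serialized weights, the architecture
#' configuration as YAML, and the global training-step counter, so training
#' and inference can resume from disk.
#'
#' @param params a `unet_params` object.
#' @param dir checkpoint directory (created if missing).
#' @return `save_checkpoint` returns `dir` invisibly; `load_checkpoint`
#'   returns the restored `unet_params`.
#' @export
save_checkpoint <- function(params, dir) {
  stopifnot(inherits(params, "unet_params"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(params$weights, file.path(dir, "weights.rds"))
  yaml::write_yaml(c(unclass(params$config), list(step = params$step)),
                   file.path(dir, "network.yaml"))
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "network.yaml"))
  cfg <- network_config(meta$depth, meta$base_filters, meta$input_size,
                        meta$in_channels)
  structure(list(config = cfg,
                 weights = readRDS(file.path(dir, "weights.rds")),
                 step = as.integer(meta$step)),
            class = "unet_params")
}
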