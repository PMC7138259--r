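#' Training configuration
#'
#' Hyperparameters for one per-class training run. Defaults are the
#' full-scale values: Adam at learning rate 1e-5 with a staircase decay
#' multiplying by 0.9 every 10,000 optimizer steps, L2 weight factor
#' lambda = 0.001, a fixed stop at 1000 epochs, and batch size 3 (class P
#' used batch size 1 at full scale, exposed via per-class overrides in the
#' pipeline config). There is no early stopping and no best-on-test weight
#' selection: the final epoch's weights are returned, because selecting
#' weights on the evaluation data would bias the reported metrics.
#'
#' @param lr0 initial learning rate.
#' @param decay_rate multiplicative staircase decay factor.
#' @param decay_every steps per staircase stair.
#' @param lambda_l2 L2 regularization weight (convolution kernels only,
#'   biases are not penalized).
#' @param epochs fixed number of training epochs.
#' @param batch_size tiles per optimizer step.
#' @param seed seed controlling initialization, shuffling and augmentation.
#' @return an object of class `train_config`.
#' @export
train_config <- function(lr0 = 1e-5, decay_rate = 0.9, decay_every = 10000L,
                         lambda_l2 = 0.001, epochs = 1000L, batch_size = 3L,
                         seed = 1L) {
  cfg <- list(lr0 = lr0, decay_rate = decay_rate,
              decay_every = as.integer(decay_every), lambda_l2 = lambda_l2,
              epochs = as.integer(epochs), batch_size = as.integer(batch_size),
              seed = as.integer(seed))
  if (cfg$lr0 <= 0 || cfg$decay_rate <= 0 || cfg$decay_every < 1)
    stop("learning-rate parameters must be positive")
  if (cfg$lambda_l2 < 0) stop("lambda_l2 must be >= 0")
  if (cfg$epochs < 1) stop("epochs must be >= 1")
  if (cfg$batch_size < 1) stop("batch_size must be >= 1")
  structure(cfg, class = "train_config")
}

#' Pixel-wise batch weighting coefficients
#'
#' For a batch K, each of the two labels l (target class and "everything
#' else") gets weight `r_lK = c_K / c_lK`, where `c_K` is the total pixel
#' count of the batch and `c_lK` the count of pixels carrying label l. Both
#' labels therefore contribute the same total weight to the loss
#' (`r_fg * c_fg = r_bg * c_bg = c_K`), which counteracts the foreground /
#' background imbalance inside every batch. A label absent from the batch
#' gets weight 0 and raises a degenerate-batch flag.
#'
#' @param targets a 0/1 matrix, a list of them, or an `H x W x N` array —
#'   the target masks of one batch.
#' @return list with `c_K`, `c_fg`, `c_bg`, `r_fg`, `r_bg`, `degenerate`.
#' @export
compute_batch_weights <- function(targets) {
  if (is.list(targets)) {
    if (!length(targets)) stop("empty batch")
    c_K <- sum(vapply(targets, length, 0))
    c_fg <- sum(vapply(targets, function(m) sum(m != 0), 0))
  } else {
    if (!length(targets)) stop("empty batch")
    c_K <- length(targets)
    c_fg <- sum(targets != 0)
  }
  c_bg <- c_K - c_fg
  list(c_K = c_K, c_fg = c_fg, c_bg = c_bg,
       r_fg = if (c_fg > 0) c_K / c_fg else 0,
       r_bg = if (c_bg > 0) c_K / c_bg else 0,
       degenerate = (c_fg == 0 || c_bg == 0))
}

#' Batch-weighted softmax cross-entropy with L2 penalty
#'
#' The training objective: the per-pixel two-way softmax cross-entropy,
#' weighted by the batch coefficient of the pixel's ground-truth label and
#' summed (not averaged) over all pixels of the batch, plus
#' `lambda * sum(w^2)` over the convolution kernels. This is the reference
#' (pure R) implementation; the training loop evaluates the identical
#' quantity in compiled code.
#'
#' @param scores an `H x W x 2` score array or a list of them (channel 1 =
#'   target class, channel 2 = rest).
#' @param targets 0/1 matrix or list matching `scores`.
#' @param weights batch weights from [compute_batch_weights()]; defaults to
#'   computing them from `targets`.
#' @param lambda_l2 L2 weight; requires `params` when nonzero.
#' @param params a `unet_params` whose kernels enter the penalty.
#' @param reduction `"sum"` (default, the training objective) or `"mean"`.
#' @return scalar loss.
#' @export
weighted_loss <- function(scores, targets, weights = NULL, lambda_l2 = 0,
                          params = NULL, reduction = c("sum", "mean")) {
  reduction <- match.arg(reduction)
  if (!is.list(scores)) { scores <- list(scores); targets <- list(targets) }
  if (!is.list(targets)) targets <- list(targets)
  weights <- weights %||% compute_batch_weights(targets)
  total <- 0; npix <- 0
  for (k in seq_along(scores)) {
    lg <- scores[[k]]
    if (any(!is.finite(lg))) stop("non-finite scores in batch element ", k)
    tg <- targets[[k]] != 0
    a <- lg[, , 1]; b <- lg[, , 2]
    m <- pmax(a, b)
    logZ <- m + log(exp(a - m) + exp(b - m))
    ce <- ifelse(tg, logZ - a, logZ - b)
    r <- ifelse(tg, weights$r_fg, weights$r_bg)
    total <- total + sum(r * ce)
    npix <- npix + length(tg)
  }
  if (reduction == "mean") total <- total / npix
  if (lambda_l2 > 0) {
    if (is.null(params)) stop("params required when lambda_l2 > 0")
    total <- total + lambda_l2 *
      sum(vapply(params$weights, function(w) sum(w$W^2), 0))
  }
  total
}

#' Staircase learning-rate schedule
#'
#' `lr = lr0 * decay_rate^floor(step / decay_every)`: constant within each
#' stair, dropping by the decay factor at every `decay_every`-th step.
#'
#' @param step global optimizer step (0-based).
#' @param cfg a [train_config()].
#' @return the learning rate at `step`.
#' @export
staircase_lr <- function(step, cfg) {
  stopifnot(all(step >= 0))
  cfg$lr0 * cfg$decay_rate^(step %/% cfg$decay_every)
}

# ---- Adam ----

adam_init <- function(weights) {
  zero_like <- function(w) list(W = array(0, dim = dim(w$W)),
                                b = numeric(length(w$b)))
  list(m = lapply(weights, zero_like), v = lapply(weights, zero_like), t = 0L)
}

adam_step <- function(weights, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (k in seq_along(weights)) {
    for (f in c("W", "b")) {
      g <- grads[[k]][[f]]
      state$m[[k]][[f]] <- beta1 * state$m[[k]][[f]] + (1 - beta1) * g
      state$v[[k]][[f]] <- beta2 * state$v[[k]][[f]] + (1 - beta2) * g^2
      weights[[k]][[f]] <- weights[[k]][[f]] -
        lr * (state$m[[k]][[f]] / bc1) / (sqrt(state$v[[k]][[f]] / bc2) + eps)
    }
  }
  list(weights = weights, state = state)
}

add_grads <- function(acc, g) {
  if (is.null(acc)) return(g)
  for (k in seq_along(acc)) {
    acc[[k]]$W <- acc[[k]]$W + g[[k]]$W
    acc[[k]]$b <- acc[[k]]$b + g[[k]]$b
  }
  acc
}

#' Train one class-specific network
#'
#' Runs the fixed-epoch training loop: per-epoch seeded shuffling, optional
#' per-sample augmentation, pixel-wise batch weighting recomputed for every
#' batch, the summed weighted cross-entropy plus L2 objective, and Adam
#' updates at the staircase learning rate. Training always runs the full
#' `cfg$epochs` and returns the final-epoch weights — there is no
#' best-on-test selection (see [train_config()]).
#'
#' @param dataset non-empty list of `tile_sample` objects (one class).
#' @param cfg a [train_config()].
#' @param net_cfg a [network_config()]; its `input_size` must match the
#'   tiles.
#' @param aug_cfg an [augment_config()] or `NULL` to disable augmentation.
#' @param eval_set optional list of `tile_sample`s monitored (loss and pixel
#'   accuracy at threshold 0.5) every `eval_every` epochs; never used for
#'   weight selection.
#' @param eval_every epochs between monitoring passes.
#' @param verbose print a line every 25 epochs.
#' @return list with `params` (trained `unet_params`) and `history` (list of
#'   data.frames `steps` and `epochs`).
#' @export
train_class_network <- function(dataset, cfg, net_cfg, aug_cfg = NULL,
                                eval_set = NULL, eval_every = 10L,
                                verbose = FALSE) {
  if (!length(dataset)) stop("dataset is empty")
  n <- length(dataset)
  tile_dim <- dim(dataset[[1]]$patch)[1]
  if (tile_dim != net_cfg$input_size)
    stop("tile size ", tile_dim, " does not match network input_size ",
         net_cfg$input_size)

  params <- build_network(net_cfg, seed = cfg$seed)
  adam <- adam_init(params$weights)
  step <- 0L
  step_log <- vector("list", 0)
  epoch_log <- vector("list", cfg$epochs)

  with_seed(cfg$seed + 1L, {
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      batches <- split(perm, ceiling(seq_along(perm) / cfg$batch_size))
      epoch_loss <- 0
      for (bi in seq_along(batches)) {
        idx <- batches[[bi]]
        pats <- vector("list", length(idx))
        tgts <- vector("list", length(idx))
        for (j in seq_along(idx)) {
          s <- dataset[[idx[j]]]
          if (!is.null(aug_cfg)) {
            ap <- augment_pair(s$patch, s$target, aug_cfg)
            pats[[j]] <- ap$patch; tgts[[j]] <- ap$mask
          } else {
            pats[[j]] <- s$patch; tgts[[j]] <- s$target
          }
        }
        bw <- compute_batch_weights(tgts)
        loss <- 0; grads <- NULL
        for (j in seq_along(idx)) {
          res <- unet_apply_cpp(params$weights, pats[[j]], net_cfg$depth,
                                tgts[[j]], bw$r_fg, bw$r_bg, TRUE)
          loss <- loss + res$loss
          grads <- add_grads(grads, res$grads)
        }
        if (cfg$lambda_l2 > 0) {
          loss <- loss + cfg$lambda_l2 *
            sum(vapply(params$weights, function(w) sum(w$W^2), 0))
          for (k in seq_along(grads))
            grads[[k]]$W <- grads[[k]]$W + 2 * cfg$lambda_l2 * params$weights[[k]]$W
        }
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch, ", batch ", bi,
               " (step ", step, ")")
        lr <- staircase_lr(step, cfg)
        upd <- adam_step(params$weights, grads, adam, lr)
        params$weights <- upd$weights
        adam <- upd$state
        step <- step + 1L
        epoch_loss <- epoch_loss + loss
        step_log[[length(step_log) + 1L]] <-
          data.frame(step = step, epoch = epoch, lr = lr, loss = loss)
      }
      ep_row <- data.frame(epoch = epoch,
                           train_loss = epoch_loss / length(batches),
                           test_loss = NA_real_, test_accuracy = NA_real_)
      if (!is.null(eval_set) &&
          (epoch %% eval_every == 0L || epoch == cfg$epochs)) {
        ev <- monitor_eval(params, eval_set, net_cfg)
        ep_row$test_loss <- ev$loss
        ep_row$test_accuracy <- ev$accuracy
      }
      epoch_log[[epoch]] <- ep_row
      if (verbose && (epoch %% 25L == 0L || epoch == 1L))
        message(sprintf("epoch %4d  loss %.2f  lr %.2e",
                        epoch, ep_row$train_loss, staircase_lr(step - 1L, cfg)))
    }
  })
  params$step <- step
  list(params = params,
       history = list(steps = do.call(rbind, step_log),
                      epochs = do.call(rbind, epoch_log)))
}

# Monitoring pass: weighted loss over the evaluation set (treated as one
# batch) and pixel accuracy at threshold 0.5.
monitor_eval <- function(params, eval_set, net_cfg) {
  tgts <- lapply(eval_set, function(s) s$target)
  bw <- compute_batch_weights(tgts)
  loss <- 0; correct <- 0; total <- 0
  for (s in eval_set) {
    res <- unet_apply_cpp(params$weights, s$patch, net_cfg$depth,
                          s$target, bw$r_fg, bw$r_bg, FALSE)
    loss <- loss + res$loss
    p <- softmax_fg(res$logits)
    correct <- correct + sum((p > 0.5) == (s$target != 0))
    total <- total + length(p)
  }
  list(loss = loss, accuracy = correct / total)
}
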