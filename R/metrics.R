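#' Pixel-wise confusion counts
#'
#' @param pred_mask,gt_mask 0/1 matrices of equal dimensions.
#' @return list with `tp`, `fp`, `tn`, `fn`; the four counts always sum to
#'   the number of evaluated pixels.
#' @export
confusion <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("prediction and ground truth dimensions differ")
  p <- pred_mask != 0
  g <- gt_mask != 0
  list(tp = sum(p & g), fp = sum(p & !g), tn = sum(!p & !g), fn = sum(!p & g))
}

#' Sensitivity, specificity and Dice score from confusion counts
#'
#' Sensitivity (true positive rate, recall) is `tp / (tp + fn)`; specificity
#' (true negative rate) is `tn / (tn + fp)`; the Dice score (DSC, F1) is
#' `2 tp / (2 tp + fp + fn)`, ranging from 0 (no overlap) to 1 (complete
#' overlap). When a rate's denominator is zero the value 0 is returned with
#' attribute `undefined = TRUE` — except Dice with both masks empty, which
#' returns 1 with attribute `both_empty = TRUE` (nothing to find, nothing
#' found). Evaluation reports handle the absent-class convention separately
#' (see [evaluate_frame()]).
#'
#' @param counts confusion counts from [confusion()].
#' @return scalar rate in \[0, 1\].
#' @export
sensitivity <- function(counts) {
  d <- counts$tp + counts$fn
  if (d == 0) return(structure(0, undefined = TRUE))
  counts$tp / d
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  d <- counts$tn + counts$fp
  if (d == 0) return(structure(0, undefined = TRUE))
  counts$tn / d
}

#' @rdname sensitivity
#' @export
dsc <- function(counts) {
  d <- 2 * counts$tp + counts$fp + counts$fn
  if (d == 0) return(structure(1, both_empty = TRUE))
  2 * counts$tp / d
}

as_prob_label <- function(prob, gt) {
  p <- if (inherits(prob, "probability_map")) prob$prob else prob
  list(scores = as.vector(p), labels = as.vector(gt != 0))
}

#' ROC curve of a probability map against ground truth
#'
#' Sweeps the threshold over the distinct predicted values (plus sentinels
#' above the maximum and below the minimum) and returns the false/true
#' positive rate at each, monotone non-decreasing in both axes. If the
#' ground truth lacks positive or negative pixels the curve is degenerate:
#' the two sentinel points are returned with attribute `degenerate = TRUE`
#' and the AUC is undefined.
#'
#' @param prob a `probability_map` or numeric matrix/vector of scores.
#' @param gt 0/1 matrix/vector of the same length.
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(prob, gt) {
  pl <- as_prob_label(prob, gt)
  scores <- pl$scores; labels <- pl$labels
  stopifnot(length(scores) == length(labels))
  m <- sum(labels); n <- sum(!labels)
  if (m == 0 || n == 0) {
    return(structure(data.frame(threshold = c(Inf, -Inf),
                                fpr = c(0, 1), tpr = c(0, 1)),
                     degenerate = TRUE))
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  # cut after the last element of each distinct score
  last <- c(s[-1] != s[-length(s)], TRUE)
  ctp <- cumsum(l)[last]
  cfp <- cumsum(!l)[last]
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, cfp / n),
             tpr = c(0, ctp / m))
}

#' Area under the ROC curve
#'
#' Trapezoidal integral of the ROC; equal (to numerical precision) to the
#' Mann-Whitney statistic: the probability that a random positive pixel
#' scores higher than a random negative one, counting ties as 1/2.
#'
#' @param curve a data.frame from [roc_curve()].
#' @return scalar AUC, or `NA` for a degenerate curve.
#' @export
auc <- function(curve) {
  if (isTRUE(attr(curve, "degenerate"))) return(NA_real_)
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + tail(curve$tpr, -1)) / 2)
}

# Mann-Whitney AUC via midranks (O(n log n)); also used by the DeLong CI.
auc_mw <- function(scores, labels) {
  m <- sum(labels); n <- sum(!labels)
  if (m == 0 || n == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - m * (m + 1) / 2) / (m * n)
}

#' AUC confidence interval
#'
#' The default method is DeLong's variance estimate for the Mann-Whitney
#' AUC (placement-value variances of the positive and negative score sets),
#' with a normal-quantile interval clipped to \[0, 1\]. Pixels are treated
#' as exchangeable observations — no spatial-correlation correction — so
#' with full-frame pixel counts the intervals are extremely tight. A seeded
#' stratified bootstrap is available as an alternative.
#'
#' @param prob a `probability_map`, matrix or vector of scores.
#' @param gt 0/1 ground truth of matching size.
#' @param level confidence level (default 0.95).
#' @param method `"delong"` or `"bootstrap"`.
#' @param n_boot bootstrap resamples (bootstrap method only).
#' @param seed seed for the bootstrap draw.
#' @return list with `auc`, `lo`, `hi`, `method`; `NA`s when the ground
#'   truth is degenerate.
#' @export
auc_ci <- function(prob, gt, level = 0.95, method = c("delong", "bootstrap"),
                   n_boot = 1000L, seed = 1L) {
  method <- match.arg(method)
  pl <- as_prob_label(prob, gt)
  scores <- pl$scores; labels <- pl$labels
  m <- sum(labels); n <- sum(!labels)
  if (m == 0 || n == 0)
    return(list(auc = NA_real_, lo = NA_real_, hi = NA_real_, method = method))
  a <- auc_mw(scores, labels)
  if (method == "delong") {
    x <- scores[labels]; y <- scores[!labels]
    r_all <- rank(c(x, y), ties.method = "average")
    v10 <- (r_all[seq_len(m)] - rank(x, ties.method = "average")) / n
    v01 <- 1 - (r_all[m + seq_len(n)] - rank(y, ties.method = "average")) / m
    se <- sqrt(var(v10) / m + var(v01) / n)
    z <- qnorm(1 - (1 - level) / 2)
    list(auc = a, lo = max(0, a - z * se), hi = min(1, a + z * se),
         method = "delong")
  } else {
    pos_i <- which(labels); neg_i <- which(!labels)
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
      bi <- c(sample(pos_i, m, replace = TRUE),
              sample(neg_i, n, replace = TRUE))
      auc_mw(scores[bi], labels[bi])
    }, 0))
    qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    list(auc = a, lo = qs[1], hi = qs[2], method = "bootstrap")
  }
}

#' Four-color pixel classification error image
#'
#' Color key: true positive white, true negative blue, false positive
#' black, false negative red.
#'
#' @param pred_mask,gt_mask 0/1 matrices of equal dimensions.
#' @return `H x W x 3` numeric array in \[0, 1\].
#' @export
error_overlay <- function(pred_mask, gt_mask) {
  if (!identical(dim(pred_mask), dim(gt_mask)))
    stop("prediction and ground truth dimensions differ")
  p <- pred_mask != 0; g <- gt_mask != 0
  H <- nrow(p); W <- ncol(p)
  out <- array(0, dim = c(H, W, 3))
  r <- matrix(0, H, W); gg <- matrix(0, H, W); b <- matrix(0, H, W)
  tp <- p & g; tn <- !p & !g; fn <- !p & g
  r[tp] <- 1; gg[tp] <- 1; b[tp] <- 1   # white
  b[tn] <- 1                            # blue
  r[fn] <- 1                            # red; false positive stays black
  out[, , 1] <- r; out[, , 2] <- gg; out[, , 3] <- b
  out
}

#' Absolute-error heat overlay on the original image
#'
#' Blends a green-to-red correctness shading (`green` = correctly
#' classified, `red` = wrong, proportional to `|probability - truth|`) over
#' the base image.
#'
#' @param prob a `probability_map` or probability matrix.
#' @param gt_mask 0/1 ground-truth matrix.
#' @param base_image `H x W x 3` array in \[0, 1\].
#' @param alpha overlay opacity.
#' @return `H x W x 3` numeric array in \[0, 1\].
#' @export
error_heatmap <- function(prob, gt_mask, base_image, alpha = 0.5) {
  p <- if (inherits(prob, "probability_map")) prob$prob else prob
  err <- abs(p - (gt_mask != 0))
  H <- nrow(err); W <- ncol(err)
  shade <- array(0, dim = c(H, W, 3))
  shade[, , 1] <- err
  shade[, , 2] <- 1 - err
  clip01((1 - alpha) * base_image + alpha * shade)
}

#' Evaluate per-class probability maps against a frame's ground truth
#'
#' For each class with a probability map and an available mask: confusion
#' counts at the operating threshold, sensitivity, specificity, Dice, and
#' AUC with its confidence interval. Classes absent from the ground truth
#' (no foreground pixels) follow the reporting convention of the original
#' evaluation tables: sensitivity 0.0 and Dice 0.0, AUC undefined, with the
#' machine-readable `class_absent` flag set so downstream users can exclude
#' those rows.
#'
#' @param prob_maps named list (class short label -> `probability_map` or
#'   probability matrix).
#' @param annotated an [annotated_image()] carrying the ground-truth masks.
#' @param threshold operating point in \[0, 1\] (default 0.5).
#' @param schema a [label_schema()].
#' @param ci_method passed to [auc_ci()].
#' @return data.frame with one row per evaluated class: `class`,
#'   `sensitivity`, `specificity`, `dsc`, `auc`, `auc_lo`, `auc_hi`,
#'   `threshold`, `class_absent`.
#' @export
evaluate_frame <- function(prob_maps, annotated, threshold = 0.5,
                           schema = default_schema(), ci_method = "delong") {
  unknown <- setdiff(names(prob_maps), schema_labels(schema))
  if (length(unknown))
    stop("probability maps for unknown class(es): ",
         paste(unknown, collapse = ", "))
  labs <- intersect(schema_labels(schema),
                    intersect(names(prob_maps), annotated$available_classes))
  rows <- lapply(labs, function(lab) {
    gt <- annotated$masks[[lab]]
    pm <- prob_maps[[lab]]
    pred <- binarize(pm, threshold)
    cc <- confusion(pred, gt)
    absent <- sum(gt != 0) == 0
    ci <- auc_ci(pm, gt, method = ci_method)
    data.frame(class = lab,
               sensitivity = if (absent) 0 else as.numeric(sensitivity(cc)),
               specificity = as.numeric(specificity(cc)),
               dsc = if (absent) 0 else as.numeric(dsc(cc)),
               auc = ci$auc, auc_lo = ci$lo, auc_hi = ci$hi,
               threshold = threshold, class_absent = absent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read an evaluation report
#'
#' Serializes the report both as JSON (one object per class) and as a CSV
#' twin; [read_report()] restores the data.frame from the JSON.
#'
#' @param report data.frame from [evaluate_frame()].
#' @param json_path,csv_path output paths (`NULL` to skip one format).
#' @return `json_path` (or `csv_path`), invisibly.
#' @export
write_report <- function(report, json_path, csv_path = NULL) {
  if (!is.null(json_path)) {
    keys <- if ("frame" %in% names(report))
      paste(report$class, report$frame, sep = ".") else report$class
    obj <- lapply(seq_len(nrow(report)), function(i)
      as.list(report[i, setdiff(names(report), "class")]))
    names(obj) <- keys
    jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv_path)) write.csv(report, csv_path, row.names = FALSE)
  invisible(json_path %||% csv_path)
}

#' @rdname write_report
#' @export
read_report <- function(json_path) {
  obj <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  rows <- lapply(names(obj), function(key) {
    rec <- lapply(obj[[key]], function(v) if (is.null(v)) NA else v)
    lab <- if (!is.null(rec$frame))
      sub(paste0("\\.", rec$frame, "$"), "", key) else key
    cbind(data.frame(class = lab, stringsAsFactors = FALSE),
          as.data.frame(rec, stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
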