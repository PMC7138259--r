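test_that("confusion counts match hand counts and partition the pixels", {
  gt <- matrix(0L, 3, 3); gt[1, 1:2] <- 1L; gt[2, 1:2] <- 1L        # 4 fg
  pred <- matrix(0L, 3, 3); pred[1, 1:2] <- 1L; pred[3, 3] <- 1L    # 2 hit + 1 extra
  cc <- confusion(pred, gt)
  expect_equal(cc, list(tp = 2L, fp = 1L, tn = 4L, fn = 2L))
  expect_equal(sensitivity(cc), 0.5, ignore_attr = TRUE)
  expect_equal(specificity(cc), 0.8, ignore_attr = TRUE)
  expect_equal(dsc(cc), 4 / 7, ignore_attr = TRUE)
  # perfect and inverted predictions
  expect_equal(confusion(gt, gt)$fp + confusion(gt, gt)$fn, 0L)
  inv <- 1L - gt
  cci <- confusion(inv, gt)
  expect_equal(cci$tp + cci$tn, 0L)
  expect_error(confusion(matrix(0, 2, 2), matrix(0, 3, 3)), "dimensions")
})

test_that("rates and Dice agree with the pixel-loop oracle on random masks", {
  set.seed(101)
  for (rep in 1:300) {
    pred <- random_mask(16, 16, runif(1))
    gt <- random_mask(16, 16, runif(1))
    o <- oracle_rates(pred, gt)
    cc <- confusion(pred, gt)
    expect_identical(cc[c("tp", "fp", "tn", "fn")],
                     o[c("tp", "fp", "tn", "fn")])
    expect_equal(as.numeric(sensitivity(cc)), o$sens)
    expect_equal(as.numeric(specificity(cc)), o$spec)
    expect_equal(as.numeric(dsc(cc)), o$dsc)
  }
})

test_that("degenerate masks follow the documented conventions", {
  empty <- matrix(0L, 4, 4)
  some <- matrix(c(1L, rep(0L, 15)), 4, 4)
  # class absent, no positive predictions: sens 0 (flagged), spec 1
  cc <- confusion(empty, empty)
  expect_equal(as.numeric(sensitivity(cc)), 0)
  expect_true(attr(sensitivity(cc), "undefined"))
  expect_equal(as.numeric(specificity(cc)), 1)
  expect_true(attr(dsc(cc), "both_empty"))
  expect_equal(as.numeric(dsc(cc)), 1)
  # disjoint non-empty masks: Dice 0
  a <- matrix(0L, 4, 4); a[1, 1] <- 1L
  b <- matrix(0L, 4, 4); b[4, 4] <- 1L
  expect_equal(as.numeric(dsc(confusion(a, b))), 0)
  expect_equal(as.numeric(dsc(confusion(some, some))), 1)
})

test_that("Dice equals the harmonic precision/recall identity", {
  set.seed(103)
  for (rep in 1:50) {
    pred <- random_mask(12, 12, runif(1, 0.2, 0.8))
    gt <- random_mask(12, 12, runif(1, 0.2, 0.8))
    cc <- confusion(pred, gt)
    if (cc$tp + cc$fp == 0 || cc$tp + cc$fn == 0) next
    prec <- cc$tp / (cc$tp + cc$fp)
    rec <- cc$tp / (cc$tp + cc$fn)
    if (prec + rec == 0) next
    expect_equal(as.numeric(dsc(cc)), 2 * prec * rec / (prec + rec),
                 tolerance = 1e-12)
  }
})

test_that("ROC curves are monotone, bounded, and AUC matches the pair oracle", {
  set.seed(104)
  for (rep in 1:100) {
    # coarse score grid to force ties
    scores <- matrix(sample(seq(0, 1, 0.1), 64, replace = TRUE), 8, 8)
    gt <- random_mask(8, 8, runif(1, 0.2, 0.8))
    if (sum(gt) == 0 || sum(gt) == 64) next
    curve <- roc_curve(scores, gt)
    expect_true(all(diff(curve$fpr) >= 0))
    expect_true(all(diff(curve$tpr) >= 0))
    expect_true(all(curve$fpr >= 0 & curve$fpr <= 1))
    expect_true(all(curve$tpr >= 0 & curve$tpr <= 1))
    expect_equal(curve$fpr[nrow(curve)], 1)
    expect_equal(curve$tpr[nrow(curve)], 1)
    a <- auc(curve)
    expect_equal(a, oracle_auc(scores, gt), tolerance = 1e-12)
    expect_equal(overlapseg:::auc_mw(as.vector(scores), as.vector(gt) != 0),
                 a, tolerance = 1e-12)
    # complement symmetry
    expect_equal(auc(roc_curve(1 - scores, gt)), 1 - a, tolerance = 1e-12)
  }
})

test_that("3 vs 3 toy with one tie reproduces the exhaustive pair probability", {
  scores <- c(0.9, 0.8, 0.5, 0.5, 0.3, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  a <- auc(roc_curve(scores, labels))
  expect_equal(a, oracle_auc(scores, labels))
  expect_equal(a, (3 + 3 + 2.5) / 9)  # hand enumeration of the 9 pairs
})

test_that("perfect separation and constant scores hit the AUC extremes", {
  gt <- matrix(c(rep(1L, 8), rep(0L, 8)), 4, 4)
  perfect <- matrix(c(rep(0.9, 8), rep(0.1, 8)), 4, 4)
  curve <- roc_curve(perfect, gt)
  expect_equal(auc(curve), 1)
  expect_true(any(curve$fpr == 0 & curve$tpr == 1))
  flat <- matrix(0.5, 4, 4)
  expect_equal(auc(roc_curve(flat, gt)), 0.5)
  # degenerate ground truth is flagged and AUC undefined
  dg <- roc_curve(perfect, matrix(1L, 4, 4))
  expect_true(attr(dg, "degenerate"))
  expect_true(is.na(auc(dg)))
})

test_that("ROC and AUC are invariant under strictly monotone transforms", {
  set.seed(105)
  scores <- matrix(runif(100), 10, 10)
  gt <- random_mask(10, 10, 0.4)
  a0 <- auc(roc_curve(scores, gt))
  expect_equal(auc(roc_curve(scores^3, gt)), a0, tolerance = 1e-12)
  expect_equal(auc(roc_curve(log(scores + 1), gt)), a0, tolerance = 1e-12)
  expect_equal(auc(roc_curve(plogis(5 * scores), gt)), a0, tolerance = 1e-12)
})

test_that("DeLong intervals agree with the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(106)
  for (rep in 1:5) {
    n <- 400
    labels <- rbinom(n, 1, 0.4)
    scores <- labels * rnorm(n, 0.6, 0.3) + (1 - labels) * rnorm(n, 0.4, 0.3)
    ours <- auc_ci(matrix(scores, 20, 20), matrix(labels, 20, 20))
    ref <- suppressMessages(
      pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE), method = "delong"))
    expect_equal(ours$auc, as.numeric(ref[2]), tolerance = 1e-10)
    expect_equal(ours$lo, max(0, as.numeric(ref[1])), tolerance = 1e-8)
    expect_equal(ours$hi, min(1, as.numeric(ref[3])), tolerance = 1e-8)
  }
})

test_that("bootstrap intervals bracket the AUC and are seed-stable", {
  set.seed(107)
  labels <- rbinom(200, 1, 0.5)
  scores <- labels * rnorm(200, 0.7, 0.25) + (1 - labels) * rnorm(200, 0.3, 0.25)
  a <- auc_ci(scores, labels, method = "bootstrap", n_boot = 200, seed = 5)
  b <- auc_ci(scores, labels, method = "bootstrap", n_boot = 200, seed = 5)
  expect_identical(a, b)
  expect_lte(a$lo, a$auc)
  expect_gte(a$hi, a$auc)
})

test_that("error overlays use the four-color key and tally with confusion", {
  set.seed(108)
  pred <- random_mask(12, 12, 0.4)
  gt <- random_mask(12, 12, 0.4)
  ov <- error_overlay(pred, gt)
  cc <- confusion(pred, gt)
  is_col <- function(r, g, b)
    sum(ov[, , 1] == r & ov[, , 2] == g & ov[, , 3] == b)
  expect_equal(is_col(1, 1, 1), cc$tp)  # white
  expect_equal(is_col(0, 0, 1), cc$tn)  # blue
  expect_equal(is_col(0, 0, 0), cc$fp)  # black
  expect_equal(is_col(1, 0, 0), cc$fn)  # red
  # identical masks: only white and blue remain
  ov2 <- error_overlay(gt, gt)
  expect_equal(is_col2 <- sum(ov2[, , 1] == 0 & ov2[, , 3] == 0), 0)
  # empty prediction: red wherever gt, blue elsewhere
  ov3 <- error_overlay(matrix(0L, 12, 12), gt)
  expect_equal(sum(ov3[, , 1] == 1 & ov3[, , 2] == 0), sum(gt))
  base <- array(0.5, dim = c(12, 12, 3))
  hm <- error_heatmap(matrix(0.5, 12, 12), gt, base)
  expect_true(all(hm >= 0 & hm <= 1))
})

test_that("frame evaluation applies the absent-class reporting convention", {
  side <- 32L
  gtO <- matrix(0L, side, side); gtO[5:12, 5:12] <- 1L
  ann <- annotated_image(array(0.5, dim = c(side, side, 3)),
                         list(O = gtO, P = matrix(0L, side, side)))
  probs <- list(O = ifelse(gtO == 1, 0.9, 0.1),
                P = matrix(0.1, side, side))
  rep <- evaluate_frame(probs, ann, threshold = 0.5)
  rO <- rep[rep$class == "O", ]
  expect_equal(rO$sensitivity, 1)
  expect_equal(rO$dsc, 1)
  expect_equal(rO$auc, 1)
  expect_false(rO$class_absent)
  rP <- rep[rep$class == "P", ]
  expect_true(rP$class_absent)
  expect_equal(rP$sensitivity, 0)
  expect_equal(rP$dsc, 0)
  expect_equal(rP$specificity, 1)
  expect_true(is.na(rP$auc))
  expect_error(evaluate_frame(list(ZZ = probs$O), ann), "unknown")
})

test_that("reports round-trip through JSON and CSV", {
  side <- 16L
  gt <- matrix(0L, side, side); gt[3:8, 3:8] <- 1L
  ann <- annotated_image(array(0.5, dim = c(side, side, 3)), list(O = gt))
  rep <- evaluate_frame(list(O = ifelse(gt == 1, 0.8, 0.2)), ann)
  jp <- withr::local_tempfile(fileext = ".json")
  cp <- withr::local_tempfile(fileext = ".csv")
  write_report(rep, jp, cp)
  back <- read_report(jp)
  for (col in c("sensitivity", "specificity", "dsc", "auc", "threshold"))
    expect_equal(back[[col]], rep[[col]], tolerance = 1e-12)
  expect_equal(back$class, rep$class)
  expect_equal(nrow(read.csv(cp)), nrow(rep))
})
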