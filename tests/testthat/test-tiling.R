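test_that("scan grid is clamped so the last origin touches the border", {
  # 1392 wide, 512 tile, stride 256: origins 0, 256, 512, then 880 (clamped)
  expect_identical(overlapseg:::scan_positions(1392L, 512L, 256L),
                   c(0L, 256L, 512L, 880L))
  expect_identical(overlapseg:::scan_positions(1040L, 512L, 256L),
                   c(0L, 256L, 528L))
  # stride dividing evenly needs no clamp
  expect_identical(overlapseg:::scan_positions(256L, 64L, 64L),
                   c(0L, 64L, 128L, 192L))
})

test_that("candidate enumeration matches a brute-force footprint scan", {
  ann <- generate_phantom(phantom_config(seed = 31), id = "p")
  cfg <- sampler_config(tile_size = 64, stride = 48, seed = 1)
  cand <- enumerate_candidates(ann, "O", cfg)
  # at min_positive_pixels = 1 every origin is either positive or negative
  xs <- overlapseg:::scan_positions(256L, 64L, 48L)
  expect_equal(nrow(cand$positives) + nrow(cand$negatives), length(xs)^2)
  m <- ann$masks$O
  for (k in seq_len(min(10, nrow(cand$positives)))) {
    x <- cand$positives$x[k]; y <- cand$positives$y[k]
    expect_gte(sum(m[(y + 1):(y + 64), (x + 1):(x + 64)]), 1)
  }
  for (k in seq_len(min(10, nrow(cand$negatives)))) {
    x <- cand$negatives$x[k]; y <- cand$negatives$y[k]
    expect_equal(sum(m[(y + 1):(y + 64), (x + 1):(x + 64)]), 0)
  }
})

test_that("a full-coverage mask makes every origin positive, an empty mask none", {
  side <- 128L
  img <- array(0.5, dim = c(side, side, 3))
  full <- annotated_image(img, list(O = matrix(1L, side, side)))
  cfg <- sampler_config(tile_size = 64, stride = 32, seed = 1)
  cand <- enumerate_candidates(full, "O", cfg)
  expect_equal(nrow(cand$negatives), 0)
  expect_equal(nrow(cand$positives), 9)  # 3x3 stride grid
  empty <- annotated_image(img, list(O = matrix(0L, side, side)))
  cand2 <- enumerate_candidates(empty, "O", cfg)
  expect_equal(nrow(cand2$positives), 0)
})

test_that("balanced sampling respects the positive cap and matches negatives", {
  # single spheroid on a desk frame: well over 20 positive candidates
  ph <- generate_phantom(phantom_config(n_spheroids = 1, n_vessels = 0,
                                        n_cells = 0, n_invasive = 0,
                                        seed = 77))
  cfg <- sampler_config(tile_size = 64, max_positive = 20, stride = 16,
                        seed = 9)
  cand <- enumerate_candidates(ph, "O", cfg)
  expect_gt(nrow(cand$positives), 20)
  expect_gt(nrow(cand$negatives), 20)
  ds <- balanced_sample(ph, "O", cfg)
  expect_length(ds, 40)
  expect_equal(sum(vapply(ds, function(s) s$is_positive, TRUE)), 20)
  # fewer positives than the cap: take all, same number of negatives
  cfg5 <- sampler_config(tile_size = 64, max_positive = 20, stride = 96,
                         seed = 9)
  cand5 <- enumerate_candidates(ph, "O", cfg5)
  stopifnot(nrow(cand5$positives) < 20)
  ds5 <- balanced_sample(ph, "O", cfg5)
  expect_length(ds5, 2 * nrow(cand5$positives))
})

test_that("a class absent from the frame contributes nothing", {
  img <- array(0.5, dim = c(128, 128, 3))
  ann <- annotated_image(img, list(O = matrix(0L, 128, 128)))
  cfg <- sampler_config(tile_size = 64, stride = 32, seed = 2)
  expect_length(balanced_sample(ann, "O", cfg), 0)
  expect_error(balanced_sample(ann, "P", cfg), "not available")
})

test_that("negative shortfall takes all negatives and warns", {
  side <- 128L
  m <- matrix(1L, side, side); m[1:40, 1:40] <- 0L
  ann <- annotated_image(array(0.5, dim = c(side, side, 3)), list(O = m))
  cfg <- sampler_config(tile_size = 64, max_positive = 8, stride = 16, seed = 3)
  cand <- enumerate_candidates(ann, "O", cfg)
  stopifnot(nrow(cand$negatives) == 0)  # no 64x64 window avoids the mask
  expect_warning(ds <- balanced_sample(ann, "O", cfg), "negative")
  expect_equal(sum(vapply(ds, function(s) s$is_positive, TRUE)), 8)
  expect_equal(sum(!vapply(ds, function(s) s$is_positive, TRUE)), 0)
})

test_that("sample labels agree with their target masks and origins are valid", {
  frames <- generate_phantom_dataset(phantom_config(), 2, seed = 55)$frames
  cfg <- sampler_config(tile_size = 64, max_positive = 6, stride = 32,
                        seed = 10)
  for (lab in c("O", "P", "S")) {
    # class P can run short of negatives on vessel-dense frames; the
    # shortfall warning is asserted in its own test above
    ds <- suppressWarnings(build_class_dataset(frames, lab, cfg))
    cands <- lapply(frames, enumerate_candidates, class_label = lab, cfg = cfg)
    names(cands) <- vapply(frames, function(f) f$id, "")
    seen <- character()
    for (s in ds) {
      expect_identical(s$is_positive, sum(s$target) >= 1)
      expect_identical(dim(s$target), c(64L, 64L))
      # selected origin is one of the enumerated candidates
      pool <- if (s$is_positive) cands[[s$source_image_id]]$positives
              else cands[[s$source_image_id]]$negatives
      expect_true(any(pool$x == s$origin[["x"]] & pool$y == s$origin[["y"]]))
      key <- paste(s$source_image_id, s$class_label, s$is_positive,
                   s$origin[["x"]], s$origin[["y"]])
      expect_false(key %in% seen)  # no duplicate draw within a frame/class
      seen <- c(seen, key)
    }
  }
})

test_that("dataset building is deterministic and order-stable", {
  frames <- generate_phantom_dataset(phantom_config(), 2, seed = 56)$frames
  cfg <- sampler_config(tile_size = 64, max_positive = 4, stride = 32,
                        seed = 11)
  d1 <- build_class_dataset(frames, "O", cfg)
  d2 <- build_class_dataset(frames, "O", cfg)
  expect_identical(d1, d2)
  cfg2 <- sampler_config(tile_size = 64, max_positive = 4, stride = 32,
                         seed = 12)
  d3 <- build_class_dataset(frames, "O", cfg2)
  expect_false(identical(lapply(d1, `[[`, "origin"),
                         lapply(d3, `[[`, "origin")))
})

test_that("tile datasets round-trip through disk with a manifest", {
  frames <- generate_phantom_dataset(phantom_config(), 1, seed = 57)$frames
  cfg <- sampler_config(tile_size = 64, max_positive = 3, stride = 32,
                        seed = 13)
  ds <- build_class_dataset(frames, "O", cfg)
  dir <- withr::local_tempdir()
  mp <- write_tile_dataset(ds, dir)
  man <- read.csv(mp)
  expect_equal(nrow(man), length(ds))
  tg <- read_mask(file.path(dir, man$target[1]))
  expect_identical(tg, ds[[1]]$target)
})
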