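#' Phantom generator configuration
#'
#' The phantom generator renders full frames that mimic the *statistical*
#' structure of phase-contrast cell-culture images — semitransparent,
#' mutually overlapping structure classes on a noisy background — without
#' attempting photorealism. Per frame it draws:
#' \itemize{
#'   \item \strong{P} — curvilinear vascular tubes as smoothed random walks
#'     with a dark tube profile;
#'   \item \strong{O} — spheroids: bright disks with darker rims;
#'   \item \strong{R} — a granular-texture halo (annulus) around each spheroid;
#'   \item \strong{IP} — short radial spikes rooted on spheroid rims;
#'   \item \strong{S} — small bright elliptical cells scattered anywhere,
#'     a fraction deliberately seeded on top of vessels so P and S overlap;
#'   \item \strong{I} — elongated dark spindles aligned along vessels, shape-
#'     and intensity-similar to P so the two classes are genuinely confusable.
#' }
#' Intensities are chosen so classes are separable by shape and texture but
#' not by a single global threshold. All randomness flows from `seed`.
#'
#' @param frame_size `c(width, height)` in pixels. The `"full"` preset is
#'   1392 x 1040 (full-frame microscope resolution), the `"desk"` preset
#'   256 x 256 for CPU-scale runs.
#' @param n_vessels,n_cells,n_invasive,n_spheroids structure counts per frame.
#' @param spike_density spikes per spheroid.
#' @param halo_width width (pixels) of the perispheroid matter annulus.
#' @param noise_level standard deviation of the additive background noise
#'   (intensity units, range 0-1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param preset `"desk"` or `"full"`; explicit arguments override preset
#'   values.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(preset = c("desk", "full"), frame_size = NULL,
                           n_vessels = NULL, n_cells = NULL,
                           n_invasive = NULL, n_spheroids = NULL,
                           spike_density = NULL, halo_width = NULL,
                           noise_level = 0.03, seed = NULL) {
  preset <- match.arg(preset)
  def <- if (preset == "desk") {
    list(frame_size = c(256L, 256L), n_vessels = 3L, n_cells = 25L,
         n_invasive = 6L, n_spheroids = 3L, spike_density = 8L,
         halo_width = 10L)
  } else {
    list(frame_size = c(1392L, 1040L), n_vessels = 12L, n_cells = 150L,
         n_invasive = 30L, n_spheroids = 8L, spike_density = 8L,
         halo_width = 18L)
  }
  cfg <- list(
    frame_size = as.integer(frame_size %||% def$frame_size),
    n_vessels = as.integer(n_vessels %||% def$n_vessels),
    n_cells = as.integer(n_cells %||% def$n_cells),
    n_invasive = as.integer(n_invasive %||% def$n_invasive),
    n_spheroids = as.integer(n_spheroids %||% def$n_spheroids),
    spike_density = as.integer(spike_density %||% def$spike_density),
    halo_width = as.integer(halo_width %||% def$halo_width),
    noise_level = noise_level,
    seed = seed)
  if (any(unlist(cfg[c("n_vessels", "n_cells", "n_invasive", "n_spheroids",
                       "spike_density")]) < 0))
    stop("structure counts must be >= 0")
  # largest structure: spheroid (radius up to 0.12 * min side) plus halo
  min_side <- min(cfg$frame_size)
  if (cfg$n_spheroids > 0 && 2 * (0.12 * min_side + cfg$halo_width + 2) >= min_side)
    stop("frame too small to hold a spheroid with halo_width = ", cfg$halo_width)
  structure(cfg, class = "phantom_config")
}

# ---- geometry stamps (linear pixel indices into an H x W matrix) ----

stamp_disk <- function(H, W, cx, cy, r) {
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(integer())
  dx <- rep(xs - cx, each = length(ys))
  dy <- rep(ys - cy, times = length(xs))
  ii <- rep(ys, times = length(xs))
  jj <- rep(xs, each = length(ys))
  keep <- dx * dx + dy * dy <= r * r
  (jj[keep] - 1L) * H + ii[keep]
}

stamp_annulus <- function(H, W, cx, cy, r0, r1) {
  setdiff(stamp_disk(H, W, cx, cy, r1), stamp_disk(H, W, cx, cy, r0))
}

stamp_ellipse <- function(H, W, cx, cy, a, b, theta) {
  r <- max(a, b)
  xs <- max(1L, floor(cx - r)):min(W, ceiling(cx + r))
  ys <- max(1L, floor(cy - r)):min(H, ceiling(cy + r))
  if (!length(xs) || !length(ys)) return(integer())
  dx <- rep(xs - cx, each = length(ys))
  dy <- rep(ys - cy, times = length(xs))
  ii <- rep(ys, times = length(xs))
  jj <- rep(xs, each = length(ys))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  keep <- (u / a)^2 + (v / b)^2 <= 1
  (jj[keep] - 1L) * H + ii[keep]
}

stamp_segment <- function(H, W, x0, y0, x1, y1, thickness) {
  n <- max(2L, ceiling(sqrt((x1 - x0)^2 + (y1 - y0)^2)) * 2L)
  t <- seq(0, 1, length.out = n)
  px <- x0 + t * (x1 - x0)
  py <- y0 + t * (y1 - y0)
  unique(unlist(lapply(seq_len(n), function(k)
    stamp_disk(H, W, px[k], py[k], thickness))))
}

# Random-walk vessel path with border reflection; returns points + headings.
vessel_path <- function(H, W, n_steps, wobble = 0.12) {
  x <- runif(1, W * 0.1, W * 0.9)
  y <- runif(1, H * 0.1, H * 0.9)
  ang <- runif(1, 0, 2 * pi)
  px <- numeric(n_steps); py <- numeric(n_steps); pa <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    ang <- ang + rnorm(1, 0, wobble)
    x <- x + cos(ang); y <- y + sin(ang)
    if (x < 2) { x <- 2; ang <- pi - ang }
    if (x > W - 1) { x <- W - 1; ang <- pi - ang }
    if (y < 2) { y <- 2; ang <- -ang }
    if (y > H - 1) { y <- H - 1; ang <- -ang }
    px[k] <- x; py[k] <- y; pa[k] <- ang
  }
  list(x = px, y = py, ang = pa)
}

#' Generate one phantom frame with per-class ground truth
#'
#' Rendering order is P, O, R, IP, S, I; masks record the exact stamped
#' geometry per class, so overlaps between classes are preserved in the
#' masks even where a later structure repaints the intensity canvas.
#'
#' @param cfg a [phantom_config()].
#' @param id image identifier for the resulting [annotated_image()].
#' @return an `annotated_image` with all six class masks.
#' @export
#' @examples
#' ph <- generate_phantom(phantom_config(seed = 1))
#' mask_stats(ph)
generate_phantom <- function(cfg = phantom_config(), id = "phantom") {
  stopifnot(inherits(cfg, "phantom_config"))
  with_seed(cfg$seed, {
    W <- cfg$frame_size[1]; H <- cfg$frame_size[2]
    canvas <- matrix(0.45, H, W)
    masks <- lapply(stats::setNames(vector("list", 6),
                                    c("P", "S", "I", "IP", "O", "R")),
                    function(.) matrix(0L, H, W))

    # illumination gradient (mild, random orientation)
    gdir <- runif(1, 0, 2 * pi)
    gx <- matrix(rep(seq_len(W) / W - 0.5, each = H), H, W)
    gy <- matrix(rep(seq_len(H) / H - 0.5, times = W), H, W)
    canvas <- canvas + 0.04 * (cos(gdir) * gx + sin(gdir) * gy)

    # --- P: vascular tubes ---
    vessel_pts <- list()
    for (v in seq_len(cfg$n_vessels)) {
      path <- vessel_path(H, W, n_steps = round(2.2 * max(H, W)))
      vessel_pts[[v]] <- path
      th <- runif(1, 2.2, 4)
      px_idx <- unique(unlist(lapply(seq_along(path$x), function(k)
        stamp_disk(H, W, path$x[k], path$y[k], th))))
      masks$P[px_idx] <- 1L
      canvas[px_idx] <- canvas[px_idx] - 0.15
    }

    # --- O: spheroids (bright disks, dark rims) + R halo + IP spikes ---
    for (s in seq_len(cfg$n_spheroids)) {
      r <- runif(1, 0.07, 0.12) * min(H, W)
      margin <- r + cfg$halo_width + 2
      cx <- runif(1, margin, W - margin)
      cy <- runif(1, margin, H - margin)
      interior <- stamp_disk(H, W, cx, cy, r)
      rim <- stamp_annulus(H, W, cx, cy, r - 3, r)
      masks$O[interior] <- 1L
      canvas[interior] <- canvas[interior] + 0.18 +
        rnorm(length(interior), 0, 0.05)
      canvas[rim] <- canvas[rim] - 0.25

      halo <- stamp_annulus(H, W, cx, cy, r, r + cfg$halo_width)
      masks$R[halo] <- 1L
      speck <- rbinom(length(halo), 1, 0.45)
      canvas[halo] <- canvas[halo] + 0.15 * speck

      for (k in seq_len(cfg$spike_density)) {
        a <- runif(1, 0, 2 * pi)
        len <- runif(1, 6, 14)
        seg <- stamp_segment(H, W,
                             cx + (r - 1) * cos(a), cy + (r - 1) * sin(a),
                             cx + (r + len) * cos(a), cy + (r + len) * sin(a),
                             thickness = runif(1, 1, 1.8))
        masks$IP[seg] <- 1L
        canvas[seg] <- canvas[seg] - 0.3
      }
    }

    # --- S: small bright cells; ~30% seeded on vessels to force P/S overlap ---
    n_on_vessel <- if (cfg$n_vessels > 0) floor(cfg$n_cells * 0.3) else 0L
    vp_all <- if (length(vessel_pts))
      do.call(rbind, lapply(vessel_pts, function(p) cbind(p$x, p$y)))
    else NULL
    for (c in seq_len(cfg$n_cells)) {
      if (c <= n_on_vessel && !is.null(vp_all)) {
        k <- sample(nrow(vp_all), 1)
        cx <- vp_all[k, 1]; cy <- vp_all[k, 2]
      } else {
        cx <- runif(1, 3, W - 2); cy <- runif(1, 3, H - 2)
      }
      ell <- stamp_ellipse(H, W, cx, cy, runif(1, 3.5, 7), runif(1, 2.5, 5),
                           runif(1, 0, pi))
      masks$S[ell] <- 1L
      canvas[ell] <- canvas[ell] + 0.15
    }

    # --- I: dark spindles along vessels (confusable with P by design) ---
    for (c in seq_len(cfg$n_invasive)) {
      if (!is.null(vp_all)) {
        k <- sample(length(vessel_pts), 1)
        j <- sample(length(vessel_pts[[k]]$x), 1)
        cx <- vessel_pts[[k]]$x[j]; cy <- vessel_pts[[k]]$y[j]
        theta <- vessel_pts[[k]]$ang[j] + rnorm(1, 0, 0.2)
      } else {
        cx <- runif(1, 10, W - 9); cy <- runif(1, 10, H - 9)
        theta <- runif(1, 0, pi)
      }
      ell <- stamp_ellipse(H, W, cx, cy, runif(1, 8, 14), runif(1, 2, 3), theta)
      masks$I[ell] <- 1L
      canvas[ell] <- canvas[ell] - 0.12
    }

    canvas <- blur_mat(canvas, 0.7)
    canvas <- canvas + matrix(rnorm(H * W, 0, cfg$noise_level), H, W)
    canvas <- clip01(canvas)
    img <- array(rep(canvas, 3L), dim = c(H, W, 3L)) +
      array(rnorm(H * W * 3L, 0, 0.005), dim = c(H, W, 3L))
    out <- annotated_image(clip01(img), masks, id = id)
    attr(out, "phantom_config") <- cfg
    out
  })
}

#' Generate a phantom dataset with a reproducibility manifest
#'
#' Draws `n_frames` phantoms with per-frame seeds derived deterministically
#' from `seed`, so any frame (or the whole set) can be regenerated exactly
#' from the manifest. Disjoint base seeds give disjoint frame sets, which is
#' how train and test frames are kept separate.
#'
#' @param cfg a [phantom_config()]; its own `seed` field is ignored here.
#' @param n_frames number of frames (>= 1).
#' @param seed base seed for the per-frame seed derivation.
#' @param prefix id prefix for the frames.
#' @return list with `frames` (list of `annotated_image`) and `manifest`
#'   (data.frame of frame ids, seeds, and generator parameters).
#' @export
generate_phantom_dataset <- function(cfg = phantom_config(), n_frames, seed = 1L,
                                     prefix = "phantom") {
  stopifnot(n_frames >= 1)
  ids <- sprintf("%s_%03d", prefix, seq_len(n_frames))
  seeds <- vapply(ids, function(id) derive_seed(seed, "phantom", id), 0L)
  frames <- lapply(seq_len(n_frames), function(i) {
    ci <- cfg; ci$seed <- seeds[i]
    generate_phantom(ci, id = ids[i])
  })
  manifest <- data.frame(id = ids, seed = seeds,
                         width = cfg$frame_size[1], height = cfg$frame_size[2],
                         n_vessels = cfg$n_vessels, n_cells = cfg$n_cells,
                         n_invasive = cfg$n_invasive,
                         n_spheroids = cfg$n_spheroids,
                         spike_density = cfg$spike_density,
                         halo_width = cfg$halo_width,
                         noise_level = cfg$noise_level,
                         stringsAsFactors = FALSE)
  list(frames = frames, manifest = manifest)
}
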