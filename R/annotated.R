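#' Annotated image: one frame plus per-class binary masks
#'
#' The multilabel container used throughout the pipeline: an intensity frame
#' and zero or more per-class binary masks of identical size. Masks may
#' overlap arbitrarily (no exclusivity constraint). A class without a mask is
#' simply unavailable for this image — it is excluded from sampling and
#' evaluation rather than treated as all-background, which accommodates
#' frames whose annotations do not cover every class.
#'
#' @param image `H x W x 3` numeric array in \[0, 1\] (a matrix is replicated
#'   to three channels).
#' @param masks named list of 0/1 matrices, names are schema short labels.
#' @param schema a [label_schema()] used to validate mask names.
#' @param id optional image identifier string.
#' @return an object of class `annotated_image` with fields `image`, `masks`,
#'   `available_classes`, `id`.
#' @export
annotated_image <- function(image, masks = list(), schema = default_schema(),
                            id = "image") {
  if (is.matrix(image)) image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  stopifnot(length(dim(image)) == 3L, dim(image)[3] == 3L)
  hw <- dim(image)[1:2]
  if (length(masks)) {
    if (is.null(names(masks)) || any(names(masks) == ""))
      stop("masks must be a named list keyed by class short label")
    unknown <- setdiff(names(masks), schema_labels(schema))
    if (length(unknown))
      stop("unknown class label(s): ", paste(unknown, collapse = ", "))
    for (lab in names(masks)) {
      m <- masks[[lab]]
      if (!is.matrix(m) || !identical(dim(m), hw))
        stop("mask for class ", lab, " has dimensions ",
             paste(dim(m), collapse = "x"), " but the image is ",
             paste(hw, collapse = "x"))
      masks[[lab]] <- as_mask(m)
    }
  }
  structure(list(image = image, masks = masks,
                 available_classes = names(masks) %||% character(),
                 id = id),
            class = "annotated_image")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.annotated_image <- function(x, ...) {
  cat("<annotated_image>", x$id, paste(dim(x$image)[1:2], collapse = "x"),
      "| classes:",
      if (length(x$available_classes)) paste(x$available_classes, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Load an annotated image from files
#'
#' Reads the intensity frame and one binary mask file per class. Mask files
#' are binarized on load (any nonzero pixel is foreground). The available
#' classes are exactly the keys of `mask_paths`.
#'
#' @param image_path path to the frame (PNG/TIFF, 8-bit, RGB or grayscale).
#' @param mask_paths named character vector or list, class short label ->
#'   mask file path.
#' @param schema a [label_schema()].
#' @param id image identifier (defaults to the file stem).
#' @return an `annotated_image`.
#' @export
load_annotated_image <- function(image_path, mask_paths = list(),
                                 schema = default_schema(), id = NULL) {
  img <- read_image(image_path)
  masks <- lapply(as.list(mask_paths), read_mask)
  annotated_image(img, masks, schema,
                  id = id %||% tools::file_path_sans_ext(basename(image_path)))
}

#' Save an annotated image's frame and masks
#'
#' Writes `<stem>.png` plus one `<stem>.<label>.png` mask file per available
#' class; the inverse of [load_annotated_image()].
#'
#' @param annotated an `annotated_image`.
#' @param dir output directory.
#' @param stem file stem (defaults to the image id).
#' @return named list of written paths, invisibly.
#' @export
save_annotated_image <- function(annotated, dir, stem = NULL) {
  stem <- stem %||% annotated$id
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(image = file.path(dir, paste0(stem, ".png")))
  write_image(annotated$image, paths$image)
  for (lab in annotated$available_classes) {
    p <- file.path(dir, mask_filename(stem, lab))
    write_mask(annotated$masks[[lab]], p)
    paths[[lab]] <- p
  }
  invisible(paths)
}

#' Composite color overlay of the class masks
#'
#' Paints each class's display color over its mask pixels, starting from a
#' uniform background-color canvas, in the given stacking order: later
#' classes occlude earlier ones. The overlay is for visualization only — it
#' is lossy wherever classes overlap and is never parsed back as ground
#' truth.
#'
#' @param annotated an `annotated_image`.
#' @param schema a [label_schema()].
#' @param order stacking order, a permutation of the available classes
#'   (default: schema order restricted to available classes).
#' @return `H x W x 3` numeric array in \[0, 1\].
#' @export
composite_overlay <- function(annotated, schema = default_schema(),
                              order = NULL) {
  avail <- annotated$available_classes
  order <- order %||% intersect(schema_labels(schema), avail)
  if (!setequal(order, avail) || length(order) != length(avail))
    stop("order must be a permutation of the available classes")
  hw <- dim(annotated$image)[1:2]
  out <- array(rep(schema$background_color / 255, each = prod(hw)),
               dim = c(hw, 3L))
  for (lab in order) {
    col <- schema_color(schema, lab) / 255
    idx <- annotated$masks[[lab]] != 0
    for (ch in 1:3) {
      plane <- out[, , ch]
      plane[idx] <- col[ch]
      out[, , ch] <- plane
    }
  }
  out
}

#' Per-class foreground pixel counts
#'
#' @param annotated an `annotated_image`.
#' @return named integer vector, one count per available class.
#' @export
mask_stats <- function(annotated) {
  vapply(annotated$masks, function(m) sum(m != 0), 0L)
}
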