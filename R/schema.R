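#' Multilabel class schema for cell-culture structures
#'
#' The segmentation problem has six foreground structure classes plus the
#' background. Structures in phase-contrast images are semitransparent and
#' may overlap, so the classes are mutually non-exclusive: ground truth is
#' kept as one binary mask per class, and the composite color image is only
#' a derived visualization. The fixed class order (P, S, I, IP, O, R) makes
#' reports comparable across runs.
#'
#' Default display colors: green background; vascular structures blue (P);
#' noninvasively growing cells red (S); invasive cells white (I); invasive
#' spikes black (IP); spheroids light blue (O); perispheroid cell matter
#' yellow (R). Colors must be unique within a schema (background included)
#' so overlays are unambiguous.
#'
#' @param classes a data.frame with columns `short_label`, `name`, `r`, `g`,
#'   `b` (8-bit per channel), or `NULL` for the default six-class schema.
#' @param background_color length-3 RGB vector (8-bit).
#' @return an object of class `label_schema`.
#' @export
#' @examples
#' sch <- label_schema()
#' sch$classes$short_label
label_schema <- function(classes = NULL, background_color = c(0L, 255L, 0L)) {
  if (is.null(classes)) {
    classes <- data.frame(
      short_label = c("P", "S", "I", "IP", "O", "R"),
      name = c("vascular structures", "noninvasive cells", "invasive cells",
               "invasive spikes", "spheroids", "perispheroid cell matter"),
      r = c(0L, 255L, 255L,   0L, 120L, 255L),
      g = c(0L,   0L, 255L,   0L, 200L, 255L),
      b = c(255L,  0L, 255L,  0L, 255L,   0L),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(classes),
            all(c("short_label", "name", "r", "g", "b") %in% names(classes)))
  if (anyDuplicated(classes$short_label))
    stop("short_label values must be unique within a schema")
  cols <- rbind(as.matrix(classes[, c("r", "g", "b")]),
                matrix(background_color, nrow = 1))
  if (anyDuplicated(cols))
    stop("class colors (background included) must be unique within a schema")
  if (any(cols < 0) || any(cols > 255)) stop("colors must be 8-bit (0-255)")
  structure(list(classes = classes,
                 background_color = as.integer(background_color)),
            class = "label_schema")
}

#' @rdname label_schema
#' @export
default_schema <- function() label_schema()

#' @export
print.label_schema <- function(x, ...) {
  cat("<label_schema>", nrow(x$classes), "foreground classes + background\n")
  print(x$classes, row.names = FALSE)
  cat("background color:", paste(x$background_color, collapse = ","), "\n")
  invisible(x)
}

schema_labels <- function(schema) schema$classes$short_label

schema_color <- function(schema, label) {
  i <- match(label, schema$classes$short_label)
  if (is.na(i)) stop("unknown class label: ", label)
  as.integer(schema$classes[i, c("r", "g", "b")])
}

#' Read or write a schema as YAML
#'
#' The YAML layout maps each short label to its long name and RGB color,
#' plus a `background` color entry; class order in the file is preserved.
#'
#' @param path file path.
#' @param schema a `label_schema` (for writing).
#' @return `schema_from_yaml` returns a `label_schema`.
#' @export
schema_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cl <- y$classes
  classes <- data.frame(
    short_label = names(cl),
    name = unname(vapply(cl, function(e) e$name, "")),
    r = unname(vapply(cl, function(e) as.integer(e$color[1]), 0L)),
    g = unname(vapply(cl, function(e) as.integer(e$color[2]), 0L)),
    b = unname(vapply(cl, function(e) as.integer(e$color[3]), 0L)),
    stringsAsFactors = FALSE)
  rownames(classes) <- NULL
  label_schema(classes, as.integer(y$background))
}

#' @rdname schema_from_yaml
#' @export
schema_to_yaml <- function(schema, path) {
  cl <- lapply(seq_len(nrow(schema$classes)), function(i) {
    list(name = schema$classes$name[i],
         color = as.integer(schema$classes[i, c("r", "g", "b")]))
  })
  names(cl) <- schema$classes$short_label
  yaml::write_yaml(list(background = schema$background_color, classes = cl),
                   path)
  invisible(path)
}
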