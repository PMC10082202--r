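# ---------------------------------------------------------------------------
# Training-label construction: expert dot annotations cross-validated against
# segmentation regions to produce labelled bounding boxes.
# ---------------------------------------------------------------------------

#' Fuse dot annotations with segmentation regions into labelled boxes
#'
#' Dots are first put in canonical order (by y, then x), so the result does
#' not depend on input ordering. A dot falling inside a segmented region
#' yields that region's bounding box with the dot's label; when a region
#' contains several dots, the first (lowest y, then x) takes the region box
#' and the rest get empirical-diameter boxes, so every dot yields exactly
#' one box and counts stay truthful. Dots outside every region get a square
#' box of the empirical cell diameter centered on them (side `s`:
#' `x_min = round(x - s/2)`, `x_max = x_min + s`), clipped to the image.
#'
#' @param dots data.frame `x, y, label` (0-based pixel coordinates; optional
#'   `annotator_id`).
#' @param regions integer label matrix (0 = background), e.g. from
#'   [segment_events()].
#' @param empirical_diameter_px named per-class box side in pixels (defaults:
#'   mCTC 65, CAF 87 — 15 and 20 um at 0.23 um/px).
#' @return boxes data.frame `x_min, y_min, x_max, y_max, label, score,
#'   area_px, source` with `source` one of `"region"` / `"empirical"`;
#'   exactly one row per dot.
#' @export
fuse_annotations <- function(dots, regions,
                             empirical_diameter_px = c(mCTC = 65, CAF = 87)) {
  nr <- nrow(regions); nc <- ncol(regions)
  if (nrow(dots) == 0)
    return(data.frame(x_min = integer(), y_min = integer(), x_max = integer(),
                      y_max = integer(), label = character(), score = numeric(),
                      area_px = integer(), source = character(),
                      stringsAsFactors = FALSE))
  if (any(dots$x < 0 | dots$x >= nc | dots$y < 0 | dots$y >= nr))
    stop("coordinate error: annotation dot outside the image")
  dots <- dots[order(dots$y, dots$x), , drop = FALSE]

  st <- .region_stats(regions, list())
  reg_at <- regions[cbind(floor(dots$y) + 1L, floor(dots$x) + 1L)]

  emp_box <- function(x, y, label) {
    s <- empirical_diameter_px[[label]]
    if (is.null(s) || is.na(s)) stop("no empirical diameter for class ", label)
    x0 <- round(x - s / 2); y0 <- round(y - s / 2)
    c(x_min = max(0, x0), y_min = max(0, y0),
      x_max = min(nc, x0 + s), y_max = min(nr, y0 + s))
  }

  seen <- integer(0)
  out <- vector("list", nrow(dots))
  for (k in seq_len(nrow(dots))) {
    rid <- reg_at[k]
    if (rid > 0 && !(rid %in% seen)) {
      seen <- c(seen, rid)
      s <- st[st$id == rid, ]
      out[[k]] <- data.frame(x_min = s$x_min, y_min = s$y_min,
                             x_max = s$x_max, y_max = s$y_max,
                             label = dots$label[k], score = 1,
                             area_px = s$area_px, source = "region",
                             stringsAsFactors = FALSE)
    } else {
      b <- emp_box(dots$x[k], dots$y[k], dots$label[k])
      out[[k]] <- data.frame(x_min = b[["x_min"]], y_min = b[["y_min"]],
                             x_max = b[["x_max"]], y_max = b[["y_max"]],
                             label = dots$label[k], score = 1,
                             area_px = (b[["x_max"]] - b[["x_min"]]) *
                               (b[["y_max"]] - b[["y_min"]]),
                             source = "empirical", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Remove boxes touching the image border
#'
#' Cells only partially visible in a field of view are excluded from
#' annotation and testing; a box lying within `margin_px` of any border is
#' dropped.
#'
#' @param boxes detections-style data.frame.
#' @param image_shape `c(rows, cols)`.
#' @param margin_px border margin (0 = drop only boxes actually touching).
#' @return filtered data.frame.
#' @export
boundary_filter <- function(boxes, image_shape, margin_px = 0) {
  if (nrow(boxes) == 0) return(boxes)
  keep <- boxes$x_min > margin_px & boxes$y_min > margin_px &
    boxes$x_max < image_shape[2] - margin_px &
    boxes$y_max < image_shape[1] - margin_px
  out <- boxes[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read dot annotations
#'
#' Accepts the CSV schema `x, y, label` or a point-annotation JSON export
#' (a list of objects with `x`, `y` and a class/label field) as produced by
#' common slide-annotation tools.
#'
#' @param path CSV or JSON file.
#' @return data.frame `x, y, label`.
#' @export
read_dots <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    js <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.data.frame(js)) {
      lab <- js[["label"]]
      if (is.null(lab)) lab <- js[["class"]]
      if (is.null(lab) && !is.null(js$properties)) lab <- js$properties$classification
      data.frame(x = js$x, y = js$y, label = lab, stringsAsFactors = FALSE)
    } else stop("unrecognised annotation JSON layout")
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("x", "y", "label") %in% names(df)))
    df[, c("x", "y", "label")]
  }
}
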