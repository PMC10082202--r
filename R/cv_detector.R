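# ---------------------------------------------------------------------------
# Rule-based (conventional computer vision) mCTC/CAF detector: per-channel
# binarization, distance-transform watershed segmentation, size filtering,
# and cross-channel marker logic with hollow-pore rejection.
# ---------------------------------------------------------------------------

#' Detector parameters for the rule-based pipeline
#'
#' All thresholds an observer would tune are explicit configuration. Size
#' bounds default to a minimum cell diameter of 8 um at 0.23 um/px
#' (min area about 950 px^2) with the maximum 40x that; the watershed seed
#' separation defaults to 0.6x the expected cell diameter.
#'
#' @param thresholds named per-channel binarization: a number in [0, 1] or
#'   `"otsu"`.
#' @param min_area_px,max_area_px inclusive region-area bounds (px^2).
#' @param dapi_mean_min minimum mean DAPI intensity inside a marker region
#'   for it to count as nucleated (rejects hollow pores).
#' @param negative_mean_max maximum mean intensity tolerated in the opposite
#'   marker channel (CK-on-CAF / FAP-on-mCTC ceiling).
#' @param watershed_min_distance_px minimum seed separation when splitting
#'   touching cells.
#' @param score_norm mean positive-marker intensity at which the heuristic
#'   confidence score saturates at 1.
#' @return object of class `detector_params`.
#' @export
detector_params <- function(thresholds = list(DAPI = "otsu", CK = "otsu", FAP = "otsu"),
                            min_area_px = 950, max_area_px = 40 * 950,
                            dapi_mean_min = 0.15, negative_mean_max = 0.10,
                            watershed_min_distance_px = 39,
                            score_norm = 0.8) {
  if (min_area_px <= 0 || max_area_px <= min_area_px)
    stop("need 0 < min_area_px < max_area_px")
  stopifnot(dapi_mean_min >= 0, dapi_mean_min <= 1,
            negative_mean_max >= 0, negative_mean_max <= 1)
  structure(list(thresholds = thresholds, min_area_px = min_area_px,
                 max_area_px = max_area_px, dapi_mean_min = dapi_mean_min,
                 negative_mean_max = negative_mean_max,
                 watershed_min_distance_px = watershed_min_distance_px,
                 score_norm = score_norm),
            class = "detector_params")
}

#' Binarize one channel
#'
#' Threshold at an absolute level, or derive it by Otsu's method. A
#' near-constant image (no bimodal histogram to split) yields an empty mask.
#'
#' @param img numeric matrix in [0, 1].
#' @param threshold_spec number in [0, 1] or `"otsu"`.
#' @return logical matrix, `img > t`.
#' @export
binarize_channel <- function(img, threshold_spec = "otsu") {
  if (identical(threshold_spec, "otsu")) {
    if (diff(range(img)) < 1e-3)
      return(matrix(FALSE, nrow(img), ncol(img)))
    t <- EBImage::otsu(EBImage::Image(img), range = c(0, 1), levels = 256)
  } else {
    t <- as.numeric(threshold_spec)
  }
  img > t
}

#' Segment positive events by distance-transform watershed
#'
#' Seeds are local maxima of the Euclidean distance transform separated by
#' at least `min_distance_px`, so touching cells split while lone discs stay
#' whole.
#'
#' @param mask logical matrix.
#' @param min_distance_px minimum seed separation (pixels).
#' @return integer label matrix (0 = background).
#' @export
segment_events <- function(mask, min_distance_px = 39) {
  m <- matrix(as.numeric(mask), nrow(mask), ncol(mask))
  if (!any(m > 0)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(EBImage::Image(m))
  w <- EBImage::watershed(dm, tolerance = 1,
                          ext = max(1L, as.integer(round(min_distance_px / 2))))
  matrix(as.integer(EBImage::imageData(w)), nrow(mask), ncol(mask))
}

#' Filter segmented regions by area
#'
#' Keeps regions with `min_area_px <= area <= max_area_px` (both ends
#' inclusive); survivors are relabelled consecutively.
#'
#' @param labels integer label matrix.
#' @param min_area_px,max_area_px inclusive bounds.
#' @return relabelled integer label matrix.
#' @export
size_filter <- function(labels, min_area_px, max_area_px) {
  if (!any(labels > 0)) return(labels)
  areas <- tabulate(labels[labels > 0])
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  lut <- integer(length(areas))
  lut[keep] <- seq_along(keep)
  out <- labels
  out[labels > 0] <- lut[labels[labels > 0]]
  out
}

# per-region mean of `img` and bounding box, for label ids >= 1
.region_stats <- function(labels, imgs) {
  ids <- sort(unique(labels[labels > 0]))
  if (!length(ids)) return(NULL)
  pix <- which(labels > 0, arr.ind = TRUE)
  lab <- labels[labels > 0]
  fac <- factor(lab, levels = ids)
  out <- data.frame(id = ids,
                    area_px = as.integer(table(fac)),
                    y_min = tapply(pix[, 1], fac, min) - 1L,
                    y_max = tapply(pix[, 1], fac, max),
                    x_min = tapply(pix[, 2], fac, min) - 1L,
                    x_max = tapply(pix[, 2], fac, max))
  for (nm in names(imgs))
    out[[paste0("mean_", nm)]] <- as.numeric(tapply(imgs[[nm]][labels > 0], fac, mean))
  rownames(out) <- NULL
  out
}

#' Classify segmented marker regions into cells
#'
#' A CK region is accepted as an mCTC if its mean DAPI intensity reaches
#' `dapi_mean_min` (nucleated — this rejects hollow filter pores) and its
#' mean FAP intensity stays at or below `negative_mean_max`; the symmetric
#' rule accepts FAP regions as CAFs. The box is the region bounding box and
#' the heuristic confidence score is the mean positive-marker intensity
#' scaled by `score_norm` and capped at 1.
#'
#' @param labels_ck,labels_fap label matrices of the CK / FAP channels.
#' @param dapi_img,ck_img,fap_img aligned channel images.
#' @param params a `detector_params`.
#' @return detections data.frame
#'   (`x_min, y_min, x_max, y_max, label, score, area_px`), boxes 0-based
#'   half-open.
#' @export
classify_events <- function(labels_ck, labels_fap, dapi_img, ck_img, fap_img,
                            params = detector_params()) {
  if (!all(dim(labels_ck) == dim(dapi_img)) ||
      !all(dim(labels_fap) == dim(dapi_img)) ||
      !all(dim(ck_img) == dim(dapi_img)) || !all(dim(fap_img) == dim(dapi_img)))
    stop("alignment error: channel images and label maps must share a shape")
  empty <- data.frame(x_min = integer(), y_min = integer(), x_max = integer(),
                      y_max = integer(), label = character(), score = numeric(),
                      area_px = integer(), stringsAsFactors = FALSE)
  rows <- list()
  st_ck <- .region_stats(labels_ck, list(dapi = dapi_img, ck = ck_img, fap = fap_img))
  if (!is.null(st_ck)) {
    acc <- st_ck$mean_dapi >= params$dapi_mean_min &
      st_ck$mean_fap <= params$negative_mean_max
    if (any(acc)) {
      s <- st_ck[acc, , drop = FALSE]
      rows[[1]] <- data.frame(x_min = s$x_min, y_min = s$y_min,
                              x_max = s$x_max, y_max = s$y_max,
                              label = "mCTC",
                              score = pmin(1, s$mean_ck / params$score_norm),
                              area_px = s$area_px, stringsAsFactors = FALSE)
    }
  }
  st_fap <- .region_stats(labels_fap, list(dapi = dapi_img, ck = ck_img, fap = fap_img))
  if (!is.null(st_fap)) {
    acc <- st_fap$mean_dapi >= params$dapi_mean_min &
      st_fap$mean_ck <= params$negative_mean_max
    if (any(acc)) {
      s <- st_fap[acc, , drop = FALSE]
      rows[[2]] <- data.frame(x_min = s$x_min, y_min = s$y_min,
                              x_max = s$x_max, y_max = s$y_max,
                              label = "CAF",
                              score = pmin(1, s$mean_fap / params$score_norm),
                              area_px = s$area_px, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) empty else { rownames(out) <- NULL; out }
}

#' Run the full rule-based detector on an image
#'
#' Chain: per-channel binarization, watershed segmentation of the CK and FAP
#' masks, size filtering, and cross-channel classification. Deterministic.
#'
#' @param img `aif_mosaic`, `aif_tile`, or `[rows, cols, channels]` array
#'   with channel dimnames including DAPI, CK, FAP.
#' @param params a `detector_params`.
#' @return detections data.frame (see [classify_events()]).
#' @export
cv_detect <- function(img, params = detector_params()) {
  dat <- if (inherits(img, "aif_mosaic") || inherits(img, "aif_tile"))
    img$data else .tile_data(img)
  ch <- dimnames(dat)[[3]]
  need <- c("DAPI", "CK", "FAP")
  if (is.null(ch) || !all(need %in% ch))
    stop("lookup error: image must carry DAPI, CK and FAP channels")
  dapi <- dat[, , "DAPI"]; ck <- dat[, , "CK"]; fap <- dat[, , "FAP"]
  thr <- function(nm, im) binarize_channel(im, params$thresholds[[nm]])
  mask_ck <- thr("CK", ck)
  mask_fap <- thr("FAP", fap)
  lab_ck <- size_filter(segment_events(mask_ck, params$watershed_min_distance_px),
                        params$min_area_px, params$max_area_px)
  lab_fap <- size_filter(segment_events(mask_fap, params$watershed_min_distance_px),
                         params$min_area_px, params$max_area_px)
  classify_events(lab_ck, lab_fap, dapi, ck, fap, params)
}

#' Write / read detections CSV
#'
#' Schema: `x_min, y_min, x_max, y_max, label, score, area_px` (plus any
#' extra columns present).
#'
#' @param det detections data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_detections <- function(det, path) {
  write.csv(det, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
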