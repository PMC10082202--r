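# ---------------------------------------------------------------------------
# Whole-slide detection orchestration: half-shift tile coverage, pluggable
# detectors, ensemble fusion, overlap-ratio deduplication, score threshold.
# Cells that straddle a base-grid seam are only partially visible in those
# tiles and would be dropped by the completely-visible rule; re-tiling with
# half-tile shifted grids guarantees every object smaller than half a tile
# is fully inside at least one window.
# ---------------------------------------------------------------------------

#' Tiling scheme for whole-slide detection
#'
#' The base grid plus grids shifted by half the tile side horizontally,
#' vertically, and (optionally) diagonally.
#'
#' @param tile_px tile side length (default 1000).
#' @param include_diagonal include the diagonal half-shift coverage.
#' @return object of class `tiling_scheme` with `tile_px` and `coverages`
#'   (matrix of `(dy, dx)` grid shifts; the base coverage `(0, 0)` is always
#'   first).
#' @export
tiling_scheme <- function(tile_px = 1000, include_diagonal = TRUE) {
  if (tile_px <= 0) stop("tile_px must be positive")
  half <- floor(tile_px / 2)
  cov <- rbind(c(0, 0), c(0, half), c(half, 0))
  if (include_diagonal) cov <- rbind(cov, c(half, half))
  colnames(cov) <- c("dy", "dx")
  structure(list(tile_px = tile_px, coverages = cov), class = "tiling_scheme")
}

#' Enumerate detection windows over a mosaic
#'
#' For each coverage shift, a grid of `tile_px` windows clipped to the
#' mosaic. The base coverage tiles the mosaic completely (the last window in
#' each dimension is clamped to the boundary); shifted coverages start at
#' their shift and are clipped at the edges.
#'
#' @param mosaic_shape `c(rows, cols)`.
#' @param scheme a `tiling_scheme`.
#' @return data.frame `coverage, y0, x0, h, w` (0-based half-open windows).
#' @export
tile_wsi <- function(mosaic_shape, scheme = tiling_scheme()) {
  tp <- scheme$tile_px
  if (tp > min(mosaic_shape))
    stop("tile_px exceeds the mosaic dimensions")
  base_starts <- function(n) unique(c(seq(0, n - tp, by = tp), n - tp))
  shift_starts <- function(n, s) {
    if (s == 0) return(base_starts(n))
    st <- seq(s, n - 1, by = tp)
    st[st + 1 <= n]  # window start must be inside; width clipped below
  }
  out <- NULL
  for (k in seq_len(nrow(scheme$coverages))) {
    sy <- shift_starts(mosaic_shape[1], scheme$coverages[k, "dy"])
    sx <- shift_starts(mosaic_shape[2], scheme$coverages[k, "dx"])
    g <- expand.grid(y0 = sy, x0 = sx)
    g$h <- pmin(tp, mosaic_shape[1] - g$y0)
    g$w <- pmin(tp, mosaic_shape[2] - g$x0)
    g$coverage <- k
    out <- rbind(out, g[, c("coverage", "y0", "x0", "h", "w")])
  }
  rownames(out) <- NULL
  out
}

#' Overlap ratio between two boxes
#'
#' Intersection area divided by the smaller box's area (`mode = "min"`,
#' the deduplication default) or by the union (`mode = "iou"`).
#'
#' @param box_a,box_b numeric `c(x_min, y_min, x_max, y_max)` half-open.
#' @param mode `"min"` or `"iou"`.
#' @return ratio in [0, 1].
#' @export
overlap_ratio <- function(box_a, box_b, mode = c("min", "iou")) {
  mode <- match.arg(mode)
  aa <- (box_a[3] - box_a[1]) * (box_a[4] - box_a[2])
  ab <- (box_b[3] - box_b[1]) * (box_b[4] - box_b[2])
  if (aa <= 0 || ab <= 0) stop("value error: degenerate box")
  iw <- max(0, min(box_a[3], box_b[3]) - max(box_a[1], box_b[1]))
  ih <- max(0, min(box_a[4], box_b[4]) - max(box_a[2], box_b[2]))
  inter <- iw * ih
  if (mode == "min") inter / min(aa, ab) else inter / (aa + ab - inter)
}

# vectorized overlap of one box against a box table
.overlap_vec <- function(box, df, mode = "min") {
  aa <- (box[3] - box[1]) * (box[4] - box[2])
  ab <- (df$x_max - df$x_min) * (df$y_max - df$y_min)
  iw <- pmax(0, pmin(box[3], df$x_max) - pmax(box[1], df$x_min))
  ih <- pmax(0, pmin(box[4], df$y_max) - pmax(box[2], df$y_min))
  inter <- iw * ih
  if (mode == "min") inter / pmin(aa, ab) else inter / (aa + ab - inter)
}

#' Deduplicate repeated detections by overlap ratio
#'
#' Boxes are sorted by descending score (ties: lower `y_min`, then `x_min`,
#' then input order) and kept greedily unless they overlap an already-kept
#' box of the same label by at least `ratio_thresh`.
#'
#' @param detections detections data.frame.
#' @param ratio_thresh overlap-ratio threshold (default 0.5).
#' @param mode overlap definition, see [overlap_ratio()].
#' @return deduplicated detections.
#' @export
dedup_detections <- function(detections, ratio_thresh = 0.5, mode = "min") {
  n <- nrow(detections)
  if (n <= 1) return(detections)
  ord <- order(-detections$score, detections$y_min, detections$x_min,
               seq_len(n))
  det <- detections[ord, , drop = FALSE]
  keep <- logical(n)
  for (i in seq_len(n)) {
    kept <- which(keep & det$label == det$label[i])
    if (length(kept)) {
      ov <- .overlap_vec(c(det$x_min[i], det$y_min[i], det$x_max[i], det$y_max[i]),
                         det[kept, , drop = FALSE], mode)
      if (any(ov >= ratio_thresh)) next
    }
    keep[i] <- TRUE
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fuse detections from an ensemble of k detectors
#'
#' Detections from the k members are clustered greedily (highest score
#' first) across members by same-label overlap at `iou_cluster_thresh`; each
#' member contributes at most one box per cluster. The fused box is the
#' score-weighted mean of member coordinates and the fused score is the sum
#' of member scores divided by k, so missing votes count as zero and
#' unanimous high-score boxes dominate.
#'
#' @param per_model_detections list of k detections data.frames in the same
#'   coordinate frame.
#' @param iou_cluster_thresh IoU threshold for clustering (default 0.5).
#' @param min_votes drop clusters supported by fewer members (default 1).
#' @return fused detections with a `votes` column.
#' @export
merge_ensemble <- function(per_model_detections, iou_cluster_thresh = 0.5,
                           min_votes = 1) {
  k <- length(per_model_detections)
  if (k < 1) stop("need at least one model")
  pool <- do.call(rbind, lapply(seq_len(k), function(m) {
    d <- per_model_detections[[m]]
    if (nrow(d) == 0) return(NULL)
    d$.model <- m
    d
  }))
  if (is.null(pool) || nrow(pool) == 0)
    return(data.frame(x_min = integer(), y_min = integer(), x_max = integer(),
                      y_max = integer(), label = character(), score = numeric(),
                      area_px = integer(), votes = integer(),
                      stringsAsFactors = FALSE))
  pool <- pool[order(-pool$score, pool$y_min, pool$x_min), , drop = FALSE]
  used <- logical(nrow(pool))
  out <- list()
  for (i in seq_len(nrow(pool))) {
    if (used[i]) next
    used[i] <- TRUE
    members <- pool[i, , drop = FALSE]
    cand <- which(!used & pool$label == pool$label[i] &
                    pool$.model != pool$.model[i])
    if (length(cand)) {
      ov <- .overlap_vec(c(pool$x_min[i], pool$y_min[i], pool$x_max[i], pool$y_max[i]),
                         pool[cand, , drop = FALSE], mode = "iou")
      cand <- cand[ov >= iou_cluster_thresh]
      # best (highest-score) box per remaining model
      for (m in unique(pool$.model[cand])) {
        j <- cand[pool$.model[cand] == m][1]
        members <- rbind(members, pool[j, , drop = FALSE])
        used[j] <- TRUE
      }
    }
    wts <- members$score
    if (sum(wts) <= 0) wts <- rep(1, nrow(members))
    fuse <- function(v) sum(v * wts) / sum(wts)
    out[[length(out) + 1L]] <- data.frame(
      x_min = fuse(members$x_min), y_min = fuse(members$y_min),
      x_max = fuse(members$x_max), y_max = fuse(members$y_max),
      label = members$label[1], score = sum(members$score) / k,
      area_px = as.integer(round(fuse(members$area_px))),
      votes = nrow(members), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, out)
  out <- out[out$votes >= min_votes, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Wrap a detector function as an ensemble member
#'
#' @param detect `function(img_array)` returning detections in tile
#'   coordinates.
#' @param name detector name (used in error messages).
#' @return object of class `detector_handle`.
#' @export
detector_handle <- function(detect, name = "detector") {
  stopifnot(is.function(detect))
  structure(list(detect = detect, name = name), class = "detector_handle")
}

#' Rule-based detector as an ensemble member
#'
#' @param params a `detector_params`.
#' @return a `detector_handle` running [cv_detect()].
#' @export
cv_detector_handle <- function(params = detector_params()) {
  detector_handle(function(img) cv_detect(img, params), name = "cv")
}

#' Detect over a whole-slide mosaic
#'
#' For every window of every coverage, each detector runs on the cropped
#' tile; boxes touching the tile border are dropped (the completely-visible
#' rule), survivors are translated to the mosaic frame and fused across
#' detectors; then all coverages are pooled, deduplicated by overlap ratio,
#' and thresholded by score. Deterministic given deterministic detectors.
#'
#' @param mosaic an `aif_mosaic` or `[rows, cols, channels]` array.
#' @param detectors list of `detector_handle`s (k = ensemble size).
#' @param scheme a `tiling_scheme`.
#' @param score_thresh discard fused boxes with score below this.
#' @param dedup_thresh overlap-ratio threshold for deduplication.
#' @param border_margin_px border-exclusion margin inside each tile.
#' @param dedup_mode overlap definition for deduplication.
#' @return detections in mosaic coordinates.
#' @export
detect_wsi <- function(mosaic, detectors, scheme = tiling_scheme(),
                       score_thresh = 0.25, dedup_thresh = 0.5,
                       border_margin_px = 0, dedup_mode = "min") {
  if (length(detectors) < 1) stop("need at least one detector")
  dat <- if (inherits(mosaic, "aif_mosaic")) mosaic$data else .tile_data(mosaic)
  win <- tile_wsi(dim(dat)[1:2], scheme)
  all_det <- list()
  for (t in seq_len(nrow(win))) {
    ri <- (win$y0[t] + 1):(win$y0[t] + win$h[t])
    cj <- (win$x0[t] + 1):(win$x0[t] + win$w[t])
    sub <- dat[ri, cj, , drop = FALSE]
    per_model <- lapply(detectors, function(h) {
      d <- h$detect(sub)
      if (nrow(d) > 0 &&
          any(d$x_min < 0 | d$y_min < 0 | d$x_max > win$w[t] | d$y_max > win$h[t]))
        stop("contract violation: detector '", h$name,
             "' returned boxes outside its tile")
      d <- boundary_filter(d, c(win$h[t], win$w[t]), border_margin_px)
      if (nrow(d) > 0) {
        d$x_min <- d$x_min + win$x0[t]; d$x_max <- d$x_max + win$x0[t]
        d$y_min <- d$y_min + win$y0[t]; d$y_max <- d$y_max + win$y0[t]
      }
      d
    })
    fused <- merge_ensemble(per_model)
    if (nrow(fused) > 0) all_det[[length(all_det) + 1L]] <- fused
  }
  if (!length(all_det))
    return(data.frame(x_min = integer(), y_min = integer(), x_max = integer(),
                      y_max = integer(), label = character(), score = numeric(),
                      area_px = integer(), votes = integer(),
                      stringsAsFactors = FALSE))
  pooled <- do.call(rbind, all_det)
  deduped <- dedup_detections(pooled, dedup_thresh, mode = dedup_mode)
  out <- deduped[deduped$score >= score_thresh, , drop = FALSE]
  rownames(out) <- NULL
  out
}
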