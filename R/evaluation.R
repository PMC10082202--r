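# ---------------------------------------------------------------------------
# Detection evaluation: box matching, precision/recall, PR curve + AUC,
# bootstrap error bars (patch resampling; 90%-area WSI crops), and the
# two-proportion z-test.
# ---------------------------------------------------------------------------

# IoU between one box and a table of boxes
.iou_vec <- function(box, df) .overlap_vec(box, df, mode = "iou")

#' Match predicted boxes against ground truth
#'
#' Greedy matching by descending prediction score: each prediction matches
#' the unmatched same-label ground-truth box with the highest IoU at or
#' above `iou_thresh` (or, with `criterion = "center"`, any unmatched box
#' containing the prediction center). Unmatched predictions are false
#' positives; unmatched ground truth, false negatives.
#'
#' @param preds,gts detections-style data.frames.
#' @param iou_thresh IoU threshold (default 0.5).
#' @param criterion `"iou"` or `"center"` (center-in-box, for dot-derived
#'   ground truth).
#' @return list `tp, fp, fn`, `pairs` data.frame `(pred_id, gt_id, iou)`
#'   with ids = row indices in the inputs.
#' @export
match_boxes <- function(preds, gts, iou_thresh = 0.5,
                        criterion = c("iou", "center")) {
  criterion <- match.arg(criterion)
  n_p <- nrow(preds); n_g <- nrow(gts)
  pairs <- data.frame(pred_id = integer(), gt_id = integer(), iou = numeric())
  if (n_p == 0 || n_g == 0)
    return(list(tp = 0L, fp = n_p, fn = n_g, pairs = pairs))
  ord <- order(-preds$score, seq_len(n_p))
  gt_used <- logical(n_g)
  for (i in ord) {
    cand <- which(!gt_used & gts$label == preds$label[i])
    if (!length(cand)) next
    box <- c(preds$x_min[i], preds$y_min[i], preds$x_max[i], preds$y_max[i])
    iou <- .iou_vec(box, gts[cand, , drop = FALSE])
    if (criterion == "center") {
      cx <- (box[1] + box[3]) / 2; cy <- (box[2] + box[4]) / 2
      inside <- gts$x_min[cand] <= cx & cx < gts$x_max[cand] &
        gts$y_min[cand] <= cy & cy < gts$y_max[cand]
      if (!any(inside)) next
      j <- cand[inside][which.max(iou[inside])]
      pairs <- rbind(pairs, data.frame(pred_id = i, gt_id = j,
                                       iou = max(iou[inside])))
    } else {
      if (max(iou) < iou_thresh) next
      j <- cand[which.max(iou)]
      pairs <- rbind(pairs, data.frame(pred_id = i, gt_id = j, iou = max(iou)))
    }
    gt_used[j] <- TRUE
  }
  tp <- nrow(pairs)
  list(tp = tp, fp = n_p - tp, fn = n_g - tp, pairs = pairs)
}

#' Precision and recall of a match result
#'
#' @param match output of [match_boxes()] (or any list with `tp, fp, fn`).
#' @return named vector `c(precision, recall)`; precision of an empty
#'   prediction set is defined as 1.
#' @export
precision_recall <- function(match) {
  p <- if (match$tp + match$fp == 0) 1 else match$tp / (match$tp + match$fp)
  r <- if (match$tp + match$fn == 0) NA_real_ else match$tp / (match$tp + match$fn)
  c(precision = p, recall = r)
}

#' Precision-recall curve and area under it
#'
#' The score threshold sweeps over every unique prediction score in
#' descending order; at each threshold the predictions at or above it are
#' matched against ground truth. The AUC is the trapezoid integral of
#' precision over recall, opened at recall 0 with the precision of the
#' top-scoring point and closed at the maximum reached recall.
#'
#' @inheritParams match_boxes
#' @return object of class `pr_curve`: `thresholds` (descending),
#'   `precision`, `recall`, `auc`.
#' @export
pr_curve <- function(preds, gts, iou_thresh = 0.5, criterion = "iou") {
  if (nrow(gts) == 0) stop("undefined recall: no ground truth boxes")
  if (nrow(preds) == 0)
    return(structure(list(thresholds = numeric(), precision = numeric(),
                          recall = numeric(), auc = 0), class = "pr_curve"))
  th <- sort(unique(preds$score), decreasing = TRUE)
  pr <- vapply(th, function(t) {
    m <- match_boxes(preds[preds$score >= t, , drop = FALSE], gts,
                     iou_thresh, criterion)
    precision_recall(m)
  }, c(precision = 0, recall = 0))
  prec <- pr["precision", ]; rec <- pr["recall", ]
  rr <- c(0, rec); pp <- c(prec[1], prec)
  auc <- sum(diff(rr) * (pp[-1] + pp[-length(pp)]) / 2)
  structure(list(thresholds = th, precision = unname(prec),
                 recall = unname(rec), auc = auc), class = "pr_curve")
}

#' Generic bootstrap over evaluation units
#'
#' Resamples the units with replacement `n_boot` times and recomputes the
#' metrics on each replicate; deterministic for a given seed.
#'
#' @param units list of exchangeable units (e.g. per-patch results).
#' @param metric_fn `function(units_subset)` returning a named numeric
#'   vector.
#' @param n_boot number of replicates (default 1000).
#' @param seed RNG seed.
#' @return list `mean`, `std` (named vectors), `replicates` matrix.
#' @export
bootstrap_metrics <- function(units, metric_fn, n_boot = 1000, seed = 1L) {
  n <- length(units)
  if (n < 1) stop("insufficient data: no units to bootstrap")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    metric_fn(units[idx])
  }, metric_fn(units))
  if (is.null(dim(reps))) reps <- matrix(reps, nrow = 1)
  list(mean = rowMeans(reps), std = apply(reps, 1, sd), replicates = reps)
}

#' Bootstrap precision/recall over testing patches
#'
#' Each unit is one patch's predictions and ground truth; replicates
#' resample patches with replacement and pool the confusion counts.
#'
#' @param patches list of `list(pred = <detections>, gt = <detections>)`.
#' @param n_boot,seed see [bootstrap_metrics()].
#' @param iou_thresh,criterion see [match_boxes()].
#' @return list `mean`, `std` over `c(precision, recall)`.
#' @export
bootstrap_patches <- function(patches, n_boot = 1000, seed = 1L,
                              iou_thresh = 0.5, criterion = "iou") {
  if (length(patches) < 2)
    stop("insufficient data: need >= 2 patches to bootstrap")
  counts <- lapply(patches, function(u) {
    m <- match_boxes(u$pred, u$gt, iou_thresh, criterion)
    c(tp = m$tp, fp = m$fp, fn = m$fn)
  })
  metric <- function(us) {
    s <- Reduce(`+`, us)
    c(precision = if (s[["tp"]] + s[["fp"]] == 0) 1 else s[["tp"]] / (s[["tp"]] + s[["fp"]]),
      recall = if (s[["tp"]] + s[["fn"]] == 0) NA_real_ else s[["tp"]] / (s[["tp"]] + s[["fn"]]))
  }
  bootstrap_metrics(counts, metric, n_boot, seed)[c("mean", "std")]
}

#' Bootstrap precision/recall by random 90%-area crops of a slide
#'
#' With a single test slide, replicates are axis-aligned crops covering
#' `area_frac` of the slide area (side factor `sqrt(area_frac)`), placed
#' uniformly at random; predictions and ground truth are assigned to a crop
#' by box center, matched, and scored.
#'
#' @param preds,gts detections in the slide frame.
#' @param slide_shape `c(rows, cols)`.
#' @param n_boot,seed see [bootstrap_metrics()].
#' @param area_frac crop area as a fraction of the slide (default 0.9).
#' @param iou_thresh see [match_boxes()].
#' @return list `mean`, `std` over `c(precision, recall)`.
#' @export
bootstrap_wsi <- function(preds, gts, slide_shape, n_boot = 1000, seed = 1L,
                          area_frac = 0.9, iou_thresh = 0.5) {
  if (nrow(gts) == 0) stop("insufficient data: no ground truth")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  f <- sqrt(area_frac)
  ch <- floor(slide_shape[1] * f); cw <- floor(slide_shape[2] * f)
  center_in <- function(df, y0, x0) {
    cx <- (df$x_min + df$x_max) / 2; cy <- (df$y_min + df$y_max) / 2
    df[cx >= x0 & cx < x0 + cw & cy >= y0 & cy < y0 + ch, , drop = FALSE]
  }
  reps <- vapply(seq_len(n_boot), function(b) {
    y0 <- runif(1, 0, slide_shape[1] - ch)
    x0 <- runif(1, 0, slide_shape[2] - cw)
    m <- match_boxes(center_in(preds, y0, x0), center_in(gts, y0, x0),
                     iou_thresh)
    precision_recall(m)
  }, c(precision = 0, recall = 0))
  list(mean = rowMeans(reps, na.rm = TRUE),
       std = apply(reps, 1, sd, na.rm = TRUE))
}

#' Two-proportion z-test (pooled, two-tailed)
#'
#' `z = (p1 - p2) / sqrt(p(1-p)(1/n1 + 1/n2))` with the pooled proportion
#' `p = (x1 + x2) / (n1 + n2)`; `p_two_sided = 2 (1 - Phi(|z|))`.
#'
#' @param x1,n1 successes and trials in group 1.
#' @param x2,n2 successes and trials in group 2.
#' @return list `z`, `p_two_sided`, `stars` (see [significance_stars()]).
#' @export
two_proportion_ztest <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0 || x1 < 0 || x2 < 0 || x1 > n1 || x2 > n2)
    stop("need 0 <= x <= n and n > 0")
  p_pool <- (x1 + x2) / (n1 + n2)
  if (p_pool <= 0 || p_pool >= 1)
    stop("degenerate variance: pooled proportion is 0 or 1")
  se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- (x1 / n1 - x2 / n2) / se
  p <- 2 * (1 - pnorm(abs(z)))
  list(z = z, p_two_sided = p, stars = significance_stars(p))
}

#' Significance stars for a p-value
#'
#' `*` p < 0.05, `**` p < 0.01, `***` p < 0.001, `****` p < 0.0001,
#' `"NS"` otherwise.
#'
#' @param p p-value.
#' @return character.
#' @export
significance_stars <- function(p) {
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 1e-2) "**"
  else if (p < 0.05) "*" else "NS"
}

#' Evaluate detections against ground truth with bootstrap error bars
#'
#' Convenience report: point precision/recall, PR curve AUC, and bootstrap
#' mean/std in either patch mode or WSI 90%-crop mode.
#'
#' @param preds,gts detections in one frame (patch mode: lists per patch).
#' @param mode `"patch"` (then `preds`/`gts` are lists of per-patch
#'   data.frames) or `"wsi"`.
#' @param slide_shape required for `"wsi"` mode.
#' @param n_boot,seed bootstrap controls.
#' @param iou_thresh matching threshold.
#' @return list `precision, recall, auc, precision_mean, precision_std,
#'   recall_mean, recall_std`.
#' @export
evaluate_detections <- function(preds, gts, mode = c("wsi", "patch"),
                                slide_shape = NULL, n_boot = 1000, seed = 1L,
                                iou_thresh = 0.5) {
  mode <- match.arg(mode)
  if (mode == "patch") {
    patches <- Map(function(p, g) list(pred = p, gt = g), preds, gts)
    pooled_p <- do.call(rbind, preds); pooled_g <- do.call(rbind, gts)
    m <- Reduce(`+`, lapply(patches, function(u) {
      mm <- match_boxes(u$pred, u$gt, iou_thresh)
      c(mm$tp, mm$fp, mm$fn)
    }))
    pr <- precision_recall(list(tp = m[1], fp = m[2], fn = m[3]))
    curve <- pr_curve(pooled_p, pooled_g, iou_thresh)
    bs <- bootstrap_patches(patches, n_boot, seed, iou_thresh)
  } else {
    if (is.null(slide_shape)) stop("wsi mode needs slide_shape")
    pr <- precision_recall(match_boxes(preds, gts, iou_thresh))
    curve <- pr_curve(preds, gts, iou_thresh)
    bs <- bootstrap_wsi(preds, gts, slide_shape, n_boot, seed,
                        iou_thresh = iou_thresh)
  }
  list(precision = unname(pr["precision"]), recall = unname(pr["recall"]),
       auc = curve$auc,
       precision_mean = unname(bs$mean["precision"]),
       precision_std = unname(bs$std["precision"]),
       recall_mean = unname(bs$mean["recall"]),
       recall_std = unname(bs$std["recall"]))
}
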