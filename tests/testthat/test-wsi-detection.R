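test_that("tiling covers the mosaic and clips shifted coverages", {
  tw <- tile_wsi(c(2000, 2000), tiling_scheme(1000))
  expect_equal(sum(tw$coverage == 1), 4)
  # base coverage union is the full mosaic
  base <- tw[tw$coverage == 1, ]
  cov <- matrix(FALSE, 2000, 2000)
  for (k in seq_len(nrow(base)))
    cov[(base$y0[k] + 1):(base$y0[k] + base$h[k]),
        (base$x0[k] + 1):(base$x0[k] + base$w[k])] <- TRUE
  expect_true(all(cov))
  # mosaic == tile: one base window, clipped shifted windows
  tw1 <- tile_wsi(c(1000, 1000), tiling_scheme(1000))
  expect_equal(sum(tw1$coverage == 1), 1)
  expect_true(all(tw1$h <= 1000 & tw1$w <= 1000))
  expect_error(tile_wsi(c(500, 500), tiling_scheme(1000)), "exceeds")
})

test_that("any object smaller than half a tile is fully inside some window", {
  scheme <- tiling_scheme(1000)
  shape <- c(3000, 3000)
  tw <- tile_wsi(shape, scheme)
  diam <- 499
  # worst-case positions: a dense grid straddling every base seam
  centers <- expand.grid(cy = seq(250, 2750, by = 125),
                         cx = seq(250, 2750, by = 125))
  for (k in seq_len(nrow(centers))) {
    y0 <- centers$cy[k] - diam / 2; y1 <- centers$cy[k] + diam / 2
    x0 <- centers$cx[k] - diam / 2; x1 <- centers$cx[k] + diam / 2
    inside <- any(tw$y0 <= y0 & y1 <= tw$y0 + tw$h &
                    tw$x0 <= x0 & x1 <= tw$x0 + tw$w)
    expect_true(inside)
  }
})

test_that("overlap ratio matches the pixel-counting oracle", {
  expect_equal(overlap_ratio(c(0, 0, 10, 10), c(0, 0, 10, 10)), 1)
  expect_equal(overlap_ratio(c(0, 0, 10, 10), c(20, 0, 30, 10)), 0)
  expect_equal(overlap_ratio(c(0, 0, 10, 10), c(5, 0, 15, 10)), 0.5)
  set.seed(41)
  for (k in 1:20) {
    a <- c(sample(0:10, 1), sample(0:10, 1), 0, 0)
    a[3] <- a[1] + sample(1:15, 1); a[4] <- a[2] + sample(1:15, 1)
    b <- c(sample(0:10, 1), sample(0:10, 1), 0, 0)
    b[3] <- b[1] + sample(1:15, 1); b[4] <- b[2] + sample(1:15, 1)
    expect_equal(overlap_ratio(a, b), fx_overlap_oracle(a, b))
    expect_equal(overlap_ratio(a, b, mode = "iou"),
                 fx_overlap_oracle(a, b, mode = "iou"))
  }
  expect_error(overlap_ratio(c(0, 0, 0, 10), c(0, 0, 5, 5)), "degenerate")
})

test_that("deduplication keeps the top-scoring box, is idempotent and never adds boxes", {
  two <- rbind(fx_box(0, 0, 10, 10, score = 0.9),
               fx_box(0, 0, 10, 10, score = 0.8))
  dd <- dedup_detections(two)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$score, 0.9)
  # chain A~B, B~C, A!~C with descending scores keeps A and C
  chain <- rbind(fx_box(0, 0, 10, 10, score = 0.9),
                 fx_box(4, 0, 14, 10, score = 0.8),
                 fx_box(10, 0, 20, 10, score = 0.7))
  kept <- dedup_detections(chain, 0.5)
  expect_equal(kept$score, c(0.9, 0.7))
  # different labels never suppress each other
  mixed <- rbind(fx_box(0, 0, 10, 10, "mCTC", 0.9),
                 fx_box(0, 0, 10, 10, "CAF", 0.8))
  expect_equal(nrow(dedup_detections(mixed)), 2)

  set.seed(42)
  for (k in 1:40) {
    n <- sample(1:25, 1)
    x0 <- sample(0:80, n, replace = TRUE); y0 <- sample(0:80, n, replace = TRUE)
    det <- data.frame(x_min = x0, y_min = y0,
                      x_max = x0 + sample(5:20, n, replace = TRUE),
                      y_max = y0 + sample(5:20, n, replace = TRUE),
                      label = sample(c("mCTC", "CAF"), n, replace = TRUE),
                      score = runif(n), area_px = 1)
    dd <- dedup_detections(det, 0.5)
    expect_lte(nrow(dd), n)
    expect_equal(dedup_detections(dd, 0.5), dd)
    # the overall top scorer always survives
    expect_true(max(det$score) %in% dd$score)
  }
})

test_that("ensemble fusion follows the sum-over-k score rule", {
  d <- fx_box(10, 10, 30, 30, score = 1)
  # k = 1: identity
  e1 <- merge_ensemble(list(d))
  expect_equal(e1$score, 1)
  expect_equal(c(e1$x_min, e1$y_min, e1$x_max, e1$y_max), c(10, 10, 30, 30))
  # unanimous five-member agreement keeps the box at score 1
  e5 <- merge_ensemble(rep(list(d), 5))
  expect_equal(nrow(e5), 1)
  expect_equal(e5$score, 1)
  expect_equal(e5$votes, 5)
  # a single vote among five scores 1/5
  e15 <- merge_ensemble(c(list(d), rep(list(d[0, ]), 4)))
  expect_equal(e15$score, 0.2)
  # disagreeing labels stay separate clusters
  mixed <- merge_ensemble(list(d, fx_box(10, 10, 30, 30, "CAF", 0.9)))
  expect_equal(nrow(mixed), 2)
})

test_that("whole-slide detection recovers seam objects through shifted coverages", {
  # mock oracle detector: reads ground-truth boxes stored in an attribute
  gt_global <- rbind(fx_box(480, 100, 544, 164),   # straddles the x = 512 seam
                     fx_box(100, 480, 164, 544),   # straddles the y = 512 seam
                     fx_box(200, 200, 264, 264))
  mos <- array(0, dim = c(1024, 1024, 3),
               dimnames = list(NULL, NULL, c("DAPI", "CK", "FAP")))
  # oracle detector: derives tile-local boxes from the global truth table
  local_mock <- detector_handle(function(img) {
    off <- attr(img, "offset")
    d <- gt_global
    d$x_min <- d$x_min - off[2]; d$x_max <- d$x_max - off[2]
    d$y_min <- d$y_min - off[1]; d$y_max <- d$y_max - off[1]
    d <- d[d$x_min >= 0 & d$y_min >= 0 &
             d$x_max <= dim(img)[2] & d$y_max <= dim(img)[1], , drop = FALSE]
    d
  }, name = "local-mock")
  # wrap detect_wsi manually over windows to inject offsets
  scheme <- tiling_scheme(512)
  win <- tile_wsi(c(1024, 1024), scheme)
  got <- NULL
  for (t in seq_len(nrow(win))) {
    sub <- mos[(win$y0[t] + 1):(win$y0[t] + win$h[t]),
               (win$x0[t] + 1):(win$x0[t] + win$w[t]), , drop = FALSE]
    attr(sub, "offset") <- c(win$y0[t], win$x0[t])
    d <- local_mock$detect(sub)
    d <- boundary_filter(d, c(win$h[t], win$w[t]))
    if (nrow(d)) {
      d$x_min <- d$x_min + win$x0[t]; d$x_max <- d$x_max + win$x0[t]
      d$y_min <- d$y_min + win$y0[t]; d$y_max <- d$y_max + win$y0[t]
      got <- rbind(got, d)
    }
  }
  got <- dedup_detections(got, 0.5)
  # all three objects recovered exactly once, including both seam straddlers
  expect_equal(nrow(got), 3)
  m <- match_boxes(got, gt_global)
  expect_equal(m$tp, 3)
})

test_that("detect_wsi runs detectors per window, dedups and thresholds", {
  opt <- fx_optics()
  ext <- 700 * opt$pixel_size_um
  surf <- generate_surface(c(ext, ext), 0, pixel_pitch_um = 5, seed = 81)
  sc <- populate_scene(surf, 8, 3, 8, 4, seed = 82, min_dist_um = 22,
                       margin_um = 12)
  wf <- render_widefield(sc, opt, shape_px = c(700, 700))
  det <- detect_wsi(wf, list(cv_detector_handle()), tiling_scheme(512),
                    score_thresh = 0.2)
  gt <- scene_boxes(sc, opt, shape_px = c(700, 700))
  m <- match_boxes(det, gt)
  expect_equal(m$fn, 0)
  expect_equal(m$fp, 0)
  # an impossible score threshold empties the output
  none <- detect_wsi(wf, list(cv_detector_handle()), tiling_scheme(512),
                     score_thresh = 1.001)
  expect_equal(nrow(none), 0)
  # a detector returning out-of-tile boxes is named in the error
  bad <- detector_handle(function(img) fx_box(-5, 0, 10, 10), name = "rogue")
  expect_error(detect_wsi(wf, list(bad), tiling_scheme(512)), "rogue")
})

test_that("shifted coverages recover seam cells the base grid drops", {
  opt <- fx_optics()
  ext <- 1024 * opt$pixel_size_um
  surf <- generate_surface(c(ext, ext), 0, pixel_pitch_um = 5, seed = 91)
  sc <- populate_scene(surf, 6, 0, 0, 0, seed = 92, min_dist_um = 30,
                       margin_um = 12)
  # drop one cell exactly on the base-grid seam at x = 512 px
  sc$objects$x_um[1] <- 512 * opt$pixel_size_um
  sc$objects$y_um[1] <- 300 * opt$pixel_size_um
  wf <- render_widefield(sc, opt, shape_px = c(1024, 1024))
  gt <- scene_boxes(sc, opt, shape_px = c(1024, 1024))
  base_only <- structure(list(tile_px = 512,
                              coverages = matrix(c(0, 0), 1, 2,
                                                 dimnames = list(NULL, c("dy", "dx")))),
                         class = "tiling_scheme")
  d_base <- detect_wsi(wf, list(cv_detector_handle()), base_only,
                       score_thresh = 0.2)
  d_full <- detect_wsi(wf, list(cv_detector_handle()), tiling_scheme(512),
                       score_thresh = 0.2)
  r_base <- precision_recall(match_boxes(d_base, gt))["recall"]
  r_full <- precision_recall(match_boxes(d_full, gt))["recall"]
  expect_gte(r_full, r_base)
  expect_equal(unname(r_full), 1)
  expect_lt(unname(r_base), 1)  # the seam cell is invisible to the base grid
})
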