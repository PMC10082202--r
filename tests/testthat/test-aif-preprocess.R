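test_that("patch windows cover the tile exactly with the requested overlap", {
  w1 <- split_patches(c(600, 600), 600, 50)
  expect_equal(nrow(w1), 1)
  expect_equal(c(w1$y0, w1$x0, w1$h, w1$w), c(0, 0, 600, 600))

  # full-size tile geometry: union covers, adjacent windows overlap >= 50 px
  w <- split_patches(c(4000, 3700), 600, 50)
  covered_y <- rep(FALSE, 4000); covered_x <- rep(FALSE, 3700)
  for (k in seq_len(nrow(w))) {
    covered_y[(w$y0[k] + 1):(w$y0[k] + w$h[k])] <- TRUE
    covered_x[(w$x0[k] + 1):(w$x0[k] + w$w[k])] <- TRUE
  }
  expect_true(all(covered_y) && all(covered_x))
  sy <- sort(unique(w$y0))
  sx <- sort(unique(w$x0))
  expect_true(all((sy[-length(sy)] + 600) - sy[-1] >= 50))
  expect_true(all((sx[-length(sx)] + 600) - sx[-1] >= 50))

  # zero overlap partitions up to the clamped last window
  w0 <- split_patches(c(1200, 1200), 600, 0)
  expect_equal(nrow(w0), 4)
  expect_error(split_patches(c(1000, 1000), 100, 100), "smaller")
  expect_error(split_patches(c(500, 500), 600), "exceed")
})

test_that("all-in-focus fusion selects the sharpest slice per patch", {
  opt <- fx_optics()
  # single-plane stack: fusion is the identity
  sc <- fx_single_cell_scene(z0 = 0)
  t1 <- render_tile(sc, opt, stage_xy_um = c(30, 30),
                    tile_shape_px = c(128, 128), z_um = 0,
                    channels = "DAPI", noise = FALSE, vignetting = FALSE)
  a1 <- fuse_aif(t1, patch_size_px = 64, patch_overlap_px = 8)
  expect_equal(a1$data[, , 1], t1$data[, , 1, 1])

  # globally sharpest plane k: every z choice is k, fusion equals plane k
  t3 <- render_tile(sc, opt, stage_xy_um = c(30, 30),
                    tile_shape_px = c(128, 128), z_um = c(-12, 0, 12),
                    channels = "DAPI", noise = FALSE, vignetting = FALSE)
  a3 <- fuse_aif(t3, patch_size_px = 128, patch_overlap_px = 0)
  expect_true(all(a3$z_choice == 2))
  expect_equal(a3$data[, , 1], t3$data[, , 2, 1])
})

test_that("objects at different depths select different slices and both end up sharp", {
  opt <- fx_optics()
  ext <- 512 * opt$pixel_size_um
  surf <- generate_surface(c(ext, ext), 0, pixel_pitch_um = 5, seed = 1)
  sc <- populate_scene(surf, 2, 0, 0, 0, seed = 2, min_dist_um = 0,
                       margin_um = 20)
  sc$objects$x_um <- c(ext * 0.2, ext * 0.8)
  sc$objects$y_um <- c(ext * 0.2, ext * 0.8)
  sc$objects$z_um <- c(-10, 10)
  tile <- render_tile(sc, opt, c(0, 0), c(512, 512), z_um = c(-10, 0, 10),
                      channels = "DAPI", noise = FALSE, vignetting = FALSE)
  aif <- fuse_aif(tile, patch_size_px = 256, patch_overlap_px = 0)
  zc <- aif$z_choice[, 1]
  expect_true(1 %in% zc && 3 %in% zc)
  # per-patch Tenengrad of the fused tile is >= the best single plane
  win <- aif$windows
  for (k in seq_len(nrow(win))) {
    ri <- (win$y0[k] + 1):(win$y0[k] + win$h[k])
    cj <- (win$x0[k] + 1):(win$x0[k] + win$w[k])
    best_single <- max(vapply(1:3, function(iz)
      tenengrad(tile$data[ri, cj, iz, 1]), numeric(1)))
    expect_gte(tenengrad(aif$data[ri, cj, 1]) + 1e-9, best_single)
  }
})

test_that("flat-field estimation recovers a synthetic vignette and normalizes to mean one", {
  nr <- 160; nc <- 160
  yy <- ((seq_len(nr) - 0.5) / nr - 0.5); xx <- ((seq_len(nc) - 0.5) / nc - 0.5)
  vig <- 1 - 0.3 * outer(yy^2, xx^2, `+`) / 0.5
  set.seed(5)
  tiles <- lapply(1:6, function(i) {
    s <- runif(1, 0.3, 0.7)
    array(s * vig, dim = c(nr, nc, 1), dimnames = list(NULL, NULL, "DAPI"))
  })
  field <- estimate_flatfield(tiles, smoothing_sigma_px = 4)
  expect_equal(mean(field[, , 1]), 1, tolerance = 1e-6)
  expect_true(all(field > 0))
  rel <- field[, , 1] / (vig / mean(vig))
  expect_lt(max(abs(rel - 1)), 0.05)

  # constant tiles -> flat field identically one
  const <- lapply(1:3, function(i)
    array(0.5, dim = c(32, 32, 1), dimnames = list(NULL, NULL, "DAPI")))
  fc <- estimate_flatfield(const, smoothing_sigma_px = 5)
  expect_equal(as.vector(fc), rep(1, 32 * 32), tolerance = 1e-9)

  # scale equivariance: scaling all tiles leaves the estimate unchanged
  f2 <- estimate_flatfield(lapply(tiles, function(t) t * 3),
                           smoothing_sigma_px = 4)
  expect_equal(f2, field, tolerance = 1e-9)
  expect_error(estimate_flatfield(tiles[1:2]), "insufficient")
})

test_that("flat-field application divides out shading exactly and round-trips", {
  nr <- 96
  yy <- ((seq_len(nr) - 0.5) / nr - 0.5)
  vig <- 1 - 0.4 * outer(yy^2, yy^2, `+`) / 0.5
  vig <- vig / mean(vig)
  tile <- array(0.5 * vig, dim = c(nr, nr, 1), dimnames = list(NULL, NULL, "DAPI"))
  # identity field
  expect_equal(apply_flatfield(tile, array(1, dim(tile))), tile)
  # exact cancellation
  corrected <- apply_flatfield(tile, array(vig, dim(tile)))
  expect_equal(as.vector(corrected[, , 1]), rep(0.5, nr * nr), tolerance = 1e-12)
  # after perfect correction the re-estimated field is ~1
  refield <- estimate_flatfield(list(corrected, corrected, corrected),
                                smoothing_sigma_px = 8)
  expect_lt(max(abs(refield - 1)), 0.02)
  expect_error(apply_flatfield(tile, array(0, dim(tile))), "positive")
})

test_that("pair registration recovers zero, integer and subpixel shifts", {
  set.seed(21)
  base <- as.matrix(EBImage::gblur(EBImage::Image(matrix(rnorm(192 * 192), 192)), 2))
  as_tile <- function(m) array(m, c(dim(m), 1), dimnames = list(NULL, NULL, "DAPI"))
  # identical tiles at zero nominal offset
  p0 <- register_pair(as_tile(base), as_tile(base), c(0, 0),
                      min_overlap_px = 64)
  expect_equal(p0$offset_px, c(0, 0), tolerance = 1 / 20)

  # integer shift (3, -2): nominal 0, content moved
  b <- matrix(mean(base), 192, 192)
  b[4:192, 1:190] <- base[1:189, 3:192]
  pi_ <- register_pair(as_tile(base), as_tile(b), c(0, 0))
  expect_equal(pi_$offset_px, c(-3, 2), tolerance = 1 / 20)

  # subpixel shift (0.4, -0.7) via Fourier shift
  bs <- fourier_shift(base, 0.4, -0.7, taper_px = 0)
  ps <- register_pair(as_tile(base), as_tile(bs), c(0, 0))
  expect_lt(max(abs(ps$offset_px - c(-0.4, 0.7))), 0.1)

  # featureless overlap: low-confidence fallback to the nominal offset
  flat <- as_tile(matrix(0.02, 192, 192))
  pf <- register_pair(flat, flat, c(0, 150))
  expect_true(pf$low_confidence)
  expect_equal(pf$offset_px, c(0, 150))
  # overlap below the minimum: fallback too
  pn <- register_pair(as_tile(base), as_tile(base), c(0, 180))
  expect_true(pn$low_confidence)
})

test_that("registration recovers jittered tile offsets to subpixel accuracy", {
  opt <- fx_optics()
  errs <- vapply(1:25, function(seed) {
    sc <- fx_grid_scene(seed + 400, grid = c(1, 2), tile_px = 384,
                        overlap_px = 128, amplitude_um = 2, n_mctc = 10,
                        n_caf = 3, n_pore = 8, n_precip = 4, min_dist_um = 8)
    scan <- render_wsi_scan(sc, opt, grid = c(1, 2),
                            tile_shape_px = c(384, 384), tile_overlap_px = 128,
                            z_um = 0, stage_jitter_px = 0.5, tilt_deg = 0.1,
                            noise = FALSE, vignetting = FALSE, seed = seed)
    a <- array(scan$tiles[[1]]$data[, , 1, ], c(384, 384, 3),
               dimnames = list(NULL, NULL, scan$channels))
    b <- array(scan$tiles[[2]]$data[, , 1, ], c(384, 384, 3),
               dimnames = list(NULL, NULL, scan$channels))
    p <- register_pair(a, b, c(0, 256))
    true_off <- c(scan$truth$true_dy_px[2], scan$truth$true_dx_px[2])
    sqrt(sum((p$offset_px - true_off)^2))
  }, numeric(1))
  expect_lt(median(errs), 0.25)
  expect_lt(max(errs), 1)
})

test_that("stitching blends a registered grid into a mosaic matching the wide-field oracle", {
  opt <- fx_optics()
  sc <- fx_grid_scene(77, grid = c(2, 2), tile_px = 384, overlap_px = 128,
                      amplitude_um = 6, n_mctc = 14, n_caf = 4, n_pore = 12,
                      n_precip = 6)
  scan <- render_wsi_scan(sc, opt, grid = c(2, 2), tile_shape_px = c(384, 384),
                          tile_overlap_px = 128, z_um = seq(-20, 20, 5),
                          stage_jitter_px = 0.8, tilt_deg = 0.15,
                          noise = FALSE, vignetting = FALSE, seed = 78)
  mos <- preprocess_scan(scan, patch_size_px = 128, patch_overlap_px = 16,
                         flatfield = FALSE)
  # single tile: mosaic equals the tile
  single <- stitch(list(fuse_aif(scan$tiles[[1]], 128, 16)),
                   data.frame(tile = 1, dy_px = 0, dx_px = 0))
  expect_equal(single$data[1:384, 1:384, ],
               fuse_aif(scan$tiles[[1]], 128, 16)$data, tolerance = 1e-9)

  # measured offsets close to the rendered truth
  cmp <- merge(scan$truth, mos$tile_offsets_px, by = "tile")
  expect_lt(max(abs(cmp$true_dy_px - cmp$dy_px)), 1)
  expect_lt(max(abs(cmp$true_dx_px - cmp$dx_px)), 1)

  # mosaic vs directly rendered wide-field ground truth
  wf <- render_widefield(sc, opt, origin_um = c(0, 0),
                         shape_px = dim(mos$data)[1:2])
  expect_lt(mean(abs(mos$data - wf)), 1e-2)

  # loop closure of the measured pairwise shifts around the 2x2 grid
  pr <- mos$registration
  g <- function(tile, dir, comp)
    pr[pr$tile == tile & pr$direction == dir, ][[comp]]
  loop_dy <- g(2, "left", "dy_px") + g(4, "top", "dy_px") -
    g(4, "left", "dy_px") - g(3, "top", "dy_px")
  loop_dx <- g(2, "left", "dx_px") + g(4, "top", "dx_px") -
    g(4, "left", "dx_px") - g(3, "top", "dx_px")
  expect_lt(abs(loop_dy), 1)
  expect_lt(abs(loop_dx), 1)

  # blending weights cover every mosaic pixel reached by a tile
  expect_true(all(mos$weight[50:600, 50:600] > 0))

  # a disconnected tile is reported by name
  expect_error(accumulate_offsets(mos$registration[-1, ], c(2, 2)),
               "tile 2")
})
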