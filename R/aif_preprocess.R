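# ---------------------------------------------------------------------------
# All-in-focus preprocessing: patch-wise z-compression of fine stacks,
# retrospective flat-field correction, subpixel phase-correlation
# registration of adjacent tiles, and distance-weighted mosaic stitching.
# ---------------------------------------------------------------------------

#' Split a tile into overlapping patch windows
#'
#' A grid of windows covering the tile exactly: interior windows are
#' `patch_size_px` square, adjacent windows share `patch_overlap_px`, and the
#' last window in each dimension is clamped to the boundary.
#'
#' @param shape_px `c(rows, cols)` of the tile.
#' @param patch_size_px window side (default 600).
#' @param patch_overlap_px overlap between adjacent windows.
#' @return data.frame `y0, x0, h, w` (0-based, half-open windows).
#' @export
split_patches <- function(shape_px, patch_size_px = 600, patch_overlap_px = 50) {
  if (patch_overlap_px >= patch_size_px)
    stop("patch_overlap_px must be smaller than patch_size_px")
  if (any(patch_size_px > shape_px))
    stop("patch_size_px must not exceed the tile dimensions")
  starts <- function(n) {
    s <- seq(0, n - patch_size_px, by = patch_size_px - patch_overlap_px)
    unique(c(s, n - patch_size_px))
  }
  sy <- starts(shape_px[1]); sx <- starts(shape_px[2])
  out <- expand.grid(y0 = sy, x0 = sx)
  out$h <- patch_size_px; out$w <- patch_size_px
  out[order(out$y0, out$x0), , drop = FALSE]
}

# linear feather weight map for one window inside a tile: ramps of width
# `ov` on the sides that abut a neighboring window, flat 1 elsewhere
.feather_weights <- function(h, w, ov, has_top, has_bottom, has_left, has_right) {
  ramp <- function(n, ov, lo, hi) {
    r <- rep(1, n)
    if (ov > 0) {
      k <- seq_len(min(ov, n))
      if (lo) r[k] <- pmin(r[k], k / (ov + 1))
      if (hi) r[n + 1 - k] <- pmin(r[n + 1 - k], k / (ov + 1))
    }
    r
  }
  outer(ramp(h, ov, has_top, has_bottom), ramp(w, ov, has_left, has_right))
}

#' Fuse a fine z-stack into an all-in-focus tile
#'
#' Per channel and per patch window, the z-slice with the highest Tenengrad
#' focus measure is selected (ties toward lower z); overlapping windows are
#' blended with linear feathering weights. Channels choose their slices
#' independently, which absorbs any residual axial chromatic offset between
#' channels.
#'
#' @param tile a `zstack_tile`.
#' @param patch_size_px,patch_overlap_px patch grid (see [split_patches()]);
#'   `patch_size_px` is clamped to the tile size.
#' @return object of class `aif_tile`: `data` array `[rows, cols, channels]`,
#'   `z_choice` array `[n_windows, channels]` of selected z indices,
#'   `windows`, `stage_xy_um`, `channels`.
#' @export
fuse_aif <- function(tile, patch_size_px = 600, patch_overlap_px = 50) {
  d <- dim(tile$data)
  nr <- d[1]; nc <- d[2]; n_z <- d[3]; n_ch <- d[4]
  ps <- min(patch_size_px, nr, nc)
  win <- split_patches(c(nr, nc), ps, min(patch_overlap_px, ps - 1))
  n_w <- nrow(win)
  out <- array(0, dim = c(nr, nc, n_ch),
               dimnames = list(NULL, NULL, tile$channels))
  zc <- matrix(0L, n_w, n_ch, dimnames = list(NULL, tile$channels))
  for (ic in seq_len(n_ch)) {
    num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
    for (k in seq_len(n_w)) {
      ri <- (win$y0[k] + 1):(win$y0[k] + win$h[k])
      cj <- (win$x0[k] + 1):(win$x0[k] + win$w[k])
      f <- vapply(seq_len(n_z),
                  function(iz) tenengrad(tile$data[ri, cj, iz, ic]),
                  numeric(1))
      best <- which.max(f)
      zc[k, ic] <- best
      wmap <- .feather_weights(win$h[k], win$w[k], patch_overlap_px,
                               has_top = win$y0[k] > 0,
                               has_bottom = win$y0[k] + win$h[k] < nr,
                               has_left = win$x0[k] > 0,
                               has_right = win$x0[k] + win$w[k] < nc)
      num[ri, cj] <- num[ri, cj] + wmap * tile$data[ri, cj, best, ic]
      den[ri, cj] <- den[ri, cj] + wmap
    }
    out[, , ic] <- num / den
  }
  structure(list(data = out, z_choice = zc, windows = win,
                 stage_xy_um = tile$stage_xy_um, channels = tile$channels),
            class = "aif_tile")
}

.tile_data <- function(x) {
  if (inherits(x, "aif_tile")) x$data
  else if (is.array(x) && length(dim(x)) == 3) x
  else if (is.matrix(x)) array(x, dim = c(dim(x), 1))
  else stop("expected an aif_tile or a [rows, cols, channels] array")
}

#' Estimate a per-channel flat-field (shading) image
#'
#' Retrospective multi-tile estimator: the per-pixel median across tiles is
#' Gaussian-smoothed (normalized convolution, so borders are not attenuated)
#' and scaled to mean 1. The cell signal is sparse, so the median across
#' tiles isolates the smooth illumination profile.
#'
#' @param tiles list of `aif_tile`s (or `[rows, cols, channels]` arrays), at
#'   least 3.
#' @param smoothing_sigma_px Gaussian smoothing sigma (pixels).
#' @return array `[rows, cols, channels]`, strictly positive, mean 1 per
#'   channel.
#' @export
estimate_flatfield <- function(tiles, smoothing_sigma_px = 40) {
  if (length(tiles) < 3)
    stop("insufficient data: need at least 3 tiles to estimate a flat field")
  arrs <- lapply(tiles, .tile_data)
  d <- dim(arrs[[1]])
  field <- array(0, dim = d, dimnames = dimnames(arrs[[1]]))
  ones <- matrix(1, d[1], d[2])
  sm_ones <- as.matrix(EBImage::gblur(EBImage::Image(ones),
                                      sigma = smoothing_sigma_px))
  for (ic in seq_len(d[3])) {
    stack <- vapply(arrs, function(a) a[, , ic], matrix(0, d[1], d[2]))
    med <- apply(stack, c(1, 2), median)
    sm <- as.matrix(EBImage::gblur(EBImage::Image(med),
                                   sigma = smoothing_sigma_px)) / sm_ones
    sm <- sm / mean(sm)
    field[, , ic] <- pmax(sm, 1e-3)
  }
  field
}

#' Apply a flat-field correction
#'
#' Pixel-wise division by the shading image, clipped back to [0, 1].
#'
#' @param tile an `aif_tile` or `[rows, cols, channels]` array.
#' @param field flat-field from [estimate_flatfield()] (or a single matrix,
#'   recycled over channels).
#' @return same type as `tile`, corrected.
#' @export
apply_flatfield <- function(tile, field) {
  dat <- .tile_data(tile)
  d <- dim(dat)
  if (is.matrix(field)) field <- array(field, dim = d)
  if (!all(dim(field)[1:2] == d[1:2])) stop("field and tile shapes differ")
  if (any(field <= 0)) stop("flat field must be strictly positive")
  corrected <- pmin(pmax(dat / field, 0), 1)
  if (inherits(tile, "aif_tile")) {
    tile$data <- corrected
    tile
  } else corrected
}

# --- phase correlation ------------------------------------------------------

# local upsampled inverse DFT of a spectrum over a small output region
# (matrix-multiply DFT; Guizar-Sicairos style)
.dftups <- function(spectrum, nor, noc, usfac, roff, coff) {
  nr <- nrow(spectrum); nc <- ncol(spectrum)
  fr <- .fft_freq(nr) * nr
  fc <- .fft_freq(nc) * nc
  kernr <- exp(2i * pi / (nr * usfac) * outer((0:(nor - 1)) - roff, fr))
  kernc <- exp(2i * pi / (nc * usfac) * outer(fc, (0:(noc - 1)) - coff))
  kernr %*% spectrum %*% kernc
}

# subpixel shift s (dy, dx) such that b(x) ~= a(x - s); also returns the
# normalized correlation peak height as a confidence measure
.phase_correlate <- function(a, b, upsample = 20) {
  nr <- nrow(a); nc <- ncol(a)
  # Hann window: suppresses the periodic-boundary discontinuity, which is
  # identical in both strips and would otherwise lock the peak at zero shift
  hann <- function(n) if (n == 1) 1 else 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  w <- outer(hann(nr), hann(nc))
  a <- (a - mean(a)) * w
  b <- (b - mean(b)) * w
  fa <- stats::fft(a); fb <- stats::fft(b)
  cross <- fa * Conj(fb)
  denom <- Mod(cross)
  cross_n <- cross / pmax(denom, .Machine$double.eps)
  cc <- Re(stats::fft(cross_n, inverse = TRUE)) / (nr * nc)
  pk <- unname(which(cc == max(cc), arr.ind = TRUE)[1, ])
  peak_val <- max(cc)
  sy <- pk[1] - 1; sx <- pk[2] - 1
  if (sy > nr / 2) sy <- sy - nr
  if (sx > nc / 2) sx <- sx - nc
  # correlation peak index equals -s (mod n)
  s_int <- c(-sy, -sx)
  if (upsample > 1) {
    reg <- ceiling(upsample * 1.5)
    dftshift <- floor(reg / 2)
    roff <- dftshift + s_int[1] * upsample
    coff <- dftshift + s_int[2] * upsample
    cc_up <- Mod(.dftups(cross_n, reg, reg, upsample, roff, coff))
    pk2 <- unname(which(cc_up == max(cc_up), arr.ind = TRUE)[1, ])
    s <- s_int - (c(pk2[1] - 1, pk2[2] - 1) - dftshift) / upsample
  } else s <- s_int
  list(shift = s, peak = peak_val)
}

#' Register two adjacent tiles to subpixel precision
#'
#' Phase correlation on the nominally overlapping strips of the registration
#' channel, refined by local Fourier-domain upsampling to a `1/upsample`
#' pixel grid. Returns the measured offset of `tile_b` relative to `tile_a`,
#' i.e. the nominal offset plus the measured subpixel correction. When the
#' overlap is too small or the correlation peak falls below the confidence
#' floor, the nominal offset is returned flagged low-confidence.
#'
#' @param tile_a,tile_b `aif_tile`s (or arrays); `tile_a` is the reference.
#' @param nominal_offset_px nominal `c(dy, dx)` of `tile_b` relative to
#'   `tile_a` (pixels, integer).
#' @param upsample_factor subpixel refinement factor (default 20 = 0.05 px).
#' @param channel registration channel (default DAPI).
#' @param min_overlap_px minimum usable overlap in the shared dimension.
#' @param confidence_floor normalized correlation peak below this falls back
#'   to the nominal offset.
#' @return list `offset_px` (measured `c(dy, dx)`), `correction_px`,
#'   `confidence`, `low_confidence` flag.
#' @export
register_pair <- function(tile_a, tile_b, nominal_offset_px,
                          upsample_factor = 20, channel = "DAPI",
                          min_overlap_px = 64, confidence_floor = 0.03) {
  a <- .tile_data(tile_a); b <- .tile_data(tile_b)
  ia <- if (!is.null(dimnames(a)[[3]])) match(channel, dimnames(a)[[3]]) else 1L
  if (is.na(ia)) stop("registration channel '", channel, "' not found")
  am <- a[, , ia]; bm <- b[, , ia]
  o <- round(nominal_offset_px)
  # overlap window in mosaic coordinates (a's frame at origin 0)
  r0 <- max(0, o[1]); r1 <- min(nrow(am), o[1] + nrow(bm))
  c0 <- max(0, o[2]); c1 <- min(ncol(am), o[2] + ncol(bm))
  low <- function() list(offset_px = as.numeric(nominal_offset_px),
                         correction_px = c(0, 0), confidence = 0,
                         low_confidence = TRUE)
  if (min(r1 - r0, c1 - c0) < min_overlap_px) return(low())
  strip_a <- am[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
  strip_b <- bm[(r0 - o[1] + 1):(r1 - o[1]), (c0 - o[2] + 1):(c1 - o[2]),
                drop = FALSE]
  pc <- .phase_correlate(strip_a, strip_b, upsample_factor)
  if (pc$peak < confidence_floor) return(low())
  # strips cropped at the nominal offset: B(x) = A(x + delta) with
  # delta = true - nominal, and .phase_correlate returns s with
  # B(x) = A(x - s), so delta = -s
  corr <- -pc$shift
  list(offset_px = o + corr, correction_px = corr, confidence = pc$peak,
       low_confidence = FALSE)
}

#' Register every adjacent tile pair of a grid
#'
#' Measures the left-neighbor and top-neighbor offsets of every tile from
#' the nominal grid geometry.
#'
#' @param tiles list of `aif_tile`s, row-major.
#' @param grid `c(n_rows, n_cols)`.
#' @param tile_shape_px `c(rows, cols)` of one tile.
#' @param tile_overlap_px nominal overlap (pixels).
#' @param ... passed to [register_pair()].
#' @return data.frame `tile, neighbor, direction, dy_px, dx_px, confidence,
#'   low_confidence` — measured offsets of `tile` relative to `neighbor`.
#' @export
register_tiles <- function(tiles, grid, tile_shape_px, tile_overlap_px, ...) {
  stride <- tile_shape_px - tile_overlap_px
  out <- NULL
  idx <- function(r, cc) (r - 1) * grid[2] + cc
  for (r in seq_len(grid[1])) for (cc in seq_len(grid[2])) {
    i <- idx(r, cc)
    if (cc > 1) {
      p <- register_pair(tiles[[idx(r, cc - 1)]], tiles[[i]],
                         nominal_offset_px = c(0, stride[2]), ...)
      out <- rbind(out, data.frame(tile = i, neighbor = idx(r, cc - 1),
                                   direction = "left", dy_px = p$offset_px[1],
                                   dx_px = p$offset_px[2],
                                   confidence = p$confidence,
                                   low_confidence = p$low_confidence))
    }
    if (r > 1) {
      p <- register_pair(tiles[[idx(r - 1, cc)]], tiles[[i]],
                         nominal_offset_px = c(stride[1], 0), ...)
      out <- rbind(out, data.frame(tile = i, neighbor = idx(r - 1, cc),
                                   direction = "top", dy_px = p$offset_px[1],
                                   dx_px = p$offset_px[2],
                                   confidence = p$confidence,
                                   low_confidence = p$low_confidence))
    }
  }
  out
}

#' Accumulate pairwise offsets into global tile placements
#'
#' The upper-left tile anchors the mosaic at (0, 0); every other tile is
#' chained from its left neighbor (or, in the first column, its top
#' neighbor), following the row-major scan order.
#'
#' @param pairs output of [register_tiles()].
#' @param grid `c(n_rows, n_cols)`.
#' @return data.frame `tile, dy_px, dx_px` relative to the anchor.
#' @export
accumulate_offsets <- function(pairs, grid) {
  n <- prod(grid)
  dy <- rep(NA_real_, n); dx <- rep(NA_real_, n)
  dy[1] <- 0; dx[1] <- 0
  idx <- function(r, cc) (r - 1) * grid[2] + cc
  for (r in seq_len(grid[1])) for (cc in seq_len(grid[2])) {
    i <- idx(r, cc)
    if (i == 1) next
    if (cc > 1) {
      p <- pairs[pairs$tile == i & pairs$direction == "left", ]
      j <- idx(r, cc - 1)
    } else {
      p <- pairs[pairs$tile == i & pairs$direction == "top", ]
      j <- idx(r - 1, cc)
    }
    if (nrow(p) == 0 || is.na(dy[j]))
      stop("placement error: tile ", i, " is not connected to the anchor")
    dy[i] <- dy[j] + p$dy_px[1]
    dx[i] <- dx[j] + p$dx_px[1]
  }
  data.frame(tile = seq_len(n), dy_px = dy, dx_px = dx)
}

#' Shift an image by a (sub)pixel amount via the Fourier domain
#'
#' Content moves by `+dy` down and `+dx` right. An 8-px raised-cosine edge
#' taper toward the image mean suppresses wraparound ringing.
#'
#' @param img numeric matrix.
#' @param dy,dx shift in pixels.
#' @param taper_px edge taper width.
#' @return shifted matrix.
#' @export
fourier_shift <- function(img, dy, dx, taper_px = 8) {
  if (dy == 0 && dx == 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  if (taper_px > 0) {
    m <- mean(img)
    tp <- function(n) {
      w <- rep(1, n)
      k <- seq_len(min(taper_px, floor(n / 2)))
      ramp <- 0.5 * (1 - cos(pi * (k - 0.5) / taper_px))
      w[k] <- ramp; w[n + 1 - k] <- ramp
      w
    }
    wmap <- outer(tp(nr), tp(nc))
    img <- wmap * img + (1 - wmap) * m
  }
  phase <- exp(-2i * pi * (outer(.fft_freq(nr) * dy, rep(1, nc)) +
                             outer(rep(1, nr), .fft_freq(nc) * dx)))
  Re(stats::fft(stats::fft(img) * phase, inverse = TRUE)) / (nr * nc)
}

#' Stitch registered tiles into a whole-slide mosaic
#'
#' Tiles are translated to their global offsets (integer placement plus
#' Fourier-domain subpixel shift) and blended where they overlap with
#' weights proportional to each tile's distance to its own border, so seams
#' fade smoothly; weights are normalized to sum to 1 at every covered pixel.
#'
#' @param tiles list of `aif_tile`s (or arrays), row-major.
#' @param offsets data.frame `tile, dy_px, dx_px` from
#'   [accumulate_offsets()] (anchor at 0, 0).
#' @return object of class `aif_mosaic`: `data` array `[H, W, channels]`,
#'   `tile_offsets_px`, `channels`, `weight` (coverage weight map).
#' @export
stitch <- function(tiles, offsets) {
  arrs <- lapply(tiles, .tile_data)
  d1 <- dim(arrs[[1]])
  n_ch <- d1[3]
  oy <- offsets$dy_px; ox <- offsets$dx_px
  y0 <- floor(min(oy)); x0 <- floor(min(ox))
  H <- ceiling(max(oy + vapply(arrs, function(a) nrow(a), 0))) - y0 + 1L
  W <- ceiling(max(ox + vapply(arrs, function(a) ncol(a), 0))) - x0 + 1L
  num <- array(0, dim = c(H, W, n_ch))
  den <- matrix(0, H, W)
  for (k in seq_along(arrs)) {
    a <- arrs[[k]]
    nr <- nrow(a); nc <- ncol(a)
    ty <- oy[k] - y0; tx <- ox[k] - x0
    iy <- round(ty); ix <- round(tx)
    fy <- ty - iy; fx <- tx - ix
    wmap <- outer(pmin(seq_len(nr), rev(seq_len(nr))),
                  pmin(seq_len(nc), rev(seq_len(nc))), pmin)
    ri <- (iy + 1):(iy + nr); cj <- (ix + 1):(ix + nc)
    for (ic in seq_len(n_ch)) {
      pl <- if (fy != 0 || fx != 0) fourier_shift(a[, , ic], fy, fx) else a[, , ic]
      num[ri, cj, ic] <- num[ri, cj, ic] + wmap * pl
    }
    den[ri, cj] <- den[ri, cj] + wmap
  }
  dat <- array(0, dim = c(H, W, n_ch), dimnames = list(NULL, NULL, dimnames(arrs[[1]])[[3]]))
  pos <- den > 0
  for (ic in seq_len(n_ch)) {
    pl <- num[, , ic]
    pl[pos] <- pl[pos] / den[pos]
    dat[, , ic] <- pmin(pmax(pl, 0), 1)
  }
  if (!is.null(tiles[[1]]$channels)) dimnames(dat)[[3]] <- tiles[[1]]$channels
  structure(list(data = dat, tile_offsets_px = offsets,
                 channels = dimnames(dat)[[3]], weight = den),
            class = "aif_mosaic")
}

#' Full preprocessing chain: fuse, correct, register, stitch
#'
#' Convenience wrapper running the whole preprocessing pipeline on a
#' simulated scan: all-in-focus fusion of every tile, flat-field estimation
#' and correction (when at least 3 tiles are available), pairwise
#' registration, chain accumulation from the anchor, and blended stitching.
#'
#' @param scan a `wsi_scan`.
#' @param patch_size_px,patch_overlap_px all-in-focus patch grid.
#' @param flatfield logical; estimate and apply the shading correction.
#' @param upsample_factor registration upsampling.
#' @param channel registration channel.
#' @return an `aif_mosaic`, with the registration table attached as
#'   `$registration`.
#' @export
preprocess_scan <- function(scan, patch_size_px = 600, patch_overlap_px = 50,
                            flatfield = TRUE, upsample_factor = 20,
                            channel = "DAPI") {
  aif <- lapply(scan$tiles, fuse_aif, patch_size_px = patch_size_px,
                patch_overlap_px = patch_overlap_px)
  if (flatfield && length(aif) >= 3) {
    field <- estimate_flatfield(aif)
    aif <- lapply(aif, apply_flatfield, field = field)
  }
  pairs <- register_tiles(aif, scan$grid, scan$tile_shape_px,
                          scan$tile_overlap_px,
                          upsample_factor = upsample_factor, channel = channel)
  offsets <- accumulate_offsets(pairs, scan$grid)
  mos <- stitch(aif, offsets)
  mos$registration <- pairs
  mos
}

#' Write a mosaic as a multi-page TIFF plus offsets CSV
#'
#' @param mosaic an `aif_mosaic`.
#' @param path output TIFF path (one page per channel).
#' @param offsets_csv optional path for the tile-offset table.
#' @return `path`, invisibly.
#' @export
write_mosaic <- function(mosaic, path, offsets_csv = NULL) {
  pages <- lapply(seq_len(dim(mosaic$data)[3]), function(ic) mosaic$data[, , ic])
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  if (!is.null(offsets_csv))
    write.csv(mosaic$tile_offsets_px, offsets_csv, row.names = FALSE)
  invisible(path)
}
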