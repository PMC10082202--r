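#' @importFrom stats rnorm runif rpois median sd quantile approx pnorm rbinom
#' @importFrom utils write.csv read.csv
NULL

# ---------------------------------------------------------------------------
# Synthetic microfilter scenes: wavy membrane surface, marker-labelled cells,
# hollow pores, precipitates, and a defocus-aware tile renderer.
# Conventions: pixels are 0-based, (row = y, col = x); boxes are half-open
# [x_min, x_max) x [y_min, y_max); stage microns run +x right, +y down;
# z increases toward the objective.
# ---------------------------------------------------------------------------

#' Generate a wavy membrane height field
#'
#' Microfilter membranes are flexible and sit slightly wavy on the slide, so
#' captured cells are spread over a range of focal planes. The surface is
#' modelled as band-limited Gaussian noise: white noise low-pass filtered at
#' the correlation length (periodic Gaussian filter in the Fourier domain) and
#' rescaled so the sample standard deviation equals `amplitude_um` exactly.
#'
#' @param extent_um slide extent in microns, `c(width_x, height_y)` (scalars
#'   are recycled to a square).
#' @param amplitude_um target standard deviation of surface height (microns).
#'   `0` gives a perfectly flat membrane.
#' @param correlation_length_um lateral correlation length of the waviness
#'   (microns); the Gaussian smoothing sigma of the underlying noise.
#' @param pixel_pitch_um grid pitch of the height field (microns per sample;
#'   this is a coarse surface grid, not the camera pixel size).
#' @param seed integer RNG seed; the field is a pure function of the
#'   parameters and the seed.
#' @return object of class `height_field`: list with `heights` (matrix,
#'   rows = y), `pixel_pitch_um`, `amplitude_um`, `correlation_length_um`,
#'   `extent_um`, `seed`.
#' @export
generate_surface <- function(extent_um = c(2000, 2000), amplitude_um = 15,
                             correlation_length_um = 500, pixel_pitch_um = 5,
                             seed = 1L) {
  if (length(extent_um) == 1L) extent_um <- rep(extent_um, 2L)
  if (any(extent_um <= 0)) stop("extent_um must be positive")
  if (amplitude_um < 0) stop("amplitude_um must be >= 0")
  if (correlation_length_um <= 0) stop("correlation_length_um must be positive")
  if (pixel_pitch_um <= 0) stop("pixel_pitch_um must be positive")

  nc <- max(2L, as.integer(ceiling(extent_um[1] / pixel_pitch_um)) + 1L)
  nr <- max(2L, as.integer(ceiling(extent_um[2] / pixel_pitch_um)) + 1L)

  if (amplitude_um == 0) {
    h <- matrix(0, nr, nc)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    noise <- matrix(rnorm(nr * nc), nr, nc)
    sig <- correlation_length_um / pixel_pitch_um
    fy <- .fft_freq(nr)
    fx <- .fft_freq(nc)
    transfer <- exp(-2 * pi^2 * sig^2 * outer(fy^2, fx^2, `+`))
    h <- Re(stats::fft(stats::fft(noise) * transfer, inverse = TRUE)) / (nr * nc)
    s <- sd(as.vector(h))
    if (s > 0) h <- (h - mean(h)) / s * amplitude_um
  }
  structure(list(heights = h, pixel_pitch_um = pixel_pitch_um,
                 amplitude_um = amplitude_um,
                 correlation_length_um = correlation_length_um,
                 extent_um = extent_um, seed = as.integer(seed)),
            class = "height_field")
}

.fft_freq <- function(n) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1)) / n
  k
}

# save/restore the global RNG state so generators are pure in (params, seed)
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Evaluate surface height at arbitrary points
#'
#' Bilinear interpolation of the height grid; points are clamped to the grid.
#'
#' @param surface a `height_field`.
#' @param x_um,y_um coordinates in microns (vectors of equal length).
#' @return heights in microns.
#' @export
surface_height_at <- function(surface, x_um, y_um) {
  h <- surface$heights
  p <- surface$pixel_pitch_um
  nr <- nrow(h); nc <- ncol(h)
  cx <- pmin(pmax(x_um / p, 0), nc - 1)
  cy <- pmin(pmax(y_um / p, 0), nr - 1)
  j0 <- pmin(floor(cx), nc - 2); i0 <- pmin(floor(cy), nr - 2)
  tx <- cx - j0; ty <- cy - i0
  i0 <- i0 + 1; j0 <- j0 + 1  # to 1-based
  h[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    h[cbind(i0, j0 + 1)] * tx * (1 - ty) +
    h[cbind(i0 + 1, j0)] * (1 - tx) * ty +
    h[cbind(i0 + 1, j0 + 1)] * tx * ty
}

#' Default class-conditional channel intensity configuration
#'
#' Peak amplitudes are drawn uniformly from the given ranges. Marker logic:
#' tumor cells (mCTC) are DAPI+/CK+/FAP-; fibroblasts (CAF) are
#' DAPI+/FAP+/CK-; pores are hollow (no DAPI anywhere) with a weak
#' autofluorescent rim in a single randomly chosen marker channel;
#' precipitates are bright specks in a single marker channel.
#'
#' @return nested list of per-class, per-channel `c(lo, hi)` amplitude ranges.
#' @export
default_intensity_config <- function() {
  list(
    mCTC        = list(DAPI = c(0.50, 0.85), CK = c(0.50, 0.90), FAP = c(0, 0)),
    CAF         = list(DAPI = c(0.45, 0.80), CK = c(0, 0), FAP = c(0.45, 0.85)),
    pore        = list(DAPI = c(0, 0), rim = c(0.15, 0.30)),
    precipitate = list(DAPI = c(0, 0), speck = c(0.40, 0.95))
  )
}

#' Populate a membrane surface with cells, pores and precipitates
#'
#' Object centers are placed uniformly at random subject to a minimum
#' pairwise center distance (rejection sampling with bounded retries;
#' `min_dist_um = 0` permits clumps). Each object's axial position is the
#' membrane height at its center. Class-conditional marker amplitudes follow
#' `intensity_config`; no object ever carries both CK and FAP signal.
#'
#' @param surface a `height_field`.
#' @param n_mctc,n_caf,n_pore,n_precip object counts (>= 0).
#' @param seed integer RNG seed.
#' @param min_dist_um minimum center-to-center distance in microns (default
#'   20, a loosely packed clean preparation; 0 allows clumps).
#' @param intensity_config see [default_intensity_config()].
#' @param margin_um keep centers at least this far inside the slide edge.
#' @return object of class `gt_scene`: `objects` data.frame with columns
#'   `id, class, x_um, y_um, z_um, diameter_um, ecc, theta, DAPI, CK, FAP`,
#'   plus `extent_um` and `seed`.
#' @export
populate_scene <- function(surface, n_mctc = 50, n_caf = 20, n_pore = 100,
                           n_precip = 50, seed = 1L, min_dist_um = 20,
                           intensity_config = default_intensity_config(),
                           margin_um = 15) {
  counts <- c(mCTC = n_mctc, CAF = n_caf, pore = n_pore, precipitate = n_precip)
  if (any(counts < 0)) stop("object counts must be >= 0")
  n_total <- sum(counts)
  ext <- surface$extent_um

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  cls <- rep(names(counts), counts)
  # diameters (microns): tumor cells > 8 um; CAFs larger and more variable;
  # pore size fixed by the filter; precipitates are small specks
  dia <- numeric(n_total)
  dia[cls == "mCTC"] <- pmin(pmax(rnorm(counts["mCTC"], 15, 1.5), 10), 20)
  dia[cls == "CAF"] <- pmin(pmax(rnorm(counts["CAF"], 20, 3), 12), 30)
  dia[cls == "pore"] <- 8
  dia[cls == "precipitate"] <- runif(counts["precipitate"], 2, 5)

  ecc <- numeric(n_total)
  ecc[cls == "CAF"] <- runif(counts["CAF"], 0, 0.8)
  theta <- runif(n_total, 0, pi)

  # rejection-sampled placement with a minimum pairwise distance
  xs <- numeric(n_total); ys <- numeric(n_total)
  placed <- 0L
  max_tries <- max(1000L, 200L * n_total)
  tries <- 0L
  lo <- margin_um
  while (placed < n_total) {
    tries <- tries + 1L
    if (tries > max_tries)
      stop("placement error: could not satisfy min_dist_um = ", min_dist_um,
           " for ", n_total, " objects on ", ext[1], " x ", ext[2], " um")
    cx <- runif(1, lo, ext[1] - lo)
    cy <- runif(1, lo, ext[2] - lo)
    if (min_dist_um > 0 && placed > 0L) {
      d2 <- (xs[seq_len(placed)] - cx)^2 + (ys[seq_len(placed)] - cy)^2
      if (any(d2 < min_dist_um^2)) next
    }
    placed <- placed + 1L
    xs[placed] <- cx; ys[placed] <- cy
  }

  z <- surface_height_at(surface, xs, ys)

  draw <- function(rg, n) if (diff(rg) == 0) rep(rg[1], n) else runif(n, rg[1], rg[2])
  dapi <- ck <- fap <- numeric(n_total)
  for (cl in names(counts)) {
    idx <- which(cls == cl)
    if (!length(idx)) next
    cfg <- intensity_config[[cl]]
    if (cl %in% c("mCTC", "CAF")) {
      dapi[idx] <- draw(cfg$DAPI, length(idx))
      ck[idx] <- draw(cfg$CK, length(idx))
      fap[idx] <- draw(cfg$FAP, length(idx))
    } else {
      # pores / precipitates light up one marker channel only, never both
      amp_rg <- if (cl == "pore") cfg$rim else cfg$speck
      amp <- draw(amp_rg, length(idx))
      in_ck <- runif(length(idx)) < 0.5
      ck[idx[in_ck]] <- amp[in_ck]
      fap[idx[!in_ck]] <- amp[!in_ck]
    }
  }

  obj <- data.frame(
    id = seq_len(n_total), class = cls, x_um = xs, y_um = ys, z_um = z,
    diameter_um = dia, ecc = ecc, theta = theta,
    DAPI = dapi, CK = ck, FAP = fap, stringsAsFactors = FALSE)
  structure(list(objects = obj, extent_um = ext, seed = as.integer(seed),
                 surface = surface),
            class = "gt_scene")
}

#' Imaging model of the scanner
#'
#' Captures the optical parameters that matter for defocus rendering: the
#' objective NA, per-channel emission wavelengths and axial chromatic
#' offsets, the camera pixel size, a defocus-to-blur mapping, vignetting and
#' noise. Defocus blur uses a disc-edge smoothing of width
#' `sigma = max(sigma_min_px, blur_k * |defocus| / pixel_size)` pixels with
#' amplitude attenuation `R^2 / (R^2 + 2 sigma^2)`; `blur_k` is calibrated so
#' `sigma` is about 1.5 px at one depth of field.
#'
#' @param na numerical aperture.
#' @param wavelength_um named per-channel emission wavelengths (microns).
#' @param pixel_size_um camera pixel size at the sample (microns/px).
#' @param chromatic_offset_um named per-channel axial focus shifts (microns).
#' @param vignetting_strength relative fall-off at the tile corner, in [0, 1).
#' @param gaussian_sigma additive Gaussian read-noise sigma ([0,1] units).
#' @param poisson_scale photon scale for shot noise (0 disables).
#' @param background constant background level.
#' @param sigma_min_px in-focus residual blur (pixels).
#' @param sigma_cap_px kernel-width cap (pixels); beyond it only the
#'   amplitude attenuation continues to grow, keeping the focus metric
#'   strictly decreasing with defocus at bounded cost.
#' @param blur_k blur slope; default calibrated from the depth of field.
#' @param ref_wavelength_um reference wavelength for [depth_of_field()].
#' @return object of class `optics_model`.
#' @export
optics_model <- function(na = 0.4,
                         wavelength_um = c(DAPI = 0.461, CK = 0.519, FAP = 0.617),
                         pixel_size_um = 0.23,
                         chromatic_offset_um = c(DAPI = 0, CK = 0, FAP = 0),
                         vignetting_strength = 0.15,
                         gaussian_sigma = 0.01,
                         poisson_scale = 2000,
                         background = 0.02,
                         sigma_min_px = 0.6,
                         sigma_cap_px = 25,
                         blur_k = NULL,
                         ref_wavelength_um = 0.55) {
  if (na <= 0 || na >= 1) stop("na must be in (0, 1)")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (vignetting_strength < 0 || vignetting_strength >= 1)
    stop("vignetting_strength must be in [0, 1)")
  dof <- ref_wavelength_um / (2 * na^2)
  if (is.null(blur_k)) blur_k <- 1.5 * pixel_size_um / dof
  structure(list(na = na, wavelength_um = wavelength_um,
                 pixel_size_um = pixel_size_um,
                 chromatic_offset_um = chromatic_offset_um,
                 vignetting_strength = vignetting_strength,
                 gaussian_sigma = gaussian_sigma,
                 poisson_scale = poisson_scale,
                 background = background,
                 sigma_min_px = sigma_min_px, sigma_cap_px = sigma_cap_px,
                 blur_k = blur_k, ref_wavelength_um = ref_wavelength_um),
            class = "optics_model")
}

#' Depth of field of the objective
#'
#' `wavelength / (2 NA^2)`; with a 0.55 um reference wavelength and NA 0.4
#' this is 1.72 um.
#'
#' @param optics an `optics_model`.
#' @param wavelength_um wavelength (microns); defaults to the model's
#'   reference wavelength.
#' @return depth of field in microns.
#' @export
depth_of_field <- function(optics, wavelength_um = optics$ref_wavelength_um) {
  wavelength_um / (2 * optics$na^2)
}

# blur width (px) at a given defocus (um); capped for compute
.blur_sigma_px <- function(optics, defocus_um) {
  pmin(optics$sigma_cap_px,
       pmax(optics$sigma_min_px,
            optics$blur_k * abs(defocus_um) / optics$pixel_size_um))
}

# uncapped blur width, used for amplitude attenuation so the rendered signal
# keeps decaying monotonically past the kernel cap
.blur_sigma_px_uncapped <- function(optics, defocus_um) {
  pmax(optics$sigma_min_px,
       optics$blur_k * abs(defocus_um) / optics$pixel_size_um)
}

# smooth-edged disc profile: 1 inside, smoothstep roll-off of half-width h
.smooth_disc <- function(r, R, h) {
  t <- pmin(pmax((R + h - r) / (2 * h), 0), 1)
  t * t * (3 - 2 * t)
}

# draw one object into `plane` (modified in place via return); all units px
.draw_object <- function(plane, cx, cy, R, amp, sigma, ecc = 0, theta = 0,
                         annulus = FALSE) {
  nr <- nrow(plane); nc <- ncol(plane)
  w0 <- pmax(1, 0.3 * R)                     # intrinsic soft edge
  h <- sqrt(w0^2 + (2 * sigma)^2)            # defocus widens the edge
  r_ext <- R + h + 2
  j0 <- floor(cx - r_ext) + 1; j1 <- ceiling(cx + r_ext) + 1
  i0 <- floor(cy - r_ext) + 1; i1 <- ceiling(cy + r_ext) + 1
  j0 <- max(1, j0); j1 <- min(nc, j1); i0 <- max(1, i0); i1 <- min(nr, i1)
  if (j0 > j1 || i0 > i1) return(plane)
  xs <- (j0:j1) - 1 - cx
  ys <- (i0:i1) - 1 - cy
  if (ecc > 0) {
    b_over_a <- sqrt(1 - ecc^2)
    ct <- cos(theta); st <- sin(theta)
    xr <- outer(ys, xs, function(y, x) x * ct + y * st)
    yr <- outer(ys, xs, function(y, x) -x * st + y * ct) / b_over_a
    r <- sqrt(xr^2 + yr^2)
  } else {
    r <- sqrt(outer(ys^2, xs^2, `+`))
  }
  prof <- .smooth_disc(r, R, h)
  if (annulus) prof <- prof - .smooth_disc(r, 0.6 * R, sqrt(1 + sigma^2))
  plane[i0:i1, j0:j1] <- plane[i0:i1, j0:j1] + amp * pmax(prof, 0)
  plane
}

#' Render one z-stack tile of a scene
#'
#' Every in-view object is drawn as a smooth-edged disc (pores as annuli,
#' CAFs as ellipses) whose edge width and amplitude follow the optics blur
#' model at defocus `|z_plane - (z_object + chromatic_offset[channel])|`.
#' A radial vignetting profile multiplies signal plus background; optional
#' shot and read noise are added; values are clipped to [0, 1].
#'
#' @param scene a `gt_scene`.
#' @param optics an `optics_model`.
#' @param stage_xy_um stage position of the tile's upper-left pixel (microns).
#' @param tile_shape_px `c(rows, cols)`.
#' @param z_um strictly increasing focal plane positions (microns).
#' @param channels channel names to render (must exist in the scene table).
#' @param noise logical; apply the optics noise model.
#' @param vignetting logical; apply the vignetting profile.
#' @param seed optional RNG seed for the noise draw.
#' @return object of class `zstack_tile`: `data` array
#'   `[rows, cols, n_z, n_channels]`, `z_um`, `stage_xy_um`, `channels`.
#' @export
render_tile <- function(scene, optics, stage_xy_um = c(0, 0),
                        tile_shape_px = c(512, 512), z_um = seq(-25, 25, 5),
                        channels = c("DAPI", "CK", "FAP"), noise = TRUE,
                        vignetting = TRUE, seed = NULL) {
  if (any(diff(z_um) <= 0)) stop("z_um must be strictly increasing")
  if (any(tile_shape_px <= 0)) stop("tile_shape_px must be positive")
  missing_ch <- setdiff(channels, names(scene$objects))
  if (length(missing_ch))
    stop("configuration error: unknown channel(s) ",
         paste(missing_ch, collapse = ", "))

  nr <- tile_shape_px[1]; nc <- tile_shape_px[2]
  px <- optics$pixel_size_um
  obj <- scene$objects
  # objects whose footprint could intersect this tile
  max_ext_um <- (max(obj$diameter_um, 0) / 2 +
                   (optics$sigma_cap_px * 2 + 10) * px)
  keep <- obj$x_um > stage_xy_um[1] - max_ext_um &
    obj$x_um < stage_xy_um[1] + nc * px + max_ext_um &
    obj$y_um > stage_xy_um[2] - max_ext_um &
    obj$y_um < stage_xy_um[2] + nr * px + max_ext_um
  obj <- obj[keep, , drop = FALSE]

  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }

  vmap <- 1
  if (vignetting && optics$vignetting_strength > 0) {
    yy <- ((seq_len(nr) - 0.5) / nr - 0.5)
    xx <- ((seq_len(nc) - 0.5) / nc - 0.5)
    r2 <- outer(yy^2, xx^2, `+`) / 0.5
    vmap <- 1 - optics$vignetting_strength * r2
  }

  dat <- array(0, dim = c(nr, nc, length(z_um), length(channels)),
               dimnames = list(NULL, NULL, NULL, channels))
  for (ic in seq_along(channels)) {
    ch <- channels[ic]
    chroma <- optics$chromatic_offset_um[ch]
    if (is.na(chroma) || is.null(chroma)) chroma <- 0
    amp_ch <- obj[[ch]]
    act <- which(amp_ch > 0)
    for (iz in seq_along(z_um)) {
      plane <- matrix(0, nr, nc)
      for (k in act) {
        defocus <- z_um[iz] - (obj$z_um[k] + chroma)
        sig <- .blur_sigma_px(optics, defocus)
        sig_full <- .blur_sigma_px_uncapped(optics, defocus)
        R <- obj$diameter_um[k] / 2 / px
        amp <- amp_ch[k] * R^2 / (R^2 + 2 * sig_full^2)
        plane <- .draw_object(plane,
                              cx = (obj$x_um[k] - stage_xy_um[1]) / px,
                              cy = (obj$y_um[k] - stage_xy_um[2]) / px,
                              R = R, amp = amp, sigma = sig,
                              ecc = obj$ecc[k], theta = obj$theta[k],
                              annulus = obj$class[k] == "pore")
      }
      plane <- (plane + optics$background) * vmap
      if (noise) {
        if (optics$poisson_scale > 0)
          plane <- matrix(rpois(length(plane), pmax(plane, 0) * optics$poisson_scale),
                          nr, nc) / optics$poisson_scale
        if (optics$gaussian_sigma > 0)
          plane <- plane + matrix(rnorm(length(plane), 0, optics$gaussian_sigma), nr, nc)
      }
      dat[, , iz, ic] <- pmin(pmax(plane, 0), 1)
    }
  }
  structure(list(data = dat, z_um = z_um, stage_xy_um = stage_xy_um,
                 channels = channels),
            class = "zstack_tile")
}

#' Render an ideal wide-field image (stitching oracle)
#'
#' Renders a region with every object drawn at its in-focus blur width,
#' without vignetting or noise — the ideal all-in-focus image that the
#' fuse/correct/stitch chain approximates.
#'
#' @inheritParams render_tile
#' @param origin_um upper-left corner of the rendered region (microns).
#' @param shape_px `c(rows, cols)` of the output.
#' @return array `[rows, cols, n_channels]` with channel dimnames.
#' @export
render_widefield <- function(scene, optics, origin_um = c(0, 0),
                             shape_px = c(1024, 1024),
                             channels = c("DAPI", "CK", "FAP")) {
  nr <- shape_px[1]; nc <- shape_px[2]
  px <- optics$pixel_size_um
  obj <- scene$objects
  out <- array(0, dim = c(nr, nc, length(channels)),
               dimnames = list(NULL, NULL, channels))
  for (ic in seq_along(channels)) {
    ch <- channels[ic]
    plane <- matrix(0, nr, nc)
    act <- which(obj[[ch]] > 0)
    for (k in act) {
      R <- obj$diameter_um[k] / 2 / px
      plane <- .draw_object(plane,
                            cx = (obj$x_um[k] - origin_um[1]) / px,
                            cy = (obj$y_um[k] - origin_um[2]) / px,
                            R = R, amp = obj[[ch]][k] * R^2 / (R^2 + 2 * optics$sigma_min_px^2),
                            sigma = optics$sigma_min_px,
                            ecc = obj$ecc[k], theta = obj$theta[k],
                            annulus = obj$class[k] == "pore")
    }
    out[, , ic] <- pmin(pmax(plane + optics$background, 0), 1)
  }
  out
}

#' Render a whole-slide scan as a grid of jittered z-stack tiles
#'
#' Tiles are laid out row-major with a nominal pixel overlap. True tile
#' positions differ from nominal ones by sub-pixel stage jitter and a small
#' global rotation between the stage axes and the camera frame, so
#' registration is non-trivial; the true offsets are returned as ground
#' truth.
#'
#' @inheritParams render_tile
#' @param grid `c(n_rows, n_cols)` of tiles.
#' @param tile_overlap_px nominal overlap between adjacent tiles (pixels).
#' @param stage_jitter_px uniform jitter half-range applied per tile (pixels).
#' @param tilt_deg rotation of stage axes relative to the camera frame
#'   (degrees).
#' @param seed integer seed controlling jitter and per-tile noise.
#' @return object of class `wsi_scan`: list with `tiles` (list of
#'   `zstack_tile`, row-major; `stage_xy_um` holds the nominal position),
#'   `truth` (data.frame `tile, row, col, nom_dy_px, nom_dx_px, true_dy_px,
#'   true_dx_px` relative to the anchor tile), `grid`, `tile_shape_px`,
#'   `tile_overlap_px`.
#' @export
render_wsi_scan <- function(scene, optics, grid = c(2, 2),
                            tile_shape_px = c(512, 512), tile_overlap_px = 64,
                            z_um = seq(-25, 25, 5),
                            channels = c("DAPI", "CK", "FAP"),
                            stage_jitter_px = 0.5, tilt_deg = 0.1,
                            noise = TRUE, vignetting = TRUE, seed = 1L) {
  if (any(tile_overlap_px >= tile_shape_px))
    stop("tile_overlap_px must be smaller than the tile dimensions")
  px <- optics$pixel_size_um
  stride <- tile_shape_px - tile_overlap_px
  n_tiles <- prod(grid)

  span_x <- ((grid[2] - 1) * stride[2] + tile_shape_px[2]) * px
  span_y <- ((grid[1] - 1) * stride[1] + tile_shape_px[1]) * px
  if (span_x < scene$extent_um[1] || span_y < scene$extent_um[2])
    warning("scan grid does not cover the full scene extent")

  geo <- .scan_geometry(grid, tile_shape_px, tile_overlap_px, px,
                        stage_jitter_px, tilt_deg, seed)
  tiles <- vector("list", n_tiles)
  for (t_i in seq_len(n_tiles)) {
    tile <- render_tile(scene, optics, stage_xy_um = geo$pos_true[t_i, ],
                        tile_shape_px = tile_shape_px, z_um = z_um,
                        channels = channels, noise = noise,
                        vignetting = vignetting, seed = geo$noise_seeds[t_i])
    tile$stage_xy_um <- c(geo$pos_nom[t_i, ])  # metadata: nominal position
    tiles[[t_i]] <- tile
  }
  structure(list(tiles = tiles, truth = geo$truth, grid = grid,
                 tile_shape_px = tile_shape_px,
                 tile_overlap_px = tile_overlap_px, z_um = z_um,
                 channels = channels, seed = as.integer(seed)),
            class = "wsi_scan")
}

#' Ground-truth bounding boxes of a scene in a pixel frame
#'
#' Boxes are half-open, 0-based pixel coordinates relative to `origin_um`.
#'
#' @param scene a `gt_scene`.
#' @param optics an `optics_model` (for the pixel size).
#' @param origin_um frame origin in microns.
#' @param classes which classes to include.
#' @param shape_px optional `c(rows, cols)`; boxes not fully inside are
#'   dropped.
#' @return detections-style data.frame
#'   (`x_min, y_min, x_max, y_max, label, score, area_px`).
#' @export
scene_boxes <- function(scene, optics, origin_um = c(0, 0),
                        classes = c("mCTC", "CAF"), shape_px = NULL) {
  obj <- scene$objects[scene$objects$class %in% classes, , drop = FALSE]
  px <- optics$pixel_size_um
  R <- obj$diameter_um / 2 / px
  cx <- (obj$x_um - origin_um[1]) / px
  cy <- (obj$y_um - origin_um[2]) / px
  out <- data.frame(
    x_min = floor(cx - R), y_min = floor(cy - R),
    x_max = ceiling(cx + R), y_max = ceiling(cy + R),
    label = obj$class, score = 1,
    area_px = (ceiling(cx + R) - floor(cx - R)) * (ceiling(cy + R) - floor(cy - R)),
    stringsAsFactors = FALSE)
  if (!is.null(shape_px)) {
    keep <- out$x_min >= 0 & out$y_min >= 0 &
      out$x_max <= shape_px[2] & out$y_max <= shape_px[1]
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Tile/scene I/O: one multi-page TIFF per tile (pages channel-major then z)
# with a JSON sidecar, plus ground-truth CSVs.
# ---------------------------------------------------------------------------

#' Write a simulated scan to disk
#'
#' Each tile becomes `tile_<i>.tif` (float pages ordered channel-major then
#' z) plus `tile_<i>.json` (stage position, z positions, channel names).
#' Ground truth is written as `scene.csv` (micron coordinates) and
#' `offsets.csv` (true pixel offsets).
#'
#' @param scan a `wsi_scan`.
#' @param scene the `gt_scene` it was rendered from.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scan <- function(scan, scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(scan$tiles)) {
    tile <- scan$tiles[[i]]
    pages <- list()
    for (ic in seq_along(tile$channels))
      for (iz in seq_along(tile$z_um))
        pages[[length(pages) + 1L]] <- tile$data[, , iz, ic]
    tiff::writeTIFF(pages, file.path(dir, sprintf("tile_%03d.tif", i)),
                    bits.per.sample = 32L, compression = "none")
    jsonlite::write_json(
      list(stage_xy_um = tile$stage_xy_um, z_positions_um = tile$z_um,
           channel_names = tile$channels),
      file.path(dir, sprintf("tile_%03d.json", i)), auto_unbox = FALSE,
      digits = NA)
  }
  write.csv(scene$objects[, c("id", "class", "x_um", "y_um", "z_um", "diameter_um")],
            file.path(dir, "scene.csv"), row.names = FALSE)
  write.csv(scan$truth, file.path(dir, "offsets.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a scan written by [write_scan()]
#'
#' @param dir directory containing `tile_*.tif` / `tile_*.json`.
#' @return list with `tiles` (list of `zstack_tile`) and, when present,
#'   `scene_table` and `truth`.
#' @export
read_scan <- function(dir) {
  tifs <- sort(list.files(dir, pattern = "^tile_[0-9]+\\.tif$", full.names = TRUE))
  tiles <- lapply(tifs, function(f) {
    meta <- jsonlite::read_json(sub("\\.tif$", ".json", f), simplifyVector = TRUE)
    pages <- tiff::readTIFF(f, all = TRUE)
    n_ch <- length(meta$channel_names); n_z <- length(meta$z_positions_um)
    stopifnot(length(pages) == n_ch * n_z)
    nr <- nrow(pages[[1]]); nc <- ncol(pages[[1]])
    dat <- array(0, dim = c(nr, nc, n_z, n_ch),
                 dimnames = list(NULL, NULL, NULL, meta$channel_names))
    k <- 0L
    for (ic in seq_len(n_ch)) for (iz in seq_len(n_z)) {
      k <- k + 1L
      dat[, , iz, ic] <- pages[[k]]
    }
    structure(list(data = dat, z_um = meta$z_positions_um,
                   stage_xy_um = meta$stage_xy_um,
                   channels = meta$channel_names),
              class = "zstack_tile")
  })
  out <- list(tiles = tiles)
  sc <- file.path(dir, "scene.csv")
  if (file.exists(sc)) out$scene_table <- read.csv(sc, stringsAsFactors = FALSE)
  of <- file.path(dir, "offsets.csv")
  if (file.exists(of)) out$truth <- read.csv(of)
  out
}
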