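# ---------------------------------------------------------------------------
# Coarse-then-fine autofocus: Tenengrad focus measure over a coarse z-stack,
# Gaussian fit of the focus curve, and fine-scan planning. Focusing runs in
# the DAPI channel only; the estimated best focus is reused for all channels.
# ---------------------------------------------------------------------------

#' Tenengrad focus measure
#'
#' Sum over the image interior (1-px border excluded) of the squared 3x3
#' Sobel gradient magnitude `Gx^2 + Gy^2`. Translation- and offset-invariant;
#' zero for any constant image. An optional threshold discards squared
#' magnitudes at or below it before summing (default 0 keeps everything).
#'
#' @param img 2-D numeric matrix, both dimensions >= 3.
#' @param threshold discard `Gx^2 + Gy^2` values `<= threshold`.
#' @return non-negative scalar.
#' @export
tenengrad <- function(img, threshold = 0) {
  if (!is.matrix(img) || min(dim(img)) < 3)
    stop("tenengrad needs a matrix with both dimensions >= 3")
  nr <- nrow(img); nc <- ncol(img)
  i <- 2:(nr - 1); j <- 2:(nc - 1)
  gx <- (img[i - 1, j + 1] + 2 * img[i, j + 1] + img[i + 1, j + 1]) -
        (img[i - 1, j - 1] + 2 * img[i, j - 1] + img[i + 1, j - 1])
  gy <- (img[i + 1, j - 1] + 2 * img[i + 1, j] + img[i + 1, j + 1]) -
        (img[i - 1, j - 1] + 2 * img[i - 1, j] + img[i - 1, j + 1])
  g2 <- gx * gx + gy * gy
  if (threshold > 0) g2 <- g2[g2 > threshold]
  sum(g2)
}

#' Axial scan plan
#'
#' Defaults: coarse 20 um steps over a 200 um range, fine 5 um steps over a
#' 50 um range, focusing on the DAPI channel.
#'
#' @param coarse_step_um,coarse_range_um coarse scan step and range (um).
#' @param fine_step_um,fine_range_um fine scan step and range (um).
#' @param focus_channel channel used for focusing.
#' @return object of class `scan_plan`.
#' @export
scan_plan <- function(coarse_step_um = 20, coarse_range_um = 200,
                      fine_step_um = 5, fine_range_um = 50,
                      focus_channel = "DAPI") {
  if (coarse_step_um <= 0 || fine_step_um <= 0) stop("steps must be positive")
  if (coarse_range_um < coarse_step_um || fine_range_um < fine_step_um)
    stop("ranges must be at least one step")
  structure(list(coarse_step_um = coarse_step_um,
                 coarse_range_um = coarse_range_um,
                 fine_step_um = fine_step_um, fine_range_um = fine_range_um,
                 focus_channel = focus_channel),
            class = "scan_plan")
}

#' Focus curve of a z-stack tile
#'
#' Tenengrad of each z-plane in the requested channel.
#'
#' @param tile a `zstack_tile` with at least 3 planes.
#' @param channel channel name (default the DAPI focus channel).
#' @param threshold passed to [tenengrad()].
#' @return object of class `focus_curve`: list `z_um`, `f_values`, `fit`
#'   (`NULL` until [fit_best_focus()] is applied).
#' @export
focus_curve <- function(tile, channel = "DAPI", threshold = 0) {
  if (!channel %in% tile$channels)
    stop("channel '", channel, "' not present in tile")
  if (length(tile$z_um) < 3) stop("need at least 3 z-planes")
  ic <- match(channel, tile$channels)
  f <- vapply(seq_along(tile$z_um),
              function(iz) tenengrad(tile$data[, , iz, ic], threshold),
              numeric(1))
  structure(list(z_um = tile$z_um, f_values = f, fit = NULL),
            class = "focus_curve")
}

#' Fit a Gaussian peak to a focus curve
#'
#' Four-parameter Levenberg-Marquardt least squares of
#' `f(z) = A exp(-(z - mu)^2 / (2 sigma^2)) + B`, initialised at the discrete
#' argmax. If the fit does not converge, or the fitted peak lies outside the
#' scanned range, the curve falls back to the discrete argmax (ties broken
#' toward lower z) and is flagged `converged = FALSE`.
#'
#' @param curve a `focus_curve` with at least 4 points.
#' @return the curve with `fit = list(mu_um, sigma_um, amplitude, offset,
#'   converged)` filled in.
#' @export
fit_best_focus <- function(curve) {
  z <- curve$z_um; f <- curve$f_values
  if (length(z) < 4) stop("insufficient data: need >= 4 points for a 4-parameter fit")
  i_max <- which.max(f)  # which.max already breaks ties toward lower index
  fallback <- list(mu_um = z[i_max], sigma_um = NA_real_,
                   amplitude = NA_real_, offset = NA_real_, converged = FALSE)
  if (diff(range(f)) <= 0) {
    curve$fit <- fallback
    return(curve)
  }
  step0 <- median(diff(z))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      fv ~ A * exp(-(zv - mu)^2 / (2 * s^2)) + B,
      data = data.frame(zv = z, fv = f),
      start = list(A = max(f) - min(f), mu = z[i_max], s = step0, B = min(f)),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-8,
                                           ptol = 1e-8)),
    error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    curve$fit <- fallback
    return(curve)
  }
  cf <- stats::coef(fit)
  if (!is.finite(cf[["mu"]]) || cf[["mu"]] < min(z) || cf[["mu"]] > max(z)) {
    curve$fit <- fallback
    return(curve)
  }
  curve$fit <- list(mu_um = unname(cf[["mu"]]),
                    sigma_um = abs(unname(cf[["s"]])),
                    amplitude = unname(cf[["A"]]), offset = unname(cf[["B"]]),
                    converged = TRUE)
  curve
}

#' Best-focus position of a fitted focus curve
#'
#' @param curve a `focus_curve` after [fit_best_focus()].
#' @return best focus z (um).
#' @export
best_focus_z <- function(curve) {
  if (is.null(curve$fit)) stop("curve has no fit; call fit_best_focus() first")
  curve$fit$mu_um
}

#' Plan the fine axial scan around a best-focus estimate
#'
#' Positions `best_z - range/2 ... best_z + range/2` at `fine_step` spacing,
#' inclusive of both ends when the range divides evenly. The same positions
#' are reused for every channel.
#'
#' @param best_z_um best focus position (um).
#' @param plan a `scan_plan`.
#' @return numeric vector of z positions (um).
#' @export
plan_fine_scan <- function(best_z_um, plan = scan_plan()) {
  half <- plan$fine_range_um / 2
  seq(best_z_um - half, best_z_um + half, by = plan$fine_step_um)
}

#' Coarse z positions of a plan
#'
#' Centered on `center_z_um`, spanning the coarse range at the coarse step.
#'
#' @param plan a `scan_plan`.
#' @param center_z_um center of the coarse scan (um).
#' @return numeric vector of z positions (um).
#' @export
plan_coarse_scan <- function(plan = scan_plan(), center_z_um = 0) {
  half <- plan$coarse_range_um / 2
  seq(center_z_um - half, center_z_um + half, by = plan$coarse_step_um)
}

#' Make a camera interface over a simulated scene
#'
#' Returns a closure `function(stage_xy_um, z_um, channel)` rendering the
#' requested planes as a `zstack_tile` — the interface [autofocus_tile()]
#' expects, which a hardware stage would otherwise provide.
#'
#' @param scene a `gt_scene`.
#' @param optics an `optics_model`.
#' @param tile_shape_px tile shape `c(rows, cols)`.
#' @param noise,vignetting passed to [render_tile()].
#' @param seed optional base seed; each render derives its own stream.
#' @return rendering closure.
#' @export
scene_camera <- function(scene, optics, tile_shape_px = c(512, 512),
                         noise = TRUE, vignetting = TRUE, seed = NULL) {
  counter <- 0L
  function(stage_xy_um, z_um, channel = "DAPI") {
    counter <<- counter + 1L
    s <- if (is.null(seed)) NULL else (seed + counter) %% .Machine$integer.max
    render_tile(scene, optics, stage_xy_um = stage_xy_um,
                tile_shape_px = tile_shape_px, z_um = z_um,
                channels = channel, noise = noise, vignetting = vignetting,
                seed = s)
  }
}

#' Autofocus one lateral position
#'
#' Renders (or acquires) the coarse DAPI z-stack at `stage_xy_um`, computes
#' the Tenengrad focus curve, and fits the Gaussian peak. Autofocusing is
#' repeated independently for every lateral position and runs only in the
#' focus channel; the result is reused across channels.
#'
#' @param camera a `function(stage_xy_um, z_um, channel)` returning a
#'   `zstack_tile` (see [scene_camera()]).
#' @param stage_xy_um lateral stage position (um).
#' @param plan a `scan_plan`.
#' @param center_z_um center of the coarse scan (um).
#' @return list `best_z_um`, `curve` (fitted `focus_curve`).
#' @export
autofocus_tile <- function(camera, stage_xy_um = c(0, 0), plan = scan_plan(),
                           center_z_um = 0) {
  z_coarse <- plan_coarse_scan(plan, center_z_um)
  tile <- camera(stage_xy_um, z_coarse, plan$focus_channel)
  curve <- focus_curve(tile, plan$focus_channel)
  curve <- fit_best_focus(curve)
  list(best_z_um = best_focus_z(curve), curve = curve)
}
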