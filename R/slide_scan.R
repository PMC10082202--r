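# ---------------------------------------------------------------------------
# Acquisition driver: repeat per-tile autofocus (coarse scan, Gaussian fit)
# and fine z-stack capture over a lateral grid — the full scan strategy the
# rest of the pipeline consumes.
# ---------------------------------------------------------------------------

# nominal and true (jittered, tilted) tile positions for a scan grid
.scan_geometry <- function(grid, tile_shape_px, tile_overlap_px, px,
                           stage_jitter_px, tilt_deg, seed) {
  stride <- tile_shape_px - tile_overlap_px
  n_tiles <- prod(grid)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  jit <- matrix(runif(2 * n_tiles, -stage_jitter_px, stage_jitter_px) * px,
                n_tiles, 2)
  noise_seeds <- sample.int(.Machine$integer.max - 1L, n_tiles)
  th <- tilt_deg * pi / 180
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  truth <- data.frame(tile = seq_len(n_tiles), row = 0L, col = 0L,
                      nom_dy_px = 0, nom_dx_px = 0,
                      true_dy_px = 0, true_dx_px = 0)
  pos_nom <- matrix(0, n_tiles, 2)   # (x, y) um
  pos_true <- matrix(0, n_tiles, 2)
  t_i <- 0L
  for (r in seq_len(grid[1])) for (cc in seq_len(grid[2])) {
    t_i <- t_i + 1L
    nom <- c((cc - 1) * stride[2] * px, (r - 1) * stride[1] * px)
    pos_nom[t_i, ] <- nom
    pos_true[t_i, ] <- as.vector(rot %*% nom) + jit[t_i, ]
    truth$row[t_i] <- r - 1L; truth$col[t_i] <- cc - 1L
    truth$nom_dx_px[t_i] <- nom[1] / px; truth$nom_dy_px[t_i] <- nom[2] / px
  }
  anchor <- pos_true[1, ]
  truth$true_dx_px <- (pos_true[, 1] - anchor[1]) / px
  truth$true_dy_px <- (pos_true[, 2] - anchor[2]) / px
  list(truth = truth, pos_nom = pos_nom, pos_true = pos_true,
       noise_seeds = noise_seeds)
}

#' Scan a slide: per-tile autofocus plus fine z-stacks
#'
#' For every lateral position of the scan grid, a coarse DAPI z-stack is
#' acquired and the Gaussian-fitted Tenengrad peak gives the tile's best
#' focus; the fine z-stack (all channels, same z positions for every
#' channel) is then captured centered on it. Stage jitter and a small
#' stage-to-camera rotation perturb the true tile positions; the true
#' offsets are recorded as ground truth.
#'
#' @param scene a `gt_scene`.
#' @param optics an `optics_model`.
#' @param grid `c(n_rows, n_cols)` of tiles.
#' @param tile_shape_px tile shape `c(rows, cols)`.
#' @param tile_overlap_px nominal tile overlap (pixels).
#' @param plan a `scan_plan` (coarse/fine steps and ranges).
#' @param stage_jitter_px uniform jitter half-range (pixels).
#' @param tilt_deg stage-to-camera rotation (degrees).
#' @param channels channels for the fine stack.
#' @param noise,vignetting rendering options.
#' @param seed master seed (jitter, noise streams).
#' @return a `wsi_scan` whose tiles carry per-tile fine `z_um`, plus a
#'   `focus` data.frame (`tile, best_z_um, converged`).
#' @export
scan_slide <- function(scene, optics, grid = c(3, 3),
                       tile_shape_px = c(512, 512), tile_overlap_px = 128,
                       plan = scan_plan(), stage_jitter_px = 0.5,
                       tilt_deg = 0.1, channels = c("DAPI", "CK", "FAP"),
                       noise = TRUE, vignetting = TRUE, seed = 1L) {
  if (any(tile_overlap_px >= tile_shape_px))
    stop("tile_overlap_px must be smaller than the tile dimensions")
  px <- optics$pixel_size_um
  geo <- .scan_geometry(grid, tile_shape_px, tile_overlap_px, px,
                        stage_jitter_px, tilt_deg, seed)
  n_tiles <- prod(grid)
  tiles <- vector("list", n_tiles)
  focus <- data.frame(tile = seq_len(n_tiles), best_z_um = NA_real_,
                      converged = NA)
  for (t_i in seq_len(n_tiles)) {
    pos <- geo$pos_true[t_i, ]
    coarse <- render_tile(scene, optics, stage_xy_um = pos,
                          tile_shape_px = tile_shape_px,
                          z_um = plan_coarse_scan(plan),
                          channels = plan$focus_channel, noise = noise,
                          vignetting = vignetting,
                          seed = geo$noise_seeds[t_i])
    curve <- fit_best_focus(focus_curve(coarse, plan$focus_channel))
    best_z <- best_focus_z(curve)
    focus$best_z_um[t_i] <- best_z
    focus$converged[t_i] <- curve$fit$converged
    tile <- render_tile(scene, optics, stage_xy_um = pos,
                        tile_shape_px = tile_shape_px,
                        z_um = plan_fine_scan(best_z, plan),
                        channels = channels, noise = noise,
                        vignetting = vignetting,
                        seed = geo$noise_seeds[t_i] + 1L)
    tile$stage_xy_um <- c(geo$pos_nom[t_i, ])
    tiles[[t_i]] <- tile
  }
  structure(list(tiles = tiles, truth = geo$truth, focus = focus,
                 grid = grid, tile_shape_px = tile_shape_px,
                 tile_overlap_px = tile_overlap_px, channels = channels,
                 seed = as.integer(seed)),
            class = "wsi_scan")
}
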