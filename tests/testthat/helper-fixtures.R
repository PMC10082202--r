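# Shared fixtures: small scenes and tiles built in code at test time.

fx_optics <- function(...) optics_model(...)

# flat membrane with a single centered tumor cell at z = z0
fx_single_cell_scene <- function(z0 = 0, extent_um = 120, diameter_um = 15,
                                 class = "mCTC", seed = 1) {
  surf <- generate_surface(c(extent_um, extent_um), amplitude_um = 0,
                           pixel_pitch_um = 5, seed = seed)
  sc <- populate_scene(surf, n_mctc = 1, n_caf = 0, n_pore = 0, n_precip = 0,
                       seed = seed, min_dist_um = 0,
                       margin_um = extent_um / 2 - 1)
  sc$objects$x_um <- extent_um / 2
  sc$objects$y_um <- extent_um / 2
  sc$objects$z_um <- z0
  sc$objects$diameter_um <- diameter_um
  if (class == "CAF") {
    sc$objects$class <- "CAF"
    sc$objects$CK <- 0
    sc$objects$FAP <- 0.7
  }
  sc
}

# a dense-enough scene sized to one tile field of view (cells per FOV
# comparable to a loaded model-system slide)
fx_tile_scene <- function(seed, tile_px = 448, optics = fx_optics(),
                          amplitude_um = 15, n_mctc = 8, n_caf = 3,
                          n_pore = 10, n_precip = 5, min_dist_um = 12) {
  ext <- tile_px * optics$pixel_size_um
  surf <- generate_surface(c(ext, ext), amplitude_um = amplitude_um,
                           correlation_length_um = 500, pixel_pitch_um = 5,
                           seed = seed)
  populate_scene(surf, n_mctc = n_mctc, n_caf = n_caf, n_pore = n_pore,
                 n_precip = n_precip, seed = seed + 5000,
                 min_dist_um = min_dist_um, margin_um = 8)
}

# scene spanning a tile grid with given overlap
fx_grid_scene <- function(seed, grid = c(2, 2), tile_px = 384,
                          overlap_px = 96, optics = fx_optics(),
                          amplitude_um = 8, n_mctc = 12, n_caf = 4,
                          n_pore = 12, n_precip = 6, min_dist_um = 12,
                          margin_um = 8) {
  span_x <- (tile_px - overlap_px) * (grid[2] - 1) + tile_px
  span_y <- (tile_px - overlap_px) * (grid[1] - 1) + tile_px
  ext <- c(span_x, span_y) * optics$pixel_size_um
  surf <- generate_surface(ext, amplitude_um = amplitude_um,
                           correlation_length_um = 400, pixel_pitch_um = 5,
                           seed = seed)
  populate_scene(surf, n_mctc = n_mctc, n_caf = n_caf, n_pore = n_pore,
                 n_precip = n_precip, seed = seed + 7000,
                 min_dist_um = min_dist_um, margin_um = margin_um)
}

# detections data.frame shorthand
fx_box <- function(x_min, y_min, x_max, y_max, label = "mCTC", score = 1) {
  data.frame(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
             label = label, score = score,
             area_px = (x_max - x_min) * (y_max - y_min),
             stringsAsFactors = FALSE)
}

# brute-force pixel-counting overlap ratio oracle (integer boxes)
fx_overlap_oracle <- function(a, b, mode = "min") {
  grid_x <- seq(min(a[1], b[1]), max(a[3], b[3]) - 1)
  grid_y <- seq(min(a[2], b[2]), max(a[4], b[4]) - 1)
  px <- expand.grid(x = grid_x, y = grid_y)
  in_a <- px$x >= a[1] & px$x < a[3] & px$y >= a[2] & px$y < a[4]
  in_b <- px$x >= b[1] & px$x < b[3] & px$y >= b[2] & px$y < b[4]
  inter <- sum(in_a & in_b)
  if (mode == "min") inter / min(sum(in_a), sum(in_b))
  else inter / sum(in_a | in_b)
}

# brute-force 3x3 Sobel Tenengrad oracle
fx_tenengrad_oracle <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  nr <- nrow(img); nc <- ncol(img)
  s <- 0
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    patch <- img[(i - 1):(i + 1), (j - 1):(j + 1)]
    s <- s + sum(patch * kx)^2 + sum(patch * ky)^2
  }
  s
}
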