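# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

# Render a filled disc into a matrix (independent of the package's
# renderer; used to build detection fixtures).
disc_image <- function(dim, centers_px, radius_px, value = 0.6) {
  im <- matrix(0, dim[1], dim[2])
  for (ctr in centers_px) {
    hit <- outer((seq_len(dim[1]) - 0.5 - ctr[2])^2,
                 (seq_len(dim[2]) - 0.5 - ctr[1])^2, `+`) <= radius_px^2
    im[hit] <- value
  }
  im
}

# Abstract profile set from centroid coordinates (no label images).
abstract_profiles <- function(x_um, y_um, section, area_um2 = 20,
                              pixel_size_um = 1, section_count = max(section),
                              positivity = NA_character_) {
  if (length(section) == 0) {
    df <- data.frame(section_index = integer(), label = integer(),
                     x_um = numeric(), y_um = numeric(),
                     area_um2 = numeric(), mean_intensity = numeric(),
                     positivity = character())
    return(profile_set(df, section_count, pixel_size_um))
  }
  df <- data.frame(section_index = section,
                   label = stats::ave(section, section, FUN = seq_along),
                   x_um = x_um, y_um = y_um,
                   area_um2 = area_um2, mean_intensity = NA_real_,
                   positivity = positivity)
  profile_set(df, section_count, pixel_size_um)
}

# All-tissue mask stack covering a given image size.
full_masks <- function(imdim, n_sections, pixel_size_um = 1) {
  mask_stack(replicate(n_sections, matrix(TRUE, imdim[1], imdim[2]),
                       simplify = FALSE), pixel_size_um)
}

# Default synthetic scene shared across test files: a 250 x 250 x 140 um
# box at density 1e-4 um^-3, q = 0.5, the reference geometry (D = 6 um,
# t = 7 um, 0.9 um/px), moderate noise.
scene_default <- function() {
  if (is.null(.fixtures$scene)) {
    gt <- sample_nuclei(solid_box(c(250, 250, 140)), 1e-4, 0.5, seed = 42)
    rend <- render_section_stack(gt, t = 7, pixel_size_um = 0.9,
                                 noise = list(gaussian_sd = 0.02))
    masks <- segment_tissue(rend$channels$tissue, "per_section_auto")
    ps <- detect_profiles_stack(rend$channels$nuclear, NULL, 10,
                                min_area_um2 = 4)
    ps <- split_large_profiles(ps)
    ps <- classify_positive(ps, rend$channels$specific$images)
    grid <- build_boxel_grid(ps, masks, 26, 7)
    .fixtures$scene <- list(gt = gt, rend = rend, masks = masks, ps = ps,
                            grid = grid)
  }
  .fixtures$scene
}

# Independent oracle for the sample-volume smoothing equivalence: bin
# profiles and mask pixels to m = 1 boxels, then take the edge-clipped
# m-cube moving sum by brute force.
oracle_moving_sum <- function(arr, m) {
  d <- dim(arr)
  h <- (m - 1) %/% 2
  out <- array(0, dim = d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    out[i, j, k] <- sum(arr[max(1, i - h):min(d[1], i + h),
                            max(1, j - h):min(d[2], j + h),
                            max(1, k - h):min(d[3], k + h)])
  }
  out
}

# Independent m = 1 binning of a profile set (centroid rule), same
# conventions as the package documents: boxel = floor((x - origin)/b),
# clamped to the grid.
oracle_bin_profiles <- function(ps, grid, which_profiles = TRUE) {
  df <- ps$profiles[which_profiles, , drop = FALSE]
  b <- grid$boxel_size_um
  clamp <- function(v, n) pmin(pmax(v, 1), n)
  ix <- clamp(floor((df$x_um - grid$origin_um[1]) / b) + 1, grid$dims[1])
  iy <- clamp(floor((df$y_um - grid$origin_um[2]) / b) + 1, grid$dims[2])
  iz <- clamp(floor((df$section_index - grid$section_offset) /
                      grid$sections_per_boxel) + 1, grid$dims[3])
  arr <- array(0, dim = grid$dims)
  for (i in seq_along(ix)) arr[ix[i], iy[i], iz[i]] <- arr[ix[i], iy[i], iz[i]] + 1
  arr
}
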