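#' Build the boxel grid over the detected content
#'
#' The bounding box of all detected profiles and tissue-mask foreground
#' is subdivided into a 3D lattice of virtual cubes ("boxels"). The
#' in-plane boxel edge is `boxel_size_um` (chosen in the order of a cell
#' diameter, ~25 um); along the cutting axis the boxel spans
#' `sections_per_boxel = round(boxel_size_um / t)` whole sections, so its
#' z-extent is snapped to a multiple of the section thickness.
#'
#' @param profiles a [profile_set()] (may be empty if `masks` is not).
#' @param masks a `tissue_mask_stack`, or `NULL`.
#' @param boxel_size_um boxel edge length (default 26).
#' @param section_thickness_um section thickness `t`.
#' @return object of class `boxel_grid`: `boxel_size_um`, `dims`
#'   `(nx, ny, nz)`, `origin_um` (x, y, z), `sections_per_boxel`,
#'   `section_offset` (first section covered), `pixel_size_um`,
#'   `section_thickness_um`.
#' @export
build_boxel_grid <- function(profiles, masks, boxel_size_um = 26,
                             section_thickness_um) {
  t <- section_thickness_um
  stopifnot(boxel_size_um >= t)
  b <- boxel_size_um
  xs <- ys <- numeric(0)
  secs <- integer(0)
  p <- NULL
  if (!is.null(profiles) && nrow(profiles$profiles) > 0) {
    xs <- profiles$profiles$x_um
    ys <- profiles$profiles$y_um
    secs <- profiles$profiles$section_index
    p <- profiles$pixel_size_um
  }
  if (!is.null(masks)) {
    p <- masks$pixel_size_um
    for (k in seq_along(masks$masks)) {
      fg <- which(masks$masks[[k]], arr.ind = TRUE)
      if (nrow(fg) == 0) next
      secs <- c(secs, k)
      xs <- c(xs, (range(fg[, 2]) - 0.5) * p)
      ys <- c(ys, (range(fg[, 1]) - 0.5) * p)
    }
  }
  if (length(xs) == 0)
    stop("empty input: no profiles and no tissue foreground")
  spb <- max(1L, as.integer(round(b / t)))
  ksec <- range(secs)
  nxy <- function(v) max(1L, as.integer(ceiling((max(v) - min(v)) / b)))
  structure(list(
    boxel_size_um = b,
    dims = c(nx = nxy(xs), ny = nxy(ys),
             nz = max(1L, as.integer(ceiling((ksec[2] - ksec[1] + 1) / spb)))),
    origin_um = c(min(xs), min(ys), (ksec[1] - 1) * t),
    sections_per_boxel = spb,
    section_offset = ksec[1],
    pixel_size_um = p,
    section_thickness_um = t
  ), class = "boxel_grid")
}

#' @export
print.boxel_grid <- function(x, ...) {
  cat(sprintf(
    "boxel_grid: %d x %d x %d boxels of %.3g um (z: %d sections = %.3g um)\n",
    x$dims[1], x$dims[2], x$dims[3], x$boxel_size_um,
    x$sections_per_boxel, x$sections_per_boxel * x$section_thickness_um))
  invisible(x)
}

# Boxel index of in-plane coordinates / section numbers, clamped so
# content exactly on the far bounding-box face joins the last boxel.
boxel_index_xy <- function(coord_um, origin, b, n) {
  pmin(pmax(floor((coord_um - origin) / b) + 1L, 1L), n)
}
boxel_index_z <- function(section, grid) {
  pmin(pmax(floor((section - grid$section_offset) /
                    grid$sections_per_boxel) + 1L, 1L), grid$dims[3])
}

#' Slide the sample volume over every boxel position
#'
#' The sample volume is a cube of `m x m x m` boxels (`m` odd so a
#' center boxel exists). For every boxel position the cube is centered
#' there (clipped at the grid edges; clipping is recorded) and three raw
#' quantities are accumulated over the cube's section/pixel footprint and
#' projected to the center boxel: the tissue-of-interest area, the total
#' number of nuclear profiles, and the number of positive profiles.
#' Profiles are counted by their centroid (each profile belongs to
#' exactly one boxel) and only within the tissue of interest.
#'
#' @param grid a [build_boxel_grid()] lattice.
#' @param profiles a [profile_set()], classified if positive counts are
#'   wanted.
#' @param masks a `tissue_mask_stack` delimiting the tissue of interest.
#' @param m sample-volume edge in boxels (odd, default 5: e.g. a 130 um
#'   sample volume of 26 um boxels).
#' @return object of class `raw_counts`: arrays `tissue_area_sum_um2`,
#'   `n_profiles_total`, `n_profiles_positive` indexed `[ix, iy, iz]`,
#'   logical array `clipped`, scalar `n_in_tissue` (profiles inside the
#'   tissue masks), plus `m` and the grid.
#' @export
measure_sample_volumes <- function(grid, profiles, masks, m = 5L) {
  m <- as.integer(m)
  if (m < 1L || m %% 2L == 0L)
    stop("sample volume edge m must be an odd positive number of boxels ",
         "(even cubes have no center boxel)")
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  b <- grid$boxel_size_um
  p <- grid$pixel_size_um
  h <- (m - 1L) %/% 2L

  df <- profiles$profiles
  if (nrow(df) > 0 && !is.null(masks)) {
    imdim <- dim(masks$masks[[1]])
    pc <- pmin(pmax(floor(df$x_um / p) + 1L, 1L), imdim[2])
    pr <- pmin(pmax(floor(df$y_um / p) + 1L, 1L), imdim[1])
    in_tissue <- vapply(seq_len(nrow(df)), function(i)
      masks$masks[[df$section_index[i]]][pr[i], pc[i]], logical(1))
    df <- df[in_tissue, , drop = FALSE]
  }
  ix <- boxel_index_xy(df$x_um, grid$origin_um[1], b, nx)
  iy <- boxel_index_xy(df$y_um, grid$origin_um[2], b, ny)
  iz <- boxel_index_z(df$section_index, grid)
  lin <- (iz - 1L) * nx * ny + (iy - 1L) * nx + ix
  tot1 <- array(tabulate(lin, nbins = nx * ny * nz), dim = c(nx, ny, nz))
  is_pos <- !is.na(df$positivity) & df$positivity == "positive"
  pos1 <- array(tabulate(lin[is_pos], nbins = nx * ny * nz),
                dim = c(nx, ny, nz))

  # per-section integral images of the tissue masks for footprint sums
  sats <- NULL
  if (!is.null(masks)) {
    sats <- lapply(masks$masks, function(msk) {
      s <- matrix(0, nrow(msk) + 1L, ncol(msk) + 1L)
      s[-1, -1] <- t(apply(apply(msk, 2, cumsum), 1, cumsum))
      s
    })
    imdim <- dim(masks$masks[[1]])
  }

  tot <- pos <- area <- array(0, dim = c(nx, ny, nz))
  clipped <- array(FALSE, dim = c(nx, ny, nz))
  for (i in seq_len(nx)) {
    i1 <- max(1L, i - h); i2 <- min(nx, i + h)
    cr <- if (!is.null(sats))
      um_range_to_pixels(grid$origin_um[1] + c(i1 - 1, i2) * b, p, imdim[2])
    for (j in seq_len(ny)) {
      j1 <- max(1L, j - h); j2 <- min(ny, j + h)
      rr <- if (!is.null(sats))
        um_range_to_pixels(grid$origin_um[2] + c(j1 - 1, j2) * b, p, imdim[1])
      # tissue pixel count of this in-plane window, per section
      sec_area <- if (!is.null(sats) && cr[2] >= cr[1] && rr[2] >= rr[1])
        vapply(sats, function(s)
          s[rr[2] + 1L, cr[2] + 1L] - s[rr[1], cr[2] + 1L] -
            s[rr[2] + 1L, cr[1]] + s[rr[1], cr[1]], numeric(1))
      else rep(0, if (is.null(masks)) 0 else length(masks$masks))
      for (k in seq_len(nz)) {
        k1 <- max(1L, k - h); k2 <- min(nz, k + h)
        tot[i, j, k] <- sum(tot1[i1:i2, j1:j2, k1:k2])
        pos[i, j, k] <- sum(pos1[i1:i2, j1:j2, k1:k2])
        if (!is.null(sats)) {
          s1 <- grid$section_offset + (k1 - 1L) * grid$sections_per_boxel
          s2 <- min(grid$section_offset + k2 * grid$sections_per_boxel - 1L,
                    length(sec_area))
          if (s2 >= s1)
            area[i, j, k] <- sum(sec_area[s1:s2]) * p^2
        }
        clipped[i, j, k] <- (i - h < 1L) || (i + h > nx) ||
          (j - h < 1L) || (j + h > ny) || (k - h < 1L) || (k + h > nz)
      }
    }
  }
  structure(list(tissue_area_sum_um2 = area,
                 n_profiles_total = tot,
                 n_profiles_positive = pos,
                 clipped = clipped,
                 n_in_tissue = nrow(df),
                 m = m, grid = grid),
            class = "raw_counts")
}

# Pixel (column or row) index range whose centers fall in [lo, hi) um.
um_range_to_pixels <- function(range_um, p, n) {
  c1 <- max(1L, as.integer(ceiling(range_um[1] / p + 0.5)))
  c2 <- min(n, as.integer(ceiling(range_um[2] / p + 0.5)) - 1L)
  c(c1, c2)
}

#' Cumulative distribution of profiles counted per sample volume
#'
#' Over the tissue-containing boxels (nonzero tissue area), the fraction
#' of boxels whose sample volume counted at most `n` profiles, as a
#' nondecreasing step function, plus the fraction counted with fewer
#' profiles than required — the fraction of the tissue volume measured
#' with less confidence.
#'
#' @param raw a [measure_sample_volumes()] result.
#' @param required_n required profiles per sample volume (default 171,
#'   see [required_profile_count()]).
#' @return list with `curve` (data.frame `n`, `fraction_le`),
#'   `fraction_below` and `required_n`.
#' @export
cumulative_count_distribution <- function(raw, required_n = 171L) {
  counts <- raw$n_profiles_total[raw$tissue_area_sum_um2 > 0]
  if (length(counts) == 0)
    stop("no tissue-containing boxels")
  ns <- sort(unique(counts))
  curve <- data.frame(n = ns,
                      fraction_le = vapply(ns, function(v) mean(counts <= v),
                                           numeric(1)))
  list(curve = curve,
       fraction_below = mean(counts < required_n),
       required_n = required_n)
}

#' Pilot sweep to choose the sample-volume size
#'
#' Measures with stepwise increasing sample volumes and picks the
#' smallest that leaves at most `tolerance` of the tissue-containing
#' boxels below the required profile count. A larger sample volume gains
#' precision but loses spatial resolution, so the smallest sufficient
#' cube is preferred; if none qualifies the best candidate is returned
#' with a warning.
#'
#' @inheritParams measure_sample_volumes
#' @param required_n required profiles per sample volume.
#' @param m_candidates odd cube edges to try, sorted increasing.
#' @param tolerance acceptable fraction of under-counted boxels
#'   (default 0.05).
#' @return list with `m`, `fraction_below` and the full `sweep`
#'   data.frame (`m`, `fraction_below`).
#' @export
choose_sample_volume <- function(grid, profiles, masks, required_n = 171L,
                                 m_candidates = c(1L, 3L, 5L, 7L),
                                 tolerance = 0.05) {
  m_candidates <- sort(as.integer(m_candidates))
  frac <- vapply(m_candidates, function(m) {
    raw <- measure_sample_volumes(grid, profiles, masks, m)
    cumulative_count_distribution(raw, required_n)$fraction_below
  }, numeric(1))
  sweep <- data.frame(m = m_candidates, fraction_below = frac)
  ok <- which(frac <= tolerance)
  if (length(ok) > 0) {
    pick <- ok[1]
  } else {
    pick <- which.min(frac)
    warning("no candidate sample volume reaches the required count in ",
            sprintf("%.0f%%", 100 * (1 - tolerance)),
            " of tissue boxels; returning the best (m = ",
            m_candidates[pick], ")")
  }
  list(m = m_candidates[pick], fraction_below = frac[pick], sweep = sweep)
}
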