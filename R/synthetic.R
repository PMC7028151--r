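#' Analytic tissue solids for simulation
#'
#' Ground-truth tissue shapes for the section-stack simulator: an
#' axis-aligned box, a z-axis cylinder, or an ellipsoid. Each solid
#' carries its bounding box, an exact membership predicate and its
#' analytic volume.
#'
#' @param size_um length-3 extents of the box (x, y, z).
#' @param origin_um corner of the box (default the origin).
#' @return object of class `tissue_solid` with fields `type`, `bbox`
#'   (2 x 3 matrix, min/max rows), `contains(x, y, z)` and `volume_um3`.
#' @export
solid_box <- function(size_um, origin_um = c(0, 0, 0)) {
  lo <- as.numeric(origin_um); hi <- lo + as.numeric(size_um)
  structure(list(
    type = "box", bbox = rbind(lo, hi),
    contains = function(x, y, z)
      x >= lo[1] & x < hi[1] & y >= lo[2] & y < hi[2] &
        z >= lo[3] & z < hi[3],
    volume_um3 = prod(size_um)), class = "tissue_solid")
}

#' @rdname solid_box
#' @param radius_um,height_um cylinder radius and height; the axis is
#'   parallel to z.
#' @param center_xy_um in-plane center of the cylinder axis.
#' @param z0_um z of the bottom face (default 0).
#' @export
solid_cylinder <- function(radius_um, height_um,
                           center_xy_um = c(radius_um, radius_um),
                           z0_um = 0) {
  c0 <- as.numeric(center_xy_um)
  lo <- c(c0 - radius_um, z0_um); hi <- c(c0 + radius_um, z0_um + height_um)
  structure(list(
    type = "cylinder", bbox = rbind(lo, hi),
    contains = function(x, y, z)
      (x - c0[1])^2 + (y - c0[2])^2 <= radius_um^2 &
        z >= z0_um & z < z0_um + height_um,
    volume_um3 = pi * radius_um^2 * height_um), class = "tissue_solid")
}

#' @rdname solid_box
#' @param semiaxes_um length-3 ellipsoid semi-axes.
#' @param center_um ellipsoid center (defaults to `semiaxes_um`).
#' @export
solid_ellipsoid <- function(semiaxes_um, center_um = semiaxes_um) {
  a <- as.numeric(semiaxes_um); ctr <- as.numeric(center_um)
  structure(list(
    type = "ellipsoid", bbox = rbind(ctr - a, ctr + a),
    contains = function(x, y, z)
      ((x - ctr[1]) / a[1])^2 + ((y - ctr[2]) / a[2])^2 +
        ((z - ctr[3]) / a[3])^2 <= 1,
    volume_um3 = 4 / 3 * pi * prod(a)), class = "tissue_solid")
}

#' Sample a ground-truth nucleus population
#'
#' Draws nuclei as an (inhomogeneous) Poisson point process inside a
#' tissue solid and labels each nucleus positive with the local labeling
#' probability. Defaults mirror a typical embryonic-tissue scene: ~6 um
#' nuclei, each comprising on average 10% of its cell's volume.
#'
#' @param tissue_solid a [solid_box()]/[solid_cylinder()]/
#'   [solid_ellipsoid()].
#' @param density nuclei per um^3: scalar or `function(x, y, z)`.
#' @param li labeling probability: scalar or `function(x, y, z)`.
#' @param D_pos_um,D_neg_um nuclear diameters per type (default 6 um).
#' @param seed RNG seed; identical seeds give identical populations.
#' @return object of class `ground_truth`: data.frame `nuclei`
#'   (`x_um, y_um, z_um, diameter_um, label`), the solid, the density
#'   and labeling fields, and the seed.
#' @export
sample_nuclei <- function(tissue_solid, density, li, D_pos_um = 6,
                          D_neg_um = 6, seed = 1L) {
  set.seed(seed)
  dens_f <- if (is.function(density)) density
  else function(x, y, z) rep(density, length(x))
  li_f <- if (is.function(li)) li else function(x, y, z) rep(li, length(x))
  bb <- tissue_solid$bbox
  vol_bb <- prod(bb[2, ] - bb[1, ])
  # thinning bound: maximal density over a probe lattice (exact for the
  # piecewise-constant and linear fields used in practice)
  probe <- expand.grid(x = seq(bb[1, 1], bb[2, 1], length.out = 11),
                       y = seq(bb[1, 2], bb[2, 2], length.out = 11),
                       z = seq(bb[1, 3], bb[2, 3], length.out = 11))
  rho_max <- max(dens_f(probe$x, probe$y, probe$z))
  n_cand <- stats::rpois(1, rho_max * vol_bb)
  x <- stats::runif(n_cand, bb[1, 1], bb[2, 1])
  y <- stats::runif(n_cand, bb[1, 2], bb[2, 2])
  z <- stats::runif(n_cand, bb[1, 3], bb[2, 3])
  keep <- tissue_solid$contains(x, y, z) &
    stats::runif(n_cand) * rho_max < dens_f(x, y, z)
  x <- x[keep]; y <- y[keep]; z <- z[keep]
  positive <- stats::runif(length(x)) < li_f(x, y, z)
  nuclei <- data.frame(
    x_um = x, y_um = y, z_um = z,
    diameter_um = ifelse(positive, D_pos_um, D_neg_um),
    label = ifelse(positive, "positive", "negative"))
  structure(list(nuclei = nuclei, tissue_solid = tissue_solid,
                 density_field = dens_f, li_field = li_f, seed = seed),
            class = "ground_truth")
}

#' Per-section profile table of a ground-truth population
#'
#' The geometric core of the sectioning model: a nucleus (a sphere of
#' diameter `D`) produces a profile in every slab
#' `[(k-1) t, k t)` its sphere intersects — the double-counting event the
#' Abercrombie correction compensates. The profile disc radius is the
#' maximal chord of the sphere-slab intersection (the microscope image is
#' a projection through the section), i.e. the full sphere radius when
#' the slab contains the equator, else the chord at the nearest slab
#' face.
#'
#' @param gt a [sample_nuclei()] population.
#' @param t section thickness in um.
#' @return data.frame `section, nucleus_id, x_um, y_um, radius_um,
#'   label`.
#' @export
profile_truth <- function(gt, t) {
  nuc <- gt$nuclei
  if (nrow(nuc) == 0)
    return(data.frame(section = integer(), nucleus_id = integer(),
                      x_um = numeric(), y_um = numeric(),
                      radius_um = numeric(), label = character()))
  R <- nuc$diameter_um / 2
  k_first <- pmax(1L, as.integer(floor((nuc$z_um - R) / t)) + 1L)
  k_last <- as.integer(floor((nuc$z_um + R) / t)) + 1L
  # a sphere tangent from below at a slab face (z + R == (k-1) t) does
  # not enter slab k
  k_last <- ifelse((nuc$z_um + R) %% t == 0, k_last - 1L, k_last)
  out <- vector("list", nrow(nuc))
  for (i in seq_len(nrow(nuc))) {
    ks <- seq(k_first[i], k_last[i])
    lo <- (ks - 1) * t; hi <- ks * t
    # distance from the sphere center to the nearest point of the slab
    d <- ifelse(nuc$z_um[i] >= lo & nuc$z_um[i] < hi, 0,
                pmin(abs(nuc$z_um[i] - lo), abs(nuc$z_um[i] - hi)))
    out[[i]] <- data.frame(section = ks, nucleus_id = i,
                           x_um = nuc$x_um[i], y_um = nuc$y_um[i],
                           radius_um = sqrt(pmax(R[i]^2 - d^2, 0)),
                           label = nuc$label[i])
  }
  do.call(rbind, out)
}

#' Render a ground-truth population into a three-channel section stack
#'
#' Sections the population into slabs of thickness `t` and renders each
#' slab at the requested pixel size: channel `nuclear` shows every
#' nuclear profile (disc of the sphere-slab maximal chord), channel
#' `specific` only the positive nuclei, channel `tissue` the filled
#' tissue-solid cross section at the slab midplane. Overlapping discs are
#' max-blended, deliberately producing merged profiles. Optional
#' degradations exercise the cleanup stages: additive Gaussian noise, a
#' linear in-plane intensity gradient (removed by the low-pass
#' subtraction), per-section multiplicative intensity jitter (caught by
#' segmentation QC), and per-section rigid misalignment.
#'
#' @param gt a [sample_nuclei()] population.
#' @param t section thickness in um (default 7).
#' @param pixel_size_um in-plane calibration (default 0.9).
#' @param noise list with `gaussian_sd`, `gradient_amplitude`,
#'   `intensity_jitter` (all on the 0-1 intensity scale; defaults 0.02,
#'   0, 0).
#' @param misalignment optional list of [rigid_transform()]s, one per
#'   section.
#' @param foreground disc/tissue intensity before degradation
#'   (default 0.6).
#' @param background unspecific staining level added to every pixel
#'   (default 0.1); keeps the background intensity distribution away
#'   from the zero clamp, as in real sections.
#' @param margin_um blank border around the solid's bounding box
#'   (default 8).
#' @param seed RNG seed for the rendering noise (defaults to the
#'   population's own seed, so a ground truth renders bit-identically
#'   every time).
#' @return list with `channels` (named list of three `section_stack`s),
#'   `truth` (the [profile_truth()] table) and `gt`.
#' @export
render_section_stack <- function(gt, t = 7, pixel_size_um = 0.9,
                                 noise = list(), misalignment = NULL,
                                 foreground = 0.6, background = 0.1,
                                 margin_um = 8, seed = gt$seed) {
  if (!is.null(seed)) set.seed(seed + 1L)
  noise <- utils::modifyList(
    list(gaussian_sd = 0.02, gradient_amplitude = 0, intensity_jitter = 0),
    noise)
  p <- pixel_size_um
  bb <- gt$tissue_solid$bbox
  width <- ceiling((bb[2, 1] + margin_um) / p)
  height <- ceiling((bb[2, 2] + margin_um) / p)
  Dmax <- if (nrow(gt$nuclei) > 0) max(gt$nuclei$diameter_um) else 0
  ns <- max(as.integer(ceiling((bb[2, 3] + Dmax / 2) / t)), 1L)
  truth <- profile_truth(gt, t)
  truth <- truth[truth$section <= ns, , drop = FALSE]
  xs <- (seq_len(width) - 0.5) * p
  ys <- (seq_len(height) - 0.5) * p
  Xg <- matrix(xs, height, width, byrow = TRUE)
  Yg <- matrix(ys, height, width)
  nuclear <- specific <- tissue <- vector("list", ns)
  for (k in seq_len(ns)) {
    imN <- matrix(0, height, width)
    imS <- matrix(0, height, width)
    tp <- truth[truth$section == k, , drop = FALSE]
    for (i in seq_len(nrow(tp)))
      imN <- render_disc(imN, tp$x_um[i] / p, tp$y_um[i] / p,
                         tp$radius_um[i] / p, foreground)
    for (i in which(tp$label == "positive"))
      imS <- render_disc(imS, tp$x_um[i] / p, tp$y_um[i] / p,
                         tp$radius_um[i] / p, foreground)
    zmid <- (k - 0.5) * t
    imT <- matrix(0, height, width)
    imT[gt$tissue_solid$contains(Xg, Yg, rep(zmid, length(Xg)))] <- foreground
    jit <- 1 + noise$intensity_jitter * stats::runif(1, -1, 1)
    grad <- noise$gradient_amplitude * Xg / max(xs)
    degrade <- function(im) {
      im <- (im + background) * jit + grad
      if (noise$gaussian_sd > 0)
        im <- im + matrix(stats::rnorm(length(im), 0, noise$gaussian_sd),
                          nrow(im))
      pmax(im, 0)
    }
    nuclear[[k]] <- degrade(imN)
    specific[[k]] <- degrade(imS)
    tissue[[k]] <- degrade(imT)
  }
  mk <- function(images, id) section_stack_new(images, p, t, id)
  channels <- list(nuclear = mk(nuclear, "pan-nuclear"),
                   specific = mk(specific, "cell-type"),
                   tissue = mk(tissue, "tissue"))
  if (!is.null(misalignment))
    channels <- lapply(channels, apply_transforms, misalignment, "nearest")
  list(channels = channels, truth = truth, gt = gt)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

# max-blend a filled disc (pixel-center membership) into an image
render_disc <- function(im, cx_px, cy_px, r_px, value) {
  if (r_px <= 0) return(im)
  d <- dim(im)
  r1 <- max(1, floor(cy_px - r_px)); r2 <- min(d[1], ceiling(cy_px + r_px) + 1)
  c1 <- max(1, floor(cx_px - r_px)); c2 <- min(d[2], ceiling(cx_px + r_px) + 1)
  if (r1 > r2 || c1 > c2) return(im)
  rr <- r1:r2; cc <- c1:c2
  inside <- outer((rr - 0.5 - cy_px)^2, (cc - 0.5 - cx_px)^2, `+`) <= r_px^2
  block <- im[rr, cc, drop = FALSE]
  block[inside] <- pmax(block[inside], value)
  im[rr, cc] <- block
  im
}

#' Exact per-boxel ground-truth fields
#'
#' Recovery-test oracle: true number density, labeling index and tissue
#' volume per boxel of a measurement grid, computed from the nucleus
#' list (centroid membership) and the analytic tissue solid (midplane
#' cross-sections sampled at pixel resolution, consistent with the
#' Cavalieri estimator).
#'
#' @param gt a [sample_nuclei()] population.
#' @param grid a [build_boxel_grid()] lattice.
#' @return list of arrays `n_v` (um^-3), `li`, `tissue_volume` (um^3),
#'   and `total_n` (nucleus count per boxel); plus scalar `n_total`.
#' @export
truth_fields <- function(gt, grid) {
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  b <- grid$boxel_size_um
  t <- grid$section_thickness_um
  spb <- grid$sections_per_boxel
  nuc <- gt$nuclei
  ix <- boxel_index_xy(nuc$x_um, grid$origin_um[1], b, nx)
  iy <- boxel_index_xy(nuc$y_um, grid$origin_um[2], b, ny)
  sec <- floor(nuc$z_um / t) + 1L
  iz <- boxel_index_z(sec, grid)
  lin <- (iz - 1L) * nx * ny + (iy - 1L) * nx + ix
  cnt <- array(tabulate(lin, nbins = nx * ny * nz), dim = c(nx, ny, nz))
  npos <- array(tabulate(lin[nuc$label == "positive"],
                         nbins = nx * ny * nz), dim = c(nx, ny, nz))
  # per-boxel tissue volume: midplane cross sections at pixel resolution
  p <- grid$pixel_size_um %||% 1
  vol <- array(0, dim = c(nx, ny, nz))
  for (k in seq_len(nz)) {
    secs <- grid$section_offset + (k - 1L) * spb + seq_len(spb) - 1L
    for (s in secs) {
      zmid <- (s - 0.5) * t
      for (i in seq_len(nx)) for (j in seq_len(ny)) {
        xs <- seq(grid$origin_um[1] + (i - 1) * b + p / 2,
                  grid$origin_um[1] + i * b - p / 4, by = p)
        ys <- seq(grid$origin_um[2] + (j - 1) * b + p / 2,
                  grid$origin_um[2] + j * b - p / 4, by = p)
        g <- expand.grid(x = xs, y = ys)
        vol[i, j, k] <- vol[i, j, k] +
          sum(gt$tissue_solid$contains(g$x, g$y, rep(zmid, nrow(g)))) *
            p^2 * t
      }
    }
  }
  list(n_v = ifelse(vol > 0, cnt / vol, NA_real_),
       li = ifelse(cnt > 0, npos / cnt, NA_real_),
       tissue_volume = vol,
       total_n = cnt,
       n_total = nrow(nuc))
}
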