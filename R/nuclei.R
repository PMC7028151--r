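#' Remove staining gradients by low-pass subtraction
#'
#' Subtracts a `kernel_px` x `kernel_px` mean-filtered copy of the image
#' from the image itself, yielding a "local-maxima" image in which slowly
#' varying staining gradients are removed and compact bright objects
#' (nuclear profiles) stand out. Negative residuals are clamped to 0 so a
#' single-sided threshold selects the profiles. Edges are handled by
#' mirror reflection; the box mean is computed exactly (summed-area
#' table), so even kernel sizes such as the default 10 are supported.
#'
#' Adding a constant to the whole image leaves the result unchanged: the
#' subtraction removes any flat background level.
#'
#' @param image numeric matrix.
#' @param kernel_px side of the mean filter in pixels (default 10). Must
#'   be at least 2 and no larger than either image dimension. The
#'   detection threshold applied afterwards depends on this kernel size.
#' @return numeric matrix, same size, values `>= 0`.
#' @export
local_maxima_image <- function(image, kernel_px = 10L) {
  kernel_px <- as.integer(kernel_px)
  stopifnot(kernel_px >= 2L)
  d <- dim(image)
  if (kernel_px > min(d))
    stop("kernel (", kernel_px, " px) larger than image (",
         d[1], " x ", d[2], ")")
  lp <- box_mean(image, kernel_px)
  pmax(image - lp, 0)
}

# Exact k x k box mean with mirror-reflected edges. For even k the
# window for pixel i spans [i - k/2 + 1, i + k/2].
box_mean <- function(im, k) {
  hl <- (k - 1L) %/% 2L
  hr <- k %/% 2L
  n <- nrow(im); m <- ncol(im)
  ri <- c(rev(seq_len(hl)), seq_len(n), n + 1L - seq_len(hr))
  ci <- c(rev(seq_len(hl)), seq_len(m), m + 1L - seq_len(hr))
  pad <- im[ri, ci, drop = FALSE]
  # summed-area table with a zero first row/col; the window of original
  # pixel (i, j) spans padded rows [i, i + k - 1], cols [j, j + k - 1]
  cs <- apply(pad, 2, cumsum)
  cs <- t(apply(cs, 1, cumsum))
  sat <- matrix(0, nrow(pad) + 1L, ncol(pad) + 1L)
  sat[-1, -1] <- cs
  a <- seq_len(n); b <- a + k - 1L
  ca <- seq_len(m); cb <- ca + k - 1L
  (sat[b + 1L, cb + 1L, drop = FALSE] - sat[a, cb + 1L, drop = FALSE] -
     sat[b + 1L, ca, drop = FALSE] + sat[a, ca, drop = FALSE]) / (k * k)
}

#' Construct a profile set
#'
#' The profile set is the contract between per-section 2D detection and
#' the 3D measurement scheme: one row per detected nuclear profile with
#' its section, calibrated area and centroid, mean intensity in the
#' cell-type-specific channel, and positivity class.
#'
#' @param profiles data.frame with columns `section_index`, `label`,
#'   `x_um`, `y_um`, `area_um2`, `mean_intensity`, `positivity`
#'   (`"positive"`, `"negative"`, `"excluded"`, or `NA` before
#'   classification).
#' @param section_count number of sections in the source stack.
#' @param pixel_size_um in-plane calibration.
#' @param detection_params list recording `kernel_px`, `threshold`,
#'   `split_factor` for reproducibility.
#' @param label_images optional list (indexed by section) of integer
#'   label matrices backing the profiles; needed for geometric profile
#'   splitting and positivity classification.
#' @return object of class `profile_set`.
#' @export
profile_set <- function(profiles, section_count, pixel_size_um,
                        detection_params = list(), label_images = NULL) {
  needed <- c("section_index", "label", "x_um", "y_um", "area_um2",
              "mean_intensity", "positivity")
  missing_cols <- setdiff(needed, names(profiles))
  for (cn in missing_cols) profiles[[cn]] <- NA
  if (nrow(profiles) > 0 && anyDuplicated(profiles[c("section_index", "label")]))
    stop("profile labels must be unique within a section")
  structure(list(profiles = profiles[needed],
                 section_count = section_count,
                 pixel_size_um = pixel_size_um,
                 detection_params = detection_params,
                 label_images = label_images),
            class = "profile_set")
}

#' @export
print.profile_set <- function(x, ...) {
  pos <- table(factor(x$profiles$positivity,
                      levels = c("positive", "negative", "excluded")))
  cat(sprintf("profile_set: %d profiles over %d sections (%s)\n",
              nrow(x$profiles), x$section_count,
              paste(names(pos), pos, sep = "=", collapse = ", ")))
  invisible(x)
}

#' Detect nuclear profiles in one local-maxima image
#'
#' Thresholds the local-maxima image, labels connected components
#' (8-connectivity) and measures each component's calibrated area and
#' centroid. Components smaller than `min_area_um2` are discarded as
#' debris.
#'
#' @param localmax numeric matrix from [local_maxima_image()].
#' @param threshold detection threshold (`> 0`); pixels with
#'   `localmax >= threshold` are profile candidates. Use
#'   `threshold = NULL` for an automatic choice (Otsu over the nonzero
#'   residuals).
#' @param pixel_size_um in-plane calibration.
#' @param min_area_um2 minimum profile area (default 0).
#' @param section_index section this image belongs to.
#' @return a [profile_set()] covering one section, with the label image
#'   retained for splitting/classification.
#' @export
detect_profiles <- function(localmax, threshold, pixel_size_um,
                            min_area_um2 = 0, section_index = 1L) {
  if (is.null(threshold)) {
    nz <- localmax[localmax > 0]
    threshold <- if (length(unique(nz)) < 2) Inf
    else auto_threshold(matrix(nz, nrow = 1))
  }
  stopifnot(threshold > 0)
  bw <- localmax >= threshold
  lab <- EBImage::bwlabel(bw)
  params <- list(threshold = threshold)
  if (max(lab) == 0)
    return(profile_set(empty_profile_df(), 1L, pixel_size_um, params,
                       label_images = setNames(list(lab),
                                               as.character(section_index))))
  px <- which(lab > 0, arr.ind = TRUE)
  lb <- lab[lab > 0]
  area_px <- tabulate(lb)
  cx <- rowsum(px[, 2] - 0.5, lb)[, 1] / area_px
  cy <- rowsum(px[, 1] - 0.5, lb)[, 1] / area_px
  keep <- area_px * pixel_size_um^2 >= min_area_um2
  # relabel kept profiles 1..n; drop small components from the label image
  new_lab <- integer(length(area_px))
  new_lab[keep] <- seq_len(sum(keep))
  lab[lab > 0] <- new_lab[lb]
  if (sum(keep) == 0)
    return(profile_set(empty_profile_df(), 1L, pixel_size_um, params,
                       label_images = setNames(list(lab),
                                               as.character(section_index))))
  df <- data.frame(
    section_index = section_index,
    label = seq_len(sum(keep)),
    x_um = cx[keep] * pixel_size_um,
    y_um = cy[keep] * pixel_size_um,
    area_um2 = area_px[keep] * pixel_size_um^2,
    mean_intensity = NA_real_,
    positivity = NA_character_)
  profile_set(df, 1L, pixel_size_um, params,
              label_images = setNames(list(lab), as.character(section_index)))
}

empty_profile_df <- function() {
  data.frame(section_index = integer(), label = integer(),
             x_um = numeric(), y_um = numeric(), area_um2 = numeric(),
             mean_intensity = numeric(), positivity = character())
}

#' Detect nuclear profiles in every section of a stack
#'
#' Runs [local_maxima_image()] and [detect_profiles()] on each section
#' of the pan-nuclear channel and merges the per-section results.
#'
#' @param stack a `section_stack` (pan-nuclear channel).
#' @param threshold detection threshold, or `NULL` for per-section auto.
#' @param kernel_px low-pass kernel, see [local_maxima_image()].
#' @param min_area_um2 minimum profile area.
#' @param border_um optional margin (micrometres) excluded along the
#'   image border, e.g. to avoid chromatic-aberration-affected corners;
#'   profiles with centroids inside the margin are dropped.
#' @return a [profile_set()] over all sections.
#' @export
detect_profiles_stack <- function(stack, threshold = NULL, kernel_px = 10L,
                                  min_area_um2 = 0, border_um = 0) {
  p <- stack$pixel_size_um
  sets <- lapply(seq_len(n_sections(stack)), function(k) {
    lm <- local_maxima_image(stack$images[[k]], kernel_px)
    detect_profiles(lm, threshold, p, min_area_um2, section_index = k)
  })
  df <- do.call(rbind, lapply(sets, function(s) s$profiles))
  if (border_um > 0) {
    d <- dim(stack$images[[1]])
    keep <- df$x_um >= border_um & df$x_um <= d[2] * p - border_um &
      df$y_um >= border_um & df$y_um <= d[1] * p - border_um
    df <- df[keep, , drop = FALSE]
  }
  labs <- do.call(c, lapply(sets, function(s) s$label_images))
  profile_set(df, n_sections(stack), p,
              detection_params = list(kernel_px = kernel_px,
                                      threshold = threshold,
                                      min_area_um2 = min_area_um2),
              label_images = labs)
}

#' Split merged nuclear profiles
#'
#' Densely packed nuclei produce merged profiles. Any profile whose area
#' is strictly larger than `split_factor` (default 2) times the median
#' profile area of its section — medians taken over the areas before any
#' splitting — is divided in two. When the pixel mask is available the
#' profile is bisected across its minor principal axis through the
#' centroid (total area conserved exactly, halves approximately equal);
#' without a mask each child simply receives half the parent's area at
#' the parent centroid.
#'
#' A section's single profile is never split (its area cannot exceed
#' twice its own median), and a profile at exactly twice the median is
#' kept whole (strict inequality).
#'
#' @param ps a [profile_set()].
#' @param split_factor multiple of the median area above which a profile
#'   is divided (default 2).
#' @return a [profile_set()] with split profiles replaced by two children
#'   (fresh labels) and label images updated accordingly.
#' @export
split_large_profiles <- function(ps, split_factor = 2) {
  df <- ps$profiles
  if (nrow(df) == 0) return(ps)
  out <- list()
  labs <- ps$label_images
  for (k in unique(df$section_index)) {
    sec <- df[df$section_index == k, , drop = FALSE]
    med <- stats::median(sec$area_um2)
    big <- sec$area_um2 > split_factor * med
    next_label <- max(sec$label) + 1L
    keep <- sec[!big, , drop = FALSE]
    parts <- list(keep)
    lab_img <- if (!is.null(labs)) labs[[as.character(k)]] else NULL
    for (i in which(big)) {
      children <- split_one_profile(sec[i, ], lab_img, ps$pixel_size_um,
                                    next_label)
      if (!is.null(children$lab_img)) lab_img <- children$lab_img
      parts[[length(parts) + 1L]] <- children$rows
      next_label <- next_label + 2L
    }
    if (!is.null(labs)) labs[[as.character(k)]] <- lab_img
    out[[length(out) + 1L]] <- do.call(rbind, parts)
  }
  df2 <- do.call(rbind, out)
  rownames(df2) <- NULL
  ps$profiles <- df2
  ps$label_images <- labs
  ps$detection_params$split_factor <- split_factor
  ps
}

# Divide one profile in two. Geometric split across the minor principal
# axis when the pixel mask is known, abstract halving otherwise.
split_one_profile <- function(row, lab_img, p, next_label) {
  abstract <- function() {
    rows <- rbind(row, row)
    rows$label <- c(next_label, next_label + 1L)
    rows$area_um2 <- row$area_um2 / 2
    list(rows = rows, lab_img = NULL)
  }
  if (is.null(lab_img)) return(abstract())
  px <- which(lab_img == row$label, arr.ind = TRUE)
  if (nrow(px) < 2) return(abstract())
  xy <- cbind(px[, 2] - 0.5, px[, 1] - 0.5)  # (x, y) pixel coords
  ctr <- colMeans(xy)
  cv <- stats::cov(xy)
  major <- eigen(cv, symmetric = TRUE)$vectors[, 1]
  proj <- (xy[, 1] - ctr[1]) * major[1] + (xy[, 2] - ctr[2]) * major[2]
  side <- proj > 0  # cut through the centroid, across the minor axis
  if (all(side) || !any(side)) side <- proj > stats::median(proj)
  if (all(side) || !any(side)) return(abstract())
  rows <- rbind(row, row)
  rows$label <- c(next_label, next_label + 1L)
  for (j in 1:2) {
    sel <- if (j == 1) !side else side
    rows$area_um2[j] <- sum(sel) * p^2
    rows$x_um[j] <- mean(xy[sel, 1]) * p
    rows$y_um[j] <- mean(xy[sel, 2]) * p
    lab_img[px[sel, , drop = FALSE]] <- rows$label[j]
  }
  list(rows = rows, lab_img = lab_img)
}

#' Classify profiles as positive or negative for the specific marker
#'
#' A profile is called positive when its mean intensity in the
#' cell-type-specific channel is significantly above the local background
#' staining: above the median of the background pixels in a window around
#' the profile (the bounding box expanded by `background_window_px`,
#' excluding every detected profile) by more than `z_cutoff` robust
#' standard deviations (MAD scaled to the normal). Profiles whose window
#' contains no background pixels are marked `excluded`.
#'
#' The rule compares medians and MADs of the same image, so it is
#' invariant under any global affine rescaling of the specific channel.
#'
#' @param ps a [profile_set()] with label images.
#' @param specific_images list of matrices (the cell-type channel),
#'   indexed by section, aligned with the detection channel; a single
#'   matrix is accepted for a one-section set.
#' @param background_window_px bounding-box expansion in pixels
#'   (default 20).
#' @param z_cutoff robust z-score cutoff (default 3).
#' @return the profile set with `mean_intensity` and `positivity` filled.
#' @export
classify_positive <- function(ps, specific_images,
                              background_window_px = 20L, z_cutoff = 3) {
  if (is.null(ps$label_images))
    stop("classification requires the detection label images")
  if (is.matrix(specific_images)) specific_images <- list(specific_images)
  df <- ps$profiles
  if (nrow(df) == 0) return(ps)
  secs <- unique(df$section_index)
  for (k in secs) {
    lab <- ps$label_images[[as.character(k)]]
    sp <- specific_images[[if (length(specific_images) == 1L) 1L else k]]
    stopifnot(identical(dim(lab), dim(sp)))
    anymask <- lab > 0
    rows <- which(df$section_index == k)
    for (i in rows) {
      px <- which(lab == df$label[i], arr.ind = TRUE)
      if (nrow(px) == 0) { df$positivity[i] <- "excluded"; next }
      r1 <- max(1L, min(px[, 1]) - background_window_px)
      r2 <- min(nrow(sp), max(px[, 1]) + background_window_px)
      c1 <- max(1L, min(px[, 2]) - background_window_px)
      c2 <- min(ncol(sp), max(px[, 2]) + background_window_px)
      win_bg <- sp[r1:r2, c1:c2][!anymask[r1:r2, c1:c2]]
      df$mean_intensity[i] <- mean(sp[px])
      if (length(win_bg) == 0) { df$positivity[i] <- "excluded"; next }
      bg_med <- stats::median(win_bg)
      bg_mad <- stats::mad(win_bg)
      df$positivity[i] <-
        if (df$mean_intensity[i] > bg_med + z_cutoff * bg_mad)
          "positive" else "negative"
    }
  }
  ps$profiles <- df
  ps$detection_params$background_window_px <- background_window_px
  ps$detection_params$z_cutoff <- z_cutoff
  ps
}

#' Nucleus-identification control image
#'
#' Renders the base image with a colored circle at every detected
#' profile centroid — positive, negative and unclassified/excluded nuclei
#' in different colors — for visual verification of detection and
#' classification.
#'
#' @param ps a [profile_set()].
#' @param base_image grayscale matrix to annotate.
#' @param section_index which section to render (default 1).
#' @param radius_px circle radius in pixels.
#' @param colors named list of RGB triplets (0-1) for `positive`,
#'   `negative`, `other`.
#' @return numeric array `[rows, cols, 3]` in `[0, 1]`.
#' @export
control_image <- function(ps, base_image, section_index = 1L,
                          radius_px = 5,
                          colors = list(positive = c(1, 0, 0),
                                        negative = c(0, 1, 0),
                                        other = c(1, 1, 0))) {
  g <- percentile_stretch(base_image)
  rgb <- array(rep(g, 3), dim = c(dim(g), 3))
  df <- ps$profiles[ps$profiles$section_index == section_index, ,
                    drop = FALSE]
  if (nrow(df) == 0) return(rgb)
  p <- ps$pixel_size_um
  for (i in seq_len(nrow(df))) {
    col <- switch(as.character(df$positivity[i]),
                  positive = colors$positive,
                  negative = colors$negative,
                  colors$other)
    rgb <- draw_circle(rgb, df$x_um[i] / p, df$y_um[i] / p, radius_px, col)
  }
  rgb
}

draw_circle <- function(rgb, cx, cy, radius, col) {
  d <- dim(rgb)
  r1 <- max(1, floor(cy - radius)); r2 <- min(d[1], ceiling(cy + radius) + 1)
  c1 <- max(1, floor(cx - radius)); c2 <- min(d[2], ceiling(cx + radius) + 1)
  rr <- r1:r2; cc <- c1:c2
  dist <- sqrt(outer((rr - 0.5 - cy)^2, (cc - 0.5 - cx)^2, `+`))
  ring <- abs(dist - radius) <= 0.6
  for (ch in 1:3) {
    plane <- rgb[rr, cc, ch]
    plane[ring] <- col[ch]
    rgb[rr, cc, ch] <- plane
  }
  rgb
}

#' Export / import a profile set as CSV
#'
#' Columns: `section, label, x_um, y_um, area_um2, mean_intensity,
#' positivity`. This file is the interface between 2D detection and the
#' 3D measurement scheme; label images are not preserved.
#'
#' @param ps a [profile_set()].
#' @param path CSV path.
#' @return `write_profiles`: `path` invisibly; `read_profiles`: a
#'   [profile_set()] without label images.
#' @export
write_profiles <- function(ps, path) {
  df <- ps$profiles
  names(df)[names(df) == "section_index"] <- "section"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @param section_count,pixel_size_um stack metadata for the imported
#'   set.
#' @export
read_profiles <- function(path, section_count, pixel_size_um) {
  df <- utils::read.csv(path)
  names(df)[names(df) == "section"] <- "section_index"
  profile_set(df, section_count, pixel_size_um)
}
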