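#' Rigid in-plane transform for one section
#'
#' Rotation about a center followed by a translation, both in specimen
#' micrometres. Sections are aligned by applying one such transform per
#' section; the same transform list is applied to every channel of the
#' same specimen so the channels stay in register.
#'
#' @param rotation_deg counter-clockwise rotation in degrees.
#' @param translation_um length-2 numeric `(tx, ty)` in micrometres.
#' @param center_um rotation center `(cx, cy)` in micrometres, or `NULL`
#'   for the image center.
#' @return object of class `rigid_transform2d`.
#' @export
rigid_transform <- function(rotation_deg = 0, translation_um = c(0, 0),
                            center_um = NULL) {
  stopifnot(is.finite(rotation_deg), length(translation_um) == 2L,
            all(is.finite(translation_um)))
  structure(list(rotation_deg = rotation_deg,
                 translation_um = as.numeric(translation_um),
                 center_um = center_um),
            class = "rigid_transform2d")
}

is_identity_transform <- function(tr) {
  tr$rotation_deg == 0 && all(tr$translation_um == 0)
}

#' Apply per-section rigid transforms to a stack
#'
#' Resamples every section under its transform (inverse mapping on pixel
#' centers). Pixels mapped from outside the frame are set to 0. `nearest`
#' keeps gray values unchanged (no interpolation), `linear` is bilinear.
#'
#' @param stack a `section_stack`.
#' @param transforms list of [rigid_transform()] objects, one per
#'   section.
#' @param interpolation `"nearest"` or `"linear"`.
#' @return a transformed `section_stack` of identical dimensions.
#' @export
apply_transforms <- function(stack, transforms,
                             interpolation = c("nearest", "linear")) {
  interpolation <- match.arg(interpolation)
  if (length(transforms) != n_sections(stack))
    stop("need exactly one transform per section (",
         length(transforms), " transforms for ",
         n_sections(stack), " sections)")
  p <- stack$pixel_size_um
  d <- dim(stack$images[[1]])
  # pixel-center coordinates in um: x along columns, y along rows
  xs <- (seq_len(d[2]) - 0.5) * p
  ys <- (seq_len(d[1]) - 0.5) * p
  X <- matrix(xs, nrow = d[1], ncol = d[2], byrow = TRUE)
  Y <- matrix(ys, nrow = d[1], ncol = d[2])
  out <- stack
  for (k in seq_len(n_sections(stack))) {
    tr <- transforms[[k]]
    if (is_identity_transform(tr)) next
    ctr <- if (is.null(tr$center_um)) c(d[2], d[1]) / 2 * p else tr$center_um
    th <- tr$rotation_deg * pi / 180
    # inverse map: undo translation, then rotate by -theta about center
    xs2 <- X - tr$translation_um[1] - ctr[1]
    ys2 <- Y - tr$translation_um[2] - ctr[2]
    xsrc <- cos(th) * xs2 + sin(th) * ys2 + ctr[1]
    ysrc <- -sin(th) * xs2 + cos(th) * ys2 + ctr[2]
    out$images[[k]] <- resample_image(stack$images[[k]],
                                      xsrc / p + 0.5, ysrc / p + 0.5,
                                      interpolation)
  }
  out
}

# Sample image at fractional pixel positions (1-based col = x, row = y);
# outside the frame -> 0.
resample_image <- function(im, xf, yf, interpolation) {
  d <- dim(im)
  res <- matrix(0, d[1], d[2])
  if (interpolation == "nearest") {
    ci <- round(xf); ri <- round(yf)
    ok <- ci >= 1 & ci <= d[2] & ri >= 1 & ri <= d[1]
    res[ok] <- im[cbind(ri[ok], ci[ok])]
  } else {
    c0 <- floor(xf); r0 <- floor(yf)
    fx <- xf - c0; fy <- yf - r0
    ok <- c0 >= 1 & c0 + 1 <= d[2] & r0 >= 1 & r0 + 1 <= d[1]
    g <- function(ri, ci) im[cbind(ri, ci)]
    res[ok] <-
      (1 - fx[ok]) * (1 - fy[ok]) * g(r0[ok], c0[ok]) +
      fx[ok] * (1 - fy[ok]) * g(r0[ok], c0[ok] + 1) +
      (1 - fx[ok]) * fy[ok] * g(r0[ok] + 1, c0[ok]) +
      fx[ok] * fy[ok] * g(r0[ok] + 1, c0[ok] + 1)
  }
  res
}

#' Estimate the translation between two sections by cross-correlation
#'
#' Convenience translation-only registration: finds the integer pixel
#' shift of `image_b` that maximizes its normalized cross-correlation
#' with `image_a` (computed via FFT). Full iterative rigid registration
#' with rotation is delegated to dedicated alignment software; externally
#' estimated parameters enter through [rigid_transform()] lists.
#'
#' @param image_a,image_b numeric matrices of identical dimensions.
#' @param pixel_size_um calibration used to express the shift in um.
#' @param min_correlation normalized correlation floor below which the
#'   result is flagged low-confidence.
#' @return list with `transform` (a [rigid_transform()], rotation 0),
#'   `correlation` (peak normalized correlation) and `ok` (logical;
#'   `FALSE` when the peak correlation is below `min_correlation`).
#' @export
estimate_translation <- function(image_a, image_b, pixel_size_um = 1,
                                 min_correlation = 0.3) {
  stopifnot(identical(dim(image_a), dim(image_b)))
  a <- image_a - mean(image_a)
  b <- image_b - mean(image_b)
  if (sd(a) == 0 || sd(b) == 0)
    stop("blank image (zero variance): translation undefined")
  d <- dim(a)
  n <- length(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  cc <- cc / (n * (n - 1) * stats::sd(a) * stats::sd(b))
  peak <- which.max(cc)
  pr <- (peak - 1) %% d[1]           # row lag of a relative to b
  pc <- (peak - 1) %/% d[1]
  if (pr > d[1] / 2) pr <- pr - d[1] # wrap to signed shifts
  if (pc > d[2] / 2) pc <- pc - d[2]
  corr <- max(cc)
  list(transform = rigid_transform(
         translation_um = c(-pc, -pr) * pixel_size_um),
       correlation = corr,
       ok = corr >= min_correlation)
}

#' Complementary-color overlay of an aligned image pair
#'
#' Alignment quality control: the first image is shown in red and the
#' second in green, each stretched to its 1st-99th intensity percentile,
#' so overlapping structures appear white and misaligned structures show
#' colored fringes.
#'
#' @param image_a,image_b numeric matrices of identical dimensions.
#' @return numeric array `[rows, cols, 3]` with values in `[0, 1]`
#'   (R = a, G = b, B = min(a, b)).
#' @export
qc_overlay <- function(image_a, image_b) {
  stopifnot(identical(dim(image_a), dim(image_b)))
  a <- percentile_stretch(image_a)
  b <- percentile_stretch(image_b)
  rgb <- array(0, dim = c(dim(a), 3))
  rgb[, , 1] <- a
  rgb[, , 2] <- b
  rgb[, , 3] <- pmin(a, b)
  rgb
}

percentile_stretch <- function(im, lo = 0.01, hi = 0.99) {
  q <- stats::quantile(im, c(lo, hi), names = FALSE)
  if (q[2] == q[1]) return(matrix(0, nrow(im), ncol(im)))
  pmin(pmax((im - q[1]) / (q[2] - q[1]), 0), 1)
}

#' Read / write a per-section transform table
#'
#' The transform list is exchanged as a CSV with columns
#' `section_index, rotation_deg, tx_um, ty_um` so that parameters
#' estimated on one channel can be applied to the other channels.
#'
#' @param transforms list of [rigid_transform()] objects.
#' @param path CSV file path.
#' @return `write_transforms`: `path` invisibly; `read_transforms`: a
#'   list of [rigid_transform()] objects ordered by `section_index`.
#' @export
write_transforms <- function(transforms, path) {
  df <- data.frame(
    section_index = seq_along(transforms),
    rotation_deg = vapply(transforms, `[[`, numeric(1), "rotation_deg"),
    tx_um = vapply(transforms, function(t) t$translation_um[1], numeric(1)),
    ty_um = vapply(transforms, function(t) t$translation_um[2], numeric(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  df <- utils::read.csv(path)
  df <- df[order(df$section_index), ]
  lapply(seq_len(nrow(df)), function(i)
    rigid_transform(df$rotation_deg[i], c(df$tx_um[i], df$ty_um[i])))
}
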