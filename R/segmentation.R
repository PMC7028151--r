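#' Threshold one section into a binary tissue mask
#'
#' Foreground (tissue-of-interest) is every pixel whose gray value is
#' greater than or equal to the threshold. Raising the threshold can
#' therefore only remove foreground, never add it.
#'
#' @param image numeric matrix.
#' @param threshold numeric scalar within the image value range.
#' @return logical matrix, `TRUE` = tissue.
#' @export
threshold_section <- function(image, threshold) {
  stopifnot(is.numeric(image), length(threshold) == 1L,
            is.finite(threshold))
  image >= threshold
}

#' Automatic threshold by between-class variance maximization
#'
#' Otsu's criterion on a 256-level histogram of the image's value range.
#' Automatically set thresholds still require per-image quality control
#' (see [segmentation_qc()]); staining differences between sections may
#' need per-section thresholds.
#'
#' @param image numeric matrix with at least two distinct values.
#' @param levels number of histogram bins (default 256).
#' @return threshold on the image's own gray scale; foreground is
#'   `image >= threshold`.
#' @export
auto_threshold <- function(image, levels = 256) {
  rng <- range(image)
  if (rng[1] == rng[2])
    stop("constant image: no threshold separates foreground from background")
  as.numeric(EBImage::otsu(as.matrix(image), range = rng, levels = levels))
}

#' Build a tissue mask stack
#'
#' Thresholds every section of the tissue channel, either with a single
#' global threshold, a per-section list of manual thresholds, or
#' per-section automatic thresholds ([auto_threshold()]).
#'
#' @param stack a `section_stack` of the tissue-specific channel.
#' @param method `"global"`, `"per_section_manual"` or
#'   `"per_section_auto"`.
#' @param thresholds numeric scalar (global) or per-section vector
#'   (manual); ignored for auto.
#' @return object of class `tissue_mask_stack`: list with `masks`
#'   (logical matrices), `threshold_per_section`, `method` and
#'   `pixel_size_um`.
#' @export
segment_tissue <- function(stack,
                           method = c("global", "per_section_manual",
                                      "per_section_auto"),
                           thresholds = NULL) {
  method <- match.arg(method)
  n <- n_sections(stack)
  th <- switch(method,
    global = {
      stopifnot(length(thresholds) == 1L)
      rep(as.numeric(thresholds), n)
    },
    per_section_manual = {
      stopifnot(length(thresholds) == n)
      as.numeric(thresholds)
    },
    per_section_auto = vapply(stack$images, function(im) {
      # a constant section holds no tissue: empty mask
      if (min(im) == max(im)) Inf else auto_threshold(im)
    }, numeric(1)))
  masks <- lapply(seq_len(n), function(k) {
    if (is.infinite(th[k]))
      array(FALSE, dim(stack$images[[k]]))
    else threshold_section(stack$images[[k]], th[k])
  })
  structure(list(masks = masks, threshold_per_section = th,
                 method = method, pixel_size_um = stack$pixel_size_um),
            class = "tissue_mask_stack")
}

#' Wrap externally drawn masks as a tissue mask stack
#'
#' Import path for manually traced masks (0/255 TIFF series): anything
#' nonzero is tissue.
#'
#' @param masks list of logical or numeric matrices.
#' @param pixel_size_um in-plane calibration.
#' @return a `tissue_mask_stack` with `method = "per_section_manual"`.
#' @export
mask_stack <- function(masks, pixel_size_um) {
  masks <- lapply(masks, function(m) m != 0)
  structure(list(masks = masks,
                 threshold_per_section = rep(NA_real_, length(masks)),
                 method = "per_section_manual",
                 pixel_size_um = pixel_size_um),
            class = "tissue_mask_stack")
}

#' Segmentation quality control
#'
#' Computes the foreground fraction of every section mask and flags
#' sections whose fraction deviates from the running median of their
#' neighbors by more than `flag_factor` (in either direction), or whose
#' mask is empty. Inconsistent staining intensity between sections shows
#' up here as isolated outliers; when more than `restain_fraction` of
#' sections are flagged the whole specimen should be reviewed.
#'
#' @param masks a `tissue_mask_stack`.
#' @param flag_factor multiplicative deviation from the neighborhood
#'   median that triggers a flag (default 2).
#' @param window running-median half-width in sections (default 2,
#'   i.e. up to 4 neighbors, the section itself excluded).
#' @param restain_fraction advisory cutoff on the flagged fraction
#'   (default 0.2).
#' @return list with `per_section` (data.frame: section, foreground
#'   fraction, threshold, flagged), `flagged` (indices), and
#'   `review_specimen` (logical).
#' @export
segmentation_qc <- function(masks, flag_factor = 2, window = 2,
                            restain_fraction = 0.2) {
  stopifnot(inherits(masks, "tissue_mask_stack"))
  fr <- vapply(masks$masks, mean, numeric(1))
  n <- length(fr)
  flagged <- logical(n)
  for (k in seq_len(n)) {
    nb <- setdiff(max(1, k - window):min(n, k + window), k)
    med <- stats::median(fr[nb])
    flagged[k] <- fr[k] == 0 ||
      (med > 0 && (fr[k] > flag_factor * med || fr[k] < med / flag_factor))
  }
  per_section <- data.frame(section = seq_len(n),
                            foreground_fraction = fr,
                            threshold = masks$threshold_per_section,
                            flagged = flagged)
  list(per_section = per_section,
       flagged = which(flagged),
       review_specimen = mean(flagged) > restain_fraction)
}

#' Write / read tissue masks as 8-bit TIFF (0/255)
#' @param masks a `tissue_mask_stack`.
#' @param path multi-page TIFF path.
#' @return `write_masks`: `path` invisibly; `read_masks`: a
#'   `tissue_mask_stack`.
#' @export
write_masks <- function(masks, path) {
  pages <- lapply(masks$masks, function(m) m * 1)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_masks
#' @param pixel_size_um calibration for the imported masks.
#' @export
read_masks <- function(path, pixel_size_um) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  mask_stack(pages, pixel_size_um)
}
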