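#' Downsample tissue masks to the boxel lattice
#'
#' A boxel belongs to the tissue when at least `occupancy_threshold` of
#' the voxels in its (section, pixel) footprint are tissue foreground.
#' The resulting boxel-resolution mask trims the quantitative matrix to
#' the segmented morphology.
#'
#' @param masks a `tissue_mask_stack`.
#' @param grid a [build_boxel_grid()] lattice consistent with the masks.
#' @param occupancy_threshold minimum occupied fraction (default 0.05).
#' @return logical 3D array `[ix, iy, iz]`.
#' @export
downsample_mask_to_boxels <- function(masks, grid,
                                      occupancy_threshold = 0.05) {
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  b <- grid$boxel_size_um
  p <- grid$pixel_size_um
  imdim <- dim(masks$masks[[1]])
  sats <- lapply(masks$masks, function(msk) {
    s <- matrix(0, nrow(msk) + 1L, ncol(msk) + 1L)
    s[-1, -1] <- t(apply(apply(msk, 2, cumsum), 1, cumsum))
    s
  })
  out <- array(FALSE, dim = c(nx, ny, nz))
  for (i in seq_len(nx)) {
    cr <- um_range_to_pixels(grid$origin_um[1] + c(i - 1, i) * b, p, imdim[2])
    if (cr[2] < cr[1]) next
    for (j in seq_len(ny)) {
      rr <- um_range_to_pixels(grid$origin_um[2] + c(j - 1, j) * b, p,
                               imdim[1])
      if (rr[2] < rr[1]) next
      npx <- (cr[2] - cr[1] + 1) * (rr[2] - rr[1] + 1)
      for (k in seq_len(nz)) {
        s1 <- grid$section_offset + (k - 1L) * grid$sections_per_boxel
        s2 <- min(grid$section_offset + k * grid$sections_per_boxel - 1L,
                  length(sats))
        if (s2 < s1) next
        fg <- sum(vapply(sats[s1:s2], function(s)
          s[rr[2] + 1L, cr[2] + 1L] - s[rr[1], cr[2] + 1L] -
            s[rr[2] + 1L, cr[1]] + s[rr[1], cr[1]], numeric(1)))
        out[i, j, k] <- fg / (npx * (s2 - s1 + 1)) >= occupancy_threshold
      }
    }
  }
  out
}

#' Mask a quantitative field with the segmented tissue
#'
#' The raw quantitative matrix extends over the whole bounding box;
#' masking it with the segmented tissue-of-interest yields the
#' quantitative 3D reconstruction, showing the variable in its proper
#' morphological context. Boxels outside the mask are set to the field's
#' reserved unmeasured value; inside-mask values are untouched, so the
#' operation is idempotent.
#'
#' @param field a [morpho_field()].
#' @param boxel_mask logical array from [downsample_mask_to_boxels()].
#' @param colormap_spec optional list (`range`, `out_of_range`) recorded
#'   for export.
#' @return object of class `masked_reconstruction` with fields `field`
#'   (masked), `tissue_mask_boxel` and `colormap_spec`.
#' @export
mask_field <- function(field, boxel_mask, colormap_spec = NULL) {
  stopifnot(inherits(field, "morpho_field"))
  if (!identical(dim(field$values), dim(boxel_mask)))
    stop("field and boxel mask dimensions differ")
  field$values[!boxel_mask] <- field$nan_policy
  field$reliability[!boxel_mask] <- FALSE
  if (is.null(colormap_spec)) {
    finite <- field$values[!is.na(field$values)]
    colormap_spec <- list(
      range = if (length(finite)) range(finite) else c(0, 0),
      out_of_range = "clamp")
  }
  structure(list(field = field, tissue_mask_boxel = boxel_mask,
                 colormap_spec = colormap_spec),
            class = "masked_reconstruction")
}

#' Export a quantitative 3D reconstruction
#'
#' Portable volume formats in place of proprietary surface rendering:
#' multi-page TIFF (via [write_morpho_field()], with the colormap spec
#' added to the sidecar) or a legacy ASCII VTK `STRUCTURED_POINTS` file
#' loadable in standard 3D viewers, with the boxel size as the point
#' spacing and unmeasured boxels stored as `nan_value`.
#'
#' @param rec a [mask_field()] reconstruction.
#' @param path output file.
#' @param format `"tiff"` or `"vtk"`.
#' @param nan_value value standing in for unmeasured boxels in the VTK
#'   export (default -1).
#' @return `path`, invisibly.
#' @export
export_reconstruction <- function(rec, path, format = c("tiff", "vtk"),
                                  nan_value = -1) {
  format <- match.arg(format)
  stopifnot(inherits(rec, "masked_reconstruction"))
  f <- rec$field
  if (format == "tiff") {
    write_morpho_field(f, path)
    side <- paste0(path, ".json")
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    meta$colormap <- rec$colormap_spec
    jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    d <- dim(f$values)
    v <- f$values
    v[is.na(v)] <- nan_value
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "# vtk DataFile Version 3.0",
      sprintf("%s [%s]", f$variable_name, f$units),
      "ASCII",
      "DATASET STRUCTURED_POINTS",
      sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
      sprintf("SPACING %g %g %g", f$boxel_size_um, f$boxel_size_um,
              f$z_size_um),
      sprintf("ORIGIN %g %g %g", f$origin_um[1], f$origin_um[2],
              f$origin_um[3]),
      sprintf("POINT_DATA %d", prod(d)),
      sprintf("SCALARS %s float 1", f$variable_name),
      "LOOKUP_TABLE default"), con)
    # VTK iterates x fastest, then y, then z - matching [ix, iy, iz]
    writeLines(format(as.vector(v), trim = TRUE, digits = 7), con)
  }
  invisible(path)
}
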