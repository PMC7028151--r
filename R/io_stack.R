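#' Construct a calibrated section stack
#'
#' A section stack is the in-memory representation of one channel of a
#' serial-section series: an ordered list of identically sized grayscale
#' rasters together with the in-plane pixel calibration and the physical
#' section thickness. Section `k` occupies the slab
#' `[(k-1)*t, k*t)` along the cutting axis.
#'
#' @param images list of numeric matrices, all with identical dimensions.
#' @param pixel_size_um in-plane calibration, micrometres per pixel
#'   (isotropic).
#' @param section_thickness_um physical section thickness `t` in
#'   micrometres.
#' @param channel_id free-text channel label (e.g. `"pan-nuclear"`).
#' @param provenance per-section character vector; `"original"` or
#'   `"substituted_from:<index>"`. Defaults to all-original.
#' @return An object of class `section_stack` with fields `images`,
#'   `channel_id`, `pixel_size_um`, `section_thickness_um`,
#'   `section_index` (consecutive integers starting at 1) and
#'   `provenance`.
#' @export
section_stack_new <- function(images, pixel_size_um, section_thickness_um,
                              channel_id = "channel", provenance = NULL) {
  stopifnot(is.list(images), length(images) >= 1L,
            is.numeric(pixel_size_um), pixel_size_um > 0,
            is.numeric(section_thickness_um), section_thickness_um > 0)
  dims <- vapply(images, function(im) dim(im)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all section images must share identical width and height")
  if (is.null(provenance)) provenance <- rep("original", length(images))
  stopifnot(length(provenance) == length(images))
  structure(list(
    images = images,
    channel_id = channel_id,
    pixel_size_um = pixel_size_um,
    section_thickness_um = section_thickness_um,
    section_index = seq_along(images),
    provenance = provenance
  ), class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf(
    "section_stack '%s': %d sections of %d x %d px, %.3g um/px, t = %.3g um\n",
    x$channel_id, length(x$images), d[1], d[2],
    x$pixel_size_um, x$section_thickness_um))
  n_sub <- sum(x$provenance != "original")
  if (n_sub > 0) cat(sprintf("  %d substituted section(s)\n", n_sub))
  invisible(x)
}

#' Number of sections in a stack
#' @param stack a `section_stack`.
#' @return integer count.
#' @export
n_sections <- function(stack) length(stack$images)

#' Read a section series from TIFF files
#'
#' Accepts either a single multi-page TIFF (one page per section) or an
#' ordered series of single-page TIFFs whose file names carry consecutive
#' numeric indices. Pixel values are read natively (no rescaling to
#' `[0, 1]`), so 8/12/16-bit data keep their integer gray values.
#'
#' With a numbered series, the numeric index is taken as the last run of
#' digits in each base name; the series must be consecutive — a gap means
#' a section was lost upstream and the error names the missing index so
#' the specimen can be re-checked (use [substitute_missing()] for a
#' single lost section).
#'
#' @param paths character vector of file paths (length 1 for a
#'   multi-page TIFF).
#' @inheritParams section_stack_new
#' @return A [section_stack_new()] object with `provenance = "original"`
#'   for every section.
#' @export
read_stack <- function(paths, pixel_size_um, section_thickness_um,
                       channel_id = "channel") {
  stopifnot(length(paths) >= 1)
  missing_files <- paths[!file.exists(paths)]
  if (length(missing_files) > 0)
    stop("file(s) not found: ", paste(missing_files, collapse = ", "))
  if (length(paths) == 1L) {
    images <- tryCatch(
      tiff::readTIFF(paths, all = TRUE, as.is = TRUE),
      error = function(e) stop("unreadable TIFF '", paths, "': ",
                               conditionMessage(e), call. = FALSE))
    images <- lapply(images, drop_to_gray)
  } else {
    idx <- vapply(paths, filename_index, numeric(1))
    if (anyNA(idx))
      stop("file name(s) without a numeric index: ",
           paste(basename(paths)[is.na(idx)], collapse = ", "))
    ord <- order(idx)
    idx <- idx[ord]
    paths <- paths[ord]
    expected <- seq(idx[1], by = 1, length.out = length(idx))
    if (any(idx != expected)) {
      missing_idx <- setdiff(seq(idx[1], idx[length(idx)]), idx)
      stop("section series is not consecutive; missing index ",
           paste(missing_idx, collapse = ", "))
    }
    images <- vector("list", length(paths))
    for (i in seq_along(paths)) {
      images[[i]] <- tryCatch(
        drop_to_gray(tiff::readTIFF(paths[i], as.is = TRUE)),
        error = function(e) stop("unreadable file at series index ", i,
                                 " ('", basename(paths[i]), "'): ",
                                 conditionMessage(e), call. = FALSE))
    }
  }
  dims <- vapply(images, function(im) dim(im)[1:2], numeric(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("dimension mismatch across sections; stack rejected")
  section_stack_new(images, pixel_size_um, section_thickness_um, channel_id)
}

# Last run of digits in the base name, or NA.
filename_index <- function(path) {
  base <- tools::file_path_sans_ext(basename(path))
  m <- regmatches(base, gregexpr("[0-9]+", base))[[1]]
  if (length(m) == 0) return(NA_real_)
  as.numeric(m[length(m)])
}

# Reduce an RGB/RGBA array read from TIFF to a single gray matrix.
drop_to_gray <- function(im) {
  if (length(dim(im)) == 3L) {
    if (dim(im)[3] >= 3 &&
        (any(im[, , 1] != im[, , 2]) || any(im[, , 1] != im[, , 3])))
      stop("expected single-channel grayscale image")
    im <- im[, , 1]
  }
  im
}

#' Promote 12-bit pixel data to a 16-bit container without stretching
#'
#' Cameras producing 12-bit data (gray values 0-4095) must be stored in a
#' 16-bit container for downstream software. The conversion is the
#' identity on pixel values: only the first 4096 gray values of the
#' 16-bit range are used and nothing is rescaled, so no information is
#' changed or lost.
#'
#' @param image numeric matrix with integer values in `[0, 4095]`.
#' @return The same values as an integer-mode matrix (16-bit range).
#' @export
convert_12_to_16_bit <- function(image) {
  stopifnot(is.numeric(image))
  if (any(image < 0) || any(image > 4095))
    stop("input is not 12-bit: values outside [0, 4095]")
  if (any(image != floor(image)))
    stop("input is not 12-bit: non-integer gray values")
  storage.mode(image) <- "integer"
  image
}

#' Substitute a lost section by a copy of a neighboring section
#'
#' When a single section is lost during sectioning or mounting, its image
#' may be replaced by a copy of a neighboring section. This must never be
#' done for more than one section in a row: if the substitution would put
#' two substituted sections next to each other the stack is refused and
#' the specimen should be discarded and re-sectioned.
#'
#' @param stack a `section_stack`.
#' @param missing_index 1-based index of the lost section.
#' @param side which neighbor supplies the copy: `"previous"` (default)
#'   or `"next"`. A boundary section uses the only neighbor it has.
#' @return The stack with the section replaced and its provenance set to
#'   `"substituted_from:<neighbor>"`.
#' @export
substitute_missing <- function(stack, missing_index,
                               side = c("previous", "next")) {
  side <- match.arg(side)
  n <- n_sections(stack)
  stopifnot(missing_index >= 1, missing_index <= n)
  neighbor <- if (missing_index == 1L) 2L
  else if (missing_index == n) n - 1L
  else if (side == "previous") missing_index - 1L
  else missing_index + 1L
  if (n < 2L) stop("cannot substitute in a single-section stack")
  prov <- stack$provenance
  prov[missing_index] <- paste0("substituted_from:", neighbor)
  sub <- prov != "original"
  if (any(sub[-1] & sub[-length(sub)]))
    stop("substitution refused: two substituted sections in a row (",
         "sections ", missing_index, " and its neighbor); ",
         "discard the specimen and repeat the sectioning")
  if (stack$provenance[neighbor] != "original")
    stop("substitution refused: source section ", neighbor,
         " is itself substituted; discard the specimen")
  stack$images[[missing_index]] <- stack$images[[neighbor]]
  stack$provenance <- prov
  stack
}

#' Check that the pixel calibration resolves nuclear profiles
#'
#' Reliable profile detection requires a nuclear profile to span at least
#' 6 x 6 pixels; e.g. a ~6 um nucleus imaged at ~0.9 um/pixel spans about
#' 6.7 pixels and passes.
#'
#' @param pixel_size_um micrometres per pixel.
#' @param nuclear_diameter_um mean nuclear diameter `D` in micrometres.
#' @param min_pixels minimum pixels across a nucleus (default 6).
#' @return list with `ok` (logical) and `pixels_per_nucleus`.
#' @export
validate_resolution <- function(pixel_size_um, nuclear_diameter_um,
                                min_pixels = 6) {
  stopifnot(pixel_size_um > 0, nuclear_diameter_um > 0)
  ppn <- nuclear_diameter_um / pixel_size_um
  list(ok = ppn >= min_pixels, pixels_per_nucleus = ppn)
}

#' Construct a per-boxel quantitative 3D field
#'
#' A morpho field stores one morphogenetic variable (cell density, cell
#' size, labeling index, ...) on the boxel lattice, together with a
#' per-boxel reliability flag (enough profiles counted) and the spatial
#' metadata needed to place the lattice back into the specimen.
#'
#' @param values numeric 3D array indexed `[ix, iy, iz]` (x = image
#'   columns, y = image rows, z = sections). `NA` marks boxels outside
#'   the measured region.
#' @param variable_name,units free text, stored in the export sidecar.
#' @param boxel_size_um in-plane boxel edge length in micrometres.
#' @param origin_um length-3 numeric, micrometre coordinates of the
#'   lattice corner (x, y, z).
#' @param reliability logical array, same dimensions as `values`.
#' @param z_size_um boxel extent along the sectioning axis (a multiple of
#'   the section thickness; defaults to `boxel_size_um`).
#' @param nan_policy the reserved "unmeasured" value (default `NA`).
#' @return object of class `morpho_field`.
#' @export
morpho_field <- function(values, variable_name, units, boxel_size_um,
                         origin_um = c(0, 0, 0), reliability = NULL,
                         z_size_um = boxel_size_um, nan_policy = NA_real_) {
  stopifnot(length(dim(values)) == 3L, boxel_size_um > 0,
            length(origin_um) == 3L)
  if (is.null(reliability))
    reliability <- array(TRUE, dim = dim(values))
  stopifnot(identical(dim(reliability), dim(values)))
  structure(list(
    values = values, variable_name = variable_name, units = units,
    boxel_size_um = boxel_size_um, z_size_um = z_size_um,
    origin_um = as.numeric(origin_um), reliability = reliability,
    nan_policy = nan_policy
  ), class = "morpho_field")
}

#' @export
print.morpho_field <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "morpho_field '%s' [%s]: %d x %d x %d boxels of %.3g um (z %.3g um)\n",
    x$variable_name, x$units, d[1], d[2], d[3],
    x$boxel_size_um, x$z_size_um))
  rng <- range(x$values, na.rm = TRUE)
  cat(sprintf("  measured: %d/%d boxels, range [%.4g, %.4g]\n",
              sum(!is.na(x$values)), length(x$values), rng[1], rng[2]))
  invisible(x)
}

#' Write a morpho field as a multi-page TIFF plus metadata sidecar
#'
#' One TIFF page per z-slice of the boxel lattice. Values are stored
#' through an affine codec `stored = s0 + (1 - s0) * (v - offset)/scale`
#' mapped onto the TIFF's `[0, 1]` sample range, with unmeasured boxels
#' at the reserved stored value 0; `offset`, `scale` and `s0` are written
#' to a JSON sidecar (`<path>.json`) so values round-trip. `float32`
#' round-trips to single precision (about `1e-7` of the value range);
#' `uint16` quantizes to at most `1/65535` of the range — gray-value
#' export for viewers that need integer TIFFs.
#'
#' @param field a [morpho_field()].
#' @param path output TIFF path; the sidecar is written to `<path>.json`.
#' @param encoding `"float32"` (default) or `"uint16"`.
#' @return `path`, invisibly.
#' @seealso [read_morpho_field()]
#' @export
write_morpho_field <- function(field, path,
                               encoding = c("float32", "uint16")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(field, "morpho_field"))
  v <- field$values
  if (!is.na(field$nan_policy)) v[v == field$nan_policy] <- NA
  if (any(!is.finite(v) & !is.na(v)))
    stop("non-finite values outside the reserved unmeasured value")
  finite <- v[!is.na(v)]
  offset <- if (length(finite)) min(finite) else 0
  scale <- if (length(finite)) max(finite) - offset else 1
  if (scale == 0) scale <- 1
  s0 <- 1 / 1024  # stored values below s0/2 are reserved for "unmeasured"
  stored <- s0 + (1 - s0) * (v - offset) / scale
  stored[is.na(stored)] <- 0
  pages <- lapply(seq_len(dim(v)[3]),
                  function(k) t(stored[, , k]))  # rows = y on disk
  bits <- if (encoding == "float32") 32L else 16L
  tiff::writeTIFF(pages, path, bits.per.sample = bits,
                  reduce = FALSE)
  meta <- list(
    variable = field$variable_name, units = field$units,
    boxel_size_um = field$boxel_size_um, z_size_um = field$z_size_um,
    origin_um = field$origin_um, dims = dim(v),
    encoding = encoding, offset = offset, scale = scale, s0 = s0,
    nan_stored = 0)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a morpho field written by [write_morpho_field()]
#'
#' @param path TIFF path with an accompanying `<path>.json` sidecar.
#' @return a [morpho_field()].
#' @export
read_morpho_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  d <- as.integer(meta$dims)
  values <- array(NA_real_, dim = d)
  for (k in seq_len(d[3])) values[, , k] <- t(pages[[k]])
  unmeasured <- values < meta$s0 / 2
  values <- meta$offset + (values - meta$s0) / (1 - meta$s0) * meta$scale
  values[unmeasured] <- NA
  rel <- array(!unmeasured, dim = d)
  morpho_field(values, meta$variable, meta$units, meta$boxel_size_um,
               origin_um = as.numeric(meta$origin_um), reliability = rel,
               z_size_um = meta$z_size_um)
}

#' Write a section stack as a multi-page 16-bit TIFF
#'
#' Gray values are stored natively (integer data in `[0, 65535]`) so that
#' [read_stack()] reproduces the arrays element-wise.
#'
#' @param stack a `section_stack` with integer gray values.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  mx <- max(vapply(stack$images, max, numeric(1)))
  if (mx > 65535) stop("gray values exceed the 16-bit range")
  pages <- lapply(stack$images, function(im) im / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}
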