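#' Stereology parameters
#'
#' The two parameters fixed per image stack that convert profile counts
#' into densities: the section thickness `t` and the mean nuclear
#' diameter `D` — per cell type when the specifically stained nuclei
#' differ in size from the rest, so that each type's density is unbiased.
#'
#' @param section_thickness_um section thickness `t` (> 0).
#' @param D_positive_um mean nuclear diameter of the specifically
#'   stained cell type.
#' @param D_negative_um mean nuclear diameter of the remaining cells
#'   (defaults to `D_positive_um`).
#' @param min_profiles_for_li minimum profiles per sample volume for a
#'   reliable labeling index (default 171; see
#'   [required_profile_count()]).
#' @return object of class `stereology_params`.
#' @export
stereology_params <- function(section_thickness_um, D_positive_um,
                              D_negative_um = D_positive_um,
                              min_profiles_for_li = 171L) {
  stopifnot(section_thickness_um > 0, D_positive_um > 0,
            D_negative_um > 0)
  structure(list(section_thickness_um = section_thickness_um,
                 D_positive_um = D_positive_um,
                 D_negative_um = D_negative_um,
                 min_profiles_for_li = as.integer(min_profiles_for_li)),
            class = "stereology_params")
}

#' Profiles per unit tissue area
#'
#' `N_A = N_profiles / sum(A)`. A boxel with zero observed tissue area is
#' unmeasured (`NA`); zero profiles over a positive area is a genuine 0.
#'
#' @param n_profiles profile count (vectorized).
#' @param area_sum_um2 summed tissue area in um^2.
#' @return `N_A` in um^-2, `NA` where `area_sum_um2` is 0.
#' @export
profiles_per_area <- function(n_profiles, area_sum_um2) {
  ifelse(area_sum_um2 > 0, n_profiles / area_sum_um2, NA_real_)
}

#' Abercrombie profile-count correction
#'
#' Converts the profile areal density into a number density:
#' `N_V = N_A / (D + t)`. The correction accounts for the fact that the
#' number of profiles per section area grows with both the nuclear
#' diameter and the section thickness — a nucleus is seen in every
#' section its sphere intersects, so some nuclei are counted twice in
#' consecutive serial sections.
#'
#' @param N_A profiles per unit area (um^-2), vectorized.
#' @param D mean nuclear diameter in um.
#' @param t section thickness in um.
#' @return `N_V` in um^-3.
#' @export
abercrombie_nv <- function(N_A, D, t) {
  stopifnot(D > 0, t > 0)
  N_A / (D + t)
}

#' Cell size (mean tissue volume per nucleus)
#'
#' The inverse of the number of nuclei per unit volume: `1 / N_V`.
#'
#' @param N_V nuclei per unit volume (um^-3), vectorized.
#' @return cell size in um^3; `NA` where `N_V` is 0 or `NA`.
#' @export
cell_size <- function(N_V) {
  ifelse(!is.na(N_V) & N_V > 0, 1 / N_V, NA_real_)
}

#' Labeling index from per-type number densities
#'
#' `LI = N_V_pos / (N_V_pos + N_V_neg)`. With equal nuclear diameters
#' this reduces to the positive fraction of profiles; with differing
#' diameters each density carries its own Abercrombie denominator.
#'
#' @param N_V_pos,N_V_neg per-type number densities (um^-3), vectorized.
#' @return LI in `[0, 1]`; `NA` where both densities are 0.
#' @export
labeling_index <- function(N_V_pos, N_V_neg) {
  s <- N_V_pos + N_V_neg
  ifelse(!is.na(s) & s > 0, N_V_pos / s, NA_real_)
}

#' Cavalieri tissue volume
#'
#' `V_tissue = t * sum(A)`: section thickness times the summed observed
#' tissue areas.
#'
#' @param area_sums_um2 tissue areas (um^2); summed internally.
#' @param t section thickness in um.
#' @return volume in um^3.
#' @export
cavalieri_volume <- function(area_sums_um2, t) {
  stopifnot(t > 0)
  t * sum(area_sums_um2)
}

#' Cell number in a volume
#'
#' `N = N_V * V_tissue`; pooled over non-overlapping (m = 1) boxels this
#' gives the total cell number of the tissue of interest.
#'
#' @param N_V number density (um^-3), vectorized.
#' @param V_tissue tissue volume (um^3), vectorized.
#' @return cell count.
#' @export
total_cell_number <- function(N_V, V_tissue) {
  N_V * V_tissue
}

#' Required profiles per sample volume for a target precision
#'
#' Smallest `n` such that the normal-approximation confidence half-width
#' of a proportion, `z * sqrt(p (1 - p) / n)`, does not exceed
#' `halfwidth`. For a labeling index of 0.5 estimated to within +/- 0.075
#' at 95% confidence this gives 171 profiles per sample volume — the
#' default reliability requirement throughout the package. The exact
#' normal quantile is used (1.959964..., not 1.96).
#'
#' @param p the proportion at which precision is required (0.5 is the
#'   worst case).
#' @param halfwidth target confidence half-width.
#' @param confidence confidence level (default 0.95).
#' @return smallest sufficient integer count (at least 1).
#' @export
required_profile_count <- function(p, halfwidth, confidence = 0.95) {
  stopifnot(p > 0, p < 1, halfwidth > 0, confidence > 0, confidence < 1)
  z <- stats::qnorm((1 + confidence) / 2)
  max(1L, as.integer(ceiling(z^2 * p * (1 - p) / halfwidth^2)))
}

#' Confidence half-width of a proportion at a given count
#'
#' Companion to [required_profile_count()]:
#' `z * sqrt(p (1 - p) / n)`.
#'
#' @param p proportion.
#' @param n count.
#' @param confidence confidence level.
#' @return the half-width.
#' @export
proportion_ci_halfwidth <- function(p, n, confidence = 0.95) {
  stats::qnorm((1 + confidence) / 2) * sqrt(p * (1 - p) / n)
}

#' Convert raw sample-volume counts into morphogenetic fields
#'
#' Applies the stereological formulas boxel-by-boxel to the raw counts:
#' number density (`n_v`, Abercrombie-corrected, summed over cell
#' types), `cell_size`, labeling index (`li`), Cavalieri `tissue_volume`
#' per sample volume, and cell number `total_n` per sample volume. Every
#' field keeps its full lattice; boxels with no observed tissue area are
#' unmeasured (`NA`) and the labeling-index reliability flag is `FALSE`
#' wherever fewer than `min_profiles_for_li` profiles were counted —
#' peripheral sample volumes typically do not include enough nuclei, but
#' their values are kept rather than suppressed.
#'
#' @param raw a [measure_sample_volumes()] result.
#' @param params a [stereology_params()] object.
#' @return named list of [morpho_field()]s: `n_v` (um^-3), `cell_size`
#'   (um^3), `li` (fraction), `tissue_volume` (um^3), `total_n` (count).
#' @export
compute_morpho_fields <- function(raw, params) {
  stopifnot(inherits(raw, "raw_counts"),
            inherits(params, "stereology_params"))
  t <- params$section_thickness_um
  A <- raw$tissue_area_sum_um2
  n_tot <- raw$n_profiles_total
  n_pos <- raw$n_profiles_positive
  nv_pos <- abercrombie_nv(profiles_per_area(n_pos, A),
                           params$D_positive_um, t)
  nv_neg <- abercrombie_nv(profiles_per_area(n_tot - n_pos, A),
                           params$D_negative_um, t)
  nv <- nv_pos + nv_neg
  li <- labeling_index(nv_pos, nv_neg)
  vol <- t * A
  grid <- raw$grid
  rel <- A > 0
  rel_li <- rel & n_tot >= params$min_profiles_for_li
  mk <- function(values, name, units, reliability) {
    morpho_field(values, name, units, grid$boxel_size_um,
                 origin_um = grid$origin_um, reliability = reliability,
                 z_size_um = grid$sections_per_boxel * t)
  }
  list(n_v = mk(nv, "cell_density", "um^-3", rel),
       cell_size = mk(cell_size(nv), "cell_size", "um^3", rel),
       li = mk(li, "labeling_index", "fraction", rel_li),
       tissue_volume = mk(ifelse(rel, vol, NA_real_), "tissue_volume",
                          "um^3", rel),
       total_n = mk(ifelse(rel, total_cell_number(nv, vol), NA_real_),
                    "cell_number", "count", rel))
}

#' Whole-specimen pooled summary
#'
#' Pools non-overlapping (`m = 1`) boxel measurements into specimen-level
#' totals: Cavalieri tissue volume, total cell number
#' (`sum(N_V * V_tissue)` over boxels), and the pooled labeling index
#' from the pooled per-type densities.
#'
#' @param raw a [measure_sample_volumes()] result with `m = 1`.
#' @param params a [stereology_params()] object.
#' @return list with `total_tissue_volume_um3`, `total_cell_number`,
#'   `labeling_index`, `n_profiles_total`, `n_profiles_positive`.
#' @export
pooled_summary <- function(raw, params) {
  if (raw$m != 1L)
    stop("pooled totals require non-overlapping sample volumes (m = 1)")
  t <- params$section_thickness_um
  A <- raw$tissue_area_sum_um2
  measured <- A > 0
  fields <- compute_morpho_fields(raw, params)
  total_n <- sum(fields$total_n$values[measured])
  sumA <- sum(A)
  n_tot <- sum(raw$n_profiles_total[measured])
  n_pos <- sum(raw$n_profiles_positive[measured])
  nv_pos <- abercrombie_nv(n_pos / sumA, params$D_positive_um, t)
  nv_neg <- abercrombie_nv((n_tot - n_pos) / sumA, params$D_negative_um, t)
  list(total_tissue_volume_um3 = cavalieri_volume(A, t),
       total_cell_number = total_n,
       labeling_index = labeling_index(nv_pos, nv_neg),
       n_profiles_total = n_tot,
       n_profiles_positive = n_pos)
}
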