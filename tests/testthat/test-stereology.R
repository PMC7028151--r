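test_that("profile areal density handles zero counts and zero areas", {
  expect_equal(profiles_per_area(171, 17100), 0.01)
  expect_equal(profiles_per_area(0, 100), 0)
  expect_true(is.na(profiles_per_area(5, 0)))
})

test_that("the Abercrombie correction divides by D + t", {
  expect_equal(abercrombie_nv(0.013, 6, 7), 0.001)
  expect_equal(abercrombie_nv(0, 6, 7), 0)
  # algebraic identity: cell_size(N_V) * N_A == D + t
  for (na in c(0.002, 0.013, 0.4)) {
    nv <- abercrombie_nv(na, 6, 7)
    expect_equal(cell_size(nv) * na, 13)
  }
})

test_that("cell size is the inverse density", {
  expect_equal(cell_size(0.001), 1000)
  expect_equal(cell_size(0.002), cell_size(0.001) / 2)
  expect_true(is.na(cell_size(0)))
})

test_that("labeling index combines per-type densities", {
  expect_equal(labeling_index(3, 1), 0.75)
  expect_equal(labeling_index(2, 0), 1)
  expect_true(is.na(labeling_index(0, 0)))
  # equal profile counts but different diameters: each type keeps its
  # own Abercrombie denominator
  nv_pos <- abercrombie_nv(1, 8, 7)   # 1/15 per unit N_A
  nv_neg <- abercrombie_nv(1, 6, 7)   # 1/13
  expect_equal(labeling_index(nv_pos, nv_neg), (1 / 15) / (1 / 15 + 1 / 13),
               tolerance = 1e-12)
  expect_equal(labeling_index(nv_pos, nv_neg), 0.4643, tolerance = 1e-4)
})

test_that("Cavalieri volume is thickness times summed area", {
  expect_equal(cavalieri_volume(c(100, 100, 100), 7), 2100)
  expect_equal(cavalieri_volume(numeric(0), 7), 0)
})

test_that("cell number is density times volume", {
  expect_equal(total_cell_number(0.001, 1e6), 1000)
  expect_equal(total_cell_number(0.002, 0), 0)
})

test_that("the required profile count reproduces the precision rule", {
  expect_equal(required_profile_count(0.5, 0.075, 0.95), 171L)
  # brute-force smallest n as an independent check
  brute <- function(p, hw, conf) {
    z <- qnorm((1 + conf) / 2)
    n <- 1L
    while (z * sqrt(p * (1 - p) / n) > hw) n <- n + 1L
    n
  }
  expect_equal(required_profile_count(0.5, 0.15, 0.95), 43L)
  expect_equal(brute(0.5, 0.15, 0.95), 43L)
  for (p in c(0.2, 0.5, 0.8)) for (hw in c(0.05, 0.11))
    expect_equal(required_profile_count(p, hw, 0.95), brute(p, hw, 0.95))
  # huge tolerated half-width needs only a single profile
  expect_equal(required_profile_count(0.5, 50, 0.95), 1L)
})

test_that("required counts fall with half-width and peak at p = 0.5", {
  hws <- c(0.02, 0.05, 0.075, 0.1, 0.2)
  ns <- vapply(hws, function(h) required_profile_count(0.5, h), integer(1))
  expect_true(all(diff(ns) <= 0))
  n_at <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                 function(p) required_profile_count(p, 0.075), integer(1))
  expect_equal(which.max(n_at), 3L)
  expect_equal(proportion_ci_halfwidth(0.5, 171), 0.075, tolerance = 0.005)
})

test_that("profile counting recovers sphere densities unbiasedly", {
  # slab-intersection counting law: E[N_A] = N_V * (D + t)
  cases <- list(c(rho = 2e-4, D = 6, t = 7),
                c(rho = 5e-5, D = 10, t = 5),
                c(rho = 1e-4, D = 4, t = 12))
  for (cs in cases) {
    side <- 400
    depth <- 40 * cs[["t"]]
    # solid kept clear of the first slab so no profile falls before
    # section 1 (the slab lattice is one-sided)
    gt <- sample_nuclei(solid_box(c(side, side, depth),
                                  origin_um = c(0, 0, 2 * cs[["t"]])),
                        cs[["rho"]], 0.5,
                        D_pos_um = cs[["D"]], D_neg_um = cs[["D"]],
                        seed = 13)
    tr <- profile_truth(gt, cs[["t"]])
    N_A <- nrow(tr) / (40 * side^2)
    nv <- abercrombie_nv(N_A, cs[["D"]], cs[["t"]])
    expect_equal(nv, cs[["rho"]], tolerance = 0.05, ignore_attr = TRUE)
    # the naive density N_A / t overestimates by (D + t) / t
    expect_equal((N_A / cs[["t"]]) / cs[["rho"]],
                 (cs[["D"]] + cs[["t"]]) / cs[["t"]],
                 tolerance = 0.06, ignore_attr = TRUE)
  }
})

test_that("labeling-index recovery is unbiased at the counting level", {
  for (q in c(0.1, 0.5, 0.9)) {
    gt <- sample_nuclei(solid_box(c(300, 300, 210)), 1e-4, q,
                        seed = 14 + round(100 * q))
    tr <- profile_truth(gt, 7)
    n <- nrow(gt$nuclei)
    li_profiles <- mean(tr$label == "positive")
    expect_lt(abs(li_profiles - q), 1.96 * sqrt(q * (1 - q) / n) + 0.01)
  }
})

test_that("morphogenetic fields apply the formulas boxel-wise", {
  sc <- scene_default()
  raw <- measure_sample_volumes(sc$grid, sc$ps, sc$masks, 5)
  params <- stereology_params(7, 6, min_profiles_for_li = 171)
  f <- compute_morpho_fields(raw, params)
  expect_named(f, c("n_v", "cell_size", "li", "tissue_volume", "total_n"))
  measured <- raw$tissue_area_sum_um2 > 0
  i <- which(measured & raw$n_profiles_total > 0)[1]
  na <- raw$n_profiles_total[i] / raw$tissue_area_sum_um2[i]
  expect_equal(f$n_v$values[i], na / 13)
  expect_equal(f$cell_size$values[i], 13 / na)
  expect_equal(f$tissue_volume$values[i], 7 * raw$tissue_area_sum_um2[i])
  expect_equal(f$li$values[i],
               raw$n_profiles_positive[i] / raw$n_profiles_total[i])
  # reliability: LI flag false exactly below the required count
  expect_equal(f$li$reliability,
               measured & raw$n_profiles_total >= 171)
  # unmeasured boxels propagate NA everywhere
  expect_true(all(is.na(f$n_v$values[!measured])))
})

test_that("all-zero raw counts give fully unmeasured fields", {
  ps <- abstract_profiles(50, 50, 1)
  m <- matrix(FALSE, 100, 100)
  masks <- mask_stack(list(m), 1)
  grid <- build_boxel_grid(ps, NULL, 26, 7)
  raw <- measure_sample_volumes(grid, ps, masks, 1)
  f <- compute_morpho_fields(raw, stereology_params(7, 6))
  expect_true(all(is.na(f$n_v$values)))
  expect_true(all(!f$li$reliability))
})

test_that("pooled totals recover the simulated population", {
  sc <- scene_default()
  raw1 <- measure_sample_volumes(sc$grid, sc$ps, sc$masks, 1)
  s <- pooled_summary(raw1, stereology_params(7, 6))
  true_n <- nrow(sc$gt$nuclei)
  # detection misses the smallest grazing profiles, so the pipeline
  # estimate sits below truth but within the counting bias budget
  expect_lt(abs(s$total_cell_number / true_n - 1), 0.2)
  expect_lt(abs(s$labeling_index - 0.5),
            1.96 * sqrt(0.25 / true_n) + 0.02)
  # truth-level counting removes the detection loss entirely
  tr <- profile_truth(sc$gt, 7)
  sumA <- sum(raw1$tissue_area_sum_um2)
  nv_true_counts <- abercrombie_nv(nrow(tr) / sumA, 6, 7)
  est <- total_cell_number(nv_true_counts, cavalieri_volume(
    raw1$tissue_area_sum_um2, 7))
  expect_lt(abs(est / true_n - 1), 0.07)
  expect_error(pooled_summary(measure_sample_volumes(sc$grid, sc$ps,
                                                     sc$masks, 3),
                              stereology_params(7, 6)), "m = 1")
})
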