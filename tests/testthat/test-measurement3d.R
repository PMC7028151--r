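test_that("boxel grid dimensions follow the bounding box and z-snap", {
  # 130 um of in-plane content at 26 um boxels -> 5 x 5
  ps <- abstract_profiles(c(0, 130), c(0, 130), c(1, 1))
  g <- build_boxel_grid(ps, NULL, 26, 7)
  expect_equal(unname(g$dims[1:2]), c(5L, 5L))
  # 20 sections of t = 7 at 26 um boxels: 4 sections per boxel, nz = 5
  ps2 <- abstract_profiles(c(0, 130), c(0, 130), c(1, 20),
                           section_count = 20)
  g2 <- build_boxel_grid(ps2, NULL, 26, 7)
  expect_equal(g2$sections_per_boxel, 4L)
  expect_equal(unname(g2$dims[3]), 5L)
  # a single profile still gets a lattice
  g3 <- build_boxel_grid(abstract_profiles(5, 5, 1), NULL, 26, 7)
  expect_equal(unname(g3$dims), c(1L, 1L, 1L))
  expect_error(build_boxel_grid(abstract_profiles(numeric(0), numeric(0),
                                                  integer(0),
                                                  section_count = 1),
                                NULL, 26, 7), "empty")
})

test_that("m = 1 assigns each profile to exactly one boxel", {
  ps <- abstract_profiles(40, 40, 2, section_count = 8)
  masks <- full_masks(c(80, 80), 8)
  grid <- build_boxel_grid(ps, masks, 26, 7)
  raw <- measure_sample_volumes(grid, ps, masks, 1)
  expect_equal(sum(raw$n_profiles_total), 1)
  hot <- which(raw$n_profiles_total == 1, arr.ind = TRUE)
  expect_equal(nrow(hot), 1)
})

test_that("even sample-volume sizes are rejected", {
  ps <- abstract_profiles(40, 40, 1)
  masks <- full_masks(c(80, 80), 1)
  grid <- build_boxel_grid(ps, masks, 26, 7)
  expect_error(measure_sample_volumes(grid, ps, masks, 2), "odd")
  expect_error(measure_sample_volumes(grid, ps, masks, 0), "odd")
})

test_that("profiles outside the tissue mask are not counted", {
  ps <- abstract_profiles(c(20, 60), c(20, 20), c(1, 1))
  m <- matrix(FALSE, 80, 80); m[, 1:40] <- TRUE  # tissue in left half
  masks <- mask_stack(list(m), 1)
  grid <- build_boxel_grid(ps, masks, 26, 7)
  raw <- measure_sample_volumes(grid, ps, masks, 1)
  expect_equal(raw$n_in_tissue, 1)
  expect_equal(sum(raw$n_profiles_total), 1)
})

test_that("sample-volume counts equal the moving sum of m = 1 counts", {
  set.seed(11)
  for (rep in 1:20) {
    nsec <- sample(9:20, 1)
    npro <- sample(30:120, 1)
    imd <- c(140, 140)
    sec <- sample(nsec, npro, TRUE)
    ps <- abstract_profiles(runif(npro, 0, 138), runif(npro, 0, 138), sec,
                            section_count = nsec,
                            positivity = sample(c("positive", "negative"),
                                                npro, TRUE))
    masks <- mask_stack(replicate(nsec, matrix(runif(prod(imd)) < 0.8,
                                               imd[1]), simplify = FALSE), 1)
    grid <- build_boxel_grid(ps, masks, 26, 7)
    m <- sample(c(3L, 5L), 1)
    raw_m <- measure_sample_volumes(grid, ps, masks, m)
    raw_1 <- measure_sample_volumes(grid, ps, masks, 1L)
    interior <- !raw_m$clipped
    sm_tot <- oracle_moving_sum(raw_1$n_profiles_total, m)
    sm_pos <- oracle_moving_sum(raw_1$n_profiles_positive, m)
    sm_area <- oracle_moving_sum(raw_1$tissue_area_sum_um2, m)
    expect_equal(as.numeric(raw_m$n_profiles_total[interior]),
                 as.numeric(sm_tot[interior]), tolerance = 0)
    expect_equal(as.numeric(raw_m$n_profiles_positive[interior]),
                 as.numeric(sm_pos[interior]), tolerance = 0)
    expect_equal(raw_m$tissue_area_sum_um2[interior], sm_area[interior],
                 tolerance = 1e-10)
  }
})

test_that("m = 1 binning matches an independent centroid binning", {
  sc <- scene_default()
  raw1 <- measure_sample_volumes(sc$grid, sc$ps, sc$masks, 1)
  # conservation: every in-tissue profile lands in exactly one boxel
  expect_equal(sum(raw1$n_profiles_total), raw1$n_in_tissue)
  expect_true(all(raw1$n_profiles_positive <= raw1$n_profiles_total))
})

test_that("shifting all profiles by one boxel shifts the counts", {
  set.seed(12)
  nsec <- 12
  ps <- abstract_profiles(runif(60, 30, 110), runif(60, 30, 110),
                          sample(5:8, 60, TRUE), section_count = nsec)
  masks <- full_masks(c(160, 160), nsec)
  grid <- build_boxel_grid(
    abstract_profiles(c(0, 156), c(0, 156), c(1, nsec),
                      section_count = nsec), masks, 26, 7)
  raw_a <- measure_sample_volumes(grid, ps, masks, 1)
  ps_shift <- ps
  ps_shift$profiles$x_um <- ps_shift$profiles$x_um + 26
  raw_b <- measure_sample_volumes(grid, ps_shift, masks, 1)
  nx <- grid$dims[1]
  expect_equal(raw_b$n_profiles_total[2:nx, , ],
               raw_a$n_profiles_total[1:(nx - 1), , ])
})

test_that("cumulative count distribution reports low-confidence fraction", {
  mk_raw <- function(counts) {
    structure(list(tissue_area_sum_um2 = array(1, dim = c(length(counts), 1, 1)),
                   n_profiles_total = array(counts,
                                            dim = c(length(counts), 1, 1)),
                   n_profiles_positive = array(0, dim = c(length(counts), 1, 1)),
                   m = 1L), class = "raw_counts")
  }
  ccd <- cumulative_count_distribution(mk_raw(rep(200, 50)), 171)
  expect_equal(ccd$fraction_below, 0)
  ccd2 <- cumulative_count_distribution(mk_raw(c(rep(100, 100),
                                                 rep(300, 100))), 171)
  expect_equal(ccd2$fraction_below, 0.5)
  expect_true(all(diff(ccd2$curve$fraction_le) >= 0))  # nondecreasing
  # boxels without tissue are excluded from the distribution
  r <- mk_raw(c(5, 10))
  r$tissue_area_sum_um2[2] <- 0
  expect_equal(cumulative_count_distribution(r, 171)$curve$n, 5)
})

test_that("the pilot sweep picks the smallest sufficient sample volume", {
  sc <- scene_default()
  pick <- suppressWarnings(
    choose_sample_volume(sc$grid, sc$ps, sc$masks, required_n = 171,
                         m_candidates = c(1, 3, 5)))
  expect_true(all(diff(pick$sweep$fraction_below) <= 0))  # monotone in m
  # requiring nothing always selects the smallest candidate
  pick0 <- choose_sample_volume(sc$grid, sc$ps, sc$masks, required_n = 0,
                                m_candidates = c(1, 3, 5))
  expect_equal(pick0$m, 1L)
  # an unreachable requirement returns the best candidate with a warning
  expect_warning(
    choose_sample_volume(sc$grid, sc$ps, sc$masks, required_n = 10000,
                         m_candidates = c(1, 3)), "no candidate")
})
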