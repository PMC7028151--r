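test_that("low-pass subtraction removes flat fields and gradients", {
  expect_true(all(local_maxima_image(matrix(5, 30, 30), 10) == 0))
  # linear ramp plus one bright disc: ramp suppressed, disc retained
  n <- 80
  ramp <- matrix(seq(0, 0.4, length.out = n), n, n, byrow = TRUE)
  im <- ramp + disc_image(c(n, n), list(c(40, 40)), 3.5, 0.6)
  lm <- local_maxima_image(im, 10)
  disc_px <- disc_image(c(n, n), list(c(40, 40)), 3.5, 1) > 0
  peak <- max(lm[disc_px])
  background <- lm[!disc_px]
  expect_lt(quantile(background, 0.99), 0.1 * peak)
  expect_gt(peak, 0.3)
})

test_that("a single bright pixel keeps value v - v/k^2", {
  for (k in c(4, 10, 11)) {
    im <- matrix(0, 50, 50); im[25, 25] <- 100
    lm <- local_maxima_image(im, k)
    expect_equal(lm[25, 25], 100 - 100 / k^2)
  }
  expect_error(local_maxima_image(matrix(0, 5, 5), 10), "larger than image")
})

test_that("background removal is invariant to a global intensity offset", {
  set.seed(10)
  im <- matrix(runif(900), 30)
  for (k in c(5, 10))
    expect_equal(local_maxima_image(im + 7, k),
                 local_maxima_image(im, k), tolerance = 1e-12)
})

test_that("profile detection measures calibrated areas and centroids", {
  p <- 0.9
  im <- disc_image(c(100, 100), list(c(30, 30), c(70, 64)), 3.3)
  ps <- detect_profiles(im, 0.3, p)
  expect_equal(nrow(ps$profiles), 2)
  got <- ps$profiles[order(ps$profiles$x_um), ]
  expect_equal(got$x_um / p, c(30, 70), tolerance = 1 / 30)
  expect_equal(got$y_um / p, c(30, 64), tolerance = 1 / 64)
  # pixel-counted disc area close to pi r^2 (in um^2)
  expect_equal(got$area_um2, rep(pi * 3.3^2 * p^2, 2), tolerance = 0.1)
  expect_equal(nrow(detect_profiles(matrix(0, 20, 20) + 1e-9, 0.5, p)$profiles), 0)
  # a disc below the minimum area is treated as debris
  expect_equal(nrow(detect_profiles(im, 0.3, p,
                                    min_area_um2 = 50)$profiles), 0)
})

test_that("profiles above twice the median area split in two", {
  ps <- abstract_profiles(c(10, 30, 50), c(10, 10, 10), c(1, 1, 1),
                          area_um2 = c(10, 10, 25))
  out <- split_large_profiles(ps)
  expect_equal(nrow(out$profiles), 4)
  expect_equal(sort(out$profiles$area_um2), c(10, 10, 12.5, 12.5))
  # boundary: exactly twice the median is kept whole
  ps2 <- abstract_profiles(c(10, 30, 50), c(10, 10, 10), c(1, 1, 1),
                           area_um2 = c(10, 10, 20))
  expect_equal(nrow(split_large_profiles(ps2)$profiles), 3)
  # a single profile can never exceed twice its own median
  ps3 <- abstract_profiles(5, 5, 1, area_um2 = 100)
  expect_equal(nrow(split_large_profiles(ps3)$profiles), 1)
})

test_that("geometric splitting conserves area and updates labels", {
  # dumbbell of two overlapping discs + four small discs to set the median
  im <- disc_image(c(80, 80), list(c(40, 35), c(40, 45)), 5)
  for (ctr in list(c(12, 12), c(12, 68), c(68, 12), c(68, 68)))
    im <- pmax(im, disc_image(c(80, 80), list(ctr), 3))
  ps <- detect_profiles(im, 0.3, 1)
  expect_equal(nrow(ps$profiles), 5)
  out <- split_large_profiles(ps)
  expect_equal(nrow(out$profiles), 6)
  expect_equal(sum(out$profiles$area_um2), sum(ps$profiles$area_um2))
  # children are roughly equal and separated along the long axis
  kids <- out$profiles[!out$profiles$label %in% ps$profiles$label, ]
  expect_equal(nrow(kids), 2)
  expect_lt(abs(kids$area_um2[1] - kids$area_um2[2]) /
              sum(kids$area_um2), 0.2)
  lab <- out$label_images[["1"]]
  expect_setequal(setdiff(unique(as.vector(lab)), 0), out$profiles$label)
})

test_that("positivity compares profile mean against local background", {
  lab <- matrix(0L, 40, 40)
  lab[18:22, 18:22] <- 1L
  ps <- profile_set(data.frame(section_index = 1, label = 1, x_um = 19.5,
                               y_um = 19.5, area_um2 = 25,
                               mean_intensity = NA, positivity = NA),
                    1, 1, label_images = list(`1` = lab))
  bg <- matrix(rep(c(40, 45, 50, 55, 60), length.out = 1600), 40)
  hot <- bg; hot[lab == 1] <- 200   # clearly above background
  out <- classify_positive(ps, hot)
  expect_equal(out$profiles$positivity, "positive")
  expect_equal(out$profiles$mean_intensity, 200)
  dim_img <- bg; dim_img[lab == 1] <- 55  # within background spread
  expect_equal(classify_positive(ps, dim_img)$profiles$positivity,
               "negative")
  # no background in the window -> excluded
  lab_full <- matrix(1L, 40, 40)
  ps_full <- profile_set(ps$profiles, 1, 1,
                         label_images = list(`1` = lab_full))
  expect_equal(classify_positive(ps_full, hot)$profiles$positivity,
               "excluded")
})

test_that("classification is invariant to affine intensity rescaling", {
  sc <- scene_default()
  ps0 <- sc$ps
  sp <- sc$rend$channels$specific$images
  scaled <- lapply(sp, function(im) 3.7 * im + 11)
  a <- classify_positive(ps0, sp)
  b <- classify_positive(ps0, scaled)
  expect_equal(a$profiles$positivity, b$profiles$positivity)
})

test_that("detection and classification recover the simulated scene", {
  sc <- scene_default()
  truth <- sc$rend$truth
  truth$section_index <- truth$section
  det <- sc$ps$profiles
  # recall/precision by nearest-centroid matching within a nucleus radius
  match_frac <- function(from, to) {
    hit <- 0
    for (k in unique(from$section_index)) {
      f <- from[from$section_index == k, ]
      g <- to[to$section_index == k, ]
      if (nrow(g) == 0) next
      for (i in seq_len(nrow(f))) {
        d2 <- (g$x_um - f$x_um[i])^2 + (g$y_um - f$y_um[i])^2
        if (min(d2) < 3^2) hit <- hit + 1
      }
    }
    hit / nrow(from)
  }
  # profiles large enough to be detectable (above the debris cut)
  visible <- truth[pi * truth$radius_um^2 >= 4, ]
  expect_gte(match_frac(visible, det), 0.9)   # recall
  expect_gte(match_frac(det, truth), 0.9)     # precision
  # classification accuracy against ground-truth labels
  correct <- 0; total <- 0
  for (k in unique(det$section_index)) {
    d <- det[det$section_index == k, ]
    g <- truth[truth$section == k, ]
    for (i in seq_len(nrow(d))) {
      d2 <- (g$x_um - d$x_um[i])^2 + (g$y_um - d$y_um[i])^2
      j <- which.min(d2)
      if (d2[j] < 3^2) {
        total <- total + 1
        if (g$label[j] == d$positivity[i]) correct <- correct + 1
      }
    }
  }
  expect_gte(correct / total, 0.95)
})

test_that("control images circle each centroid in its class color", {
  base <- matrix(0.2, 60, 60)
  ps <- abstract_profiles(c(15, 30, 45, 20, 40), c(15, 30, 45, 45, 15),
                          rep(1, 5),
                          positivity = c("positive", "positive", "positive",
                                         "negative", "negative"))
  img <- control_image(ps, base, radius_px = 4)
  is_col <- function(rgbv) img[, , 1] == rgbv[1] & img[, , 2] == rgbv[2] &
    img[, , 3] == rgbv[3]
  pos_px <- which(is_col(c(1, 0, 0)), arr.ind = TRUE)
  neg_px <- which(is_col(c(0, 1, 0)), arr.ind = TRUE)
  expect_gt(nrow(pos_px), 0)
  expect_gt(nrow(neg_px), 0)
  # decode ring centers: cluster by nearest annotated centroid
  centers <- ps$profiles[c("x_um", "y_um")]
  for (i in 1:3) {
    sel <- (pos_px[, 2] - centers$x_um[i])^2 +
      (pos_px[, 1] - centers$y_um[i])^2 < 6^2
    expect_equal(mean(pos_px[sel, 2] - 0.5), centers$x_um[i], tolerance = 1)
    expect_equal(mean(pos_px[sel, 1] - 0.5), centers$y_um[i], tolerance = 1)
  }
  # no profiles: base returned as plain RGB
  empty <- abstract_profiles(numeric(0), numeric(0), integer(0),
                             section_count = 1)
  img0 <- control_image(empty, base)
  expect_equal(img0[, , 1], img0[, , 2])
})

test_that("profile sets round-trip through CSV", {
  sc <- scene_default()
  f <- withr::local_tempfile(fileext = ".csv")
  write_profiles(sc$ps, f)
  back <- read_profiles(f, sc$ps$section_count, sc$ps$pixel_size_um)
  expect_equal(back$profiles$area_um2, sc$ps$profiles$area_um2)
  expect_equal(back$profiles$positivity, sc$ps$profiles$positivity)
})
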