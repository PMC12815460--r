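mk_img <- function(rec, arr, ps = 0.1) {
  two_channel_image(channel_image(rec, ps), channel_image(arr, ps))
}

test_that("Mander's coefficients hit the exact binary identities", {
  m <- matrix(0, 20, 20); m[5:10, 5:10] <- 100
  expect_equal(manders(mk_img(m, m), NULL, 10, 10)$m1, 1)
  expect_equal(manders(mk_img(m, m), NULL, 10, 10)$m2, 1)
  disj <- matrix(0, 20, 20); disj[14:18, 14:18] <- 100
  cc <- manders(mk_img(m, disj), NULL, 10, 10)
  expect_equal(cc$m1, 0)
  expect_equal(cc$m2, 0)
  # receptor uniform over a region, arrestin covering exactly half of it
  rec <- matrix(0, 20, 20); rec[1:10, 1:10] <- 50
  arr <- matrix(0, 20, 20); arr[1:10, 1:5] <- 50
  expect_equal(manders(mk_img(rec, arr), NULL, 1, 1)$m1, 0.5)
  # no above-threshold signal is undefined, not zero
  expect_error(manders(mk_img(m, disj), NULL, 1000, 10), "undefined")
})

test_that("Mander's is invariant under matched linear rescaling", {
  g <- gen_coloc_images(15, 0.5, 96, 0.1, 0.2, snr = 10, seed = 3)
  tr <- auto_threshold(g$image$receptor)
  ta <- auto_threshold(g$image$arrestin)
  base <- manders(g$image, NULL, tr, ta)
  scaled <- mk_img(g$image$receptor$pixels * 7, g$image$arrestin$pixels * 7)
  resc <- manders(scaled, NULL, tr * 7, ta * 7)
  expect_equal(resc$m1, base$m1, tolerance = 1e-12)
  expect_equal(resc$m2, base$m2, tolerance = 1e-12)
})

test_that("auto_threshold separates two-level images and flags constants", {
  two <- matrix(c(rep(0, 200), rep(100, 56)), 16, 16)
  thr <- auto_threshold(channel_image(two, 0.1), "otsu")
  expect_gt(thr, 0); expect_lt(thr, 100)
  set.seed(9)
  bg <- matrix(rnorm(256^2, 10, 2), 256)
  bg[10, 10] <- 200  # one bright punctum barely moves the moments
  thr2 <- auto_threshold(channel_image(pmax(bg, 0), 0.1), "mean_plus_k_sd",
                         k = 2)
  expect_equal(thr2, mean(pmax(bg, 0)) + 2 * sd(pmax(bg, 0)))
  expect_equal(thr2, 14, tolerance = 0.03)  # background moments dominate
  expect_error(auto_threshold(channel_image(matrix(5, 4, 4), 0.1)),
               "degenerate")
})

test_that("detect_puncta uses 8-connectivity, physical areas and min-area", {
  m <- matrix(0, 20, 20)
  m[3:5, 3:5] <- 10  # 3x3 square: 9 px * (0.1 um)^2 = 0.09 um^2
  p <- detect_puncta(channel_image(m, 0.1), threshold = 1,
                     min_area_um2 = 0.05)
  expect_equal(nrow(p), 1)
  expect_equal(p$area_um2, 0.09)
  expect_equal(p$centroid_row, 3)  # 0-based centre of rows 3:5 (1-based)
  expect_equal(p$centroid_col, 3)
  # corner-touching squares merge under 8-connectivity
  m2 <- matrix(0, 20, 20); m2[1:2, 1:2] <- 10; m2[3:4, 3:4] <- 10
  expect_equal(nrow(detect_puncta(channel_image(m2, 0.1), 1, 0)), 1)
  # empty mask and min-area filtering
  expect_equal(nrow(detect_puncta(channel_image(m, 0.1), 100, 0)), 0)
  expect_equal(nrow(detect_puncta(channel_image(m, 0.1), 1, 0.5)), 0)
})

test_that("classify_puncta partitions the punctum set", {
  g <- gen_coloc_images(20, 0.5, 128, 0.1, 0.2, snr = Inf, seed = 8)
  thr <- 20
  pts <- detect_puncta(g$image$receptor, thr, 0.02)
  cls <- classify_puncta(pts, g$image$arrestin, thr)
  expect_equal(cls$n_receptor_only + cls$n_double_positive, nrow(pts))
  # arrestin identically zero -> all receptor-only
  zero <- channel_image(matrix(0, 128, 128), 0.1)
  cls0 <- classify_puncta(pts, zero, thr)
  expect_equal(cls0$n_double_positive, 0)
  # arrestin == receptor -> all double-positive
  cls1 <- classify_puncta(pts, g$image$receptor, thr)
  expect_equal(cls1$n_receptor_only, 0)
})

test_that("puncta_density scales counts to 100 um^2", {
  # 20 puncta inside a 100 um^2 ROI (100 x 100 px at 0.1 um)
  m <- matrix(0, 120, 120)
  centres <- expand.grid(r = seq(10, 86, by = 19), c = seq(10, 86, by = 19))
  centres <- centres[1:20, ]
  for (i in seq_len(20)) m[centres$r[i] + 1, centres$c[i] + 1] <- 10
  pts <- detect_puncta(channel_image(m, 0.1), 1, 0)
  expect_equal(puncta_density(pts, roi(0, 0, 100)), 20)
  # 5 puncta in a 50 um^2 ROI -> 10 per 100 um^2
  m2 <- matrix(0, 120, 120)
  for (r in seq(5, 61, by = 14)) m2[r + 1, 6] <- 10
  pts2 <- detect_puncta(channel_image(m2, 0.1), 1, 0)
  r50 <- roi(0, 0, round(sqrt(50) / 0.1))  # ~50 um^2
  expect_equal(puncta_density(pts2, r50), 5 * 100 / roi_area_um2(r50, 0.1))
  # empty ROI
  expect_equal(puncta_density(pts2, roi(110, 110, 5)), 0)
})

test_that("line_profile interpolates bilinearly in physical units", {
  const <- mk_img(matrix(7, 30, 30), matrix(3, 30, 30))
  prof <- line_profile(const, c(2, 2), c(25, 20), n_samples = 11)
  expect_equal(prof$receptor_AU, rep(7, 11))
  expect_equal(prof$arrestin_AU, rep(3, 11))
  expect_equal(prof$distance_um[11], sqrt(23^2 + 18^2) * 0.1)
  # linear ramp along rows stays linear along a row-wise profile
  ramp <- matrix(rep(0:29, each = 30), 30, 30, byrow = FALSE)
  ramp <- matrix(rep(0:29, times = 30), 30, 30)  # value = row index
  img <- mk_img(ramp, ramp)
  p2 <- line_profile(img, c(0, 5), c(29, 5), n_samples = 30)
  expect_equal(p2$receptor_AU, as.numeric(0:29), tolerance = 1e-12)
  # planted Gaussian spot crossed centrally peaks at the centre
  g <- matrix(0, 41, 41)
  for (r in 1:41) for (cl in 1:41)
    g[r, cl] <- exp(-((r - 21)^2 + (cl - 21)^2) / (2 * 2^2))
  p3 <- line_profile(mk_img(g, g), c(20, 0), c(20, 40), n_samples = 41)
  expect_equal(which.max(p3$receptor_AU), 21)
  expect_error(line_profile(img, c(0, 0), c(50, 5), 10), "bounds")
})

test_that("recovered colocalization tracks the planted fraction", {
  for (p in c(0, 0.5, 1)) {
    devs_m1 <- devs_dp <- numeric(10)
    for (i in 1:10) {
      g <- gen_coloc_images(20, p, 128, 0.1, 0.2, snr = 10, seed = 100 + i)
      tr <- auto_threshold(g$image$receptor)
      ta <- auto_threshold(g$image$arrestin)
      m1 <- manders(g$image, NULL, tr, ta)$m1
      pts <- detect_puncta(g$image$receptor, tr, 0.05)
      cls <- classify_puncta(pts, g$image$arrestin, ta)
      devs_m1[i] <- m1 - g$truth$coloc_fraction
      devs_dp[i] <- cls$n_double_positive / nrow(pts) -
        g$truth$coloc_fraction
    }
    expect_lt(max(abs(devs_m1)), 0.1)
    expect_lt(max(abs(devs_dp)), 0.1)
  }
})
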