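test_that("peak_list validates keys, groups and intensities", {
  df <- data.frame(residue_number = c(1, 1), residue_type = "A",
                   atom_group = "backbone_amide", shift_h_ppm = 8,
                   shift_x_ppm = 120, intensity = 1)
  expect_error(peak_list(df), "duplicate")
  df$residue_number <- c(1, 2); df$atom_group <- "sidechain"
  expect_error(peak_list(df), "atom_group")
})

test_that("intensity ratios implement the mean - 1 SD significance rule", {
  apo <- quick_peaklist(1:4, intensity = 10)
  bound <- quick_peaklist(1:4, intensity = c(10, 10, 10, 2))
  prof <- intensity_ratios(apo, bound)
  # hand arithmetic on {1, 1, 1, 0.2}
  expect_equal(prof$mean, 0.8)
  expect_equal(prof$sd, 0.4)          # sample SD
  expect_equal(prof$threshold, 0.4)
  expect_equal(prof$significant, 4L)

  # identical lists: sd = 0 and the strict inequality flags nothing
  same <- intensity_ratios(apo, apo)
  expect_true(all(same$entries$ratio == 1))
  expect_length(same$significant, 0)
})

test_that("ratio profiles handle exclusions without failing globally", {
  apo <- quick_peaklist(1:4, intensity = c(10, 0, 10, 10))
  bound <- quick_peaklist(c(1:4, 9), intensity = 5)
  expect_warning(prof <- intensity_ratios(apo, bound), "zero apo")
  expect_equal(nrow(prof$entries), 3)        # residue 2 excluded
  expect_true(any(grepl("^2 ", prof$excluded)))
  expect_true(any(grepl("^9 ", prof$excluded)))  # only in bound list
  disjoint <- quick_peaklist(10:12, intensity = 5)
  expect_error(intensity_ratios(apo, disjoint), "empty overlap")
})

test_that("combined CSP follows the weighted quadrature formula", {
  apo <- quick_peaklist(1:3, intensity = 10, shift_h = c(8, 8, 8),
                        shift_x = c(120, 120, 120))
  bound <- quick_peaklist(1:3, intensity = 10,
                          shift_h = c(8, 8 - 0.02, 8),
                          shift_x = c(120 - 3.6, 120 - 0.10, 120))
  prof <- combined_csp(apo, bound)
  # dH = 0, dX = 3.6 -> exactly 1 ppm; (0.02, 0.10) -> 0.0342 by hand
  expect_equal(prof$entries$csp[1], 1.0)
  expect_equal(prof$entries$csp[2], 0.03422871, tolerance = 1e-6)
  expect_equal(prof$entries$csp[3], 0)
  expect_equal(prof$threshold, prof$mean + prof$sd)
})

test_that("significance sets are invariant under rescaling and offsets", {
  g <- gen_peaklist_pair(60, c(25, 30), attenuation_depth = 0.7,
                         csp_peak = 0.06, noise_sd = 0.03, seed = 42)
  base_att <- intensity_ratios(g$apo, g$bound)
  base_csp <- combined_csp(g$apo, g$bound)

  scale_int <- function(pl, k) {
    df <- as.data.frame(pl); df$intensity <- df$intensity * k
    peak_list(df, attr(pl, "condition_label"))
  }
  shift_all <- function(pl, dh, dx) {
    df <- as.data.frame(pl)
    df$shift_h_ppm <- df$shift_h_ppm + dh
    df$shift_x_ppm <- df$shift_x_ppm + dx
    peak_list(df, attr(pl, "condition_label"))
  }
  resc <- intensity_ratios(scale_int(g$apo, 3.7), g$bound)
  expect_equal(sort(resc$significant), sort(base_att$significant))
  offs <- combined_csp(shift_all(g$apo, 0.5, -2),
                       shift_all(g$bound, 0.5, -2))
  expect_equal(sort(offs$significant), sort(base_csp$significant))
  # key handling is an intersection
  expect_true(all(base_att$entries$residue_number %in% g$apo$residue_number))
})

test_that("segment_regions groups runs with the gap rule", {
  r <- segment_regions(374:381)
  expect_equal(r, data.frame(start_residue = 374L, end_residue = 381L))
  r2 <- segment_regions(c(39, 40, 48, 49, 50), max_gap = 0)
  expect_equal(r2$start_residue, c(39L, 48L))
  expect_equal(r2$end_residue, c(40L, 50L))
  expect_equal(segment_regions(c(10, 12), max_gap = 1),
               data.frame(start_residue = 10L, end_residue = 12L))
  expect_equal(nrow(segment_regions(integer())), 0)
})

test_that("planted binding sites are recovered exactly without noise", {
  for (seed in 1:5) {
    g <- gen_peaklist_pair(100, c(60, 67), attenuation_depth = 0.8,
                           csp_peak = 0.05, noise_sd = 0, seed = seed)
    att <- intensity_ratios(g$apo, g$bound)
    expect_equal(sort(att$significant), 60:67)
    csp <- combined_csp(g$apo, g$bound)
    expect_equal(sort(csp$significant), 60:67)
    expect_equal(segment_regions(att$significant),
                 data.frame(start_residue = 60L, end_residue = 67L))
  }
  # zero depth: nothing to find
  g0 <- gen_peaklist_pair(100, c(60, 67), attenuation_depth = 0,
                          csp_peak = 0, noise_sd = 0, seed = 1)
  expect_length(intensity_ratios(g0$apo, g0$bound)$significant, 0)
})

test_that("extract_titration follows one resonance across a ladder", {
  grid <- c(0, 25, 50, 100, 200, 400, 600)
  mk <- function(l) {
    shift <- 13 - predicted_response(50, l, 104, 0.05)
    quick_peaklist(c(300, 377), intensity = 10, shift_h = 0.8,
                   shift_x = c(10, shift), atom_group = "ile_d1_methyl")
  }
  series <- extract_titration(lapply(grid, mk), grid, residue_number = 377,
                              atom_group = "ile_d1_methyl",
                              protein_total = 50)
  expect_s3_class(series, "titration_series")
  expect_equal(series$response[1], 0)
  f <- fit_kd(series)
  expect_equal(f$kd, 104, tolerance = 1e-6)

  # identical lists give zero responses; missing keys are dropped
  flat <- extract_titration(list(mk(0), mk(0)), c(0, 100),
                            377, "ile_d1_methyl", 50)
  expect_equal(flat$response, c(0, 0))
  one_missing <- lapply(grid, mk)
  one_missing[[3]] <- quick_peaklist(300, 10, atom_group = "ile_d1_methyl")
  expect_warning(
    s2 <- extract_titration(one_missing, grid, 377, "ile_d1_methyl", 50),
    "dropped")
  expect_equal(nrow(s2), length(grid) - 1)
  expect_error(
    extract_titration(list(mk(0), mk(10)), c(5, 10), 377, "ile_d1_methyl", 50),
    "zero-ligand")
})
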