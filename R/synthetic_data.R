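#' Generate a synthetic titration series
#'
#' Responses lie exactly on the 1:1 ligand-depletion isotherm
#' ([predicted_response()]) plus additive Gaussian noise. The planted
#' parameters are attached as ground truth, so [fit_kd()] can be scored
#' without re-deriving them.
#'
#' @param kd Planted dissociation constant (uM).
#' @param response_max Planted saturation response (ppm).
#' @param protein_total Observed-protein concentration (uM).
#' @param ligand_grid Ligand concentrations (uM), distinct.
#' @param noise_sd SD of additive Gaussian response noise (ppm).
#' @param seed Integer seed; identical calls are bit-identical.
#' @return A [titration_series()] with attribute
#'   `truth = list(kd, response_max)`.
#' @export
gen_titration <- function(kd, response_max, protein_total, ligand_grid,
                          noise_sd = 0, seed) {
  stopifnot(noise_sd >= 0)
  resp <- withr::with_seed(seed,
    predicted_response(protein_total, ligand_grid, kd, response_max) +
      stats::rnorm(length(ligand_grid), 0, noise_sd))
  s <- titration_series(ligand_grid, resp, protein_total,
                        label = sprintf("synthetic kd=%g", kd))
  attr(s, "truth") <- list(kd = kd, response_max = response_max)
  s
}

#' Generate an apo/bound peak-list pair with a planted binding site
#'
#' The apo list has uniform intensities and random but fixed shifts; the
#' bound list attenuates intensities inside the planted contiguous site by
#' `attenuation_depth` and shifts those resonances so their combined
#' perturbation ([combined_csp()]) equals `csp_peak`. `noise_sd` is the SD
#' of Gaussian noise on the intensity *ratio*; shift noise is scaled as
#' `noise_sd * csp_peak` so that `noise_sd = 0` makes both profiles exact
#' two-level functions with closed-form significance thresholds.
#'
#' @param n_residues Number of residues (1..n).
#' @param site Integer `c(start, end)` of the planted site, inside 1..n.
#' @param attenuation_depth Fractional intensity loss inside the site,
#'   in (0, 1].
#' @param csp_peak Planted combined shift perturbation inside the site
#'   (ppm).
#' @param noise_sd SD of Gaussian ratio noise (dimensionless).
#' @param seed Integer seed.
#' @return List with elements `apo`, `bound` ([peak_list()]s) and
#'   `truth = list(site)`.
#' @export
gen_peaklist_pair <- function(n_residues, site, attenuation_depth,
                              csp_peak = 0.05, noise_sd = 0, seed) {
  stopifnot(length(site) == 2L, site[1] <= site[2],
            site[1] >= 1, site[2] <= n_residues,
            attenuation_depth >= 0, attenuation_depth <= 1, noise_sd >= 0)
  withr::with_seed(seed, {
    res <- seq_len(n_residues)
    in_site <- res >= site[1] & res <= site[2]
    types <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                    n_residues, replace = TRUE)
    apo_df <- data.frame(
      residue_number = res, residue_type = types,
      atom_group = "backbone_amide",
      shift_h_ppm = stats::runif(n_residues, 7.5, 9.5),
      shift_x_ppm = stats::runif(n_residues, 105, 130),
      intensity = 1000)
    ratio <- ifelse(in_site, 1 - attenuation_depth, 1) +
      stats::rnorm(n_residues, 0, noise_sd)
    d_comb <- ifelse(in_site, csp_peak, 0)
    dh <- d_comb / sqrt(2) + stats::rnorm(n_residues, 0, noise_sd * csp_peak)
    dx <- 3.6 * (d_comb / sqrt(2) +
                   stats::rnorm(n_residues, 0, noise_sd * csp_peak))
    bound_df <- apo_df
    bound_df$intensity <- pmax(apo_df$intensity * ratio, 0)
    bound_df$shift_h_ppm <- apo_df$shift_h_ppm - dh
    bound_df$shift_x_ppm <- apo_df$shift_x_ppm - dx
    list(apo = peak_list(apo_df, "apo"),
         bound = peak_list(bound_df, "bound"),
         truth = list(site = as.integer(site)))
  })
}

#' Generate a synthetic SEC chromatogram set under a coupled equilibrium
#'
#' Species concentrations follow the activation-gated adaptor equilibrium:
#' the activated fraction `f_act` comes from the peptide-protein binding
#' ([fraction_bound()]), the apparent affinity is
#' `kd_intrinsic / f_act`, and the complex concentration solves the 1:1 mass
#' balance at the planted apparent affinity. Each species (complex, free A,
#' free B) elutes as a Gaussian peak whose integral equals its Beer-Lambert
#' absorbance integral `conc * epsilon * path * injection_volume` (AU*ml);
#' the complex absorbs with `epsilon_a + epsilon_b`. By default the free-A
#' peak lies inside the complex integration window (mimicking a partner
#' that co-elutes with the complex, so apo-profile subtraction cancels its
#' absorbance) and the free-B peak lies well outside it.
#'
#' @param a_total,b_total Total partner concentrations (uM).
#' @param peptide_total Activating-peptide concentration (uM), >= 0.
#' @param kd_activation Peptide-protein dissociation constant (uM).
#' @param kd_intrinsic Intrinsic adaptor affinity of activated A (uM).
#' @param peak_centres Named `c(complex=, a=, b=)` elution centres (ml).
#' @param peak_sigmas Named Gaussian widths (ml), same names.
#' @param epsilons Named `c(a=, b=)` extinction coefficients (M^-1 cm^-1).
#' @param config A [quant_config()] (its `epsilon` is ignored here; optics
#'   and injection volume are used for scaling).
#' @param noise_sd SD of additive Gaussian absorbance noise (AU).
#' @param seed Integer seed.
#' @return List with `mixture`, `apo_a`, `apo_b` ([chromatogram()]s) and
#'   `truth` (complex_conc, kd_app, f_act, window_overlap_b: fraction of the
#'   free-B peak inside the window, flagged when non-negligible).
#' @export
gen_chromatogram_set <- function(a_total, b_total, peptide_total,
                                 kd_activation, kd_intrinsic,
                                 peak_centres = c(complex = 2.6, a = 2.65,
                                                  b = 3.1),
                                 peak_sigmas = c(complex = 0.05, a = 0.05,
                                                 b = 0.05),
                                 epsilons = c(a = 24000, b = 20000),
                                 config = quant_config(epsilon = 20000),
                                 noise_sd = 0, seed = 1) {
  stopifnot(all(c("complex", "a", "b") %in% names(peak_centres)),
            all(c("complex", "a", "b") %in% names(peak_sigmas)),
            all(c("a", "b") %in% names(epsilons)), noise_sd >= 0)
  f_act <- if (peptide_total > 0)
    fraction_bound(a_total, peptide_total, kd_activation) else 0
  if (f_act > 0) {
    kd_app <- kd_intrinsic / f_act
    cplx <- complex_from_kd(a_total, b_total, kd_app)
  } else {
    kd_app <- Inf
    cplx <- 0
  }
  v <- seq(2.0, 4.2, by = 0.002)
  scale_au_ml <- function(conc_um, eps)
    conc_um * 1e-6 * eps * config$path_cm * config$injection_volume_ml
  peak <- function(conc_um, eps, centre, sigma) {
    scale_au_ml(conc_um, eps) / (sigma * sqrt(2 * pi)) *
      exp(-(v - centre)^2 / (2 * sigma^2))
  }
  eps_c <- epsilons["a"] + epsilons["b"]
  withr::with_seed(seed, {
    mix <- peak(cplx, eps_c, peak_centres["complex"],
                peak_sigmas["complex"]) +
      peak(a_total - cplx, epsilons["a"], peak_centres["a"],
           peak_sigmas["a"]) +
      peak(b_total - cplx, epsilons["b"], peak_centres["b"],
           peak_sigmas["b"]) +
      stats::rnorm(length(v), 0, noise_sd)
    apo_a <- peak(a_total, epsilons["a"], peak_centres["a"],
                  peak_sigmas["a"]) + stats::rnorm(length(v), 0, noise_sd)
    apo_b <- peak(b_total, epsilons["b"], peak_centres["b"],
                  peak_sigmas["b"]) + stats::rnorm(length(v), 0, noise_sd)
    overlap_b <- diff(stats::pnorm(config$window, peak_centres["b"],
                                   peak_sigmas["b"]))
    list(mixture = chromatogram(v, mix, "mixture"),
         apo_a = chromatogram(v, apo_a, "apo A"),
         apo_b = chromatogram(v, apo_b, "apo B"),
         truth = list(complex_conc = unname(cplx), kd_app = unname(kd_app),
                      f_act = unname(f_act),
                      window_overlap_b = unname(overlap_b),
                      overlap_flagged = unname(overlap_b > 1e-3)))
  })
}

#' Generate synthetic limited-proteolysis time courses
#'
#' Full-length band decays first-order, `100 * exp(-k_obs * t)`, with the
#' cleaved band as its complement; both bands carry multiplicative Gaussian
#' noise. Ground truth is the half-life `ln(2)/k_obs`.
#'
#' @param k_obs Observed digestion rate(s) (min^-1), >= 0; a named vector
#'   yields one time course per condition.
#' @param times Sampling times (min), default the conventional
#'   0, 5, 10, 20, 30, 60, 90 grid.
#' @param noise_sd SD of multiplicative Gaussian band noise (fractional).
#' @param seed Integer seed.
#' @return For scalar `k_obs`, a [digestion_timecourse()] with attribute
#'   `truth = list(half_life)`; for a vector, a named list of them.
#' @export
gen_proteolysis <- function(k_obs, times = c(0, 5, 10, 20, 30, 60, 90),
                            noise_sd = 0, seed) {
  stopifnot(all(k_obs >= 0), noise_sd >= 0)
  if (length(k_obs) > 1L) {
    nm <- if (is.null(names(k_obs))) paste0("condition", seq_along(k_obs))
          else names(k_obs)
    out <- lapply(seq_along(k_obs), function(i)
      gen_proteolysis(k_obs[[i]], times, noise_sd, seed + i - 1L))
    names(out) <- nm
    return(out)
  }
  withr::with_seed(seed, {
    full <- 100 * exp(-k_obs * times)
    clv <- 100 - full
    full <- pmax(full * (1 + stats::rnorm(length(times), 0, noise_sd)), 0)
    clv <- pmax(clv * (1 + stats::rnorm(length(times), 0, noise_sd)), 0)
    bad <- full + clv <= 0
    full[bad] <- 1e-9
    tc <- digestion_timecourse(times, full, clv,
                               label = sprintf("synthetic k=%g", k_obs))
    attr(tc, "truth") <- list(half_life = if (k_obs > 0) log(2) / k_obs
                              else Inf)
    tc
  })
}

# rejection-sample n points with margin and minimum pairwise separation,
# optionally also separated from an existing set
.place_spots <- function(n, size, margin, min_sep, avoid = NULL) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0L
  while (nrow(pts) < n) {
    tries <- tries + 1L
    if (tries > 20000L)
      stop("could not place puncta: image too crowded for the requested count")
    p <- stats::runif(2, margin, size - 1 - margin)
    ok <- TRUE
    for (set in list(pts, avoid)) {
      if (!is.null(set) && nrow(set) > 0 &&
          min(sqrt((set[, 1] - p[1])^2 + (set[, 2] - p[2])^2)) < min_sep)
        ok <- FALSE
    }
    if (ok) pts <- rbind(pts, p)
  }
  pts
}

# add a Gaussian spot of given amplitude/sigma (px) at 0-based (row, col)
.render_spot <- function(img, row, col, amplitude, sigma_px) {
  w <- ceiling(4 * sigma_px)
  r <- max(0, floor(row) - w):min(nrow(img) - 1, ceiling(row) + w)
  c <- max(0, floor(col) - w):min(ncol(img) - 1, ceiling(col) + w)
  g <- outer(exp(-(r - row)^2 / (2 * sigma_px^2)),
             exp(-(c - col)^2 / (2 * sigma_px^2)))
  img[r + 1, c + 1] <- img[r + 1, c + 1] + amplitude * g
  img
}

#' Generate a synthetic two-channel puncta image
#'
#' The receptor channel carries `n_puncta` Gaussian spots (amplitude 100 AU,
#' PSF width `psf_sigma_um`). The arrestin channel reproduces a
#' `coloc_fraction` subset at identical positions and places the remaining
#' spots independently, away from all receptor spots. Gaussian background
#' noise is set by `snr` (amplitude / noise SD; `Inf` for noiseless).
#'
#' @param n_puncta Number of receptor puncta.
#' @param coloc_fraction Fraction of receptor puncta reproduced in the
#'   arrestin channel, in `[0, 1]`.
#' @param image_size Image side (pixels), square.
#' @param pixel_size_um Pixel edge (um).
#' @param psf_sigma_um Gaussian spot SD (um).
#' @param snr Peak amplitude over background-noise SD; `Inf` disables noise.
#' @param seed Integer seed.
#' @return List with `image` (a [two_channel_image()]) and `truth`: data
#'   frame `puncta` (0-based receptor centres + `colocalized` flag),
#'   `coloc_fraction` actually planted, and `arrestin_extra` centres.
#' @export
gen_coloc_images <- function(n_puncta, coloc_fraction, image_size = 128,
                             pixel_size_um = 0.1, psf_sigma_um = 0.2,
                             snr = 10, seed) {
  stopifnot(n_puncta >= 1, coloc_fraction >= 0, coloc_fraction <= 1,
            snr > 0)
  sigma_px <- psf_sigma_um / pixel_size_um
  amplitude <- 100
  withr::with_seed(seed, {
    margin <- 4 * sigma_px
    min_sep <- 6 * sigma_px
    rec_pts <- .place_spots(n_puncta, image_size, margin, min_sep)
    n_coloc <- round(coloc_fraction * n_puncta)
    coloc_idx <- if (n_coloc > 0) sample.int(n_puncta, n_coloc) else integer()
    n_extra <- n_puncta - n_coloc
    extra_pts <- if (n_extra > 0)
      .place_spots(n_extra, image_size, margin, min_sep, avoid = rec_pts)
    else matrix(numeric(0), ncol = 2)
    rec <- matrix(0, image_size, image_size)
    arr <- matrix(0, image_size, image_size)
    for (i in seq_len(n_puncta))
      rec <- .render_spot(rec, rec_pts[i, 1], rec_pts[i, 2], amplitude,
                          sigma_px)
    for (i in coloc_idx)
      arr <- .render_spot(arr, rec_pts[i, 1], rec_pts[i, 2], amplitude,
                          sigma_px)
    for (i in seq_len(nrow(extra_pts)))
      arr <- .render_spot(arr, extra_pts[i, 1], extra_pts[i, 2], amplitude,
                          sigma_px)
    if (is.finite(snr)) {
      nsd <- amplitude / snr
      rec <- pmax(rec + matrix(stats::rnorm(length(rec), 0, nsd),
                               image_size), 0)
      arr <- pmax(arr + matrix(stats::rnorm(length(arr), 0, nsd),
                               image_size), 0)
    }
    truth_df <- data.frame(row = rec_pts[, 1], col = rec_pts[, 2],
                           colocalized = seq_len(n_puncta) %in% coloc_idx)
    list(image = two_channel_image(channel_image(rec, pixel_size_um),
                                   channel_image(arr, pixel_size_um)),
         truth = list(puncta = truth_df,
                      coloc_fraction = n_coloc / n_puncta,
                      arrestin_extra = extra_pts))
  })
}
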