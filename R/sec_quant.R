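#' Construct a chromatogram
#'
#' An elution trace: strictly increasing elution volumes with the matching
#' 280 nm absorbance readings.
#'
#' @param volumes Elution volumes (ml), strictly increasing, length >= 2.
#' @param absorbance A280 readings (AU), same length, finite.
#' @param label Trace label.
#' @return An object of class `chromatogram` (a data frame with columns
#'   `volume_ml`, `a280_AU`).
#' @export
chromatogram <- function(volumes, absorbance, label = "") {
  if (length(volumes) < 2L) stop("a chromatogram needs >= 2 points")
  if (length(volumes) != length(absorbance))
    stop("'volumes' and 'absorbance' must have the same length")
  if (any(diff(volumes) <= 0)) stop("'volumes' must be strictly increasing")
  if (any(!is.finite(absorbance))) stop("absorbance must be finite")
  structure(data.frame(volume_ml = as.numeric(volumes),
                       a280_AU = as.numeric(absorbance)),
            class = c("chromatogram", "data.frame"),
            label = as.character(label))
}

#' Integrate a chromatogram over an elution window
#'
#' Trapezoidal integral of the absorbance between two elution volumes, with
#' linear interpolation of the trace at the window edges. This is the
#' standard peak-quantification primitive for SEC binding assays (e.g.
#' integrating a complex peak between 2.4 and 2.8 ml).
#'
#' @param chrom A [chromatogram()].
#' @param window Numeric `c(v_lo, v_hi)` in ml, `v_lo < v_hi`; must overlap
#'   the trace's volume range.
#' @return Integral in AU*ml.
#' @export
integrate_window <- function(chrom, window) {
  stopifnot(inherits(chrom, "chromatogram"),
            length(window) == 2L, window[1] < window[2])
  v <- chrom$volume_ml
  a <- chrom$a280_AU
  lo <- max(window[1], v[1])
  hi <- min(window[2], v[length(v)])
  if (lo >= hi)
    stop("no overlap: integration window lies outside the trace's volume range")
  inside <- v > lo & v < hi
  vv <- c(lo, v[inside], hi)
  aa <- c(stats::approx(v, a, xout = lo)$y, a[inside],
          stats::approx(v, a, xout = hi)$y)
  sum(diff(vv) * (utils::head(aa, -1) + utils::tail(aa, -1)) / 2)
}

#' Quantification configuration for SEC complex estimation
#'
#' Optical and injection parameters used to convert an absorbance integral
#' into a concentration via Beer-Lambert.
#'
#' @param epsilon Molar extinction coefficient at 280 nm of the species the
#'   absorbance difference is attributed to (M^-1 cm^-1), > 0.
#' @param path_cm Detector path length (cm), default 1.
#' @param injection_volume_ml Injected sample volume (ml), default 0.25
#'   (a 250 uL sample loop).
#' @param window Integration window `c(v_lo, v_hi)` in ml, default
#'   `c(2.4, 2.8)` around a complex eluting at 2.6 ml.
#' @return An object of class `quant_config`.
#' @export
quant_config <- function(epsilon, path_cm = 1, injection_volume_ml = 0.25,
                         window = c(2.4, 2.8)) {
  stopifnot(epsilon > 0, path_cm > 0, injection_volume_ml > 0,
            length(window) == 2L, window[1] < window[2])
  structure(list(epsilon = epsilon, path_cm = path_cm,
                 injection_volume_ml = injection_volume_ml,
                 window = as.numeric(window)),
            class = "quant_config")
}

#' Complex concentration from mixture and apo reference traces
#'
#' Estimates the concentration of a 1:1 complex in the injected sample by
#' integrating the mixture trace over the complex window, subtracting the
#' integral of the apo reference profile of the co-eluting partner over the
#' same window, and converting the excess absorbance through Beer-Lambert
#' with the extinction coefficient of the other partner (the species whose
#' arrival in the window creates the excess). Peptide absorbance is assumed
#' negligible (no tryptophan).
#'
#' The returned concentration refers to the injected sample:
#' `c = (I_mix - I_apo) / (epsilon * path_cm * injection_volume_ml)`, with
#' the AU*ml integral difference divided by AU*M^-1 (epsilon x path) and the
#' injected ml.
#'
#' @param mixture,apo_reference [chromatogram()] objects covering the window.
#' @param config A [quant_config()].
#' @return Complex concentration (uM), >= 0 (a negative difference is
#'   clamped to zero with a warning). Attribute `integrals` carries the two
#'   window integrals (AU*ml).
#' @export
complex_concentration <- function(mixture, apo_reference, config) {
  stopifnot(inherits(config, "quant_config"))
  i_mix <- integrate_window(mixture, config$window)
  i_apo <- integrate_window(apo_reference, config$window)
  diff_au_ml <- i_mix - i_apo
  if (diff_au_ml < 0) {
    warning("mixture integral below apo reference; complex clamped to 0 uM")
    diff_au_ml <- 0
  }
  conc_M <- diff_au_ml / (config$epsilon * config$path_cm *
                            config$injection_volume_ml)
  structure(conc_M * 1e6,
            integrals = c(mixture = i_mix, apo_reference = i_apo))
}

#' Apparent dissociation constant from measured complex concentration
#'
#' Mass-balance inversion for a 1:1 complex:
#' `kd = (a_total - c)(b_total - c)/c`. The result is "apparent" whenever
#' complex formation is conditional on a cofactor (e.g. an activating
#' phosphopeptide) that is not modelled explicitly.
#'
#' @param complex_conc Measured complex concentration `c` (uM), with
#'   `0 < c < min(a_total, b_total)`.
#' @param a_total,b_total Total partner concentrations (uM).
#' @return Apparent dissociation constant (uM).
#' @export
apparent_kd <- function(complex_conc, a_total, b_total) {
  if (!is.finite(complex_conc) || complex_conc <= 0)
    stop("no complex: measured concentration must be > 0")
  if (complex_conc >= min(a_total, b_total))
    stop("super-stoichiometric: complex exceeds a total concentration")
  (a_total - complex_conc) * (b_total - complex_conc) / complex_conc
}
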