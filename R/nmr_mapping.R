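#' Construct a peak list
#'
#' A peak list holds one sample condition's resolved resonances: per residue
#' and atom group, the 1H shift, the heteronuclear (15N or 13C) shift, and
#' the peak intensity. Keys `(residue_number, atom_group)` must be unique.
#'
#' @param resonances Data frame with columns `residue_number` (integer >= 1),
#'   `residue_type` (one-letter code), `atom_group` (one of
#'   `"backbone_amide"`, `"ile_d1_methyl"`), `shift_h_ppm`, `shift_x_ppm`
#'   (may be `NA` for missing assignments), `intensity` (>= 0).
#' @param condition_label Text describing the sample condition.
#' @return An object of class `peak_list` (a data frame).
#' @export
peak_list <- function(resonances, condition_label = "") {
  need <- c("residue_number", "residue_type", "atom_group",
            "shift_h_ppm", "shift_x_ppm", "intensity")
  if (!all(need %in% names(resonances)))
    stop("missing columns: ", paste(setdiff(need, names(resonances)),
                                    collapse = ", "))
  if (nrow(resonances) == 0L) stop("peak list must be nonempty")
  if (any(resonances$residue_number < 1))
    stop("residue numbers must be >= 1")
  bad <- !resonances$atom_group %in% c("backbone_amide", "ile_d1_methyl")
  if (any(bad)) stop("unknown atom_group: ",
                     paste(unique(resonances$atom_group[bad]), collapse = ", "))
  if (any(resonances$intensity < 0, na.rm = TRUE))
    stop("intensities must be >= 0")
  key <- paste(resonances$residue_number, resonances$atom_group)
  if (anyDuplicated(key))
    stop("duplicate (residue_number, atom_group) keys")
  out <- resonances[need]
  out$residue_number <- as.integer(out$residue_number)
  out <- out[order(out$residue_number, out$atom_group), ]
  rownames(out) <- NULL
  structure(out, class = c("peak_list", "data.frame"),
            condition_label = as.character(condition_label))
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("Peak list '%s': %d resonances\n",
              attr(x, "condition_label"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat("...\n")
  invisible(x)
}

# shared-key join of two peak lists; returns merged df with .apo/.bound cols
.match_peaklists <- function(apo, bound) {
  stopifnot(inherits(apo, "peak_list"), inherits(bound, "peak_list"))
  m <- merge(as.data.frame(apo), as.data.frame(bound),
             by = c("residue_number", "atom_group"),
             suffixes = c(".apo", ".bound"))
  if (nrow(m) == 0L)
    stop("empty overlap: the peak lists share no (residue, atom group) keys")
  m[order(m$residue_number), ]
}

#' Per-residue intensity attenuation I/I0
#'
#' Ratio of each shared resonance's intensity in the complexed sample to its
#' intensity in the apo sample. Interface residues broaden on binding and
#' show ratios well below the bulk. A residue is called significant when its
#' ratio falls more than one sample standard deviation *below* the mean of
#' all ratios (strict inequality, so a zero-variance profile flags nothing).
#'
#' @param apo,bound [peak_list()] objects for the apo and complexed samples.
#' @return An object of class `attenuation_profile`: list with `entries`
#'   (data frame `residue_number`, `atom_group`, `ratio`), `mean`, `sd`
#'   (sample SD), `threshold` (`mean - sd`), `significant` (residue numbers),
#'   and `excluded` (keys present in one list only, or with zero apo
#'   intensity).
#' @export
intensity_ratios <- function(apo, bound) {
  m <- .match_peaklists(apo, bound)
  zero <- !is.na(m$intensity.apo) & m$intensity.apo == 0
  if (any(zero))
    warning(sprintf("%d resonance(s) excluded: zero apo intensity (residues %s)",
                    sum(zero),
                    paste(m$residue_number[zero], collapse = ", ")))
  dropped_keys <- c(
    setdiff(paste(apo$residue_number, apo$atom_group),
            paste(m$residue_number, m$atom_group)),
    setdiff(paste(bound$residue_number, bound$atom_group),
            paste(m$residue_number, m$atom_group)),
    paste(m$residue_number[zero], m$atom_group[zero]))
  m <- m[!zero, ]
  if (nrow(m) == 0L) stop("no usable resonances after exclusions")
  entries <- data.frame(residue_number = m$residue_number,
                        atom_group = m$atom_group,
                        ratio = m$intensity.bound / m$intensity.apo)
  mu <- mean(entries$ratio)
  sdv <- stats::sd(entries$ratio)
  if (is.na(sdv)) sdv <- 0
  thr <- mu - sdv
  structure(list(entries = entries, mean = mu, sd = sdv, threshold = thr,
                 significant = entries$residue_number[entries$ratio < thr],
                 excluded = unique(dropped_keys)),
            class = "attenuation_profile")
}

#' Combined 1H/13C (or 1H/15N) chemical shift perturbation
#'
#' Per shared resonance,
#' \deqn{\Delta\delta_{comb} = \sqrt{\Delta\delta_H^2 + (\Delta\delta_X / w)^2}}
#' with shift differences taken apo minus bound and the heteronuclear
#' difference scaled by `x_weight` (default 3.6, the conventional 13C-methyl
#' weighting that equalizes typical shift dispersions). A residue is
#' significant when its perturbation exceeds the mean of all perturbations
#' by more than one sample standard deviation (strict inequality).
#'
#' @inheritParams intensity_ratios
#' @param x_weight Scaling divisor for the heteronuclear shift difference.
#' @return An object of class `csp_profile`: list with `entries`
#'   (`residue_number`, `atom_group`, `csp`), `mean`, `sd`, `threshold`
#'   (`mean + sd`), `significant`, `excluded`.
#' @export
combined_csp <- function(apo, bound, x_weight = 3.6) {
  stopifnot(is.numeric(x_weight), x_weight > 0)
  m <- .match_peaklists(apo, bound)
  miss <- !is.finite(m$shift_h_ppm.apo) | !is.finite(m$shift_h_ppm.bound) |
    !is.finite(m$shift_x_ppm.apo) | !is.finite(m$shift_x_ppm.bound)
  if (any(miss))
    warning(sprintf("%d resonance(s) excluded: missing shifts", sum(miss)))
  dropped_keys <- c(
    setdiff(paste(apo$residue_number, apo$atom_group),
            paste(m$residue_number, m$atom_group)),
    setdiff(paste(bound$residue_number, bound$atom_group),
            paste(m$residue_number, m$atom_group)),
    paste(m$residue_number[miss], m$atom_group[miss]))
  m <- m[!miss, ]
  if (nrow(m) == 0L) stop("no usable resonances after exclusions")
  dh <- m$shift_h_ppm.apo - m$shift_h_ppm.bound
  dx <- m$shift_x_ppm.apo - m$shift_x_ppm.bound
  entries <- data.frame(residue_number = m$residue_number,
                        atom_group = m$atom_group,
                        csp = sqrt(dh^2 + (dx / x_weight)^2))
  mu <- mean(entries$csp)
  sdv <- stats::sd(entries$csp)
  if (is.na(sdv)) sdv <- 0
  thr <- mu + sdv
  structure(list(entries = entries, mean = mu, sd = sdv, threshold = thr,
                 significant = entries$residue_number[entries$csp > thr],
                 excluded = unique(dropped_keys)),
            class = "csp_profile")
}

#' @export
print.attenuation_profile <- function(x, ...) {
  cat(sprintf("Attenuation profile: %d resonances, mean I/I0 = %.3f, sd = %.3f\n",
              nrow(x$entries), x$mean, x$sd))
  cat(sprintf("Significant (ratio < %.3f): %s\n", x$threshold,
              if (length(x$significant)) paste(x$significant, collapse = ", ")
              else "none"))
  invisible(x)
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf("CSP profile: %d resonances, mean = %.4f ppm, sd = %.4f ppm\n",
              nrow(x$entries), x$mean, x$sd))
  cat(sprintf("Significant (csp > %.4f): %s\n", x$threshold,
              if (length(x$significant)) paste(x$significant, collapse = ", ")
              else "none"))
  invisible(x)
}

#' Segment significant residues into contiguous binding regions
#'
#' Collapses a set of residue numbers into maximal runs, the convention used
#' to report interface stretches (e.g. "374-381"). Two residues belong to
#' the same region when their gap does not exceed `max_gap` intervening
#' residues.
#'
#' @param significant Integer vector of residue numbers (any order,
#'   duplicates ignored).
#' @param max_gap Maximum number of missing residues bridged within one
#'   region (default 0: strictly consecutive).
#' @return Data frame with columns `start_residue`, `end_residue`
#'   (inclusive), sorted ascending; zero rows for an empty input.
#' @export
segment_regions <- function(significant, max_gap = 0L) {
  stopifnot(max_gap >= 0)
  r <- sort(unique(as.integer(significant)))
  if (length(r) == 0L)
    return(data.frame(start_residue = integer(), end_residue = integer()))
  new_run <- c(TRUE, diff(r) > max_gap + 1L)
  grp <- cumsum(new_run)
  data.frame(start_residue = as.integer(tapply(r, grp, min)),
             end_residue = as.integer(tapply(r, grp, max)),
             row.names = NULL)
}

#' Extract a titration series from a ladder of peak lists
#'
#' Follows one resonance across peak lists recorded at increasing ligand
#' concentrations and turns its shift changes into a [titration_series()]
#' ready for [fit_kd()]. Responses are absolute shift differences relative
#' to the zero-ligand list: the heteronuclear shift alone
#' (`metric = "shift_x"`, the usual choice for 13C-methyl titrations) or the
#' combined perturbation of [combined_csp()] (`metric = "combined"`).
#'
#' @param peaklists List of [peak_list()] objects, one per titration point.
#' @param ligand_totals Ligand concentrations (uM), same length; must
#'   include 0.
#' @param residue_number,atom_group Key of the followed resonance.
#' @param protein_total Observed-protein concentration (uM).
#' @param metric `"shift_x"` or `"combined"`.
#' @param x_weight Weighting for `metric = "combined"`.
#' @return A [titration_series()]. Titration points where the key is missing
#'   are dropped with a warning.
#' @export
extract_titration <- function(peaklists, ligand_totals, residue_number,
                              atom_group = "ile_d1_methyl", protein_total,
                              metric = c("shift_x", "combined"),
                              x_weight = 3.6) {
  metric <- match.arg(metric)
  stopifnot(length(peaklists) == length(ligand_totals))
  ord <- order(ligand_totals)
  peaklists <- peaklists[ord]
  ligand_totals <- ligand_totals[ord]
  if (ligand_totals[1] != 0)
    stop("the series must contain a zero-ligand reference list")
  find_key <- function(pl) {
    i <- which(pl$residue_number == residue_number &
                 pl$atom_group == atom_group)
    if (length(i)) pl[i, ] else NULL
  }
  ref <- find_key(peaklists[[1]])
  if (is.null(ref))
    stop(sprintf("key (%d, %s) absent from the zero-ligand list",
                 residue_number, atom_group))
  resp <- vapply(peaklists, function(pl) {
    row <- find_key(pl)
    if (is.null(row)) return(NA_real_)
    if (metric == "shift_x") {
      abs(ref$shift_x_ppm - row$shift_x_ppm)
    } else {
      sqrt((ref$shift_h_ppm - row$shift_h_ppm)^2 +
             ((ref$shift_x_ppm - row$shift_x_ppm) / x_weight)^2)
    }
  }, numeric(1))
  if (anyNA(resp)) {
    warning(sprintf("dropped %d titration point(s): key missing",
                    sum(is.na(resp))))
    keep <- !is.na(resp)
    ligand_totals <- ligand_totals[keep]
    resp <- resp[keep]
  }
  titration_series(ligand_totals, resp, protein_total,
                   label = sprintf("%d/%s", residue_number, atom_group))
}
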