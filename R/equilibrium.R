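#' Fraction of protein bound under ligand depletion
#'
#' Exact solution of the 1:1 mass-action equilibrium P + L <-> PL at total
#' concentrations, i.e. without the free-ligand approximation. The bound
#' fraction of the observed protein is the root of the quadratic
#' \deqn{f = \frac{[L] + [P] + K_D - \sqrt{([L] + [P] + K_D)^2 - 4 [P][L]}}{2 [P]}}
#' where \eqn{[P]} and \eqn{[L]} are *total* protein and ligand
#' concentrations. Ligand depletion matters whenever \eqn{[P]} is comparable
#' to \eqn{K_D}, the regime of weak-affinity NMR titrations.
#'
#' @param protein_total Total concentration of the observed protein (uM), > 0.
#' @param ligand_total Total ligand concentration (uM), >= 0.
#' @param kd Dissociation constant (uM), > 0.
#'   All three arguments are vectorized with the usual recycling.
#' @return Bound fraction(s) in `[0, min(1, ligand_total/protein_total)]`.
#' @examples
#' fraction_bound(50, 250, 45)   # ~0.82: arrestin activation by 5x peptide
#' @export
fraction_bound <- function(protein_total, ligand_total, kd) {
  if (!is.numeric(protein_total) || any(!is.finite(protein_total)) ||
      any(protein_total <= 0))
    stop("invalid parameter: 'protein_total' must be positive")
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0))
    stop("invalid parameter: 'kd' must be positive")
  if (!is.numeric(ligand_total) || any(!is.finite(ligand_total)) ||
      any(ligand_total < 0))
    stop("invalid parameter: 'ligand_total' must be finite and >= 0")
  s <- ligand_total + protein_total + kd
  disc <- s^2 - 4 * protein_total * ligand_total
  # disc >= (P - L)^2 + kd^2 > 0 analytically; clamp tiny negative rounding
  f <- (s - sqrt(pmax(disc, 0))) / (2 * protein_total)
  pmin(pmax(f, 0), 1)
}

#' Predicted titration response for a 1:1 binding isotherm
#'
#' Observed chemical-shift change in fast exchange is the population-weighted
#' average of the apo and bound shifts, so the response is
#' `response_max * fraction_bound(...)`.
#'
#' @inheritParams fraction_bound
#' @param response_max Limiting response at full saturation (ppm).
#' @return Predicted response(s) in the same units as `response_max`.
#' @export
predicted_response <- function(protein_total, ligand_total, kd, response_max) {
  if (!is.numeric(response_max) || any(!is.finite(response_max)))
    stop("invalid parameter: 'response_max' must be finite")
  response_max * fraction_bound(protein_total, ligand_total, kd)
}

#' Construct a titration series
#'
#' A titration series holds ligand-concentration/response pairs at a fixed
#' concentration of the observed protein, ready for [fit_kd()].
#'
#' @param ligand_total Total ligand concentrations (uM), distinct, >= 0.
#' @param response Observed responses (ppm), same length.
#' @param protein_total Total observed-protein concentration (uM), > 0.
#' @param label Identifier for the observed resonance (e.g. `"I377 13C"`).
#' @return An object of class `titration_series`: a data frame with columns
#'   `ligand_total` and `response`, plus `protein_total` and `label`
#'   attributes. Rows are ordered by increasing `ligand_total`.
#' @export
titration_series <- function(ligand_total, response, protein_total,
                             label = "") {
  if (length(ligand_total) != length(response))
    stop("'ligand_total' and 'response' must have the same length")
  if (!is.numeric(protein_total) || protein_total <= 0)
    stop("'protein_total' must be positive")
  if (anyDuplicated(ligand_total))
    stop("'ligand_total' values must be distinct")
  if (any(!is.finite(response)))
    stop("responses must be finite")
  if (any(ligand_total < 0))
    stop("'ligand_total' must be >= 0")
  ord <- order(ligand_total)
  out <- data.frame(ligand_total = as.numeric(ligand_total[ord]),
                    response = as.numeric(response[ord]))
  structure(out, class = c("titration_series", "data.frame"),
            protein_total = as.numeric(protein_total),
            label = as.character(label))
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series '%s': protein_total = %g uM, %d points\n",
              attr(x, "label"), attr(x, "protein_total"), nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Fit a dissociation constant to a titration series
#'
#' Unweighted nonlinear least squares of the 1:1 ligand-depletion isotherm
#' ([predicted_response()]) to the observed responses, by
#' Levenberg-Marquardt. Standard errors come from the linearized covariance
#' at the optimum. `kd` is constrained positive; `response_max` is
#' unconstrained in sign.
#'
#' Default starting values are `kd = median(ligand_total)` and
#' `response_max = 1.2 * max(|response|)`, which are scale-aware and robust
#' for saturable series.
#'
#' @param series A [titration_series()] with at least 3 distinct ligand
#'   concentrations and non-constant responses.
#' @param init Optional numeric vector `c(kd, response_max)` of starting
#'   values.
#' @return An object of class `kd_fit`: a list with elements `kd`,
#'   `kd_stderr`, `response_max`, `response_max_stderr` (all numeric),
#'   `residuals` (observed minus fitted, one per point), `converged`
#'   (logical), and `series`.
#' @examples
#' s <- gen_titration(kd = 104, response_max = 0.05, protein_total = 50,
#'                    ligand_grid = seq(0, 600, length.out = 8),
#'                    noise_sd = 0, seed = 1)
#' fit_kd(s)
#' @export
fit_kd <- function(series, init = NULL) {
  stopifnot(inherits(series, "titration_series"))
  if (nrow(series) < 3L)
    stop("fit requires >= 3 titration points")
  if (diff(range(series$response)) == 0)
    stop("fit-degenerate: all responses are identical")
  p_tot <- attr(series, "protein_total")
  if (is.null(init)) {
    init <- c(kd = stats::median(series$ligand_total),
              response_max = 1.2 * max(abs(series$response)))
    if (init[1] <= 0) init[1] <- 1
  } else {
    init <- c(kd = init[[1]], response_max = init[[2]])
  }
  dat <- data.frame(L = series$ligand_total, y = series$response)
  # kd is optimized on the log scale: positivity without a hard bound, on
  # which Levenberg-Marquardt can otherwise stall with a singular gradient
  start <- list(log_kd = log(init[["kd"]]),
                response_max = init[["response_max"]])
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ response_max * fraction_bound(p_tot, L, exp(log_kd)),
      data = dat, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    res <- list(kd = NA_real_, kd_stderr = NA_real_,
                response_max = NA_real_, response_max_stderr = NA_real_,
                residuals = rep(NA_real_, nrow(series)),
                converged = FALSE, message = conditionMessage(fit),
                series = series)
    class(res) <- "kd_fit"
    return(res)
  }
  cf <- summary(fit)$coefficients
  kd_hat <- exp(unname(cf["log_kd", "Estimate"]))
  # delta method maps the log-scale standard error back to concentration
  res <- list(kd = kd_hat,
              kd_stderr = kd_hat * unname(cf["log_kd", "Std. Error"]),
              response_max = unname(cf["response_max", "Estimate"]),
              response_max_stderr = unname(cf["response_max", "Std. Error"]),
              residuals = as.numeric(stats::residuals(fit)),
              converged = isTRUE(fit$convInfo$isConv),
              series = series)
  class(res) <- "kd_fit"
  res
}

#' @export
print.kd_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) cat("Fit did NOT converge.\n")
  cat(sprintf("K_D = %.4g +- %.2g uM;  response_max = %.4g +- %.2g ppm\n",
              x$kd, x$kd_stderr, x$response_max, x$response_max_stderr))
  invisible(x)
}

#' Coupled activation -> adaptor-binding system
#'
#' Describes an adaptor interaction that is gated by an activation
#' equilibrium: a phosphopeptide activates the observed protein with
#' dissociation constant `kd_activation`, and only the activated protein
#' binds the adaptor with intrinsic constant `kd_intrinsic`.
#'
#' @param kd_activation Peptide-protein dissociation constant (uM).
#' @param kd_intrinsic Adaptor dissociation constant of the activated
#'   protein (uM).
#' @param arrestin_total Total concentration of the activatable protein (uM).
#' @param peptide_total Total activating-peptide concentration (uM), >= 0.
#' @return An object of class `coupled_system`.
#' @export
coupled_system <- function(kd_activation, kd_intrinsic, arrestin_total,
                           peptide_total) {
  vals <- c(kd_activation = kd_activation, kd_intrinsic = kd_intrinsic,
            arrestin_total = arrestin_total)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all concentrations and constants must be positive")
  if (!is.finite(peptide_total) || peptide_total < 0)
    stop("'peptide_total' must be >= 0")
  structure(as.list(c(vals, peptide_total = peptide_total)),
            class = "coupled_system")
}

#' Apparent adaptor affinity under partial activation
#'
#' With only a fraction `f_act` of the protein activated by the peptide, the
#' adaptor affinity measured against *total* protein is diluted:
#' `kd_apparent = kd_intrinsic / f_act`, where `f_act` is the bound fraction
#' of the activation equilibrium under ligand depletion. At saturating
#' peptide the apparent value reduces to the intrinsic one; it diverges as
#' the peptide is withdrawn.
#'
#' This is an explicit modelling choice (activation gating with no
#' peptide-adaptor coupling beyond the activated fraction); it is not claimed
#' to capture avidity or conformational-selection effects.
#'
#' @param system A [coupled_system()].
#' @return Apparent dissociation constant (uM), with the activated fraction
#'   attached as attribute `f_act`.
#' @export
apparent_adaptor_kd <- function(system) {
  stopifnot(inherits(system, "coupled_system"))
  f_act <- fraction_bound(system$arrestin_total, system$peptide_total,
                          system$kd_activation)
  if (f_act <= 0)
    stop("undefined affinity: activated fraction is zero")
  structure(system$kd_intrinsic / f_act, f_act = f_act)
}

#' Equilibrium complex concentration from totals and K_D
#'
#' Forward solver of the 1:1 mass balance: the complex concentration `c`
#' satisfying `(a - c)(b - c)/c = kd`, taken on the physical branch
#' `0 <= c <= min(a, b)`.
#'
#' @param a_total,b_total Total concentrations of the two partners (uM).
#' @param kd Dissociation constant (uM), > 0.
#' @return Complex concentration (uM).
#' @export
complex_from_kd <- function(a_total, b_total, kd) {
  stopifnot(a_total >= 0, b_total >= 0, kd > 0)
  s <- a_total + b_total + kd
  (s - sqrt(s^2 - 4 * a_total * b_total)) / 2
}
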