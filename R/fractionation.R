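#' Delta notation from isotope ratios
#'
#' Per-mil deviation of a sample's isotope ratio from a standard,
#' `delta = 1000 (R_sample / R_standard - 1)`. For oxygen the conventional
#' standard is VSMOW; any positive reference ratio may be supplied.
#'
#' @param R_sample,R_standard positive isotope ratios (heavy over light).
#' @return delta in per mil.
#' @examples
#' delta_from_ratio(1.027, 1) # 27 permil
#' @export
delta_from_ratio <- function(R_sample, R_standard) {
  if (any(R_sample <= 0) || any(R_standard <= 0)) {
    stop("isotope ratios must be positive", call. = FALSE)
  }
  1000 * (R_sample / R_standard - 1)
}

#' Fractionation factor from delta values
#'
#' `alpha_{A/B} = (delta_A + 1000) / (delta_B + 1000)`, the exact algebraic
#' relation between the fractionation factor and per-mil enrichments.
#'
#' @param delta_A,delta_B delta values in per mil; each must exceed -1000.
#' @return the fractionation factor.
#' @examples
#' alpha_from_deltas(27, 0) # 1.027
#' @export
alpha_from_deltas <- function(delta_A, delta_B) {
  if (any(delta_A <= -1000) || any(delta_B <= -1000)) {
    stop("delta values must exceed -1000 permil", call. = FALSE)
  }
  (delta_A + 1000) / (delta_B + 1000)
}

#' Fractionation result
#' @keywords internal
fractionation_result <- function(alpha, stderr_alpha, ratio_A, ratio_B,
                                 stderr_A = 0, stderr_B = 0) {
  structure(
    list(alpha = alpha, delta_permil = 1000 * (alpha - 1),
         stderr_alpha = stderr_alpha,
         ratio_A = ratio_A, stderr_A = stderr_A,
         ratio_B = ratio_B, stderr_B = stderr_B),
    class = "fractionation_result"
  )
}

#' @export
print.fractionation_result <- function(x, ...) {
  cat(sprintf(
    "<fractionation_result> alpha = %.6f +/- %.6f  (delta = %.2f permil)\n",
    x$alpha, x$stderr_alpha, x$delta_permil))
  cat(sprintf("  R_A = %.6f +/- %.6f, R_B = %.6f +/- %.6f\n",
              x$ratio_A, x$stderr_A, x$ratio_B, x$stderr_B))
  invisible(x)
}

#' Fractionation factor from two partition-function ratio estimates
#'
#' `alpha_{A/B} = R_A / R_B` where `R_X = Q_H/Q_L` of substance (or phase)
#' `X`, with first-order propagation of independent uncertainties:
#' `se_alpha = alpha sqrt((se_A/R_A)^2 + (se_B/R_B)^2)`. Accepts
#' `ratio_estimate` objects from [estimate_ratio()], plain numbers, or
#' `list(ratio =, stderr =)` pairs (for printed literature values).
#'
#' @param R_A,R_B ratio estimates for substances A and B.
#' @return a `fractionation_result` with fields `alpha`, `delta_permil`
#'   (`= 1000 (alpha - 1)`), `stderr_alpha` and the input ratios.
#' @examples
#' alpha_from_ratio_estimates(list(ratio = 1.1251, stderr = 0.0007),
#'                            list(ratio = 1.0828, stderr = 0.0024))
#' @export
alpha_from_ratio_estimates <- function(R_A, R_B) {
  coerce <- function(x, nm) {
    if (inherits(x, "ratio_estimate")) {
      list(ratio = x$ratio, stderr = x$stderr)
    } else if (is.numeric(x) && length(x) == 1) {
      list(ratio = x, stderr = 0)
    } else if (is.list(x) && !is.null(x$ratio)) {
      list(ratio = x$ratio, stderr = if (is.null(x$stderr)) 0 else x$stderr)
    } else {
      stop(sprintf("cannot interpret `%s` as a ratio estimate", nm),
           call. = FALSE)
    }
  }
  a <- coerce(R_A, "R_A")
  b <- coerce(R_B, "R_B")
  if (a$ratio <= 0 || b$ratio <= 0) {
    stop("partition-function ratios must be positive", call. = FALSE)
  }
  alpha <- a$ratio / b$ratio
  se <- alpha * sqrt((a$stderr / a$ratio)^2 + (b$stderr / b$ratio)^2)
  fractionation_result(alpha, se, a$ratio, b$ratio, a$stderr, b$stderr)
}

#' Site-specific isotopomer exchange constant
#'
#' For an intramolecular isotope exchange between two sites, the per-site
#' equilibrium constant is the ratio of the two heavy/light
#' partition-function ratios; when one site represents `symmetry_factor`
#' equivalent positions, the total per-mil enhancement is
#' `1000 (K_per_site - 1) * symmetry_factor`.
#'
#' @param ratio_site_A,ratio_site_B positive partition-function ratios for
#'   substitution at sites A and B.
#' @param symmetry_factor number of equivalent positions at site A
#'   (positive integer, default 1).
#' @return list with `per_site` (the exchange constant) and
#'   `enhancement_permil`.
#' @examples
#' exchange_constant(23.72, 19.20, symmetry_factor = 3)
#' @export
exchange_constant <- function(ratio_site_A, ratio_site_B,
                              symmetry_factor = 1L) {
  if (ratio_site_A <= 0 || ratio_site_B <= 0) {
    stop("partition-function ratios must be positive", call. = FALSE)
  }
  if (symmetry_factor < 1 || symmetry_factor != round(symmetry_factor)) {
    stop("`symmetry_factor` must be a positive integer", call. = FALSE)
  }
  per_site <- ratio_site_A / ratio_site_B
  list(per_site = per_site,
       enhancement_permil = 1000 * (per_site - 1) * symmetry_factor)
}
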