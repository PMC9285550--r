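# Reversible probit conversion of prevalence rates.
#
# A prevalence beyond a z-score cut-off maps to a probit z-score
# Z = -sign(z) * qnorm(p); shifting Z by the cut-off distance dz and
# back-transforming predicts the prevalence under the other cut-off.
# With slope multiplier b = 1 the conversion is exactly reversible.

#' Round half away from zero
#'
#' Presentation rounding in the convention used for reported prevalence
#' rates and z-scores (0.955 -> 0.96 at 2 dp), unlike [round()]'s
#' round-half-even. A small epsilon guards against values stored just
#' below the half due to binary representation.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

.check_sign <- function(cutoff_sign) {
  if (!all(cutoff_sign %in% c(-1, 1)))
    stop("'cutoff_sign' must be +1 (overweight/obesity) or -1 (thinness)")
  cutoff_sign
}

#' Probit z-score of a prevalence
#'
#' `Z = -sign(z) * qnorm(p)`: for an upper-tail (overweight/obesity)
#' cut-off a smaller prevalence means a larger Z; for thinness the sign
#' flips. Boundary prevalences 0 and 1 have infinite probits; when the
#' denominator `n` is supplied they are continuity-corrected to `1/(2n)`
#' and `1 - 1/(2n)`, otherwise they raise an error.
#'
#' @param p Prevalence as a proportion in `[0, 1]`.
#' @param cutoff_sign +1 for overweight/obesity, -1 for thinness.
#' @param n Optional denominator count(s) for the continuity correction.
#' @return Probit z-score(s).
#' @examples
#' prevalence_to_Z(0.293, +1)  # 0.54 to 2 dp
#' prevalence_to_Z(0.5, -1)    # 0
#' @export
prevalence_to_Z <- function(p, cutoff_sign = 1, n = NULL) {
  .check_sign(cutoff_sign)
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("'p' must be a proportion in [0, 1]")
  at_bound <- p <= 0 | p >= 1
  if (any(at_bound)) {
    if (is.null(n))
      stop("prevalence 0 or 1 needs a denominator 'n' for the continuity correction")
    n <- rep_len(n, length(p))
    if (any(!is.finite(n[at_bound]) | n[at_bound] < 1))
      stop("denominator 'n' must be >= 1")
    p <- ifelse(p <= 0, 1 / (2 * n), ifelse(p >= 1, 1 - 1 / (2 * n), p))
  }
  -cutoff_sign * stats::qnorm(p)
}

#' Prevalence implied by a probit z-score
#'
#' `p = pnorm(-sign(z) * Z)`; the exact inverse of [prevalence_to_Z()].
#'
#' @param Z Probit z-score(s), finite.
#' @inheritParams prevalence_to_Z
#' @return Prevalence(s) as proportions.
#' @examples
#' Z_to_prevalence(1, +1)     # 0.1587 -- the nominal WHO +1 prevalence
#' Z_to_prevalence(1.04, +1)  # 0.1492 -- the nominal CDC 85 prevalence
#' @export
Z_to_prevalence <- function(Z, cutoff_sign = 1) {
  .check_sign(cutoff_sign)
  if (any(!is.finite(Z))) stop("'Z' must be finite")
  stats::pnorm(-cutoff_sign * Z)
}

#' Bias-adjustment slope preset
#'
#' The slope multiplier that compensates for target BMI distributions
#' with heavier tails than the references, obtained as the equal-weight
#' mean of per-source, per-category validation slopes. Use as
#' `convert_prevalence(..., b = bias_adjusted_b)`.
#' @export
bias_adjusted_b <- 0.84

#' Convert a prevalence between two cut-offs
#'
#' Transforms the input prevalence to its probit `Z_in`, shifts by
#' `b * dz` and back-transforms: `p_out = pnorm(-sign * (Z_in + b*dz))`.
#' The reverse conversion uses `-dz`; with `b = 1` forward then reverse
#' returns the input exactly. Conversions are only defined within a
#' category, so the cut-off signs must match.
#'
#' @param p_in Observed prevalence (proportion). For the overweight
#'   category it must include obesity; see
#'   [overweight_including_obesity()].
#' @param dz Cut-off distance from input to output cut-off (from
#'   [cutoff_distance()] or [lookup_dz()]); negate it for the reverse
#'   direction.
#' @param sign_in,sign_out Cut-off signs (+1 overweight/obesity,
#'   -1 thinness); must be equal.
#' @param b Slope multiplier on `dz`; 1 for the plain algorithm,
#'   [bias_adjusted_b] (0.84) for the bias-adjusted preset.
#' @param n Optional denominator for boundary continuity correction.
#' @return An object of class `prevalence_conversion` with fields
#'   `p_in`, `p_out`, `Z_in`, `Z_out`, `dz`, `b`.
#' @examples
#' # overweight prevalence 29.3% under one cut-off, distance 0.435 to a
#' # higher cut-off:
#' convert_prevalence(0.293, dz = 0.435)  # 16.4%
#' @export
convert_prevalence <- function(p_in, dz, sign_in = 1, sign_out = sign_in,
                               b = 1, n = NULL) {
  .check_sign(c(sign_in, sign_out))
  if (sign_in != sign_out)
    stop("cannot convert across categories: cut-off signs differ")
  if (!is.finite(dz)) stop("'dz' must be finite")
  if (!is.numeric(b) || b <= 0) stop("'b' must be positive")
  Z_in <- prevalence_to_Z(p_in, sign_in, n = n)
  Z_out <- Z_in + b * dz
  structure(list(p_in = p_in, p_out = Z_to_prevalence(Z_out, sign_out),
                 Z_in = Z_in, Z_out = Z_out, dz = dz, b = b,
                 sign = sign_in),
            class = "prevalence_conversion")
}

#' @export
print.prevalence_conversion <- function(x, ...) {
  cat(sprintf("<prevalence_conversion> %s cut-off (b = %g)\n",
              if (x$sign > 0) "upper-tail" else "lower-tail", x$b))
  cat(sprintf("  p_in  = %.1f%%  (Z_in  = %.2f)\n",
              round_half_up(100 * x$p_in, 1), round_half_up(x$Z_in, 2)))
  cat(sprintf("  dz    = %+.3f\n", x$dz))
  cat(sprintf("  p_out = %.1f%%  (Z_out = %.2f)\n",
              round_half_up(100 * x$p_out, 1), round_half_up(x$Z_out, 2)))
  invisible(x)
}

#' Overweight prevalence inclusive of obesity
#'
#' Cut-offs define tail areas, so the conversion requires overweight
#' prevalence to count every child above the overweight cut-off,
#' including the obese. Adds obesity prevalence to net-of-obesity
#' overweight prevalence.
#'
#' @param p_ow_net Overweight prevalence net of obesity (proportion).
#' @param p_ob Obesity prevalence (proportion).
#' @return Inclusive overweight prevalence.
#' @export
overweight_including_obesity <- function(p_ow_net, p_ob) {
  if (any(p_ow_net < 0) || any(p_ob < 0))
    stop("prevalences must be non-negative")
  total <- p_ow_net + p_ob
  if (any(total > 1 + 1e-9))
    stop("overweight + obesity prevalence exceeds 1")
  pmin(total, 1)
}
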