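#' Prescribed input/output density response
#'
#' The design goal is expressed as a target steady-state density as a
#' function of the inducer dose,
#' `N_ref(I) = base + amplitude / (1 + scale * I^exponent)`: the population
#' sits at `base + amplitude` with no inducer and is driven down towards
#' `base` at saturating inducer. The default parameters
#' (`base = 0.1`, `amplitude = 0.6`, `scale = 2`, `exponent = 2`) prescribe
#' 0.5 O.D. at 0.5 nM and 0.3 O.D. at 1 nM of inducer.
#'
#' @param base Density floor at saturating inducer (O.D. 600, >= 0).
#' @param amplitude Density span above the floor (O.D. 600, >= 0).
#' @param scale Coefficient on `I^exponent` (nM^-exponent, > 0).
#' @param exponent Power on the inducer concentration (> 0).
#' @return An object of class `reference_response`.
#' @examples
#' ref <- reference_response()
#' reference_density(ref, c(0.5, 1))  # 0.5, 0.3
#' @export
reference_response <- function(base = 0.1, amplitude = 0.6, scale = 2,
                               exponent = 2) {
  check_number(base, "base", lower = 0)
  check_number(amplitude, "amplitude", lower = 0)
  check_number(scale, "scale", lower = 0, strict = TRUE)
  check_number(exponent, "exponent", lower = 0, strict = TRUE)
  structure(list(base = base, amplitude = amplitude, scale = scale,
                 exponent = exponent),
            class = "reference_response")
}

#' @export
print.reference_response <- function(x, ...) {
  cat(sprintf("<reference_response> N_ref(I) = %g + %g / (1 + %g * I^%g)\n",
              x$base, x$amplitude, x$scale, x$exponent))
  invisible(x)
}

#' @rdname reference_response
#' @param ref A `reference_response`.
#' @param I Inducer concentration(s) (nM, >= 0); vectorized.
#' @export
reference_density <- function(ref, I) {
  stopifnot(inherits(ref, "reference_response"))
  check_nonneg_vec(I, "I")
  ref$base + ref$amplitude / (1 + ref$scale * I^ref$exponent)
}

#' Recommend an inducer dose for a target density
#'
#' Inverts the prescribed response in closed form:
#' `I = ((amplitude / (target - base) - 1) / scale)^(1/exponent)`. The
#' target must lie within the densities attainable on `I_range`,
#' `[N_ref(I_max), N_ref(I_min)]`; outside it, the error reports the
#' attainable interval.
#'
#' @param ref A [reference_response()].
#' @param target Desired steady-state density (O.D. 600).
#' @param I_range Feasible inducer range `c(I_min, I_max)` (nM).
#' @return The inducer concentration (nM) at which `N_ref` equals `target`.
#' @examples
#' recommend_inducer(reference_response(), target = 0.5)  # 0.5 nM
#' recommend_inducer(reference_response(), target = 0.3)  # 1 nM
#' @export
recommend_inducer <- function(ref, target, I_range = c(0.1, 10)) {
  stopifnot(inherits(ref, "reference_response"))
  check_number(target, "target")
  if (length(I_range) != 2L || I_range[1] <= 0 || I_range[2] <= I_range[1])
    abort("`I_range` must be an increasing positive range.")
  attainable <- rev(reference_density(ref, I_range))  # response is decreasing
  if (target < attainable[1] || target > attainable[2])
    stop_numeric(sprintf(
      "target density %g is outside the attainable interval [%.6g, %.6g] on I in [%g, %g] nM.",
      target, attainable[1], attainable[2], I_range[1], I_range[2]))
  ((ref$amplitude / (target - ref$base) - 1) / ref$scale)^(1 / ref$exponent)
}

#' Percentage tracking error of an observed density
#'
#' Relative deviation of an observed steady-state density from the desired
#' density, in percent: `100 |observed - desired| / desired`. Used to score
#' how closely a built circuit realizes the prescribed response at a given
#' inducer dose.
#'
#' @param observed Measured density (O.D. 600).
#' @param desired Prescribed density (O.D. 600, > 0).
#' @return Percentage error, vectorized.
#' @examples
#' percent_error(0.487, 0.5)  # 2.6
#' @export
percent_error <- function(observed, desired) {
  check_nonneg_vec(observed, "observed")
  if (any(desired <= 0)) abort("`desired` must be > 0.")
  100 * abs(observed - desired) / desired
}
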