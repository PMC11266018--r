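#' Complex-valued time series
#'
#' A `complex_series` stores one complex-valued signal as a pair of aligned
#' real vectors: a magnitude channel and a phase channel. The two channels
#' are analysed jointly by the complex-valued transfer entropy estimators,
#' but each is treated as an ordinary real-valued series, so any pair of
#' aligned real series (for example an envelope and an instantaneous phase,
#' or two arbitrary covariates) can be wrapped in a `complex_series`.
#'
#' Magnitude data from complex-valued images are non-negative by
#' construction; simulated benchmark signals, however, drive the magnitude
#' channel with autoregressive series that take both signs, so negativity
#' is permitted and only flagged via the `nonneg` attribute.
#'
#' @param magnitude Real numeric vector, the magnitude channel.
#' @param phase Real numeric vector of the same length, the phase channel
#'   (radians for genuine phases; any real-valued series is accepted).
#' @return An object of class `complex_series` with fields `magnitude`,
#'   `phase` and `n` (number of time points).
#' @examples
#' z <- complex_series(abs(rnorm(50)), runif(50, -pi, pi))
#' z
#' @seealso [decompose_complex()] to build one from real/imaginary parts.
#' @export
complex_series <- function(magnitude, phase) {
  magnitude <- as.numeric(magnitude)
  phase <- as.numeric(phase)
  if (length(magnitude) != length(phase))
    stop("magnitude and phase must have the same length", call. = FALSE)
  if (length(magnitude) < 1L)
    stop("a complex_series needs at least 1 time point", call. = FALSE)
  if (anyNA(magnitude) || anyNA(phase) ||
      any(!is.finite(magnitude)) || any(!is.finite(phase)))
    stop("magnitude and phase must be finite and non-missing", call. = FALSE)
  structure(
    list(magnitude = magnitude, phase = phase, n = length(magnitude)),
    nonneg = all(magnitude >= 0),
    class = "complex_series"
  )
}

#' @export
print.complex_series <- function(x, ...) {
  cat("<complex_series> ", x$n, " time points\n", sep = "")
  cat("  magnitude: [", format(min(x$magnitude), digits = 4), ", ",
      format(max(x$magnitude), digits = 4), "]\n", sep = "")
  cat("  phase:     [", format(min(x$phase), digits = 4), ", ",
      format(max(x$phase), digits = 4), "]\n", sep = "")
  invisible(x)
}

#' @export
length.complex_series <- function(x) x$n

#' @export
as.complex.complex_series <- function(x, ...) x$magnitude * exp(1i * x$phase)

#' Decompose a complex signal into magnitude and phase
#'
#' Converts a signal given as real and imaginary parts into its polar
#' representation: elementwise modulus and argument. The argument is
#' returned in (-pi, pi]; samples with zero modulus have no defined
#' argument and get phase 0 with a warning.
#'
#' @param real_part,imag_part Real numeric vectors of equal length.
#' @return A [complex_series()].
#' @examples
#' decompose_complex(c(1, 0), c(0, 1))  # magnitudes 1, phases 0 and pi/2
#' @export
decompose_complex <- function(real_part, imag_part) {
  if (length(real_part) != length(imag_part))
    stop("real_part and imag_part must have the same length", call. = FALSE)
  if (anyNA(real_part) || anyNA(imag_part) ||
      any(!is.finite(real_part)) || any(!is.finite(imag_part)))
    stop("inputs must be finite and non-missing", call. = FALSE)
  z <- complex(real = real_part, imaginary = imag_part)
  mag <- Mod(z)
  ph <- Arg(z)
  zero <- mag == 0
  if (any(zero)) {
    warning(sum(zero), " zero-modulus sample(s); phase set to 0")
    ph[zero] <- 0
  }
  # Arg() returns values in (-pi, pi] already; -pi can appear through
  # signed-zero imaginary parts, fold it onto pi.
  ph[ph == -pi] <- pi
  complex_series(mag, ph)
}
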