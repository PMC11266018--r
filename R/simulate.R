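#' Simulated complex-valued signal pairs with known causal direction
#'
#' Generates one pair of complex-valued signals from one of six benchmark
#' families built on a stable AR(2) driver (coefficients 0.952, -0.9025;
#' complex roots of modulus 0.95). In every family the source magnitude
#' drives the target magnitude with a one-sample delay; families differ
#' in how the phase channels are formed:
#' \describe{
#'   \item{L1}{linear coupling `b(t) = 0.5 a(t-1) + w2`; phases derived
#'     from the source magnitude (`theta = 0.95 a(t) - 0.9025 a(t-2) + w1`,
#'     `phi = -0.6 a(t) + w2`), giving full magnitude/phase causality.}
#'   \item{L2}{linear magnitude coupling; phases form their own AR pair
#'     with linear coupling (`phi = -0.6 theta + w4`), so only
#'     within-channel causality exists.}
#'   \item{L3}{linear magnitude coupling; phases are independent white
#'     noise (no phase causality).}
#'   \item{N1,N2,N3}{as L1-L3 with non-linear coupling: quadratic in the
#'     magnitude channel (`b(t) = 0.5 a^2(t-1) + w2`) and cubic in the
#'     phase couplings.}
#' }
#' Innovations are i.i.d. standard normal. In L1/N1 the phase equations
#' reuse the same innovation realizations as the magnitude equations,
#' which is what links magnitude and phase across the two signals. The
#' recursions start from zero initial conditions and a burn-in period is
#' discarded so each returned series has length exactly `T`. The ground
#' truth direction for the pair is z1 -> z2 in every family.
#'
#' The generated phase channels are unbounded real series (they are not
#' wrapped into (-pi, pi]); the estimators accept any real-valued series
#' as phase.
#'
#' @param family One of `"L1"`, `"L2"`, `"L3"`, `"N1"`, `"N2"`, `"N3"`.
#' @param T Number of retained time points (default 146).
#' @param seed Optional integer seed.
#' @param burn_in Number of initial samples discarded (default 100).
#' @return An object of class `simulated_pair`: list with `z1`, `z2`
#'   ([complex_series()]), `family`, `T`, `seed` and `truth`, a list of
#'   per-channel ground-truth direction labels (`magnitude`, `phase`,
#'   `cross`; each `"forward"` or `"none"`).
#' @examples
#' p <- simulate_cpair("N1", seed = 1)
#' p$truth
#' @export
simulate_cpair <- function(family = c("L1", "L2", "L3", "N1", "N2", "N3"),
                           T = 146L, seed = NULL, burn_in = 100L) {
  family <- match.arg(family)
  T <- as.integer(T)
  if (T < 10L) stop("T must be >= 10", call. = FALSE)
  .with_seed(seed, {
    N <- T + as.integer(burn_in)
    w1 <- stats::rnorm(N)
    w2 <- stats::rnorm(N)
    a <- numeric(N)
    b <- numeric(N)
    nonlin <- family %in% c("N1", "N2", "N3")
    for (t in 3:N) {
      a[t] <- 0.952 * a[t - 1] - 0.9025 * a[t - 2] + w1[t]
      b[t] <- if (nonlin) 0.5 * a[t - 1]^2 + w2[t]
              else 0.5 * a[t - 1] + w2[t]
    }
    if (family %in% c("L1", "N1")) {
      th <- numeric(N)
      for (t in 3:N) th[t] <- 0.95 * a[t] - 0.9025 * a[t - 2] + w1[t]
      ph <- if (nonlin) -0.6 * a^3 + w2 else -0.6 * a + w2
    } else if (family %in% c("L2", "N2")) {
      w3 <- stats::rnorm(N)
      w4 <- stats::rnorm(N)
      th <- numeric(N)
      for (t in 3:N) th[t] <- 0.95 * th[t - 1] - 0.9025 * th[t - 2] + w3[t]
      ph <- if (nonlin) -0.6 * th^3 + w4 else -0.6 * th + w4
    } else {  # L3 / N3: causality-free random phases
      th <- stats::rnorm(N)
      ph <- stats::rnorm(N)
    }
    keep <- (N - T + 1L):N
    truth <- list(
      magnitude = "forward",
      phase = if (family %in% c("L3", "N3")) "none" else "forward",
      cross = if (family %in% c("L1", "N1")) "forward" else "none"
    )
    structure(list(z1 = complex_series(a[keep], th[keep]),
                   z2 = complex_series(b[keep], ph[keep]),
                   family = family, T = T, seed = seed, truth = truth),
              class = "simulated_pair")
  })
}

#' @export
print.simulated_pair <- function(x, ...) {
  cat("<simulated_pair> family", x$family, "-", x$T, "time points\n")
  cat("  truth: magnitude", x$truth$magnitude, "| phase", x$truth$phase,
      "| cross", x$truth$cross, "\n")
  invisible(x)
}

#' Add Gaussian noise at a target signal-to-noise ratio
#'
#' Adds independent zero-mean Gaussian noise to each of the four
#' component series of a simulated pair (both magnitudes and both
#' phases), with the per-series noise variance chosen so that
#' `10 log10(var(series) / var(noise)) = snr_db`. Alternatively
#' (`mode = "complex"`) noise is added to the real and imaginary parts of
#' the assembled complex signals and the pair is re-decomposed.
#'
#' Magnitude channels that were non-negative before noise injection are
#' clipped at zero afterwards (with a warning reporting the count), since
#' a negative modulus is not meaningful; signed magnitude channels (as
#' produced by the simulators) are left unclipped.
#'
#' @param pair A [simulate_cpair()] result (or any list with `z1`, `z2`).
#' @param snr_db Target signal-to-noise ratio in decibels.
#' @param seed Optional integer seed.
#' @param mode `"per_series"` (default) or `"complex"`.
#' @return The pair with noisy `z1`, `z2` and an `snr_db` field.
#' @export
add_noise <- function(pair, snr_db, seed = NULL,
                      mode = c("per_series", "complex")) {
  mode <- match.arg(mode)
  stopifnot(is.finite(snr_db))
  .with_seed(seed, {
    noisify <- function(x) {
      v <- stats::var(x)
      if (v == 0) return(x)
      x + stats::rnorm(length(x), sd = sqrt(v / 10^(snr_db / 10)))
    }
    if (mode == "per_series") {
      clip <- function(x, was_nonneg) {
        if (!was_nonneg || all(x >= 0)) return(x)
        nneg <- sum(x < 0)
        warning(nneg, " negative magnitude sample(s) clipped at 0")
        pmax(x, 0)
      }
      m1 <- clip(noisify(pair$z1$magnitude), attr(pair$z1, "nonneg"))
      m2 <- clip(noisify(pair$z2$magnitude), attr(pair$z2, "nonneg"))
      pair$z1 <- complex_series(m1, noisify(pair$z1$phase))
      pair$z2 <- complex_series(m2, noisify(pair$z2$phase))
    } else {
      redo <- function(z) {
        zc <- as.complex(z)
        decompose_complex(noisify(Re(zc)), noisify(Im(zc)))
      }
      pair$z1 <- redo(pair$z1)
      pair$z2 <- redo(pair$z2)
    }
    pair$snr_db <- snr_db
    pair
  })
}

#' Accuracy of causality verdicts
#'
#' Fraction of verdicts equal to the ground-truth direction. A `"none"`
#' verdict counts as incorrect whenever the truth names a direction.
#'
#' @param verdicts Character vector of `"forward"`, `"reverse"`, `"none"`.
#' @param truth Single ground-truth label.
#' @return Proportion correct in `[0, 1]`.
#' @examples
#' aoc(c("forward", "reverse", "none", "forward"), "forward")  # 0.5
#' @export
aoc <- function(verdicts, truth) {
  if (length(verdicts) == 0L)
    stop("verdicts must be non-empty", call. = FALSE)
  mean(verdicts == truth)
}
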