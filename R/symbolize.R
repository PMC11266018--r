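#' Four-level symbolic encoding of a real-valued series
#'
#' Maps every sample to one of four integer codes, using thresholds placed
#' at the mean of the positive samples (`mu_p`) and at `(1 +/- beta) *
#' mu_p`; negative samples are coded with the mirrored rule around the
#' mean of the negative samples (`mu_n`). The encoding is invariant to
#' multiplication by a positive constant, which gives the downstream
#' symbolic estimators robustness to amplitude scaling and (relative to
#' raw-value histograms) to additive noise.
#'
#' For a non-negative sample x with thresholds around `mu_p`:
#' code 1 if x > (1+beta) mu_p, code 0 if mu_p < x <= (1+beta) mu_p,
#' code 2 if (1-beta) mu_p < x <= mu_p, code 3 if 0 <= x <= (1-beta) mu_p.
#' Negative samples use the analogous four bands around `mu_n` (note
#' `(1+beta) mu_n < mu_n < (1-beta) mu_n < 0`).
#'
#' @param x Finite numeric vector.
#' @param beta Band-width control parameter in (0, 1), default 0.05.
#' @return An integer vector of codes in `{0,1,2,3}` of class
#'   `symbol_series`, with attributes `beta`, `mu_p` and `mu_n` (the
#'   latter `NA` when no sample of that sign exists).
#' @examples
#' symbolize(c(10, 2, 6, 4))      # codes 1 3 1 3
#' symbolize(c(5, 5, 5, 5))       # constant series: all code 2
#' @export
symbolize <- function(x, beta = 0.05) {
  if (anyNA(x) || any(!is.finite(x)))
    stop("x must be finite and non-missing", call. = FALSE)
  if (beta <= 0 || beta >= 1)
    stop("beta must be in (0, 1)", call. = FALSE)
  codes <- .symbolize_codes(x, beta, warn = TRUE)
  structure(codes,
            beta = beta,
            mu_p = if (any(x > 0)) mean(x[x > 0]) else NA_real_,
            mu_n = if (any(x < 0)) mean(x[x < 0]) else NA_real_,
            class = "symbol_series")
}

# bare-integer kernel shared with the fast causality path
.symbolize_codes <- function(x, beta = 0.05, warn = FALSE) {
  out <- integer(length(x))
  nonneg <- x >= 0
  if (any(nonneg)) {
    if (any(x > 0)) {
      mp <- mean(x[x > 0])
      xp <- x[nonneg]
      cp <- integer(length(xp))
      cp[xp > (1 + beta) * mp] <- 1L
      sel <- xp > mp & xp <= (1 + beta) * mp
      cp[sel] <- 0L
      sel <- xp > (1 - beta) * mp & xp <= mp
      cp[sel] <- 2L
      cp[xp <= (1 - beta) * mp] <- 3L
      out[nonneg] <- cp
    } else {
      # only zeros on the non-negative side: mu_p undefined, lowest band
      if (warn) warning("no positive samples; non-negative samples coded 3")
      out[nonneg] <- 3L
    }
  }
  if (any(!nonneg)) {
    mn <- mean(x[x < 0])
    xn <- x[!nonneg]
    cn <- integer(length(xn))
    cn[xn < (1 + beta) * mn] <- 1L
    sel <- xn >= (1 + beta) * mn & xn < mn
    cn[sel] <- 0L
    sel <- xn >= mn & xn < (1 - beta) * mn
    cn[sel] <- 2L
    cn[xn >= (1 - beta) * mn] <- 3L
    out[!nonneg] <- cn
  }
  out
}

#' @export
print.symbol_series <- function(x, ...) {
  cat("<symbol_series> ", length(x), " codes (beta = ",
      attr(x, "beta"), ")\n", sep = "")
  print(as.integer(x))
  invisible(x)
}

#' Histogram binning with data-length-determined width
#'
#' Assigns every sample of `x` to an integer bin of width
#' `(max - min) / T`, where the range is taken jointly over `x` and
#' `y_context` and `T` is the series length. This is the bin rule used by
#' the raw-value (histogram) transfer entropy; symbolic estimators do not
#' bin. The last bin is closed so the maximum falls in bin `T - 1`.
#'
#' @param x Numeric vector to bin.
#' @param y_context Numeric vector whose range is pooled with `x` when
#'   computing the bin width (defaults to `x` itself).
#' @return Integer vector of 0-based bin indices in `0..T-1`.
#' @examples
#' bin_raw(c(0, 1), c(0, 1))   # bins 0 and 1 (width 0.5)
#' @export
bin_raw <- function(x, y_context = x) {
  n <- length(x)
  if (n < 2L) stop("need at least 2 samples", call. = FALSE)
  lo <- min(x, y_context)
  hi <- max(x, y_context)
  if (hi == lo) return(integer(n))
  width <- (hi - lo) / n
  pmin(as.integer(floor((x - lo) / width)), n - 1L)
}
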