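#' Direction-inference accuracy benchmark on simulated pairs
#'
#' Runs the full significance pipeline over freshly simulated pairs for
#' every combination of method, signal family, noise level and data
#' length, scoring each pair's verdict against the z1 -> z2 ground truth
#' and reporting group-wise accuracies (the pairs are split into
#' `n_groups` equal groups, giving a mean and standard deviation per
#' condition).
#'
#' @param methods Character vector of estimators: any of `"cte"`,
#'   `"scte"`, `"cte_direct"`, `"ste"`, `"hte"`, `"granger"`.
#' @param families Character vector of signal families (see
#'   [simulate_cpair()]).
#' @param n_pairs Pairs per condition (default 1000); must be divisible
#'   by `n_groups`.
#' @param n_groups Number of accuracy groups (default 10).
#' @param snr_db Optional numeric vector of noise levels in dB; `NULL`
#'   (default) runs noiseless.
#' @param T Data length(s); may be a vector for a data-length sweep.
#' @param R Shuffle repetitions per pair.
#' @param seed Master seed; the entire benchmark is reproducible from it.
#' @param p_th Verdict significance threshold.
#' @param beta Symbolization parameter.
#' @param max_lag Delay scan range.
#' @param sign_only If `TRUE`, skip the surrogate test and score the raw
#'   sign of `C(1->2) - C(2->1)` (not available for `"granger"`).
#' @return A data frame of class `cvte_benchmark` with columns `method`,
#'   `family`, `snr_db`, `T`, `group`, `accuracy`.
#' @seealso [summary.cvte_benchmark()] for a table of mean +/- sd,
#'   [plot.cvte_benchmark()] for accuracy-vs-SNR curves.
#' @examples
#' \donttest{
#' b <- run_benchmark("cte", "L1", n_pairs = 20, n_groups = 2,
#'                    R = 25, seed = 1)
#' summary(b)
#' }
#' @export
run_benchmark <- function(methods, families, n_pairs = 1000L,
                          n_groups = 10L, snr_db = NULL, T = 146L,
                          R = 100L, seed = 1L, p_th = 0.05, beta = 0.05,
                          max_lag = 10L, sign_only = FALSE) {
  methods <- match.arg(methods,
                       c("cte", "scte", "cte_direct", "ste", "hte",
                         "granger"), several.ok = TRUE)
  families <- match.arg(families,
                        c("L1", "L2", "L3", "N1", "N2", "N3"),
                        several.ok = TRUE)
  n_pairs <- as.integer(n_pairs)
  n_groups <- as.integer(n_groups)
  if (n_pairs %% n_groups != 0L)
    stop("n_pairs must be divisible by n_groups", call. = FALSE)
  snr_grid <- if (is.null(snr_db)) NA_real_ else as.numeric(snr_db)
  grid <- expand.grid(method = methods, family = families,
                      snr_db = snr_grid, T = as.integer(T),
                      stringsAsFactors = FALSE)
  per_group <- n_pairs %/% n_groups

  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cond <- grid[g, ]
    # one deterministic sub-seed per condition, derived from the master
    cond_seed <- (as.integer(seed) + 7919L * g) %% .Machine$integer.max
    verdicts <- .with_seed(cond_seed, {
      vapply(seq_len(n_pairs), function(i) {
        p <- simulate_cpair(cond$family, T = cond$T)
        if (!is.na(cond$snr_db)) p <- add_noise(p, cond$snr_db)
        if (sign_only && cond$method != "granger") {
          est <- switch(cond$method,
                        cte = cte, scte = scte, cte_direct = cte_direct,
                        ste = ste, hte = hte)
          d <- as.numeric(est(p$z1, p$z2, beta = beta,
                              max_lag = max_lag)) -
               as.numeric(est(p$z2, p$z1, beta = beta, max_lag = max_lag))
          if (d > 0) "forward" else if (d < 0) "reverse" else "none"
        } else {
          causality(p$z1, p$z2, estimator = cond$method, R = R,
                    p_th = p_th, beta = beta, max_lag = max_lag)$direction
        }
      }, character(1))
    })
    acc <- vapply(seq_len(n_groups), function(k) {
      idx <- ((k - 1L) * per_group + 1L):(k * per_group)
      aoc(verdicts[idx], "forward")
    }, numeric(1))
    rows[[g]] <- data.frame(method = cond$method, family = cond$family,
                            snr_db = cond$snr_db, T = cond$T,
                            group = seq_len(n_groups), accuracy = acc,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(n_pairs = n_pairs, n_groups = n_groups,
                              R = R, seed = seed, p_th = p_th,
                              beta = beta, max_lag = max_lag,
                              sign_only = sign_only)
  class(out) <- c("cvte_benchmark", "data.frame")
  out
}

#' Summarise a benchmark as mean and sd accuracy per condition
#'
#' @param object A [run_benchmark()] result.
#' @param ... Unused.
#' @return Data frame with one row per (method, family, snr_db, T) and
#'   columns `mean_accuracy`, `sd_accuracy` (in percent).
#' @export
summary.cvte_benchmark <- function(object, ...) {
  key <- paste(object$method, object$family, object$snr_db, object$T)
  agg <- lapply(split(as.data.frame(object), key), function(d) {
    data.frame(method = d$method[1], family = d$family[1],
               snr_db = d$snr_db[1], T = d$T[1],
               mean_accuracy = 100 * mean(d$accuracy),
               sd_accuracy = 100 * stats::sd(d$accuracy),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  out[order(out$family, out$method, out$snr_db, out$T), ]
}

#' @export
print.cvte_benchmark <- function(x, ...) {
  s <- summary(x)
  cat("<cvte_benchmark> accuracy of direction inference (% , mean +/- sd)\n")
  s$accuracy <- sprintf("%.1f +/- %.1f", s$mean_accuracy, s$sd_accuracy)
  print(s[, c("method", "family", "snr_db", "T", "accuracy")],
        row.names = FALSE)
  invisible(x)
}

#' Plot benchmark accuracy against noise level or data length
#'
#' Draws one line per method; panels are not used, so restrict the
#' benchmark (or subset the data frame) to a single family first.
#'
#' @param x A `cvte_benchmark`.
#' @param against `"snr_db"` or `"T"` on the horizontal axis.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.cvte_benchmark <- function(x, against = c("snr_db", "T"), ...) {
  against <- match.arg(against)
  s <- summary(x)
  if (length(unique(s$family)) > 1L)
    warning("multiple families present; curves are pooled over families")
  xs <- sort(unique(s[[against]]))
  methods <- unique(s$method)
  m <- sapply(methods, function(me) {
    vapply(xs, function(v) {
      sel <- s$method == me & s[[against]] == v
      mean(s$mean_accuracy[sel])
    }, numeric(1))
  })
  graphics::matplot(xs, m, type = "b", pch = 19, lty = 1,
                    xlab = against, ylab = "accuracy (%)",
                    ylim = c(0, 100), ...)
  graphics::legend("bottomright", legend = methods, col = seq_along(methods),
                   pch = 19, lty = 1, bty = "n")
  invisible(x)
}
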