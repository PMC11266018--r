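# ROI time-series extraction and group-level connectivity analysis.

#' Extract per-ROI complex time series from 4D magnitude/phase volumes
#'
#' Averages, per region of interest and time point, the voxel magnitudes
#' and voxel phases inside each atlas label. Phase averaging is
#' arithmetic (not circular), matching the convention used for
#' complex-valued fMRI ROI series. Inputs may be 4D arrays
#' (x, y, z, time) plus a 3D integer label array, or paths to NIfTI
#' files (read with the RNifti package).
#'
#' @param magnitude 4D numeric array or NIfTI file path.
#' @param phase 4D numeric array or NIfTI file path, same grid.
#' @param atlas 3D integer label array or NIfTI file path; label 0 is
#'   background, labels 1..N index ROIs.
#' @return An object of class `roi_series_set`: list with `series` (list
#'   of [complex_series()], one per ROI), `roi_ids`, `excluded` (ids of
#'   empty ROIs, whose series are `NULL`), and `T`.
#' @export
extract_roi_series <- function(magnitude, phase, atlas) {
  load_vol <- function(x) {
    if (is.character(x)) {
      if (!requireNamespace("RNifti", quietly = TRUE))
        stop("reading NIfTI files requires the RNifti package",
             call. = FALSE)
      x <- RNifti::readNifti(x)
    }
    unclass(as.array(x))
  }
  magnitude <- load_vol(magnitude)
  phase <- load_vol(phase)
  atlas <- load_vol(atlas)
  if (length(dim(magnitude)) != 4L || length(dim(phase)) != 4L)
    stop("magnitude and phase must be 4D (x, y, z, time)", call. = FALSE)
  if (!identical(dim(magnitude), dim(phase)))
    stop("magnitude and phase dimensions differ", call. = FALSE)
  if (!identical(dim(atlas), dim(magnitude)[1:3]))
    stop("atlas grid does not match the data volumes", call. = FALSE)
  Tn <- dim(magnitude)[4]
  labels <- seq_len(max(as.integer(atlas)))  # gaps are empty ROIs
  nvox <- prod(dim(atlas))
  mag_mat <- matrix(magnitude, nrow = nvox, ncol = Tn)
  ph_mat <- matrix(phase, nrow = nvox, ncol = Tn)
  atlas_vec <- as.integer(atlas)

  series <- vector("list", length(labels))
  excluded <- integer(0)
  for (i in seq_along(labels)) {
    vox <- which(atlas_vec == labels[i])
    if (length(vox) == 0L) {
      warning("ROI ", labels[i], " has no voxels; excluded")
      excluded <- c(excluded, labels[i])
      next
    }
    series[[i]] <- complex_series(colMeans(mag_mat[vox, , drop = FALSE]),
                                  colMeans(ph_mat[vox, , drop = FALSE]))
  }
  structure(list(series = series, roi_ids = labels,
                 excluded = excluded, T = Tn),
            class = "roi_series_set")
}

#' @export
print.roi_series_set <- function(x, ...) {
  cat("<roi_series_set>", length(x$roi_ids), "ROIs,", x$T, "time points\n")
  if (length(x$excluded))
    cat("  excluded (empty):", paste(x$excluded, collapse = ", "), "\n")
  invisible(x)
}

#' All-pairs directed connectivity matrix
#'
#' Runs [causality()] over every unordered pair of ROI series and
#' assembles the signed Delta-C values into an antisymmetric N x N
#' matrix with zero diagonal, together with the p-value matrix and a
#' significance mask. P-values are adjusted across the N(N-1)/2 edges
#' with Benjamini-Hochberg FDR before the mask and the direction gating
#' are applied.
#'
#' @param roi_set A `roi_series_set`, or a plain list of
#'   [complex_series()].
#' @param estimator,R,p_th,beta,max_lag,seed Passed to [causality()].
#' @param fdr Apply BH adjustment across edges (default `TRUE`).
#' @return Object of class `connectivity_matrix`: list with `delta_c`,
#'   `p` (adjusted when `fdr`), `sig` (logical mask), `roi_ids`.
#' @export
connectivity_matrix <- function(roi_set, estimator = "cte", R = 100L,
                                p_th = 0.05, beta = 0.05, max_lag = 10L,
                                seed = NULL, fdr = TRUE) {
  series <- if (inherits(roi_set, "roi_series_set")) roi_set$series
            else roi_set
  ids <- if (inherits(roi_set, "roi_series_set")) roi_set$roi_ids
         else seq_along(series)
  N <- length(series)
  dc <- matrix(0, N, N, dimnames = list(ids, ids))
  pm <- matrix(1, N, N, dimnames = list(ids, ids))
  .with_seed(seed, {
    for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
      if (is.null(series[[i]]) || is.null(series[[j]])) {
        dc[i, j] <- dc[j, i] <- NA_real_
        pm[i, j] <- pm[j, i] <- NA_real_
        next
      }
      ct <- causality(series[[i]], series[[j]], estimator = estimator,
                      R = R, p_th = p_th, beta = beta, max_lag = max_lag)
      dc[i, j] <- ct$delta_c_mean
      dc[j, i] <- -ct$delta_c_mean
      pm[i, j] <- pm[j, i] <- ct$p_value
    }
  })
  upper <- upper.tri(pm)
  if (fdr) {
    padj <- pm
    padj[upper] <- stats::p.adjust(pm[upper], method = "BH")
    padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
    pm <- padj
  }
  sig <- !is.na(pm) & pm < p_th
  diag(sig) <- FALSE
  structure(list(delta_c = dc, p = pm, sig = sig, roi_ids = ids,
                 estimator = estimator, p_th = p_th, fdr = fdr),
            class = "connectivity_matrix")
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  n_edges <- sum(x$sig[upper.tri(x$sig)], na.rm = TRUE)
  cat("<connectivity_matrix>", nrow(x$delta_c), "ROIs,",
      n_edges, "significant edge(s) (", x$estimator, ")\n")
  invisible(x)
}

#' Subject-averaged magnitude-phase correlation matrix
#'
#' Entry (m, n) is the Pearson correlation between ROI m's magnitude
#' series and ROI n's phase series, averaged over subjects. Used as a
#' diagnostic for magnitude-phase dependence (the rationale for the
#' partial cross terms in the complex-valued estimator). The diagonal
#' (m = n) is included.
#'
#' @param subjects A list of `roi_series_set` objects (or lists of
#'   [complex_series()]), one per subject, all with the same ROIs and T.
#' @return N x N numeric matrix of averaged correlations in `[-1, 1]`.
#' @export
magphase_correlation <- function(subjects) {
  get_series <- function(s)
    if (inherits(s, "roi_series_set")) s$series else s
  first <- get_series(subjects[[1]])
  N <- length(first)
  acc <- matrix(0, N, N)
  for (s in subjects) {
    ser <- get_series(s)
    if (length(ser) != N)
      stop("all subjects must have the same number of ROIs", call. = FALSE)
    mags <- sapply(ser, function(z) z$magnitude)
    phs <- sapply(ser, function(z) z$phase)
    cc <- suppressWarnings(stats::cor(mags, phs))
    if (any(is.na(cc))) {
      warning("constant series encountered; correlations set to 0")
      cc[is.na(cc)] <- 0
    }
    acc <- acc + cc
  }
  acc / length(subjects)
}

#' Edge-wise two-group comparison of connectivity matrices
#'
#' For every edge (upper-triangle entry), performs a two-sample t-test
#' between the two groups' Delta-C values, adjusts the p-values across
#' all N(N-1)/2 edges with Benjamini-Hochberg FDR, and returns the
#' t-value matrix with non-surviving edges set to 0. Edges with zero
#' variance in both groups are shortcut: identical group means give
#' p = 1, differing means p = 0.
#'
#' @param group1,group2 Lists of `connectivity_matrix` objects or plain
#'   numeric matrices (one per subject).
#' @param p_th Significance level applied to the adjusted p-values.
#' @param network_map Optional integer/character vector of length N
#'   assigning each ROI to a network; when supplied, a block matrix of
#'   significant-edge counts per network pair is attached.
#' @return Object of class `group_edge_test`: list with `t` (t-values,
#'   0 where not significant), `p` (adjusted), `sig` (mask),
#'   `n1`, `n2`, and optionally `network_counts`.
#' @export
group_edge_test <- function(group1, group2, p_th = 0.05,
                            network_map = NULL) {
  as_mat <- function(x)
    if (inherits(x, "connectivity_matrix")) x$delta_c else as.matrix(x)
  g1 <- lapply(group1, as_mat)
  g2 <- lapply(group2, as_mat)
  if (length(g1) < 2L || length(g2) < 2L)
    stop("need at least 2 subjects per group", call. = FALSE)
  N <- nrow(g1[[1]])
  tmat <- matrix(0, N, N, dimnames = dimnames(g1[[1]]))
  pmat <- matrix(1, N, N, dimnames = dimnames(g1[[1]]))
  for (i in seq_len(N - 1L)) for (j in (i + 1L):N) {
    x <- vapply(g1, function(m) m[i, j], numeric(1))
    y <- vapply(g2, function(m) m[i, j], numeric(1))
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      pmat[i, j] <- if (mean(x) == mean(y)) 1 else 0
      tmat[i, j] <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
    } else {
      tt <- stats::t.test(x, y, var.equal = TRUE)
      pmat[i, j] <- tt$p.value
      tmat[i, j] <- unname(tt$statistic)
    }
  }
  upper <- upper.tri(pmat)
  pmat[upper] <- stats::p.adjust(pmat[upper], method = "BH")
  pmat[lower.tri(pmat)] <- t(pmat)[lower.tri(pmat)]
  tmat[lower.tri(tmat)] <- -t(tmat)[lower.tri(tmat)]
  sig <- pmat < p_th
  diag(sig) <- FALSE
  d <- ifelse(sig, tmat, 0)
  out <- list(t = d, p = pmat, sig = sig,
              n1 = length(g1), n2 = length(g2), p_th = p_th)
  if (!is.null(network_map)) {
    if (length(network_map) != N)
      stop("network_map must have one entry per ROI", call. = FALSE)
    nets <- sort(unique(network_map))
    counts <- matrix(0L, length(nets), length(nets),
                     dimnames = list(nets, nets))
    idx <- which(sig & upper, arr.ind = TRUE)
    for (r in seq_len(nrow(idx))) {
      a <- as.character(network_map[idx[r, 1]])
      b <- as.character(network_map[idx[r, 2]])
      counts[a, b] <- counts[a, b] + 1L
      if (a != b) counts[b, a] <- counts[b, a] + 1L
    }
    out$network_counts <- counts
  }
  class(out) <- "group_edge_test"
  out
}

#' @export
print.group_edge_test <- function(x, ...) {
  cat("<group_edge_test>", sum(x$sig[upper.tri(x$sig)]),
      "significant edge(s) at FDR", x$p_th,
      sprintf("(n1 = %d, n2 = %d)\n", x$n1, x$n2))
  invisible(x)
}
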