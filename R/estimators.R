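# Complex-valued and real-valued transfer-entropy estimators.
#
# The public functions (cte, scte, cte_direct, ste, hte) validate inputs,
# resolve the time delay, and delegate to closure factories that are also
# reused by the surrogate significance pipeline in causality(). A closure
# evaluates one ordered direction and takes the (possibly permuted) source
# code vectors as arguments, so the surrogate loop never re-symbolizes.

# Order-symmetric delay: scan both orders and keep the lag of the
# stronger correlation, so the same tau serves both directions and the
# surrogate Delta-C is exactly antisymmetric under argument swap.
.sym_delay <- function(x, y, max_lag, envelope) {
  f <- select_delay(x, y, max_lag = max_lag, envelope = envelope)
  b <- select_delay(y, x, max_lag = max_lag, envelope = envelope)
  if (abs(b$correlation) > abs(f$correlation)) b$tau else f$tau
}

# Resolve the per-pair shared delay for an estimator family.
.resolve_tau <- function(z1, z2, tau, max_lag, envelope) {
  if (!is.null(tau)) return(as.integer(tau))
  .sym_delay(z1$magnitude, z2$magnitude, max_lag, envelope)
}

# Factory for the symbolic complex-valued estimators. Returns a function
# (src_mag_codes, src_phase_codes) -> named term vector in nats.
# variant: "cte" (TE + partial TE cross terms), "scte" (TE terms only),
# "cte_direct" (TE terms + direct cross-channel TE, the ablation variant).
.eval_complex_factory <- function(sm_src, sp_src, m_tgt, p_tgt, tau, variant) {
  T <- length(m_tgt)
  n <- T - tau
  it <- (tau + 1L):T
  il <- seq_len(n)
  b <- m_tgt[it]; bl <- m_tgt[il]
  f <- p_tgt[it]; fl <- p_tgt[il]
  xlx <- c(0, seq_len(n) * log(seq_len(n)))
  logn <- log(n)
  ent <- function(keys1, nb) logn - sum(xlx[tabulate(keys1, nb) + 1L]) / n
  i_b_bl <- b + 4L * bl + 1L
  i_f_fl <- f + 4L * fl + 1L
  H_b_bl <- ent(i_b_bl, 16L); H_bl <- ent(bl + 1L, 4L)
  H_f_fl <- ent(i_f_fl, 16L); H_fl <- ent(fl + 1L, 4L)
  function(am, ap) {
    al <- am[il]; tl <- ap[il]
    mag_te <- H_b_bl + ent(al + 4L * bl + 1L, 16L) - H_bl -
      ent(i_b_bl + 16L * al, 64L)
    phase_te <- H_f_fl + ent(tl + 4L * fl + 1L, 16L) - H_fl -
      ent(i_f_fl + 16L * tl, 64L)
    if (variant == "scte")
      return(c(mag_te = mag_te, phase_te = phase_te))
    if (variant == "cte_direct") {
      tt <- ap[it]
      i_t_tl <- tt + 4L * tl + 1L
      cross_mag2_phase1 <- ent(i_t_tl, 16L) + ent(bl + 4L * tl + 1L, 16L) -
        ent(tl + 1L, 4L) - ent(i_t_tl + 16L * bl, 64L)
      cross_mag1_phase2 <- H_f_fl + ent(al + 4L * fl + 1L, 16L) - H_fl -
        ent(i_f_fl + 16L * al, 64L)
      return(c(mag_te = mag_te, phase_te = phase_te,
               cross_mag2_phase1 = cross_mag2_phase1,
               cross_mag1_phase2 = cross_mag1_phase2))
    }
    # partial cross terms: I(b_t; a_l | b_l, theta_l), I(f_t; th_l | f_l, a_l)
    j1 <- bl + 4L * tl
    p_mag <- ent(b + 4L * j1 + 1L, 64L) + ent(al + 4L * j1 + 1L, 64L) -
      ent(j1 + 1L, 16L) - ent(b + 4L * al + 16L * j1 + 1L, 256L)
    j2 <- fl + 4L * al
    p_phase <- ent(f + 4L * j2 + 1L, 64L) + ent(tl + 4L * j2 + 1L, 64L) -
      ent(j2 + 1L, 16L) - ent(f + 4L * tl + 16L * j2 + 1L, 256L)
    c(mag_te = mag_te, phase_te = phase_te,
      partial_mag = p_mag, partial_phase = p_phase)
  }
}

# Factory for the single-channel (magnitude) estimators, generic alphabet.
.eval_mag_factory <- function(src_codes, tgt_codes, tau, k) {
  T <- length(tgt_codes)
  n <- T - tau
  it <- (tau + 1L):T
  il <- seq_len(n)
  b <- tgt_codes[it]; bl <- tgt_codes[il]
  k2 <- as.numeric(k) * k
  i_b_bl <- b + k * bl + 1
  H_b_bl <- .ent_keys(i_b_bl, k2)
  H_bl <- .ent_keys(bl + 1, k)
  function(am) {
    al <- am[il]
    c(mag_te = H_b_bl + .ent_keys(al + k * bl + 1, k2) - H_bl -
        .ent_keys(i_b_bl + k2 * al, k2 * k))
  }
}

# literal-weighting complex evaluator (slow path, optional mode)
.eval_complex_literal <- function(sm_src, sp_src, m_tgt, p_tgt, tau) {
  T <- length(m_tgt)
  n <- T - tau
  it <- (tau + 1L):T
  il <- seq_len(n)
  b <- m_tgt[it]; bl <- m_tgt[il]
  f <- p_tgt[it]; fl <- p_tgt[il]
  function(am, ap) {
    al <- am[il]; tl <- ap[il]
    c(mag_te = .te_kernel(b, bl, al, 4L),
      phase_te = .te_kernel(f, fl, tl, 4L),
      partial_mag = .pte_literal(b, bl, al, tl, 4L),
      partial_phase = .pte_literal(f, fl, tl, al, 4L))
  }
}

.complex_terms <- function(z1, z2, tau, beta, variant, weighting = "joint") {
  sm1 <- .symbolize_codes(z1$magnitude, beta)
  sp1 <- .symbolize_codes(z1$phase, beta)
  sm2 <- .symbolize_codes(z2$magnitude, beta)
  sp2 <- .symbolize_codes(z2$phase, beta)
  ev <- if (variant == "cte" && weighting == "conditional")
    .eval_complex_literal(sm1, sp1, sm2, sp2, tau)
  else
    .eval_complex_factory(sm1, sp1, sm2, sp2, tau, variant)
  ev(sm1, sp1)
}

.check_pair <- function(z1, z2) {
  stopifnot(inherits(z1, "complex_series"), inherits(z2, "complex_series"))
  if (z1$n != z2$n)
    stop("z1 and z2 must have the same number of time points", call. = FALSE)
}

#' Complex-valued transfer entropy
#'
#' Directed coupling strength from complex signal `z1` to complex signal
#' `z2`, combining four symbolic plug-in terms: magnitude-magnitude
#' transfer entropy, phase-phase transfer entropy, and two partial
#' transfer entropy cross terms in which the source's other channel acts
#' as the conditioner (magnitude -> magnitude given source phase, and
#' phase -> phase given source magnitude). The cross terms capture
#' magnitude-phase interplay that the plain channel-wise sum misses.
#'
#' All four series are symbolized with [symbolize()] before counting. The
#' time delay is shared by all terms; when `tau` is `NULL` it is selected
#' by [select_delay()] on the magnitude channels with `envelope = TRUE`
#' (absolute-value correlation), which also detects sign-symmetric
#' non-linear coupling.
#'
#' @param z1,z2 [complex_series()] objects of equal length (source, target).
#' @param tau Time delay in samples; `NULL` (default) selects it from the
#'   data.
#' @param beta Symbolization control parameter (default 0.05).
#' @param base Logarithm base of the result (2 = bits, default).
#' @param max_lag Largest delay scanned when `tau` is `NULL`.
#' @param weighting Weighting of the partial terms: `"joint"` (standard
#'   conditional mutual information, default) or `"conditional"`.
#' @return Scalar coupling value; attribute `"terms"` holds the four
#'   components and attribute `"tau"` the delay used.
#' @seealso [scte()], [cte_direct()], [ste()], [hte()], [causality()]
#' @examples
#' p <- simulate_cpair("L1", T = 146, seed = 1)
#' cte(p$z1, p$z2)
#' @export
cte <- function(z1, z2, tau = NULL, beta = 0.05, base = 2, max_lag = 10L,
                weighting = c("joint", "conditional")) {
  weighting <- match.arg(weighting)
  .check_pair(z1, z2)
  tau <- .resolve_tau(z1, z2, tau, max_lag, envelope = TRUE)
  terms <- .complex_terms(z1, z2, tau, beta, "cte", weighting) / log(base)
  structure(sum(terms), terms = terms, tau = tau)
}

#' Simplified complex-valued transfer entropy
#'
#' The channel-wise sum of magnitude-magnitude and phase-phase symbolic
#' transfer entropy, without the partial cross terms of [cte()].
#'
#' @inheritParams cte
#' @return Scalar value with `"terms"` and `"tau"` attributes.
#' @export
scte <- function(z1, z2, tau = NULL, beta = 0.05, base = 2, max_lag = 10L) {
  .check_pair(z1, z2)
  tau <- .resolve_tau(z1, z2, tau, max_lag, envelope = TRUE)
  terms <- .complex_terms(z1, z2, tau, beta, "scte") / log(base)
  structure(sum(terms), terms = terms, tau = tau)
}

#' Complex-valued transfer entropy with direct cross-channel terms
#'
#' Ablation variant of [cte()] in which the two partial cross terms are
#' replaced by plain transfer entropies between channels (target
#' magnitude -> source phase and source magnitude -> target phase),
#' ignoring the complementary channel. Used to demonstrate the value of
#' partial conditioning.
#'
#' @inheritParams cte
#' @return Scalar value with `"terms"` and `"tau"` attributes.
#' @export
cte_direct <- function(z1, z2, tau = NULL, beta = 0.05, base = 2,
                       max_lag = 10L) {
  .check_pair(z1, z2)
  tau <- .resolve_tau(z1, z2, tau, max_lag, envelope = TRUE)
  terms <- .complex_terms(z1, z2, tau, beta, "cte_direct") / log(base)
  structure(sum(terms), terms = terms, tau = tau)
}

#' Symbolic transfer entropy (magnitude only)
#'
#' Real-valued baseline: [transfer_entropy()] between the symbolized
#' magnitude channels, ignoring phase. The delay is scanned on the raw
#' magnitude series with the plain (linear) correlation rule.
#'
#' @inheritParams cte
#' @return Scalar value with a `"tau"` attribute.
#' @export
ste <- function(z1, z2, tau = NULL, beta = 0.05, base = 2, max_lag = 10L) {
  .check_pair(z1, z2)
  tau <- .resolve_tau(z1, z2, tau, max_lag, envelope = FALSE)
  ev <- .eval_mag_factory(.symbolize_codes(z1$magnitude, beta),
                          .symbolize_codes(z2$magnitude, beta), tau, 4L)
  structure(sum(ev(.symbolize_codes(z1$magnitude, beta))) / log(base),
            tau = tau)
}

#' Histogram transfer entropy (magnitude only)
#'
#' Real-valued baseline: transfer entropy on the raw magnitude values,
#' binned with [bin_raw()] over the pooled range of the two series (bin
#' width = range / T), without symbolization.
#'
#' @inheritParams cte
#' @return Scalar value with a `"tau"` attribute.
#' @export
hte <- function(z1, z2, tau = NULL, base = 2, max_lag = 10L) {
  .check_pair(z1, z2)
  tau <- .resolve_tau(z1, z2, tau, max_lag, envelope = FALSE)
  ca <- bin_raw(z1$magnitude, z2$magnitude)
  cb <- bin_raw(z2$magnitude, z1$magnitude)
  k <- max(ca, cb) + 1L
  ev <- .eval_mag_factory(ca, cb, tau, k)
  structure(sum(ev(ca)) / log(base), tau = tau)
}
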