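# Plug-in entropy machinery shared by all transfer-entropy estimators.
#
# Discrete variables are combined into a single integer key per tuple and
# counted either with tabulate() (small alphabets) or by radix sort (large,
# sparse alphabets as produced by raw-value binning). All entropies are in
# nats internally; public functions convert to the requested log base.

# Shannon entropy of a vector of 1-based cell keys.
# H = log(n) - sum(c * log c) / n over occupied cells.
.ent_keys <- function(keys, nbins = NA_integer_) {
  n <- length(keys)
  if (!is.na(nbins) && nbins <= 4096L) {
    cnt <- tabulate(keys, nbins)
    cnt <- cnt[cnt > 0L]
  } else {
    s <- sort.int(keys, method = "radix")
    changed <- c(s[-1] != s[-n], TRUE)
    cnt <- diff(c(0L, which(changed)))
  }
  log(n) - sum(cnt * log(cnt)) / n
}

# Combine 0-based code vectors into 1-based mixed-radix keys.
.combine_codes <- function(..., k) {
  vars <- list(...)
  key <- vars[[1]]
  mult <- as.numeric(k)  # double keys: no integer overflow for large alphabets
  if (length(vars) > 1L) for (v in vars[-1L]) {
    key <- key + mult * v
    mult <- mult * k
  }
  key + 1
}

.as_codes <- function(x, arg = "input") {
  x <- as.integer(x)
  if (anyNA(x) || any(x < 0L))
    stop(arg, " must be non-negative integer codes", call. = FALSE)
  x
}

#' Transfer entropy between two discrete series
#'
#' Plug-in estimate of the information the source's past (at a single lag
#' `tau`) carries about the target's present beyond the target's own past:
#' the conditional mutual information
#' I(target_t ; source_(t-tau) | target_(t-tau)) of the empirical joint
#' distribution over the `T - tau` aligned tuples. Cells with zero
#' probability contribute nothing (0 log 0 = 0), and the estimate is
#' non-negative up to floating-point rounding.
#'
#' @param source,target Equal-length vectors of non-negative integer codes
#'   (e.g. from [symbolize()] or [bin_raw()]).
#' @param tau Positive integer time delay.
#' @param base Logarithm base of the returned value (2 = bits, default).
#' @return Non-negative scalar transfer entropy.
#' @examples
#' s <- symbolize(rnorm(200)); t <- symbolize(rnorm(200))
#' transfer_entropy(s, t, tau = 1)   # near 0: independent streams
#' @export
transfer_entropy <- function(source, target, tau = 1L, base = 2) {
  source <- .as_codes(source, "source")
  target <- .as_codes(target, "target")
  if (length(source) != length(target))
    stop("source and target must have the same length", call. = FALSE)
  tau <- as.integer(tau)
  n <- length(target)
  if (tau < 1L || n <= tau + 2L)
    stop("need series length > tau + 2", call. = FALSE)
  k <- max(source, target) + 1L
  bt <- target[(tau + 1L):n]
  bl <- target[1:(n - tau)]
  al <- source[1:(n - tau)]
  .te_kernel(bt, bl, al, k) / log(base)
}

# TE in nats from pre-aligned code vectors
.te_kernel <- function(bt, bl, al, k) {
  k2 <- k * k
  .ent_keys(.combine_codes(bt, bl, k = k), k2) +
    .ent_keys(.combine_codes(al, bl, k = k), k2) -
    .ent_keys(bl + 1, k) -
    .ent_keys(.combine_codes(bt, bl, al, k = k), k2 * k)
}

#' Partial transfer entropy (conditioned transfer entropy)
#'
#' Transfer entropy from `source` to `target` additionally conditioned on
#' a third series' past: the conditional mutual information
#' I(target_t ; source_(t-tau) | target_(t-tau), conditioner_(t-tau)).
#' This quantifies what the source's past adds beyond both the target's
#' own past and the conditioner's past, and is the cross
#' (magnitude-phase) building block of the complex-valued estimator.
#'
#' With `weighting = "joint"` (default) each log-ratio term is weighted by
#' the joint cell probability, the standard plug-in form, which is
#' non-negative and reduces to [transfer_entropy()] when the conditioner
#' is constant. `weighting = "conditional"` weights each term by the
#' conditional probability itself; this variant is not a proper
#' conditional mutual information (it can be negative) and is provided
#' only for comparison.
#'
#' @inheritParams transfer_entropy
#' @param conditioner Vector of non-negative integer codes, same length.
#' @param weighting `"joint"` or `"conditional"` (see Details).
#' @return Scalar partial transfer entropy (non-negative for
#'   `weighting = "joint"`).
#' @export
partial_transfer_entropy <- function(source, target, conditioner, tau = 1L,
                                     base = 2,
                                     weighting = c("joint", "conditional")) {
  weighting <- match.arg(weighting)
  source <- .as_codes(source, "source")
  target <- .as_codes(target, "target")
  conditioner <- .as_codes(conditioner, "conditioner")
  if (length(source) != length(target) ||
      length(conditioner) != length(target))
    stop("all series must have the same length", call. = FALSE)
  tau <- as.integer(tau)
  n <- length(target)
  if (tau < 1L || n <= tau + 2L)
    stop("need series length > tau + 2", call. = FALSE)
  k <- max(source, target, conditioner) + 1L
  bt <- target[(tau + 1L):n]
  bl <- target[1:(n - tau)]
  al <- source[1:(n - tau)]
  cl <- conditioner[1:(n - tau)]
  val <- if (weighting == "joint") {
    .pte_kernel(bt, bl, al, cl, k)
  } else {
    .pte_literal(bt, bl, al, cl, k)
  }
  val / log(base)
}

# joint-weighted partial TE in nats:
# I(bt; al | bl, cl) = H(bt,bl,cl) + H(al,bl,cl) - H(bl,cl) - H(bt,al,bl,cl)
.pte_kernel <- function(bt, bl, al, cl, k) {
  k2 <- as.numeric(k) * k
  cond <- .combine_codes(bl, cl, k = k) - 1
  .ent_keys(.combine_codes(bt, bl, cl, k = k), k2 * k) +
    .ent_keys(.combine_codes(al, bl, cl, k = k), k2 * k) -
    .ent_keys(cond + 1, k2) -
    .ent_keys(.combine_codes(bt, al, k = k) + k2 * cond, k2 * k2)
}

# literal conditional-probability weighting:
# -sum p(bt|cond) log p(bt|cond) + sum p(bt|al,cond) log p(bt|al,cond),
# summed over occupied cells.
.pte_literal <- function(bt, bl, al, cl, k) {
  term <- function(xt, cond_key) {
    joint <- paste(xt, cond_key)
    nj <- table(joint)
    nc <- table(cond_key)
    cond_of <- sub("^[^ ]+ ", "", names(nj))
    p <- as.numeric(nj) / as.numeric(nc[cond_of])
    sum(p * log(p))
  }
  cond1 <- .combine_codes(bl, cl, k = k)
  cond2 <- .combine_codes(al, bl, cl, k = k)
  -term(bt, cond1) + term(bt, cond2)
}

#' Empirical joint probability mass function
#'
#' Counts aligned tuples of discrete variables into a multidimensional
#' contingency array. Marginalising over any set of axes reproduces the
#' joint PMF of the remaining variables, which is how the conditional
#' probabilities inside the transfer-entropy estimators are formed.
#'
#' @param variables A named list of equal-length vectors of non-negative
#'   integer codes.
#' @return An object of class `joint_pmf`: list with `counts` (integer
#'   array, one dimension per variable), `prob` (`counts / total`),
#'   `total` (number of tuples) and `dims` (variable names).
#' @examples
#' p <- joint_pmf(list(x = c(0, 1, 0, 1), y = c(0, 1, 1, 0)))
#' p$prob
#' marginal_pmf(p, "x")
#' @export
joint_pmf <- function(variables) {
  if (!is.list(variables) || length(variables) == 0L)
    stop("variables must be a non-empty list", call. = FALSE)
  if (is.null(names(variables)) || any(names(variables) == ""))
    names(variables) <- paste0("v", seq_along(variables))
  lens <- lengths(variables)
  if (length(unique(lens)) != 1L)
    stop("all variables must have the same length", call. = FALSE)
  vars <- lapply(seq_along(variables), function(i)
    .as_codes(variables[[i]], names(variables)[i]))
  k <- vapply(vars, function(v) max(v) + 1L, integer(1))
  key <- vars[[1]]
  mult <- k[1]
  if (length(vars) > 1L) for (i in 2:length(vars)) {
    key <- key + mult * vars[[i]]
    mult <- mult * k[i]
  }
  counts <- array(tabulate(key + 1L, nbins = prod(k)), dim = k,
                  dimnames = lapply(k, function(ki) as.character(0:(ki - 1L))))
  names(dimnames(counts)) <- names(variables)
  structure(list(counts = counts,
                 prob = counts / lens[1],
                 total = as.integer(lens[1]),
                 dims = names(variables)),
            class = "joint_pmf")
}

#' Marginalise a joint PMF
#'
#' @param pmf A [joint_pmf()].
#' @param keep Character vector of variable names to keep.
#' @return A `joint_pmf` over the kept variables.
#' @export
marginal_pmf <- function(pmf, keep) {
  stopifnot(inherits(pmf, "joint_pmf"))
  idx <- match(keep, pmf$dims)
  if (anyNA(idx)) stop("unknown variable in 'keep'", call. = FALSE)
  counts <- apply(pmf$counts, idx, sum)
  if (length(idx) == 1L) {
    counts <- array(counts, dim = length(counts),
                    dimnames = dimnames(pmf$counts)[idx])
    names(dimnames(counts)) <- keep
  }
  structure(list(counts = counts, prob = counts / pmf$total,
                 total = pmf$total, dims = keep),
            class = "joint_pmf")
}

#' @export
print.joint_pmf <- function(x, ...) {
  cat("<joint_pmf> ", paste(x$dims, collapse = " x "),
      " (", x$total, " tuples)\n", sep = "")
  print(x$prob)
  invisible(x)
}
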