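# Independent brute-force oracles: plug-in information quantities computed
# by explicit enumeration over all symbol combinations. Deliberately slow
# and structurally unlike the package kernels (probabilities via mean() of
# logical masks, nested loops over value ranges).

oracle_te <- function(src, tgt, tau, base = 2) {
  n <- length(tgt)
  bt <- tgt[(tau + 1):n]
  bl <- tgt[1:(n - tau)]
  al <- src[1:(n - tau)]
  total <- 0
  for (i in unique(bt)) for (j in unique(bl)) for (k in unique(al)) {
    p_ijk <- mean(bt == i & bl == j & al == k)
    if (p_ijk == 0) next
    p_jk <- mean(bl == j & al == k)
    p_ij <- mean(bt == i & bl == j)
    p_j <- mean(bl == j)
    total <- total + p_ijk * log((p_ijk / p_jk) / (p_ij / p_j))
  }
  total / log(base)
}

oracle_pte <- function(src, tgt, cond, tau, base = 2) {
  n <- length(tgt)
  bt <- tgt[(tau + 1):n]
  bl <- tgt[1:(n - tau)]
  al <- src[1:(n - tau)]
  cl <- cond[1:(n - tau)]
  total <- 0
  for (i in unique(bt)) for (j in unique(bl)) {
    for (k in unique(al)) for (m in unique(cl)) {
      p_full <- mean(bt == i & bl == j & al == k & cl == m)
      if (p_full == 0) next
      p_cond <- mean(bl == j & cl == m)
      p_src_cond <- mean(bl == j & al == k & cl == m)
      p_tgt_cond <- mean(bt == i & bl == j & cl == m)
      total <- total + p_full *
        log((p_full / p_src_cond) / (p_tgt_cond / p_cond))
    }
  }
  total / log(base)
}

# direct lag scan used to cross-check select_delay
oracle_delay_scan <- function(x, y, max_lag) {
  n <- length(x)
  sapply(seq_len(max_lag), function(l)
    cor(x[1:(n - l)], y[(1 + l):n]))
}

random_codes <- function(n, k = 4) sample.int(k, n, replace = TRUE) - 1L

white_pair <- function(T = 146) {
  complex_series(rnorm(T), rnorm(T))
}
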