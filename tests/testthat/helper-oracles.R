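# exact two-sided permutation p-value for the Mann-Whitney U by exhaustive
# enumeration of all assignments of the pooled sample (oracle for small n)
exact_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  rk <- rank(pooled)
  us <- apply(idx, 2, function(i) sum(rk[i]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# exact mid-p (half weight on the observed point mass): the quantity an
# uncorrected normal approximation is centred on for discrete U
exact_mw_midp <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  rk <- rank(pooled)
  us <- apply(idx, 2, function(i) sum(rk[i]) - n1 * (n1 + 1) / 2)
  u_obs <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  dev <- abs(us - mu); d0 <- abs(u_obs - mu)
  mean(dev > d0 + 1e-9) + 0.5 * mean(abs(dev - d0) < 1e-9)
}

# every tie-free two-sample split of ranks 1..N for n1 + n2 <= 8 (the U
# distribution is rank-universal without ties, so this enumeration is
# exhaustive over all tie-free datasets of these sizes)
all_small_splits <- function() {
  out <- list()
  for (n1 in 2:6) for (n2 in 2:min(6, 8 - n1)) {
    N <- n1 + n2
    sel <- utils::combn(N, n1)
    for (j in seq_len(ncol(sel)))
      out[[length(out) + 1]] <- list(x = (1:N)[sel[, j]],
                                     y = (1:N)[-sel[, j]])
  }
  out
}
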