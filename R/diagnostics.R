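# MCMC convergence diagnostics: split Gelman-Rubin R-hat and effective
# sample size (the latter via coda's spectral estimator on the pooled
# chains).

# `x`: list of per-chain draw matrices (iter x d, equal shapes).
split_rhat <- function(x) {
  n <- nrow(x[[1L]])
  half <- floor(n / 2)
  seqs <- list()
  for (ch in x) {
    seqs <- c(seqs, list(ch[seq_len(half), , drop = FALSE],
                         ch[(n - half + 1L):n, , drop = FALSE]))
  }
  m <- length(seqs)
  d <- ncol(x[[1L]])
  means <- vapply(seqs, colMeans, numeric(d))
  vars <- vapply(seqs, function(s) apply(s, 2L, stats::var), numeric(d))
  if (d == 1L) {
    means <- matrix(means, 1L); vars <- matrix(vars, 1L)
  }
  w <- rowMeans(vars)
  b <- half * apply(means, 1L, stats::var)
  var_plus <- (half - 1) / half * w + b / half
  out <- sqrt(var_plus / w)
  out[w < 1e-300] <- 1  # constant parameter: no variance to diagnose
  out
}

ess_coda <- function(x) {
  ml <- coda::mcmc.list(lapply(x, coda::mcmc))
  as.numeric(coda::effectiveSize(ml))
}
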