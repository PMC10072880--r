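# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and the stats:: routines the implementation calls) so that
# agreement is a genuine cross-check.

# Per-position tally over consensus records by plain looping.
oracle_pileup_tally <- function(records, L) {
  counts <- matrix(0L, nrow = L, ncol = 4L,
                   dimnames = list(NULL, c("A", "C", "G", "T")))
  for (rec in records) {
    if (is.null(rec)) next
    bases <- strsplit(rec$consensus, "")[[1]]
    for (i in seq_along(bases)) {
      if (bases[i] == "N") next
      pos <- ((rec$start + i - 1L - 1L) %% L) + 1L
      counts[pos, bases[i]] <- counts[pos, bases[i]] + 1L
    }
  }
  counts
}

# Upper-tail Poisson probability P(X >= o) by direct pmf summation with a
# recursively computed pmf (no dpois/ppois).
oracle_poisson_upper <- function(lambda, o, cap = 5000L) {
  if (o <= 0) return(1)
  pmf <- exp(-lambda)
  cdf <- pmf  # P(X <= 0)
  k <- 0L
  while (k < o - 1L) {
    k <- k + 1L
    pmf <- pmf * lambda / k
    cdf <- cdf + pmf
  }
  1 - cdf
}

oracle_poisson_lower <- function(lambda, o) {
  pmf <- exp(-lambda)
  cdf <- pmf
  k <- 0L
  while (k < o) {
    k <- k + 1L
    pmf <- pmf * lambda / k
    cdf <- cdf + pmf
  }
  cdf
}

# OLS slope/intercept through the normal equations, solved by hand.
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x * x); sxy <- sum(x * y)
  det <- n * sxx - sx * sx
  c(intercept = (sxx * sy - sx * sxy) / det,
    slope = (n * sxy - sx * sy) / det)
}

# Two-sided permutation p-value for a difference in means.
oracle_permutation_p <- function(a, b, n_perm = 20000L, seed = 1L) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    d <- abs(mean(pooled[idx]) - mean(pooled[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  (hits + 1L) / (n_perm + 1L)
}

# Studentized-range distribution P(Q <= q) for k groups and df degrees of
# freedom, by direct double numeric integration (inner integral over the
# normal range process, outer over the chi distribution of the scale).
oracle_ptukey <- function(q, k, df) {
  inner <- function(u) {
    # P(range of k std normals <= u)
    f <- function(z) dnorm(z) * (pnorm(z + u) - pnorm(z))^(k - 1)
    k * integrate(f, -8, 8, rel.tol = 1e-10)$value
  }
  # s ~ sqrt(chisq_df / df); density of s
  dens_s <- function(s) {
    2 * s * df * dchisq(s^2 * df, df)
  }
  f_outer <- Vectorize(function(s) inner(q * s) * dens_s(s))
  integrate(f_outer, 0, 5, rel.tol = 1e-8)$value
}

# One-sided Kolmogorov-Smirnov check that an empirical p-value sample is not
# anti-conservative: D+ = max(ECDF - U) with its asymptotic tail bound.
oracle_ks_superuniform_p <- function(p) {
  n <- length(p)
  d_plus <- max(seq_len(n) / n - sort(p))
  exp(-2 * n * d_plus^2)
}
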