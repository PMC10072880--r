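#' Detect heteroplasmic clones in a somatic call set
#'
#' A heteroplasmic clone is a variant supported by three or more
#' error-corrected (duplex consensus) reads; variants detected once or
#' twice are "unique". Only the somatic subset of the calls is considered.
#'
#' @param calls Flagged call table for one sample.
#' @param min_support Minimum supporting reads for a clone (default 3).
#' @param total_bases Optional sequenced-base denominator `B` for the clone
#'   frequency (e.g. `spectrum_summary(...)$total_bases`).
#' @return A `CloneSummary` list: `sample_id`, `clones` (call rows),
#'   `n_clones`, `n_snvs` (distinct somatic SNVs), `clone_frequency`
#'   (`NA` without `total_bases`), `clonality_pct`, `class_clone_counts`.
#' @export
detect_clones <- function(calls, min_support = 3L, total_bases = NULL) {
  som <- calls[is_somatic(calls) & calls$six_class != "indel", , drop = FALSE]
  clones <- som[som$supporting_reads >= min_support, , drop = FALSE]
  n_snvs <- nrow(som)
  class_counts <- vapply(SNV_CLASSES, function(cls) {
    sum(clones$six_class == cls)
  }, numeric(1))
  structure(
    list(
      sample_id = if (nrow(calls)) calls$sample_id[1] else NA_character_,
      clones = clones,
      n_clones = nrow(clones),
      n_snvs = n_snvs,
      clone_frequency = if (is.null(total_bases)) NA_real_ else
        sum(clones$supporting_reads) / total_bases,
      clonality_pct = if (n_snvs > 0L) 100 * nrow(clones) / n_snvs else
        NA_real_,
      class_clone_counts = class_counts
    ),
    class = "CloneSummary"
  )
}

#' @export
print.CloneSummary <- function(x, ...) {
  cat(sprintf("CloneSummary '%s': %d clones among %d SNVs (%.1f%% clonality)\n",
              x$sample_id, x$n_clones, x$n_snvs, x$clonality_pct))
  invisible(x)
}

#' Percentage of somatic SNVs that are heteroplasmic clones
#'
#' @param summary A [detect_clones()] result.
#' @return Percentage in `[0, 100]`; `NA` when the sample has no SNVs.
#' @export
clonality_percentage <- function(summary) {
  summary$clonality_pct
}

#' Clonality-weighted expected clone spectrum
#'
#' Under the null that heteroplasmic clones arise randomly as a consequence
#' of mutation burden, the expected number of clones of class `c` is
#' \deqn{\lambda_c = \sum_t N_t \, p_t \, s_{t,c},}
#' summing over tissues/samples `t`, where `N_t` is the tissue's SNV count,
#' `p_t` its mean clonality fraction, and `s_{t,c}` its per-class spectral
#' fraction (summing to 1 over classes). The total expected clone count is
#' `Lambda = sum_t N_t p_t`.
#'
#' @param inputs data.frame with one row per tissue/sample: a `n_snv`
#'   column, a clonality column (`clonality` as a fraction or
#'   `clonality_pct` as a percentage), and one spectral-fraction column per
#'   class named as in [SNV_CLASSES] (or `s_1` ... `s_6` in that order).
#' @return An `ExpectedCloneSpectrum` list: `lambda` (named per-class
#'   expectations), `total` (Lambda), `inputs`.
#' @export
expected_clone_spectrum <- function(inputs) {
  if (!("n_snv" %in% names(inputs))) stopf("inputs need an n_snv column")
  p <- if ("clonality" %in% names(inputs)) {
    inputs$clonality
  } else if ("clonality_pct" %in% names(inputs)) {
    inputs$clonality_pct / 100
  } else {
    stopf("inputs need a clonality or clonality_pct column")
  }
  if (any(p < 0 | p > 1)) stopf("clonality fractions must lie in [0, 1]")
  s_cols <- if (all(SNV_CLASSES %in% names(inputs))) SNV_CLASSES else
    paste0("s_", seq_along(SNV_CLASSES))
  if (!all(s_cols %in% names(inputs))) {
    stopf("inputs need spectral-fraction columns named by class")
  }
  s <- as.matrix(inputs[s_cols])
  if (any(abs(rowSums(s) - 1) > 1e-9)) {
    stopf("spectral fractions must sum to 1 per tissue (tolerance 1e-9)")
  }
  w <- inputs$n_snv * p
  lambda <- setNames(as.numeric(colSums(s * w)), SNV_CLASSES)
  structure(
    list(lambda = lambda, total = sum(w), inputs = inputs),
    class = "ExpectedCloneSpectrum"
  )
}

#' @export
print.ExpectedCloneSpectrum <- function(x, ...) {
  cat(sprintf("ExpectedCloneSpectrum: %.1f clones expected in total\n",
              x$total))
  print(round(x$lambda, 2))
  invisible(x)
}

#' Poisson comparison of expected and observed clone counts
#'
#' Per class, reports the fold difference between observed and expected
#' clone counts (`lambda / O` as an under-representation when `O <= lambda`,
#' `O / lambda` as an over-representation otherwise; infinite when `O = 0`
#' with positive expectation) and a two-sided Poisson p-value obtained by
#' doubling the smaller exact tail probability, capped at 1. No normal
#' approximation is used.
#'
#' @param expected Numeric vector of expected counts `lambda_c` (optionally
#'   named by class).
#' @param observed Non-negative integer vector of observed counts.
#' @return data.frame with `class`, `expected`, `observed`, `fold`,
#'   `direction` (`"under"`, `"over"`, `"equal"`), `p_value`.
#' @export
poisson_compare <- function(expected, observed) {
  if (length(expected) != length(observed)) {
    stopf("expected and observed must have equal length")
  }
  if (any(expected < 0) || any(observed < 0)) {
    stopf("counts must be non-negative")
  }
  if (any(observed != round(observed))) {
    stopf("observed counts must be integers")
  }
  cls <- if (!is.null(names(expected))) names(expected) else
    as.character(seq_along(expected))
  fold <- numeric(length(expected))
  direction <- character(length(expected))
  p <- numeric(length(expected))
  for (i in seq_along(expected)) {
    lam <- expected[i]
    o <- observed[i]
    if (o <= lam) {
      fold[i] <- if (o > 0) lam / o else if (lam > 0) Inf else 1
      direction[i] <- if (o == lam) "equal" else "under"
    } else {
      fold[i] <- o / lam
      direction[i] <- "over"
    }
    p[i] <- poisson_two_sided_p(lam, o)
  }
  data.frame(class = cls, expected = unname(expected),
             observed = unname(observed), fold = fold,
             direction = direction, p_value = p)
}

# Exact two-sided Poisson p-value: double the smaller of the lower tail
# P(X <= o) and the upper tail P(X >= o), capped at 1.
poisson_two_sided_p <- function(lambda, o) {
  if (lambda == 0) return(if (o == 0) 1 else 0)
  lower <- ppois(o, lambda)
  upper <- ppois(o - 1, lambda, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Read a clone-spectrum input table
#'
#' Reads a TSV in the layout of a per-tissue clone source-data sheet: one
#' row per tissue/sample with SNV counts, clonality, and six per-class
#' spectral fractions (see [expected_clone_spectrum()] for the accepted
#' column names). Observed per-class clone-count columns (`obs_` prefix
#' followed by the class label) are returned alongside when present.
#'
#' @param path Path to the TSV.
#' @return List with `inputs` (data.frame) and `observed` (named numeric of
#'   per-class totals, or `NULL`).
#' @export
read_clone_inputs <- function(path) {
  d <- read.delim(path, check.names = FALSE)
  obs_cols <- paste0("obs_", SNV_CLASSES)
  observed <- NULL
  if (all(obs_cols %in% names(d))) {
    observed <- setNames(colSums(as.matrix(d[obs_cols])), SNV_CLASSES)
  }
  list(inputs = d[setdiff(names(d), obs_cols)], observed = observed)
}

#' Simulate clone spectra under the random-formation null
#'
#' Draws per-tissue clone counts `Poisson(N_t p_t)` and distributes them
#' over classes by the tissue's spectral fractions, mirroring the null
#' hypothesis of the expected-clone model. Optionally suppresses chosen
#' classes by a factor to emulate selective clone removal.
#'
#' @param inputs As for [expected_clone_spectrum()].
#' @param n_rep Number of replicates.
#' @param suppress Named numeric of per-class multiplicative factors on the
#'   clone-formation probability (e.g. `c("G>T/C>A" = 0.1)`).
#' @param seed Integer seed.
#' @return Matrix of per-class observed counts, `n_rep` rows.
#' @export
simulate_clone_null <- function(inputs, n_rep = 500L, suppress = NULL,
                                seed = 1L) {
  spec <- expected_clone_spectrum(inputs)
  s_cols <- if (all(SNV_CLASSES %in% names(inputs))) SNV_CLASSES else
    paste0("s_", seq_along(SNV_CLASSES))
  s <- as.matrix(inputs[s_cols])
  colnames(s) <- SNV_CLASSES
  if (!is.null(suppress)) {
    for (cls in names(suppress)) s[, cls] <- s[, cls] * suppress[[cls]]
  }
  p <- if ("clonality" %in% names(inputs)) inputs$clonality else
    inputs$clonality_pct / 100
  w <- inputs$n_snv * p
  with_seed(seed, {
    out <- matrix(0L, nrow = n_rep, ncol = length(SNV_CLASSES),
                  dimnames = list(NULL, SNV_CLASSES))
    for (r in seq_len(n_rep)) {
      for (t in seq_len(nrow(inputs))) {
        # class-wise Poisson thinning of the tissue's clone process
        out[r, ] <- out[r, ] + rpois(length(SNV_CLASSES), w[t] * s[t, ])
      }
    }
    out
  })
}
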