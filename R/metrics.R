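#' Per-sample mutation frequency and six-class spectrum
#'
#' Frequencies follow the sequenced-bases definition: the number of
#' variant-supporting consensus reads divided by the total number of
#' sequenced bases `B` (the summed duplex depth over unmasked positions).
#' The overall SNV frequency is exactly the sum of the six per-class
#' frequencies.
#'
#' @param calls A flagged call table for one sample; only its somatic subset
#'   (see [is_somatic()]) contributes.
#' @param pileup The DCS `Pileup` supplying the depth denominator.
#' @param reference The `MitoReference` (defines masked positions).
#' @return A `SpectrumSummary` list: `sample_id`, `total_bases`,
#'   `class_reads`, `class_unique` (named by [SNV_CLASSES]), `class_freq`,
#'   `snv_frequency`, `indel_reads`, `indel_unique`, `indel_frequency`.
#' @export
spectrum_summary <- function(calls, pileup, reference) {
  masked <- masked_positions(reference)
  depth <- pileup_depth(pileup)
  if (length(masked)) depth <- depth[-masked]
  B <- sum(as.numeric(depth))
  if (B <= 0) stopf("zero total depth: frequency undefined")

  som <- calls[is_somatic(calls), , drop = FALSE]
  snv <- som[som$six_class != "indel", , drop = FALSE]
  ind <- som[som$six_class == "indel", , drop = FALSE]

  class_reads <- vapply(SNV_CLASSES, function(cls) {
    sum(snv$supporting_reads[snv$six_class == cls])
  }, numeric(1))
  class_unique <- vapply(SNV_CLASSES, function(cls) {
    sum(snv$six_class == cls)
  }, numeric(1))

  structure(
    list(
      sample_id = if (nrow(calls)) calls$sample_id[1] else NA_character_,
      total_bases = B,
      class_reads = class_reads,
      class_unique = class_unique,
      class_freq = class_reads / B,
      snv_frequency = sum(class_reads) / B,
      indel_reads = sum(ind$supporting_reads),
      indel_unique = nrow(ind),
      indel_frequency = sum(ind$supporting_reads) / B
    ),
    class = "SpectrumSummary"
  )
}

#' @export
print.SpectrumSummary <- function(x, ...) {
  cat(sprintf("SpectrumSummary '%s': %.3g SNV/base, %.3g In/Del/base over %.3g bases\n",
              x$sample_id, x$snv_frequency, x$indel_frequency, x$total_bases))
  invisible(x)
}

#' Overall mutation frequency of a filtered call set
#'
#' Total variant-supporting reads in scope divided by total sequenced bases
#' over unmasked positions.
#'
#' @inheritParams spectrum_summary
#' @param scope `"SNV"` or `"indel"`.
#' @return List with `frequency` and named `class_freq` breakdown (SNV
#'   scope only).
#' @export
mutation_frequency <- function(calls, pileup, reference, scope = c("SNV", "indel")) {
  scope <- match.arg(scope)
  s <- spectrum_summary(calls, pileup, reference)
  if (scope == "SNV") {
    list(frequency = s$snv_frequency, class_freq = s$class_freq,
         total_bases = s$total_bases)
  } else {
    list(frequency = s$indel_frequency, class_freq = NULL,
         total_bases = s$total_bases)
  }
}

#' Old/young fold change of a class frequency with a Fieller interval
#'
#' Ratio of group mean frequencies (old over young) with the confidence
#' interval for a ratio of two independent Gaussian means from Fieller's
#' construction.
#'
#' @param old,young Numeric vectors of per-sample frequencies (>= 2 each).
#' @param level Confidence level (default 0.95).
#' @return List with `ratio`, `lower`, `upper`, `bounded`.
#' @export
fold_change <- function(old, young, level = 0.95) {
  if (length(old) < 2L || length(young) < 2L) {
    stopf("fold_change needs >= 2 samples per group")
  }
  if (mean(young) == 0) stopf("young mean is zero: ratio undefined")
  fieller_ratio_ci(old, young, level = level)
}

#' SSCS-versus-DCS frequency comparison (damage diagnostic)
#'
#' Strand-specific damage (8-oxo-dG-like lesions fixed during copying)
#' produces variants in the single-strand consensus that vanish from the
#' duplex consensus; the per-class SSCS-minus-DCS frequency excess is
#' therefore a diagnostic for damage-derived G>T/C>A signal.
#'
#' @param sscs_pileup,dcs_pileup Pileups of the two layers for one sample.
#' @param reference The shared `MitoReference`.
#' @return data.frame with one row per class: `class`, `f_sscs`, `f_dcs`,
#'   `excess`.
#' @export
sscs_dcs_compare <- function(sscs_pileup, dcs_pileup, reference) {
  layer_freq <- function(pileup) {
    bases <- strsplit(reference$sequence, "")[[1]]
    masked <- masked_positions(reference)
    keep <- rep(TRUE, reference$length)
    if (length(masked)) keep[masked] <- FALSE
    depth <- pileup_depth(pileup)
    B <- sum(as.numeric(depth[keep]))
    reads <- setNames(numeric(length(SNV_CLASSES)), SNV_CLASSES)
    for (b in BASES) {
      cnt <- pileup$counts[, b]
      hit <- which(cnt > 0L & bases != b & keep)
      if (length(hit)) {
        cls <- classify_snv(bases[hit], rep(b, length(hit)))
        for (u in unique(cls)) {
          reads[u] <- reads[u] + sum(cnt[hit][cls == u])
        }
      }
    }
    reads / B
  }
  f_s <- layer_freq(sscs_pileup)
  f_d <- layer_freq(dcs_pileup)
  data.frame(class = SNV_CLASSES, f_sscs = unname(f_s),
             f_dcs = unname(f_d), excess = unname(f_s - f_d))
}
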