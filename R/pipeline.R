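#' Run the analysis pipeline on one simulated sample
#'
#' Simulates a molecule pool, draws a duplex-consensus pileup at the target
#' depth, calls variants, applies the masked-region and VAF/depth somatic
#' filters, and summarises frequencies, spectra and heteroplasmic clones.
#' (Read-level simulation plus consensus calling is available through
#' [simulate_read_families()] and [duplex_consensus()]; this entry point
#' works at the consensus level so that full-genome, 10,000x experiments
#' stay cheap.)
#'
#' @param reference A `MitoReference`.
#' @param profile A `TissueProfile`.
#' @param n_molecules mtDNA copies in the pool (default 10,000).
#' @param depth Duplex consensus depth (default 10,000).
#' @param seed Integer seed.
#' @param vaf_max,min_depth Somatic cutoffs, see [somatic_filter()].
#' @return List with `pool`, `pileup`, `calls`, `spectrum`
#'   (`SpectrumSummary`), and `clones` (`CloneSummary`).
#' @export
run_sample <- function(reference, profile, n_molecules = 10000L,
                       depth = 10000L, seed = 1L, vaf_max = 0.01,
                       min_depth = 100L) {
  pool <- simulate_sample(reference, profile, n_molecules, seed = seed)
  pileup <- sample_pileup(pool, reference, depth, seed = seed + 1L)
  calls <- call_variants(pileup, reference,
                         sample_id = profile$name %||% "sample")
  calls <- filter_calls(calls, reference, vaf_max = vaf_max,
                        min_depth = min_depth)
  spectrum <- spectrum_summary(calls, pileup, reference)
  clones <- detect_clones(calls, total_bases = spectrum$total_bases)
  list(pool = pool, pileup = pileup, calls = calls, spectrum = spectrum,
       clones = clones)
}

#' Run the pipeline across a cohort of tissue profiles
#'
#' @param reference A `MitoReference`.
#' @param profiles Named list of `TissueProfile`s (e.g.
#'   [preset_tissue_profiles()]).
#' @param seed Base seed; sample `i` uses `seed + 13 * i`.
#' @inheritParams run_sample
#' @return List of [run_sample()] results, one per profile.
#' @export
run_cohort <- function(reference, profiles, n_molecules = 10000L,
                       depth = 10000L, seed = 1L) {
  out <- lapply(seq_along(profiles), function(i) {
    run_sample(reference, profiles[[i]], n_molecules = n_molecules,
               depth = depth, seed = seed + 13L * i)
  })
  names(out) <- names(profiles)
  out
}

#' Cohort summary table
#'
#' One row per sample: overall SNV and In/Del frequencies, per-class
#' frequencies, clone count and clonality percentage.
#'
#' @param cohort A [run_cohort()] result.
#' @return data.frame.
#' @export
cohort_summary <- function(cohort) {
  rows <- lapply(names(cohort), function(nm) {
    s <- cohort[[nm]]$spectrum
    cl <- cohort[[nm]]$clones
    d <- data.frame(sample_id = nm, snv_frequency = s$snv_frequency,
                    indel_frequency = s$indel_frequency,
                    n_snvs = cl$n_snvs, n_clones = cl$n_clones,
                    clonality_pct = cl$clonality_pct)
    for (cls in SNV_CLASSES) d[[cls]] <- s$class_freq[[cls]]
    d
  })
  do.call(rbind, rows)
}

#' Expected-clone model inputs from a cohort
#'
#' Builds the per-tissue table the clonality-weighted expected-clone model
#' consumes: SNV counts, clonality fractions, and spectral fractions taken
#' from the unique (support <= 2) mutations of each sample.
#'
#' @param cohort A [run_cohort()] result.
#' @param spectral_source `"unique"` (default; spectral fractions from
#'   variants with support <= 2, matching the partition used for the
#'   observed-clone comparison) or `"total"` (all somatic SNVs).
#' @return data.frame accepted by [expected_clone_spectrum()].
#' @export
clone_model_inputs <- function(cohort, spectral_source = c("unique", "total")) {
  spectral_source <- match.arg(spectral_source)
  rows <- lapply(names(cohort), function(nm) {
    calls <- cohort[[nm]]$calls
    som <- calls[is_somatic(calls) & calls$six_class != "indel", ,
                 drop = FALSE]
    pickset <- if (spectral_source == "unique") {
      som[som$supporting_reads <= 2L, , drop = FALSE]
    } else {
      som
    }
    n_by_class <- vapply(SNV_CLASSES, function(cls) {
      sum(pickset$six_class == cls)
    }, numeric(1))
    s <- if (sum(n_by_class) > 0) n_by_class / sum(n_by_class) else
      rep(1 / length(SNV_CLASSES), length(SNV_CLASSES))
    d <- data.frame(tissue = nm, n_snv = nrow(som),
                    clonality = cohort[[nm]]$clones$clonality_pct / 100)
    for (i in seq_along(SNV_CLASSES)) d[[SNV_CLASSES[i]]] <- s[i]
    d
  })
  do.call(rbind, rows)
}
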