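#' Construct a tissue mutation profile
#'
#' A `TissueProfile` holds the per-base, per-molecule de novo event rates
#' driving the simulator for one tissue: the six-class SNV rates, an In/Del
#' rate, the probability that an event is seeded as a heteroplasmic clone
#' (onto three or more molecules), the clone-size model, control-region
#' enrichment of clone placement, and the strand-specific oxidative damage
#' rate.
#'
#' @param class_rates Named numeric of length 6 (names from [SNV_CLASSES]):
#'   per-base per-molecule de novo rate of each SNV class. Somatic mtDNA
#'   rates are of order 1e-7 to 1e-6 per base.
#' @param indel_rate Per-base per-molecule rate of small (<= 15 bp) In/Dels;
#'   roughly 10-fold below the summed SNV rate in real tissue.
#' @param clonal_fraction Probability that a mutation event is seeded onto
#'   `k >= 3` molecules (a heteroplasmic clone) rather than 1-2.
#' @param clone_size_mean Mean of the clone-size distribution
#'   `k = 3 + Poisson(clone_size_mean - 3)`.
#' @param cr_enrichment Multiplier (>= 1) for clone placement inside the
#'   control region, where clones cluster in real tissues.
#' @param damage_rate Per-G-site probability of a strand-specific lesion
#'   (8-oxo-dG-like) that miscodes as G>T during copying; such lesions
#'   appear in single-strand consensus but not duplex consensus.
#' @param p_double Probability that a non-clonal event is present on 2
#'   molecules instead of 1.
#' @param name Optional tissue name.
#' @return A `TissueProfile` list.
#' @export
tissue_profile <- function(class_rates, indel_rate = 0,
                           clonal_fraction = 0, clone_size_mean = 5,
                           cr_enrichment = 1, damage_rate = 0,
                           p_double = 0.05, name = NA_character_) {
  if (is.null(names(class_rates))) names(class_rates) <- SNV_CLASSES
  if (!setequal(names(class_rates), SNV_CLASSES)) {
    stopf("class_rates must be named by the 6 spectrum classes")
  }
  class_rates <- class_rates[SNV_CLASSES]
  rates <- c(class_rates, indel_rate, damage_rate)
  if (any(rates < 0) || any(rates > 1)) stopf("rates must lie in [0, 1]")
  if (clonal_fraction < 0 || clonal_fraction > 1) {
    stopf("clonal_fraction must lie in [0, 1]")
  }
  if (cr_enrichment < 1) stopf("cr_enrichment must be >= 1")
  if (clone_size_mean < 3) stopf("clone_size_mean must be >= 3")
  structure(
    list(class_rates = class_rates, indel_rate = indel_rate,
         clonal_fraction = clonal_fraction, clone_size_mean = clone_size_mean,
         cr_enrichment = cr_enrichment, damage_rate = damage_rate,
         p_double = p_double, name = name),
    class = "TissueProfile"
  )
}

#' Preset aged-mouse tissue profiles
#'
#' Eight tissue profiles emulating an aged (26-month) mouse cohort: overall
#' SNV rates of order 1e-6 per base (kidney highest, heart lowest), spectra
#' dominated by G>A/C>T transitions, elevated ROS-linked transversion shares
#' in heart and skeletal muscle, In/Del rates ~10-fold below SNVs, and
#' per-tissue clonality anchored at the reported values (kidney ~10.4%,
#' liver/retina ~5.6%, remaining tissues 2-3%).
#'
#' @return Named list of eight [tissue_profile()] objects.
#' @export
preset_tissue_profiles <- function() {
  total <- c(kidney = 6.60e-6, liver = 4.50e-6, rpe_choroid = 3.50e-6,
             hippocampus = 3.05e-6, retina = 3.00e-6, cerebellum = 2.50e-6,
             muscle = 2.20e-6, heart = 1.74e-6)
  spectra <- rbind(
    kidney      = c(0.60, 0.19, 0.09, 0.04, 0.06, 0.02),
    liver       = c(0.62, 0.20, 0.07, 0.03, 0.06, 0.02),
    rpe_choroid = c(0.58, 0.23, 0.08, 0.04, 0.05, 0.02),
    hippocampus = c(0.60, 0.23, 0.08, 0.04, 0.04, 0.01),
    retina      = c(0.62, 0.21, 0.08, 0.04, 0.04, 0.01),
    cerebellum  = c(0.52, 0.21, 0.15, 0.07, 0.04, 0.01),
    muscle      = c(0.54, 0.17, 0.18, 0.07, 0.03, 0.01),
    heart       = c(0.46, 0.17, 0.23, 0.11, 0.02, 0.01)
  )
  colnames(spectra) <- SNV_CLASSES
  clonality <- c(kidney = 0.104, liver = 0.056, rpe_choroid = 0.030,
                 hippocampus = 0.025, retina = 0.056, cerebellum = 0.025,
                 muscle = 0.030, heart = 0.020)
  out <- lapply(names(total), function(t) {
    # The anchors are observed frequencies, which include clonal
    # amplification: divide by the expected molecule multiplicity so the
    # recovered frequency, not the seeding rate, matches the anchor.
    ek <- (1 - clonality[[t]]) * 1.05 + clonality[[t]] * 5
    tissue_profile(
      class_rates = total[[t]] * spectra[t, ] / ek,
      indel_rate = total[[t]] / 10 / ek,
      clonal_fraction = clonality[[t]],
      cr_enrichment = 5,
      name = t
    )
  })
  names(out) <- names(total)
  out
}

# Expected molecule multiplicity E[k] of one event under a profile.
expected_multiplicity <- function(profile) {
  uniq <- 1 + profile$p_double
  clon <- profile$clone_size_mean
  (1 - profile$clonal_fraction) * uniq + profile$clonal_fraction * clon
}

#' Expected per-class mutation frequency under a profile
#'
#' Closed-form expectation of the per-class variant-read frequency the
#' pipeline recovers from a simulated sample: de novo rate times expected
#' molecule multiplicity. Used as the oracle in parameter-recovery checks.
#'
#' @param profile A [tissue_profile()].
#' @return Named numeric of 6 expected class frequencies.
#' @export
expected_class_frequency <- function(profile) {
  profile$class_rates * expected_multiplicity(profile)
}

# Variance of the recovered per-class frequency estimate at a given constant
# sequencing depth: compound-Poisson event counts with binomially sampled
# per-event read support.
class_frequency_variance <- function(profile, reference, n_molecules, depth) {
  L <- reference$length
  lam <- profile$class_rates * L * n_molecules
  # Moments of per-event read support X ~ Binom(depth, k / N), k mixed over
  # the multiplicity distribution.
  ex2_for_k <- function(k) {
    p <- k / n_molecules
    depth * p * (1 - p) + (depth * p)^2
  }
  p2 <- profile$p_double
  cf <- profile$clonal_fraction
  # clone sizes: 3 + Poisson(m - 3); E[k^2] = Var + mean^2 = (m-3) + m^2
  m <- profile$clone_size_mean
  ex2 <- (1 - cf) * ((1 - p2) * ex2_for_k(1) + p2 * ex2_for_k(2)) +
    cf * (depth^2 / n_molecules^2 * ((m - 3) + m^2) +
            depth / n_molecules * m)  # approx E[d p (1-p)] ~ d E[k]/N
  lam * ex2 / (L * depth)^2
}
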