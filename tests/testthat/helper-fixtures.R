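# Small fixtures shared across test files, built in code.

test_reference <- function(length = 3000L, seed = 11L) {
  build_reference(length = length, seed = seed)
}

flat_profile <- function(rate_total = 1.2e-4, clonal_fraction = 0,
                         indel_rate = 0, damage_rate = 0, ...) {
  tissue_profile(setNames(rep(rate_total / 6, 6), SNV_CLASSES),
                 indel_rate = indel_rate,
                 clonal_fraction = clonal_fraction,
                 damage_rate = damage_rate, name = "testtissue", ...)
}

# Hand-built read family: n copies of `seq` mapped at `start`.
make_family <- function(seqs, start = 101L, strand = "top",
                        umi = "U01-U02", indels = "") {
  data.frame(
    read_id = sprintf("r%03d", seq_along(seqs)),
    umi_pair = umi, strand = strand,
    start = start, end = start + nchar(seqs[1]) - 1L,
    seq = seqs, indels = indels, provenance = "", fragment_id = 1L)
}

# Flagged call table from bare columns, as call_variants would emit.
as_call_table <- function(d) {
  d$vaf <- d$supporting_reads / d$depth
  d$six_class <- ifelse(grepl("^(ins|del)", d$alt), "indel",
                        classify_snv_safe(d$ref, d$alt))
  if (is.null(d$indel_length)) d$indel_length <- 0L
  for (flag in c("masked", "numt_removed", "inherited", "high_vaf",
                 "low_depth")) {
    d[[flag]] <- FALSE
  }
  d$long_indel <- d$six_class == "indel" & d$indel_length > 15L
  d
}

classify_snv_safe <- function(ref, alt) {
  out <- rep(NA_character_, length(ref))
  ok <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  if (any(ok)) out[ok] <- classify_snv(ref[ok], alt[ok])
  out
}

extdata <- function(file) {
  system.file("extdata", file, package = "duplexmt", mustWork = TRUE)
}

load_toy_calls <- function() {
  as_call_table(read.delim(extdata("toy_calls.tsv")))
}

load_synthetic_cohort <- function() {
  read.delim(extdata("aged_cohort_clone_inputs_synthetic.tsv"),
             check.names = FALSE)
}
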