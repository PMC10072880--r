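#!/usr/bin/env Rscript
# Stage 3: call variants on full-scale duplex pileups for the aged cohort
# and apply the somatic filter chain (masked regions, VAF/depth cutoffs);
# demonstrates the NUMT and inherited-variant contracts on the packaged
# fixture.
suppressPackageStartupMessages(library(duplexmt))

dir.create("results", showWarnings = FALSE)
ref <- build_reference(length = 16299, seed = 1)
profiles <- preset_tissue_profiles()
cohort <- run_cohort(ref, profiles, n_molecules = 10000, depth = 10000,
                     seed = 500)

all_calls <- do.call(rbind, lapply(cohort, function(s) s$calls))
cat(sprintf("called %d variants across %d tissues; %d somatic after filters\n",
            nrow(all_calls), length(cohort), sum(is_somatic(all_calls))))
write_calls_tsv(all_calls, "results/cohort_calls.tsv")
write_calls_vcf(cohort$kidney$calls, "results/kidney_calls.vcf",
                contig_length = ref$length)

# Filter demonstration on the packaged 12-call fixture
toy <- read.delim(system.file("extdata", "toy_calls.tsv",
                              package = "duplexmt"))
toy$vaf <- toy$supporting_reads / toy$depth
toy$six_class <- ifelse(grepl("^(ins|del)", toy$alt), "indel",
                        classify_snv(ifelse(grepl("^(ins|del)", toy$alt),
                                            "G", toy$ref),
                                     ifelse(grepl("^(ins|del)", toy$alt),
                                            "A", toy$alt)))
for (f in c("masked", "numt_removed", "inherited", "high_vaf", "low_depth"))
  toy[[f]] <- FALSE
toy$long_indel <- toy$six_class == "indel" & toy$indel_length > 15L

keep <- numt_filter(read.delim(system.file(
  "extdata", "toy_numt_alignments.tsv", package = "duplexmt")))
support <- read.delim(system.file(
  "extdata", "toy_numt_support.tsv", package = "duplexmt"))
toy <- apply_numt_filter(toy, support, keep)
toy <- apply_masks(toy, ref)
toy <- remove_inherited(toy, c(k1 = "m1", l1 = "m1", h1 = "m1"))
toy <- somatic_filter(toy)
cat(sprintf("\ntoy fixture: %d of %d focal-sample calls survive the filters\n",
            sum(toy$sample_id == "k1" & is_somatic(toy)),
            sum(toy$sample_id == "k1")))
write_calls_tsv(toy, "results/toy_filtered_calls.tsv")
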