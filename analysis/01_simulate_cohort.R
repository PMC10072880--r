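#!/usr/bin/env Rscript
# Stage 1: build the synthetic reference and the aged-cohort molecule pools,
# and write a small read-family library to disk for the consensus stage.
suppressPackageStartupMessages(library(duplexmt))

dir.create("results", showWarnings = FALSE)
dir.create("results/simdata", showWarnings = FALSE)

ref <- build_reference(length = 16299, seed = 1)
write_reference(ref, "results/simdata/reference.fa",
                "results/simdata/reference.bed")
cat(sprintf("reference: %d bp, OriL %d-%d, %d masked intervals\n",
            ref$length, ref$ori_l[["start"]], ref$ori_l[["end"]],
            nrow(ref$masked_intervals)))

profiles <- preset_tissue_profiles()
cat(sprintf("simulating %d tissues at 10,000 molecules each\n",
            length(profiles)))
pools <- lapply(seq_along(profiles), function(i) {
  simulate_sample(ref, profiles[[i]], 10000, seed = 100 + i)
})
names(pools) <- names(profiles)
ev <- do.call(rbind, lapply(names(pools), function(nm) {
  e <- pools[[nm]]$events
  data.frame(tissue = nm, n_events = nrow(e), n_clonal = sum(e$clonal),
             n_indel = sum(e$is_indel))
}))
write.table(ev, "results/simdata/event_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(ev)

# A read-level library for one small region-scale sample: used by stage 2
# to demonstrate consensus error correction with damage injected.
small_ref <- build_reference(length = 3000, seed = 2)
write_reference(small_ref, "results/simdata/small_reference.fa")
prof <- profiles$heart
prof$class_rates <- setNames(rep(2e-5, 6), SNV_CLASSES)  # region-scale rates
pool <- simulate_sample(small_ref, prof, 200, seed = 3)
reads <- simulate_read_families(pool, small_ref, target_depth = 40,
                                family_size_mean = 4, pcr_error = 0.001,
                                seq_error = 0.005, damage_rate = 0.01,
                                seed = 4)
write_read_families(reads, "results/simdata/families.fq",
                    "results/simdata/families_tags.tsv")
cat(sprintf("wrote %d reads in %d families with damage injected\n",
            nrow(reads), length(group_families(reads))))
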