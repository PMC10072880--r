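test_that("default reference layout places OriL at 5160-5191 and is deterministic", {
  ref <- build_reference(length = 16299, seed = 7)
  expect_equal(unname(ref$ori_l), c(5160L, 5191L))
  expect_equal(nchar(ref$sequence), 16299L)
  expect_true(ref$control_region[["end"]] == 16299L)
  expect_true(all(strsplit(ref$sequence, "")[[1]] %in% c("A", "C", "G", "T")))

  ref2 <- build_reference(length = 16299, seed = 7)
  expect_identical(ref$sequence, ref2$sequence)
  ref3 <- build_reference(length = 16299, seed = 8)
  expect_false(identical(ref$sequence, ref3$sequence))
})

test_that("realized GC fraction tracks the requested fraction", {
  for (gc in c(0.37, 0.40, 0.55)) {
    ref <- build_reference(length = 16299, gc_fraction = gc, seed = 3)
    bases <- strsplit(ref$sequence, "")[[1]]
    expect_lt(abs(mean(bases %in% c("G", "C")) - gc), 0.02)
  }
})

test_that("invalid reference configurations are rejected", {
  expect_error(build_reference(length = 500), "length")
  expect_error(build_reference(gc_fraction = 1.2), "gc_fraction")
  spec <- default_feature_spec(16299L)
  spec$masked_intervals <- data.frame(start = c(100L, 105L),
                                      end = c(110L, 120L))
  expect_error(build_reference(feature_spec = spec), "overlap")
})

test_that("zero rates produce an empty molecule pool", {
  ref <- test_reference()
  prof <- flat_profile(rate_total = 0)
  pool <- simulate_sample(ref, prof, 100, seed = 1)
  expect_equal(nrow(pool$events), 0L)
})

test_that("event counts are Poisson around rate * L * N", {
  # Dominant-class rate 5e-6 over 16,299 bases and 10,000 molecules gives
  # lambda ~ 815; a single draw must fall within 3 sqrt(lambda).
  ref <- build_reference(length = 16299, seed = 5)
  rates <- setNames(c(5e-6, 0, 0, 0, 0, 0), SNV_CLASSES)
  prof <- tissue_profile(rates, name = "ga")
  pool <- simulate_sample(ref, prof, 10000, seed = 41)
  lambda <- 5e-6 * 16299 * 10000
  n <- sum(pool$events$class == "G>A/C>T")
  expect_lt(abs(n - lambda), 3 * sqrt(lambda))
  expect_true(all(pool$events$ref %in% c("G", "C")))
  expect_true(all(pool$events$alt == ifelse(pool$events$ref == "G", "A", "T")))
})

test_that("clonal fraction of seeded events falls in its binomial band", {
  ref <- test_reference(length = 5000)
  prof <- flat_profile(rate_total = 6e-4, clonal_fraction = 0.1)
  pool <- simulate_sample(ref, prof, 400, seed = 9)
  n <- nrow(pool$events)
  expect_gt(n, 500)
  frac <- mean(pool$events$k >= 3)
  half <- qnorm(0.995) * sqrt(0.1 * 0.9 / n)
  expect_lt(abs(frac - 0.1), half)
  # clonal events have k >= 3; non-clonal 1 or 2
  expect_true(all(pool$events$k[pool$events$clonal] >= 3))
  expect_true(all(pool$events$k[!pool$events$clonal] %in% c(1L, 2L)))
  # multiplicity bookkeeping: each event's molecule list has k members
  expect_equal(lengths(pool$events$molecules), pool$events$k)
})

test_that("clone placement is enriched in the control region", {
  ref <- test_reference(length = 8000)
  prof <- flat_profile(rate_total = 8e-4, clonal_fraction = 0.5,
                       cr_enrichment = 20)
  pool <- simulate_sample(ref, prof, 300, seed = 3)
  cr <- ref$control_region
  in_cr <- function(p) p >= cr[["start"]] & p <= cr[["end"]]
  cr_frac_len <- (cr[["end"]] - cr[["start"]] + 1) / ref$length
  clonal <- pool$events[pool$events$clonal & !pool$events$is_indel, ]
  uniq <- pool$events[!pool$events$clonal & !pool$events$is_indel, ]
  expect_gt(mean(in_cr(clonal$position)), 3 * cr_frac_len)
  expect_lt(mean(in_cr(uniq$position)), 3 * cr_frac_len)
})

test_that("excessive rates are a configuration error", {
  ref <- test_reference()
  prof <- flat_profile(rate_total = 0.6)
  expect_error(simulate_sample(ref, prof, 100, seed = 1), "expected event")
})

test_that("read families have the configured mean size and valid structure", {
  ref <- test_reference(length = 2000)
  prof <- flat_profile(rate_total = 0)
  pool <- simulate_sample(ref, prof, 50, seed = 2)
  reads <- simulate_read_families(pool, ref, target_depth = 150,
                                  family_size_mean = 5, seed = 4)
  fams <- group_families(reads)
  sizes <- vapply(fams, nrow, 1L)
  expect_gte(length(sizes), 1000L)
  expect_lt(abs(mean(sizes) - 5) / 5, 0.05)
  expect_true(all(sizes >= 1L))
  # within a family all reads agree on the tag fields
  one <- fams[[which.max(sizes)]]
  expect_equal(length(unique(one$umi_pair)), 1L)
  expect_equal(length(unique(one$start)), 1L)
})

test_that("simulated reads are deterministic given (config, seed)", {
  ref <- test_reference(length = 1500)
  prof <- flat_profile(rate_total = 2e-4, indel_rate = 2e-5,
                       clonal_fraction = 0.1, damage_rate = 0.01)
  pool1 <- simulate_sample(ref, prof, 80, seed = 5)
  pool2 <- simulate_sample(ref, prof, 80, seed = 5)
  expect_identical(pool1$events, pool2$events)
  r1 <- simulate_read_families(pool1, ref, 20, seq_error = 0.01, seed = 6)
  r2 <- simulate_read_families(pool2, ref, 20, seq_error = 0.01, seed = 6)
  expect_identical(r1, r2)
})

test_that("every variant-bearing read traces to an event or error process", {
  ref <- test_reference(length = 2000)
  prof <- flat_profile(rate_total = 3e-4)
  pool <- simulate_sample(ref, prof, 60, seed = 12)
  reads <- simulate_read_families(pool, ref, 25, pcr_error = 0.002,
                                  seq_error = 0.004, damage_rate = 0.01,
                                  seed = 13)
  bases <- strsplit(ref$sequence, "")[[1]]
  L <- ref$length
  for (i in sample.int(nrow(reads), 200)) {
    rd <- strsplit(reads$seq[i], "")[[1]]
    pos <- ((reads$start[i] + seq_along(rd) - 1L - 1L) %% L) + 1L
    mism <- which(rd != bases[pos])
    if (!length(mism)) next
    prov <- reads$provenance[i]
    tagged <- as.integer(unlist(regmatches(
      prov, gregexpr("(?<=:)[0-9]+", prov, perl = TRUE))))
    expect_true(all(pos[mism] %in% tagged),
                info = sprintf("read %s has untraced mismatches", reads$read_id[i]))
  }
})

test_that("variant read fraction converges to the k-weighted event frequency", {
  ref <- build_reference(length = 16299, seed = 21)
  prof <- flat_profile(rate_total = 3e-6, clonal_fraction = 0.1)
  pool <- simulate_sample(ref, prof, 10000, seed = 22)
  pu <- sample_pileup(pool, ref, depth = 10000, seed = 23)
  calls <- call_variants(pu, ref)
  got <- sum(calls$supporting_reads[calls$six_class != "indel"]) /
    sum(as.numeric(pileup_depth(pu)))
  # truth for this realized pool: sum of k over events / (L * N)
  truth <- sum(pool$events$k[!pool$events$is_indel]) / (16299 * 10000)
  # binomial sampling error of the supporting-read total, Var ~ sum(k)
  se <- sqrt(sum(pool$events$k[!pool$events$is_indel])) / (16299 * 10000)
  expect_lt(abs(got - truth), 3 * se + 1e-12)
})

test_that("simulation round-trips through FASTA/BED and FASTQ/TSV files", {
  ref <- test_reference(length = 2000)
  tmp <- withr::local_tempdir()
  fa <- file.path(tmp, "ref.fa"); bed <- file.path(tmp, "ref.bed")
  write_reference(ref, fa, bed)
  back <- read_reference(fa, bed)
  expect_identical(back$sequence, ref$sequence)
  expect_equal(unname(back$ori_l), unname(ref$ori_l))
  expect_equal(back$masked_intervals$start, ref$masked_intervals$start)
  expect_equal(unname(back$control_region), unname(ref$control_region))

  prof <- flat_profile(rate_total = 2e-4, indel_rate = 3e-5)
  pool <- simulate_sample(ref, prof, 50, seed = 31)
  reads <- simulate_read_families(pool, ref, 10, seed = 32)
  fq <- file.path(tmp, "reads.fq"); tags <- file.path(tmp, "reads.tsv")
  write_read_families(reads, fq, tags)
  back_reads <- read_read_families(fq, tags)
  expect_equal(nrow(back_reads), nrow(reads))
  i <- match(reads$read_id, back_reads$read_id)
  expect_identical(back_reads$seq[i], reads$seq)
  expect_identical(back_reads$umi_pair[i], reads$umi_pair)
})

test_that("a YAML configuration reconstructs tissue profiles", {
  cfg <- read_sim_config(extdata("sim_config.yaml"))
  expect_named(cfg$profiles, c("kidney_like", "heart_like"))
  expect_s3_class(cfg$profiles$kidney_like, "TissueProfile")
  expect_equal(cfg$profiles$kidney_like$clonal_fraction, 0.104)
  expect_equal(unname(cfg$profiles$heart_like$class_rates[1]), 6.4e-7)
})
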