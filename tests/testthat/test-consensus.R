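test_that("family grouping is a partition keyed by UMI, strand and coordinates", {
  a <- make_family(rep("ACGT", 3), start = 10L, umi = "U01-U02")
  b <- make_family(rep("ACGT", 7), start = 20L, umi = "U01-U02")
  reads <- rbind(a, b)
  reads$read_id <- sprintf("r%02d", seq_len(nrow(reads)))
  fams <- group_families(reads)
  expect_length(fams, 2L)
  expect_equal(sum(vapply(fams, nrow, 1L)), 10L)
  # same UMI pair at different start -> distinct families
  expect_setequal(vapply(fams, function(f) f$start[1], 1L), c(10L, 20L))
  # empty stream
  expect_length(group_families(reads[0, ]), 0L)
  # read without a tag entry is an input error naming the read
  reads$umi_pair[3] <- NA
  expect_error(group_families(reads), reads$read_id[3])
})

test_that("SSCS majority calling honours min_reads, agreement and ties", {
  fam <- make_family(rep("ACGTT", 3))
  rec <- build_sscs(fam, min_reads = 3, agreement = 0.7)
  expect_equal(rec$consensus, "ACGTT")
  expect_equal(rec$family_size, 3L)

  expect_null(build_sscs(make_family(rep("ACGTT", 2)), min_reads = 3))

  # 3 A vs 2 G at position 1: fraction 0.6 < 0.7 -> N
  fam <- make_family(c("AAT", "AAT", "AAT", "GAT", "GAT"))
  rec <- build_sscs(fam, min_reads = 3, agreement = 0.7)
  expect_equal(substr(rec$consensus, 1, 1), "N")
  expect_equal(substr(rec$consensus, 2, 3), "AT")

  # exact tie resolves to N even at agreement 0.5 equivalents
  fam <- make_family(c("AT", "GT", "AT", "GT"))
  rec <- build_sscs(fam, min_reads = 2, agreement = 0.51)
  expect_equal(substr(rec$consensus, 1, 1), "N")
})

test_that("DCS emits agreement bases and N elsewhere", {
  top <- build_sscs(make_family(rep("ACGT", 3), strand = "top"), 3, 0.7)
  bottom <- build_sscs(make_family(rep("ACGT", 3), strand = "bottom"), 3, 0.7)
  dcs <- build_dcs(top, bottom)
  expect_equal(dcs$consensus, "ACGT")

  bottom2 <- build_sscs(make_family(rep("ACGG", 3), strand = "bottom"), 3, 0.7)
  dcs2 <- build_dcs(top, bottom2)
  expect_equal(dcs2$consensus, "ACGN")

  # N on either strand propagates
  topN <- top; topN$consensus <- "ACNT"
  expect_equal(build_dcs(topN, bottom)$consensus, "ACNT")

  # mismatched keys are a logic error
  shifted <- bottom; shifted$start <- shifted$start + 1L; shifted$end <- shifted$end + 1L
  expect_error(build_dcs(top, shifted), "share")
})

test_that("end clipping removes the configured margins from pileups", {
  ref <- test_reference(length = 2000)
  cons <- paste(rep("A", 300), collapse = "")
  rec <- structure(list(umi_pair = "U01-U02", start = 101L, end = 400L,
                        consensus = cons, clip_applied = 0L,
                        indels = character(0)), class = "DCSRecord")
  clipped <- clip_ends(rec, 10)
  pu <- make_pileup(list(clipped), ref)
  expect_equal(sum(pileup_depth(pu)), 280L)
  expect_equal(sum(pileup_depth(pu)[101:110]), 0L)
  # clip 0 is the identity
  expect_equal(clip_ends(rec, 0)$consensus, cons)
  # over-clipping is an input error
  expect_error(clip_ends(rec, 150), "clip")
})

test_that("a variant seeded near a fragment end is clipped out of the pileup", {
  ref <- test_reference(length = 2000)
  prof <- flat_profile(rate_total = 0)
  pool <- simulate_sample(ref, prof, 10, seed = 1)
  # place one variant 5 bp from the fragment end by hand
  frag_start <- 501L
  vpos <- frag_start + 295L  # offset 296 of 300, inside the 10 bp margin
  vref <- substr(ref$sequence, vpos, vpos)
  valt <- setdiff(c("A", "C", "G", "T"), vref)[1]
  pool$events <- data.frame(position = vpos, ref = vref, alt = valt,
                            k = 10L, is_indel = FALSE, indel_length = 0L,
                            class = classify_snv(vref, valt), clonal = TRUE)
  pool$events$molecules <- list(1:10)
  reads <- simulate_read_families(pool, ref, target_depth = 2, seed = 2)
  # keep only the hand-placed fragment's coordinates
  reads <- reads[reads$start == reads$start[1] & FALSE | TRUE, ]
  reads$start <- frag_start; reads$end <- frag_start + 299L
  # rebuild sequences for the forced coordinates
  base <- strsplit(ref_fragment(ref, frag_start, 300L), "")[[1]]
  base[296] <- valt
  reads$seq <- paste(base, collapse = "")
  cons <- duplex_consensus(reads, ref, clip_len = 10)
  calls <- call_variants(cons$dcs_pileup, ref)
  expect_false(vpos %in% calls$position)
  cons0 <- duplex_consensus(reads, ref, clip_len = 0)
  calls0 <- call_variants(cons0$dcs_pileup, ref)
  expect_true(vpos %in% calls0$position)
})

test_that("pileup tallies match a brute-force per-position oracle", {
  ref <- test_reference(length = 1000)
  prof <- flat_profile(rate_total = 5e-4)
  pool <- simulate_sample(ref, prof, 30, seed = 7)
  reads <- simulate_read_families(pool, ref, target_depth = 8,
                                  fragment_length = 60, seq_error = 0.01,
                                  seed = 8)
  cons <- duplex_consensus(reads, ref, clip_len = 3)
  for (layer in c("sscs", "dcs")) {
    recs <- cons[[paste0(layer, "_records")]]
    pu <- cons[[paste0(layer, "_pileup")]]
    expect_identical(unname(pu$counts),
                     unname(oracle_pileup_tally(recs, ref$length)))
  }
  # conservation: total non-N DCS bases equals summed DCS depth
  emitted <- sum(vapply(cons$dcs_records, function(r) {
    sum(strsplit(r$consensus, "")[[1]] != "N")
  }, 1L))
  expect_equal(emitted, sum(pileup_depth(cons$dcs_pileup)))
})

test_that("circular fragments wrap the origin in pileups", {
  ref <- test_reference(length = 1000)
  ref_seq <- ref$sequence
  rec <- structure(list(umi_pair = "U01-U02", start = 981L, end = 1020L,
                        consensus = paste0(substr(ref_seq, 981, 1000),
                                           substr(ref_seq, 1, 20)),
                        clip_applied = 0L, indels = character(0)),
                   class = "DCSRecord")
  pu <- make_pileup(list(rec), ref)
  expect_equal(sum(pileup_depth(pu)[981:1000]), 20L)
  expect_equal(sum(pileup_depth(pu)[1:20]), 20L)
  expect_equal(call_variants(pu, ref)$position, integer(0))
})

test_that("error rates are suppressed in the order raw >= SSCS >= DCS", {
  ref <- test_reference(length = 2000)
  prof <- flat_profile(rate_total = 0)
  pool <- simulate_sample(ref, prof, 50, seed = 3)
  reads <- simulate_read_families(pool, ref, target_depth = 40,
                                  family_size_mean = 5, pcr_error = 0.002,
                                  seq_error = 0.01, seed = 4)
  bases <- strsplit(ref$sequence, "")[[1]]
  # raw error rate from the reads themselves
  L <- ref$length
  mism <- 0L; tot <- 0L
  for (i in seq_len(nrow(reads))) {
    rd <- strsplit(reads$seq[i], "")[[1]]
    pos <- ((reads$start[i] + seq_along(rd) - 2L) %% L) + 1L
    mism <- mism + sum(rd != bases[pos])
    tot <- tot + length(rd)
  }
  raw_rate <- mism / tot
  cons <- duplex_consensus(reads, ref, clip_len = 0)
  layer_rate <- function(pu) {
    alt <- sum(pu$counts[cbind(seq_len(L), match(bases, c("A","C","G","T")))])
    1 - alt / sum(pileup_depth(pu))
  }
  sscs_rate <- layer_rate(cons$sscs_pileup)
  dcs_rate <- layer_rate(cons$dcs_pileup)
  expect_gt(raw_rate, sscs_rate)
  expect_gt(sscs_rate, dcs_rate)
  expect_lt(dcs_rate, 1e-3)
})

test_that("strand-specific damage survives SSCS but never DCS", {
  ref <- test_reference(length = 2000)
  prof <- flat_profile(rate_total = 0)
  pool <- simulate_sample(ref, prof, 50, seed = 5)
  reads <- simulate_read_families(pool, ref, target_depth = 40,
                                  family_size_mean = 4, damage_rate = 0.01,
                                  seed = 6)
  cons <- duplex_consensus(reads, ref, clip_len = 0)
  bases <- strsplit(ref$sequence, "")[[1]]
  # G>T on the reference strand: T calls at G sites, A calls at C sites
  sscs_gt <- sum(cons$sscs_pileup$counts[bases == "G", "T"]) +
    sum(cons$sscs_pileup$counts[bases == "C", "A"])
  dcs_gt <- sum(cons$dcs_pileup$counts[bases == "G", "T"]) +
    sum(cons$dcs_pileup$counts[bases == "C", "A"])
  expect_gt(sscs_gt, 0)
  expect_equal(dcs_gt, 0)
  # with damage off, the two layers agree wherever DCS has coverage
  reads0 <- simulate_read_families(pool, ref, target_depth = 40,
                                   family_size_mean = 4, seed = 7)
  cons0 <- duplex_consensus(reads0, ref, clip_len = 0)
  expect_equal(sum(cons0$sscs_pileup$counts[bases == "G", "T"]), 0)
  expect_equal(sum(cons0$dcs_pileup$counts[bases == "G", "T"]), 0)
})

test_that("In/Del alleles require both strands and reach the pileup", {
  fam_t <- make_family(rep("ACGT", 3), strand = "top", indels = "102:2:del")
  fam_b <- make_family(rep("ACGT", 3), strand = "bottom", indels = "102:2:del")
  top <- build_sscs(fam_t, 3, 0.7); bottom <- build_sscs(fam_b, 3, 0.7)
  dcs <- build_dcs(top, bottom)
  expect_equal(dcs$indels, "102:2:del")
  # one-strand In/Del is dropped at the duplex stage
  fam_b0 <- make_family(rep("ACGT", 3), strand = "bottom", indels = "")
  dcs0 <- build_dcs(top, build_sscs(fam_b0, 3, 0.7))
  expect_length(dcs0$indels, 0L)

  ref <- test_reference(length = 2000)
  pu <- make_pileup(list(dcs), ref)
  expect_equal(pu$indels$position, 102L)
  expect_equal(pu$indels$count, 1L)
  expect_equal(pu$indels$allele, "del2")
})
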