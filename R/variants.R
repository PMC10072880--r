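#' Call variants from a duplex-consensus pileup
#'
#' Emits one call per `(position, non-reference allele)` with at least one
#' supporting consensus read, so each type of mutation is scored only once
#' at each genome position. In/Del alleles of different lengths at one
#' position count as distinct alleles; In/Dels longer than 15 bp are flagged
#' for exclusion.
#'
#' @param pileup A DCS `Pileup` (see [make_pileup()] / [sample_pileup()]).
#' @param reference The matching `MitoReference`.
#' @param sample_id Sample label carried on every call.
#' @return data.frame of calls with columns `sample_id`, `position`, `ref`,
#'   `alt`, `supporting_reads`, `depth`, `vaf`, `six_class`, and logical
#'   flag columns `masked`, `numt_removed`, `inherited`, `high_vaf`,
#'   `low_depth`, `long_indel`.
#' @export
call_variants <- function(pileup, reference, sample_id = "sample") {
  if (!identical(pileup$layer, "DCS")) {
    stopf("variant calling expects a DCS pileup, got layer '%s'",
          pileup$layer)
  }
  bases <- strsplit(reference$sequence, "")[[1]]
  depth <- pileup_depth(pileup)
  calls <- list()
  for (b in BASES) {
    cnt <- pileup$counts[, b]
    hit <- which(cnt > 0L & bases != b)
    if (length(hit)) {
      calls[[b]] <- data.frame(
        position = hit, ref = bases[hit], alt = b,
        supporting_reads = cnt[hit], depth = depth[hit])
    }
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(position = integer(0), ref = character(0),
               alt = character(0), supporting_reads = integer(0),
               depth = integer(0))
  out$six_class <- if (nrow(out)) classify_snv(out$ref, out$alt) else
    character(0)
  out$indel_length <- rep(0L, nrow(out))

  ind <- pileup$indels
  if (!is.null(ind) && nrow(ind)) {
    agg <- stats::aggregate(count ~ position + allele + indel_length,
                            data = ind, FUN = sum)
    out <- rbind(out, data.frame(
      position = agg$position, ref = bases[agg$position],
      alt = agg$allele, supporting_reads = agg$count,
      depth = depth[agg$position], six_class = "indel",
      indel_length = agg$indel_length))
  }
  out <- out[order(out$position, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out$vaf <- ifelse(out$depth > 0, out$supporting_reads / out$depth, NA_real_)
  out$sample_id <- rep(sample_id, nrow(out))
  for (flag in c("masked", "numt_removed", "inherited", "high_vaf",
                 "low_depth")) {
    out[[flag]] <- rep(FALSE, nrow(out))
  }
  out$long_indel <- out$six_class == "indel" & out$indel_length > 15L
  cols <- c("sample_id", "position", "ref", "alt", "supporting_reads",
            "depth", "vaf", "six_class", "indel_length", "masked",
            "numt_removed", "inherited", "high_vaf", "low_depth",
            "long_indel")
  out[cols]
}

#' Flag calls inside masked regions
#'
#' Sets the `masked` flag for calls inside any masked interval or OriL;
#' these positions suffer alignment artifacts (short polynucleotide repeats)
#' or replication-origin structure and are excluded from all downstream
#' frequencies. Intervals are 1-based closed; boundaries are inclusive.
#'
#' @param calls A [call_variants()] table.
#' @param reference A `MitoReference`, or a data.frame of intervals with
#'   `start`/`end` columns (OriL is then not added automatically).
#' @return `calls` with the `masked` flag updated.
#' @export
apply_masks <- function(calls, reference) {
  iv <- if (inherits(reference, "MitoReference")) {
    iv0 <- reference$masked_intervals
    if (!is.null(reference$ori_l)) {
      iv0 <- rbind(iv0, data.frame(start = reference$ori_l[["start"]],
                                   end = reference$ori_l[["end"]]))
    }
    iv0
  } else {
    reference
  }
  calls$masked <- calls$masked | in_any_interval(calls$position, iv)
  calls
}

#' Decide read retention against candidate NUMT alignments
#'
#' For each read carrying a variant, compares the e-score of its original
#' mitochondrial alignment with every other candidate (nuclear) alignment:
#' the read is kept if and only if no non-mitochondrial candidate aligns
#' with a strictly lower e-score (exact ties keep the read). This encodes
#' the keep/drop contract for excluding reads that likely originate from
#' nuclear-embedded mitochondrial pseudogenes (NUMTs); running the aligner
#' itself is out of scope.
#'
#' @param alignments data.frame with columns `read_id`, `e_score`, and
#'   logical `is_original` marking the mitochondrial alignment; one or more
#'   rows per read.
#' @return data.frame with one row per read: `read_id`, `keep`.
#' @export
numt_filter <- function(alignments) {
  required <- c("read_id", "e_score", "is_original")
  if (!all(required %in% names(alignments))) {
    stopf("alignments need columns: %s", paste(required, collapse = ", "))
  }
  out <- lapply(split(alignments, alignments$read_id), function(d) {
    if (nrow(d) == 0L || !any(d$is_original)) {
      stopf("read %s lacks its original mitochondrial alignment",
            d$read_id[1])
    }
    orig <- min(d$e_score[d$is_original])
    others <- d$e_score[!d$is_original]
    data.frame(read_id = d$read_id[1],
               keep = !length(others) || min(others) >= orig)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Recompute call support after NUMT read removal
#'
#' Dropped reads decrement both the supporting-read count of the variants
#' they carried and the depth at the positions they covered; calls whose
#' support reaches zero are removed, and every call gets the `numt_removed`
#' flag when any of its supporting reads was dropped. Must run before VAF
#' filtering, since it changes the VAF denominator.
#'
#' @param calls A [call_variants()] table.
#' @param read_support data.frame linking reads to calls: columns
#'   `read_id`, `position`, `alt`.
#' @param keep A [numt_filter()] decision table.
#' @return `calls` with adjusted `supporting_reads`, `depth`, `vaf`.
#' @export
apply_numt_filter <- function(calls, read_support, keep) {
  dropped <- keep$read_id[!keep$keep]
  if (!length(dropped)) return(calls)
  lost <- read_support[read_support$read_id %in% dropped, , drop = FALSE]
  if (!nrow(lost)) return(calls)
  key <- paste(calls$position, calls$alt)
  lost_tab <- table(paste(lost$position, lost$alt))
  hit <- key %in% names(lost_tab)
  calls$supporting_reads[hit] <- calls$supporting_reads[hit] -
    as.integer(lost_tab[key[hit]])
  calls$numt_removed[hit] <- TRUE
  # each dropped read also reduces depth at its call position
  depth_tab <- table(lost$position)
  pos_hit <- match(calls$position, as.integer(names(depth_tab)))
  adj <- ifelse(is.na(pos_hit), 0L, as.integer(depth_tab)[pos_hit])
  calls$depth <- calls$depth - adj
  calls <- calls[calls$supporting_reads > 0L, , drop = FALSE]
  calls$vaf <- calls$supporting_reads / calls$depth
  rownames(calls) <- NULL
  calls
}

#' Flag variants inherited within an animal
#'
#' A `(position, alt)` present in every sequenced sample of one animal
#' indicates an inherited (or early developmental) variant rather than a
#' somatic one; it is flagged `inherited` in all samples of that animal and
#' excluded downstream. Animals contributing a single sample trigger a
#' warning and are left untouched.
#'
#' @param calls Combined call table across samples (column `sample_id`).
#' @param animals Named character vector mapping `sample_id` to animal id.
#' @return `calls` with the `inherited` flag updated.
#' @export
remove_inherited <- function(calls, animals) {
  if (!nrow(calls)) return(calls)
  unknown <- setdiff(unique(calls$sample_id), names(animals))
  if (length(unknown)) {
    stopf("samples without an animal assignment: %s",
          paste(unknown, collapse = ", "))
  }
  calls$.animal <- unname(animals[calls$sample_id])
  for (an in unique(calls$.animal)) {
    samples <- unique(names(animals)[animals == an])
    if (length(samples) < 2L) {
      warning(sprintf("animal '%s' has a single sample; inherited-variant removal skipped", an),
              call. = FALSE)
      next
    }
    sub <- calls$.animal == an
    key <- paste(calls$position[sub], calls$alt[sub])
    n_samples <- tapply(calls$sample_id[sub], key,
                        function(s) length(unique(s)))
    shared <- names(n_samples)[n_samples == length(samples)]
    calls$inherited[sub] <- calls$inherited[sub] | key %in% shared
  }
  calls$.animal <- NULL
  calls
}

#' Apply the somatic VAF/depth cutoff
#'
#' Flags calls with VAF strictly above `vaf_max` (default 1%, removing
#' high-heteroplasmy variants that could be inherited or early
#' developmental) as `high_vaf`, and calls at positions with depth strictly
#' below `min_depth` (default 100) as `low_depth`. Both are excluded from
#' frequency computations; boundary values (VAF exactly 1%, depth exactly
#' 100) are retained.
#'
#' @param calls A call table.
#' @param vaf_max Maximum retained VAF (exclusive cutoff above).
#' @param min_depth Minimum retained depth (exclusive cutoff below).
#' @return `calls` with `high_vaf` / `low_depth` flags updated.
#' @export
somatic_filter <- function(calls, vaf_max = 0.01, min_depth = 100L) {
  if (vaf_max <= 0 || vaf_max > 1) stopf("vaf_max must lie in (0, 1]")
  calls$high_vaf <- calls$high_vaf | calls$vaf > vaf_max
  calls$low_depth <- calls$low_depth | calls$depth < min_depth
  calls
}

#' Somatic subset of a call table
#'
#' Calls carrying none of the exclusion flags (masked, NUMT-removed beyond
#' support loss, inherited, high VAF, low depth, over-long In/Del).
#'
#' @param calls A flagged call table.
#' @return Logical vector marking somatic calls.
#' @export
is_somatic <- function(calls) {
  !(calls$masked | calls$inherited | calls$high_vaf | calls$low_depth |
      calls$long_indel)
}

#' Run the standard filter chain on one sample's calls
#'
#' Masked-region flags, then the somatic VAF/depth cutoff (the NUMT and
#' inherited-variant filters need cross-read or cross-sample evidence and
#' are applied separately when available).
#'
#' @inheritParams apply_masks
#' @inheritParams somatic_filter
#' @return Flagged call table.
#' @export
filter_calls <- function(calls, reference, vaf_max = 0.01,
                         min_depth = 100L) {
  calls <- apply_masks(calls, reference)
  somatic_filter(calls, vaf_max = vaf_max, min_depth = min_depth)
}
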