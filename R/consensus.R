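#' Group tagged reads into duplex families
#'
#' Partitions a read table into families keyed by
#' `(umi_pair, strand, start, end)`; every read belongs to exactly one
#' family.
#'
#' @param reads data.frame as emitted by [simulate_read_families()] or read
#'   back with [read_read_families()]; must carry `read_id`, `umi_pair`,
#'   `strand`, `start`, `end`, `seq`.
#' @return Named list of per-family data.frames; names are the family keys.
#' @export
group_families <- function(reads) {
  required <- c("read_id", "umi_pair", "strand", "start", "end", "seq")
  missing_col <- setdiff(required, names(reads))
  if (length(missing_col)) {
    stopf("read table lacks columns: %s", paste(missing_col, collapse = ", "))
  }
  if (nrow(reads) == 0L) return(structure(list(), names = character(0)))
  bad <- !complete.cases(reads[required])
  if (any(bad)) {
    stopf("read without a complete tag entry: %s",
          reads$read_id[which(bad)[1]])
  }
  key <- paste(reads$umi_pair, reads$strand, reads$start, reads$end,
               sep = "|")
  split(reads, key)
}

#' Build a single-strand consensus sequence (SSCS) from one family
#'
#' Per position, the consensus base is the unique majority base when its
#' fraction reaches `agreement`; otherwise (including ties) `N`. Families
#' smaller than `min_reads` yield no consensus. In/Del annotations are kept
#' when present on at least the `agreement` fraction of reads.
#'
#' @param family One element of [group_families()].
#' @param min_reads Minimum family size (default 3).
#' @param agreement Minimum fraction of reads that must agree (default 0.7;
#'   must exceed 0.5).
#' @return An `SSCSRecord` list (`umi_pair`, `strand`, `start`, `end`,
#'   `consensus`, `family_size`, `indels`) or `NULL`.
#' @export
build_sscs <- function(family, min_reads = 3L, agreement = 0.7) {
  if (min_reads < 1L) stopf("min_reads must be >= 1")
  if (agreement <= 0.5 || agreement > 1) {
    stopf("agreement must lie in (0.5, 1]")
  }
  n <- nrow(family)
  if (n < min_reads) return(NULL)
  m <- do.call(rbind, strsplit(family$seq, ""))
  cons <- apply(m, 2L, function(col) {
    tab <- tabulate(match(col, BASES), 4L)
    top <- max(tab)
    if (top / n >= agreement && sum(tab == top) == 1L) {
      BASES[which.max(tab)]
    } else {
      "N"
    }
  })
  indels <- character(0)
  if (!is.null(family$indels)) {
    ann <- unlist(strsplit(family$indels, ";", fixed = TRUE))
    ann <- ann[nzchar(ann)]
    if (length(ann)) {
      tab <- table(ann)
      indels <- names(tab)[tab / n >= agreement]
    }
  }
  structure(
    list(umi_pair = family$umi_pair[1], strand = family$strand[1],
         start = family$start[1], end = family$end[1],
         consensus = paste(cons, collapse = ""), family_size = n,
         indels = indels),
    class = "SSCSRecord"
  )
}

#' Build a duplex consensus sequence (DCS) from a strand pair
#'
#' Emits a base where the two strand consensuses agree; `N` where they
#' disagree or either strand is `N`. An In/Del allele is kept only when it
#' is present on both strand consensuses. Strand-specific artifacts (PCR
#' errors, damage-driven miscoding) are thereby removed.
#'
#' @param top,bottom `SSCSRecord`s sharing `(umi_pair, start, end)`.
#' @return A `DCSRecord` list (`umi_pair`, `start`, `end`, `consensus`,
#'   `clip_applied`, `indels`).
#' @export
build_dcs <- function(top, bottom) {
  if (is.null(top) || is.null(bottom)) {
    stopf("both strand consensuses are required to form a duplex consensus")
  }
  if (top$umi_pair != bottom$umi_pair || top$start != bottom$start ||
      top$end != bottom$end) {
    stopf("strand consensuses do not share (umi_pair, start, end)")
  }
  a <- strsplit(top$consensus, "")[[1]]
  b <- strsplit(bottom$consensus, "")[[1]]
  cons <- ifelse(a == b & a != "N", a, "N")
  structure(
    list(umi_pair = top$umi_pair, start = top$start, end = top$end,
         consensus = paste(cons, collapse = ""), clip_applied = 0L,
         indels = intersect(top$indels, bottom$indels)),
    class = "DCSRecord"
  )
}

#' Clip consensus read ends
#'
#' Masks the first and last `clip_len` bases of a consensus record so they
#' contribute to no pileup; end-of-fragment bases are where shearing-induced
#' damage artifacts concentrate in real libraries.
#'
#' @param record A `DCSRecord` (or `SSCSRecord`).
#' @param clip_len Bases to remove from each end; `2 * clip_len` must be
#'   smaller than the consensus length.
#' @param genome_length Circle length used to resolve In/Del annotation
#'   offsets on fragments that wrap the origin; optional.
#' @return The record with ends set to `N` and `clip_applied` recorded.
#' @export
clip_ends <- function(record, clip_len = 10L, genome_length = NULL) {
  clip_len <- as.integer(clip_len)
  if (clip_len < 0L) stopf("clip_len must be >= 0")
  len <- nchar(record$consensus)
  if (2L * clip_len >= len) {
    stopf("clip_len %d would remove the whole %d bp consensus", clip_len, len)
  }
  if (clip_len > 0L) {
    cons <- strsplit(record$consensus, "")[[1]]
    cons[seq_len(clip_len)] <- "N"
    cons[seq.int(len - clip_len + 1L, len)] <- "N"
    record$consensus <- paste(cons, collapse = "")
    # In/Del annotations inside the clipped margins are dropped too.
    if (length(record$indels)) {
      pos <- as.integer(vapply(strsplit(record$indels, ":", fixed = TRUE),
                               `[`, "", 1L))
      off <- pos - record$start + 1L
      if (!is.null(genome_length)) {
        off[off < 1L] <- off[off < 1L] + genome_length
      }
      keep <- off > clip_len & off <= len - clip_len
      record$indels <- record$indels[keep]
    }
  }
  record$clip_applied <- clip_len
  record
}

new_pileup <- function(layer, L, counts, indels) {
  structure(list(layer = layer, L = L, counts = counts, indels = indels),
            class = "Pileup")
}

#' @export
print.Pileup <- function(x, ...) {
  cat(sprintf("Pileup (%s): %d positions, mean depth %.1f, %d In/Del alleles\n",
              x$layer, x$L, mean(pileup_depth(x)), nrow(x$indels)))
  invisible(x)
}

#' Per-position depth of a pileup
#'
#' Depth is the sum of A/C/G/T calls at each position; consensus `N` bases
#' contribute nothing.
#'
#' @param pileup A `Pileup`.
#' @return Integer vector of length `pileup$L`.
#' @export
pileup_depth <- function(pileup) {
  as.integer(rowSums(pileup$counts))
}

#' Build a per-position pileup from consensus records
#'
#' Resolves circular coordinates (fragments may wrap the origin) and
#' tallies A/C/G/T calls per reference position; `N` bases contribute to
#' neither depth nor allele counts.
#'
#' @param records List of `SSCSRecord`s or `DCSRecord`s.
#' @param reference The `MitoReference` the records map to.
#' @param layer Layer label, `"SSCS"` or `"DCS"`.
#' @return A `Pileup`: list with `layer`, `L`, `counts` (L x 4 matrix), and
#'   `indels` (data.frame `position`, `allele`, `count`).
#' @export
make_pileup <- function(records, reference, layer = "DCS") {
  L <- reference$length
  counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  all_pos <- integer(0)
  all_base <- integer(0)
  indel_ann <- character(0)
  for (rec in records) {
    if (is.null(rec)) next
    len <- nchar(rec$consensus)
    if (rec$start < 1L) stopf("record start %d outside [1, %d]", rec$start, L)
    if (len != rec$end - rec$start + 1L) {
      stopf("consensus length %d does not match interval %d-%d",
            len, rec$start, rec$end)
    }
    bases <- strsplit(rec$consensus, "")[[1]]
    keep <- bases != "N"
    if (any(keep)) {
      pos <- wrap_pos(rec$start + which(keep) - 1L, L)
      all_pos <- c(all_pos, pos)
      all_base <- c(all_base, match(bases[keep], BASES))
    }
    if (length(rec$indels)) indel_ann <- c(indel_ann, rec$indels)
  }
  if (length(all_pos)) {
    tab <- tabulate((all_pos - 1L) * 4L + all_base, nbins = 4L * L)
    counts <- matrix(tab, ncol = 4L, byrow = TRUE,
                     dimnames = list(NULL, BASES))
  }
  indels <- data.frame(position = integer(0), allele = character(0),
                       indel_length = integer(0), count = integer(0))
  if (length(indel_ann)) {
    tab <- table(indel_ann)
    parts <- strsplit(names(tab), ":", fixed = TRUE)
    indels <- data.frame(
      position = wrap_pos(as.integer(vapply(parts, `[`, "", 1L)), L),
      allele = paste0(vapply(parts, `[`, "", 3L),
                      vapply(parts, `[`, "", 2L)),
      indel_length = as.integer(vapply(parts, `[`, "", 2L)),
      count = as.integer(tab))
  }
  new_pileup(layer = layer, L = L, counts = counts, indels = indels)
}

#' Run the full consensus stage over a read table
#'
#' Groups reads into families, builds per-strand SSCS, pairs strands into
#' DCS, clips DCS ends, and returns both pileups along with the records.
#'
#' @inheritParams group_families
#' @inheritParams build_sscs
#' @param reference The `MitoReference` the reads map to.
#' @param clip_len End bases clipped from each duplex consensus.
#' @return List with `sscs_records`, `dcs_records`, `sscs_pileup`,
#'   `dcs_pileup`.
#' @export
duplex_consensus <- function(reads, reference, min_reads = 3L,
                             agreement = 0.7, clip_len = 10L) {
  fams <- group_families(reads)
  sscs <- lapply(fams, build_sscs, min_reads = min_reads,
                 agreement = agreement)
  sscs <- sscs[!vapply(sscs, is.null, TRUE)]

  frag_key <- vapply(sscs, function(r) {
    paste(r$umi_pair, r$start, r$end, sep = "|")
  }, "")
  dcs <- list()
  for (key in unique(frag_key)) {
    pair <- sscs[frag_key == key]
    strands <- vapply(pair, `[[`, "", "strand")
    if (all(c("top", "bottom") %in% strands)) {
      rec <- build_dcs(pair[[match("top", strands)]],
                       pair[[match("bottom", strands)]])
      if (clip_len > 0L) {
        rec <- clip_ends(rec, clip_len, genome_length = reference$length)
      }
      dcs[[key]] <- rec
    }
  }
  list(
    sscs_records = sscs,
    dcs_records = dcs,
    sscs_pileup = make_pileup(sscs, reference, layer = "SSCS"),
    dcs_pileup = make_pileup(dcs, reference, layer = "DCS")
  )
}
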