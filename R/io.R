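#' Write a reference genome to FASTA and its features to BED
#'
#' The sequence goes to FASTA; the control region, OriL, masked intervals
#' and genes go to a BED file (0-based half-open on disk, converted from the
#' internal 1-based closed convention).
#'
#' @param reference A `MitoReference`.
#' @param fasta_path,bed_path Output paths.
#' @param name Sequence name in the FASTA/BED.
#' @return Invisibly, the reference.
#' @export
write_reference <- function(reference, fasta_path, bed_path = NULL,
                            name = "chrM") {
  seq <- Biostrings::DNAStringSet(reference$sequence)
  names(seq) <- name
  Biostrings::writeXStringSet(seq, fasta_path)
  if (!is.null(bed_path)) {
    iv <- reference_features(reference)
    gr <- GenomicRanges::GRanges(
      seqnames = name,
      ranges = IRanges::IRanges(start = iv$start, end = iv$end),
      feature = iv$feature)
    names(gr) <- iv$feature
    rtracklayer::export(gr, bed_path, format = "BED")
  }
  invisible(reference)
}

# Feature table in internal 1-based closed coordinates. The control region
# may wrap the origin; on disk it is then split in two.
reference_features <- function(reference) {
  cr <- reference$control_region
  rows <- if (cr[["start"]] <= cr[["end"]]) {
    data.frame(feature = "control_region", start = cr[["start"]],
               end = cr[["end"]])
  } else {
    data.frame(feature = c("control_region", "control_region"),
               start = c(cr[["start"]], 1L),
               end = c(reference$length, cr[["end"]]))
  }
  if (!is.null(reference$ori_l)) {
    rows <- rbind(rows, data.frame(feature = "ori_l",
                                   start = reference$ori_l[["start"]],
                                   end = reference$ori_l[["end"]]))
  }
  m <- reference$masked_intervals
  if (!is.null(m) && nrow(m)) {
    rows <- rbind(rows, data.frame(
      feature = sprintf("masked_%02d", seq_len(nrow(m))),
      start = m$start, end = m$end))
  }
  g <- reference$genes
  if (!is.null(g) && nrow(g)) {
    rows <- rbind(rows, data.frame(feature = paste0("gene_", g$name),
                                   start = g$start, end = g$end))
  }
  rows
}

#' Read a reference genome from FASTA (and features from BED)
#'
#' Inverse of [write_reference()]; BED intervals (0-based half-open) are
#' converted back to 1-based closed coordinates, and a split control region
#' is re-joined across the origin.
#'
#' @param fasta_path,bed_path Input paths; `bed_path` may be `NULL`, in
#'   which case the default feature layout for the sequence length is used.
#' @return A `MitoReference`.
#' @export
read_reference <- function(fasta_path, bed_path = NULL) {
  seq <- Biostrings::readDNAStringSet(fasta_path)
  sequence <- as.character(seq[[1]])
  L <- nchar(sequence)
  spec <- default_feature_spec(L)
  if (!is.null(bed_path)) {
    gr <- rtracklayer::import(bed_path, format = "BED")
    feat <- gr$name
    start <- GenomicRanges::start(gr)
    end <- GenomicRanges::end(gr)
    cr_i <- which(feat == "control_region")
    if (length(cr_i) == 1L) {
      spec$control_region <- c(start = start[cr_i], end = end[cr_i])
    } else if (length(cr_i) == 2L) {
      hi <- cr_i[which.max(start[cr_i])]
      lo <- cr_i[which.min(start[cr_i])]
      spec$control_region <- c(start = start[hi], end = end[lo])
    }
    ori_i <- which(feat == "ori_l")
    spec$ori_l <- if (length(ori_i)) {
      c(start = start[ori_i[1]], end = end[ori_i[1]])
    } else {
      NULL
    }
    m_i <- grep("^masked_", feat)
    spec$masked_intervals <- data.frame(start = start[m_i], end = end[m_i])
    g_i <- grep("^gene_", feat)
    spec$genes <- data.frame(name = sub("^gene_", "", feat[g_i]),
                             start = start[g_i], end = end[g_i],
                             strand = "+", coding = TRUE)
  }
  structure(
    list(sequence = sequence, length = L,
         control_region = spec$control_region, ori_l = spec$ori_l,
         masked_intervals = spec$masked_intervals, genes = spec$genes),
    class = "MitoReference"
  )
}

#' Write simulated read families as FASTQ plus a tag table
#'
#' Reads go to a FASTQ (constant placeholder qualities, since base-quality
#' modelling is out of scope); the UMI/strand/coordinate/provenance tags go
#' to a TSV keyed by read id.
#'
#' @param reads A [simulate_read_families()] table.
#' @param fastq_path,tags_path Output paths.
#' @return Invisibly, `reads`.
#' @export
write_read_families <- function(reads, fastq_path, tags_path) {
  seq <- Biostrings::DNAStringSet(reads$seq)
  names(seq) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$seq)))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(
      seq, Biostrings::PhredQuality(qual)),
    fastq_path)
  tags <- reads[c("read_id", "umi_pair", "strand", "start", "end",
                  "indels", "provenance")]
  write.table(tags, tags_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(reads)
}

#' Read back a FASTQ + tag-table read set
#'
#' @param fastq_path,tags_path Paths written by [write_read_families()].
#' @return A read table suitable for [group_families()].
#' @export
read_read_families <- function(fastq_path, tags_path) {
  seq <- Biostrings::readDNAStringSet(fastq_path, format = "fastq")
  tags <- read.delim(tags_path, na.strings = NULL,
                     colClasses = c(indels = "character",
                                    provenance = "character"))
  i <- match(tags$read_id, names(seq))
  if (anyNA(i)) stopf("tag table and FASTQ disagree on read ids")
  tags$seq <- as.character(seq[i])
  tags
}

#' Write a call table as TSV
#'
#' @param calls A call table.
#' @param path Output path.
#' @export
write_calls_tsv <- function(calls, path) {
  write.table(calls, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Read a call table from TSV
#'
#' @param path A TSV written by [write_calls_tsv()].
#' @return Call table data.frame.
#' @export
read_calls_tsv <- function(path) {
  read.delim(path)
}

#' Write somatic calls as VCF 4.2
#'
#' Minimal single-sample VCF emitter with INFO fields DP (depth), SR
#' (supporting reads), VAF, CLASS (six-class label) and FLAGS. In/Del
#' alleles are written symbolically (`<ins3>` etc.) since the pipeline
#' tracks In/Dels as length-typed alleles, not resolved sequences.
#'
#' @param calls A flagged call table.
#' @param path Output path.
#' @param contig Contig name.
#' @param contig_length Contig length for the header.
#' @export
write_calls_vcf <- function(calls, path, contig = "chrM",
                            contig_length = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##source=duplexmt %s",
            as.character(utils::packageVersion("duplexmt"))),
    if (!is.null(contig_length)) {
      sprintf("##contig=<ID=%s,length=%d>", contig, contig_length)
    },
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Duplex consensus depth\">",
    "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Supporting duplex reads\">",
    "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
    "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"Six-class spectrum label\">",
    "##INFO=<ID=FLAGS,Number=.,Type=String,Description=\"Filter flags set\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
  ), con)
  if (nrow(calls)) {
    flags <- apply(calls[c("masked", "numt_removed", "inherited",
                           "high_vaf", "low_depth", "long_indel")], 1L,
                   function(r) {
                     f <- names(r)[as.logical(r)]
                     if (length(f)) paste(f, collapse = ",") else "."
                   })
    alt <- ifelse(calls$six_class == "indel",
                  paste0("<", calls$alt, ">"), calls$alt)
    cls <- gsub(">", "to", calls$six_class, fixed = TRUE)
    cls <- gsub("/", "_", cls, fixed = TRUE)
    writeLines(sprintf(
      "%s\t%d\t.\t%s\t%s\t.\t%s\tDP=%d;SR=%d;VAF=%.3g;CLASS=%s;FLAGS=%s",
      contig, calls$position, calls$ref, alt,
      ifelse(is_somatic(calls), "PASS", "excluded"),
      calls$depth, calls$supporting_reads, calls$vaf, cls, flags), con)
  }
  invisible(calls)
}

#' Write a pileup as TSV
#'
#' One row per position: `pos`, `depth`, `A`, `C`, `G`, `T`; In/Del allele
#' counts go to a companion table when requested.
#'
#' @param pileup A `Pileup`.
#' @param path Output path.
#' @param indel_path Optional path for the In/Del allele table.
#' @export
write_pileup_tsv <- function(pileup, path, indel_path = NULL) {
  d <- data.frame(pos = seq_len(pileup$L), depth = pileup_depth(pileup),
                  pileup$counts)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(indel_path)) {
    write.table(pileup$indels, indel_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(pileup)
}

#' Load a simulation configuration
#'
#' YAML with documented keys: `reference` (`length`, `gc_fraction`, `seed`),
#' `depth`, `n_molecules`, `seed`, and `profiles`, a map of tissue name to
#' the [tissue_profile()] arguments (`class_rates` in [SNV_CLASSES] order,
#' `indel_rate`, `clonal_fraction`, `cr_enrichment`, `damage_rate`, ...).
#'
#' @param path YAML path.
#' @return List with `reference` args, `depth`, `n_molecules`, `seed`, and
#'   `profiles` (list of `TissueProfile`).
#' @export
read_sim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  profiles <- lapply(names(cfg$profiles), function(nm) {
    args <- cfg$profiles[[nm]]
    args$class_rates <- setNames(as.numeric(args$class_rates), SNV_CLASSES)
    args$name <- nm
    do.call(tissue_profile, args)
  })
  names(profiles) <- names(cfg$profiles)
  list(reference = cfg$reference,
       depth = cfg$depth %||% 10000,
       n_molecules = cfg$n_molecules %||% 10000,
       seed = cfg$seed %||% 1L,
       profiles = profiles)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
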