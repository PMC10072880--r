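#' Simulate the mutated mtDNA molecule pool of one sample
#'
#' Seeds de novo mutation events onto a pool of `n_molecules` mtDNA copies.
#' Event counts per class are Poisson with mean `rate * L * n_molecules`.
#' Non-clonal events land on 1 molecule (or 2, with probability `p_double`);
#' with probability `clonal_fraction` an event is a heteroplasmic clone on
#' `k >= 3` molecules, with clone placement enriched in the control region
#' by `cr_enrichment`.
#'
#' @param reference A [build_reference()] genome.
#' @param profile A [tissue_profile()].
#' @param n_molecules Number of mtDNA copies in the pool.
#' @param seed Integer seed (deterministic output for a fixed seed).
#' @param sample_id Sample label; defaults to the profile's tissue name.
#' @return A `MoleculePool`: list with `sample_id`, `n_molecules`, and
#'   `events`, a data.frame with columns `position`, `ref`, `alt`, `k`,
#'   `is_indel`, `indel_length`, `class`, `clonal`, and a list-column
#'   `molecules` of molecule indices carrying each event.
#' @export
simulate_sample <- function(reference, profile, n_molecules, seed = 1L,
                            sample_id = profile$name) {
  if (n_molecules < 1L) stopf("n_molecules must be >= 1")
  if (any(profile$class_rates * n_molecules > 1) ||
      profile$indel_rate * n_molecules > 1) {
    stopf("rates imply > 1 expected event per site; lower the rates")
  }
  L <- reference$length
  bases <- strsplit(reference$sequence, "")[[1]]
  cr <- reference$control_region
  in_cr <- in_interval(seq_len(L), cr[["start"]], cr[["end"]])

  events <- with_seed(seed, {
    rows <- list()
    for (cls in SNV_CLASSES) {
      lam <- profile$class_rates[[cls]] * L * n_molecules
      n_ev <- rpois(1L, lam)
      if (n_ev == 0L) next
      eligible <- which(bases %in% class_ref_bases(cls))
      clonal <- runif(n_ev) < profile$clonal_fraction
      k <- ifelse(clonal,
                  3L + rpois(n_ev, profile$clone_size_mean - 3),
                  1L + rbinom(n_ev, 1L, profile$p_double))
      k <- pmin(k, n_molecules)
      w <- rep(1, length(eligible))
      w_cl <- w
      w_cl[in_cr[eligible]] <- profile$cr_enrichment
      pos <- integer(n_ev)
      if (any(clonal)) {
        pos[clonal] <- sample(eligible, sum(clonal), replace = TRUE,
                              prob = w_cl)
      }
      if (any(!clonal)) {
        pos[!clonal] <- sample(eligible, sum(!clonal), replace = TRUE)
      }
      ref <- bases[pos]
      alt <- class_alt_for_base(cls, ref)
      rows[[cls]] <- data.frame(position = pos, ref = ref, alt = alt,
                                k = k, is_indel = FALSE, indel_length = 0L,
                                class = cls, clonal = clonal)
    }
    n_ind <- rpois(1L, profile$indel_rate * L * n_molecules)
    if (n_ind > 0L) {
      pos <- sample.int(L, n_ind, replace = TRUE)
      len <- pmin(1L + rgeom(n_ind, 0.55), 15L)
      type <- sample(c("ins", "del"), n_ind, replace = TRUE)
      clonal <- runif(n_ind) < profile$clonal_fraction
      k <- ifelse(clonal,
                  3L + rpois(n_ind, profile$clone_size_mean - 3),
                  1L + rbinom(n_ind, 1L, profile$p_double))
      rows[["indel"]] <- data.frame(
        position = pos, ref = bases[pos],
        alt = paste0(type, len), k = pmin(k, n_molecules),
        is_indel = TRUE, indel_length = len, class = "indel",
        clonal = clonal)
    }
    ev <- if (length(rows)) do.call(rbind, rows) else
      data.frame(position = integer(0), ref = character(0),
                 alt = character(0), k = integer(0), is_indel = logical(0),
                 indel_length = integer(0), class = character(0),
                 clonal = logical(0))
    rownames(ev) <- NULL
    # One event per (position, alt): merge duplicates by summing k.
    key <- paste(ev$position, ev$alt)
    if (anyDuplicated(key)) {
      keep <- !duplicated(key)
      ksum <- tapply(ev$k, key, sum)
      ev <- ev[keep, , drop = FALSE]
      ev$k <- pmin(as.integer(ksum[paste(ev$position, ev$alt)]), n_molecules)
      # independent events merged onto >= 3 molecules are de facto clones
      ev$clonal <- ev$clonal | ev$k >= 3L
    }
    ev$molecules <- lapply(ev$k, function(k) sample.int(n_molecules, k))
    ev
  })

  structure(list(sample_id = sample_id, n_molecules = n_molecules,
                 events = events),
            class = "MoleculePool")
}

#' @export
print.MoleculePool <- function(x, ...) {
  cat(sprintf("MoleculePool '%s': %d molecules, %d events (%d clonal, %d In/Del)\n",
              x$sample_id, x$n_molecules, nrow(x$events),
              sum(x$events$clonal), sum(x$events$is_indel)))
  invisible(x)
}

#' Sample a consensus-level pileup directly from a molecule pool
#'
#' Draws a duplex-consensus pileup at constant `depth` without simulating
#' individual reads: per-position depth is `depth`, and each seeded event
#' receives `Binomial(depth, k / n_molecules)` supporting reads. With
#' per-read error rates of zero this is distribution-equivalent to running
#' the full read-family route and lets parameter-recovery experiments run at
#' the study's 10,000x depth over a full-length genome at desk scale.
#'
#' @param pool A [simulate_sample()] molecule pool.
#' @param reference The reference used to build the pool.
#' @param depth Constant per-position consensus depth.
#' @param seed Integer seed.
#' @param layer `"DCS"` or `"SSCS"` label carried by the pileup.
#' @return A `Pileup` (see [make_pileup()]).
#' @export
sample_pileup <- function(pool, reference, depth, seed = 1L, layer = "DCS") {
  L <- reference$length
  depth <- as.integer(depth)
  if (depth < 1L) stopf("depth must be >= 1")
  bases <- strsplit(reference$sequence, "")[[1]]
  counts <- matrix(0L, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  counts[cbind(seq_len(L), match(bases, BASES))] <- depth

  ev <- pool$events
  indels <- data.frame(position = integer(0), allele = character(0),
                       indel_length = integer(0), count = integer(0))
  if (nrow(ev)) {
    supp <- with_seed(seed,
                      rbinom(nrow(ev), depth, ev$k / pool$n_molecules))
    snv <- !ev$is_indel & supp > 0L
    if (any(snv)) {
      i <- which(snv)
      counts[cbind(ev$position[i], match(ev$alt[i], BASES))] <-
        counts[cbind(ev$position[i], match(ev$alt[i], BASES))] + supp[i]
      counts[cbind(ev$position[i], match(ev$ref[i], BASES))] <-
        counts[cbind(ev$position[i], match(ev$ref[i], BASES))] - supp[i]
    }
    ind <- ev$is_indel & supp > 0L
    if (any(ind)) {
      i <- which(ind)
      indels <- data.frame(position = ev$position[i], allele = ev$alt[i],
                           indel_length = ev$indel_length[i],
                           count = supp[i])
    }
  }
  new_pileup(layer = layer, L = L, counts = counts, indels = indels)
}

#' Simulate UMI-tagged duplex read families from a molecule pool
#'
#' Fragments molecules uniformly around the circle (fixed fragment length),
#' tags each fragment with a UMI pair from a 96-tag alphabet, and emits a
#' top-strand and a bottom-strand read family per fragment. True mutations
#' of the source molecule appear on both strands; strand-specific damage
#' lesions (G sites of one randomly chosen strand, miscoding as T during
#' copying) and PCR errors appear on exactly one strand's family, so they
#' survive single-strand consensus but not duplex consensus; sequencing
#' errors are independent per read and per base.
#'
#' @param pool A [simulate_sample()] molecule pool.
#' @param reference The reference genome.
#' @param target_depth Approximate per-position raw fragment depth.
#' @param fragment_length Fixed fragment length in bp (default 300).
#' @param family_size_mean Mean reads per strand family (truncated-at-1
#'   Poisson).
#' @param pcr_error Per-base probability of a family-wide (strand-specific)
#'   PCR substitution, in `[0, 0.05]`.
#' @param seq_error Per-read per-base substitution probability, in
#'   `[0, 0.05]`.
#' @param damage_rate Per-eligible-site lesion probability on the chosen
#'   strand of each fragment, in `[0, 0.05]`.
#' @param seed Integer seed.
#' @return data.frame of reads with columns `read_id`, `umi_pair`, `strand`
#'   (`top`/`bottom`), `start`, `end` (1-based inclusive; `end` may exceed
#'   the genome length for fragments wrapping the origin), `seq`, `indels`
#'   (semicolon-joined `pos:len:type` annotations), `provenance`
#'   (semicolon-joined event/error tags), and `fragment_id`.
#' @export
simulate_read_families <- function(pool, reference, target_depth,
                                   fragment_length = 300L,
                                   family_size_mean = 3,
                                   pcr_error = 0, seq_error = 0,
                                   damage_rate = 0, seed = 1L) {
  if (target_depth <= 0) stopf("target_depth must be positive")
  for (p in c(pcr_error, seq_error, damage_rate)) {
    if (p < 0 || p > 0.05) stopf("error probabilities must lie in [0, 0.05]")
  }
  L <- reference$length
  flen <- as.integer(fragment_length)
  if (flen < 30L || flen > L) stopf("fragment_length out of range")
  n_frag <- max(1L, as.integer(round(target_depth * L / flen)))

  ev <- pool$events
  # molecule -> event indices
  mol_events <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      for (m in ev$molecules[[i]]) {
        key <- as.character(m)
        mol_events[[key]] <- c(mol_events[[key]], i)
      }
    }
  }

  with_seed(seed, {
    rows <- vector("list", n_frag * 2L)
    used_keys <- new.env(hash = TRUE, parent = emptyenv())
    read_no <- 0L
    for (f in seq_len(n_frag)) {
      mol <- sample.int(pool$n_molecules, 1L)
      start <- sample.int(L, 1L)
      end <- start + flen - 1L
      frag <- strsplit(ref_fragment(reference, start, flen), "")[[1]]

      # UMI pair; collisions on identical coordinates are re-drawn so the
      # family key (UMI pair + coordinates + strand) stays unique.
      repeat {
        umi <- sprintf("U%02d-U%02d", sample.int(96L, 1L), sample.int(96L, 1L))
        key <- paste(umi, start, end)
        if (is.null(used_keys[[key]])) {
          used_keys[[key]] <- TRUE
          break
        }
      }

      prov <- character(0)
      indel_ann <- character(0)
      idx <- mol_events[[as.character(mol)]]
      if (!is.null(idx)) {
        for (i in idx) {
          off <- ((ev$position[i] - start) %% L) + 1L
          if (off > flen) next
          if (ev$is_indel[i]) {
            indel_ann <- c(indel_ann,
                           sprintf("%d:%d:%s", ev$position[i],
                                   ev$indel_length[i],
                                   sub("[0-9]+$", "", ev$alt[i])))
            prov <- c(prov, sprintf("mut:%d:%s", ev$position[i], ev$alt[i]))
          } else {
            frag[off] <- ev$alt[i]
            prov <- c(prov, sprintf("mut:%d%s>%s", ev$position[i],
                                    ev$ref[i], ev$alt[i]))
          }
        }
      }
      indel_str <- paste(indel_ann, collapse = ";")

      lesion_strand <- sample(c("top", "bottom"), 1L)
      for (strand in c("top", "bottom")) {
        fam_frag <- frag
        fam_prov <- prov
        if (damage_rate > 0 && strand == lesion_strand) {
          eligible <- which(fam_frag == if (strand == "top") "G" else "C")
          hit <- eligible[runif(length(eligible)) < damage_rate]
          if (length(hit)) {
            fam_frag[hit] <- if (strand == "top") "T" else "A"
            fam_prov <- c(fam_prov,
                          sprintf("dam:%d", wrap_pos(start + hit - 1L, L)))
          }
        }
        if (pcr_error > 0) {
          hit <- which(runif(flen) < pcr_error)
          if (length(hit)) {
            for (h in hit) {
              fam_frag[h] <- sample(setdiff(BASES, fam_frag[h]), 1L)
            }
            fam_prov <- c(fam_prov,
                          sprintf("pcr:%d", wrap_pos(start + hit - 1L, L)))
          }
        }
        fam_size <- rtpois1(1L, family_size_mean)
        seqs <- character(fam_size)
        read_prov <- character(fam_size)
        for (r in seq_len(fam_size)) {
          rd <- fam_frag
          rp <- fam_prov
          if (seq_error > 0) {
            hit <- which(runif(flen) < seq_error)
            if (length(hit)) {
              for (h in hit) rd[h] <- sample(setdiff(BASES, rd[h]), 1L)
              rp <- c(rp, sprintf("err:%d", wrap_pos(start + hit - 1L, L)))
            }
          }
          seqs[r] <- paste(rd, collapse = "")
          read_prov[r] <- paste(rp, collapse = ";")
        }
        rows[[2L * (f - 1L) + (strand == "bottom") + 1L]] <- data.frame(
          read_id = sprintf("rd%07d", read_no + seq_len(fam_size)),
          umi_pair = umi, strand = strand, start = start, end = end,
          seq = seqs, indels = indel_str, provenance = read_prov,
          fragment_id = f)
        read_no <- read_no + fam_size
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}
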