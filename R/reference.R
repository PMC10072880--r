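#' Build a synthetic circular mitochondrial reference genome
#'
#' Generates a random circular nucleotide sequence with a mouse-mtDNA-like
#' feature layout: a control region near the sequence end, the origin of
#' light-strand replication (OriL, 5160-5191 by default), a small set of
#' masked low-complexity intervals, and a coarse gene map. All coordinates
#' are 1-based closed intervals on the circle; only the control region may
#' wrap the origin.
#'
#' @param length Genome length in bases (default 16,299, the mouse mtDNA
#'   length used throughout).
#' @param gc_fraction Target G+C fraction of the emitted sequence. The mouse
#'   mitochondrial genome is AT-rich (~0.37 G+C), which is the default.
#' @param feature_spec Optional feature layout as produced by
#'   [default_feature_spec()]; `NULL` uses the default layout.
#' @param seed Integer seed; the same `(length, gc_fraction, seed)` always
#'   yields a byte-identical sequence.
#' @return A `MitoReference` object: a list with elements `sequence`
#'   (character scalar), `length`, `control_region`, `ori_l`,
#'   `masked_intervals` (data.frame with `start`, `end`), and `genes`
#'   (data.frame with `name`, `start`, `end`, `strand`, `coding`).
#' @examples
#' ref <- build_reference(length = 16299, seed = 1)
#' ref$ori_l
#' @export
build_reference <- function(length = 16299L, gc_fraction = 0.37,
                            feature_spec = NULL, seed = 1L) {
  length <- as.integer(length)
  if (length < 1000L) stopf("reference length must be >= 1000, got %d", length)
  if (gc_fraction <= 0 || gc_fraction >= 1) {
    stopf("gc_fraction must lie strictly between 0 and 1")
  }
  if (is.null(feature_spec)) feature_spec <- default_feature_spec(length)
  validate_feature_spec(feature_spec, length)

  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  seq <- with_seed(seed, sample(BASES, length, replace = TRUE, prob = p))

  ref <- structure(
    list(
      sequence = paste(seq, collapse = ""),
      length = length,
      control_region = feature_spec$control_region,
      ori_l = feature_spec$ori_l,
      masked_intervals = feature_spec$masked_intervals,
      genes = feature_spec$genes
    ),
    class = "MitoReference"
  )
  ref
}

#' Default feature layout for a synthetic mitochondrial reference
#'
#' Places OriL at 5160-5191 (when the genome is long enough to hold it), a
#' ~900 bp control region ending at the last base, seven small masked
#' intervals at fixed relative positions (standing in for the short
#' polynucleotide repeats that are masked in real data because of alignment
#' artifacts), and a coarse gene map with one minus-strand coding gene.
#'
#' @param length Genome length the layout is scaled to.
#' @return A list with `control_region`, `ori_l`, `masked_intervals`, `genes`.
#' @export
default_feature_spec <- function(length = 16299L) {
  length <- as.integer(length)
  cr_len <- min(877L, max(200L, length %/% 18L))
  control_region <- c(start = length - cr_len + 1L, end = length)
  ori_l <- if (length >= 5300L) c(start = 5160L, end = 5191L) else NULL

  # Seven short masked intervals at fixed genome fractions, widths 6-10 bp.
  fr <- c(0.065, 0.145, 0.225, 0.405, 0.540, 0.660, 0.820)
  w <- c(8L, 6L, 10L, 7L, 9L, 6L, 8L)
  start <- pmax(1L, as.integer(round(fr * length)))
  masked <- data.frame(start = start, end = pmin(start + w - 1L, length))

  genes <- data.frame(
    name = c("rRNA-small", "rRNA-large", "ND1", "ND2", "COX1", "ATP6",
             "CYTB", "ND6"),
    start = as.integer(round(c(0.004, 0.065, 0.165, 0.24, 0.33, 0.48,
                               0.87, 0.835) * length)),
    end = as.integer(round(c(0.06, 0.155, 0.23, 0.32, 0.42, 0.52,
                             0.935, 0.865) * length)),
    strand = c("+", "+", "+", "+", "+", "+", "+", "-"),
    coding = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
  genes <- genes[genes$end <= length, , drop = FALSE]
  list(control_region = control_region, ori_l = ori_l,
       masked_intervals = masked, genes = genes)
}

validate_feature_spec <- function(spec, length) {
  chk <- function(iv, name, allow_wrap = FALSE) {
    if (is.null(iv)) return(invisible())
    if (any(iv < 1L) || any(iv > length)) {
      stopf("%s interval outside [1, %d]", name, length)
    }
    if (!allow_wrap && iv[["start"]] > iv[["end"]]) {
      stopf("%s interval may not wrap the origin", name)
    }
  }
  chk(spec$control_region, "control_region", allow_wrap = TRUE)
  chk(spec$ori_l, "ori_l")
  m <- spec$masked_intervals
  if (!is.null(m) && nrow(m) > 0L) {
    if (any(m$start < 1L) || any(m$end > length) || any(m$start > m$end)) {
      stopf("masked interval outside [1, %d] or inverted", length)
    }
    o <- order(m$start)
    if (nrow(m) > 1L && any(m$start[o][-1L] <= m$end[o][-nrow(m)])) {
      stopf("masked intervals overlap after sorting; merge them first")
    }
  }
  invisible(spec)
}

#' @export
print.MitoReference <- function(x, ...) {
  cat(sprintf("MitoReference: %d bp circular genome\n", x$length))
  cat(sprintf("  control region: %d-%d\n",
              x$control_region[["start"]], x$control_region[["end"]]))
  if (!is.null(x$ori_l)) {
    cat(sprintf("  OriL: %d-%d\n", x$ori_l[["start"]], x$ori_l[["end"]]))
  }
  cat(sprintf("  masked intervals: %d; genes: %d\n",
              nrow(x$masked_intervals), nrow(x$genes)))
  invisible(x)
}

# Reference bases at (possibly wrapped) positions, as a character vector.
ref_base <- function(reference, pos) {
  pos <- wrap_pos(as.integer(pos), reference$length)
  substring(reference$sequence, pos, pos)
}

# Fragment sequence of `len` bases starting at `start` on the circle.
ref_fragment <- function(reference, start, len) {
  L <- reference$length
  start <- wrap_pos(start, L)
  end <- start + len - 1L
  if (end <= L) {
    substring(reference$sequence, start, end)
  } else {
    paste0(substring(reference$sequence, start, L),
           substring(reference$sequence, 1L, end - L))
  }
}

#' Positions excluded from frequency denominators
#'
#' Masked low-complexity intervals plus OriL; variant calls inside these and
#' the bases they contribute to sequencing depth are excluded from all
#' downstream frequency computations.
#'
#' @param reference A `MitoReference`.
#' @return Integer vector of masked 1-based positions.
#' @export
masked_positions <- function(reference) {
  iv <- reference$masked_intervals
  if (!is.null(reference$ori_l)) {
    iv <- rbind(iv, data.frame(start = reference$ori_l[["start"]],
                               end = reference$ori_l[["end"]]))
  }
  pos <- integer(0)
  if (!is.null(iv) && nrow(iv) > 0L) {
    pos <- unlist(lapply(seq_len(nrow(iv)),
                         function(i) seq.int(iv$start[i], iv$end[i])))
  }
  sort(unique(as.integer(pos)))
}
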