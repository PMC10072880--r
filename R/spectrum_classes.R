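#' Six-class SNV spectrum labels
#'
#' The 12 ordered base substitutions collapsed by strand complementarity
#' into 6 classes, printed reference-strand first as in the field's figures
#' (e.g. `"G>A/C>T"` covers both G>A and C>T).
#'
#' @format Character vector of the 6 class labels.
#' @export
SNV_CLASSES <- c("G>A/C>T", "T>C/A>G", "G>T/C>A", "G>C/C>G",
                 "T>A/A>T", "T>G/A>C")

.SNV_CLASS_MAP <- c(
  "G>A" = "G>A/C>T", "C>T" = "G>A/C>T",
  "T>C" = "T>C/A>G", "A>G" = "T>C/A>G",
  "G>T" = "G>T/C>A", "C>A" = "G>T/C>A",
  "G>C" = "G>C/C>G", "C>G" = "G>C/C>G",
  "T>A" = "T>A/A>T", "A>T" = "T>A/A>T",
  "T>G" = "T>G/A>C", "A>C" = "T>G/A>C"
)

#' Collapse a substitution to its six-class spectrum label
#'
#' Complementary substitutions (e.g. C>T and G>A) receive the same label, so
#' the 12 ordered substitutions map onto exactly 6 classes, two each.
#'
#' @param ref,alt Single bases (vectorised); `ref != alt`.
#' @return Character vector of class labels from [SNV_CLASSES].
#' @examples
#' classify_snv("C", "T")  # "G>A/C>T"
#' @export
classify_snv <- function(ref, alt) {
  if (length(ref) != length(alt)) stopf("ref and alt must have equal length")
  bad <- !(ref %in% BASES) | !(alt %in% BASES)
  if (any(bad)) stopf("non-base input to classify_snv: %s>%s",
                      ref[bad][1], alt[bad][1])
  if (any(ref == alt)) stopf("ref and alt must differ")
  unname(.SNV_CLASS_MAP[paste0(ref, ">", alt)])
}

# For a class label, the substitution applying at a given reference base,
# e.g. class "G>A/C>T" mutates G to A and C to T. Returns NA for bases the
# class does not touch.
class_alt_for_base <- function(class, base) {
  halves <- strsplit(strsplit(class, "/", fixed = TRUE)[[1]], ">", fixed = TRUE)
  from <- vapply(halves, `[`, "", 1L)
  to <- vapply(halves, `[`, "", 2L)
  out <- rep(NA_character_, length(base))
  for (i in seq_along(from)) out[base == from[i]] <- to[i]
  out
}

# The two reference bases a class can occur on.
class_ref_bases <- function(class) {
  halves <- strsplit(strsplit(class, "/", fixed = TRUE)[[1]], ">", fixed = TRUE)
  vapply(halves, `[`, "", 1L)
}
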