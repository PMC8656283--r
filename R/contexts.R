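# Pyrimidine-normalized trinucleotide context machinery.
#
# The 96 single-base-substitution channels follow the fixed lexicographic
# order used by COSMIC-style signature matrices: substitution classes
# C>A, C>G, C>T, T>A, T>C, T>G; within a class the 5' flank cycles A,C,G,T
# and, innermost, the 3' flank cycles A,C,G,T.

DNA_BASES <- c("A", "C", "G", "T")
SUB_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 trinucleotide context labels
#'
#' Returns the standard labels (e.g. `"A[C>T]G"`) for the 96 single-base
#' substitution channels, in the fixed order used throughout the package:
#' substitution class (C>A, C>G, C>T, T>A, T>C, T>G), then 5' flank
#' (A, C, G, T), then 3' flank (A, C, G, T). Context indices used in
#' [trinucleotide_context()] and [build_96_profile()] are 1-based positions
#' into this vector.
#'
#' @return Character vector of length 96.
#' @export
#' @examples
#' trinucleotide_contexts()[1:4]
trinucleotide_contexts <- function() {
  labs <- character(96L)
  k <- 0L
  for (cls in SUB_CLASSES) {
    ref <- substr(cls, 1L, 1L)
    alt <- substr(cls, 3L, 3L)
    for (up in DNA_BASES) {
      for (down in DNA_BASES) {
        k <- k + 1L
        labs[k] <- paste0(up, "[", ref, ">", alt, "]", down)
      }
    }
  }
  labs
}

# complement of a vector of single-character bases
comp_base <- function(x) chartr("ACGT", "TGCA", x)

# reverse-complement of character strings (vectorized, plain R; used for
# short allele strings where constructing DNAStringSet objects would be
# overkill)
revcomp_chr <- function(x) {
  vapply(strsplit(chartr("ACGT", "TGCA", x), ""), function(b) {
    paste(rev(b), collapse = "")
  }, character(1))
}

# Map (ref, alt, up, down) -> context index 1..96, vectorized.
# Purine references are reverse-complemented so the reported channel always
# has a pyrimidine reference; flanks swap and complement accordingly.
context_index_of <- function(ref, alt, up, down) {
  stopifnot(length(ref) == length(alt), length(up) == length(ref),
            length(down) == length(ref))
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, comp_base(ref), ref)
  a <- ifelse(pur, comp_base(alt), alt)
  u <- ifelse(pur, comp_base(down), up)
  d <- ifelse(pur, comp_base(up), down)
  cls <- match(paste0(r, ">", a), SUB_CLASSES)
  ui <- match(u, DNA_BASES)
  di <- match(d, DNA_BASES)
  idx <- (cls - 1L) * 16L + (ui - 1L) * 4L + di
  idx[is.na(cls) | is.na(ui) | is.na(di)] <- NA_integer_
  idx
}

# context *class* (1..32): pyrimidine-normalized (ref, up, down) triple
# ignoring the alternate allele; class k covers channels of the same
# reference trinucleotide. Used by the simulator to index genomic positions
# by mutational opportunity.
context_class_of <- function(ref, up, down) {
  pur <- ref %in% c("A", "G")
  r <- ifelse(pur, comp_base(ref), ref)
  u <- ifelse(pur, comp_base(down), up)
  d <- ifelse(pur, comp_base(up), down)
  ri <- match(r, c("C", "T"))
  ui <- match(u, DNA_BASES)
  di <- match(d, DNA_BASES)
  (ri - 1L) * 16L + (ui - 1L) * 4L + di
}

# channel index -> context class and pyrimidine-strand alt base
channel_class <- function(idx) {
  cls <- (idx - 1L) %/% 16L + 1L     # 1..6 substitution class
  ref_i <- ifelse(cls <= 3L, 1L, 2L) # C or T
  rest <- (idx - 1L) %% 16L
  (ref_i - 1L) * 16L + rest + 1L
}

channel_alt <- function(idx) {
  cls <- (idx - 1L) %/% 16L + 1L
  substr(SUB_CLASSES[cls], 3L, 3L)
}

channel_ref <- function(idx) {
  cls <- (idx - 1L) %/% 16L + 1L
  substr(SUB_CLASSES[cls], 1L, 1L)
}

# integer-code variant of context_index_of: bases encoded 1=A,2=C,3=G,4=T
# (complement = 5 - code); fast path for genome-scale vectors
context_index_codes <- function(ref, alt, up, down) {
  pur <- ref == 1L | ref == 3L
  r <- ifelse(pur, 5L - ref, ref)
  a <- ifelse(pur, 5L - alt, alt)
  u <- ifelse(pur, 5L - down, up)
  d <- ifelse(pur, 5L - up, down)
  # substitution class: C (r=2) -> A,G,T = classes 1..3; T (r=4) -> A,C,G = 4..6
  cls <- ifelse(r == 2L, match(a, c(1L, 3L, 4L)),
                3L + match(a, c(1L, 2L, 3L)))
  (cls - 1L) * 16L + (u - 1L) * 4L + d
}

# integer base codes of each contig (1=A,2=C,3=G,4=T)
genome_codes <- function(reference) {
  lapply(setNames(names(reference), names(reference)), function(ch)
    match(strsplit(as.character(reference[[ch]]), "")[[1]], DNA_BASES))
}
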