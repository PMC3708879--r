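# Shared low-level helpers: coordinates, codons, translation.
#
# Coordinate convention used throughout the package: signed, 0-based transcript
# positions on the concatenation utr5 + orf. Position 0 is the 'A' of the main
# START ATG, so negative positions index the 5'UTR (-1 = last UTR nucleotide)
# and a triplet's reading frame is simply pos %% 3.

NUCLEOTIDES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

# codon -> one-letter amino acid, "*" for stops (standard genetic code)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  # GENETIC_CODE is RNA-alphabet keyed; convert U -> T
  setNames(as.character(gc), chartr("U", "T", names(gc)))
}

SENSE_CODONS <- setdiff(chartr("U", "T", names(Biostrings::GENETIC_CODE)), STOP_CODONS)

#' Split ORFs into codons
#'
#' @param orfs Character vector of in-frame coding sequences.
#' @return A list of character vectors, one per input, each element a codon.
#' @keywords internal
split_codons <- function(orfs) {
  nc <- nchar(orfs)
  if (any(nc %% 3L != 0L)) abort("ORF lengths must be divisible by 3.")
  k <- nc %/% 3L
  idx <- rep.int(seq_along(orfs), k)
  starts <- sequence(k, from = 1L, by = 3L)
  cods <- substring(orfs[idx], starts, starts + 2L)
  unname(split(cods, factor(idx, levels = seq_along(orfs))))
}

#' Translate an in-frame nucleotide sequence
#'
#' @param codons Character vector of codons.
#' @return Character vector of one-letter amino acids ("*" for stop codons).
#' @keywords internal
translate_codons <- function(codons) {
  unname(codon_table()[codons])
}

# signed transcript position -> 1-based string index in paste0(utr5, orf)
tx_index <- function(pos, utr_len) pos + utr_len + 1L

# geometric mean of probabilities via mean log; NA if any input is NA
geo_mean <- function(p) exp(mean(log(p)))

# permute the characters of each string (vectorised over genes)
permute_strings <- function(x) {
  vapply(x, function(s) {
    ch <- strsplit(s, "", fixed = TRUE)[[1L]]
    paste0(sample(ch), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# all start positions (1-based) of `pattern` in `x`, overlaps allowed;
# list of integer vectors
locate_all <- function(x, pattern) {
  loc <- stringi::stri_locate_all_fixed(x, pattern, overlap = TRUE)
  lapply(loc, function(m) {
    s <- m[, 1L]
    s[!is.na(s)]
  })
}

# prepend a subclass to a tibble so autoplot()/print dispatch can find it
new_tbl <- function(x, subclass) {
  class(x) <- c(subclass, class(as_tibble(x)))
  x
}

# drop subclass before dplyr ops that would strip attributes anyway
strip_tbl <- function(x) as_tibble(x)
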