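# Enumeration of ATG (and arbitrary codon) occurrences on the signed
# transcript coordinate system, and extraction of context windows around them.

#' Enumerate ATG sites around the START codon
#'
#' Scans the concatenated transcript `utr5 + orf` of every gene and returns
#' each position `p` in `[-min(up_span, |utr5|), min(down_span, |orf| - 3)]`
#' whose triplet reads `ATG`, including `p = 0` (the main START). Positions are
#' signed and 0-based with 0 at the first ORF nucleotide, so the reading frame
#' of a site is `p %% 3` and sites with negative positions lie in the 5'UTR.
#'
#' @param genes A gene-set tibble (see [load_gene_set()]).
#' @param up_span Maximum upstream extent (nt) into the 5'UTR; non-negative.
#' @param down_span Maximum downstream start position (nt) inside the ORF;
#'   non-negative. A site starting at `down_span` is still reported.
#' @return A tibble `gene_id`, `pos`, `frame`, `region` (`"UTR5"`/`"ORF"`),
#'   one row per ATG occurrence.
#' @export
enumerate_atgs <- function(genes, up_span, down_span) {
  enumerate_codon_sites(genes, "ATG", up_span, down_span)
}

#' Enumerate occurrences of an arbitrary codon around the START
#'
#' Generalisation of [enumerate_atgs()] to any nucleotide triplet (used by the
#' non-ATG control profiles). Overlapping occurrences are all reported.
#'
#' @inheritParams enumerate_atgs
#' @param codon A 3-letter nucleotide string.
#' @return A tibble `gene_id`, `pos`, `frame`, `region`.
#' @export
enumerate_codon_sites <- function(genes, codon, up_span, down_span) {
  codon <- toupper(codon)
  if (nchar(codon) != 3L || stringr::str_detect(codon, "[^ACGT]")) {
    abort("`codon` must be a triplet over A/C/G/T.")
  }
  if (up_span < 0 || down_span < 0) abort("Spans must be non-negative.")
  ul <- nchar(genes$utr5)
  ol <- nchar(genes$orf)
  tx <- paste0(genes$utr5, genes$orf)
  hits <- locate_all(tx, codon)
  n_hits <- lengths(hits)
  if (sum(n_hits) == 0) {
    return(tibble(gene_id = character(), pos = integer(),
                  frame = integer(), region = character()))
  }
  idx <- rep.int(seq_len(nrow(genes)), n_hits)
  pos <- unlist(hits, use.names = FALSE) - ul[idx] - 1L
  keep <- pos >= -pmin(up_span, ul[idx]) & pos <= pmin(down_span, ol[idx] - 3L)
  idx <- idx[keep]
  pos <- pos[keep]
  tibble(
    gene_id = genes$gene_id[idx],
    pos = as.integer(pos),
    frame = as.integer(pos %% 3L),
    region = if_else(pos < 0L, "UTR5", "ORF")
  ) %>% arrange(match(.data$gene_id, genes$gene_id), .data$pos)
}

#' Extract the start-context window around a set of sites
#'
#' The context window covers signed offsets relative to the ATG triplet
#' (default -6..-1 and +1..+3; the ATG itself is never part of the window).
#' Offset `-1` is the nucleotide immediately before the 'A', offset `+1` the
#' nucleotide immediately after the 'G'. Offsets falling outside the transcript
#' are returned as `NA`, so callers can score partial contexts.
#'
#' @param genes A gene-set tibble.
#' @param sites A site tibble with `gene_id` and `pos` (as from
#'   [enumerate_atgs()]).
#' @param offsets Integer vector of context offsets (0 not allowed).
#' @return A character matrix, one row per site, one column per offset
#'   (column names `"-6"` .. `"+3"`).
#' @export
context_matrix <- function(genes, sites, offsets = context_offsets()) {
  if (any(offsets == 0)) abort("Offset 0 is inside the ATG.")
  gi <- match(sites$gene_id, genes$gene_id)
  if (anyNA(gi)) abort("Some sites refer to genes absent from `genes`.")
  ul <- nchar(genes$utr5)[gi]
  tx <- paste0(genes$utr5, genes$orf)[gi]
  txlen <- nchar(tx)
  out <- matrix(NA_character_, nrow = nrow(sites), ncol = length(offsets),
                dimnames = list(NULL, sprintf("%+d", offsets)))
  for (k in seq_along(offsets)) {
    o <- offsets[k]
    p <- sites$pos + if (o < 0) o else o + 2L
    i <- tx_index(p, ul)
    valid <- i >= 1L & i <= txlen
    out[valid, k] <- substring(tx[valid], i[valid], i[valid])
  }
  out
}

#' Default start-context offsets
#'
#' Six nucleotides upstream and three downstream of the ATG triplet, the span
#' of the optimal-context window used to train the PSSM.
#'
#' @return Integer vector `c(-6:-1, 1:3)`.
#' @export
context_offsets <- function() c(-6:-1, 1:3)
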