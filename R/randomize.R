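# Null genomes: synonymous codon resampling by genomic codon bias, per-gene
# codon permutation, the ramp-preserving variant, and the empirical
# per-position depletion/enrichment flags against replicate nulls.

#' Genome-wide codon frequency table
#'
#' Counts every codon (including START and stop) across all ORFs of a gene set.
#'
#' @param genes A gene-set tibble.
#' @return Named integer vector of codon counts over the 64 codons.
#' @export
genome_codon_counts <- function(genes) {
  cods <- unlist(split_codons(genes$orf), use.names = FALSE)
  tab <- table(factor(cods, levels = names(codon_table())))
  setNames(as.integer(tab), names(tab))
}

# sample synonymous replacements for a vector of codons, using family
# probabilities proportional to `counts`; codons of single-codon families
# (Met, Trp) come back unchanged
resample_synonymous <- function(codons, counts) {
  ct <- codon_table()
  aa <- ct[codons]
  out <- codons
  for (a in unique(aa)) {
    fam <- names(ct)[ct == a]
    w <- counts[fam]
    if (sum(w) == 0) w <- rep(1, length(fam))  # unseen family: uniform
    at <- which(aa == a)
    out[at] <- sample(fam, length(at), replace = TRUE, prob = w)
  }
  out
}

#' Generate a randomized genome
#'
#' Three null schemes, all preserving each gene's protein (or at least its
#' amino-acid composition) and permuting 5'UTR nucleotides so UTR nucleotide
#' multisets - hence GC content - are untouched:
#'
#' * `"codon_resample"`: every non-terminal codon after the START is replaced
#'   by a synonymous codon drawn with probability proportional to its
#'   genome-wide frequency; the terminal stop is resampled among stop codons by
#'   their genomic frequencies. Translation is identical to the real gene, and
#'   genomic codon bias and GC content are maintained in expectation.
#' * `"codon_permute"`: the internal codons of each gene are permuted; the
#'   START ATG stays at position 0 and the stop stays terminal, so the per-gene
#'   codon multiset is preserved exactly.
#' * `"ramp_preserving"`: like `"codon_resample"`, but synonymous frequencies
#'   for the first `ramp_len` codons of the ORF are estimated from - and
#'   applied to - that region only, preserving the distinct codon distribution
#'   of the translational ramp; codons beyond `ramp_len` use genome-wide
#'   frequencies. Amino acids absent from the ramp-region table fall back to
#'   genome-wide frequencies (logged).
#'
#' In every scheme the frame-0 ATG content of the ORF is unchanged, since ATG
#' is the sole methionine codon.
#'
#' @param genes A gene-set tibble.
#' @param scheme One of `"codon_resample"`, `"codon_permute"`,
#'   `"ramp_preserving"`.
#' @param ramp_len Ramp length in codons (default 40; `"ramp_preserving"`
#'   only), counted from the START codon inclusive.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return A gene-set tibble of the same shape as the input.
#' @export
randomize_genome <- function(genes,
                             scheme = c("codon_resample", "codon_permute",
                                        "ramp_preserving"),
                             ramp_len = 40L, seed = 1L) {
  scheme <- match.arg(scheme)
  set.seed(seed)
  out <- as_tibble(genes)
  out$utr5 <- permute_strings(out$utr5)

  cod_list <- split_codons(genes$orf)
  k <- lengths(cod_list)
  if (scheme == "codon_permute") {
    new_orf <- vapply(cod_list, function(cods) {
      m <- length(cods)
      mid <- if (m > 2) sample(cods[2:(m - 1)]) else character(0)
      paste0(c(cods[1L], mid, cods[m]), collapse = "")
    }, character(1))
    out$orf <- unname(new_orf)
    return(out)
  }

  counts <- genome_codon_counts(genes)
  all_cods <- unlist(cod_list, use.names = FALSE)
  gene_idx <- rep.int(seq_along(cod_list), k)
  cod_pos <- sequence(k)              # 1-based codon index within the gene
  is_start <- cod_pos == 1L
  is_stop <- cod_pos == k[gene_idx]
  body <- !is_start & !is_stop

  new_cods <- all_cods
  stop_counts <- counts[STOP_CODONS]
  if (sum(stop_counts) == 0) stop_counts <- rep(1, 3)
  new_cods[is_stop] <- sample(STOP_CODONS, sum(is_stop), replace = TRUE,
                              prob = stop_counts)

  if (scheme == "codon_resample") {
    new_cods[body] <- resample_synonymous(all_cods[body], counts)
  } else {
    in_ramp <- body & cod_pos <= ramp_len
    ramp_counts <- table(factor(all_cods[cod_pos <= ramp_len],
                                levels = names(codon_table())))
    ramp_counts <- setNames(as.integer(ramp_counts), names(ramp_counts))
    ct <- codon_table()
    missing_aa <- setdiff(unique(ct[all_cods[in_ramp]]),
                          unique(ct[names(ramp_counts)[ramp_counts > 0]]))
    if (length(missing_aa) > 0) {
      inform(sprintf("Amino acid(s) %s absent from the ramp region; using genome-wide frequencies for them.",
                     paste(missing_aa, collapse = ", ")))
      for (a in missing_aa) {
        fam <- names(ct)[ct == a]
        ramp_counts[fam] <- counts[fam]
      }
    }
    if (any(in_ramp)) new_cods[in_ramp] <- resample_synonymous(all_cods[in_ramp], ramp_counts)
    post <- body & !in_ramp
    if (any(post)) new_cods[post] <- resample_synonymous(all_cods[post], counts)
  }
  out$orf <- vapply(split(new_cods, factor(gene_idx, levels = seq_along(cod_list))),
                    paste0, character(1), collapse = "")
  out$orf <- unname(out$orf)
  out
}

#' Empirical per-position depletion/enrichment flags
#'
#' Compares a real per-position count profile to the same profile computed on
#' replicate null genomes. A position is `DEPLETED` when at least
#' `ceiling(level * n_replicates)` replicates have a strictly larger count than
#' the real genome (with the default 0.95 and 20 replicates: 19 of 20), and
#' `ENRICHED` symmetrically; ties count toward neither side, which makes the
#' rule conservative.
#'
#' @param real A count profile tibble with `pos` and `count` (see
#'   [atg_count_profile()]), or a named numeric vector.
#' @param nulls A tibble `replicate`, `pos`, `count` holding the same profile
#'   for each null genome, or a matrix with one row per replicate and one
#'   column per position (column order matching `real`).
#' @param level Required fraction of replicates (default 0.95).
#' @return A tibble `pos`, `count`, `n_greater`, `n_less`, `flag` with `flag`
#'   in `{"DEPLETED", "ENRICHED", "NS"}`.
#' @export
empirical_position_flags <- function(real, nulls, level = 0.95) {
  if (is.matrix(nulls)) {
    null_mat <- nulls
    if (is.numeric(real) && is.null(dim(real))) {
      real_tbl <- tibble(pos = seq_along(real) - 1L, count = as.numeric(real))
    } else {
      real_tbl <- as_tibble(real)[c("pos", "count")]
    }
    if (ncol(null_mat) != nrow(real_tbl)) abort("Null matrix and real profile have mismatched position axes.")
  } else {
    real_tbl <- as_tibble(real)[c("pos", "count")]
    nulls <- as_tibble(nulls)
    wide <- tidyr::pivot_wider(nulls, id_cols = "replicate",
                               names_from = "pos", values_from = "count")
    null_pos <- as.integer(names(wide)[-1])
    if (!setequal(null_pos, real_tbl$pos) || anyNA(as.matrix(wide[-1]))) {
      abort("Null profiles and real profile have mismatched position axes.")
    }
    null_mat <- as.matrix(wide[-1])[, match(real_tbl$pos, null_pos), drop = FALSE]
  }
  n_rep <- nrow(null_mat)
  need <- ceiling(level * n_rep)
  n_greater <- colSums(null_mat > rep(real_tbl$count, each = n_rep))
  n_less <- colSums(null_mat < rep(real_tbl$count, each = n_rep))
  tibble(
    pos = real_tbl$pos,
    count = real_tbl$count,
    n_greater = as.integer(n_greater),
    n_less = as.integer(n_less),
    flag = dplyr::case_when(
      n_greater >= need ~ "DEPLETED",
      n_less >= need ~ "ENRICHED",
      TRUE ~ "NS"
    )
  )
}
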