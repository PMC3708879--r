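# The ATG-vs-folding-energy control: windowed sequence randomization that
# preserves amino-acid content (ORF) or nucleotide content (UTR), a pluggable
# minimum-free-energy engine contract, and per-window-position paired t-tests
# comparing variants with and without ATGs.

#' Construct a folding engine
#'
#' A folding engine predicts the minimum free energy (MFE, kcal/mol, <= 0) of
#' the RNA secondary structure of each sequence. The contract: `mfe` is a
#' vectorised function from a character vector of sequences to a numeric
#' vector; it is deterministic, returns 0 for the empty sequence and 0 for an
#' unpairable homopolymer. The analysis bookkeeping (variant generation,
#' pairing, dropping, testing) is identical whichever engine is plugged in.
#'
#' @param name Engine name (reported in outputs).
#' @param mfe Vectorised function `character -> numeric`.
#' @return A `folding_engine` object.
#' @export
folding_engine <- function(name, mfe) {
  stopifnot(is.function(mfe))
  structure(list(name = name, mfe = mfe), class = "folding_engine")
}

#' @export
print.folding_engine <- function(x, ...) {
  cat(sprintf("<folding_engine: %s>\n", x$name))
  invisible(x)
}

#' Built-in folding engines
#'
#' * `folding_engine_constant()` returns the same (non-positive) value for
#'   every sequence - the null engine, useful to verify that the paired test
#'   flags nothing in the absence of signal.
#' * `folding_engine_basepair()` is a fast heuristic proxy: the energy is
#'   `-(0.5 * min(#G, #C) + 0.3 * min(#A, #T))`, a stand-in for the number of
#'   stackable G:C and A:U pairs. It is 0 on homopolymers and monotone in
#'   pairing potential, which is all the control needs.
#' * `folding_engine_rnafold()` wraps the ViennaRNA `RNAfold` command-line
#'   predictor when it is installed; it is the thermodynamic backend for real
#'   analyses.
#'
#' @param value Constant MFE returned by the constant engine (default 0).
#' @return A `folding_engine`.
#' @export
folding_engine_constant <- function(value = 0) {
  stopifnot(value <= 0)
  folding_engine("constant", function(seqs) rep(value, length(seqs)))
}

#' @rdname folding_engine_constant
#' @export
folding_engine_basepair <- function() {
  folding_engine("basepair", function(seqs) {
    g <- stringi::stri_count_fixed(seqs, "G")
    c_ <- stringi::stri_count_fixed(seqs, "C")
    a <- stringi::stri_count_fixed(seqs, "A")
    t <- stringi::stri_count_fixed(seqs, "T")
    -(0.5 * pmin(g, c_) + 0.3 * pmin(a, t))
  })
}

#' @rdname folding_engine_constant
#' @param path Path to the `RNAfold` executable.
#' @export
folding_engine_rnafold <- function(path = "RNAfold") {
  folding_engine("rnafold", function(seqs) {
    if (length(seqs) == 0) return(numeric(0))
    out <- system2(path, args = c("--noPS"), input = seqs, stdout = TRUE)
    energies <- stringr::str_match(out, "\\((\\s*-?[0-9.]+)\\)$")[, 2]
    as.numeric(energies[!is.na(energies)])
  })
}

#' Randomized variants of one sequence window
#'
#' Produces `n` randomizations of the `window_len`-nt window starting at
#' signed position `window_start` of the transcript. The portion overlapping
#' the ORF is randomized by synonymous-codon resampling of the codons fully
#' contained in the window (amino acids preserved; partially covered boundary
#' codons are left untouched so the window length never changes); the portion
#' in the 5'UTR is randomized by permuting its nucleotides (GC content
#' preserved). The total number of ATG triplets (all frames) in each variant
#' window is recorded; the main START triplet, which is fixed and identical in
#' every variant when the window covers position 0, is not counted - only
#' alternative ATGs carry contrast between variants.
#'
#' @param gene One-row gene-set tibble.
#' @param window_start Signed window start (nt, 0 = START).
#' @param window_len Window length in nt (default 39 = 13 codons, the
#'   approximate ribosome footprint).
#' @param n Number of variants (default 20).
#' @param seed Integer seed.
#' @param codon_counts Genome-wide codon counts used for synonymous sampling
#'   (default: uniform within each family).
#' @return A tibble `variant`, `seq`, `atg_count`.
#' @export
window_variants <- function(gene, window_start, window_len = 39L, n = 20L,
                            seed = 1L, codon_counts = NULL) {
  gene <- as_tibble(gene)
  stopifnot(nrow(gene) == 1)
  set.seed(seed)
  ul <- nchar(gene$utr5)
  ol <- nchar(gene$orf)
  if (window_start < -ul || window_start + window_len - 1L > ol - 1L) {
    abort("Window crosses a transcript end.")
  }
  counts <- codon_counts %||% setNames(rep(1L, 64L), names(codon_table()))
  mk <- variant_maker(gene$utr5, gene$orf, window_start, window_len, counts)
  seqs <- vapply(seq_len(n), function(i) mk(), character(1))
  tibble(variant = seq_len(n), seq = seqs,
         atg_count = count_alt_atgs(seqs, window_start, window_len))
}

# ATG occurrences in variant windows, excluding the fixed START triplet when
# the window covers transcript position 0 (it is present in every variant and
# carries no contrast)
count_alt_atgs <- function(seqs, window_start, window_len) {
  n_atg <- stringi::stri_count_fixed(seqs, "ATG")
  if (window_start <= 0L && window_start + window_len - 1L >= 2L) {
    n_atg <- n_atg - 1L  # the START itself
  }
  pmax(n_atg, 0L)
}

# closure producing one randomized window string per call; shared between
# window_variants() and the per-gene loop of atg_folding_test()
variant_maker <- function(utr5, orf, window_start, window_len, counts) {
  ul <- nchar(utr5)
  wend <- window_start + window_len - 1L
  utr_part <- if (window_start < 0) {
    substring(utr5, ul + window_start + 1L, ul + min(-1L, wend) + 1L)
  } else ""
  orf_lo <- max(window_start, 0L)
  orf_part <- if (wend >= 0) substring(orf, orf_lo + 1L, wend + 1L) else ""
  utr_chars <- strsplit(utr_part, "", fixed = TRUE)[[1]]

  # codons fully contained in the ORF portion [orf_lo, wend]
  first_cod <- ceiling(orf_lo / 3)            # 0-based codon index
  last_cod <- (wend - 2L) %/% 3L
  fixed_head <- fixed_tail <- ""
  cods <- character(0)
  aa <- character(0)
  if (nchar(orf_part) > 0 && last_cod >= first_cod) {
    fixed_head <- substring(orf, orf_lo + 1L, 3L * first_cod)        # partial codon at left
    fixed_tail <- substring(orf, 3L * (last_cod + 1L) + 1L, wend + 1L) # partial at right
    starts <- 3L * (first_cod:last_cod) + 1L
    cods <- substring(orf, starts, starts + 2L)
    aa <- codon_table()[cods]
  } else if (nchar(orf_part) > 0) {
    fixed_head <- orf_part
  }
  ct <- codon_table()
  fams <- lapply(unique(aa), function(a) {
    fam <- names(ct)[ct == a]
    w <- counts[fam]
    if (sum(w) == 0) w <- rep(1, length(fam))
    list(fam = fam, w = w)
  })
  names(fams) <- unique(aa)

  function() {
    u <- if (length(utr_chars) > 0) paste0(sample(utr_chars), collapse = "") else ""
    o <- if (length(cods) > 0) {
      new_cods <- cods
      for (a in names(fams)) {
        at <- which(aa == a)
        new_cods[at] <- sample(fams[[a]]$fam, length(at), replace = TRUE,
                               prob = fams[[a]]$w)
      }
      paste0(fixed_head, paste0(new_cods, collapse = ""), fixed_tail)
    } else fixed_head
    paste0(u, o)
  }
}

#' Paired test of folding energy in ATG-containing vs ATG-free window variants
#'
#' For every window position, each gene's window is randomized `n` times
#' (amino-acid content preserved in the ORF portion, nucleotide content in the
#' UTR portion); variants are split by whether they contain at least one ATG
#' in any frame, and the per-gene pair (mean MFE of ATG-free variants, mean
#' MFE of ATG-containing variants) enters a paired t-test across genes. Genes
#' with an empty class at a position are dropped there. The sign of the mean
#' difference (`ATG-containing - ATG-free`) says whether ATGs associate with
#' weaker (positive) or stronger (negative) predicted folding, independently
#' of amino-acid content and position.
#'
#' @param genes A gene-set tibble.
#' @param engine A [folding_engine()].
#' @param n Variants per gene per window (default 20).
#' @param seed Integer seed.
#' @param window_len Window length in nt (default 39).
#' @param window_starts Signed window start positions (default `-37:36`, i.e.
#'   windows up to 37 nt up- and downstream of the START).
#' @return A tibble `window_start`, `n_genes`, `mean_diff`, `p_value` of class
#'   `folding_test`. Windows with fewer than 2 usable genes get `NA`.
#' @export
atg_folding_test <- function(genes, engine, n = 20L, seed = 1L,
                             window_len = 39L, window_starts = -37:36) {
  stopifnot(inherits(engine, "folding_engine"))
  counts <- genome_codon_counts(genes)
  ul <- nchar(genes$utr5)
  ol <- nchar(genes$orf)
  res <- purrr::map_dfr(seq_along(window_starts), function(wi) {
    ws <- window_starts[wi]
    eligible <- which(ws >= -ul & ws + window_len - 1L <= ol - 1L)
    if (length(eligible) < 2L) {
      return(tibble(window_start = ws, n_genes = length(eligible),
                    mean_diff = NA_real_, p_value = NA_real_))
    }
    set.seed(seed + wi)
    seqs <- character(length(eligible) * n)
    gene_of <- rep(seq_along(eligible), each = n)
    for (j in seq_along(eligible)) {
      g <- eligible[j]
      mk <- variant_maker(genes$utr5[g], genes$orf[g], ws, window_len, counts)
      seqs[((j - 1L) * n + 1L):(j * n)] <- vapply(seq_len(n), function(i) mk(),
                                                  character(1))
    }
    has_atg <- count_alt_atgs(seqs, ws, window_len) > 0
    mfe <- engine$mfe(seqs)
    if (length(mfe) != length(seqs)) {
      abort(sprintf("Engine '%s' returned %d values for %d sequences.",
                    engine$name, length(mfe), length(seqs)))
    }
    with_m <- tapply(ifelse(has_atg, mfe, NA_real_), gene_of, mean, na.rm = TRUE)
    without_m <- tapply(ifelse(has_atg, NA_real_, mfe), gene_of, mean, na.rm = TRUE)
    ok <- is.finite(with_m) & is.finite(without_m)
    if (sum(ok) < 2L) {
      return(tibble(window_start = ws, n_genes = as.integer(sum(ok)),
                    mean_diff = NA_real_, p_value = NA_real_))
    }
    d <- with_m[ok] - without_m[ok]
    p <- if (sd(d) == 0) {
      if (all(d == 0)) 1 else 0
    } else t.test(with_m[ok], without_m[ok], paired = TRUE)$p.value
    tibble(window_start = ws, n_genes = as.integer(sum(ok)),
           mean_diff = mean(d), p_value = p)
  })
  new_tbl(res, "folding_test")
}
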