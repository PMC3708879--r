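# Fixtures and independent oracles shared across the test files.
# All genomes are generated in code; nothing is read from disk except the
# bundled cost table.

# build a valid gene-set tibble from utr5/orf strings
make_genes <- function(utr5, orf, ids = NULL) {
  ids <- ids %||% sprintf("t%03d", seq_along(orf))
  tibble::tibble(gene_id = ids, utr5 = utr5, orf = orf,
                 utr_ok = nchar(utr5) >= 6)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# random valid gene set: uniform random UTRs and ORF bodies, START + stop
# enforced; used to feed the brute-force oracles
random_genes <- function(n, utr_min = 0, utr_max = 60, body_codons_max = 40,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nts <- c("A", "C", "G", "T")
  utr5 <- vapply(seq_len(n), function(i) {
    len <- sample(utr_min:utr_max, 1)
    paste0(sample(nts, len, replace = TRUE), collapse = "")
  }, character(1))
  sense <- setdiff(
    apply(expand.grid(nts, nts, nts), 1, paste0, collapse = ""),
    c("TAA", "TAG", "TGA"))
  orf <- vapply(seq_len(n), function(i) {
    k <- sample(1:body_codons_max, 1)
    paste0(c("ATG", sample(sense, k, replace = TRUE),
             sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
  }, character(1))
  make_genes(utr5, orf)
}

# ORACLE: position-by-position substring scan for codon occurrences, the
# independent check for enumerate_atgs()/enumerate_codon_sites()
oracle_codon_sites <- function(gene, codon, up_span, down_span) {
  tx <- paste0(gene$utr5, gene$orf)
  ul <- nchar(gene$utr5)
  ol <- nchar(gene$orf)
  lo <- -min(up_span, ul)
  hi <- min(down_span, ol - 3L)
  if (hi < lo) return(integer(0))
  pos <- lo:hi
  idx <- pos + ul + 1L
  pos[substring(tx, idx, idx + 2L) == codon]
}

# ORACLE: brute-force walk to the first in-frame stop
oracle_stop_distance <- function(tx, i) {
  # i: 1-based index of the ATG's first nt
  j <- i
  while (j + 2L <= nchar(tx)) {
    if (substring(tx, j, j + 2L) %in% c("TAA", "TAG", "TGA")) return(j - i)
    j <- j + 3L
  }
  NA_integer_
}

# ORACLE: per-gene translation via a hand-built codon loop (independent of
# split_codons/translate internals)
oracle_translate <- function(orf) {
  code <- vapply(strsplit(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(orf), no.init.codon = TRUE)), "", fixed = TRUE),
    paste0, character(1), collapse = "")
  code
}

# sorted codon multiset of an ORF
codon_multiset <- function(orf) {
  sort(substring(orf, seq(1, nchar(orf) - 2, 3), seq(3, nchar(orf), 3)))
}

# sorted character multiset of a string
nt_multiset <- function(x) sort(strsplit(x, "", fixed = TRUE)[[1]])

# small simulated genome reused across tests (cheap, deterministic)
tiny_sim <- function(n_genes = 150, seed = 11, ...) {
  simulate_genome(sim_params(n_genes = n_genes, seed = seed, ...))
}

# uniform PSSM over the default context window
uniform_pssm <- function() {
  probs <- matrix(0.25, nrow = 4, ncol = 9,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  structure(probs, offsets = c(-6:-1, 1:3), pseudocount = 0,
            n_training = 0L, class = c("pssm", "matrix"))
}

# mildly informative PSSM (A favoured everywhere) so context scores vary
biased_pssm <- function(p_a = 0.4) {
  probs <- matrix((1 - p_a) / 3, nrow = 4, ncol = 9,
                  dimnames = list(c("A", "C", "G", "T"), NULL))
  probs["A", ] <- p_a
  structure(probs, offsets = c(-6:-1, 1:3), pseudocount = 0,
            n_training = 0L, class = c("pssm", "matrix"))
}
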