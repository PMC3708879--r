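# Start-context PSSM: training-set selection, matrix estimation, positional
# entropy, relative context scores, Kozak hamming distance, and the windowed
# context-score profile.

#' Select the PSSM training set of highly translated genes
#'
#' Ranks genes by ribosomal load (mRNA level x ribosomal density), takes the
#' top `pool_frac` fraction as a pool, and randomly samples `top_frac`/
#' `pool_frac` of the pool (i.e. a random half under the defaults) as the
#' training set. The random-half step decouples the training set from the
#' exact expression ranking and lets downstream stages exclude it to avoid
#' over-fitting.
#'
#' @param expr Expression tibble with `gene_id` and `ribosomal_load`.
#' @param top_frac Fraction of all scored genes returned (default 0.02).
#' @param pool_frac Fraction of all scored genes forming the sampling pool
#'   (default 0.04). With `pool_frac == top_frac` the selection degenerates to
#'   the deterministic top-k set.
#' @param seed Integer seed for the random half-sampling.
#' @return Character vector of training `gene_id`s.
#' @export
select_training_set <- function(expr, top_frac = 0.02, pool_frac = 0.04, seed = 1L) {
  stopifnot(pool_frac >= top_frac, top_frac > 0)
  scored <- expr %>% filter(!is.na(.data$ribosomal_load))
  n <- nrow(scored)
  n_pool <- round(pool_frac * n)
  n_train <- round(top_frac * n)
  if (n_pool < 1 || n_train < 1) {
    abort("Too few genes with ribosomal load to form a training set.")
  }
  pool <- scored %>%
    arrange(desc(.data$ribosomal_load)) %>%
    head(n_pool) %>%
    pull("gene_id")
  if (n_train >= n_pool) return(pool)
  set.seed(seed)
  sort(sample(pool, n_train))
}

#' Build the start-context PSSM
#'
#' Estimates per-position nucleotide probabilities from the START contexts of
#' the training genes: `p[i, nt] = (count + pseudocount) / (N + 4 * pseudocount)`.
#' Genes whose full context window is unavailable (5'UTR shorter than the
#' upstream extent of the window) are dropped from the counts.
#'
#' @param genes A gene-set tibble.
#' @param training_ids Character vector of training gene ids.
#' @param offsets Context offsets (default [context_offsets()], -6..-1, +1..+3).
#' @param pseudocount Added to every cell before normalisation (default 0.5);
#'   any positive value guarantees strictly positive probabilities.
#' @return A `pssm` object: a 4 x length(offsets) probability matrix (rows
#'   A/C/G/T, columns the signed offsets), with attributes `offsets`,
#'   `pseudocount` and `n_training`.
#' @export
build_pssm <- function(genes, training_ids, offsets = context_offsets(),
                       pseudocount = 0.5) {
  train <- genes %>% filter(.data$gene_id %in% training_ids)
  if (nrow(train) == 0) abort("Empty training set.")
  starts <- tibble(gene_id = train$gene_id, pos = 0L)
  ctx <- context_matrix(train, starts, offsets)
  full <- stats::complete.cases(ctx)
  ctx <- ctx[full, , drop = FALSE]
  if (nrow(ctx) == 0) abort("No training gene has a complete context window.")
  probs <- apply(ctx, 2, function(col) {
    cnt <- table(factor(col, levels = NUCLEOTIDES))
    (as.numeric(cnt) + pseudocount) / (length(col) + 4 * pseudocount)
  })
  rownames(probs) <- NUCLEOTIDES
  structure(probs, offsets = offsets, pseudocount = pseudocount,
            n_training = nrow(ctx), class = c("pssm", "matrix"))
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("Start-context PSSM: %d positions, %d training genes, pseudocount %g\n",
              ncol(x), attr(x, "n_training"), attr(x, "pseudocount")))
  print(round(unclass(x), 3))
  invisible(x)
}

#' @rdname build_pssm
#' @param x A `pssm` object.
#' @param ... Unused.
#' @method tidy pssm
#' @export
tidy.pssm <- function(x, ...) {
  tibble(
    offset = rep(attr(x, "offsets"), each = 4L),
    nt = rep(NUCLEOTIDES, ncol(x)),
    prob = as.numeric(unclass(x))
  )
}

#' @rdname build_pssm
#' @method glance pssm
#' @export
glance.pssm <- function(x, ...) {
  tibble(n_positions = ncol(x), n_training = attr(x, "n_training"),
         pseudocount = attr(x, "pseudocount"),
         mean_entropy = mean(positional_entropy(x)$entropy))
}

#' Write / read a PSSM as TSV
#'
#' Rows are signed offsets, columns `A C G T`.
#'
#' @param pssm A `pssm` object.
#' @param path Output path.
#' @return `write_pssm` returns the input invisibly; `read_pssm` a `pssm`.
#' @export
write_pssm <- function(pssm, path) {
  tbl <- as_tibble(t(unclass(pssm)))
  tbl <- bind_cols(tibble(offset = attr(pssm, "offsets")), tbl)
  readr::write_tsv(tbl, path)
  invisible(pssm)
}

#' @rdname write_pssm
#' @export
read_pssm <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "d"))
  probs <- t(as.matrix(tbl[NUCLEOTIDES]))
  structure(probs, offsets = as.integer(tbl$offset), pseudocount = NA_real_,
            n_training = NA_integer_, class = c("pssm", "matrix"))
}

#' Per-position entropy of a PSSM
#'
#' Shannon entropy in bits, `-sum(p * log2(p))` with `0 * log2(0) = 0`, for
#' each context position; 2 bits for a uniform column, 0 for a point mass.
#' Optionally z-scored across the window's positions (each value expressed as
#' its number of standard deviations from the across-position mean), the
#' scaling used when comparing conservation profiles between organisms.
#'
#' @param pssm A `pssm` object.
#' @param zscore If `TRUE`, add a z-scored column.
#' @return A tibble `offset`, `entropy` (bits) and, if requested, `z`.
#' @export
positional_entropy <- function(pssm, zscore = FALSE) {
  h <- apply(unclass(pssm), 2, function(p) {
    terms <- ifelse(p > 0, p * log2(p), 0)
    -sum(terms)
  })
  out <- tibble(offset = attr(pssm, "offsets"), entropy = as.numeric(h))
  if (zscore) out$z <- as.numeric(scale(out$entropy))
  new_tbl(out, "entropy_profile")
}

#' Score ATG sites against the PSSM
#'
#' The raw context score of a site is the geometric mean of the PSSM
#' probabilities of its context nucleotides over the window positions; the
#' relative score divides by the raw score of the gene's own START ATG, so the
#' START itself always scores exactly 1 and alternative sites are measured
#' against their gene's initiation context. Sites whose window is truncated by
#' a transcript end are scored over the available positions (the geometric
#' mean renormalises automatically to the available count) and flagged
#' `partial`. A gene whose START context is entirely unavailable yields
#' missing scores, never zero.
#'
#' @param genes A gene-set tibble.
#' @param sites Site tibble with `gene_id`, `pos` (see [enumerate_atgs()]).
#' @param pssm A `pssm` object.
#' @return The site tibble with added columns `raw`, `relative`, `partial`.
#' @export
context_scores <- function(genes, sites, pssm) {
  offsets <- attr(pssm, "offsets")
  raw_of <- function(site_tbl) {
    ctx <- context_matrix(genes, site_tbl, offsets)
    probs <- matrix(NA_real_, nrow = nrow(ctx), ncol = ncol(ctx))
    for (k in seq_len(ncol(ctx))) {
      nt <- ctx[, k]
      ok <- !is.na(nt)
      probs[ok, k] <- unclass(pssm)[cbind(match(nt[ok], NUCLEOTIDES), k)]
    }
    n_avail <- rowSums(!is.na(probs))
    raw <- exp(rowSums(log(probs), na.rm = TRUE) / n_avail)
    raw[n_avail == 0] <- NA_real_
    list(raw = raw, partial = n_avail < length(offsets) & n_avail > 0)
  }
  site_sc <- raw_of(sites)
  start_tbl <- tibble(gene_id = genes$gene_id, pos = 0L)
  start_sc <- raw_of(start_tbl)
  start_raw <- setNames(start_sc$raw, genes$gene_id)
  out <- as_tibble(sites)
  out$raw <- site_sc$raw
  out$relative <- unname(out$raw / start_raw[out$gene_id])
  out$relative[out$pos == 0L & !is.na(out$raw)] <- 1
  out$partial <- site_sc$partial
  out
}

#' Context score of a single site
#'
#' Convenience scalar wrapper around [context_scores()].
#'
#' @param pssm A `pssm` object.
#' @param gene One-row gene-set tibble (or a row of one).
#' @param pos Signed site position (0 = START).
#' @return A one-row tibble `raw`, `relative`, `partial`.
#' @export
context_score <- function(pssm, gene, pos) {
  gene <- as_tibble(gene)
  stopifnot(nrow(gene) == 1)
  context_scores(gene, tibble(gene_id = gene$gene_id, pos = as.integer(pos)),
                 pssm)[, c("raw", "relative", "partial")]
}

#' Hamming distance from the optimal Kozak context
#'
#' Counts mismatches of a site's `(-3, -2, -1, +1)` context nucleotides against
#' the optimal eukaryotic initiation context `ACCATGG` (i.e. `A`, `C`, `C`
#' upstream and `G` downstream of the ATG). 0 means a perfect Kozak context;
#' sites with a truncated context yield `NA`.
#'
#' @param genes A gene-set tibble.
#' @param sites Site tibble with `gene_id`, `pos`. Default: the START of every
#'   gene.
#' @return Integer vector of distances (0-4), one per site.
#' @export
kozak_hamming <- function(genes, sites = NULL) {
  if (is.null(sites)) sites <- tibble(gene_id = genes$gene_id, pos = 0L)
  ctx <- context_matrix(genes, sites, offsets = c(-3L, -2L, -1L, 1L))
  optimal <- c("A", "C", "C", "G")
  mm <- sweep(ctx, 2, optimal, FUN = "!=")
  out <- rowSums(mm)
  out[!stats::complete.cases(ctx)] <- NA_integer_
  as.integer(out)
}

#' Position-averaged relative context-score profile of alternative ATGs
#'
#' Computes the relative context score of every alternative ATG (START sites
#' excluded) and averages the scores in sliding windows of `window` nt (slide
#' 1 nt) centred on each transcript position, mirroring how ribosome-footprint
#' profiles are smoothed. Positions whose window contains no scored site are
#' missing.
#'
#' @param genes A gene-set tibble.
#' @param pssm A `pssm` object.
#' @param up_span Upstream extent (nt) of the profile.
#' @param down_span Downstream extent (nt; default 600, i.e. 200 codons).
#' @param window Smoothing window in nt (default 30).
#' @param exclude Character vector of gene ids to leave out (the PSSM training
#'   set, to avoid over-fitting).
#' @return A tibble `pos`, `mean_score`, `n_sites` of class
#'   `context_profile`.
#' @export
context_score_profile <- function(genes, pssm, up_span = 90L, down_span = 600L,
                                  window = 30L, exclude = character()) {
  keep <- genes %>% filter(!.data$gene_id %in% exclude, .data$utr_ok)
  positions <- seq(-up_span, down_span)
  empty <- new_tbl(tibble(pos = as.integer(positions), mean_score = NA_real_,
                          n_sites = 0L), "context_profile")
  if (nrow(keep) == 0) return(empty)
  sites <- enumerate_atgs(keep, up_span = up_span, down_span = down_span) %>%
    filter(.data$pos != 0L)
  if (nrow(sites) == 0) return(empty)
  scored <- context_scores(keep, sites, pssm) %>% filter(!is.na(.data$relative))
  sums <- tapply(scored$relative, factor(scored$pos, levels = positions),
                 sum, default = 0)
  counts <- tapply(rep(1, nrow(scored)), factor(scored$pos, levels = positions),
                   sum, default = 0)
  half_lo <- window %/% 2L       # centre covers [c - half_lo, c + half_hi]
  half_hi <- window - half_lo - 1L
  roll <- function(x) {
    padded <- c(rep(0, half_lo), x, rep(0, half_hi))
    zoo::rollsum(padded, k = window, align = "left")
  }
  win_sum <- roll(as.numeric(sums))
  win_n <- roll(as.numeric(counts))
  new_tbl(tibble(
    pos = as.integer(positions),
    mean_score = if_else(win_n > 0, win_sum / win_n, NA_real_),
    n_sites = as.integer(win_n)
  ), "context_profile")
}
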