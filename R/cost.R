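# Distance-to-stop and metabolic-cost statistics for alternative ATG sites:
# per-site scan to the first in-frame stop, peptide synthesis cost from an
# amino-acid ATP table, near/far comparisons, and the planted-ATG
# real-vs-null cost comparison.

#' Amino-acid ATP cost table
#'
#' Reads a two-column TSV (`aa`, `atp`; one-letter amino-acid codes) giving the
#' biosynthetic cost of each amino acid in ATP equivalents.
#' [default_cost_table()] returns the bundled table of total energy costs under
#' respiratory conditions in budding yeast.
#'
#' @param path Path to a TSV file.
#' @return A tibble `aa`, `atp` covering all 20 amino acids.
#' @export
read_cost_table <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(aa = "c", atp = "d"))
  if (!setequal(tbl$aa, unique(unname(codon_table()[SENSE_CODONS])))) {
    abort("Cost table must cover exactly the 20 amino acids (one-letter codes).")
  }
  if (any(tbl$atp < 0)) abort("Costs must be non-negative.")
  tbl
}

#' @rdname read_cost_table
#' @export
default_cost_table <- function() {
  read_cost_table(system.file("extdata", "aa_cost_respiratory.tsv",
                              package = "atgscan", mustWork = TRUE))
}

#' Cost of translating one amino acid
#'
#' The canonical in-vivo figure of 7 ATP per incorporated amino acid (tRNA
#' charging, decoding, translocation, E-site release, plus futile cycles).
#'
#' @return The number 7.
#' @export
translation_cost_per_aa <- function() 7

#' Distance to the first in-frame stop and induced peptide cost
#'
#' For each site, scans in-frame triplets of the transcript (`utr5 + orf`, so
#' a 5'UTR uORF may terminate downstream of the START) from the ATG until the
#' first stop codon. Reports the distance in nt from the ATG's first
#' nucleotide to the stop's first nucleotide, the induced peptide (initiator
#' Met included) length, its biosynthesis cost (sum of amino-acid ATP costs)
#' and the total cost including the per-residue translation cost. Sites with
#' no in-frame stop before the transcript end are flagged `open_ended` with
#' missing distance/cost, and should be excluded from means.
#'
#' @param genes A gene-set tibble.
#' @param sites Site tibble with `gene_id`, `pos` (see [enumerate_atgs()]).
#' @param cost_table Amino-acid cost tibble (default [default_cost_table()]).
#' @param translation_cost ATP per translated residue added into `total_cost`
#'   (default [translation_cost_per_aa()]).
#' @param include_met Include the initiator methionine in the peptide cost
#'   (default `TRUE`).
#' @return The site tibble with columns `stop_distance_nt`, `peptide_len_aa`,
#'   `synthesis_cost`, `total_cost`, `open_ended`.
#' @export
alt_orf_stats <- function(genes, sites, cost_table = default_cost_table(),
                          translation_cost = translation_cost_per_aa(),
                          include_met = TRUE) {
  gi <- match(sites$gene_id, genes$gene_id)
  if (anyNA(gi)) abort("Some sites refer to genes absent from `genes`.")
  ul <- nchar(genes$utr5)[gi]
  tx <- paste0(genes$utr5, genes$orf)[gi]
  aa_cost <- setNames(cost_table$atp, cost_table$aa)
  ct <- codon_table()

  n <- nrow(sites)
  dist <- rep(NA_integer_, n)
  pep_len <- rep(NA_integer_, n)
  syn <- rep(NA_real_, n)
  for (s in seq_len(n)) {
    i <- tx_index(sites$pos[s], ul[s])
    sub <- substring(tx[s], i)
    m <- nchar(sub) %/% 3L
    if (m < 1L) next
    starts <- seq(1L, by = 3L, length.out = m)
    cods <- substring(sub, starts, starts + 2L)
    if (cods[1L] != "ATG") abort("Site does not point at an ATG triplet.")
    stop_at <- match(TRUE, cods %in% STOP_CODONS)
    if (is.na(stop_at)) next
    dist[s] <- 3L * (stop_at - 1L)
    pep <- cods[seq_len(stop_at - 1L)]
    if (!include_met) pep <- pep[-1L]
    pep_len[s] <- stop_at - 1L
    syn[s] <- sum(aa_cost[ct[pep]])
  }
  out <- as_tibble(sites)
  out$stop_distance_nt <- dist
  out$peptide_len_aa <- pep_len
  out$synthesis_cost <- syn
  out$total_cost <- syn + translation_cost * pep_len
  out$open_ended <- is.na(dist)
  out
}

#' Near vs far alternative ATGs: stop distance and metabolic cost
#'
#' Out-of-frame alternative ATGs within `span` nt on either side of the START
#' are split into a *near* group (strictly under `near_cutoff` codons from the
#' START) and a *far* group (the remainder of the span), separately for the
#' 5'UTR and the ORF. For each region the group means of the distance to the
#' first in-frame stop and of the induced peptide cost are reported together
#' with two-sample KS p-values. Under selection for cheap spurious initiation,
#' near ATGs have closer stops and cheaper peptides. Open-ended sites are
#' excluded.
#'
#' @param genes A gene-set tibble.
#' @param near_cutoff Near-group cutoff in codons (default 6).
#' @param span Analysed span in nt on each side (default 300).
#' @param cost_table Amino-acid cost tibble.
#' @param include_translation Use `total_cost` (synthesis + 7 ATP/aa) instead
#'   of the synthesis cost alone.
#' @return A list with `groups` (tibble `region`, `group`, `n`,
#'   `mean_stop_distance_nt`, `mean_cost`) and `tests` (tibble `region`,
#'   `metric`, `p_value`). Empty groups are dropped with a message.
#' @export
near_far_comparison <- function(genes, near_cutoff = 6L, span = 300L,
                                cost_table = default_cost_table(),
                                include_translation = FALSE) {
  sites <- enumerate_atgs(genes, up_span = span, down_span = span) %>%
    filter(.data$frame != 0L)
  stats <- alt_orf_stats(genes, sites, cost_table = cost_table) %>%
    filter(!.data$open_ended) %>%
    mutate(cost = if (include_translation) .data$total_cost else .data$synthesis_cost,
           group = if_else(abs(.data$pos) < 3L * near_cutoff, "near", "far"))
  groups <- stats %>%
    group_by(.data$region, .data$group) %>%
    summarise(n = n(),
              mean_stop_distance_nt = mean(.data$stop_distance_nt),
              mean_cost = mean(.data$cost), .groups = "drop")
  tests <- purrr::map_dfr(c("UTR5", "ORF"), function(rg) {
    near <- stats %>% filter(.data$region == rg, .data$group == "near")
    far <- stats %>% filter(.data$region == rg, .data$group == "far")
    if (nrow(near) == 0 || nrow(far) == 0) {
      inform(sprintf("Region %s: empty near or far group; comparison skipped.", rg))
      return(tibble(region = character(), metric = character(), p_value = numeric()))
    }
    tibble(
      region = rg,
      metric = c("stop_distance_nt", "cost"),
      p_value = c(
        suppressWarnings(ks.test(near$stop_distance_nt, far$stop_distance_nt)$p.value),
        suppressWarnings(ks.test(near$cost, far$cost)$p.value)
      )
    )
  })
  list(groups = groups, tests = tests, sites = stats)
}

#' Cost of alternative initiation: real genome vs planted-ATG null genomes
#'
#' Generates `n_replicates` codon-resampled null genomes and *plants* the real
#' genome's alternative ATGs into each: the triplet at every real alternative
#' ATG position is overwritten with `ATG` in the null gene, so real and null
#' genomes carry the same alternative-initiation sites and differ only in the
#' sequence downstream (hence in where the first in-frame stop falls). The
#' peptide cost at each planted site is then compared between the real and
#' null genomes. Sites whose triplet would collide with the START or the
#' terminal stop are skipped.
#'
#' @param genes A gene-set tibble.
#' @param n_replicates Number of null genomes (default 20).
#' @param seed Base seed; replicate `r` uses `seed + r`.
#' @param span Span in nt on each side of the START for site collection
#'   (default 300).
#' @param cost_table Amino-acid cost tibble.
#' @param include_translation Compare total cost instead of synthesis cost.
#' @return A list with `sites` (per-site tibble with `cost_real`,
#'   `cost_null_mean`) and `summary` (per-region tibble with `mean_real`,
#'   `mean_null`, one-sided KS `p_value` for real costs being stochastically
#'   smaller than null costs).
#' @export
cost_vs_null <- function(genes, n_replicates = 20L, seed = 1L, span = 300L,
                         cost_table = default_cost_table(),
                         include_translation = FALSE) {
  pick_cost <- function(tbl) if (include_translation) tbl$total_cost else tbl$synthesis_cost
  ol <- setNames(nchar(genes$orf), genes$gene_id)
  sites <- enumerate_atgs(genes, up_span = span, down_span = span) %>%
    filter(.data$pos != 0L) %>%
    mutate(skip = .data$pos %in% c(-1L, -2L) | .data$pos >= ol[.data$gene_id] - 5L)
  n_skip <- sum(sites$skip)
  if (n_skip > 0) inform(sprintf("%d site(s) collide with the START or terminal stop; skipped.", n_skip))
  sites <- sites %>% filter(!.data$skip) %>% select(-"skip")
  real_stats <- alt_orf_stats(genes, sites, cost_table = cost_table)

  null_costs <- matrix(NA_real_, nrow = nrow(sites), ncol = n_replicates)
  for (r in seq_len(n_replicates)) {
    null_genes <- randomize_genome(genes, scheme = "codon_resample", seed = seed + r)
    null_genes <- plant_atgs(null_genes, sites)
    null_costs[, r] <- pick_cost(alt_orf_stats(null_genes, sites, cost_table = cost_table))
  }
  out <- real_stats %>%
    mutate(cost_real = pick_cost(real_stats),
           cost_null_mean = rowMeans(null_costs, na.rm = TRUE))
  summary <- purrr::map_dfr(c("UTR5", "ORF"), function(rg) {
    at <- out$region == rg
    x <- out$cost_real[at]
    y <- as.numeric(null_costs[at, ])
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) return(tibble())
    tibble(region = rg, n_sites = sum(at),
           mean_real = mean(x), mean_null = mean(y),
           p_value = suppressWarnings(
             ks.test(x, y, alternative = "greater")$p.value))
  })
  list(sites = out, summary = summary)
}

# overwrite the triplet at each site position with "ATG" in the (null) genes
plant_atgs <- function(genes, sites) {
  gi <- match(sites$gene_id, genes$gene_id)
  ul <- nchar(genes$utr5)
  for (s in seq_len(nrow(sites))) {
    g <- gi[s]
    p <- sites$pos[s]
    if (p < 0) {
      i <- ul[g] + p + 1L
      substr(genes$utr5[g], i, i + 2L) <- "ATG"
    } else {
      substr(genes$orf[g], p + 1L, p + 3L) <- "ATG"
    }
  }
  genes
}
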