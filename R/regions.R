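# The two estimators of the boundary-anchored region depleted of alternative
# ATGs, the cross-organism averaging rule, and the expression-stratified
# comparison of ATG counts.

#' Region of depressed ATG counts by sliding-window KS tests
#'
#' Slides a window of `window` codons (11 by default, the approximate ribosome
#' footprint; slide 1 codon) from the region boundary inward - from the START
#' into the ORF, or outward from position -1 into the 5'UTR - over the first
#' `span` nt. For each window a two-sample Kolmogorov-Smirnov test compares the
#' per-position ATG counts inside the window against the counts at all
#' remaining in-frame positions of the span; a window counts toward the region
#' only when it is significant at `alpha` *and* its mean count is below the
#' remainder's mean (the directional gate, so only depletion extends the
#' region). If the first window is not significant the region length is 0;
#' otherwise it is `(window - 1) + number of consecutive significant windows
#' from the boundary`, in codons.
#'
#' The frame-0 ORF analysis excludes position 0 itself: the START count equals
#' the number of genes and is not an alternative-initiation signal.
#'
#' @param profile An `atg_profile` tibble for a single frame (see
#'   [atg_count_profile()]).
#' @param region `"ORF"` or `"UTR5"`: which side of the START to analyse.
#' @param window Window length in codons (default 11).
#' @param span Extent of the analysed region in nt (default 90).
#' @param alpha Significance level for each window's KS test (default 0.05).
#' @return A one-row tibble `frame`, `region`, `length_codons`, `n_windows`,
#'   plus list-columns `p_values` and `significant` with the per-window detail,
#'   of class `region_result`.
#' @export
detect_region_ks <- function(profile, region = c("ORF", "UTR5"), window = 11L,
                             span = 90L, alpha = 0.05) {
  region <- match.arg(region)
  frame <- unique(profile$frame)
  if (length(frame) != 1) abort("`profile` must contain a single frame.")
  prof <- strip_tbl(profile) %>% filter(.data$region == !!region)
  if (region == "ORF") {
    prof <- prof %>% filter(.data$pos >= 0L, .data$pos <= span - 1L, .data$pos != 0L) %>%
      arrange(.data$pos)
  } else {
    prof <- prof %>% filter(.data$pos <= -1L, .data$pos >= -span) %>%
      arrange(desc(.data$pos))   # outward from -1
  }
  counts <- prof$count
  n_pos <- length(counts)
  if (window > n_pos) abort("Window longer than the analysed span.")
  n_win <- n_pos - window + 1L
  p_values <- numeric(n_win)
  significant <- logical(n_win)
  for (w in seq_len(n_win)) {
    inside <- counts[w:(w + window - 1L)]
    remainder <- counts[-(w:(w + window - 1L))]
    p <- suppressWarnings(ks.test(inside, remainder)$p.value)
    p_values[w] <- p
    significant[w] <- is.finite(p) && p < alpha && mean(inside) < mean(remainder)
  }
  run <- 0L
  while (run < n_win && significant[run + 1L]) run <- run + 1L
  len <- if (run == 0L) 0L else (window - 1L) + run
  new_tbl(tibble(
    frame = as.integer(frame), region = region,
    length_codons = as.integer(len), n_windows = n_win,
    p_values = list(p_values), significant = list(significant)
  ), "region_result")
}

#' Region of depressed ATG counts from empirical null-genome flags
#'
#' The null-comparison estimator: the region is the maximal run of consecutive
#' in-frame `DEPLETED` positions starting at the region boundary, converted to
#' codons (one in-frame position per codon). A depleted run that does not
#' touch the boundary contributes nothing. The boundary is the first position
#' at which an alternative ATG is *possible*: positions 1, 2, -1 and -2
#' overlap the START triplet (whose `A`/`AT` make an ATG there impossible in
#' any genome), tie with every null replicate, and are therefore skipped -
#' the ORF run starts at position 3, the 5'UTR run at -3 moving outward.
#'
#' @param flags A tibble `pos`, `flag` from [empirical_position_flags()],
#'   holding in-frame positions of one frame.
#' @param frame Reading frame of the flags (0, 1 or 2).
#' @param region `"ORF"` or `"UTR5"`.
#' @return A one-row tibble `frame`, `region`, `length_codons` of class
#'   `region_result`.
#' @export
detect_region_vs_null <- function(flags, frame, region = c("ORF", "UTR5")) {
  region <- match.arg(region)
  flags <- as_tibble(flags)
  if (region == "ORF") {
    f <- flags %>% filter(.data$pos >= 3L) %>% arrange(.data$pos)
  } else {
    f <- flags %>% filter(.data$pos <= -3L) %>% arrange(desc(.data$pos))
  }
  f <- f %>% filter(.data$pos %% 3L == frame)
  run <- 0L
  while (run < nrow(f) && f$flag[run + 1L] == "DEPLETED") run <- run + 1L
  new_tbl(tibble(frame = as.integer(frame), region = region,
                 length_codons = run), "region_result")
}

#' Two-stage mean of region lengths
#'
#' Averages region lengths first across frames within each organism, then
#' across organisms - the convention for reporting a single cross-organism
#' region length.
#'
#' @param results A tibble with columns `organism`, `frame`, `length_codons`
#'   (one row per organism x frame).
#' @param frames Frames to include (default all present).
#' @return A single numeric mean region length in codons.
#' @export
mean_region <- function(results, frames = NULL) {
  results <- as_tibble(results)
  if (!"organism" %in% names(results)) results$organism <- "organism"
  if (!is.null(frames)) results <- results %>% filter(.data$frame %in% frames)
  if (nrow(results) == 0) abort("No region results after frame filtering.")
  results %>%
    group_by(.data$organism) %>%
    summarise(m = mean(.data$length_codons), .groups = "drop") %>%
    pull("m") %>%
    mean()
}

#' Expression-stratified comparison of ATG counts near the START
#'
#' Splits genes into the top and bottom `frac` strata by ribosomal load and
#' compares, per frame and for all frames pooled, the per-gene number of
#' alternative ATGs in the first `span` codons of the 5'UTR and of the ORF
#' (START excluded) between the two strata with two-sample KS tests - eight
#' tests in total. Under selection against spurious initiation, highly
#' translated genes carry fewer ATGs near the START, so small p-values with
#' `mean_top < mean_bottom` are the expected signature.
#'
#' @param genes A gene-set tibble.
#' @param expr Expression tibble with `gene_id`, `ribosomal_load`.
#' @param frac Stratum fraction (default 0.15).
#' @param span Window size in codons on each side of the START (default 30).
#' @return A tibble `region`, `frame` (`"all"` pools frames), `n_top`,
#'   `n_bottom`, `mean_top`, `mean_bottom`, `p_value`.
#' @export
stratified_atg_comparison <- function(genes, expr, frac = 0.15, span = 30L) {
  scored <- inner_join(as_tibble(genes)["gene_id"],
                       expr %>% filter(!is.na(.data$ribosomal_load)),
                       by = "gene_id") %>%
    arrange(desc(.data$ribosomal_load))
  n <- nrow(scored)
  n_strat <- max(1L, floor(frac * n))
  if (n < 2L || n_strat < 2L) abort("Need at least 2 genes per stratum.")
  top_ids <- scored$gene_id[seq_len(n_strat)]
  bottom_ids <- scored$gene_id[(n - n_strat + 1L):n]
  if (frac >= 0.5) bottom_ids <- setdiff(scored$gene_id, top_ids)

  span_nt <- 3L * span
  sites <- enumerate_atgs(genes, up_span = span_nt, down_span = span_nt - 1L) %>%
    filter(.data$pos != 0L)
  per_gene_counts <- function(ids, rg, fr) {
    s <- sites %>% filter(.data$gene_id %in% ids, .data$region == rg)
    if (!identical(fr, "all")) s <- s %>% filter(.data$frame == fr)
    cnt <- table(factor(s$gene_id, levels = ids))
    as.numeric(cnt)
  }
  grid <- tidyr::expand_grid(region = c("UTR5", "ORF"),
                             frame = list(0L, 1L, 2L, "all"))
  purrr::pmap_dfr(grid, function(region, frame) {
    x <- per_gene_counts(top_ids, region, frame)
    y <- per_gene_counts(bottom_ids, region, frame)
    p <- suppressWarnings(ks.test(x, y)$p.value)
    tibble(region = region,
           frame = as.character(frame),
           n_top = length(x), n_bottom = length(y),
           mean_top = mean(x), mean_bottom = mean(y),
           p_value = p)
  })
}
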