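test_that("count profiles match the string-scan oracle", {
  g3 <- make_genes(rep("ATGCAT", 3), rep("ATGATGTAA", 3),
                   ids = c("a", "b", "c"))
  p0 <- atg_count_profile(g3, frame = 0, up_span = 6, down_span = 9)
  expect_equal(p0$count[p0$pos == -6], 3L)
  expect_equal(p0$count[p0$pos == 0], 3L)
  expect_equal(p0$count[p0$pos == 3], 3L)
  for (f in 1:2) {
    pf <- atg_count_profile(g3, frame = f, up_span = 6, down_span = 9)
    expect_true(all(pf$count == 0L))
  }

  # empty gene set -> zero profile
  p_empty <- atg_count_profile(make_genes(character(), character()), 1)
  expect_true(all(p_empty$count == 0L))

  # random genes vs oracle, all frames
  genes <- random_genes(300, seed = 44)
  for (f in 0:2) {
    prof <- atg_count_profile(genes, frame = f, up_span = 60, down_span = 60)
    oracle <- integer(nrow(prof))
    for (i in seq_len(nrow(genes))) {
      hits <- oracle_codon_sites(genes[i, ], "ATG", 60, 59)
      hits <- hits[hits %% 3 == f]
      oracle <- oracle + as.integer(prof$pos %in% hits)
    }
    expect_identical(prof$count, oracle)
  }
})

test_that("denominators shrink with distance for variable-length UTRs", {
  genes <- random_genes(200, utr_min = 0, utr_max = 80, seed = 46)
  prof <- atg_count_profile(genes, frame = 1, up_span = 80, down_span = 30)
  utr <- prof[prof$region == "UTR5", ]
  expect_true(all(diff(utr$denom) >= 0))  # positions ordered -80 .. -2
  expect_true(all(prof$count <= prof$denom))
})

test_that("codon profiles generalise the ATG profile and see no frame-0 interior stops", {
  genes <- random_genes(100, seed = 47)
  a <- codon_count_profile(genes, "ATG", 1, denom_normalize = FALSE)
  b <- atg_count_profile(genes, frame = 1)
  expect_identical(a$count, b$count)

  # frame-0 ORF interior has no stop triplets before the terminal one
  long <- random_genes(100, body_codons_max = 40, seed = 48)
  taa <- codon_count_profile(long, "TAA", 0, up_span = 0, down_span = 90)
  interior <- taa$pos > 0 & taa$pos <= 90 - 3
  lens <- nchar(long$orf)
  expect_true(all(taa$count[interior & !(taa$pos %in% (lens - 3))] <=
                    sapply(taa$pos[interior & !(taa$pos %in% (lens - 3))],
                           function(p) sum(lens - 3 == p))))
  expect_error(codon_count_profile(genes, "AT", 0), "triplet")
})

test_that("detect_region_ks applies the window formula and the first-window gate", {
  # flat profile: no region
  flat <- tibble::tibble(pos = seq(1, 90), frame = 1L) %>%
    dplyr::filter(pos %% 3 == 1) %>%
    dplyr::mutate(region = "ORF", count = 50L, denom = 100L, scaled = 0)
  class(flat) <- c("atg_profile", class(flat))
  r_flat <- detect_region_ks(flat, "ORF")
  expect_equal(r_flat$length_codons, 0L)

  # hand-built depletion: first 12 in-frame positions empty, rest high
  counts <- c(rep(0L, 12), rep(60L, 18))
  dep <- tibble::tibble(pos = seq(1, 90)[seq(1, 90) %% 3 == 1],
                        frame = 1L, region = "ORF",
                        count = counts, denom = 100L, scaled = 0)
  class(dep) <- c("atg_profile", class(dep))
  r_dep <- detect_region_ks(dep, "ORF", window = 11)
  # consecutive significant windows from the boundary: window k covers
  # in-frame positions k..k+10; windows 1..2 are all-zero, later windows mix
  expect_gte(r_dep$length_codons, 11L)
  expect_lte(r_dep$length_codons, 15L)
  sig <- r_dep$significant[[1]]
  expect_true(sig[1])

  # the directional gate: an *enriched* first window must not open a region
  enr <- dep %>% dplyr::mutate(count = rev(counts))
  class(enr) <- c("atg_profile", class(enr))
  expect_equal(detect_region_ks(enr, "ORF")$length_codons, 0L)

  expect_error(detect_region_ks(dep, "ORF", window = 40), "longer")
})

test_that("region length formula is (window - 1) + consecutive significant windows", {
  # verify on the hand-built profile by recomputing the run length directly
  counts <- c(rep(0L, 14), rep(70L, 16))
  dep <- tibble::tibble(pos = seq(1, 90)[seq(1, 90) %% 3 == 1],
                        frame = 1L, region = "ORF",
                        count = counts, denom = 100L, scaled = 0)
  class(dep) <- c("atg_profile", class(dep))
  res <- detect_region_ks(dep, "ORF", window = 11)
  sig <- res$significant[[1]]
  run <- match(FALSE, sig) - 1
  if (is.na(run)) run <- length(sig)
  expect_equal(res$length_codons, if (run == 0) 0L else 10L + run)
})

test_that("UTR region detection mirrors the ORF procedure outward from -1", {
  # depletion next to the START on the UTR side, frame 2 (positions -1, -4, ...)
  pos <- seq(-90, -1)[seq(-90, -1) %% 3 == 2]
  counts <- ifelse(pos >= -36, 0L, 55L)
  utr <- tibble::tibble(pos = pos, frame = 2L, region = "UTR5",
                        count = counts, denom = 100L, scaled = 0)
  class(utr) <- c("atg_profile", class(utr))
  res <- detect_region_ks(utr, "UTR5", window = 11)
  expect_gte(res$length_codons, 11L)
  # and an un-anchored depletion (far from the boundary) opens nothing
  counts2 <- ifelse(pos <= -60, 0L, 55L)
  utr2 <- utr %>% dplyr::mutate(count = counts2)
  class(utr2) <- c("atg_profile", class(utr2))
  expect_equal(detect_region_ks(utr2, "UTR5", window = 11)$length_codons, 0L)
})

test_that("detect_region_vs_null counts boundary-anchored depleted runs in codons", {
  flags <- tibble::tibble(pos = seq(1, 90)[seq(1, 90) %% 3 == 1],
                          flag = "NS")
  expect_equal(detect_region_vs_null(flags, 1, "ORF")$length_codons, 0L)
  # position 1 overlaps the START and is skipped; the run anchors at 4
  flags$flag[flags$pos %in% c(4, 7, 10, 13, 16)] <- "DEPLETED"
  expect_equal(detect_region_vs_null(flags, 1, "ORF")$length_codons, 5L)
  # a permanently tied (NS) structural position must not break the anchor
  flags$flag[flags$pos == 1] <- "NS"
  expect_equal(detect_region_vs_null(flags, 1, "ORF")$length_codons, 5L)
  # run not touching the boundary -> 0
  flags$flag <- "NS"
  flags$flag[flags$pos %in% c(10, 13, 16)] <- "DEPLETED"
  expect_equal(detect_region_vs_null(flags, 1, "ORF")$length_codons, 0L)
  # UTR side anchors at the outermost possible position (-4 for frame 2)
  uflags <- tibble::tibble(pos = seq(-90, -1)[seq(-90, -1) %% 3 == 2],
                           flag = "NS")
  uflags$flag[uflags$pos >= -10] <- "DEPLETED"
  expect_equal(detect_region_vs_null(uflags, 2, "UTR5")$length_codons, 3L)
})

test_that("mean_region is a two-stage mean over frames then organisms", {
  res <- tibble::tibble(
    organism = c("o1", "o1", "o1", "o2", "o2", "o2"),
    frame = c(0L, 1L, 2L, 0L, 1L, 2L),
    length_codons = c(12, 6, 0, 30, 15, 15))
  expect_equal(mean_region(res), mean(c(mean(c(12, 6, 0)), mean(c(30, 15, 15)))))
  expect_equal(mean_region(res, frames = 1:2), mean(c(3, 15)))
  one <- res[res$organism == "o1", ]
  expect_equal(mean_region(one), 6)
})

test_that("stratified comparison returns 8 tests and maximal p for identical strata", {
  genes <- random_genes(60, utr_min = 20, seed = 50)
  expr <- expression_table(tibble::tibble(
    gene_id = genes$gene_id, mrna = seq_len(60), rd = 1, pa = 1))
  out <- stratified_atg_comparison(genes, expr, frac = 0.15)
  expect_equal(nrow(out), 8L)
  expect_setequal(unique(out$region), c("UTR5", "ORF"))
  expect_setequal(unique(out$frame), c("0", "1", "2", "all"))
  expect_true(all(out$p_value >= 0 & out$p_value <= 1))

  # duplicate the same genes in both strata -> identical count vectors, p = 1
  dup <- dplyr::bind_rows(genes, genes %>% dplyr::mutate(gene_id = paste0(gene_id, "_b")))
  expr_dup <- expression_table(tibble::tibble(
    gene_id = dup$gene_id,
    mrna = c(rep(2, nrow(genes)), rep(1, nrow(genes))), rd = 1, pa = 1))
  out_dup <- stratified_atg_comparison(dup, expr_dup, frac = 0.5)
  expect_true(all(out_dup$p_value == 1))
  expect_equal(out_dup$n_top[1] + out_dup$n_bottom[1], nrow(dup))
})

test_that("stratified comparison detects expression-coupled depletion", {
  sim <- simulate_genome(sim_params(
    n_genes = 2000, seed = 53, expr_noise_sd = 0.2,
    depletion = list(utr_len_codons = 20L, orf_len_codons = 10L,
                     strength = 0.6, expr_coupling = 3)))
  out <- stratified_atg_comparison(sim$genes, sim$expression, frac = 0.15)
  pooled_orf <- out$p_value[out$region == "ORF" & out$frame == "all"]
  expect_lt(pooled_orf, 0.01)
  expect_lt(out$mean_top[out$region == "ORF" & out$frame == "all"],
            out$mean_bottom[out$region == "ORF" & out$frame == "all"])
})

test_that("a planted strength-1 zone is recovered within [L-1, L+window-1] and the estimators bracket", {
  window <- 11L
  L <- 12L
  for (s in 1:4) {
    sim <- simulate_genome(sim_params(
      n_genes = 1500, seed = 300 + s,
      depletion = list(utr_len_codons = 0L, orf_len_codons = L, strength = 1),
      context_effect = 0))
    nulls <- purrr::map_dfr(1:20, function(r) {
      ng <- randomize_genome(sim$genes, "codon_resample", seed = 400 + r)
      tibble::as_tibble(atg_count_profile(ng, frame = 1))[c("pos", "count")] %>%
        dplyr::mutate(replicate = r)
    })
    prof <- atg_count_profile(sim$genes, frame = 1)
    ks_len <- detect_region_ks(prof, "ORF", window = window)$length_codons
    expect_gte(ks_len, L - 1L)
    expect_lte(ks_len, L + window - 1L)
    flags <- empirical_position_flags(prof, nulls)
    vs_len <- detect_region_vs_null(flags, 1, "ORF")$length_codons
    # lower/upper bracket: the flag estimator never exceeds KS + window
    expect_lte(vs_len, ks_len + window)
    expect_gte(vs_len, L - 2L)  # strength-1 zone positions are all depleted
  }
})
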