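test_that("training-set selection takes a seeded random half of the top pool", {
  expr <- expression_table(tibble::tibble(
    gene_id = sprintf("g%04d", 1:1000),
    mrna = seq(1000, 1, length.out = 1000), rd = 1, pa = 1))
  ts <- select_training_set(expr, seed = 5)
  expect_length(ts, 20)                       # 2% of 1000
  expect_true(all(ts %in% sprintf("g%04d", 1:40)))  # drawn from top 4%
  expect_identical(ts, select_training_set(expr, seed = 5))
  expect_false(identical(ts, select_training_set(expr, seed = 6)))
  # degenerate: pool == training -> deterministic top-k
  top <- select_training_set(expr, top_frac = 0.04, pool_frac = 0.04, seed = 1)
  expect_setequal(top, sprintf("g%04d", 1:40))
  expect_error(select_training_set(expr[0, ]), "Too few")
})

test_that("PSSM probabilities follow the count/pseudocount formula", {
  g <- make_genes(c("AAAAAA", "CCCCCA"), c("ATGAAATAA", "ATGAAATAA"))
  pssm0 <- build_pssm(g, g$gene_id, pseudocount = 0)
  expect_equal(unclass(pssm0)["A", "-1"], 1.0)   # both genes have A at -1
  # 4 genes covering all nucleotides at -3 -> uniform column
  g4 <- make_genes(c("AAAAAA", "AAACAA", "AAAGAA", "AAATAA"),
                   rep("ATGAAATAA", 4))
  p4 <- build_pssm(g4, g4$gene_id, pseudocount = 0)
  expect_equal(unname(unclass(p4)[, "-3"]), rep(0.25, 4))
  # single gene with pseudocount: observed 1.5/3, others 0.5/3
  g1 <- make_genes("AAAAAA", "ATGAAATAA")
  p1 <- build_pssm(g1, g1$gene_id, pseudocount = 0.5)
  expect_equal(unclass(p1)["A", "-1"], 1.5 / 3)
  expect_equal(unclass(p1)["C", "-1"], 0.5 / 3, tolerance = 1e-12)
  # columns always sum to 1
  expect_equal(colSums(unclass(p1)), setNames(rep(1, 9), colnames(p1)))
  expect_error(build_pssm(g1, character(0)), "Empty training set")
})

test_that("positional entropy matches the analytic values and bounds", {
  g4 <- make_genes(c("AAAAAA", "AAACAA", "AAAGAA", "AAATAA"),
                   rep("ATGAAATAA", 4))
  p4 <- build_pssm(g4, g4$gene_id, pseudocount = 0)
  h <- positional_entropy(p4)
  expect_equal(h$entropy[h$offset == -3], 2.0)   # uniform column
  expect_equal(h$entropy[h$offset == -1], 0.0)   # point mass (all A)
  # (0.5, 0.5, 0, 0) column: two genes differing at -3
  g2 <- make_genes(c("AAAAAA", "AAACAA"), rep("ATGAAATAA", 2))
  p2 <- build_pssm(g2, g2$gene_id, pseudocount = 0)
  h2 <- positional_entropy(p2)
  expect_equal(h2$entropy[h2$offset == -3], 1.0)
  # bounds + z-scoring on random PSSMs
  set.seed(8)
  for (i in 1:20) {
    probs <- matrix(stats::rexp(36), nrow = 4)
    probs <- sweep(probs, 2, colSums(probs), "/")
    dimnames(probs) <- list(c("A", "C", "G", "T"), NULL)
    pr <- structure(probs, offsets = c(-6:-1, 1:3), pseudocount = 0,
                    n_training = 0L, class = c("pssm", "matrix"))
    hz <- positional_entropy(pr, zscore = TRUE)
    expect_true(all(hz$entropy >= 0 & hz$entropy <= 2))
    expect_equal(mean(hz$z), 0, tolerance = 1e-10)
    expect_equal(sd(hz$z), 1, tolerance = 1e-10)
  }
})

test_that("relative context score is 1 at the START and follows the PSSM ratio", {
  genes <- random_genes(100, utr_min = 6, seed = 12)
  pssm <- uniform_pssm()
  starts <- tibble::tibble(gene_id = genes$gene_id, pos = 0L)
  sc <- context_scores(genes, starts, pssm)
  full <- !sc$partial
  expect_equal(sc$raw[full], rep(0.25, sum(full)))  # uniform PSSM analytic
  expect_equal(sc$relative, rep(1, nrow(sc)))       # self-ratio

  # PSSM with p(-1, A) = 0.6, else uniform; contexts differing only at -1
  probs <- matrix(0.25, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  probs[, 6] <- c(0.6, 0.4 / 3, 0.4 / 3, 0.4 / 3)
  pr <- structure(probs, offsets = c(-6:-1, 1:3), pseudocount = 0,
                  n_training = 0L, class = c("pssm", "matrix"))
  # gene with A at -1 before the START, and an alternative ATG with C at -1
  g <- make_genes("AAAAAAATGCCCCCA", "ATGAAATAA")
  sites <- enumerate_atgs(g, up_span = 15, down_span = 0)
  alt <- context_scores(g, sites[sites$pos == -9, ], pr)
  start_raw <- context_scores(g, tibble::tibble(gene_id = g$gene_id, pos = 0L), pr)$raw
  # alternative context has A at its -1 (pos -10); START has A at -1: ratio 1
  expect_equal(alt$raw / start_raw, 1)
  # analytic ratio for two contexts differing only at -1 (A vs C)
  expect_equal((0.6 / (0.4 / 3))^(1 / 9), 1.182, tolerance = 5e-4)
})

test_that("a gene without a 5'UTR yields missing START scores, not zero", {
  g <- make_genes("", "ATGAAATAA")
  sc <- context_score(uniform_pssm(), g, 0L)
  expect_false(is.na(sc$raw))   # +1..+3 still available -> partial
  expect_true(sc$partial)
  g_sites <- enumerate_atgs(g, 0, 6)
  sc2 <- context_scores(g, g_sites, uniform_pssm())
  expect_true(all(!is.na(sc2$relative)))
})

test_that("context score is monotone in the probability of the observed nucleotide", {
  set.seed(3)
  g <- make_genes("ACGTCA", "ATGGGGTAA")
  for (i in 1:10) {
    probs <- matrix(stats::rexp(36), 4)
    probs <- sweep(probs, 2, colSums(probs), "/")
    dimnames(probs) <- list(c("A", "C", "G", "T"), NULL)
    pr <- structure(probs, offsets = c(-6:-1, 1:3), pseudocount = 0,
                    n_training = 0L, class = c("pssm", "matrix"))
    raw0 <- context_score(pr, g, 0L)$raw
    # bump the probability of the observed nt at a random position
    k <- sample(9, 1)
    obs <- substring(paste0("ACGTCA", "GGG"), k, k)  # context nts of the START
    probs2 <- probs
    probs2[obs, k] <- probs2[obs, k] + 0.2
    probs2[, k] <- probs2[, k] / sum(probs2[, k])
    pr2 <- structure(probs2, offsets = c(-6:-1, 1:3), pseudocount = 0,
                     n_training = 0L, class = c("pssm", "matrix"))
    expect_gte(context_score(pr2, g, 0L)$raw, raw0)
  }
})

test_that("Kozak hamming distance counts mismatches against ACC..G", {
  g <- make_genes(c("AAAACC", "AAATTT", "AAAGCC"),
                  c("ATGGGGTAA", "ATGAAATAA", "ATGGGGTAA"))
  expect_equal(kozak_hamming(g), c(0L, 4L, 1L))
  # truncated context -> missing
  g_short <- make_genes("CC", "ATGGGGTAA")
  expect_true(is.na(kozak_hamming(g_short)))
})

test_that("high-expression genes get higher START scores under a trained PSSM", {
  sim <- simulate_genome(sim_params(n_genes = 1500, seed = 19,
                                    context_effect = 2))
  train <- select_training_set(sim$expression, seed = 1)
  pssm <- build_pssm(sim$genes, train)
  rest <- sim$genes %>% dplyr::filter(!gene_id %in% train)
  sc <- context_scores(rest, tibble::tibble(gene_id = rest$gene_id, pos = 0L), pssm)
  df <- dplyr::inner_join(tibble::tibble(gene_id = rest$gene_id, raw = sc$raw),
                          sim$expression, by = "gene_id")
  df <- df[order(-df$ribosomal_load), ]
  n <- nrow(df)
  top <- df$raw[1:floor(n / 10)]
  bottom <- df$raw[(n - floor(n / 10) + 1):n]
  expect_gt(mean(top, na.rm = TRUE), mean(bottom, na.rm = TRUE))
})

test_that("context-score profile smooths sites over 30-nt windows", {
  pssm <- uniform_pssm()
  # no alternative ATGs at all -> all-missing profile
  g_none <- make_genes("CCCCCC", "ATGAAACCCTAA")
  prof0 <- context_score_profile(g_none, pssm, up_span = 10, down_span = 10)
  expect_true(all(is.na(prof0$mean_score)))

  # single site: exactly `window` consecutive positions carry its score
  g1 <- make_genes("CCCCCCCCCCCCCCCCCCCCATGCCCCCCCCC", "ATGAAACCCTAA")
  prof1 <- context_score_profile(g1, pssm, up_span = 40, down_span = 9,
                                 window = 30)
  carried <- which(!is.na(prof1$mean_score))
  expect_length(carried, 30)
  expect_true(all(diff(carried) == 1))

  # two sites 10 nt apart: overlapping window positions average their scores
  g2 <- make_genes("CCCCCCATGCCCCCCCATGCCCCCC", "ATGAAACCCTAA")
  sites2 <- enumerate_atgs(g2, up_span = 30, down_span = 0) %>%
    dplyr::filter(pos != 0)
  expect_equal(sort(sites2$pos), c(-19L, -9L))
  prof2 <- context_score_profile(g2, pssm, up_span = 30, down_span = 9,
                                 window = 30)
  sc2 <- context_scores(g2, sites2, pssm)
  both <- prof2$n_sites == 2
  expect_true(any(both))
  expect_equal(unique(round(prof2$mean_score[both], 12)),
               round(mean(sc2$relative), 12))
})

test_that("PSSM TSV round-trip preserves probabilities", {
  sim <- tiny_sim(80, seed = 2)
  pssm <- build_pssm(sim$genes, sim$genes$gene_id[1:20])
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pssm(pssm, path)
  back <- read_pssm(path)
  expect_equal(unclass(back), unclass(pssm), ignore_attr = TRUE)
  expect_equal(attr(back, "offsets"), attr(pssm, "offsets"))
})
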