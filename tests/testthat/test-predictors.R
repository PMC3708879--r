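test_that("features follow their definitions on constructed genes", {
  pssm <- biased_pssm()
  # gene with no ATGs in codons 1-29 after the START
  g0 <- make_genes("AAACCC", "ATGGGGCCCGGGTAA")
  f0 <- compute_features(g0, pssm)
  expect_equal(f0$alt_atg_count_30, 0L)
  expect_true(is.na(f0$alt_context_mean_30))
  # optimal Kozak context -> distance 0
  g_koz <- make_genes("AAAACC", "ATGGGGTAA")
  expect_equal(compute_features(g_koz, pssm)$kozak_dist, 0L)
  # two planted downstream ATGs inside the 30-codon window
  body <- paste0(rep("GGC", 35), collapse = "")
  orf <- paste0("ATG", substring(body, 1, 27), "ATG", "ATG",
                substring(body, 34), "TAA")
  g2 <- make_genes("CCCCCC", orf)
  f2 <- compute_features(g2, pssm)
  expect_equal(f2$alt_atg_count_30, 2L)
  expect_false(is.na(f2$alt_context_mean_30))
  # count-missing pairing invariant
  sim <- tiny_sim(n_genes = 200, seed = 83)
  ff <- compute_features(sim$genes, pssm)
  expect_identical(is.na(ff$alt_context_mean_30), ff$alt_atg_count_30 == 0L)
})

test_that("binning by descending target averages consecutive blocks", {
  vals <- rnorm(45)
  targ <- runif(45)
  b <- bin_by_target(vals, targ, bin_size = 15)
  expect_equal(nrow(b), 3L)
  ord <- order(targ, decreasing = TRUE)
  expect_equal(b$value_mean[1], mean(vals[ord[1:15]]))
  expect_equal(b$target_mean[3], mean(targ[ord[31:45]]))
  # bin size 1 is the identity (sorted)
  b1 <- bin_by_target(vals, targ, bin_size = 1)
  expect_equal(b1$value_mean, vals[ord])
  expect_error(bin_by_target(vals[1:5], targ[1:5], bin_size = 15), "Fewer")
})

test_that("a noiseless single-feature target is predicted perfectly", {
  sim <- tiny_sim(n_genes = 400, seed = 85)
  pssm <- biased_pssm()
  feats <- compute_features(sim$genes, pssm)
  # target is an exact affine function of the (aligned) feature, so binned
  # Pearson correlation must be 1 up to floating error
  target <- tibble::tibble(gene_id = feats$gene_id,
                           value = 10 + scale(-feats$kozak_dist)[, 1])
  ev <- evaluate_predictor("kozak_dist", feats, target, bin_size = 15,
                           reps = 5, seed = 2)
  expect_gt(ev$r, 0.999)
  # a monotone (exponential) transform still gives perfect rank correlation
  target_exp <- tibble::tibble(gene_id = feats$gene_id,
                               value = exp(scale(-feats$kozak_dist)[, 1]))
  ev_exp <- evaluate_predictor("kozak_dist", feats, target_exp, bin_size = 15,
                               reps = 5, seed = 2)
  expect_gt(ev_exp$r_spearman, 0.99)
})

test_that("pure-noise features yield near-zero cross-validated correlation", {
  set.seed(7)
  n <- 1800
  feats <- tibble::tibble(
    gene_id = sprintf("g%04d", 1:n),
    kozak_dist = sample(0:4, n, replace = TRUE),
    start_context = runif(n),
    alt_atg_count_30 = rpois(n, 1),
    alt_context_mean_30 = runif(n))
  target <- tibble::tibble(gene_id = feats$gene_id, value = rlnorm(n))
  ev <- evaluate_predictor(c("start_context", "alt_atg_count_30"), feats,
                           target, bin_size = 15, reps = 20, seed = 3)
  expect_lt(abs(ev$r), 0.15)   # 60 test bins
})

test_that("adjusted correlation is bounded by the raw one and guards k >= n-1", {
  sim <- tiny_sim(n_genes = 150, seed = 87)
  pssm <- biased_pssm()
  feats <- compute_features(sim$genes, pssm)
  target <- plant_feature_expression(sim$genes, pssm,
                                     c(start_context = 0.5), 0.5, seed = 4)
  names(target)[2] <- "value"
  ev <- evaluate_predictor(c("start_context", "alt_atg_count_30"), feats,
                           target, bin_size = 15, reps = 10, seed = 5)
  expect_lte(ev$r_adjusted, abs(ev$r) + 1e-12)
  # with bins so large that n_bins = k + 1, the adjusted value collapses to 0
  ev_deg <- evaluate_predictor("start_context", feats, target,
                               bin_size = 38, reps = 5, seed = 6)
  expect_equal(ev_deg$n_bins, 2)
  expect_equal(ev_deg$r_adjusted, 0)
})

test_that("bin size 1 reduces to the unbinned correlation", {
  set.seed(11)
  n <- 300
  feats <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                          kozak_dist = 0L,
                          start_context = runif(n),
                          alt_atg_count_30 = 0L,
                          alt_context_mean_30 = NA_real_)
  target <- tibble::tibble(gene_id = feats$gene_id,
                           value = feats$start_context + rnorm(n, sd = 0.1))
  ev <- evaluate_predictor("start_context", feats, target, bin_size = 1,
                           reps = 30, seed = 7)
  # each test half is an unbinned sample; compare to the full-sample correlation
  expect_equal(ev$r, cor(feats$start_context, target$value), tolerance = 0.05)
})

test_that("the ladder recovers planted all-feature structure as A < D", {
  sim <- simulate_genome(sim_params(n_genes = 1200, seed = 89,
                                    context_effect = 1.5))
  train <- select_training_set(sim$expression, seed = 1)
  pssm <- build_pssm(sim$genes, train)
  target <- plant_feature_expression(
    sim$genes, pssm,
    c(kozak_dist = 0.25, start_context = 0.6, alt_atg_count_30 = 0.45,
      alt_context_mean_30 = 0.35),
    noise_sd = 0.35, seed = 13)
  names(target)[2] <- "value"
  feats <- compute_features(sim$genes, pssm, exclude = train)
  rep_out <- ladder_report(feats, target, reps = 20, seed = 17)
  expect_equal(rep_out$predictor, c("A", "B", "C", "D"))
  expect_lt(rep_out$r[rep_out$predictor == "A"],
            rep_out$r[rep_out$predictor == "D"])
  expect_true(all(rep_out$r_adjusted <= abs(rep_out$r) + 1e-12))
  g <- glance(rep_out)
  expect_true(is.logical(g$monotone))
  expect_equal(tidy(rep_out)$r, rep_out$r)
})

test_that("expression planted on feature 2 alone separates B-D from A", {
  sim <- simulate_genome(sim_params(n_genes = 1000, seed = 91,
                                    context_effect = 1.5))
  train <- select_training_set(sim$expression, seed = 2)
  pssm <- build_pssm(sim$genes, train)
  target <- plant_feature_expression(sim$genes, pssm,
                                     c(start_context = 1), 0.2, seed = 3)
  names(target)[2] <- "value"
  feats <- compute_features(sim$genes, pssm, exclude = train)
  rep_out <- ladder_report(feats, target, reps = 15, seed = 4)
  rB <- rep_out$r[rep_out$predictor == "B"]
  rA <- rep_out$r[rep_out$predictor == "A"]
  rD <- rep_out$r[rep_out$predictor == "D"]
  expect_gt(rB, rA)
  expect_equal(rD, rB, tolerance = 0.1)
})

test_that("cross-validated r does not exceed in-sample r beyond noise", {
  sim <- tiny_sim(n_genes = 600, seed = 93)
  pssm <- biased_pssm()
  feats <- compute_features(sim$genes, pssm)
  target <- plant_feature_expression(sim$genes, pssm,
                                     c(start_context = 0.5,
                                       alt_atg_count_30 = 0.3), 0.6, seed = 5)
  names(target)[2] <- "value"
  ev <- evaluate_predictor(c("start_context", "alt_atg_count_30"), feats,
                           target, reps = 20, seed = 6)
  # in-sample: fit and score on the full binned data
  dat <- dplyr::inner_join(feats, target, by = "gene_id")
  z <- atgscan:::aligned_feature_matrix(dat, c("start_context", "alt_atg_count_30"))
  b <- atgscan:::bin_matrix(z, dat$value, 15L)
  fit <- stats::lm.fit(cbind(1, b$x), b$y)
  r_in <- cor(as.numeric(cbind(1, b$x) %*% fit$coefficients), b$y)
  expect_lte(ev$r, r_in + 0.05)
})
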