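# End-to-end orchestration: configuration with the standard defaults, staged
# execution, and a deterministic TSV/JSON report bundle.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its standard
#' default: profile spans of 90 nt, KS windows of 11 codons, 20 null-genome
#' replicates, a 2%-of-4% training set, 15% expression strata, a 6-codon near
#' cutoff over 300 nt, 13-codon folding windows, bins of 15 genes and 100
#' 2-fold cross-validations.
#'
#' @param sim A [sim_params()] list, or `NULL` when loading from files.
#' @param utr5_fasta,orf_fasta,expression_tsv Input paths (used when `sim` is
#'   `NULL`).
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer master seed for every stochastic stage.
#' @param span Profile span in nt on each side of the START.
#' @param ks_window KS window in codons.
#' @param n_replicates Null-genome replicates.
#' @param null_scheme Null scheme for the flags stage.
#' @param top_frac,pool_frac Training-set fractions.
#' @param strat_frac Expression stratum fraction.
#' @param near_cutoff,cost_span Near/far cutoff (codons) and span (nt).
#' @param fold_engine A [folding_engine()] (default the base-pair heuristic).
#' @param fold_n Variants per folding window.
#' @param fold_window_len Folding window length in nt.
#' @param fold_window_starts Folding window start positions.
#' @param bin_size,folds,reps Predictor evaluation parameters.
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_params(),
                       utr5_fasta = NULL, orf_fasta = NULL,
                       expression_tsv = NULL,
                       out_dir = tempfile("atgscan_run_"),
                       seed = 1L,
                       span = 90L, ks_window = 11L,
                       n_replicates = 20L,
                       null_scheme = "codon_resample",
                       top_frac = 0.02, pool_frac = 0.04,
                       strat_frac = 0.15,
                       near_cutoff = 6L, cost_span = 300L,
                       fold_engine = folding_engine_basepair(),
                       fold_n = 20L, fold_window_len = 39L,
                       fold_window_starts = -37:36,
                       bin_size = 15L, folds = 2L, reps = 100L) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full initiation-fidelity analysis
#'
#' Executes, in order: genome simulation (or loading), PSSM training,
#' frame-resolved ATG profiles, null-genome generation and empirical flags,
#' both region estimators, the context-score profile, the expression-stratified
#' comparison, the near/far stop-distance and cost statistics, the folding
#' control, and the predictor ladder. Every stage writes a TSV or JSON file to
#' `out_dir` with a provenance header (`# key: value` lines echoing the seed
#' and parameters), and the whole bundle is deterministic given the seed.
#' When no expression data is available the training-set, stratified and
#' predictor stages are skipped with a logged notice.
#'
#' @param config A [run_config()].
#' @return Invisibly, a named list of stage results (the same objects that
#'   were serialised).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    inform(sprintf("[atgscan] stage: %s", name))
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s (partial outputs retained in %s)",
                    name, conditionMessage(e), config$out_dir))
    })
  }
  prov <- c(seed = config$seed, span = config$span, ks_window = config$ks_window,
            n_replicates = config$n_replicates, null_scheme = config$null_scheme)
  write_stage <- function(tbl, file, extra = NULL) {
    path <- file.path(config$out_dir, file)
    hdr <- sprintf("# %s: %s", names(c(prov, extra)), c(prov, extra))
    writeLines(hdr, path)
    readr::write_tsv(as_tibble(tbl), path, append = TRUE, col_names = TRUE)
    path
  }
  results <- list()

  gen <- stage("input", {
    if (!is.null(config$sim)) {
      sim <- config$sim
      sim$seed <- config$seed
      simulate_genome(sim)
    } else {
      genes <- load_gene_set(config$utr5_fasta, config$orf_fasta)
      expr <- if (!is.null(config$expression_tsv)) read_expression(config$expression_tsv)
      list(genes = genes, expression = expr)
    }
  })
  genes <- gen$genes
  expr <- gen$expression
  results$genes <- genes
  write_stage(genes %>% select(-dplyr::any_of("latent")), "genes.tsv")
  has_expr <- !is.null(expr) && any(!is.na(expr$ribosomal_load))

  training <- character(0)
  pssm <- stage("pssm", {
    if (has_expr) {
      training <- select_training_set(expr, config$top_frac, config$pool_frac,
                                       seed = config$seed)
    } else {
      inform("No expression data: training the PSSM on all context-complete genes.")
      training <- genes$gene_id[genes$utr_ok]
    }
    build_pssm(genes, training)
  })
  results$pssm <- pssm
  write_pssm(pssm, file.path(config$out_dir, "pssm.tsv"))
  write_stage(positional_entropy(pssm, zscore = TRUE), "entropy.tsv")

  profiles <- stage("profiles", count_profiles(genes, up_span = config$span,
                                               down_span = config$span))
  results$profiles <- profiles
  write_stage(profiles, "atg_profiles.tsv")

  flags <- stage("randomize", {
    null_profiles <- purrr::map_dfr(seq_len(config$n_replicates), function(r) {
      ng <- randomize_genome(genes, scheme = config$null_scheme,
                             seed = config$seed + r)
      strip_tbl(count_profiles(ng, up_span = config$span, down_span = config$span)) %>%
        mutate(replicate = r)
    })
    purrr::map_dfr(0:2, function(f) {
      real <- strip_tbl(profiles) %>% filter(.data$frame == f)
      nulls <- null_profiles %>% filter(.data$frame == f) %>%
        select("replicate", "pos", "count")
      empirical_position_flags(real, nulls) %>% mutate(frame = f)
    })
  })
  results$flags <- flags
  write_stage(flags, "position_flags.tsv")

  regions <- stage("regions", {
    ks <- purrr::map_dfr(0:2, function(f) {
      prof <- strip_tbl(profiles) %>% filter(.data$frame == f) %>%
        new_tbl("atg_profile")
      bind_rows(
        strip_tbl(detect_region_ks(prof, "ORF", config$ks_window, config$span)),
        strip_tbl(detect_region_ks(prof, "UTR5", config$ks_window, config$span))
      ) %>% select("frame", "region", "length_codons") %>%
        mutate(estimator = "ks")
    })
    vs <- purrr::map_dfr(0:2, function(f) {
      fl <- flags %>% filter(.data$frame == f)
      bind_rows(
        strip_tbl(detect_region_vs_null(fl, f, "ORF")),
        strip_tbl(detect_region_vs_null(fl, f, "UTR5"))
      ) %>% mutate(estimator = "vs_null")
    })
    bind_rows(ks, vs)
  })
  results$regions <- regions
  write_stage(regions, "regions.tsv")

  results$context_profile <- stage("context_profile",
    context_score_profile(genes, pssm, up_span = config$span,
                          down_span = config$span, exclude = training))
  write_stage(results$context_profile, "context_profile.tsv")

  if (has_expr) {
    results$stratified <- stage("stratified",
      stratified_atg_comparison(genes, expr, frac = config$strat_frac))
    write_stage(results$stratified, "stratified.tsv")
  } else {
    inform("No expression data: stratified comparison skipped.")
  }

  results$near_far <- stage("cost", {
    nf <- near_far_comparison(genes, near_cutoff = config$near_cutoff,
                              span = config$cost_span)
    write_stage(nf$groups, "near_far_groups.tsv")
    write_stage(nf$tests, "near_far_tests.tsv")
    nf
  })

  results$folding <- stage("folding",
    atg_folding_test(genes, config$fold_engine, n = config$fold_n,
                     seed = config$seed, window_len = config$fold_window_len,
                     window_starts = config$fold_window_starts))
  write_stage(results$folding, "folding_test.tsv", extra = c(engine = config$fold_engine$name))

  if (has_expr) {
    results$ladder <- stage("predictors", {
      feats <- compute_features(genes, pssm, exclude = training)
      target <- expr %>%
        select("gene_id", value = "pa") %>%
        filter(!is.na(.data$value))
      ladder_report(feats, target, bin_size = config$bin_size,
                    folds = config$folds, reps = config$reps,
                    seed = config$seed)
    })
    write_stage(results$ladder, "ladder.tsv")
    jsonlite::write_json(
      list(seed = config$seed, reps = config$reps,
           predictors = strip_tbl(results$ladder)),
      file.path(config$out_dir, "ladder.json"),
      auto_unbox = TRUE, digits = NA)
  } else {
    inform("No expression data: predictor ladder skipped.")
  }
  invisible(results)
}
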