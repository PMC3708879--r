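# The staged predictor ladder: initiation-rule features, target-ordered
# binning, repeated 2-fold cross-validated correlations, and the A-D report.

PREDICTOR_FEATURES <- list(
  A = "kozak_dist",
  B = "start_context",
  C = c("start_context", "alt_atg_count_30"),
  D = c("start_context", "alt_atg_count_30", "alt_context_mean_30")
)

#' Initiation-rule features per gene
#'
#' The four features of the predictor ladder:
#'
#' 1. `kozak_dist` - hamming distance of the START context from the optimal
#'    Kozak context `ACCATGG` (smaller = better context);
#' 2. `start_context` - raw PSSM context score of the START ATG (geometric
#'    mean of PSSM probabilities over the window; larger = better);
#' 3. `alt_atg_count_30` - number of alternative ATGs (all frames, START
#'    excluded) starting less than 30 codons downstream of the START;
#' 4. `alt_context_mean_30` - mean relative context score of those sites
#'    (missing when there are none).
#'
#' Genes without a sufficient 5'UTR (`utr_ok = FALSE`) get missing
#' context-dependent features. The PSSM training genes should be passed as
#' `exclude` downstream of PSSM fitting so correlations are not inflated by
#' over-fitting.
#'
#' @param genes A gene-set tibble.
#' @param pssm A [build_pssm()] object.
#' @param exclude Gene ids to drop (typically the PSSM training set).
#' @return A tibble `gene_id`, `kozak_dist`, `start_context`,
#'   `alt_atg_count_30`, `alt_context_mean_30`.
#' @export
compute_features <- function(genes, pssm, exclude = character()) {
  genes <- as_tibble(genes) %>% filter(!.data$gene_id %in% exclude)
  starts <- tibble(gene_id = genes$gene_id, pos = 0L)
  start_sc <- context_scores(genes, starts, pssm)
  kd <- kozak_hamming(genes)
  down <- enumerate_atgs(genes, up_span = 0L, down_span = 3L * 30L - 1L) %>%
    filter(.data$pos > 0L)
  cnt <- down %>% count(.data$gene_id, name = "alt_atg_count_30")
  alt_sc <- context_scores(genes, down, pssm) %>%
    filter(!is.na(.data$relative)) %>%
    group_by(.data$gene_id) %>%
    summarise(alt_context_mean_30 = mean(.data$relative), .groups = "drop")
  out <- tibble(gene_id = genes$gene_id,
                kozak_dist = kd,
                start_context = start_sc$raw) %>%
    left_join(cnt, by = "gene_id") %>%
    left_join(alt_sc, by = "gene_id") %>%
    mutate(alt_atg_count_30 = tidyr::replace_na(.data$alt_atg_count_30, 0L))
  # context of alternative sites is only meaningful where context scoring is
  if (any(!genes$utr_ok)) {
    out$kozak_dist[!genes$utr_ok] <- NA_integer_
    out$start_context[!genes$utr_ok] <- NA_real_
  }
  out
}

# standardized, direction-aligned feature matrix (larger = stronger predicted
# initiation): kozak_dist is negated, counts negated too so every feature has
# the documented orientation of its rule
FEATURE_SIGN <- c(kozak_dist = -1, start_context = 1,
                  alt_atg_count_30 = -1, alt_context_mean_30 = -1)

aligned_feature_matrix <- function(features, which, center = NULL, scale = NULL) {
  x <- as.matrix(features[which])
  x <- sweep(x, 2, FEATURE_SIGN[which], `*`)
  ctr <- center %||% colMeans(x, na.rm = TRUE)
  scl <- scale %||% apply(x, 2, sd, na.rm = TRUE)
  scl[!is.finite(scl) | scl == 0] <- 1
  z <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  z[is.na(z)] <- 0  # genes with no alternative ATG sit at the feature mean
  attr(z, "center") <- ctr
  attr(z, "scale") <- scl
  z
}

#' Bin paired values by descending target
#'
#' Sorts genes by descending target value and averages features and target in
#' consecutive bins of `bin_size` (the last, possibly partial, bin is kept).
#' Binning filters measurement noise before correlating predicted and
#' observed expression.
#'
#' @param values Numeric vector (the feature or prediction).
#' @param target Numeric vector of the same length (the expression measure).
#' @param bin_size Genes per bin (default 15; 1 = no binning).
#' @return A tibble `bin`, `value_mean`, `target_mean`, `n`.
#' @export
bin_by_target <- function(values, target, bin_size = 15L) {
  ok <- !is.na(values) & !is.na(target)
  values <- values[ok]; target <- target[ok]
  n <- length(values)
  if (n < bin_size || n == 0) abort("Fewer usable genes than one bin.")
  ord <- order(target, decreasing = TRUE)
  bin <- (seq_len(n) - 1L) %/% bin_size + 1L
  tibble(bin = bin, value = values[ord], target = target[ord]) %>%
    group_by(.data$bin) %>%
    summarise(value_mean = mean(.data$value), target_mean = mean(.data$target),
              n = n(), .groups = "drop")
}

#' Cross-validated correlation of one predictor
#'
#' Evaluates a predictor built from a feature subset with repeated 2-fold
#' cross-validation: in each repetition the genes are split at random into
#' halves; an ordinary least-squares combination of the standardized,
#' direction-aligned features is fitted to the binned training half (bins of
#' `bin_size` genes in descending target order; bin means of features against
#' bin means of the target) and scored on the binned test half by the Pearson
#' correlation between predicted and observed bin means. The mean over folds
#' and repetitions is returned together with the adjusted correlation
#' `sqrt(max(0, 1 - (1 - r^2) (n - 1) / (n - k - 1)))` (`k` features, `n` test
#' bins), which discounts the gain from adding features.
#'
#' @param feature_names Character vector of feature columns to combine.
#' @param features Feature tibble from [compute_features()].
#' @param target Tibble `gene_id`, `value` (or a numeric vector aligned to
#'   `features`).
#' @param bin_size Genes per bin (default 15).
#' @param folds Number of folds (default 2).
#' @param reps Number of repetitions (default 100).
#' @param seed Integer seed.
#' @return A one-row tibble `r`, `r_adjusted`, `r_spearman`, `n_bins`,
#'   `n_genes`, `reps`.
#' @export
evaluate_predictor <- function(feature_names, features, target, bin_size = 15L,
                               folds = 2L, reps = 100L, seed = 1L) {
  stopifnot(all(feature_names %in% names(features)))
  if (is.numeric(target)) {
    target <- tibble(gene_id = features$gene_id, value = target)
  }
  dat <- features %>%
    inner_join(target, by = "gene_id") %>%
    filter(!is.na(.data$value))
  usable <- stats::complete.cases(dat[c("kozak_dist", "start_context")])
  dat <- dat[usable, , drop = FALSE]
  n <- nrow(dat)
  if (n < folds * bin_size) abort("Too few usable genes for the requested folds and bin size.")
  set.seed(seed)
  rs <- rs_sp <- nb <- c()
  for (rep_i in seq_len(reps)) {
    fold_id <- sample(rep_len(seq_len(folds), n))
    for (f in seq_len(folds)) {
      train <- dat[fold_id != f, , drop = FALSE]
      test <- dat[fold_id == f, , drop = FALSE]
      z_tr <- aligned_feature_matrix(train, feature_names)
      z_te <- aligned_feature_matrix(test, feature_names,
                                     center = attr(z_tr, "center"),
                                     scale = attr(z_tr, "scale"))
      # bin the training half and fit OLS on bin means
      btr <- bin_matrix(z_tr, train$value, bin_size)
      fit <- stats::lm.fit(cbind(1, btr$x), btr$y)
      bte <- bin_matrix(z_te, test$value, bin_size)
      pred <- as.numeric(cbind(1, bte$x) %*% fit$coefficients)
      if (sd(pred) == 0 || sd(bte$y) == 0) next  # degenerate split, skip
      rs <- c(rs, cor(pred, bte$y))
      rs_sp <- c(rs_sp, cor(pred, bte$y, method = "spearman"))
      nb <- c(nb, length(bte$y))
    }
  }
  if (length(rs) == 0) abort("All repetitions degenerate; cannot evaluate predictor.")
  r <- mean(rs)
  n_bins <- mean(nb)
  k <- length(feature_names)
  r_adj <- if (n_bins - k - 1 <= 0) 0 else
    sqrt(max(0, 1 - (1 - r^2) * (n_bins - 1) / (n_bins - k - 1)))
  tibble(r = r, r_adjusted = r_adj, r_spearman = mean(rs_sp),
         n_bins = n_bins, n_genes = n, reps = reps)
}

# bin a feature matrix + target by descending target; returns bin-mean design
bin_matrix <- function(z, target, bin_size) {
  ord <- order(target, decreasing = TRUE)
  z <- z[ord, , drop = FALSE]
  target <- target[ord]
  bin <- (seq_along(target) - 1L) %/% bin_size + 1L
  x <- apply(z, 2, function(col) tapply(col, bin, mean))
  if (is.null(dim(x))) x <- matrix(x, ncol = ncol(z))
  y <- as.numeric(tapply(target, bin, mean))
  list(x = x, y = y)
}

#' The A-D predictor ladder
#'
#' Evaluates the four nested predictors - A: Kozak hamming distance only;
#' B: START context score; C: B plus the count of alternative ATGs within 30
#' codons downstream; D: C plus their mean relative context score - with
#' [evaluate_predictor()] and reports whether the cross-validated correlation
#' increases along the ladder.
#'
#' @inheritParams evaluate_predictor
#' @return A tibble `predictor`, `features`, `r`, `r_adjusted`, `r_spearman`,
#'   `n_bins` of class `ladder_report`; the attribute `monotone` records
#'   whether `r` increases strictly from A to D.
#' @export
ladder_report <- function(features, target, bin_size = 15L, folds = 2L,
                          reps = 100L, seed = 1L) {
  rows <- purrr::imap_dfr(PREDICTOR_FEATURES, function(fset, id) {
    ev <- evaluate_predictor(fset, features, target, bin_size = bin_size,
                             folds = folds, reps = reps, seed = seed)
    tibble(predictor = id, features = paste(fset, collapse = "+"),
           r = ev$r, r_adjusted = ev$r_adjusted, r_spearman = ev$r_spearman,
           n_bins = ev$n_bins)
  })
  out <- new_tbl(rows, "ladder_report")
  attr(out, "monotone") <- !is.unsorted(rows$r, strictly = TRUE)
  out
}

#' @rdname ladder_report
#' @param x A `ladder_report`.
#' @param ... Unused.
#' @method tidy ladder_report
#' @export
tidy.ladder_report <- function(x, ...) strip_tbl(x)

#' @rdname ladder_report
#' @method glance ladder_report
#' @export
glance.ladder_report <- function(x, ...) {
  tibble(monotone = isTRUE(attr(x, "monotone")),
         best_predictor = x$predictor[which.max(x$r)],
         best_r = max(x$r))
}
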