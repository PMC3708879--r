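# Seeded generator of synthetic genomes with the statistical structure the
# analysis assumes: variable-length 5'UTRs, codon-usage-biased ORFs, a tunable
# ATG-depletion zone flanking the START, start contexts whose strength is
# coupled to a latent expression level, and log-normal expression measurements.

#' Simulation parameters
#'
#' Builds and checks the parameter list consumed by [simulate_genome()].
#' Defaults describe a compact yeast-like genome: 5'UTR lengths around the
#' yeast mean of 82 nt, ORFs of 150 codons on average (only the first ~100 nt
#' of the ORF enter any downstream analysis), a mild codon-usage bias, and an
#' ATG-depletion zone of 20 codons of 5'UTR and 8 codons of ORF flanking the
#' START at strength 0.5 - inside the 16-27 / 5-11 codon ranges typical of
#' eukaryotic genomes.
#'
#' @param n_genes Number of genes.
#' @param utr_len_mean Mean 5'UTR length (nt); lengths are Poisson with this
#'   mean, truncated below at 6 nt.
#' @param orf_len_codons_mean Mean ORF length (codons, including START and
#'   stop); Poisson, truncated below at `orf_len_min_codons`.
#' @param orf_len_min_codons Minimum ORF length (codons). Default 40, so every
#'   gene covers the 90-nt analysis span with margin.
#' @param codon_usage Named probability vector over the 61 sense codons;
#'   probabilities must sum to 1 within each synonymous family. Default:
#'   [default_codon_usage()].
#' @param stop_usage Named probability vector over the three stop codons.
#' @param aa_usage Named probability vector over the 20 amino acids giving the
#'   marginal amino-acid composition of simulated ORFs. Default uniform.
#' @param gc_utr GC content of 5'UTR nucleotides.
#' @param depletion List with `utr_len_codons`, `orf_len_codons`,
#'   `strength` (probability in `[0,1]` that a sampled ATG triplet inside the
#'   zone is rejected and resampled) and `expr_coupling` (log-odds slope tying
#'   the per-gene rejection strength to latent expression; 0 = no coupling).
#' @param context_effect Strength of the coupling between latent expression and
#'   the probability that a gene's START context is drawn from the "strong"
#'   (consensus-like) PSSM rather than the uniform one.
#' @param expr_noise_sd Standard deviation of log-scale measurement noise.
#' @param seed Integer seed; all draws flow from this single seed.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(n_genes = 500L,
                       utr_len_mean = 82,
                       orf_len_codons_mean = 150,
                       orf_len_min_codons = 40L,
                       codon_usage = default_codon_usage(),
                       stop_usage = c(TAA = 0.47, TGA = 0.30, TAG = 0.23),
                       aa_usage = NULL,
                       gc_utr = 0.4,
                       depletion = list(utr_len_codons = 20L, orf_len_codons = 8L,
                                        strength = 0.5, expr_coupling = 0),
                       context_effect = 1,
                       expr_noise_sd = 0.5,
                       seed = 1L) {
  depletion <- utils::modifyList(
    list(utr_len_codons = 20L, orf_len_codons = 8L, strength = 0.5, expr_coupling = 0),
    depletion)
  p <- list(n_genes = as.integer(n_genes), utr_len_mean = utr_len_mean,
            orf_len_codons_mean = orf_len_codons_mean,
            orf_len_min_codons = as.integer(orf_len_min_codons),
            codon_usage = codon_usage, stop_usage = stop_usage / sum(stop_usage),
            aa_usage = aa_usage, gc_utr = gc_utr, depletion = depletion,
            context_effect = context_effect, expr_noise_sd = expr_noise_sd,
            seed = as.integer(seed))
  stopifnot(p$n_genes > 0, p$utr_len_mean > 0, p$orf_len_codons_mean > 0,
            p$gc_utr >= 0, p$gc_utr <= 1,
            p$depletion$strength >= 0, p$depletion$strength <= 1,
            p$depletion$utr_len_codons >= 0, p$depletion$orf_len_codons >= 0,
            p$expr_noise_sd >= 0)
  check_codon_usage(p$codon_usage)
  class(p) <- "sim_params"
  p
}

#' Default (mildly biased) codon usage
#'
#' Within each synonymous family the codons receive weights proportional to
#' 1, 2, ..., k (alphabetical order), normalised to sum to 1. This produces a
#' deterministic, moderately biased usage comparable in skew to real unicellular
#' genomes without privileging any particular organism.
#'
#' @return Named numeric vector over the 61 sense codons.
#' @export
default_codon_usage <- function() {
  ct <- codon_table()
  fam <- split(SENSE_CODONS, ct[SENSE_CODONS])
  usage <- unlist(lapply(fam, function(cods) {
    cods <- sort(cods)
    setNames(seq_along(cods) / sum(seq_along(cods)), cods)
  }))
  names(usage) <- sub("^[A-Z*]\\.", "", names(usage))
  usage[SENSE_CODONS]
}

check_codon_usage <- function(usage) {
  if (!all(SENSE_CODONS %in% names(usage))) abort("codon_usage must cover all 61 sense codons.")
  if (any(usage < 0 | usage > 1)) abort("codon_usage entries must be probabilities.")
  ct <- codon_table()
  sums <- tapply(usage[SENSE_CODONS], ct[SENSE_CODONS], sum)
  if (any(abs(sums - 1) > 1e-9)) {
    abort("codon_usage must sum to 1 within each synonymous family.")
  }
  invisible(TRUE)
}

# strong (consensus-like) start-context PSSM used by the generator: columns are
# the 9 context offsets, consensus A A A A C C | G C T at probability `w`
strong_context_probs <- function(w = 0.7) {
  consensus <- c("A", "A", "A", "A", "C", "C", "G", "C", "T")
  sapply(consensus, function(nt) {
    p <- rep((1 - w) / 3, 4)
    names(p) <- NUCLEOTIDES
    p[nt] <- w
    p
  })
}

#' Simulate a genome and matched expression data
#'
#' Generates `n_genes` gene models plus expression measurements, deterministic
#' given the seed. Each ORF begins with ATG, ends with a stop drawn from
#' `stop_usage`, and is internally stop-free in frame 0 by construction (stops
#' are excluded from the body codon alphabet). Within the depletion zones
#' flanking the START, every sampled ATG triplet - in any reading frame - is
#' rejected and locally resampled with probability `depletion$strength`
#' (per-gene strength when `expr_coupling != 0`). Each gene's START context is
#' drawn from a mixture of a strong consensus PSSM and a uniform PSSM with
#' mixture weight `plogis(context_effect * latent)`, tying context strength to
#' the latent log-expression. Measurements are
#' `exp(latent-component + Normal(0, expr_noise_sd))` for mRNA, ribosomal
#' density and protein abundance.
#'
#' @param params A [sim_params()] list.
#' @return A list with elements `genes` (gene-set tibble, including the latent
#'   log-expression in column `latent`) and `expression` (tibble `gene_id`,
#'   `mrna`, `rd`, `pa`, `ribosomal_load`).
#' @export
simulate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(params$seed)
  n <- params$n_genes
  ct <- codon_table()
  usage <- params$codon_usage
  aa_of <- ct[SENSE_CODONS]
  aa_usage <- params$aa_usage %||%
    setNames(rep(1 / 20, 20), sort(unique(aa_of)))
  # overall sampling distribution of body codons: P(aa) * P(codon | aa)
  body_probs <- unname(aa_usage[aa_of]) * usage
  body_probs <- body_probs / sum(body_probs)

  latent <- rnorm(n)
  utr_len <- pmax(6L, stats::rpois(n, params$utr_len_mean))
  orf_cod <- pmax(params$orf_len_min_codons, stats::rpois(n, params$orf_len_codons_mean))

  w_ctx <- plogis(params$context_effect * latent)
  strong <- runif(n) < w_ctx
  strong_p <- strong_context_probs()

  dep <- params$depletion
  strength <- if (dep$expr_coupling != 0 && dep$strength > 0 && dep$strength < 1) {
    plogis(qlogis(dep$strength) + dep$expr_coupling * latent)
  } else rep(dep$strength, n)

  genes <- vector("list", n)
  for (g in seq_len(n)) {
    genes[[g]] <- build_sim_gene(
      utr_len = utr_len[g], orf_codons = orf_cod[g],
      body_probs = body_probs, stop_usage = params$stop_usage,
      gc_utr = params$gc_utr, strong = strong[g], strong_p = strong_p,
      dep_utr = dep$utr_len_codons, dep_orf = dep$orf_len_codons,
      strength = strength[g])
  }
  gene_tbl <- tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    utr5 = vapply(genes, `[[`, character(1), "utr5"),
    orf = vapply(genes, `[[`, character(1), "orf"),
    utr_ok = TRUE,
    latent = latent
  )
  expr <- expression_table(tibble(
    gene_id = gene_tbl$gene_id,
    mrna = exp(0.5 * latent + rnorm(n, sd = params$expr_noise_sd)),
    rd = exp(0.5 * latent + rnorm(n, sd = params$expr_noise_sd)),
    pa = exp(latent + rnorm(n, sd = params$expr_noise_sd))
  ))
  list(genes = gene_tbl, expression = expr, params = params)
}

# Assemble one gene: sample UTR and ORF, plant the START context, then enforce
# the depletion zones by rejection-resampling of the unit (codon, UTR triplet
# or whole context block) containing each tolerated-or-rejected ATG hit.
build_sim_gene <- function(utr_len, orf_codons, body_probs, stop_usage, gc_utr,
                           strong, strong_p, dep_utr, dep_orf, strength) {
  nt_probs <- c(A = (1 - gc_utr) / 2, C = gc_utr / 2, G = gc_utr / 2, T = (1 - gc_utr) / 2)
  utr <- sample(NUCLEOTIDES, utr_len, replace = TRUE, prob = nt_probs)
  n_body <- orf_codons - 2L
  codons <- c("ATG",
              sample(names(body_probs), n_body, replace = TRUE, prob = body_probs),
              sample(names(stop_usage), 1L, prob = stop_usage))

  draw_context <- function() {
    # reject draws whose +1..+3 triplet is a stop: codon 2 of a real ORF is
    # never a stop, and an internal frame-0 stop would break the gene model
    repeat {
      ctx <- if (strong) {
        vapply(seq_len(9), function(k) sample(NUCLEOTIDES, 1L, prob = strong_p[, k]),
               character(1))
      } else sample(NUCLEOTIDES, 9L, replace = TRUE)
      if (!paste0(ctx[7:9], collapse = "") %in% STOP_CODONS) return(ctx)
    }
  }
  ctx <- draw_context()
  # plant: offsets -6..-1 = last 6 UTR nt; +1..+3 = codon 2 of the ORF
  utr[(utr_len - 5L):utr_len] <- ctx[1:6]
  codons[2L] <- paste0(ctx[7:9], collapse = "")

  if (strength > 0 && (dep_utr > 0 || dep_orf > 0)) {
    tolerated <- integer(0)
    converged <- FALSE
    for (iter in seq_len(200L)) {
      orf <- paste0(codons, collapse = "")
      tx <- paste0(paste0(utr, collapse = ""), orf)
      # zone triplet starts (signed): UTR [-3*dep_utr, -3], ORF [3, 3*dep_orf]
      zone <- c(if (dep_utr > 0) seq(-3L * dep_utr, -3L),
                if (dep_orf > 0) seq(3L, 3L * dep_orf))
      zone <- zone[zone >= -utr_len & zone <= nchar(orf) - 3L]
      i <- tx_index(zone, utr_len)
      hit <- zone[substring(tx, i, i + 2L) == "ATG"]
      hit <- setdiff(hit, tolerated)
      if (length(hit) == 0) {
        converged <- TRUE
        break
      }
      rejected <- hit[runif(length(hit)) < strength]
      tolerated <- c(tolerated, setdiff(hit, rejected))
      if (length(rejected) == 0) next
      for (p in rejected) {
        if (p < 0) {
          at <- (utr_len + p + 1L):(utr_len + p + 3L)
          # context block is sacrosanct apart from full redraws
          if (any(at > utr_len - 6L)) {
            ctx <- draw_context()
            utr[(utr_len - 5L):utr_len] <- ctx[1:6]
            codons[2L] <- paste0(ctx[7:9], collapse = "")
          } else {
            utr[at] <- sample(NUCLEOTIDES, 3L, replace = TRUE, prob = nt_probs)
          }
        } else {
          ci <- unique(c(p %/% 3L, (p + 2L) %/% 3L)) + 1L  # codon indices (1-based)
          for (cc in ci) {
            if (cc == 2L) {
              ctx <- draw_context()
              utr[(utr_len - 5L):utr_len] <- ctx[1:6]
              codons[2L] <- paste0(ctx[7:9], collapse = "")
            } else if (cc > 2L && cc < length(codons)) {
              codons[cc] <- sample(names(body_probs), 1L, prob = body_probs)
            }
          }
        }
      }
    }
    if (!converged) {
      abort("Depletion resampling did not converge after 200 passes; the zone may be infeasible at this strength.")
    }
  }
  list(utr5 = paste0(utr, collapse = ""), orf = paste0(codons, collapse = ""))
}

#' Plant expression driven by initiation features
#'
#' Generates synthetic expression from a linear model on the standardized,
#' direction-aligned initiation features of [compute_features()]:
#' `expression = exp(sum(effect * z_feature) + Normal(0, noise_sd))`. Used to
#' test that the predictor ladder recovers planted effects.
#'
#' @param genes A gene-set tibble.
#' @param pssm A [build_pssm()] matrix used to compute context features.
#' @param effects Named numeric vector; names must be feature names of
#'   [compute_features()].
#' @param noise_sd Log-scale noise standard deviation.
#' @param seed Integer seed.
#' @return A tibble `gene_id`, `expression`.
#' @export
plant_feature_expression <- function(genes, pssm, effects, noise_sd, seed) {
  feats <- compute_features(genes, pssm)
  known <- setdiff(names(feats), "gene_id")
  bad <- setdiff(names(effects), known)
  if (length(bad) > 0) {
    abort(sprintf("Unknown feature name(s): %s. Known: %s.",
                  paste(bad, collapse = ", "), paste(known, collapse = ", ")))
  }
  z <- aligned_feature_matrix(feats, names(effects))
  set.seed(seed)
  lin <- as.numeric(z %*% effects[colnames(z)])
  tibble(gene_id = feats$gene_id,
         expression = exp(lin + rnorm(nrow(feats), sd = noise_sd)))
}
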