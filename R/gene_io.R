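# Reading, validating and writing gene models and expression tables.
#
# A gene set is a tibble with one row per gene:
#   gene_id, utr5, orf, utr3 (optional), utr_ok (logical; 5'UTR long enough for
#   context analyses). Every retained row satisfies the gene-model invariants:
#   ORF length >= 6 and divisible by 3, starts with ATG, ends with a stop, and
#   all characters in {A,C,G,T}.

#' Load a gene set from a 5'UTR/ORF FASTA pair
#'
#' Reads one FASTA record per gene per region, matches records by id, and
#' applies the gene-model filters: ORFs must be in-frame (length divisible by 3,
#' at least 6 nt), start with `ATG`, end with a stop codon, and contain only
#' `A/C/G/T`. Records failing any rule are excluded and counted. Genes whose
#' 5'UTR is shorter than `min_utr_len` are retained but flagged
#' (`utr_ok = FALSE`) so that context analyses can skip them while ORF-only
#' analyses keep them.
#'
#' @param utr5_source Path to the 5'UTR FASTA (one record per gene; a record may
#'   be an empty sequence).
#' @param orf_source Path to the ORF FASTA.
#' @param utr3_source Optional path to a 3'UTR FASTA.
#' @param min_utr_len Minimum 5'UTR length (nt) for a gene to enter
#'   context-dependent analyses. Default 6, the upstream extent of the
#'   start-context window.
#' @return A tibble with columns `gene_id`, `utr5`, `orf`, (`utr3`,) `utr_ok`.
#'   The exclusion log (a tibble of `gene_id`, `reason`) is attached as
#'   attribute `"exclusions"` and summarised in a message.
#' @export
load_gene_set <- function(utr5_source, orf_source, utr3_source = NULL,
                          min_utr_len = 6L) {
  utr5 <- read_fasta_tbl(utr5_source, "utr5")
  orf <- read_fasta_tbl(orf_source, "orf")
  genes <- inner_join(orf, utr5, by = "gene_id")
  if (nrow(genes) < nrow(orf) || nrow(genes) < nrow(utr5)) {
    warn(sprintf("%d records present in only one of the two FASTA files were dropped.",
                 nrow(orf) + nrow(utr5) - 2L * nrow(genes)))
  }
  if (!is.null(utr3_source)) {
    genes <- left_join(genes, read_fasta_tbl(utr3_source, "utr3"), by = "gene_id")
  }
  validate_gene_set(genes, min_utr_len = min_utr_len)
}

#' Load a gene set from a single annotation TSV
#'
#' Alternative input dialect: a tab-separated table with columns `gene_id`,
#' `utr5`, `orf` and optionally `utr3`. Same validation as [load_gene_set()].
#'
#' @inheritParams load_gene_set
#' @param path Path to the TSV file.
#' @return See [load_gene_set()].
#' @export
load_gene_table <- function(path, min_utr_len = 6L) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  required <- c("gene_id", "utr5", "orf")
  if (!all(required %in% names(tbl))) {
    abort("Annotation TSV must have columns gene_id, utr5, orf.")
  }
  tbl$utr5[is.na(tbl$utr5)] <- ""
  validate_gene_set(tbl, min_utr_len = min_utr_len)
}

read_fasta_tbl <- function(path, col) {
  seqs <- tryCatch(Biostrings::readBStringSet(path),
                   error = function(e) abort(sprintf("Malformed FASTA '%s': %s", path, conditionMessage(e))))
  ids <- names(seqs)
  if (anyDuplicated(ids)) {
    abort(sprintf("Duplicate gene_id in '%s': %s", path,
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  out <- tibble(gene_id = ids, seq = unname(toupper(as.character(seqs))))
  names(out)[2] <- col
  out
}

#' Validate a gene table against the gene-model invariants
#'
#' @param genes Tibble with `gene_id`, `utr5`, `orf` (and optionally `utr3`).
#' @param min_utr_len Minimum 5'UTR length (nt) for the `utr_ok` flag.
#' @return The validated tibble with an `utr_ok` column; excluded records are
#'   logged in the `"exclusions"` attribute.
#' @export
validate_gene_set <- function(genes, min_utr_len = 6L) {
  genes <- as_tibble(genes)
  if (anyDuplicated(genes$gene_id)) {
    abort(sprintf("Duplicate gene_id: %s",
                  paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", ")))
  }
  genes$utr5 <- toupper(genes$utr5)
  genes$orf <- toupper(genes$orf)
  ok_chars <- !stringr::str_detect(paste0(genes$utr5, genes$orf), "[^ACGT]")
  nc <- nchar(genes$orf)
  reason <- dplyr::case_when(
    !ok_chars ~ "non_acgt_character",
    nc < 6L | nc %% 3L != 0L ~ "orf_not_in_frame",
    !stringr::str_starts(genes$orf, stringr::fixed("ATG")) ~ "orf_no_start_atg",
    !(substring(genes$orf, nc - 2L, nc) %in% STOP_CODONS) ~ "orf_no_terminal_stop",
    TRUE ~ NA_character_
  )
  excl <- tibble(gene_id = genes$gene_id[!is.na(reason)],
                 reason = reason[!is.na(reason)])
  kept <- genes[is.na(reason), , drop = FALSE]
  kept$utr_ok <- nchar(kept$utr5) >= min_utr_len
  if (nrow(excl) > 0) {
    inform(sprintf("Excluded %d record(s): %s.", nrow(excl),
                   paste(sprintf("%s (%d)", names(table(excl$reason)), table(excl$reason)),
                         collapse = ", ")))
  }
  n_flag <- sum(!kept$utr_ok)
  if (n_flag > 0) {
    inform(sprintf("Flagged %d gene(s) with 5'UTR shorter than %d nt (retained for ORF-only analyses).",
                   n_flag, min_utr_len))
  }
  attr(kept, "exclusions") <- excl
  kept
}

#' Write a gene set as a 5'UTR/ORF FASTA pair
#'
#' @param genes A gene-set tibble.
#' @param utr5_path,orf_path Output FASTA paths.
#' @param utr3_path Optional output path for 3'UTRs.
#' @return Invisibly, the input gene set.
#' @export
write_gene_set <- function(genes, utr5_path, orf_path, utr3_path = NULL) {
  write_one <- function(seqs, path) {
    x <- Biostrings::BStringSet(seqs)
    names(x) <- genes$gene_id
    Biostrings::writeXStringSet(x, path)
  }
  write_one(genes$utr5, utr5_path)
  write_one(genes$orf, orf_path)
  if (!is.null(utr3_path) && "utr3" %in% names(genes)) write_one(genes$utr3, utr3_path)
  invisible(genes)
}

#' Read an expression table
#'
#' Expects a TSV with header `gene_id  mrna  rd  pa` (tab-separated; missing
#' measurements encoded as `NA` or empty). The derived ribosomal load
#' (mRNA level x ribosomal density, the per-gene ribosome flux) is added when
#' both factors are present; missing values propagate as missing.
#'
#' @param path Path to the TSV file.
#' @return A tibble `gene_id`, `mrna`, `rd`, `pa`, `ribosomal_load`.
#' @export
read_expression <- function(path) {
  tbl <- readr::read_tsv(path, col_types = readr::cols(
    gene_id = "c", .default = "d"))
  expression_table(tbl)
}

#' Derive the ribosomal load column of an expression table
#'
#' @param tbl Tibble with `gene_id` and any of `mrna`, `rd`, `pa`.
#' @return The table with a `ribosomal_load = mrna * rd` column (NA when either
#'   factor is missing).
#' @export
expression_table <- function(tbl) {
  tbl <- as_tibble(tbl)
  for (col in c("mrna", "rd", "pa")) if (!col %in% names(tbl)) tbl[[col]] <- NA_real_
  bad <- vapply(tbl[c("mrna", "rd", "pa")],
                function(x) any(x < 0, na.rm = TRUE), logical(1))
  if (any(bad)) abort("Expression measurements must be non-negative.")
  tbl$ribosomal_load <- tbl$mrna * tbl$rd
  tbl[c("gene_id", "mrna", "rd", "pa", "ribosomal_load")]
}

#' Combine replicate expression datasets
#'
#' Each dataset is first normalised by its own mean (computed over non-missing
#' entries), then datasets are averaged per gene; a gene present in any input
#' appears in the output, with missing entries ignored in the average. This is
#' the standard way of averaging expression measurements from heterogeneous
#' platforms onto a common unit-mean scale, and makes the result invariant to
#' rescaling any one dataset by a positive constant.
#'
#' @param tables A list of tibbles, each with a `gene_id` column and exactly
#'   one numeric measurement column (any name).
#' @return A tibble `gene_id`, `value` with the combined, unit-mean measure.
#' @export
combine_expression <- function(tables) {
  if (length(tables) < 1) abort("Need at least one expression table.")
  norm <- purrr::imap(tables, function(tbl, i) {
    tbl <- as_tibble(tbl)
    value_col <- setdiff(names(tbl), "gene_id")
    if (length(value_col) != 1) {
      abort("Each table must have gene_id plus exactly one value column.")
    }
    v <- tbl[[value_col]]
    m <- mean(v, na.rm = TRUE)
    if (!is.finite(m)) abort(sprintf("Table %s has no non-missing values.", i))
    tibble(gene_id = tbl$gene_id, value = v / m)
  })
  bind_rows(norm, .id = "table") %>%
    group_by(.data$gene_id) %>%
    summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
    mutate(value = if_else(is.nan(.data$value), NA_real_, .data$value))
}
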