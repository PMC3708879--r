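# Frame-resolved per-position codon count profiles around the START, with
# per-position denominators and STD scaling.

#' Frame-resolved ATG count profile
#'
#' For one reading frame, counts at every in-frame position `p` in
#' `[-up_span, down_span - 1]` the number of genes with an ATG starting at `p`
#' (position 0, the main START, is included in frame 0 - the data layer stores
#' the raw count and leaves any log-scaling to the presentation layer).
#' Per-position denominators record how many genes reach that position, so
#' genes with short 5'UTRs contribute only their available positions. The
#' `scaled` column expresses each count as its number of standard deviations
#' from the mean count, computed separately for the 5'UTR and ORF segments of
#' the profile.
#'
#' @param genes A gene-set tibble.
#' @param frame Reading frame, 0, 1 or 2 (offset of the triplet start relative
#'   to the ORF frame).
#' @param up_span Upstream extent in nt (default 90).
#' @param down_span Downstream extent in nt (default 90; positions
#'   `0 .. down_span - 1`).
#' @return A tibble `pos`, `frame`, `region`, `count`, `denom`, `scaled` of
#'   class `atg_profile`, one row per in-frame position.
#' @export
atg_count_profile <- function(genes, frame, up_span = 90L, down_span = 90L) {
  codon_count_profile(genes, "ATG", frame, up_span, down_span,
                      denom_normalize = FALSE)
}

#' Frame-resolved count profile of an arbitrary codon
#'
#' As [atg_count_profile()] for any triplet (the non-ATG control). With
#' `denom_normalize = TRUE` counts are divided by the per-position denominator
#' (the maximal possible number of appearances at that position) before the
#' per-segment STD scaling, which removes the length artefact of variable
#' 5'UTRs from the scaled values.
#'
#' @inheritParams atg_count_profile
#' @param codon A 3-letter nucleotide string.
#' @param denom_normalize Normalise by denominators before scaling (default
#'   `TRUE` here; [atg_count_profile()] stores raw-count scaling).
#' @return A tibble of class `atg_profile` (see [atg_count_profile()]).
#' @export
codon_count_profile <- function(genes, codon, frame, up_span = 90L,
                                down_span = 90L, denom_normalize = TRUE) {
  if (!frame %in% 0:2) abort("`frame` must be 0, 1 or 2.")
  positions <- seq(-up_span, down_span - 1L)
  positions <- positions[positions %% 3L == frame]
  ul <- nchar(genes$utr5)
  ol <- nchar(genes$orf)
  denom <- vapply(positions, function(p) {
    if (p < 0) sum(ul >= -p) else sum(ol - 3L >= p)
  }, numeric(1))
  sites <- enumerate_codon_sites(genes, codon, up_span = up_span,
                                 down_span = down_span - 1L)
  sites <- sites %>% filter(.data$frame == !!frame)
  cnt <- tapply(rep(1L, nrow(sites)), factor(sites$pos, levels = positions),
                sum, default = 0L)
  out <- tibble(
    pos = as.integer(positions),
    frame = as.integer(frame),
    region = if_else(positions < 0, "UTR5", "ORF"),
    count = as.integer(cnt),
    denom = as.integer(denom)
  )
  val <- if (denom_normalize) ifelse(out$denom > 0, out$count / out$denom, NA) else out$count
  z_segment <- function(v) {
    s <- sd(v, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v, na.rm = TRUE)) / s
  }
  out$scaled <- NA_real_
  for (rg in unique(out$region)) {
    at <- out$region == rg
    out$scaled[at] <- z_segment(val[at])
  }
  new_tbl(out, "atg_profile")
}

#' Count profiles for all three frames
#'
#' Convenience wrapper binding [atg_count_profile()] over frames 0-2 (or
#' [codon_count_profile()] when a codon is given).
#'
#' @inheritParams codon_count_profile
#' @return A tibble of class `atg_profile` with all frames stacked.
#' @export
count_profiles <- function(genes, codon = "ATG", up_span = 90L, down_span = 90L,
                           denom_normalize = FALSE) {
  bind_rows(lapply(0:2, function(f) {
    strip_tbl(codon_count_profile(genes, codon, f, up_span, down_span,
                                  denom_normalize = denom_normalize))
  })) %>% new_tbl("atg_profile")
}
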