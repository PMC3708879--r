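# ggplot2 views of the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_col geom_point geom_hline
#'   facet_wrap labs scale_y_log10
NULL

#' Plot a frame-resolved codon count profile
#'
#' Raw per-position counts against signed position, one panel per frame; the
#' dashed line marks the START.
#'
#' @param object An `atg_profile` tibble (see [atg_count_profile()]).
#' @param scaled Plot the per-segment STD-scaled values instead of raw counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot atg_profile
#' @export
autoplot.atg_profile <- function(object, scaled = FALSE, ...) {
  df <- strip_tbl(object)
  y <- if (scaled) "scaled" else "count"
  ggplot(df, aes(x = .data$pos, y = .data[[y]])) +
    geom_col(width = 2, fill = "grey25") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "red") +
    facet_wrap(~frame, ncol = 1, labeller = ggplot2::label_both) +
    labs(x = "position relative to START (nt)",
         y = if (scaled) "count (SD from segment mean)" else "genes with codon at position")
}

#' Plot a positional entropy profile
#'
#' @param object An `entropy_profile` tibble (see [positional_entropy()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot entropy_profile
#' @export
autoplot.entropy_profile <- function(object, ...) {
  ggplot(strip_tbl(object), aes(x = .data$offset, y = .data$entropy)) +
    geom_line() + geom_point() +
    labs(x = "context offset (nt, ATG excluded)", y = "entropy (bits)")
}

#' Plot a windowed context-score profile
#'
#' @param object A `context_profile` tibble (see [context_score_profile()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot context_profile
#' @export
autoplot.context_profile <- function(object, ...) {
  ggplot(strip_tbl(object) %>% filter(!is.na(.data$mean_score)),
         aes(x = .data$pos, y = .data$mean_score)) +
    geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "red") +
    labs(x = "position relative to START (nt)",
         y = "mean relative context score (30-nt windows)")
}

#' Plot the folding-control test
#'
#' Mean MFE difference (ATG-containing minus ATG-free variants) per window
#' position; significant windows are highlighted.
#'
#' @param object A `folding_test` tibble (see [atg_folding_test()]).
#' @param alpha Highlight threshold (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot folding_test
#' @export
autoplot.folding_test <- function(object, alpha = 0.05, ...) {
  df <- strip_tbl(object) %>%
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha)
  ggplot(df, aes(x = .data$window_start, y = .data$mean_diff,
                 colour = .data$significant)) +
    geom_hline(yintercept = 0, linetype = "dotted") +
    geom_point() +
    labs(x = "window start relative to START (nt)",
         y = "mean MFE difference (with ATG - without, kcal/mol)",
         colour = sprintf("p < %g", alpha))
}

#' Plot the predictor ladder
#'
#' @param object A `ladder_report` tibble (see [ladder_report()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ladder_report
#' @export
autoplot.ladder_report <- function(object, ...) {
  df <- strip_tbl(object) %>%
    tidyr::pivot_longer(c("r", "r_adjusted"), names_to = "measure",
                        values_to = "correlation")
  ggplot(df, aes(x = .data$predictor, y = .data$correlation,
                 fill = .data$measure)) +
    geom_col(position = "dodge") +
    labs(x = "predictor", y = "cross-validated correlation")
}
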