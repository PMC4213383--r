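#' Fold-change map of the metabolome
#'
#' Retention time vs m/z scatter of all groups, with point size and color
#' encoding the log10 fold change — an at-a-glance view of where on the
#' chromatogram and mass range the perturbation acts. Requires ggplot2.
#'
#' @param diff a `diff_results` from [diff_table()].
#' @param table the collapsed [feature_table()] the results came from.
#' @return a ggplot object.
#' @export
plot_fold_map <- function(diff, table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_fold_map needs the ggplot2 package")
  }
  d <- merge(as.data.frame(diff),
             data.frame(group_id = table$features$feature_id,
                        mz = table$features$mz, rt = table$features$rt),
             by = "group_id")
  d <- d[is.finite(d$log_fold), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rt, y = .data$mz,
                                  size = abs(.data$log_fold),
                                  color = .data$log_fold)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_color_gradient2(low = "steelblue", mid = "grey80",
                                   high = "firebrick", midpoint = 0) +
    ggplot2::labs(x = "retention time (s)", y = "m/z",
                  color = "log10 fold", size = "|log10 fold|") +
    ggplot2::theme_minimal()
}

#' Fold changes with Fieller confidence whiskers
#'
#' Bar chart of log10 fold change per group with the Fieller interval as
#' whiskers and dotted guides at the classification threshold; groups with
#' an unbounded interval are drawn without whiskers. Requires ggplot2.
#'
#' @param diff a `diff_results`.
#' @param fold_threshold guide lines at `+/- log10(fold_threshold)`.
#' @param max_groups show at most this many groups, ordered by |log fold|.
#' @return a ggplot object.
#' @export
plot_fold_ci <- function(diff, fold_threshold = 3, max_groups = 40) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_fold_ci needs the ggplot2 package")
  }
  d <- as.data.frame(diff)
  d <- d[is.finite(d$log_fold), ]
  d <- d[order(-abs(d$log_fold)), ]
  d <- utils::head(d, max_groups)
  d$lo <- ifelse(d$ci_low > 0, log10(d$ci_low), NA_real_)
  d$hi <- ifelse(is.finite(d$ci_high) & d$ci_high > 0, log10(d$ci_high), NA_real_)
  d$group_id <- factor(d$group_id, levels = d$group_id[order(d$log_fold)])
  th <- log10(fold_threshold)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group_id, y = .data$log_fold)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.3, color = "firebrick", na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = c(-th, th), linetype = "dotted",
                        color = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "log10 fold (B / A)") +
    ggplot2::theme_minimal()
}
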