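#' Bar plot of per-chromosome mean contact frequencies
#'
#' Positive-pair versus negative-pair mean CF per chromosome, with a star
#' over chromosomes whose comparison is significant.
#'
#' @param summary output of [intra_chromosome_summary()].
#' @return a ggplot object.
#' @export
plot_intra_cf <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_intra_cf needs the ggplot2 package")
  long <- rbind(
    data.frame(chrom = summary$chrom, group = "pos-pos",
               mean_cf = summary$mean_pos),
    data.frame(chrom = summary$chrom, group = "neg-neg",
               mean_cf = summary$mean_neg))
  long$chrom <- factor(long$chrom, levels = summary$chrom)
  stars <- summary[summary$significant, , drop = FALSE]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$chrom, y = .data$mean_cf,
                                          fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "mean contact frequency", fill = NULL)
  if (nrow(stars) > 0L)
    p <- p + ggplot2::annotate(
      "text", x = match(stars$chrom, summary$chrom),
      y = pmax(stars$mean_pos, stars$mean_neg) * 1.05, label = "*")
  p
}

#' ROC and precision-recall curves for scored methods
#'
#' @param scores LOOCV score table (from [loocv_scores()] or
#'   `compare_methods()$scores`).
#' @param which `"roc"` or `"pr"`.
#' @return a ggplot object.
#' @export
plot_curves <- function(scores, which = c("roc", "pr")) {
  which <- match.arg(which)
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_curves needs the ggplot2 package")
  methods <- list(combined = scores$combined_score,
                  baseline = scores$baseline_score)
  dfs <- lapply(names(methods), function(m) {
    if (which == "roc") {
      r <- roc_auc(methods[[m]], scores$label, "lower")
      data.frame(x = r$fpr, y = r$tpr,
                 method = sprintf("%s (AUC %.3f)", m, r$auc))
    } else {
      r <- pr_aupr(methods[[m]], scores$label, "lower")
      data.frame(x = r$recall, y = r$precision,
                 method = sprintf("%s (AUPR %.3f)", m, r$aupr))
    }
  })
  df <- do.call(rbind, dfs)
  labs <- if (which == "roc")
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  colour = NULL)
  else ggplot2::labs(x = "recall", y = "precision", colour = NULL)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$method)) +
    ggplot2::geom_line() + labs
}
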