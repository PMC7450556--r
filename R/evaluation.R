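#' Leave-one-out combined scores
#'
#' Scores every located labeled epitope with the combined 3D-genome KNN
#' method, removing each epitope from the vote pool when it is the target
#' (self-exclusion is by peptide identity, so LOOCV is a single call with
#' the same table as targets and training).
#'
#' @param epitopes located labeled epitopes.
#' @param ensemble a `conformation_ensemble`.
#' @param baseline baseline score table (see [read_baseline_scores()]).
#' @param k neighbourhood size.
#' @return data frame from [predict_immunogenicity()] including the
#'   ground-truth `label` column.
#' @export
loocv_scores <- function(epitopes, ensemble, baseline, k = 10L) {
  ep <- epitopes[epitopes$located, , drop = FALSE]
  if (length(unique(ep$label)) < 2L)
    stop("LOOCV needs located epitopes of both labels")
  predict_immunogenicity(ep, ep, ensemble, baseline, k = k)
}

orient_scores <- function(scores, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  if (orientation == "lower") -as.numeric(scores) else as.numeric(scores)
}

#' ROC curve and AUC
#'
#' Sweeps all score thresholds (tied scores grouped at one threshold) and
#' integrates the curve by the trapezoid rule, which equals the
#' concordant-pair rank statistic with half credit for ties.
#'
#' @param scores numeric prediction scores.
#' @param labels ground truth; `"positive"`/`"negative"` or logical.
#' @param orientation `"lower"` if smaller scores mean predicted positive
#'   (the combined score's convention), `"higher"` otherwise.
#' @return list with `fpr`, `tpr` (curve points, threshold-descending) and
#'   `auc`.
#' @export
roc_auc <- function(scores, labels, orientation = c("lower", "higher")) {
  y <- as_binary_labels(labels)
  if (length(unique(y)) < 2L)
    stop("ROC is undefined with a single class")
  s <- orient_scores(scores, orientation)
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]
  s <- s[ord]
  # group tied scores at a single threshold
  last_of_group <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_group]
  fp <- cumsum(!y)[last_of_group]
  tpr <- c(0, tp / sum(y))
  fpr <- c(0, fp / sum(!y))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Precision-recall curve and area
#'
#' Thresholds sweep the scores from most to least confidently positive
#' (tied scores grouped); the area is accumulated as precision times
#' recall increment (step interpolation, the average-precision
#' convention).
#'
#' @inheritParams roc_auc
#' @return list with `recall`, `precision` and `aupr`.
#' @export
pr_aupr <- function(scores, labels, orientation = c("lower", "higher")) {
  y <- as_binary_labels(labels)
  if (sum(y) == 0L) stop("PR curve needs at least one positive")
  s <- orient_scores(scores, orientation)
  ord <- order(s, decreasing = TRUE)
  y <- y[ord]
  s <- s[ord]
  last_of_group <- c(diff(s) != 0, TRUE)
  tp <- cumsum(y)[last_of_group]
  n_seen <- which(last_of_group)
  precision <- tp / n_seen
  recall <- tp / sum(y)
  aupr <- sum(diff(c(0, recall)) * precision)
  list(recall = recall, precision = precision, aupr = aupr)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels > 0)
  labels == "positive"
}

#' Compare combined scoring against the baseline alone
#'
#' Runs LOOCV, computes AUC and AUPR for the combined score and for the
#' baseline-only score, and attaches percentile bootstrap confidence
#' intervals (resampling epitopes with replacement).
#'
#' @param epitopes located labeled epitopes.
#' @param ensemble a `conformation_ensemble`.
#' @param baseline baseline score table.
#' @param k neighbourhood size.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @param conf confidence level.
#' @return list with `table` (method x metric data frame with CI bounds)
#'   and `scores` (the LOOCV score table).
#' @export
compare_methods <- function(epitopes, ensemble, baseline, k = 10L,
                            n_boot = 1000L, seed = 1L, conf = 0.95) {
  sc <- loocv_scores(epitopes, ensemble, baseline, k = k)
  methods <- list(combined = sc$combined_score, baseline = sc$baseline_score)
  y <- sc$label
  alpha <- (1 - conf) / 2
  rows <- lapply(names(methods), function(m) {
    s <- methods[[m]]
    auc <- roc_auc(s, y, "lower")$auc
    aupr <- pr_aupr(s, y, "lower")$aupr
    boot <- withr::with_seed(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(length(s), replace = TRUE)
        if (length(unique(y[idx])) < 2L) return(c(NA_real_, NA_real_))
        c(roc_auc(s[idx], y[idx], "lower")$auc,
          pr_aupr(s[idx], y[idx], "lower")$aupr)
      }, numeric(2))
    })
    data.frame(method = m, auc = auc,
               auc_lo = stats::quantile(boot[1L, ], alpha, na.rm = TRUE),
               auc_hi = stats::quantile(boot[1L, ], 1 - alpha, na.rm = TRUE),
               aupr = aupr,
               aupr_lo = stats::quantile(boot[2L, ], alpha, na.rm = TRUE),
               aupr_hi = stats::quantile(boot[2L, ], 1 - alpha, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, scores = sc)
}

#' Write a method-comparison report
#'
#' Emits the comparison table as TSV and, with the per-epitope scores and
#' run metadata, as JSON.
#'
#' @param report result of [compare_methods()].
#' @param path_tsv,path_json output paths (either may be `NULL` to skip).
#' @return invisibly, the report.
#' @export
write_comparison_report <- function(report, path_tsv = NULL,
                                    path_json = NULL) {
  if (!is.null(path_tsv))
    utils::write.table(report$table, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(path_json))
    jsonlite::write_json(list(table = report$table, scores = report$scores),
                         path_json, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(report)
}
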