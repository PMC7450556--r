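#' Contact frequency between two located epitopes
#'
#' Looks up the Hi-C contact count between the bins holding the two loci.
#' Symmetric in its arguments; epitopes in the same bin return the diagonal
#' entry.
#'
#' @param x a [contact_matrix()].
#' @param bin_a,bin_b 1-based genome-wide bin indices (vectors recycle).
#' @return numeric contact frequency vector.
#' @export
pair_contact_frequency <- function(x, bin_a, bin_b) {
  stopifnot(inherits(x, "contact_matrix"))
  if (anyNA(bin_a) || anyNA(bin_b))
    stop("unlocated epitope: bin index is NA")
  n <- max(length(bin_a), length(bin_b))
  a <- rep_len(as.integer(bin_a), n)
  b <- rep_len(as.integer(bin_b), n)
  if (any(a < 1L | a > nrow(x$counts) | b < 1L | b > nrow(x$counts)))
    stop("bin index outside the contact matrix")
  x$counts[cbind(a, b)]
}

pair_cf_values <- function(bins_a, bins_b, x) {
  # all unordered pairs between two bin sets (or within one if identical)
  if (identical(bins_a, bins_b)) {
    n <- length(bins_a)
    if (n < 2L) return(numeric(0))
    pr <- utils::combn(n, 2L)
    pair_contact_frequency(x, bins_a[pr[1L, ]], bins_a[pr[2L, ]])
  } else {
    g <- expand.grid(a = bins_a, b = bins_b)
    pair_contact_frequency(x, g$a, g$b)
  }
}

group_summary <- function(group, scope, cf) {
  data.frame(group = group, scope = scope, n_pairs = length(cf),
             mean = if (length(cf)) mean(cf) else NA_real_,
             median = if (length(cf)) stats::median(cf) else NA_real_,
             stringsAsFactors = FALSE)
}

two_sample_cf_test <- function(cf_pos, cf_neg, bins_pos, bins_neg, x,
                               test, n_perm, seed) {
  if (length(cf_pos) < 2L || length(cf_neg) < 2L) return(NA_real_)
  if (test == "wilcoxon") {
    if (all(cf_pos == cf_pos[1L]) && all(cf_neg == cf_neg[1L]) &&
        cf_pos[1L] == cf_neg[1L])
      return(1)
    return(suppressWarnings(
      stats::wilcox.test(cf_pos, cf_neg, exact = FALSE)$p.value))
  }
  # label-permutation test on the difference of group means; exact under
  # label exchange even though pair CFs share epitopes
  obs <- mean(cf_pos) - mean(cf_neg)
  labels <- c(rep(TRUE, length(bins_pos)), rep(FALSE, length(bins_neg)))
  all_bins <- c(bins_pos, bins_neg)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      lab <- sample(labels)
      pp <- pair_cf_values(all_bins[lab], all_bins[lab], x)
      nn <- pair_cf_values(all_bins[!lab], all_bins[!lab], x)
      mean(pp) - mean(nn)
    }, numeric(1))
  })
  if (!is.finite(obs)) return(NA_real_)
  (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
}

#' Per-chromosome contact-frequency comparison of epitope pairs
#'
#' On each chromosome with at least `min_per_group` located positives and
#' negatives, collects the contact frequencies of all unordered
#' positive-positive and negative-negative epitope pairs and tests whether
#' the two CF samples differ. Chromosomes below the minimum are skipped
#' with a message.
#'
#' The default test is the two-sided Mann-Whitney (Wilcoxon rank-sum) test.
#' Because pair-level CF values share epitopes, the rank test's independence
#' assumption is only approximate; `test = "permutation"` permutes epitope
#' labels and is exact under label exchangeability.
#'
#' @param epitopes located labeled epitopes ([attach_loci()] output).
#' @param x a [contact_matrix()].
#' @param test `"wilcoxon"` (default) or `"permutation"`.
#' @param n_perm permutations when `test = "permutation"`.
#' @param drop_same_bin drop pairs whose two epitopes share a bin instead
#'   of using the diagonal entry.
#' @param min_per_group minimum located epitopes per label per chromosome.
#' @param alpha significance level for the `significant` flag.
#' @param seed RNG seed for the permutation test.
#' @param quiet suppress skip messages.
#' @return data frame, one row per analyzed chromosome: pair counts, CF
#'   means/medians per group, `p_value`, `significant`.
#' @export
intra_chromosome_summary <- function(epitopes, x,
                                     test = c("wilcoxon", "permutation"),
                                     n_perm = 1000L, drop_same_bin = FALSE,
                                     min_per_group = 2L, alpha = 0.05,
                                     seed = 1L, quiet = FALSE) {
  test <- match.arg(test)
  ep <- epitopes[epitopes$located, , drop = FALSE]
  rows <- list()
  for (chrom in x$bins$chrom_names) {
    on_chr <- ep[ep$chrom == chrom, , drop = FALSE]
    bp <- on_chr$bin[on_chr$label == "positive"]
    bn <- on_chr$bin[on_chr$label == "negative"]
    if (length(bp) < min_per_group || length(bn) < min_per_group) {
      if (!quiet)
        message("skipping ", chrom, ": fewer than ", min_per_group,
                " located epitopes of each label")
      next
    }
    cfp <- pair_cf_values(bp, bp, x)
    cfn <- pair_cf_values(bn, bn, x)
    if (drop_same_bin) {
      prp <- utils::combn(length(bp), 2L)
      cfp <- cfp[bp[prp[1L, ]] != bp[prp[2L, ]]]
      prn <- utils::combn(length(bn), 2L)
      cfn <- cfn[bn[prn[1L, ]] != bn[prn[2L, ]]]
    }
    p <- two_sample_cf_test(cfp, cfn, bp, bn, x, test, n_perm, seed)
    rows[[chrom]] <- data.frame(
      chrom = chrom, n_pos = length(bp), n_neg = length(bn),
      n_pairs_pos = length(cfp), n_pairs_neg = length(cfn),
      mean_pos = mean(cfp), mean_neg = mean(cfn),
      median_pos = stats::median(cfp), median_neg = stats::median(cfn),
      p_value = p, significant = is.finite(p) && p < alpha,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), n_pos = integer(), n_neg = integer(),
               n_pairs_pos = integer(), n_pairs_neg = integer(),
               mean_pos = numeric(), mean_neg = numeric(),
               median_pos = numeric(), median_neg = numeric(),
               p_value = numeric(), significant = logical())
  rownames(out) <- NULL
  out
}

#' Genome-wide contact-frequency distributions of inter-chromosomal pairs
#'
#' Restricts to epitope pairs on *different* chromosomes and summarizes the
#' contact-frequency distributions of the three pair types
#' (positive-positive, negative-negative, positive-negative), with pairwise
#' two-sided rank tests between them. With many epitopes the pair counts
#' are huge, so small p-values partly reflect sample size; interpret the
#' effect sizes (mean/median differences) alongside them.
#'
#' @param epitopes located labeled epitopes.
#' @param x a [contact_matrix()].
#' @param alpha significance level.
#' @return list with `summary` (per-group n/mean/median), `tests`
#'   (pairwise comparisons and p-values), `cf` (named list of the three CF
#'   vectors), and a `note` on sample-size-driven significance.
#' @export
inter_chromosome_distributions <- function(epitopes, x, alpha = 0.05) {
  ep <- epitopes[epitopes$located, , drop = FALSE]
  bp <- ep$bin[ep$label == "positive"]
  cp <- ep$chrom[ep$label == "positive"]
  bn <- ep$bin[ep$label == "negative"]
  cn <- ep$chrom[ep$label == "negative"]
  cf <- list(
    "pos-pos" = inter_pair_cf(bp, cp, bp, cp, x, same_set = TRUE),
    "neg-neg" = inter_pair_cf(bn, cn, bn, cn, x, same_set = TRUE),
    "pos-neg" = inter_pair_cf(bp, cp, bn, cn, x, same_set = FALSE))
  summary <- do.call(rbind, lapply(names(cf), function(g)
    group_summary(g, "inter", cf[[g]])))
  combos <- list(c("pos-pos", "neg-neg"), c("pos-pos", "pos-neg"),
                 c("neg-neg", "pos-neg"))
  tests <- do.call(rbind, lapply(combos, function(cb) {
    a <- cf[[cb[1L]]]; b <- cf[[cb[2L]]]
    p <- if (length(a) < 2L || length(b) < 2L) NA_real_
    else if (length(unique(c(a, b))) == 1L) 1
    else suppressWarnings(stats::wilcox.test(a, b, exact = FALSE)$p.value)
    data.frame(group_a = cb[1L], group_b = cb[2L], p_value = p,
               significant = is.finite(p) && p < alpha,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, tests = tests, cf = cf,
       note = paste("pair counts grow quadratically with epitope number;",
                    "large samples alone can drive small p-values"))
}

inter_pair_cf <- function(bins_a, chrom_a, bins_b, chrom_b, x, same_set) {
  if (same_set) {
    n <- length(bins_a)
    if (n < 2L) return(numeric(0))
    pr <- utils::combn(n, 2L)
    keep <- chrom_a[pr[1L, ]] != chrom_a[pr[2L, ]]
    if (!any(keep)) return(numeric(0))
    pair_contact_frequency(x, bins_a[pr[1L, keep]], bins_a[pr[2L, keep]])
  } else {
    if (length(bins_a) == 0L || length(bins_b) == 0L) return(numeric(0))
    g <- expand.grid(i = seq_along(bins_a), j = seq_along(bins_b))
    keep <- chrom_a[g$i] != chrom_b[g$j]
    if (!any(keep)) return(numeric(0))
    pair_contact_frequency(x, bins_a[g$i[keep]], bins_b[g$j[keep]])
  }
}

#' Write a contact-frequency summary table as TSV
#'
#' @param summary a data frame from [intra_chromosome_summary()] or the
#'   `summary`/`tests` element of [inter_chromosome_distributions()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cf_summary <- function(summary, path) {
  utils::write.table(summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
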