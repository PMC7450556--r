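#' Ensemble-averaged distance between two beads
#'
#' The model-space distance between two loci: the Euclidean distance
#' between their beads, averaged over the conformation replicas. Replica
#' orientations are arbitrary, so distances are averaged — never
#' coordinates.
#'
#' @param ensemble a `conformation_ensemble`.
#' @param bin_a,bin_b 1-based genome-wide bin indices (vectors recycle).
#' @return numeric mean distance(s).
#' @export
pairwise_model_distance <- function(ensemble, bin_a, bin_b) {
  stopifnot(inherits(ensemble, "conformation_ensemble"))
  if (length(ensemble$replicas) == 0L) stop("empty ensemble")
  n <- max(length(bin_a), length(bin_b))
  a <- rep_len(as.integer(bin_a), n)
  b <- rep_len(as.integer(bin_b), n)
  acc <- numeric(n)
  for (cf in ensemble$replicas) {
    dvec <- cf$coords[a, , drop = FALSE] - cf$coords[b, , drop = FALSE]
    acc <- acc + sqrt(rowSums(dvec^2))
  }
  acc / length(ensemble$replicas)
}

# mean-over-replica distance matrix among a set of beads
mean_distance_matrix <- function(ensemble, bin_idx) {
  n <- length(bin_idx)
  acc <- matrix(0, n, n)
  for (cf in ensemble$replicas)
    acc <- acc + as.matrix(stats::dist(cf$coords[bin_idx, , drop = FALSE]))
  acc / length(ensemble$replicas)
}

#' Same-chromosome KNN immunogenicity score
#'
#' For a located target epitope, ranks the located training epitopes *on
#' the same chromosome* by ensemble-averaged model distance (chromosome
#' territories make inter-chromosomal distances incommensurable) and
#' returns the fraction of immuno-positives among the `k` nearest. Ties in
#' distance are broken by genome-wide bin index, then peptide string, so
#' results are reproducible. The target itself is excluded by peptide
#' identity. With fewer than `k` same-chromosome neighbours all available
#' ones vote; with none, the global training positive rate is returned with
#' `n_neighbors = 0`.
#'
#' @param target a one-row data frame (or list) with `peptide`, `chrom`,
#'   `bin`; must be located.
#' @param training located labeled epitopes (columns `peptide`, `chrom`,
#'   `bin`, `label`, `located`).
#' @param ensemble a `conformation_ensemble`.
#' @param k neighbourhood size (default 10).
#' @return list with `knn_score` (positive fraction in \[0, 1\]) and
#'   `n_neighbors` actually used.
#' @export
knn_score <- function(target, training, ensemble, k = 10L) {
  if (is.data.frame(target)) target <- as.list(target[1L, ])
  if (is.null(target$bin) || is.na(target$bin))
    stop("target peptide ", target$peptide, " is unlocated")
  if (k < 1L) stop("k must be >= 1")
  tr <- training[training$located & training$peptide != target$peptide, ,
                 drop = FALSE]
  if (nrow(tr) == 0L) stop("no located training epitopes")
  same <- tr[tr$chrom == target$chrom, , drop = FALSE]
  if (nrow(same) == 0L) {
    return(list(knn_score = mean(tr$label == "positive"), n_neighbors = 0L))
  }
  d <- pairwise_model_distance(ensemble, target$bin, same$bin)
  ord <- order(d, same$bin, same$peptide)
  use <- ord[seq_len(min(k, length(ord)))]
  list(knn_score = mean(same$label[use] == "positive"),
       n_neighbors = length(use))
}

#' Rescale raw baseline predictor scores to \[0, 1\]
#'
#' The combined score subtracts the KNN vote from a baseline peptide-MHC
#' binding score, which therefore must be on a \[0, 1\] scale with **lower
#' = stronger predicted binder** (as a percentile rank is).
#'
#' `"rank"` maps each raw score to its fractional rank `(rank - 1) /
#' (n - 1)` (average ties; a constant vector maps to all 0.5), preserving
#' lower-is-better raw orientation, or inverting it with `invert = TRUE`
#' for higher-is-better inputs. `"affinity"` treats raw scores as binding
#' affinities in nM and applies `log(aff) / log(max_affinity)` clamped to
#' \[0, 1\], keeping the lower-is-stronger orientation.
#'
#' @param raw numeric raw scores.
#' @param mode `"rank"` or `"affinity"`.
#' @param invert flip orientation before rank rescaling.
#' @param max_affinity affinity (nM) mapping to 1 in `"affinity"` mode.
#' @return numeric scores in \[0, 1\], lower = stronger binder.
#' @export
rescale_baseline <- function(raw, mode = c("rank", "affinity"),
                             invert = FALSE, max_affinity = 50000) {
  mode <- match.arg(mode)
  raw <- as.numeric(raw)
  if (length(raw) == 0L) stop("empty score vector")
  if (anyNA(raw)) stop("raw scores contain NA")
  if (mode == "rank") {
    if (invert) raw <- -raw
    if (length(raw) == 1L || diff(range(raw)) == 0)
      return(rep(0.5, length(raw)))
    (rank(raw, ties.method = "average") - 1) / (length(raw) - 1)
  } else {
    if (any(raw <= 0)) stop("affinities must be positive (nM)")
    pmin(pmax(log(raw) / log(max_affinity), 0), 1)
  }
}

#' Combine baseline and KNN scores
#'
#' Final immunogenicity score = baseline − KNN vote. Lower combined score =
#' higher predicted immunogenicity (strong predicted binder in a
#' positive-rich spatial neighbourhood); prioritization sorts ascending.
#'
#' @param baseline_score numeric in \[0, 1\], lower = stronger binder (see
#'   [rescale_baseline()]).
#' @param knn_score numeric in \[0, 1\].
#' @return combined score in \[-1, 1\].
#' @export
combine_scores <- function(baseline_score, knn_score) {
  if (any(!is.finite(baseline_score)) ||
      any(baseline_score < 0 | baseline_score > 1))
    stop("baseline scores must lie in [0, 1]; see rescale_baseline()")
  if (any(!is.finite(knn_score)) || any(knn_score < 0 | knn_score > 1))
    stop("knn scores must lie in [0, 1]")
  baseline_score - knn_score
}

#' Read a baseline predictor score table
#'
#' TSV with columns `peptide`, `allele`, `raw_score` and optionally
#' `scale`, a tag naming the raw scale (`"rank"` for percentile-rank-like,
#' lower-better raw scores — the default — or `"affinity"` for nM
#' affinities).
#'
#' @param path TSV path.
#' @return data frame with `peptide`, `allele`, `raw_score`, `scale`.
#' @export
read_baseline_scores <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("peptide", "allele", "raw_score")
  if (!all(need %in% names(df)))
    stop("baseline table needs columns: ", paste(need, collapse = ", "))
  if (is.null(df$scale)) df$scale <- "rank"
  df
}

#' Score candidate epitopes by the combined 3D-genome KNN method
#'
#' For each located epitope, computes the same-chromosome KNN vote against
#' the training set (in leave-one-out fashion when `targets` and
#' `training` are the same table — self is always excluded by peptide) and
#' combines it with the rescaled baseline score.
#'
#' @param targets located epitopes to score.
#' @param training located labeled epitopes forming the vote pool.
#' @param ensemble a `conformation_ensemble`.
#' @param baseline baseline score table ([read_baseline_scores()] layout);
#'   raw scores are rank-rescaled across the targets unless already tagged
#'   `scale = "unit"` (meaning: already in \[0, 1\], lower = better).
#' @param k neighbourhood size (default 10).
#' @return data frame `peptide`, `allele`, `label` (if present in
#'   `targets`), `knn_score`, `n_neighbors`, `baseline_score`,
#'   `combined_score`, `rank` (1 = top priority).
#' @export
predict_immunogenicity <- function(targets, training, ensemble, baseline,
                                   k = 10L) {
  targets <- targets[targets$located, , drop = FALSE]
  if (nrow(targets) == 0L) stop("no located target epitopes")
  bidx <- match(targets$peptide, baseline$peptide)
  if (anyNA(bidx))
    stop("baseline scores missing for ",
         sum(is.na(bidx)), " peptide(s), e.g. ",
         targets$peptide[which(is.na(bidx))[1L]])
  raw <- baseline$raw_score[bidx]
  scale_tag <- if (!is.null(baseline$scale)) baseline$scale[bidx][1L] else "rank"
  base <- switch(scale_tag,
                 unit = raw,
                 affinity = rescale_baseline(raw, mode = "affinity"),
                 rescale_baseline(raw, mode = "rank"))
  ks <- knn_scores_bulk(targets, training, ensemble, k)
  out <- data.frame(peptide = targets$peptide,
                    allele = if (!is.null(targets$allele)) targets$allele
                             else NA_character_,
                    knn_score = ks$knn_score,
                    n_neighbors = ks$n_neighbors,
                    baseline_score = base,
                    stringsAsFactors = FALSE)
  if (!is.null(targets$label)) out$label <- targets$label
  out$combined_score <- combine_scores(out$baseline_score, out$knn_score)
  out$rank <- rank(out$combined_score, ties.method = "min")
  out
}

# vectorized KNN over many targets, reusing per-chromosome distance matrices
knn_scores_bulk <- function(targets, training, ensemble, k) {
  tr <- training[training$located, , drop = FALSE]
  if (nrow(tr) == 0L) stop("no located training epitopes")
  global_rate <- mean(tr$label == "positive")
  scores <- numeric(nrow(targets))
  nn <- integer(nrow(targets))
  for (chrom in unique(targets$chrom)) {
    t_idx <- which(targets$chrom == chrom)
    pool <- tr[tr$chrom == chrom, , drop = FALSE]
    all_bins <- unique(c(targets$bin[t_idx], pool$bin))
    dm <- if (nrow(pool) > 0L) mean_distance_matrix(ensemble, all_bins)
    for (ti in t_idx) {
      cand <- pool[pool$peptide != targets$peptide[ti], , drop = FALSE]
      if (nrow(cand) == 0L) {
        scores[ti] <- global_rate
        nn[ti] <- 0L
        next
      }
      d <- dm[match(targets$bin[ti], all_bins),
              match(cand$bin, all_bins)]
      ord <- order(d, cand$bin, cand$peptide)
      use <- ord[seq_len(min(k, length(ord)))]
      scores[ti] <- mean(cand$label[use] == "positive")
      nn[ti] <- length(use)
    }
  }
  list(knn_score = scores, n_neighbors = nn)
}
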