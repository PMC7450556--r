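#' Planted A/B compartment labels
#'
#' Alternating blocks of `block_size` bins per chromosome, starting with
#' "A". Real compartments span consecutive bins, so blocks (not
#' single-bin alternation) are the realistic default.
#'
#' @param bins a [bin_table()].
#' @param block_size bins per compartment block.
#' @return character vector ("A"/"B") of length `bins$n_bins`.
#' @export
simulate_compartment_labels <- function(bins, block_size = 5L) {
  unlist(lapply(bins$n_bins_chrom, function(n) {
    blk <- ((seq_len(n) - 1L) %/% block_size) %% 2L
    c("A", "B")[blk + 1L]
  }), use.names = FALSE)
}

#' Simulate a Hi-C contact matrix with planted structure
#'
#' Expected intra-chromosomal counts decay as a power law of bin
#' separation, `intra_scale * max(|i - j|, 1)^(-decay_exponent)`, and are
#' multiplied by `checkerboard_strength` when bins share a compartment
#' label and divided by it when they differ — the classic A/B checkerboard.
#' Inter-chromosomal counts have flat expectation `inter_scale` with the
#' same compartment multiplier. Counts are Poisson (optionally
#' negative-binomial) draws around expectation, symmetrized by
#' construction.
#'
#' @param bins a [bin_table()].
#' @param compartment_labels per-bin "A"/"B" labels (default
#'   [simulate_compartment_labels()]).
#' @param decay_exponent power-law exponent (> 0), default 1.
#' @param intra_scale expected count at separation 1 (neutral pair).
#' @param inter_scale expected inter-chromosomal count (neutral pair).
#' @param checkerboard_strength compartment multiplier (>= 1); 1 plants no
#'   compartment signal.
#' @param noise `"poisson"` (default), `"negbin"`, or `"none"` (exact
#'   expectations).
#' @param dispersion negative-binomial size parameter when
#'   `noise = "negbin"`.
#' @param seed RNG seed.
#' @param cell_label provenance tag on the result.
#' @return a [contact_matrix()]; the planted labels are attached as
#'   attribute `"compartment_labels"`.
#' @export
simulate_hic <- function(bins, compartment_labels = NULL,
                         decay_exponent = 1, intra_scale = 100,
                         inter_scale = 1, checkerboard_strength = 1,
                         noise = c("poisson", "negbin", "none"),
                         dispersion = 10, seed = 1L,
                         cell_label = "synthetic") {
  noise <- match.arg(noise)
  stopifnot(inherits(bins, "bin_table"))
  if (checkerboard_strength < 1) stop("checkerboard_strength must be >= 1")
  if (decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (is.null(compartment_labels))
    compartment_labels <- simulate_compartment_labels(bins)
  if (length(compartment_labels) != bins$n_bins)
    stop("need one compartment label per bin")
  n <- bins$n_bins
  chrom <- bin_chrom(bins)
  same_chrom <- outer(chrom, chrom, "==")
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  same_comp <- outer(compartment_labels, compartment_labels, "==")
  mult <- ifelse(same_comp, checkerboard_strength, 1 / checkerboard_strength)
  mu <- ifelse(same_chrom,
               intra_scale * pmax(sep, 1)^(-decay_exponent),
               inter_scale) * mult
  counts <- withr::with_seed(as.integer(seed), {
    up <- upper.tri(mu, diag = TRUE)
    v <- switch(noise,
                none = mu[up],
                poisson = stats::rpois(sum(up), mu[up]),
                negbin = stats::rnbinom(sum(up), size = dispersion,
                                        mu = mu[up]))
    m <- matrix(0, n, n)
    m[up] <- v
    m <- m + t(m) - diag(diag(m))
    m
  })
  cm <- contact_matrix(counts, bins, cell_label = cell_label)
  attr(cm, "compartment_labels") <- compartment_labels
  cm
}

random_peptides <- function(n, length = 9L) {
  # unique random 9-mers; sequences deliberately carry no signal
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    pep <- vapply(seq_len(need), function(i)
      paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = ""),
      character(1))
    out <- unique(c(out, pep))
  }
  out[seq_len(n)]
}

#' Simulate a labeled, located epitope set
#'
#' Places `n_pos` immuno-positive and `n_neg` immuno-negative 9-mer
#' epitopes on the genome. In `"clustered"` mode a fraction `1 - leak` of
#' the positives falls uniformly within `cluster_bins` (e.g. one planted
#' compartment) and the rest — plus all negatives — uniformly genome-wide;
#' `"uniform"` mode places both labels uniformly (the no-signal null).
#' Positions are uniform within the chosen bin.
#'
#' @param bins a [bin_table()].
#' @param n_pos,n_neg label counts.
#' @param spatial_mode `"clustered"` or `"uniform"`.
#' @param cluster_bins genome-wide bin indices hosting clustered
#'   positives; required in clustered mode.
#' @param leak fraction of positives escaping the cluster (default 0.1).
#' @param allele allele string stamped on every record.
#' @param seed RNG seed.
#' @return located labeled epitope data frame (`peptide`, `allele`,
#'   `positive_rate`, `label`, `chrom`, `position`, `bin`, `located`).
#' @export
simulate_epitopes <- function(bins, n_pos, n_neg,
                              spatial_mode = c("clustered", "uniform"),
                              cluster_bins = NULL, leak = 0.1,
                              allele = "HLA-A*02:01", seed = 1L) {
  spatial_mode <- match.arg(spatial_mode)
  stopifnot(inherits(bins, "bin_table"))
  if (spatial_mode == "clustered" &&
      (is.null(cluster_bins) || length(cluster_bins) == 0L))
    stop("clustered mode needs non-empty cluster_bins")
  if (leak < 0 || leak > 1) stop("leak must lie in [0, 1]")
  br <- bin_ranges(bins)
  withr::with_seed(as.integer(seed), {
    n <- n_pos + n_neg
    label <- c(rep("positive", n_pos), rep("negative", n_neg))
    bin <- integer(n)
    if (spatial_mode == "clustered") {
      in_cluster <- stats::runif(n_pos) >= leak
      bin[seq_len(n_pos)][in_cluster] <-
        cluster_bins[sample.int(length(cluster_bins),
                                sum(in_cluster), replace = TRUE)]
      n_out <- sum(!in_cluster)
      bin[seq_len(n_pos)][!in_cluster] <-
        sample.int(bins$n_bins, n_out, replace = TRUE)
    } else {
      bin[seq_len(n_pos)] <- sample.int(bins$n_bins, n_pos, replace = TRUE)
    }
    bin[n_pos + seq_len(n_neg)] <- sample.int(bins$n_bins, n_neg,
                                              replace = TRUE)
    start <- br$start[bin]
    end <- br$end[bin]
    position <- floor(stats::runif(n, start, end))
    data.frame(peptide = random_peptides(n),
               allele = allele,
               positive_rate = ifelse(label == "positive", 1, 0),
               label = label,
               chrom = br$chrom[bin],
               position = position,
               bin = bin,
               located = TRUE,
               stringsAsFactors = FALSE)
  })
}

#' Simulate baseline predictor scores of tunable quality
#'
#' Draws scores from the binormal model: negatives from N(mu, 1) and
#' positives from N(0, 1) with `mu = sqrt(2) * qnorm(target_auc)`, so the
#' expected AUC of the lower-is-better orientation equals `target_auc`.
#' Scores are then rank-rescaled to \[0, 1\] (rank transforms preserve
#' AUC).
#'
#' @param epitopes labeled epitopes (uses the `label` column).
#' @param target_auc expected discrimination, in \[0.5, 1\].
#' @param seed RNG seed.
#' @return baseline score data frame: `peptide`, `allele`, `raw_score`,
#'   `scale = "unit"` (already in \[0, 1\], lower = better).
#' @export
simulate_baseline_scores <- function(epitopes, target_auc = 0.7, seed = 1L) {
  if (target_auc < 0.5 || target_auc > 1)
    stop("target_auc must lie in [0.5, 1]")
  y <- epitopes$label == "positive"
  mu <- sqrt(2) * stats::qnorm(target_auc)
  raw <- withr::with_seed(as.integer(seed), {
    stats::rnorm(length(y), mean = ifelse(y, 0, mu), sd = 1)
  })
  data.frame(peptide = epitopes$peptide,
             allele = epitopes$allele,
             raw_score = rescale_baseline(raw, mode = "rank"),
             scale = "unit",
             stringsAsFactors = FALSE)
}

#' Write a simulated study as pipeline-ready fixture files
#'
#' Emits exactly the dialects the pipeline consumes: `chrom.sizes`, a
#' triplet contact matrix, a per-assay epitope TSV whose positive rates
#' reproduce the planted labels (positives get 9/10 positive assays, rate
#' 0.9; negatives 1/10, rate 0.1), a peptide mapping TSV, a baseline score
#' TSV, and a `truth.json` with the planted composition.
#'
#' @param sim list with elements `bins`, `hic` (a [contact_matrix()]),
#'   `epitopes`, `baseline` — e.g. from [simulate_study()].
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
write_study_fixture <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(chrom_sizes = file.path(dir, "chrom.sizes"),
             hic = file.path(dir, "hic_triplet.txt"),
             epitopes = file.path(dir, "epitope_assays.tsv"),
             mapping = file.path(dir, "peptide_mapping.tsv"),
             baseline = file.path(dir, "baseline_scores.tsv"),
             truth = file.path(dir, "truth.json"))
  utils::write.table(
    data.frame(chrom = sim$bins$chrom_names,
               length = format(sim$bins$chrom_lengths, scientific = FALSE,
                               trim = TRUE)),
    paths["chrom_sizes"], sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  write_contact_matrix(sim$hic, paths["hic"], format = "triplet")
  ep <- sim$epitopes
  n_pos_assay <- ifelse(ep$label == "positive", 9L, 1L)
  assays <- data.frame(
    peptide = rep(ep$peptide, each = 10L),
    mhc_allele = rep(ep$allele, each = 10L),
    mhc_class = "I",
    host = "Homo sapiens",
    assay_outcome = unlist(lapply(n_pos_assay, function(np)
      c(rep("Positive", np), rep("Negative", 10L - np)))),
    stringsAsFactors = FALSE)
  utils::write.table(assays, paths["epitopes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(peptide = ep$peptide, chrom = ep$chrom,
               position = format(ep$position, scientific = FALSE,
                                 trim = TRUE)),
    paths["mapping"], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$baseline, paths["baseline"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n_pos = sum(ep$label == "positive"),
         n_neg = sum(ep$label == "negative"),
         compartment_labels = attr(sim$hic, "compartment_labels"),
         epitopes = ep),
    paths["truth"], auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(paths)
}

#' Simulate a complete study
#'
#' One call producing everything a pipeline run needs, with planted
#' structure: compartment blocks, a checkerboard Hi-C matrix, epitopes
#' whose positives cluster in the A compartment (or not, under the
#' uniform null), and baseline scores of tunable quality.
#'
#' @param chrom_sizes named lengths (default: three toy chromosomes).
#' @param bin_size bin width in bp.
#' @param n_pos,n_neg epitope counts (defaults keep the roughly 1:3.8
#'   positive:negative imbalance typical of curated assay sets).
#' @param spatial_mode `"clustered"` or `"uniform"`.
#' @param checkerboard_strength,decay_exponent,intra_scale,inter_scale
#'   passed to [simulate_hic()].
#' @param leak passed to [simulate_epitopes()].
#' @param target_auc passed to [simulate_baseline_scores()].
#' @param block_size compartment block width in bins.
#' @param seed master seed; stage seeds are derived from it.
#' @return list with `bins`, `labels` (compartment), `hic`, `cluster_bins`,
#'   `epitopes`, `baseline`.
#' @export
simulate_study <- function(chrom_sizes = c(chr1 = 2.0e7, chr2 = 1.5e7,
                                           chr3 = 1.25e7),
                           bin_size = 500000, n_pos = 80, n_neg = 320,
                           spatial_mode = c("clustered", "uniform"),
                           checkerboard_strength = 3, decay_exponent = 1,
                           intra_scale = 100, inter_scale = 1, leak = 0.1,
                           target_auc = 0.7, block_size = 5L, seed = 1L) {
  spatial_mode <- match.arg(spatial_mode)
  seed <- as.integer(seed)
  bins <- bin_table(chrom_sizes, bin_size = bin_size)
  labels <- simulate_compartment_labels(bins, block_size = block_size)
  hic <- simulate_hic(bins, labels, decay_exponent = decay_exponent,
                      intra_scale = intra_scale, inter_scale = inter_scale,
                      checkerboard_strength = checkerboard_strength,
                      seed = seed * 3L + 1L)
  cluster_bins <- which(labels == "A")
  epitopes <- simulate_epitopes(bins, n_pos, n_neg,
                                spatial_mode = spatial_mode,
                                cluster_bins = cluster_bins, leak = leak,
                                seed = seed * 3L + 2L)
  baseline <- simulate_baseline_scores(epitopes, target_auc = target_auc,
                                       seed = seed * 3L + 3L)
  list(bins = bins, labels = labels, hic = hic, cluster_bins = cluster_bins,
       epitopes = epitopes, baseline = baseline)
}
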