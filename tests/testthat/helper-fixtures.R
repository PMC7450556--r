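# shared fixtures; everything is generated in code, no data files

toy_bins <- function(sizes = c(chr1 = 1.5e6, chr2 = 1.0e6),
                     bin_size = 5e5) {
  bin_table(sizes, bin_size = bin_size)
}

# contact matrix with counts depending only on bin separation (plus a
# chromosome-block offset), handy for O/E identities
decay_matrix <- function(bins, base = 10) {
  n <- bins$n_bins
  chrom <- bin_chrom(bins)
  sep <- abs(outer(seq_len(n), seq_len(n), "-"))
  m <- ifelse(outer(chrom, chrom, "=="), base / (1 + sep), 1)
  contact_matrix(m, bins)
}

# hand-built ensemble from a list of coordinate matrices
manual_ensemble <- function(coord_list, bins) {
  replicas <- lapply(seq_along(coord_list), function(i) {
    structure(list(coords = coord_list[[i]],
                   chain_breaks = as.integer(bins$bin_offsets + 1L),
                   energy = NA_real_, seed = i, bins = bins),
              class = "conformation")
  })
  structure(list(replicas = replicas, restraints = NULL, bins = bins,
                 base_seed = 0L),
            class = "conformation_ensemble")
}

# located labeled epitope table from parallel vectors
epitope_frame <- function(peptide, label, bin, bins,
                          allele = "HLA-A*02:01") {
  br <- bin_ranges(bins)
  data.frame(peptide = peptide, allele = allele,
             positive_rate = ifelse(label == "positive", 1, 0),
             label = label, chrom = br$chrom[bin],
             position = br$start[bin], bin = as.integer(bin),
             located = TRUE, stringsAsFactors = FALSE)
}

# independent exhaustive KNN oracle: same contract, naive implementation
knn_oracle <- function(target, training, ensemble, k) {
  tr <- training[training$located & training$peptide != target$peptide, ,
                 drop = FALSE]
  tr <- tr[tr$chrom == target$chrom, , drop = FALSE]
  if (nrow(tr) == 0L) {
    pool <- training[training$located & training$peptide != target$peptide, ]
    return(mean(pool$label == "positive"))
  }
  d <- vapply(seq_len(nrow(tr)), function(i) {
    mean(vapply(ensemble$replicas, function(cf) {
      sqrt(sum((cf$coords[target$bin, ] - cf$coords[tr$bin[i], ])^2))
    }, numeric(1)))
  }, numeric(1))
  ord <- order(d, tr$bin, tr$peptide)
  use <- ord[seq_len(min(k, length(ord)))]
  mean(tr$label[use] == "positive")
}

# concordant-pair AUC oracle (half credit for ties); lower score = positive
auc_pair_oracle <- function(scores, labels) {
  pos <- scores[labels == "positive"]
  neg <- scores[labels != "positive"]
  total <- 0
  for (p in pos) total <- total + sum(p < neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# per-assay epitope table builder: one row per assay outcome
assay_table <- function(peptide, allele = "HLA-A*02:01", n_pos, n_neg,
                        host = "Homo sapiens", mhc_class = "I") {
  do.call(rbind, lapply(seq_along(peptide), function(i) {
    data.frame(peptide = peptide[i], mhc_allele = allele,
               mhc_class = mhc_class, host = host,
               assay_outcome = c(rep("Positive", n_pos[i]),
                                 rep("Negative", n_neg[i])),
               stringsAsFactors = FALSE)
  }))
}
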