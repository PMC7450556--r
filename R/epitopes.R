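AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

is_valid_peptide <- function(x) {
  nzchar(x) & !is.na(x) & grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", x)
}

#' Read an epitope assay table
#'
#' Parses a TSV of per-assay T-cell records (one row per peptide x allele x
#' assay, IEDB-export-like). Column names are configurable via `column_map`.
#' Rows whose peptide contains characters outside the 20-letter amino-acid
#' alphabet, or with empty required fields, are skipped and counted.
#'
#' @param path TSV file with a header row.
#' @param column_map named list mapping the roles `peptide`, `allele`,
#'   `mhc_class`, `host`, `outcome` to column names in the file.
#' @param quiet suppress the skipped-row message.
#' @return data frame of assay records with columns `peptide`, `allele`,
#'   `mhc_class`, `host`, `outcome` (`outcome` normalized to
#'   `"positive"`/`"negative"`); attribute `n_skipped` counts dropped rows.
#' @export
read_epitope_table <- function(path,
                               column_map = list(peptide = "peptide",
                                                 allele = "mhc_allele",
                                                 mhc_class = "mhc_class",
                                                 host = "host",
                                                 outcome = "assay_outcome"),
                               quiet = FALSE) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  needed <- unlist(column_map)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0L)
    stop("epitope table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  df <- data.frame(peptide = toupper(trimws(raw[[column_map$peptide]])),
                   allele = trimws(raw[[column_map$allele]]),
                   mhc_class = trimws(raw[[column_map$mhc_class]]),
                   host = trimws(raw[[column_map$host]]),
                   outcome = tolower(trimws(raw[[column_map$outcome]])),
                   stringsAsFactors = FALSE)
  ok_pep <- is_valid_peptide(df$peptide)
  # IEDB qualitative measures: "Positive", "Positive-High", ..., "Negative"
  is_pos <- grepl("^positive", df$outcome)
  is_neg <- grepl("^negative", df$outcome)
  ok <- ok_pep & (is_pos | is_neg) & nzchar(df$allele) & nzchar(df$host)
  n_skipped <- sum(!ok)
  if (n_skipped > 0L && !quiet)
    message(n_skipped, " malformed row(s) skipped (illegal peptide alphabet ",
            "or unparseable fields)")
  out <- df[ok, , drop = FALSE]
  out$outcome <- ifelse(grepl("^positive", out$outcome), "positive", "negative")
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Filter epitope records to the modeled population
#'
#' Restricts assay records to a host organism, an MHC class, and a fixed
#' peptide length (human MHC-I 9-mers by default). Row order is preserved.
#'
#' @param records assay records from [read_epitope_table()].
#' @param host host organism to keep.
#' @param mhc_class MHC class to keep (`"I"` or `"II"`).
#' @param peptide_length required amino-acid length.
#' @return the retained subset, same columns.
#' @export
filter_epitopes <- function(records, host = "Homo sapiens", mhc_class = "I",
                            peptide_length = 9L) {
  keep <- records$host == host &
    records$mhc_class == mhc_class &
    nchar(records$peptide) == peptide_length
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label peptides by assay positive rate
#'
#' Merges duplicated peptides: assay records are grouped on exact
#' (peptide, allele) identity and the positive rate (positive assays /
#' total assays) is computed per group. Groups with rate strictly above
#' `pos_threshold` are labeled immuno-positive, strictly below
#' `neg_threshold` immuno-negative; everything in between — including rates
#' exactly at a threshold — is dropped as ambiguous.
#'
#' @param records assay records (columns `peptide`, `allele`, `outcome`).
#' @param pos_threshold,neg_threshold strict positive-rate cutoffs
#'   (defaults 0.8 and 0.2).
#' @return data frame of labeled epitopes: `peptide`, `allele`, `n_assays`,
#'   `positive_rate`, `label`; attribute `n_dropped` counts ambiguous
#'   groups.
#' @export
label_by_positive_rate <- function(records, pos_threshold = 0.8,
                                   neg_threshold = 0.2) {
  # tolerate raw table headers alongside parsed-record names
  if (is.null(records$allele) && !is.null(records$mhc_allele))
    records$allele <- records$mhc_allele
  if (is.null(records$outcome) && !is.null(records$assay_outcome))
    records$outcome <- tolower(records$assay_outcome)
  need <- c("peptide", "allele", "outcome")
  if (!all(need %in% names(records)))
    stop("records need columns: ", paste(need, collapse = ", "))
  if (nrow(records) == 0L) {
    out <- data.frame(peptide = character(), allele = character(),
                      n_assays = integer(), positive_rate = numeric(),
                      label = character(), stringsAsFactors = FALSE)
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  key <- paste(records$peptide, records$allele, sep = "\r")
  n_assays <- as.vector(table(key)[unique(key)])
  n_pos <- tapply(grepl("^positive", records$outcome), key, sum)[unique(key)]
  groups <- data.frame(do.call(rbind, strsplit(unique(key), "\r", fixed = TRUE)),
                       stringsAsFactors = FALSE)
  names(groups) <- c("peptide", "allele")
  groups$n_assays <- as.integer(n_assays)
  groups$positive_rate <- as.numeric(n_pos) / as.numeric(n_assays)
  groups$label <- ifelse(groups$positive_rate > pos_threshold, "positive",
                         ifelse(groups$positive_rate < neg_threshold,
                                "negative", NA_character_))
  n_dropped <- sum(is.na(groups$label))
  out <- groups[!is.na(groups$label), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Attach genomic loci and bin indices to labeled epitopes
#'
#' Joins a peptide-to-genome mapping table (the end product of an external
#' sequence-alignment + gene-coordinate lookup) onto labeled epitopes. When
#' a peptide has several mapping rows, the first row wins (mirroring a
#' first-alignment-hit rule). Mapping rows whose position falls outside the
#' chromosome are rejected with a message. Peptides without a usable
#' mapping are retained but flagged unlocated; spatial analyses ignore
#' them.
#'
#' @param labeled labeled epitopes from [label_by_positive_rate()].
#' @param mapping a data frame or TSV path with columns `peptide`, `chrom`,
#'   `position` (0-based bp).
#' @param bins a [bin_table()].
#' @param quiet suppress messages about rejected rows.
#' @return `labeled` plus columns `chrom`, `position`, `bin` (NA when
#'   unlocated) and logical `located`.
#' @export
attach_loci <- function(labeled, mapping, bins, quiet = FALSE) {
  stopifnot(inherits(bins, "bin_table"))
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- utils::read.delim(mapping, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
  need <- c("peptide", "chrom", "position")
  if (!all(need %in% names(mapping)))
    stop("mapping table needs columns: ", paste(need, collapse = ", "))
  mapping <- mapping[!duplicated(mapping$peptide), , drop = FALSE]
  ok_chrom <- mapping$chrom %in% bins$chrom_names
  pos <- as.numeric(mapping$position)
  ok_pos <- ok_chrom & is.finite(pos) & pos >= 0
  ok_pos[ok_chrom] <- ok_pos[ok_chrom] &
    pos[ok_chrom] < bins$chrom_lengths[mapping$chrom[ok_chrom]]
  n_bad <- sum(!ok_pos)
  if (n_bad > 0L && !quiet)
    message(n_bad, " mapping row(s) rejected (unknown chromosome or ",
            "position outside chromosome)")
  mapping <- mapping[ok_pos, , drop = FALSE]
  idx <- match(labeled$peptide, mapping$peptide)
  out <- labeled
  out$chrom <- mapping$chrom[idx]
  out$position <- as.numeric(mapping$position)[idx]
  out$located <- !is.na(idx)
  out$bin <- NA_integer_
  if (any(out$located))
    out$bin[out$located] <- locus_to_bin(bins, out$chrom[out$located],
                                         out$position[out$located])
  out
}

#' Run the full curation chain
#'
#' Parse, filter (human MHC-I 9-mers), label by positive rate, and attach
#' genomic loci in one call.
#'
#' @param epitope_path assay TSV (see [read_epitope_table()]).
#' @param mapping mapping TSV path or data frame (see [attach_loci()]).
#' @param bins a [bin_table()].
#' @param column_map passed to [read_epitope_table()].
#' @param host,mhc_class,peptide_length passed to [filter_epitopes()].
#' @param quiet suppress progress messages.
#' @return located labeled epitope data frame.
#' @export
curate_epitopes <- function(epitope_path, mapping, bins,
                            column_map = list(peptide = "peptide",
                                              allele = "mhc_allele",
                                              mhc_class = "mhc_class",
                                              host = "host",
                                              outcome = "assay_outcome"),
                            host = "Homo sapiens", mhc_class = "I",
                            peptide_length = 9L, quiet = FALSE) {
  rec <- read_epitope_table(epitope_path, column_map = column_map,
                            quiet = quiet)
  rec <- filter_epitopes(rec, host = host, mhc_class = mhc_class,
                         peptide_length = peptide_length)
  lab <- label_by_positive_rate(rec)
  attach_loci(lab, mapping, bins, quiet = quiet)
}

#' Write labeled located epitopes as TSV
#'
#' @param x located labeled epitopes.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_labeled_epitopes <- function(x, path) {
  cols <- intersect(c("peptide", "allele", "n_assays", "positive_rate",
                      "label", "chrom", "position", "bin", "located"),
                    names(x))
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
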