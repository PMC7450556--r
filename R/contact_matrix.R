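#' Hi-C contact matrix
#'
#' A symmetric, non-negative bin-by-bin matrix of contact frequencies over a
#' genome-wide [bin_table()]. Counts may be raw or pre-normalized; no
#' balancing is applied.
#'
#' @param counts square numeric matrix, dimension equal to `bins$n_bins`.
#'   Mild asymmetry (from e.g. text round-trips) is symmetrized as
#'   `(M + t(M)) / 2`.
#' @param bins a [bin_table()].
#' @param cell_label free-text provenance tag (e.g. the cell line).
#' @return an object of class `contact_matrix` with elements `counts`,
#'   `bins`, `cell_label`.
#' @export
contact_matrix <- function(counts, bins, cell_label = "") {
  stopifnot(inherits(bins, "bin_table"))
  counts <- as.matrix(counts)
  if (nrow(counts) != ncol(counts))
    stop("contact matrix must be square")
  if (nrow(counts) != bins$n_bins)
    stop(sprintf("matrix dimension %d does not match bin count %d",
                 nrow(counts), bins$n_bins))
  if (anyNA(counts) || any(!is.finite(counts)))
    stop("contact matrix contains non-finite values")
  if (any(counts < 0))
    stop("contact matrix contains negative counts")
  counts <- (counts + t(counts)) / 2
  dimnames(counts) <- NULL
  structure(list(counts = counts, bins = bins, cell_label = cell_label),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d x %d bins%s, total counts %.4g\n",
              nrow(x$counts), ncol(x$counts),
              if (nzchar(x$cell_label)) paste0(" (", x$cell_label, ")") else "",
              sum(x$counts)))
  invisible(x)
}

#' Read a contact matrix from text
#'
#' Two dialects are supported. `dense`: whitespace-delimited numeric text,
#' one row per genome-wide bin. `triplet`: rows `i j value` with 0-based
#' genome-wide bin indices (converted to 1-based internally); unlisted cells
#' are zero and each entry is mirrored to keep the matrix symmetric.
#'
#' @param path input file path.
#' @param bins a [bin_table()] defining the expected dimension.
#' @param format `"auto"` (detect triplet as exactly-3-column integer-indexed
#'   rows), `"dense"`, or `"triplet"`.
#' @param cell_label provenance tag stored on the result.
#' @return a [contact_matrix()].
#' @export
read_contact_matrix <- function(path, bins,
                                format = c("auto", "dense", "triplet"),
                                cell_label = "") {
  format <- match.arg(format)
  stopifnot(inherits(bins, "bin_table"))
  n <- bins$n_bins
  first <- readLines(path, n = 1L)
  if (format == "auto") {
    format <- if (length(first) == 0L) "triplet"
    else if (length(strsplit(trimws(first), "\\s+")[[1L]]) == 3L && n != 3L)
      "triplet" else "dense"
  }
  if (format == "dense") {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    if (!all(dim(m) == n))
      stop(sprintf("dense matrix is %dx%d, expected %dx%d",
                   nrow(m), ncol(m), n, n))
    return(contact_matrix(m, bins, cell_label))
  }
  m <- matrix(0, n, n)
  if (file.size(path) > 0 && length(readLines(path, n = 1L)) > 0L &&
      nzchar(trimws(first))) {
    tr <- utils::read.table(path, header = FALSE,
                            col.names = c("i", "j", "value"))
    i <- tr$i + 1L
    j <- tr$j + 1L
    if (any(i < 1L | i > n | j < 1L | j > n))
      stop("triplet index outside bin table")
    m[cbind(i, j)] <- tr$value
    m[cbind(j, i)] <- tr$value
  }
  contact_matrix(m, bins, cell_label)
}

#' Write a contact matrix to text
#'
#' Inverse of [read_contact_matrix()]; the triplet writer emits the upper
#' triangle (including diagonal) of non-zero cells with 0-based indices.
#'
#' @param x a [contact_matrix()].
#' @param path output file path.
#' @param format `"dense"` or `"triplet"`.
#' @return `path`, invisibly.
#' @export
write_contact_matrix <- function(x, path, format = c("triplet", "dense")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "contact_matrix"))
  if (format == "dense") {
    utils::write.table(x$counts, path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else {
    idx <- which(upper.tri(x$counts, diag = TRUE) & x$counts != 0,
                 arr.ind = TRUE)
    df <- data.frame(i = idx[, 1L] - 1L, j = idx[, 2L] - 1L,
                     value = x$counts[idx])
    utils::write.table(df, path, sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Per-chromosome submatrix of a contact matrix
#'
#' @param x a [contact_matrix()].
#' @param chrom chromosome name.
#' @return square numeric matrix of the chromosome's intra-chromosomal
#'   contacts.
#' @export
chrom_submatrix <- function(x, chrom) {
  stopifnot(inherits(x, "contact_matrix"))
  idx <- chrom_bin_indices(x$bins, chrom)
  x$counts[idx, idx, drop = FALSE]
}

chrom_bin_indices <- function(bins, chrom) {
  if (!chrom %in% bins$chrom_names)
    stop("unknown chromosome: ", chrom)
  off <- bins$bin_offsets[[chrom]]
  seq.int(off + 1L, off + bins$n_bins_chrom[[chrom]])
}
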