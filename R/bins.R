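#' Genome bin table
#'
#' Partitions a genome into fixed-size bins, one bead per bin in the polymer
#' model. Coordinates are 0-based; bins are half-open intervals
#' `[k * bin_size, (k + 1) * bin_size)`. The last bin of each chromosome may
#' be shorter than `bin_size` but still counts as one bin (one bead).
#' Genome-wide bin indices are 1-based and contiguous in chromosome order.
#'
#' @param chrom_sizes either a named numeric vector of chromosome lengths
#'   (base pairs), or a two-column data frame `(chrom, length)` as produced
#'   by [read_chrom_sizes()].
#' @param bin_size bin width in base pairs. Default 500000 (500 kb).
#' @param chr_prefix chromosome-name normalization: `"keep"` leaves names as
#'   given, `"add"` ensures a `"chr"` prefix, `"strip"` removes it.
#' @return an object of class `bin_table` with elements `chrom_names`,
#'   `chrom_lengths`, `bin_size`, `n_bins_chrom`, `bin_offsets` (number of
#'   bins preceding each chromosome) and `n_bins`.
#' @examples
#' bt <- bin_table(c(chrA = 1200000, chrB = 500000), bin_size = 500000)
#' bt$n_bins # 3 + 1
#' @export
bin_table <- function(chrom_sizes, bin_size = 500000L,
                      chr_prefix = c("keep", "add", "strip")) {
  chr_prefix <- match.arg(chr_prefix)
  if (is.data.frame(chrom_sizes)) {
    if (ncol(chrom_sizes) < 2L)
      stop("chrom_sizes data frame needs two columns (chrom, length)")
    lens <- as.numeric(chrom_sizes[[2L]])
    names(lens) <- as.character(chrom_sizes[[1L]])
    chrom_sizes <- lens
  }
  if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes)))
    stop("chromosome lengths must be named")
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicated chromosome names")
  if (!all(is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("all chromosome lengths must be positive")
  if (length(bin_size) != 1L || !is.finite(bin_size) || bin_size <= 0)
    stop("bin_size must be a single positive number")
  nm <- normalize_chrom(names(chrom_sizes), chr_prefix)
  if (anyDuplicated(nm))
    stop("chromosome names collide after prefix normalization")
  lens <- as.numeric(chrom_sizes)
  names(lens) <- nm
  nb <- ceiling(lens / bin_size)
  offsets <- c(0, cumsum(nb))[seq_along(nb)]
  names(offsets) <- nm
  structure(
    list(chrom_names = nm, chrom_lengths = lens, bin_size = as.numeric(bin_size),
         n_bins_chrom = nb, bin_offsets = offsets, n_bins = sum(nb)),
    class = "bin_table"
  )
}

normalize_chrom <- function(x, chr_prefix = "keep") {
  x <- as.character(x)
  switch(chr_prefix,
         keep = x,
         add = ifelse(grepl("^chr", x), x, paste0("chr", x)),
         strip = sub("^chr", "", x))
}

#' @export
print.bin_table <- function(x, ...) {
  cat(sprintf("bin_table: %d chromosomes, %d bins of %g bp\n",
              length(x$chrom_names), x$n_bins, x$bin_size))
  invisible(x)
}

#' Read a chrom.sizes file
#'
#' Two-column whitespace/tab-delimited text: chromosome name, length in bp.
#'
#' @param path file path.
#' @return data frame with columns `chrom`, `length`.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          col.names = c("chrom", "length"))
  df$length <- as.numeric(df$length)
  df
}

#' Map genomic loci to genome-wide bin indices
#'
#' @param bins a [bin_table()].
#' @param chrom chromosome name(s), recycled against `pos`.
#' @param pos 0-based base-pair position(s); must satisfy
#'   `0 <= pos < chromosome length`.
#' @return integer vector of 1-based genome-wide bin indices.
#' @examples
#' bt <- bin_table(c(chr1 = 1500000, chr2 = 1000000), 500000)
#' locus_to_bin(bt, "chr2", 0) # 4: chr1 contributes 3 bins
#' @export
locus_to_bin <- function(bins, chrom, pos) {
  stopifnot(inherits(bins, "bin_table"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  unknown <- !(chrom %in% bins$chrom_names)
  if (any(unknown))
    stop("unknown chromosome(s): ", paste(unique(chrom[unknown]), collapse = ", "))
  len <- bins$chrom_lengths[chrom]
  bad <- !is.finite(pos) | pos < 0 | pos >= len
  if (any(bad))
    stop(sprintf("position out of range for %s: %s",
                 chrom[which(bad)[1L]], format(pos[which(bad)[1L]])))
  as.integer(bins$bin_offsets[chrom] + floor(pos / bins$bin_size) + 1)
}

#' Chromosome of each genome-wide bin
#'
#' @param bins a [bin_table()].
#' @param index 1-based genome-wide bin indices (default all bins).
#' @return character vector of chromosome names.
#' @export
bin_chrom <- function(bins, index = seq_len(bins$n_bins)) {
  stopifnot(inherits(bins, "bin_table"))
  if (any(index < 1L | index > bins$n_bins))
    stop("bin index out of range")
  all_chrom <- rep(bins$chrom_names, times = bins$n_bins_chrom)
  all_chrom[index]
}

#' Bin definitions as a BED-like data frame
#'
#' @param bins a [bin_table()].
#' @return data frame with `chrom`, `start`, `end` (0-based half-open) and
#'   the genome-wide `bin` index.
#' @export
bin_ranges <- function(bins) {
  stopifnot(inherits(bins, "bin_table"))
  chrom <- rep(bins$chrom_names, times = bins$n_bins_chrom)
  within_idx <- unlist(lapply(bins$n_bins_chrom, seq_len), use.names = FALSE) - 1
  start <- within_idx * bins$bin_size
  end <- pmin(start + bins$bin_size, bins$chrom_lengths[chrom])
  data.frame(chrom = chrom, start = start, end = end,
             bin = seq_len(bins$n_bins), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Write bin definitions as BED3
#'
#' @param bins a [bin_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bins_bed <- function(bins, path) {
  br <- bin_ranges(bins)
  utils::write.table(format(br[, c("chrom", "start", "end")], scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
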