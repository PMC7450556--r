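#' Observed-over-expected matrix for one chromosome
#'
#' Divides each intra-chromosomal contact by the mean contact at the same
#' bin separation, removing the distance-decay trend so that the A/B
#' compartment checkerboard becomes visible. Separations with zero total
#' coverage yield zeros.
#'
#' @param x a [contact_matrix()].
#' @param chrom chromosome name.
#' @return square numeric O/E matrix over the chromosome's bins (diagonal
#'   included).
#' @export
observed_over_expected <- function(x, chrom) {
  m <- chrom_submatrix(x, chrom)
  n <- nrow(m)
  if (n < 3L)
    stop("chromosome ", chrom, " has fewer than 3 bins")
  if (all(m == 0))
    stop("chromosome ", chrom, " has no contacts (all-zero matrix)")
  d <- abs(row(m) - col(m))
  expected <- vapply(0:(n - 1L), function(k) mean(m[d == k]), numeric(1))
  oe <- m
  nz <- expected > 0
  oe[] <- ifelse(nz[d + 1L], m / expected[d + 1L], 0)
  oe
}

#' Compartment degree of one chromosome
#'
#' Chromatin-activity score per bin: the leading eigenvector of the Pearson
#' correlation matrix of the observed-over-expected matrix, centered to zero
#' mean over valid bins and scaled to unit maximum absolute value. The sign
#' of the eigenvector is arbitrary; it is oriented so that its correlation
#' with `orientation_track` (e.g. gene density) is non-negative, or, absent
#' a track, so that the larger sign-group of bins is negative.
#'
#' Bins with zero marginal coverage are masked before the correlation step
#' and receive the degree of their nearest valid neighbour afterwards, so
#' downstream radial restraints cover every bead.
#'
#' @param x a [contact_matrix()].
#' @param chrom chromosome name.
#' @param orientation_track optional per-bin numeric vector (full chromosome
#'   length) used only to fix the eigenvector sign.
#' @return a list of class `compartment_profile` with `chrom`, `degree`
#'   (length = bins on the chromosome, masked bins interpolated), `mask`
#'   (TRUE where the bin had coverage), and `eigenvalue`.
#' @export
compartment_degree <- function(x, chrom, orientation_track = NULL) {
  m <- chrom_submatrix(x, chrom)
  n <- nrow(m)
  valid <- rowSums(m) > 0
  if (sum(valid) < 3L)
    stop("chromosome ", chrom, " has fewer than 3 bins with coverage")
  oe <- observed_over_expected(x, chrom)
  oev <- oe[valid, valid, drop = FALSE]
  sds <- apply(oev, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate correlation matrix on ", chrom,
         " (constant O/E rows); cannot orient compartments")
  cc <- stats::cor(oev)
  eg <- eigen(cc, symmetric = TRUE)
  v <- eg$vectors[, 1L]
  v <- v - mean(v)
  if (max(abs(v)) == 0)
    stop("degenerate leading eigenvector on ", chrom)
  v <- v / max(abs(v))
  if (!is.null(orientation_track)) {
    if (length(orientation_track) != n)
      stop("orientation_track must have one value per bin of ", chrom)
    s <- stats::cor(v, orientation_track[valid])
    if (is.finite(s) && s < 0) v <- -v
  } else if (sum(v > 0) > sum(v < 0)) {
    # larger compartment goes negative
    v <- -v
  }
  degree <- rep(NA_real_, n)
  degree[valid] <- v
  degree <- fill_nearest(degree)
  structure(list(chrom = chrom, degree = degree, mask = valid,
                 eigenvalue = eg$values[1L]),
            class = "compartment_profile")
}

# nearest-valid-neighbour interpolation of NA runs (ties -> left neighbour)
fill_nearest <- function(x) {
  if (!anyNA(x)) return(x)
  idx <- which(!is.na(x))
  if (length(idx) == 0L) stop("no valid values to interpolate from")
  for (i in which(is.na(x))) {
    j <- idx[which.min(abs(idx - i))]
    x[i] <- x[j]
  }
  x
}

#' Genome-wide compartment profile
#'
#' Runs [compartment_degree()] on every chromosome with at least 3 covered
#' bins and concatenates the per-bin degrees in genome order.
#'
#' @param x a [contact_matrix()].
#' @param orientation_tracks optional named list of per-chromosome tracks.
#' @return list of class `genome_compartments` with `degree` (length
#'   `bins$n_bins`), `mask`, and `profiles` (per-chromosome results).
#' @export
genome_compartments <- function(x, orientation_tracks = NULL) {
  bins <- x$bins
  degree <- rep(NA_real_, bins$n_bins)
  mask <- rep(FALSE, bins$n_bins)
  profiles <- list()
  for (chrom in bins$chrom_names) {
    trk <- if (!is.null(orientation_tracks)) orientation_tracks[[chrom]] else NULL
    p <- compartment_degree(x, chrom, orientation_track = trk)
    idx <- chrom_bin_indices(bins, chrom)
    degree[idx] <- p$degree
    mask[idx] <- p$mask
    profiles[[chrom]] <- p
  }
  structure(list(degree = degree, mask = mask, profiles = profiles,
                 bins = bins),
            class = "genome_compartments")
}

#' Write a compartment degree track as bedGraph
#'
#' @param degree numeric per-bin degree vector over the whole genome.
#' @param bins the matching [bin_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(degree, bins, path) {
  br <- bin_ranges(bins)
  stopifnot(length(degree) == nrow(br))
  df <- cbind(format(br[, c("chrom", "start", "end")], scientific = FALSE,
                     trim = TRUE),
              value = format(degree, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
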