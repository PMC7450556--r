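#' Run the full prioritization pipeline from files
#'
#' Reads a Hi-C matrix, curates and locates epitopes, computes the
#' genome-wide compartment profile, reconstructs a conformation ensemble,
#' and produces leave-one-out combined scores plus the method comparison
#' against the baseline alone.
#'
#' @param chrom_sizes chrom.sizes path or a named length vector.
#' @param hic_path contact matrix text file (dense or triplet).
#' @param epitope_path per-assay epitope TSV.
#' @param mapping_path peptide-to-locus TSV.
#' @param baseline_path baseline score TSV.
#' @param bin_size bin width in bp (default 500 kb).
#' @param hic_format passed to [read_contact_matrix()].
#' @param k KNN neighbourhood size (default 10).
#' @param n_replicas conformation replicas (default 300).
#' @param seed master seed for the ensemble.
#' @param r_min,r_max radial target range (model units).
#' @param max_iter per-replica optimization budget.
#' @param out_dir if non-NULL, writes the scored table, comparison report,
#'   compartment bedGraph and ensemble there.
#' @param quiet suppress progress messages.
#' @return list with `bins`, `hic`, `compartments`, `ensemble`, `epitopes`,
#'   `scores`, `comparison`.
#' @export
run_pipeline <- function(chrom_sizes, hic_path, epitope_path, mapping_path,
                         baseline_path, bin_size = 500000, hic_format = "auto",
                         k = 10L, n_replicas = 300L, seed = 1L,
                         r_min = 2.0, r_max = 9.5, max_iter = 5000L,
                         out_dir = NULL, quiet = FALSE) {
  if (is.character(chrom_sizes) && length(chrom_sizes) == 1L)
    chrom_sizes <- read_chrom_sizes(chrom_sizes)
  bins <- bin_table(chrom_sizes, bin_size = bin_size)
  say <- function(...) if (!quiet) message(...)
  say("reading contact matrix (", bins$n_bins, " bins)")
  hic <- read_contact_matrix(hic_path, bins, format = hic_format)
  say("curating epitopes")
  epitopes <- curate_epitopes(epitope_path, mapping_path, bins, quiet = quiet)
  say("computing compartment profile")
  comp <- genome_compartments(hic)
  targets <- assign_radial_targets(comp$degree, r_min = r_min, r_max = r_max)
  restraints <- restraint_set(targets)
  say("optimizing ", n_replicas, " conformation replicas")
  ensemble <- generate_ensemble(bins, restraints, n_replicas = n_replicas,
                                base_seed = seed, max_iter = max_iter)
  baseline <- read_baseline_scores(baseline_path)
  say("scoring epitopes (leave-one-out, k = ", k, ")")
  comparison <- compare_methods(epitopes, ensemble, baseline, k = k,
                                seed = seed)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_labeled_epitopes(epitopes, file.path(out_dir, "epitopes.tsv"))
    utils::write.table(comparison$scores, file.path(out_dir, "scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_comparison_report(comparison,
                            path_tsv = file.path(out_dir, "comparison.tsv"),
                            path_json = file.path(out_dir, "report.json"))
    write_bedgraph(comp$degree, bins,
                   file.path(out_dir, "compartment_degree.bedgraph"))
    write_ensemble(ensemble, file.path(out_dir, "ensemble"))
  }
  list(bins = bins, hic = hic, compartments = comp, ensemble = ensemble,
       epitopes = epitopes, scores = comparison$scores,
       comparison = comparison)
}
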