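# End-to-end orchestration: classify -> partition -> sites ->
# selection -> indels -> polymorphism curation -> pairwise comparison,
# with every configurable threshold gathered in one place.

#' Pipeline configuration
#'
#' Collects the analysis constants: assumed TTR values (1, 3, 5), the
#' low-coverage threshold (10 reads), the large-indel size floor
#' (100 bp), the polymorphism frequency floor (0.02) and the per-gene
#' reporting threshold (0.95).
#'
#' @param kappa_values TTR values for the selection scan.
#' @param coverage_threshold Depth below which a position counts as
#'   uncovered.
#' @param min_run Minimum low-coverage run length.
#' @param large_indel_min Minimum large-indel size (bp).
#' @param polymorphism_min_freq Polymorphic-variant frequency floor.
#' @param strand_bounds Forward-fraction bounds for curation.
#' @param min_count Minimum supporting reads for curation.
#' @param report_threshold Per-gene dN/dS flagging threshold.
#' @param normalization Site-count normalization.
#' @param overlap Overlapping-ORF policy for genome totals.
#' @param decompose_mnp Classify MNPs as constituent SNPs.
#' @param fallback Zero-synonymous fallback mode.
#' @param seed Seed for any stochastic steps.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(kappa_values = c(1, 3, 5),
                            coverage_threshold = 10L, min_run = 20L,
                            large_indel_min = 100L,
                            polymorphism_min_freq = 0.02,
                            strand_bounds = c(0.30, 0.70),
                            min_count = 10L, report_threshold = 0.95,
                            normalization = "per_position",
                            overlap = "longest",
                            decompose_mnp = FALSE, fallback = "sites",
                            seed = 1L) {
  stopifnot(length(kappa_values) >= 1L, all(kappa_values > 0),
            coverage_threshold > 0, large_indel_min > 0,
            polymorphism_min_freq > 0, report_threshold > 0)
  structure(list(kappa_values = kappa_values,
                 coverage_threshold = as.integer(coverage_threshold),
                 min_run = as.integer(min_run),
                 large_indel_min = as.integer(large_indel_min),
                 polymorphism_min_freq = polymorphism_min_freq,
                 strand_bounds = strand_bounds,
                 min_count = as.integer(min_count),
                 report_threshold = report_threshold,
                 normalization = normalization, overlap = overlap,
                 decompose_mnp = decompose_mnp, fallback = fallback,
                 seed = as.integer(seed)), class = "pipeline_config")
}

#' Run the full isolate-comparison pipeline
#'
#' Reads the reference genome and one isolate's mapping summaries,
#' classifies and partitions variants, computes possible-site totals
#' and the dN/dS / dI/dS scan, maps large deletions from the depth and
#' clip evidence, curates polymorphisms, and writes TSV/JSON reports.
#'
#' @param reference_fasta,reference_gff Reference genome files.
#' @param variants_vcf VCF (subset) of variant calls against the
#'   reference.
#' @param depth_tsv Optional per-position depth TSV.
#' @param clips_tsv Optional soft-clip consensus TSV.
#' @param isolate_fasta Optional de novo consensus FASTA for the
#'   alignment-gap indel route.
#' @param out_dir Report directory (created).
#' @param config A [pipeline_config()].
#' @return (Invisibly) a list with `effects`, `scan`, `report`,
#'   `deletions`, `polymorphisms`, `site_counts` and the paths written.
#' @export
run_pipeline <- function(reference_fasta, reference_gff, variants_vcf,
                         depth_tsv = NULL, clips_tsv = NULL,
                         isolate_fasta = NULL, out_dir,
                         config = pipeline_config()) {
  genome <- read_annotated_genome(reference_fasta, reference_gff)
  variants <- read_vcf(variants_vcf)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  effects <- classify_variants(variants, genome,
                               decompose_mnp = config$decompose_mnp)
  fixed_eff <- effects[effects$fixed, , drop = FALSE]
  scan <- selection_scan(fixed_eff, genome, kappas = config$kappa_values,
                         overlap = config$overlap,
                         fallback = config$fallback)
  report <- selection_report(scan, threshold = config$report_threshold,
                             genome = genome)
  sct <- site_count_table(genome, kappas = config$kappa_values)
  dels <- list()
  if (!is.null(depth_tsv)) {
    depth <- read_depth_tsv(depth_tsv)
    clips <- if (!is.null(clips_tsv)) read_clip_tsv(clips_tsv) else NULL
    cands <- scan_low_coverage(depth, threshold = config$coverage_threshold,
                               min_run = config$min_run,
                               circular = genome$circular)
    for (i in seq_len(nrow(cands))) {
      call <- refine_breakpoints(cands[i, ], clips, genome)
      if (call$size > config$large_indel_min) {
        dels[[length(dels) + 1L]] <- call
      }
    }
  }
  if (!is.null(isolate_fasta)) {
    iso <- read_annotated_genome(isolate_fasta, circular = genome$circular)
    gap_calls <- alignment_gap_indels(iso, genome,
                                      min_size = config$large_indel_min)
    dels <- c(dels, gap_calls)
  }
  poly <- variants[!variants$fixed, , drop = FALSE]
  curated <- if (nrow(poly)) {
    curate_polymorphisms(poly, genome,
                         min_freq = config$polymorphism_min_freq,
                         strand_bounds = config$strand_bounds,
                         min_count = config$min_count)
  } else NULL
  poly_report <- if (!is.null(curated) && any(curated$keep)) {
    polymorphism_summary(curated[curated$keep, , drop = FALSE], genome)
  } else polymorphism_summary(variant_table(integer(), character(),
                                            character()), genome)
  paths <- c(effects = file.path(out_dir, "effects.tsv"),
             scan = file.path(out_dir, "selection_scan.tsv"),
             report = file.path(out_dir, "selection_report.tsv"),
             scan_json = file.path(out_dir, "selection_scan.json"),
             sites = file.path(out_dir, "site_counts.tsv"),
             deletions = file.path(out_dir, "deletions.tsv"),
             polymorphisms = file.path(out_dir, "polymorphisms.tsv"))
  write_effect_table(effects, paths["effects"])
  write_selection_tsv(scan, paths["scan"])
  write_selection_tsv(report, paths["report"])
  write_selection_json(scan, paths["scan_json"])
  write_site_counts_tsv(sct, paths["sites"])
  write_deletions_tsv(dels, paths["deletions"], genome)
  utils::write.table(poly_report, paths["polymorphisms"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(genome = genome, effects = effects, scan = scan,
                 report = report, site_counts = sct, deletions = dels,
                 polymorphisms = poly_report, curated = curated,
                 paths = paths))
}
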