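#' Load the SpltNPV-G2b reference genome bundle
#'
#' The whole-genome and per-gene selection scans are calibrated against
#' the SpltNPV-G2b reference sequence (GenBank accession MN342245) and
#' its CDS annotations. That record is not redistributed with the
#' package; to use it, download the accession and place
#' `MN342245.fasta` (the genome, optionally split into records named
#' `MN342245.part1`, `MN342245.part2`, ... each under the FASTA line
#' limit) and `MN342245.gff3` (CDS features with `ID=ORF<n>`
#' attributes, `repeat_region` features for the homologous regions)
#' either in the directory given by `path` or in the package's
#' `extdata`.
#'
#' @param path Directory containing the two files (default: the
#'   package's `extdata`).
#' @return An `annotated_genome`.
#' @export
load_spltnpv_g2b <- function(path = system.file("extdata",
                                                package = "virocomp")) {
  fasta <- file.path(path, "MN342245.fasta")
  gff <- file.path(path, "MN342245.gff3")
  if (!file.exists(fasta) || !file.exists(gff)) {
    stop("SpltNPV-G2b reference bundle not found: place MN342245.fasta ",
         "and MN342245.gff3 (from GenBank accession MN342245) in ",
         if (nzchar(path)) path else "the package extdata directory",
         call. = FALSE)
  }
  read_annotated_genome(fasta, gff, circular = TRUE, name = "MN342245")
}
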