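# File formats: FASTA via Biostrings; the minimal GFF3 dialect used for
# ORF (CDS) and repeat_region annotations is read/written directly so
# that ID attributes and 1-based inclusive coordinates round-trip
# exactly.

#' Read a single-record FASTA file as a genome sequence
#'
#' @param path FASTA file.
#' @param which Record index when the file holds several (default 1).
#' @return Named character: the sequence, named by its FASTA header word.
#' @export
read_fasta_sequence <- function(path, which = 1L) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < which) stop("FASTA record ", which, " not present in ", path)
  seqs <- as.character(set)
  stats::setNames(seqs[which], sub("\\s.*$", "", names(set)[which]))
}

#' Write sequences to FASTA (70-column wrap)
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read ORF and repeat annotations from GFF3
#'
#' Understands the dialect this package writes: `CDS` features with an
#' `ID` attribute become ORFs, `repeat_region` features become repeats.
#' Coordinates are GFF3 native (1-based inclusive). Wrapped ORFs cannot
#' be represented in GFF3 and are not expected in input files.
#'
#' @param path GFF3 file.
#' @return List with `orfs` and `repeat_regions` data frames as accepted
#'   by [annotated_genome()].
#' @export
read_annotations_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(list(orfs = NULL, repeat_regions = NULL))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad)) stop("malformed GFF3 line ", bad[1L], " in ", path)
  m <- do.call(rbind, parts)
  type <- m[, 3L]
  attr_id <- sub("^.*ID=([^;]+).*$", "\\1", m[, 9L])
  start <- as.integer(m[, 4L])
  end <- as.integer(m[, 5L])
  cds <- type == "CDS"
  rep <- type == "repeat_region"
  orfs <- if (any(cds)) {
    data.frame(orf_id = attr_id[cds], first = start[cds], last = end[cds],
               strand = m[cds, 7L])
  }
  repeat_regions <- if (any(rep)) {
    data.frame(label = attr_id[rep], first = start[rep], last = end[rep])
  }
  list(orfs = orfs, repeat_regions = repeat_regions)
}

#' Write genome annotations as GFF3
#'
#' @param genome An `annotated_genome`.
#' @param path Output file.
#' @export
write_annotations_gff3 <- function(genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$name,
                     genome_length(genome)), con)
  o <- genome$orfs
  if (nrow(o)) {
    writeLines(sprintf("%s\tvirocomp\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
                       genome$name, o$first, o$last, o$strand, o$orf_id), con)
  }
  r <- genome$repeat_regions
  if (nrow(r)) {
    writeLines(sprintf("%s\tvirocomp\trepeat_region\t%d\t%d\t.\t+\t.\tID=%s",
                       genome$name, r$first, r$last, r$label), con)
  }
  invisible(path)
}

#' Read an annotated genome from FASTA + GFF3
#'
#' @param fasta Genome FASTA (first record used). A multi-part FASTA
#'   whose records are named `<name>.part1`, `<name>.part2`, ... is
#'   concatenated in record order into one sequence.
#' @param gff GFF3 annotation file (optional).
#' @param circular Topology flag (default `TRUE`).
#' @param name Override the genome label (default: FASTA header).
#' @return An `annotated_genome`.
#' @export
read_annotated_genome <- function(fasta, gff = NULL, circular = TRUE,
                                  name = NULL) {
  set <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(set))
  if (length(set) > 1L && all(grepl("\\.part[0-9]+$", ids))) {
    ord <- order(as.integer(sub("^.*\\.part", "", ids)))
    sequence <- paste(as.character(set)[ord], collapse = "")
    label <- sub("\\.part[0-9]+$", "", ids[1L])
  } else {
    sequence <- as.character(set)[1L]
    label <- ids[1L]
  }
  ann <- if (!is.null(gff)) read_annotations_gff3(gff) else
    list(orfs = NULL, repeat_regions = NULL)
  annotated_genome(name = if (is.null(name)) label else name,
                   sequence = sequence, circular = circular,
                   orfs = ann$orfs, repeat_regions = ann$repeat_regions)
}

#' Write an annotated genome as FASTA + GFF3
#'
#' @param genome An `annotated_genome`.
#' @param fasta,gff Output paths (either may be `NULL` to skip).
#' @export
write_annotated_genome <- function(genome, fasta = NULL, gff = NULL) {
  if (!is.null(fasta)) {
    write_fasta(stats::setNames(genome$sequence, genome$name), fasta)
  }
  if (!is.null(gff)) write_annotations_gff3(genome, gff)
  invisible(genome)
}
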