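
.BASES <- c("A", "C", "G", "T")

.s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

.complement <- function(x) chartr("ACGT", "TGCA", x)

.revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  .complement(paste(rev(.s2c(x)), collapse = ""))
}

.is_transition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}

#' Construct an annotated genome
#'
#' Container for a (usually circular) viral genome sequence together with
#' its ORF and repeat-region annotations. All coordinates are 1-based
#' inclusive; an ORF whose `first` exceeds its `last` wraps through the
#' origin of a circular genome. This object is the coordinate authority
#' for every downstream analysis.
#'
#' @param name Text label for the genome/isolate.
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T` (case is
#'   normalised to upper). Ambiguity codes are rejected unless
#'   `ambiguity = "mask"`, in which case non-ACGT characters are replaced
#'   by `N` and treated as non-codable downstream.
#' @param circular Logical; circular topology (default `TRUE`).
#' @param orfs `data.frame` with columns `orf_id`, `first`, `last`,
#'   `strand` (`"+"`/`"-"`) and optionally `aa_length`. If `aa_length` is
#'   absent it is computed as (span - 3)/3, i.e. the annotated span is
#'   assumed to include the terminal stop codon.
#' @param repeat_regions `data.frame` with columns `label`, `first`,
#'   `last` (homologous regions and other repeats).
#' @param ambiguity `"error"` (default) or `"mask"`.
#'
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(name, sequence, circular = TRUE,
                             orfs = NULL, repeat_regions = NULL,
                             ambiguity = c("error", "mask")) {
  ambiguity <- match.arg(ambiguity)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(unname(sequence))
  L <- nchar(sequence)
  if (L == 0L) stop("genome sequence must be non-empty")
  bad <- gsub("[ACGT]", "", sequence)
  if (nchar(bad) > 0L) {
    if (ambiguity == "error") {
      stop("sequence contains non-ACGT characters: ",
           paste(unique(.s2c(bad)), collapse = ""))
    }
    sequence <- gsub("[^ACGT]", "N", sequence)
  }
  if (is.null(orfs)) {
    orfs <- data.frame(orf_id = character(), first = integer(),
                       last = integer(), strand = character(),
                       aa_length = integer())
  } else {
    orfs <- as.data.frame(orfs)
    req <- c("orf_id", "first", "last", "strand")
    if (!all(req %in% names(orfs))) {
      stop("orfs must have columns ", paste(req, collapse = ", "))
    }
    if (anyDuplicated(orfs$orf_id)) stop("ORF identifiers must be unique")
    if (!all(orfs$strand %in% c("+", "-"))) stop("ORF strand must be '+' or '-'")
    if (any(orfs$first < 1L | orfs$first > L | orfs$last < 1L | orfs$last > L)) {
      stop("ORF coordinates out of range [1, ", L, "]")
    }
    if (!circular && any(orfs$first > orfs$last)) {
      stop("wrapped ORF (first > last) on a non-circular genome")
    }
    span <- .span_length(orfs$first, orfs$last, L)
    if (any(span %% 3L != 0L)) {
      stop("ORF coding span must be a multiple of 3: ",
           paste(orfs$orf_id[span %% 3L != 0L], collapse = ", "))
    }
    if (is.null(orfs$aa_length)) orfs$aa_length <- (span - 3L) %/% 3L
  }
  if (is.null(repeat_regions)) {
    repeat_regions <- data.frame(label = character(), first = integer(),
                                 last = integer())
  } else {
    repeat_regions <- as.data.frame(repeat_regions)
    if (!all(c("label", "first", "last") %in% names(repeat_regions))) {
      stop("repeat_regions must have columns label, first, last")
    }
    if (any(repeat_regions$first < 1L | repeat_regions$last > L)) {
      stop("repeat region coordinates out of range")
    }
  }
  structure(list(name = name, sequence = sequence, circular = circular,
                 orfs = orfs, repeat_regions = repeat_regions),
            class = "annotated_genome")
}

.span_length <- function(first, last, L) {
  ifelse(first <= last, last - first + 1L, L - first + 1L + last)
}

#' Genome length in nucleotides
#' @param genome An `annotated_genome`.
#' @return Integer length.
#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, %s, %d ORFs, %d repeat regions\n",
              x$name, genome_length(x),
              if (x$circular) "circular" else "linear",
              nrow(x$orfs), nrow(x$repeat_regions)))
  invisible(x)
}

#' Genomic positions of an ORF in coding order
#'
#' Expands an ORF annotation into the vector of genome positions that its
#' coding sequence visits, in 5'→3' coding order (reversed for the minus
#' strand), wrapping through the origin if needed.
#'
#' @param genome An `annotated_genome`.
#' @param orf One row of `genome$orfs` (or a list with `first`, `last`,
#'   `strand`).
#' @return Integer vector of 1-based genome positions.
#' @export
orf_positions <- function(genome, orf) {
  L <- genome_length(genome)
  if (orf$first <= orf$last) {
    pos <- orf$first:orf$last
  } else {
    if (!genome$circular) stop("wrapped ORF on linear genome")
    pos <- c(orf$first:L, 1:orf$last)
  }
  if (orf$strand == "-") pos <- rev(pos)
  pos
}

#' Rotate a circular genome to a new origin
#'
#' Re-linearises a circular genome so that `anchor` becomes position 1
#' (the convention in baculovirus genomics is to anchor the origin at the
#' polyhedrin start codon). All ORF and repeat annotations are remapped;
#' annotations that now span the join simply wrap (first > last).
#'
#' @param genome A circular `annotated_genome`.
#' @param anchor 1-based position that becomes position 1.
#' @return Rotated `annotated_genome`.
#' @export
rotate_to_origin <- function(genome, anchor) {
  L <- genome_length(genome)
  if (!genome$circular) stop("rotation requires a circular genome")
  if (anchor < 1L || anchor > L) stop("anchor out of range [1, ", L, "]")
  if (anchor == 1L) return(genome)
  s <- genome$sequence
  newseq <- paste0(substr(s, anchor, L), substr(s, 1L, anchor - 1L))
  remap <- function(p) ((p - anchor) %% L) + 1L
  out <- genome
  out$sequence <- newseq
  if (nrow(out$orfs)) {
    out$orfs$first <- remap(out$orfs$first)
    out$orfs$last <- remap(out$orfs$last)
  }
  if (nrow(out$repeat_regions)) {
    out$repeat_regions$first <- remap(out$repeat_regions$first)
    out$repeat_regions$last <- remap(out$repeat_regions$last)
  }
  out
}

#' Extract the coding sequence of an ORF
#'
#' Plus-strand ORFs yield the genome subsequence `first..last` (wrapping
#' the origin when needed); minus-strand ORFs yield its reverse
#' complement. The result begins with the annotated start codon.
#'
#' @param genome An `annotated_genome`.
#' @param orf An ORF id (character) or a row of `genome$orfs`.
#' @return Coding nucleotide string (length a multiple of 3).
#' @export
extract_cds <- function(genome, orf) {
  if (is.character(orf)) {
    i <- match(orf, genome$orfs$orf_id)
    if (is.na(i)) stop("unknown ORF id: ", orf)
    orf <- genome$orfs[i, ]
  }
  pos <- orf_positions(genome, orf)
  if (length(pos) %% 3L != 0L) stop("coding span not a multiple of 3")
  chars <- .s2c(genome$sequence)[pos]
  cds <- paste(chars, collapse = "")
  if (orf$strand == "-") cds <- .complement(cds)
  cds
}

.genetic_code <- function() {
  code <- get0(".genetic_code_tab", envir = .virocomp_cache)
  if (is.null(code)) {
    gc <- Biostrings::GENETIC_CODE
    code <- stats::setNames(as.character(gc), names(gc))
    assign(".genetic_code_tab", code, envir = .virocomp_cache)
  }
  code
}

#' Translate a coding sequence
#'
#' Standard genetic code; the stop codon is rendered `*`. Internal stop
#' codons are permitted but reported with a warning.
#'
#' @param cds Nucleotide string, length a multiple of 3, over ACGT.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds) {
  n <- nchar(cds)
  if (n == 0L) return("")
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3")
  if (grepl("[^ACGT]", cds)) stop("non-ACGT character in CDS")
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- .genetic_code()[codons]
  k <- length(aa)
  if (k > 1L && any(aa[-k] == "*")) {
    warning("internal stop codon(s) in CDS")
  }
  paste(aa, collapse = "")
}

#' Logical mask of coding positions
#'
#' @param genome An `annotated_genome`.
#' @return Logical vector of genome length; `TRUE` where covered by at
#'   least one ORF.
#' @export
coding_mask <- function(genome) {
  L <- genome_length(genome)
  mask <- logical(L)
  if (nrow(genome$orfs)) {
    for (i in seq_len(nrow(genome$orfs))) {
      mask[orf_positions(genome, genome$orfs[i, ])] <- TRUE
    }
  }
  mask
}

#' Positions outside all ORFs
#'
#' Intergenic positions are exactly those covered by no ORF. Repeat
#' regions (homologous regions) do not remove positions: an hr is
#' intergenic unless it lies inside an ORF.
#'
#' @param genome An `annotated_genome`.
#' @return Sorted integer vector of 1-based positions.
#' @export
intergenic_positions <- function(genome) {
  which(!coding_mask(genome))
}

#' Reverse-complement a genome with its annotations
#'
#' Used mainly by strand-symmetry checks: each ORF keeps its identity but
#' flips strand and has its coordinates mirrored.
#'
#' @param genome An `annotated_genome` (no wrapped ORFs).
#' @return The reverse-complemented `annotated_genome`.
#' @export
reverse_complement_genome <- function(genome) {
  L <- genome_length(genome)
  out <- genome
  out$sequence <- .revcomp(genome$sequence)
  if (nrow(out$orfs)) {
    if (any(out$orfs$first > out$orfs$last)) {
      stop("reverse_complement_genome does not support wrapped ORFs")
    }
    first <- L - genome$orfs$last + 1L
    last <- L - genome$orfs$first + 1L
    out$orfs$first <- first
    out$orfs$last <- last
    out$orfs$strand <- ifelse(genome$orfs$strand == "+", "-", "+")
  }
  if (nrow(out$repeat_regions)) {
    first <- L - genome$repeat_regions$last + 1L
    last <- L - genome$repeat_regions$first + 1L
    out$repeat_regions$first <- first
    out$repeat_regions$last <- last
  }
  out
}
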