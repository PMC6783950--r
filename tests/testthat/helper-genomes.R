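# Small fixture builders used across the test files.

toy_plus <- function() {
  annotated_genome("toy+", "ATGTTTTAA", circular = FALSE,
                   orfs = data.frame(orf_id = "ORF1", first = 1L, last = 9L,
                                     strand = "+"))
}

toy_minus <- function() {
  annotated_genome("toy-", "TTACATCAT", circular = FALSE,
                   orfs = data.frame(orf_id = "ORF1", first = 1L, last = 9L,
                                     strand = "-"))
}

# independent translation oracle: direct GENETIC_CODE lookup
oracle_translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# brute-force oracle for weighted codon site counts: enumerate the nine
# single-nucleotide changes and compare translations
oracle_codon_sites <- function(codon, kappa,
                               normalization = "per_position",
                               stop_changes = "nonsynonymous") {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(codon, "")[[1]]
  aa <- oracle_translate_codon(codon)
  s <- n <- 0
  for (j in 1:3) {
    for (b in setdiff(bases, chars[j])) {
      mut <- chars
      mut[j] <- b
      pair <- paste0(sort(c(chars[j], b)), collapse = "")
      w <- if (pair %in% c("AG", "CT")) kappa else 1
      if (normalization == "per_position") w <- w / (kappa + 2)
      maa <- oracle_translate_codon(paste(mut, collapse = ""))
      if (maa == "*") {
        if (stop_changes == "nonsynonymous") n <- n + w
      } else if (maa == aa) s <- s + w else n <- n + w
    }
  }
  c(s_sites = s, n_sites = n)
}

# whole-proteome rediff oracle for effect classification: apply the
# variant to the genome, re-extract and re-translate every ORF, and
# compare protein sequences
oracle_effect <- function(variant_row, genome) {
  chars <- strsplit(genome$sequence, "")[[1]]
  span <- variant_row$position:(variant_row$position +
                                  nchar(variant_row$ref) - 1L)
  chars[span] <- strsplit(variant_row$alt, "")[[1]]
  mut <- genome
  mut$sequence <- paste(chars, collapse = "")
  changed <- FALSE
  hit_orf <- FALSE
  for (i in seq_len(nrow(genome$orfs))) {
    cds0 <- extract_cds(genome, genome$orfs[i, ])
    cds1 <- extract_cds(mut, genome$orfs[i, ])
    if (cds0 == cds1) next
    hit_orf <- TRUE
    p0 <- as.character(Biostrings::translate(Biostrings::DNAString(cds0)))
    p1 <- as.character(Biostrings::translate(Biostrings::DNAString(cds1)))
    if (p0 != p1) changed <- TRUE
  }
  if (!hit_orf) "intergenic" else if (changed) "nonsynonymous" else "synonymous"
}

random_codon <- function() {
  repeat {
    codon <- paste(sample(c("A", "C", "G", "T"), 3, replace = TRUE),
                   collapse = "")
    if (!codon %in% c("TAA", "TAG", "TGA")) return(codon)
  }
}
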