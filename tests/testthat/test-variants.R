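test_that("variant classes are inferred from allele shapes", {
  expect_equal(variant_class("A", "G"), "SNP")
  expect_equal(variant_class("AC", "GT"), "MNP")
  expect_equal(variant_class("ACGT", "A"), "short_indel")
  expect_error(variant_class("A", "A"), "differ")
  expect_error(variant_table(1, "A", paste(rep("G", 150), collapse = "")),
               "1-99")
  expect_error(variant_table(1, "A", "G", count = 10, coverage = 5),
               "exceeds coverage")
})

test_that("SNP effects match the spec'd worked examples", {
  eff <- classify_variants(variant_table(6L, "T", "C"), toy_plus())
  expect_equal(eff$effect, "synonymous")   # TTT -> TTC, both Phe
  expect_equal(eff$orf_id, "ORF1")
  expect_equal(eff$codon_index, 2L)
  eff2 <- classify_variants(variant_table(8L, "A", "G"), toy_minus())
  expect_equal(eff2$effect, "nonsynonymous")  # ATG -> ACG on coding strand
  expect_equal(eff2$aa_change, "M1T")
  g <- annotated_genome("x", "ATGTTTTAACCC", circular = FALSE,
                        orfs = data.frame(orf_id = "ORF1", first = 1L,
                                          last = 9L, strand = "+"))
  eff3 <- classify_variants(variant_table(11L, "C", "T"), g)
  expect_equal(eff3$effect, "intergenic")
  expect_true(is.na(eff3$orf_id))
  expect_error(classify_variants(variant_table(6L, "A", "C"), toy_plus()),
               "mismatch")
})

test_that("MNPs are classified jointly per codon, or decomposed on request", {
  # ATG TTT TAA ; MNP over positions 5-6 changes codon 2 TTT->TCA (Phe->Ser)
  eff <- classify_variants(variant_table(5L, "TT", "CA"), toy_plus())
  expect_equal(nrow(eff), 1L)
  expect_equal(eff$effect, "nonsynonymous")
  expect_equal(eff$aa_change, "F2S")
  # decomposition classifies each constituent SNP alone
  dec <- classify_variants(variant_table(5L, "TT", "CA"), toy_plus(),
                           decompose_mnp = TRUE)
  expect_equal(nrow(dec), 2L)
  expect_setequal(dec$position, c(5L, 6L))
  # an MNP spanning two codons yields one event per affected codon
  g <- annotated_genome("x", "ATGTTTAAATAA", circular = FALSE,
                        orfs = data.frame(orf_id = "o", first = 1L,
                                          last = 12L, strand = "+"))
  eff2 <- classify_variants(variant_table(6L, "TA", "CG"), g)
  expect_equal(nrow(eff2), 2L)
  expect_setequal(eff2$codon_index, c(2L, 3L))
})

test_that("classification agrees with the whole-proteome rediff oracle", {
  cfg <- sim_config(genome_length = 9000L, orf_count = 6L, seed = 21L)
  g <- gen_genome(cfg)
  set.seed(22)
  chars <- strsplit(g$sequence, "")[[1]]
  for (i in 1:120) {
    pos <- sample.int(genome_length(g), 1)
    ref <- chars[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    v <- variant_table(pos, ref, alt)
    eff <- classify_variants(v, g)
    got <- if (all(is.na(eff$orf_id))) "intergenic" else {
      if (any(eff$effect == "nonsynonymous")) "nonsynonymous"
      else "synonymous"
    }
    expect_equal(got, oracle_effect(v[1, ], g),
                 label = sprintf("effect at %d %s>%s", pos, ref, alt))
  }
})

test_that("classification is strand-symmetric", {
  cfg <- sim_config(genome_length = 6000L, orf_count = 4L, seed = 31L)
  g <- gen_genome(cfg)
  rc <- reverse_complement_genome(g)
  L <- genome_length(g)
  set.seed(32)
  chars <- strsplit(g$sequence, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in 1:40) {
    pos <- sample.int(L, 1)
    ref <- chars[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    e1 <- classify_variants(variant_table(pos, ref, alt), g)
    e2 <- classify_variants(variant_table(L - pos + 1L, comp[[ref]],
                                          comp[[alt]]), rc)
    expect_equal(sort(e1$effect), sort(e2$effect))
  }
})

test_that("partition is a disjoint cover keyed on (position, ref, alt)", {
  a <- variant_table(c(100L, 200L), c("C", "G"), c("T", "A"))
  b <- variant_table(c(100L, 300L), c("C", "A"), c("T", "G"))
  p <- partition_variants(a, b)
  expect_equal(p$shared$position, 100L)
  expect_equal(p$unique_a$position, 200L)
  expect_equal(p$unique_b$position, 300L)
  p2 <- partition_variants(a, a)
  expect_equal(nrow(p2$shared), 2L)
  expect_equal(nrow(p2$unique_a), 0L)
  # same position, different alt: both unique
  x <- variant_table(100L, "C", "T")
  y <- variant_table(100L, "C", "A")
  p3 <- partition_variants(x, y)
  expect_equal(nrow(p3$shared), 0L)
  expect_equal(nrow(p3$unique_a), 1L)
  expect_equal(nrow(p3$unique_b), 1L)
  expect_error(partition_variants(variant_table(1L, "A", "G", fixed = FALSE),
                                  y), "fixed")
})

test_that("per-ORF tallies count events once and bucket intergenic hits", {
  g <- annotated_genome("x", "ATGTTTAAATAACCCCCC", circular = FALSE,
                        orfs = data.frame(orf_id = "ORF36", first = 1L,
                                          last = 12L, strand = "+"))
  v <- rbind(variant_table(c(4L, 7L, 8L), c("T", "A", "A"),
                           c("C", "G", "T")),
             variant_table(14L, "C", "T"))
  tab <- tally_per_orf(classify_variants(v, g))
  expect_equal(tab$snps[tab$orf_id == "ORF36"], 3L)
  expect_equal(tab$snps[tab$orf_id == "intergenic"], 1L)
  expect_equal(nrow(tally_per_orf(classify_variants(
    variant_table(integer(), character(), character()), g))), 0L)
  # MNP across two codons of one ORF counts once
  tab2 <- tally_per_orf(classify_variants(variant_table(6L, "TA", "CG"), g))
  expect_equal(tab2$snps, 1L)
})

test_that("transition/transversion tallies follow the purine/pyrimidine rule", {
  v <- variant_table(1:3, c("C", "C", "G"), c("T", "A", "A"))
  expect_equal(ts_tv_tally(v),
               c(transitions = 2L, transversions = 1L))
  expect_equal(ts_tv_tally(variant_table(integer(), character(),
                                         character())),
               c(transitions = 0L, transversions = 0L))
  allag <- variant_table(1:4, rep("A", 4), rep("G", 4))
  expect_equal(ts_tv_tally(allag)[["transversions"]], 0L)
  expect_error(ts_tv_tally(variant_table(1L, "AA", "GG")), "SNPs only")
})

test_that("mask regions drop variants in deletion flanks", {
  g <- toy_plus()
  v <- variant_table(c(2L, 6L), c("T", "T"), c("C", "C"))
  eff <- classify_variants(v, g,
                           mask_regions = data.frame(first = 1L, last = 3L))
  expect_equal(eff$position, 6L)
})

test_that("VCF subset round-trips fixed and polymorphic records", {
  v <- rbind(variant_table(c(10L, 20L), c("A", "CC"), c("G", "TT")),
             variant_table(30L, "G", "C", fixed = FALSE, count = 150L,
                           coverage = 3000L, forward_fraction = 0.47))
  path <- tempfile(fileext = ".vcf")
  write_vcf(v, path, chrom = "refx")
  v2 <- read_vcf(path)
  expect_equal(v2$position, v$position)
  expect_equal(v2$ref, v$ref)
  expect_equal(v2$alt, v$alt)
  expect_equal(v2$fixed, v$fixed)
  expect_equal(v2$count[3], 150L)
  expect_equal(v2$coverage[3], 3000L)
  expect_equal(v2$forward_fraction[3], 0.47, tolerance = 1e-4)
  expect_equal(attr(v2, "chrom"), "refx")
  # malformed line reported with its number
  lines <- readLines(path)
  lines[7] <- "broken line"
  writeLines(lines, path)
  expect_error(read_vcf(path), "line 7")
})
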