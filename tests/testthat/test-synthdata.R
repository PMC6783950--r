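test_that("generated genomes satisfy their structural contract", {
  cfg <- sim_config(seed = 501L)
  g <- gen_genome(cfg)
  expect_equal(genome_length(g), cfg$genome_length)
  expect_equal(nrow(g$orfs), cfg$orf_count)
  expect_equal(nrow(g$repeat_regions), cfg$hr_count)
  for (i in seq_len(nrow(g$orfs))) {
    prot <- translate_cds(extract_cds(g, g$orfs[i, ]))
    expect_match(prot, "^M[^*]*\\*$")  # start, no internal stop, stop
  }
  # ORFs do not overlap
  o <- g$orfs[order(g$orfs$first), ]
  expect_true(all(o$first[-1] > o$last[-nrow(o)]))
  # repeats are tandem: the unit repeats hr_copies times
  r <- g$repeat_regions[1, ]
  block <- substr(g$sequence, r$first, r$last)
  unit <- substr(block, 1, cfg$hr_unit_length)
  expect_equal(block, strrep(unit, cfg$hr_copies))
})

test_that("the generator is deterministic under its seed", {
  cfg <- sim_config(seed = 502L, n_substitutions = 100L,
                    deletions = data.frame(first = 5001L, last = 5200L,
                                           inserted_sequence = ""))
  g1 <- gen_genome(cfg)
  g2 <- gen_genome(cfg)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$orfs, g2$orfs)
  ev1 <- evolve_isolate(g1, cfg)
  ev2 <- evolve_isolate(g2, cfg)
  expect_identical(ev1$isolate$sequence, ev2$isolate$sequence)
  expect_identical(ev1$truth$variants, ev2$truth$variants)
  mp1 <- gen_mapping_outputs(g1, ev1$truth, cfg)
  mp2 <- gen_mapping_outputs(g2, ev2$truth, cfg)
  expect_identical(mp1$depth, mp2$depth)
  expect_identical(mp1$variants, mp2$variants)
  # a different seed changes the genome
  expect_false(identical(gen_genome(sim_config(seed = 503L))$sequence,
                         g1$sequence))
})

test_that("orf_count 0 gives an all-intergenic genome", {
  g <- gen_genome(sim_config(seed = 504L, genome_length = 2000L,
                             orf_count = 0L))
  expect_length(intergenic_positions(g), 2000L)
})

test_that("infeasible packing is rejected", {
  expect_error(gen_genome(sim_config(seed = 1L, genome_length = 3000L,
                                     orf_count = 10L)),
               "infeasible")
})

test_that("ground truth reconstructs the isolate byte for byte", {
  set.seed(505)
  ins <- paste(sample(c("A", "C", "G", "T"), 25, TRUE), collapse = "")
  cfg <- sim_config(seed = 506L, n_substitutions = 400L,
                    deletions = data.frame(
                      first = c(7001L, 20001L), last = c(7400L, 21000L),
                      inserted_sequence = c("", ins)))
  g <- gen_genome(cfg)
  ev <- evolve_isolate(g, cfg)
  expect_identical(apply_ground_truth(g, ev$truth), ev$isolate$sequence)
  expect_equal(genome_length(ev$isolate),
               genome_length(g) - 1400L + 25L)
  # truth tallies are consistent with the variant list
  v <- ev$truth$variants
  expect_equal(ev$truth$observed$n_obs, sum(v$effect == "nonsynonymous"))
  expect_equal(ev$truth$observed$s_obs, sum(v$effect == "synonymous"))
  expect_equal(ev$truth$observed$i_obs, sum(v$effect == "intergenic"))
})

test_that("depth profiles are overdispersed, zeroed over deletions, tapered", {
  dl <- data.frame(first = 10001L, last = 11000L, inserted_sequence = "")
  cfg <- sim_config(seed = 507L, n_substitutions = 50L, deletions = dl)
  g <- gen_genome(cfg)
  ev <- evolve_isolate(g, cfg)
  mp <- gen_mapping_outputs(g, ev$truth, cfg)
  expect_length(mp$depth, genome_length(g))
  expect_true(all(mp$depth[10001:11000] == 0L))
  outside <- mp$depth[c(1:9800, 11300:30000)]
  expect_lt(abs(mean(outside) - cfg$depth_mean) / cfg$depth_mean, 0.05)
  cv <- stats::sd(outside) / mean(outside)
  expect_gt(cv, 0.15)   # clearly beyond Poisson noise
  expect_lt(cv, 0.35)
  # shoulder taper: depth just outside the deletion is depressed
  expect_lt(mean(mp$depth[9996:10000]), 0.25 * cfg$depth_mean)
  # no spurious low-coverage runs away from the deletion
  runs <- scan_low_coverage(mp$depth)
  expect_equal(nrow(runs), 1L)
})

test_that("polymorphic sampling recovers configured frequencies", {
  poly <- data.frame(position = c(5000L, 15000L), alt = c("T", "C"),
                     frequency = c(0.10, 0.30),
                     forward_fraction = c(0.5, 0.45))
  cfg <- sim_config(seed = 508L, n_substitutions = 10L,
                    polymorphisms = poly)
  g <- gen_genome(cfg)
  ev <- evolve_isolate(g, cfg)
  mp <- gen_mapping_outputs(g, ev$truth, cfg)
  pv <- mp$variants[!mp$variants$fixed, ]
  expect_equal(nrow(pv), 2L)
  freq <- pv$count / pv$coverage
  expect_lt(abs(freq[1] - 0.10), 0.02)
  expect_lt(abs(freq[2] - 0.30), 0.02)
})

test_that("simulation bundles round-trip through their files", {
  cfg <- sim_config(seed = 509L, n_substitutions = 60L,
                    genome_length = 12000L, orf_count = 6L,
                    deletions = data.frame(first = 6001L, last = 6300L,
                                           inserted_sequence = ""))
  g <- gen_genome(cfg)
  ev <- evolve_isolate(g, cfg)
  mp <- gen_mapping_outputs(g, ev$truth, cfg)
  dir <- file.path(tempdir(), "vc_bundle_test")
  paths <- write_simulation_bundle(dir, g, ev$isolate, ev$truth, mp)
  expect_true(all(file.exists(paths)))
  g2 <- read_annotated_genome(paths["reference_fasta"],
                              paths["reference_gff"])
  expect_identical(g2$sequence, g$sequence)
  v2 <- read_vcf(paths["variants_vcf"])
  expect_equal(nrow(v2), nrow(mp$variants))
  expect_identical(read_depth_tsv(paths["depth_tsv"]), mp$depth)
  expect_equal(read_clip_tsv(paths["clips_tsv"]), mp$clips)
})
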