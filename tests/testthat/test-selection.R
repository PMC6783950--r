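test_that("dN/dS and dI/dS follow the rate-ratio definition", {
  # 100 TTT codons: N_poss = 800/3, S_poss = 100/3 at TTR 1
  sites <- region_site_counts(strrep("TTT", 100), weight_scheme(1))
  obs <- observed_counts(n_obs = 8L, s_obs = 1L)
  expect_equal(dnds(obs, sites), 1.0, tolerance = 1e-12)
  expect_equal(dnds(observed_counts(n_obs = 0L, s_obs = 5L), sites), 0)
  expect_error(dnds(observed_counts(n_obs = 3L, s_obs = 0L), sites),
               "gene_dnds")
  g <- annotated_genome("x", paste0(strrep("TTT", 30), strrep("ACGT", 30)),
                        orfs = data.frame(orf_id = "o", first = 1L,
                                          last = 90L, strand = "+"))
  gsites <- genome_site_counts(g, weight_scheme(1))
  # i_obs/i_poss equal to s_obs/s_poss gives exactly 1
  i_obs <- 12L
  s_obs <- round(i_obs * gsites$s_poss / gsites$i_poss)
  scaled <- observed_counts(n_obs = 1L, s_obs = s_obs, i_obs = i_obs)
  expect_equal(dids(scaled, gsites),
               (i_obs / gsites$i_poss) / (s_obs / gsites$s_poss))
  expect_equal(dids(observed_counts(1L, 10L, 0L), gsites), 0)
})

test_that("gene-level fallback approximates dS from the genome-wide rate", {
  cfg <- sim_config(genome_length = 9000L, orf_count = 6L, seed = 41L)
  g <- gen_genome(cfg)
  scheme <- weight_scheme(3)
  gsites <- genome_site_counts(g, scheme)
  gene_sites <- region_site_counts(extract_cds(g, g$orfs[1, ]), scheme)
  genome_obs <- observed_counts(n_obs = 120L, s_obs = 80L, i_obs = 30L)
  obs <- observed_counts(n_obs = 3L, s_obs = 0L)
  res_sites <- gene_dnds(obs, gene_sites, genome_obs, gsites, "sites")
  res_len <- gene_dnds(obs, gene_sites, genome_obs, gsites, "length")
  expect_true(res_sites$s_approximated)
  expect_true(is.finite(res_sites$dnds) && res_sites$dnds > 0)
  # site-proportional expectation: genome s_obs scaled by the gene's
  # share of possible synonymous sites
  expect_equal(res_sites$expected_s,
               genome_obs$s_obs * gene_sites$s_poss / gsites$s_poss)
  # the two fallback modes differ only through codon usage
  expect_false(isTRUE(all.equal(res_sites$dnds, res_len$dnds)))
  expect_equal(res_sites$dnds / res_len$dnds,
               res_len$expected_s / res_sites$expected_s,
               tolerance = 1e-9)
  # with observed synonymous substitutions no approximation happens
  res_obs <- gene_dnds(observed_counts(3L, 2L), gene_sites, genome_obs,
                       gsites)
  expect_false(res_obs$s_approximated)
  expect_error(gene_dnds(observed_counts(0L, 0L), gene_sites, genome_obs,
                         gsites), "undefined")
})

recover_mean <- function(seeds, omega, kappa_true, kappa_fit,
                         intergenic_rate = 1, stat = dnds) {
  # averages replicate simulations to control Monte Carlo error; the
  # per-replicate conditions (2000 substitutions) are unchanged
  mean(vapply(seeds, function(s) {
    cfg <- sim_config(seed = s, n_substitutions = 2000L, omega = omega,
                      kappa_true = kappa_true,
                      intergenic_rate = intergenic_rate)
    g <- gen_genome(cfg)
    ev <- evolve_isolate(g, cfg)
    stat(ev$truth$observed, genome_site_counts(g, weight_scheme(kappa_fit)))
  }, numeric(1)))
}

test_that("neutral and purifying simulations recover omega", {
  d1 <- recover_mean(101:103, omega = 1, kappa_true = 1, kappa_fit = 1)
  expect_gt(d1, 0.9)
  expect_lt(d1, 1.1)
  d2 <- recover_mean(111:113, omega = 0.2, kappa_true = 3, kappa_fit = 3)
  expect_lt(abs(d2 - 0.2), 0.05)
})

test_that("analysing transition-biased data at kappa 1 understates dN/dS", {
  cfg <- sim_config(seed = 103L, n_substitutions = 2000L, omega = 1,
                    kappa_true = 5)
  g <- gen_genome(cfg)
  ev <- evolve_isolate(g, cfg)
  d_matched <- dnds(ev$truth$observed, genome_site_counts(g, weight_scheme(5)))
  d_mismatched <- dnds(ev$truth$observed,
                       genome_site_counts(g, weight_scheme(1)))
  expect_lt(d_mismatched, d_matched)
})

test_that("dI/dS recovers a planted intergenic/synonymous rate ratio", {
  d <- recover_mean(121:123, omega = 1, kappa_true = 1, kappa_fit = 1,
                    intergenic_rate = 0.5, stat = dids)
  expect_lt(abs(d - 0.5), 0.1)
})

test_that("selection scan plus report flag genes crossing the threshold", {
  scan <- data.frame(
    scope = rep(c("genome", "ORF1", "ORF2"), each = 3),
    kappa = rep(c(1, 3, 5), 3),
    n_obs = rep(c(50L, 4L, 2L), each = 3),
    s_obs = rep(c(60L, 1L, 3L), each = 3),
    i_obs = 0L, n_poss = 1, s_poss = 1, i_poss = 1, dn = 1, ds = 1,
    dnds = c(0.5, 0.6, 0.7, 0.90, 0.96, 1.01, 0.2, 0.3, 0.4),
    dids = NA_real_, s_approximated = FALSE)
  rep_all <- selection_report(scan, flagged_only = FALSE)
  expect_equal(rep_all$flagged, c(FALSE, TRUE, FALSE))
  rep_fl <- selection_report(scan)
  expect_setequal(rep_fl$scope, c("genome", "ORF1"))
  expect_equal(rep_fl$dnds_ttr3[rep_fl$scope == "ORF1"], 0.96)
  expect_equal(nrow(selection_report(scan[0, ])), 0L)
})

test_that("selection scan on classified effects matches direct computation", {
  cfg <- sim_config(seed = 105L, genome_length = 12000L, orf_count = 8L,
                    n_substitutions = 250L, omega = 0.5)
  g <- gen_genome(cfg)
  ev <- evolve_isolate(g, cfg)
  v <- ev$truth$variants
  effects <- classify_variants(variant_table(v$position, v$ref, v$alt), g)
  scan <- selection_scan(effects, g, kappas = c(1, 3))
  grow <- scan[scan$scope == "genome" & scan$kappa == 1, ]
  expect_equal(grow$n_obs, ev$truth$observed$n_obs)
  expect_equal(grow$s_obs, ev$truth$observed$s_obs)
  expect_equal(grow$i_obs, ev$truth$observed$i_obs)
  expect_equal(grow$dnds,
               dnds(ev$truth$observed, genome_site_counts(g, weight_scheme(1))))
  # genes with zero observed substitutions are omitted (no data)
  quiet <- setdiff(g$orfs$orf_id, v$orf_id)
  expect_true(all(!quiet %in% scan$scope))
})
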