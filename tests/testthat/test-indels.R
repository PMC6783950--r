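test_that("low-coverage scan finds maximal runs and honours thresholds", {
  depth <- c(50L, 48L, 3L, 0L, 0L, 1L, 2L, 47L, 52L)
  runs <- scan_low_coverage(depth, threshold = 10L, min_run = 1L,
                            circular = FALSE)
  expect_equal(runs$first, 3L)
  expect_equal(runs$last, 7L)
  expect_equal(nrow(scan_low_coverage(rep(10L, 50), min_run = 1L)), 0L)
  all0 <- scan_low_coverage(rep(0L, 50), min_run = 1L)
  expect_equal(c(all0$first, all0$last, all0$length), c(1L, 50L, 50L))
  # min_run suppresses short dropouts
  d2 <- rep(100L, 200)
  d2[50:52] <- 0L
  expect_equal(nrow(scan_low_coverage(d2, min_run = 20L)), 0L)
})

test_that("low-coverage runs merge across the origin on circular genomes", {
  depth <- rep(100L, 100)
  depth[c(1:5, 96:100)] <- 0L
  runs <- scan_low_coverage(depth, min_run = 5L, circular = TRUE)
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$first, 96L)
  expect_equal(runs$last, 5L)
  expect_equal(runs$length, 10L)
  runs_lin <- scan_low_coverage(depth, min_run = 5L, circular = FALSE)
  expect_equal(nrow(runs_lin), 2L)
})

test_that("scan output regions are maximal, disjoint and sorted", {
  set.seed(51)
  for (i in 1:20) {
    depth <- stats::rnbinom(5000, mu = 40, size = 2)
    runs <- scan_low_coverage(depth, threshold = 10L, min_run = 3L,
                              circular = FALSE)
    if (nrow(runs) < 2) next
    expect_true(all(diff(runs$first) > 0))
    expect_true(all(runs$first[-1] > runs$last[-nrow(runs)] + 1L))
    # maximality: the flanking positions are not low
    expect_true(all(depth[pmax(runs$first - 1L, 1L)] >= 10L |
                      runs$first == 1L))
    expect_true(all(depth[pmin(runs$last + 1L, 5000L)] >= 10L |
                      runs$last == 5000L))
  }
})

test_that("deletion sizes follow the first/last missing convention", {
  expect_equal(deletion_length(123487L, 125222L), 1736L)
  expect_equal(deletion_length(122661L, 123153L), 493L)
  expect_equal(deletion_length(7L, 7L), 1L)
  expect_error(deletion_length(10L, 5L), "inverted")
})

test_that("clip evidence refines breakpoints and recovers junction inserts", {
  set.seed(61)
  ins40 <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                 collapse = "")
  dl <- data.frame(first = 10001L, last = 10500L,
                   inserted_sequence = ins40)
  cfg <- sim_config(seed = 62L, n_substitutions = 100L, deletions = dl)
  g <- gen_genome(cfg)
  ev <- evolve_isolate(g, cfg)
  mp <- gen_mapping_outputs(g, ev$truth, cfg)
  cands <- scan_low_coverage(mp$depth)
  expect_equal(nrow(cands), 1L)
  call <- refine_breakpoints(cands[1, ], mp$clips, g)
  expect_equal(call$first_missing, 10001L)
  expect_equal(call$last_missing, 10500L)
  expect_equal(call$size, 500L)
  expect_equal(call$evidence, "clip_confirmed")
  expect_equal(call$inserted_sequence, ins40)
  # without clips the scan bounds are returned as coverage-only
  call2 <- refine_breakpoints(cands[1, ], NULL, g)
  expect_equal(call2$evidence, "coverage_only")
  expect_equal(call2$first_missing, cands$first[1])
  # contradictory evidence raises an ambiguity error
  bad <- mp$clips
  bad$anchor_position[bad$side == "right_flank"] <-
    bad$anchor_position[bad$side == "right_flank"] + 40L
  expect_error(refine_breakpoints(cands[1, ], bad, g), "contradictory")
})

test_that("anchor chaining recovers a constructed deletion exactly", {
  set.seed(71)
  A <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  D <- paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = "")
  B <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  ref <- annotated_genome("r", paste0(A, D, B), circular = FALSE)
  qry <- annotated_genome("q", paste0(A, B), circular = FALSE)
  calls <- alignment_gap_indels(qry, ref)
  expect_length(calls, 1L)
  x <- calls[[1]]
  expect_equal(attr(x, "type"), "deletion")
  expect_equal(x$size, 500L)
  # placement is exact up to left-normalised junction homology:
  # excising the called span reproduces the query
  rebuilt <- paste0(substr(ref$sequence, 1, x$first_missing - 1L),
                    substr(ref$sequence, x$last_missing + 1L,
                           genome_length(ref)))
  expect_identical(rebuilt, qry$sequence)
  # identity comparison yields nothing
  expect_length(alignment_gap_indels(ref, ref), 0L)
  # sub-threshold gaps are ignored
  ref80 <- annotated_genome("r80", paste0(A, substr(D, 1, 80), B),
                            circular = FALSE)
  expect_length(alignment_gap_indels(qry, ref80, min_size = 100L), 0L)
  # and reported when they meet the floor
  expect_length(alignment_gap_indels(qry, ref80, min_size = 80L), 1L)
})

test_that("anchor chaining reports insertions in the query", {
  set.seed(72)
  A <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  I <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  B <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  ref <- annotated_genome("r", paste0(A, B), circular = FALSE)
  qry <- annotated_genome("q", paste0(A, I, B), circular = FALSE)
  calls <- alignment_gap_indels(qry, ref)
  expect_length(calls, 1L)
  expect_equal(attr(calls[[1]], "type"), "insertion")
  expect_equal(calls[[1]]$inserted_sequence, I)
})

test_that("aligned-FASTA gap extraction mirrors the anchor route", {
  aln_ref <- paste0("ACGT", strrep("A", 120), "GGCC")
  aln_qry <- paste0("ACGT", strrep("-", 120), "GGCC")
  calls <- gaps_from_alignment(aln_qry, aln_ref, min_size = 100L)
  expect_length(calls, 1L)
  expect_equal(calls[[1]]$first_missing, 5L)
  expect_equal(calls[[1]]$last_missing, 124L)
  expect_equal(calls[[1]]$size, 120L)
  # gap in the reference row = insertion in the query
  calls2 <- gaps_from_alignment(aln_ref, aln_qry, min_size = 100L)
  expect_length(calls2, 1L)
  expect_equal(attr(calls2[[1]], "type"), "insertion")
  expect_error(gaps_from_alignment("AC-", "ACGT"), "equal length")
})

test_that("coverage and assembly routes agree on the same planted truth", {
  dl <- data.frame(first = 8001L, last = 9000L, inserted_sequence = "")
  cfg <- sim_config(seed = 81L, n_substitutions = 150L, deletions = dl)
  g <- gen_genome(cfg)
  ev <- evolve_isolate(g, cfg)
  mp <- gen_mapping_outputs(g, ev$truth, cfg)
  cands <- scan_low_coverage(mp$depth)
  cov_call <- refine_breakpoints(cands[1, ], mp$clips, g)
  asm_calls <- alignment_gap_indels(ev$isolate, g)
  asm_calls <- Filter(function(x) attr(x, "type") == "deletion", asm_calls)
  expect_length(asm_calls, 1L)
  expect_equal(asm_calls[[1]]$size, cov_call$size)
  expect_lte(abs(asm_calls[[1]]$first_missing - cov_call$first_missing), 3L)
})

test_that("deletion annotation distinguishes full, partial and repeat loss", {
  g <- annotated_genome(
    "x", strrep("ACGT", 300),
    orfs = data.frame(orf_id = c("ORF125", "ORF126"),
                      first = c(100L, 400L), last = c(300L, 600L),
                      strand = c("+", "+"), aa_length = c(66L, 66L)),
    repeat_regions = data.frame(label = "hr17", first = 800L, last = 900L))
  full <- virocomp:::.new_deletion_call(380L, 650L, "clip_confirmed")
  expect_equal(annotate_deletion(full, g), "ORF126 deleted")
  part <- virocomp:::.new_deletion_call(250L, 350L, "clip_confirmed")
  expect_equal(annotate_deletion(part, g), "ORF125 partial deletion")
  hr <- virocomp:::.new_deletion_call(790L, 910L, "clip_confirmed")
  expect_equal(annotate_deletion(hr, g), "hr17 deleted")
  none <- virocomp:::.new_deletion_call(700L, 750L, "coverage_only")
  expect_equal(annotate_deletion(none, g), "intergenic")
})

test_that("depth and clip TSVs round-trip and deletion TSV carries both conventions", {
  depth <- c(5L, 0L, 12L, 40L)
  p <- tempfile(fileext = ".tsv")
  write_depth_tsv(depth, p)
  expect_identical(read_depth_tsv(p), depth)
  clips <- clip_evidence(c(10L, 20L), c("left_flank", "right_flank"),
                         c("ACGTACGTACGTACGTA", "TTTTACGTACGTACGTT"))
  pc <- tempfile(fileext = ".tsv")
  write_clip_tsv(clips, pc)
  expect_equal(read_clip_tsv(pc), clips)
  call <- virocomp:::.new_deletion_call(11L, 110L, "clip_confirmed")
  pd <- tempfile(fileext = ".tsv")
  write_deletions_tsv(list(call), pd)
  tab <- utils::read.table(pd, header = TRUE, sep = "\t")
  expect_equal(tab$bed_start, 10L)
  expect_equal(tab$bed_end, 110L)
  expect_equal(tab$first_missing, 11L)
  expect_equal(tab$size, 100L)
})

test_that("ORF aa-length bookkeeping matches the coding span", {
  # 313 aa at 942 nt span (including stop), 246 aa at 741 nt
  g <- gen_genome(sim_config(genome_length = 9000L, orf_count = 4L,
                             seed = 91L))
  span <- with(g$orfs, last - first + 1L)
  expect_equal(g$orfs$aa_length, (span - 3L) %/% 3L)
})
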