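# Seeded synthetic-data generator. Emulates the outputs of deep
# sequencing two derived isolates of an annotated circular virus
# genome: an ancestral genome with ORFs and homologous-region-like
# tandem repeats; a derived isolate carrying fixed substitutions
# accepted under a nonsynonymous acceptance ratio omega and transition
# bias kappa_true, large deletions with optional junction inserts, and
# low-frequency polymorphisms; and the read-mapping summaries the
# analysis consumes (overdispersed per-position depth, soft-clip
# consensus at deletion breakpoints, variant calls). Because
# nonsynonymous proposals are accepted with probability omega while
# synonymous and intergenic proposals are neutral, the analysis-side
# dN/dS estimand equals omega by construction — the parameter-recovery
# contract used throughout the tests.

#' Simulation configuration
#'
#' Defaults describe a compact test genome (30 kb) whose mapping
#' summaries mirror the deep-sequencing regime the analysis targets:
#' mean depth in the thousands with ~23% overdispersion, 150 nt reads.
#'
#' @param genome_length Genome size in bp (default 30000).
#' @param orf_count Number of non-overlapping ORFs (default 25; together
#'   with the length distribution this makes the genome ~80% coding,
#'   mirroring the gene-dense organisation of baculovirus genomes).
#' @param orf_aa_mean,orf_aa_sd Mean/SD of ORF length in amino acids
#'   (default 320 +/- 60, floored at 50).
#' @param gc_content Genomic G+C fraction (default 0.43, typical of
#'   group II alphabaculoviruses).
#' @param hr_count Homologous-region-like repeat loci (default 3).
#' @param hr_unit_length,hr_copies Tandem repeat unit length (70 bp)
#'   and copy number (4).
#' @param n_substitutions Fixed substitutions to accept (default 600).
#' @param omega Nonsynonymous acceptance ratio (default 0.2,
#'   purifying).
#' @param kappa_true Transition bias of the substitution process
#'   (default 1).
#' @param intergenic_rate Intergenic acceptance relative to the neutral
#'   synonymous rate (default 1).
#' @param deletions `data.frame` with `first`, `last`,
#'   `inserted_sequence` (may be `""`): large deletions applied to the
#'   derived isolate, in reference coordinates; must not overlap.
#' @param polymorphisms `data.frame` with `position`, `alt`,
#'   `frequency`, `forward_fraction`: within-isolate polymorphic SNPs.
#' @param depth_mean Mean sequencing depth (default 4545).
#' @param depth_cv Coefficient of variation of depth (default 0.23,
#'   matching SD/mean of deep viral resequencing runs).
#' @param read_length Read length for clip/taper modelling (default
#'   150).
#' @param clip_length Length of the soft-clip consensus emitted at each
#'   breakpoint (default 75, about half a read).
#' @param min_spacer Minimum intergenic spacer between ORFs (default
#'   30 bp).
#' @param seed Integer seed; fully determines all generator output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome_length = 30000L, orf_count = 25L,
                       orf_aa_mean = 320, orf_aa_sd = 60,
                       gc_content = 0.43, hr_count = 3L,
                       hr_unit_length = 70L, hr_copies = 4L,
                       n_substitutions = 600L, omega = 0.2,
                       kappa_true = 1, intergenic_rate = 1,
                       deletions = NULL, polymorphisms = NULL,
                       depth_mean = 4545, depth_cv = 0.23,
                       read_length = 150L, clip_length = 75L,
                       min_spacer = 30L, seed = 1L) {
  stopifnot(omega > 0, kappa_true > 0, intergenic_rate > 0,
            genome_length > 0, depth_mean > 0)
  if (!is.null(deletions) && nrow(deletions) > 1L) {
    d <- deletions[order(deletions$first), ]
    if (any(d$first[-1L] <= d$last[-nrow(d)])) {
      stop("configured deletions must not overlap")
    }
  }
  structure(list(genome_length = as.integer(genome_length),
                 orf_count = as.integer(orf_count),
                 orf_aa_mean = orf_aa_mean, orf_aa_sd = orf_aa_sd,
                 gc_content = gc_content, hr_count = as.integer(hr_count),
                 hr_unit_length = as.integer(hr_unit_length),
                 hr_copies = as.integer(hr_copies),
                 n_substitutions = as.integer(n_substitutions),
                 omega = omega, kappa_true = kappa_true,
                 intergenic_rate = intergenic_rate,
                 deletions = deletions, polymorphisms = polymorphisms,
                 depth_mean = depth_mean, depth_cv = depth_cv,
                 read_length = as.integer(read_length),
                 clip_length = as.integer(clip_length),
                 min_spacer = as.integer(min_spacer),
                 seed = as.integer(seed)),
            class = "sim_config")
}

.base_probs <- function(gc) {
  c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
}

.random_dna <- function(n, gc) {
  if (n <= 0L) return("")
  paste(sample(.BASES, n, replace = TRUE, prob = .base_probs(gc)),
        collapse = "")
}

.random_cds <- function(aa_length, gc) {
  p <- .base_probs(gc)
  sense <- setdiff(.ALL_CODONS, .STOP_CODONS)
  w <- vapply(sense, function(cdn) prod(p[.s2c(cdn)]), numeric(1))
  body <- sample(sense, aa_length - 1L, replace = TRUE, prob = w)
  paste0("ATG", paste(body, collapse = ""), sample(.STOP_CODONS, 1L))
}

#' Generate a random annotated genome
#'
#' Circular genome with non-overlapping ORFs (proper start codon, no
#' internal stops, terminal stop), random intergenic spacers, and
#' tandem-repeat loci emulating homologous regions placed in the
#' largest spacers. Deterministic under `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return An `annotated_genome`.
#' @export
gen_genome <- function(cfg) {
  set.seed(cfg$seed)
  L <- cfg$genome_length
  gc <- cfg$gc_content
  no <- cfg$orf_count
  if (no == 0L) {
    return(annotated_genome("synthetic_ref", .random_dna(L, gc),
                            circular = TRUE))
  }
  aa_len <- pmax(50L, as.integer(round(stats::rnorm(no, cfg$orf_aa_mean,
                                                    cfg$orf_aa_sd))))
  orf_nt <- (aa_len + 1L) * 3L
  n_gaps <- no + 1L
  spare <- L - sum(orf_nt) - n_gaps * cfg$min_spacer
  hr_nt <- cfg$hr_unit_length * cfg$hr_copies
  if (spare < cfg$hr_count * hr_nt) {
    stop("infeasible packing: ORFs and repeats exceed genome length")
  }
  # reserve space for the repeat arrays up front, then spread the rest
  extra <- as.vector(stats::rmultinom(1L, spare - cfg$hr_count * hr_nt,
                                      rep(1, n_gaps)))
  gaps <- cfg$min_spacer + extra
  hr_gaps <- if (cfg$hr_count > 0L) {
    chosen <- sample.int(n_gaps, cfg$hr_count)
    gaps[chosen] <- gaps[chosen] + hr_nt
    chosen
  } else integer()
  strands <- sample(c("+", "-"), no, replace = TRUE)
  pieces <- character(0)
  cursor <- 0L
  orfs <- data.frame(orf_id = sprintf("ORF%d", seq_len(no)),
                     first = integer(no), last = integer(no),
                     strand = strands)
  reps <- data.frame(label = character(), first = integer(),
                     last = integer())
  emit_gap <- function(i) {
    g <- gaps[i]
    if (i %in% hr_gaps && g >= hr_nt + 2L) {
      unit <- .random_dna(cfg$hr_unit_length, gc)
      block <- paste(rep(unit, cfg$hr_copies), collapse = "")
      lpad <- (g - hr_nt) %/% 2L
      rpad <- g - hr_nt - lpad
      reps <<- rbind(reps, data.frame(
        label = sprintf("hr%d", match(i, hr_gaps)),
        first = cursor + lpad + 1L, last = cursor + lpad + hr_nt))
      paste0(.random_dna(lpad, gc), block, .random_dna(rpad, gc))
    } else .random_dna(g, gc)
  }
  for (i in seq_len(no)) {
    gseq <- emit_gap(i)
    pieces <- c(pieces, gseq)
    cursor <- cursor + nchar(gseq)
    cds <- .random_cds(aa_len[i], gc)
    oseq <- if (strands[i] == "+") cds else .revcomp(cds)
    orfs$first[i] <- cursor + 1L
    orfs$last[i] <- cursor + nchar(oseq)
    pieces <- c(pieces, oseq)
    cursor <- cursor + nchar(oseq)
  }
  gseq <- emit_gap(n_gaps)
  pieces <- c(pieces, gseq)
  sequence <- paste(pieces, collapse = "")
  stopifnot(nchar(sequence) == L)
  annotated_genome("synthetic_ref", sequence, circular = TRUE,
                   orfs = orfs, repeat_regions = reps)
}

.TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

#' Evolve a derived isolate from a reference genome
#'
#' Substitution proposals are drawn uniformly over eligible positions;
#' the proposed base is the transition partner with probability
#' `kappa_true/(kappa_true + 2)`, otherwise one of the two
#' transversions. Synonymous proposals are always accepted,
#' nonsynonymous with probability `min(omega, 1)` (for `omega > 1`
#' synonymous acceptance is down-weighted to `1/omega` instead), and
#' intergenic with probability proportional to `intergenic_rate`.
#' Terminal stop codons and configured deletion spans are not mutated.
#' Deletions (with optional junction inserts) are applied after the
#' substitutions. Ground truth records every planted event.
#'
#' @param genome Reference `annotated_genome` (e.g. from
#'   [gen_genome()]).
#' @param cfg A [sim_config()].
#' @return List with `isolate` (`annotated_genome`, annotations
#'   dropped: coordinates shift under deletions) and `truth` (list:
#'   `variants` data frame with effect labels, `deletions`, `observed`
#'   [observed_counts()], `per_orf` tallies).
#' @export
evolve_isolate <- function(genome, cfg) {
  set.seed(cfg$seed + 1L)
  L <- genome_length(genome)
  seq_chars <- .s2c(genome$sequence)
  maps <- .coding_maps(genome)
  code <- .genetic_code()
  o <- genome$orfs
  opos <- lapply(seq_len(nrow(o)), function(i) orf_positions(genome, o[i, ]))
  eligible <- rep(TRUE, L)
  # terminal stop codons are excluded from possible-site tallies, so
  # the simulation does not mutate them either (keeps the estimand
  # exactly omega)
  for (i in seq_len(nrow(o))) {
    np <- length(opos[[i]])
    eligible[opos[[i]][(np - 2L):np]] <- FALSE
  }
  dels <- cfg$deletions
  if (!is.null(dels)) {
    for (i in seq_len(nrow(dels))) {
      eligible[dels$first[i]:dels$last[i]] <- FALSE
    }
  }
  ref_chars <- seq_chars
  kap <- cfg$kappa_true
  p_ts <- kap / (kap + 2)
  p_nonsyn <- min(cfg$omega, 1)
  p_syn <- if (cfg$omega > 1) 1 / cfg$omega else 1
  p_inter <- min(cfg$intergenic_rate, 1)
  n_target <- cfg$n_substitutions
  recs_pos <- integer(n_target)
  recs_ref <- recs_alt <- recs_eff <- recs_orf <- character(n_target)
  recs_codon <- integer(n_target)
  accepted <- 0L
  tries <- 0L
  max_tries <- 200L * max(n_target, 1L)
  while (accepted < n_target) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("substitution count exceeds available sites")
    }
    p <- sample.int(L, 1L)
    if (!eligible[p]) next
    ref <- ref_chars[p]
    alt <- if (stats::runif(1) < p_ts) .TRANSITION_OF[[ref]] else {
      sample(setdiff(.BASES, c(ref, .TRANSITION_OF[[ref]])), 1L)
    }
    oi <- maps$owner[p]
    if (oi == 0L) {
      eff <- "intergenic"
      orf_id <- NA_character_
      ci <- NA_integer_
      p_acc <- p_inter
    } else {
      idx <- maps$index[p]
      ci <- (idx - 1L) %/% 3L + 1L
      cpos <- opos[[oi]][(3L * (ci - 1L) + 1L):(3L * ci)]
      # effects are classified against the pristine reference context —
      # exactly how the analysis pipeline classifies each variant —
      # even when an earlier substitution hit a neighbouring base
      ref_cod <- ref_chars[cpos]
      alt_cod <- ref_cod
      alt_cod[match(p, cpos)] <- alt
      if (o$strand[oi] == "-") {
        ref_cod <- .complement(ref_cod)
        alt_cod <- .complement(alt_cod)
      }
      syn <- code[[paste(ref_cod, collapse = "")]] ==
        code[[paste(alt_cod, collapse = "")]]
      eff <- if (syn) "synonymous" else "nonsynonymous"
      orf_id <- o$orf_id[oi]
      p_acc <- if (syn) p_syn else p_nonsyn
    }
    if (stats::runif(1) >= p_acc) next
    accepted <- accepted + 1L
    recs_pos[accepted] <- p
    recs_ref[accepted] <- ref
    recs_alt[accepted] <- alt
    recs_eff[accepted] <- eff
    recs_orf[accepted] <- orf_id
    recs_codon[accepted] <- ci
    seq_chars[p] <- alt
    eligible[p] <- FALSE
  }
  variants <- data.frame(position = recs_pos, ref = recs_ref,
                         alt = recs_alt, effect = recs_eff,
                         orf_id = recs_orf, codon_index = recs_codon,
                         fixed = TRUE)[seq_len(accepted), , drop = FALSE]
  variants <- variants[order(variants$position), , drop = FALSE]
  rownames(variants) <- NULL
  iso_seq <- paste(seq_chars, collapse = "")
  truth_dels <- data.frame(first_missing = integer(),
                           last_missing = integer(), size = integer(),
                           inserted_sequence = character())
  if (!is.null(dels) && nrow(dels)) {
    dels <- dels[order(dels$first, decreasing = TRUE), , drop = FALSE]
    if (is.null(dels$inserted_sequence)) dels$inserted_sequence <- ""
    for (i in seq_len(nrow(dels))) {
      iso_seq <- paste0(substr(iso_seq, 1L, dels$first[i] - 1L),
                        dels$inserted_sequence[i],
                        substr(iso_seq, dels$last[i] + 1L, nchar(iso_seq)))
    }
    truth_dels <- data.frame(first_missing = rev(dels$first),
                             last_missing = rev(dels$last),
                             size = rev(dels$last - dels$first + 1L),
                             inserted_sequence = rev(dels$inserted_sequence))
  }
  per_orf <- tallyframe <- NULL
  if (nrow(variants)) {
    bucket <- ifelse(is.na(variants$orf_id), "intergenic", variants$orf_id)
    tab <- table(bucket)
    per_orf <- data.frame(orf_id = names(tab), snps = as.integer(tab),
                          row.names = NULL)
  } else {
    per_orf <- data.frame(orf_id = character(), snps = integer())
  }
  truth <- list(
    variants = variants, deletions = truth_dels,
    observed = observed_counts(
      n_obs = sum(variants$effect == "nonsynonymous"),
      s_obs = sum(variants$effect == "synonymous"),
      i_obs = sum(variants$effect == "intergenic")),
    per_orf = per_orf)
  isolate <- annotated_genome(paste0(genome$name, "_derived"), iso_seq,
                              circular = genome$circular)
  list(isolate = isolate, truth = truth)
}

#' Rebuild an isolate sequence from its ground truth
#'
#' Applies the recorded substitutions and deletions to the reference;
#' by construction the result must equal the emitted isolate sequence
#' byte for byte (the generator's consistency contract).
#'
#' @param genome The reference `annotated_genome`.
#' @param truth The `truth` element returned by [evolve_isolate()].
#' @return Nucleotide string.
#' @export
apply_ground_truth <- function(genome, truth) {
  chars <- .s2c(genome$sequence)
  v <- truth$variants
  stopifnot(all(chars[v$position] == v$ref))
  chars[v$position] <- v$alt
  s <- paste(chars, collapse = "")
  d <- truth$deletions
  if (nrow(d)) {
    d <- d[order(d$first_missing, decreasing = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(d))) {
      s <- paste0(substr(s, 1L, d$first_missing[i] - 1L),
                  d$inserted_sequence[i],
                  substr(s, d$last_missing[i] + 1L, nchar(s)))
    }
  }
  s
}

.nb_size <- function(mu, cv) {
  v <- (cv * mu)^2
  if (v <= mu) return(Inf)
  mu^2 / (v - mu)
}

#' Generate mock read-mapping outputs
#'
#' Emulates the summaries a read mapper would produce for the derived
#' isolate mapped against the reference: a per-position depth profile
#' (negative-binomial around `depth_mean`, zero across deleted spans
#' with a linear shoulder taper of up to one read length), soft-clip
#' consensus records at each deletion breakpoint, and the variant
#' calls (fixed substitutions plus binomially sampled polymorphic
#' SNPs).
#'
#' @param reference Reference `annotated_genome`.
#' @param truth Ground truth from [evolve_isolate()].
#' @param cfg The [sim_config()].
#' @return List with `depth` (integer vector), `clips`
#'   ([clip_evidence()] frame) and `variants` ([variant_table()]
#'   frame).
#' @export
gen_mapping_outputs <- function(reference, truth, cfg) {
  set.seed(cfg$seed + 2L)
  L <- genome_length(reference)
  size <- .nb_size(cfg$depth_mean, cfg$depth_cv)
  depth <- if (is.finite(size)) {
    stats::rnbinom(L, mu = cfg$depth_mean, size = size)
  } else stats::rpois(L, cfg$depth_mean)
  refseq <- reference$sequence
  clips <- clip_evidence(integer(), character(), character())
  d <- truth$deletions
  taper <- max(1L, cfg$read_length %/% 2L)
  for (i in seq_len(nrow(d))) {
    f <- d$first_missing[i]; l <- d$last_missing[i]
    depth[f:l] <- 0L
    for (j in seq_len(taper)) {
      lhs <- f - j
      rhs <- l + j
      fac <- j / taper
      if (lhs >= 1L) depth[lhs] <- as.integer(round(depth[lhs] * fac))
      if (rhs <= L) depth[rhs] <- as.integer(round(depth[rhs] * fac))
    }
    ins <- d$inserted_sequence[i]
    cl <- cfg$clip_length
    clips <- rbind(clips, clip_evidence(
      anchor_position = c(f - 1L, l + 1L),
      side = c("left_flank", "right_flank"),
      consensus = c(paste0(ins, substr(refseq, l + 1L, l + cl)),
                    paste0(substr(refseq, f - cl, f - 1L), ins))))
  }
  v <- truth$variants
  fixed <- if (nrow(v)) {
    variant_table(v$position, v$ref, v$alt, fixed = TRUE,
                  count = depth[v$position], coverage = depth[v$position],
                  forward_fraction = 0.5)
  } else variant_table(integer(), character(), character())
  poly <- cfg$polymorphisms
  if (!is.null(poly) && nrow(poly)) {
    cov <- pmax(depth[poly$position], 1L)
    cnt <- stats::rbinom(nrow(poly), cov, poly$frequency)
    refb <- substring(refseq, poly$position, poly$position)
    alt <- toupper(poly$alt)
    # a configured alt that collides with the reference base falls back
    # to the transition partner
    alt <- ifelse(alt == refb, .TRANSITION_OF[refb], alt)
    pv <- variant_table(poly$position, refb, alt, fixed = FALSE,
                        count = cnt, coverage = cov,
                        forward_fraction = poly$forward_fraction)
    fixed <- rbind(fixed, pv)
  }
  list(depth = as.integer(depth), clips = clips, variants = fixed)
}

#' Write a full simulation bundle to disk
#'
#' Emits the pipeline's native formats: reference FASTA + GFF3, isolate
#' FASTA, variant VCF, depth TSV, clip TSV and a ground-truth JSON.
#'
#' @param dir Output directory (created if needed).
#' @param reference,isolate `annotated_genome`s.
#' @param truth Ground truth from [evolve_isolate()].
#' @param mapping Output of [gen_mapping_outputs()].
#' @return Named character vector of the files written.
#' @export
write_simulation_bundle <- function(dir, reference, isolate, truth,
                                    mapping) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(reference_fasta = file.path(dir, "reference.fasta"),
             reference_gff = file.path(dir, "reference.gff3"),
             isolate_fasta = file.path(dir, "isolate.fasta"),
             variants_vcf = file.path(dir, "variants.vcf"),
             depth_tsv = file.path(dir, "depth.tsv"),
             clips_tsv = file.path(dir, "clips.tsv"),
             truth_json = file.path(dir, "truth.json"))
  write_annotated_genome(reference, paths["reference_fasta"],
                         paths["reference_gff"])
  write_fasta(stats::setNames(isolate$sequence, isolate$name),
              paths["isolate_fasta"])
  write_vcf(mapping$variants, paths["variants_vcf"],
            chrom = reference$name)
  write_depth_tsv(mapping$depth, paths["depth_tsv"])
  write_clip_tsv(mapping$clips, paths["clips_tsv"])
  jsonlite::write_json(truth[c("variants", "deletions", "per_orf")],
                       paths["truth_json"], dataframe = "rows",
                       digits = NA, na = "null")
  paths
}
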