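# Counting estimators of dN/dS and dI/dS. Observed fixed substitutions
# (numerators) are contrasted with TTR-weighted possible-site totals
# (denominators): dN = n_obs/N_poss, dS = s_obs/S_poss,
# dI = i_obs/I_poss. dN/dS < 1 indicates purifying selection, > 1
# directional selection; dI/dS uses coding-region dS as the neutral
# baseline for intergenic change.

#' Observed fixed substitution counts
#'
#' @param n_obs,s_obs,i_obs Non-negative integers: fixed nonsynonymous,
#'   synonymous and intergenic substitutions. Polymorphic variants must
#'   be excluded upstream.
#' @return An `observed_counts` object.
#' @export
observed_counts <- function(n_obs = 0L, s_obs = 0L, i_obs = 0L) {
  stopifnot(n_obs >= 0, s_obs >= 0, i_obs >= 0)
  structure(list(n_obs = as.integer(n_obs), s_obs = as.integer(s_obs),
                 i_obs = as.integer(i_obs)), class = "observed_counts")
}

#' Tally observed counts from classified effects
#'
#' Counts fixed substitution events from an effect table: one event per
#' classified codon (SNPs contribute one, an MNP one per affected
#' codon), intergenic SNP/MNP events counted per variant. Indels and
#' polymorphic variants are excluded.
#'
#' @param effects Output of [classify_variants()].
#' @param orf_id Restrict to one ORF (default `NULL`: genome-wide).
#' @return An `observed_counts` object.
#' @export
observed_from_effects <- function(effects, orf_id = NULL) {
  eff <- effects[effects$fixed & effects$effect != "indel", , drop = FALSE]
  if (!is.null(orf_id)) {
    eff <- eff[!is.na(eff$orf_id) & eff$orf_id == orf_id, , drop = FALSE]
    return(observed_counts(n_obs = sum(eff$effect == "nonsynonymous"),
                           s_obs = sum(eff$effect == "synonymous"),
                           i_obs = 0L))
  }
  coding <- eff[!is.na(eff$orf_id), , drop = FALSE]
  # genome-wide: count each (variant, codon) event once even when the
  # variant lies in several overlapping ORFs; nonsynonymous wins.
  if (nrow(coding)) {
    key <- paste(coding$variant_id, coding$codon_index)
    ord <- order(key, coding$effect != "nonsynonymous")
    coding <- coding[ord, , drop = FALSE]
    coding <- coding[!duplicated(paste(coding$variant_id,
                                       coding$codon_index)), , drop = FALSE]
  }
  inter <- eff[is.na(eff$orf_id) & eff$effect == "intergenic", , drop = FALSE]
  observed_counts(n_obs = sum(coding$effect == "nonsynonymous"),
                  s_obs = sum(coding$effect == "synonymous"),
                  i_obs = length(unique(inter$variant_id)))
}

#' dN/dS from observed counts and possible sites
#'
#' @param obs An [observed_counts()] (requires `s_obs > 0`; for genes
#'   without synonymous substitutions use [gene_dnds()]).
#' @param sites A `site_counts` object from the matching scope and TTR.
#' @return The ratio (n_obs/n_poss)/(s_obs/s_poss).
#' @export
dnds <- function(obs, sites) {
  if (sites$n_poss <= 0 || sites$s_poss <= 0) stop("zero possible sites")
  if (obs$s_obs == 0L) {
    stop("no observed synonymous substitutions; use gene_dnds() for the ",
         "genome-calibrated fallback")
  }
  (obs$n_obs / sites$n_poss) / (obs$s_obs / sites$s_poss)
}

#' dI/dS from observed counts and possible sites
#'
#' @inheritParams dnds
#' @return The ratio (i_obs/i_poss)/(s_obs/s_poss).
#' @export
dids <- function(obs, sites) {
  if (sites$i_poss <= 0 || sites$s_poss <= 0) stop("zero possible sites")
  if (obs$s_obs == 0L) stop("no observed synonymous substitutions")
  (obs$i_obs / sites$i_poss) / (obs$s_obs / sites$s_poss)
}

#' Per-gene dN/dS with a zero-synonymous fallback
#'
#' Genes with nonsynonymous but no synonymous substitutions have an
#' undefined dS; it is approximated from the genome-wide occurrence of
#' synonymous substitutions scaled to the gene: by the gene's share of
#' possible synonymous sites (default) or literally by its share of
#' coding length (`fallback = "length"`; differs from the default only
#' through codon usage).
#'
#' @param obs [observed_counts()] for the gene.
#' @param gene_sites `site_counts` for the gene's CDS at the chosen TTR.
#' @param genome_obs [observed_counts()] genome-wide.
#' @param genome_sites `site_counts` genome-wide, same TTR.
#' @param fallback `"sites"` or `"length"`.
#' @return List: `dn`, `ds`, `dnds`, `s_approximated`, `expected_s`.
#' @export
gene_dnds <- function(obs, gene_sites, genome_obs, genome_sites,
                      fallback = c("sites", "length")) {
  fallback <- match.arg(fallback)
  if (gene_sites$n_poss <= 0 || gene_sites$s_poss <= 0) {
    stop("zero possible sites in gene")
  }
  if (obs$n_obs + obs$s_obs == 0L) {
    stop("gene has no observed substitutions; dN/dS undefined")
  }
  if (obs$s_obs > 0L) {
    s_eff <- obs$s_obs
    approx <- FALSE
  } else {
    share <- if (fallback == "sites") {
      gene_sites$s_poss / genome_sites$s_poss
    } else {
      (gene_sites$n_poss + gene_sites$s_poss) /
        (genome_sites$n_poss + genome_sites$s_poss)
    }
    s_eff <- genome_obs$s_obs * share
    if (s_eff <= 0) stop("fallback expected synonymous count is zero")
    approx <- TRUE
  }
  dn <- obs$n_obs / gene_sites$n_poss
  ds <- s_eff / gene_sites$s_poss
  list(dn = dn, ds = ds, dnds = dn / ds, s_approximated = approx,
       expected_s = if (approx) s_eff else NA_real_)
}

#' Genome-wide and per-gene selection scan
#'
#' Runs the dN/dS (and genome-wide dI/dS) analysis across a set of
#' assumed transition:transversion ratios.
#'
#' @param effects Effect table of fixed variants
#'   ([classify_variants()]).
#' @param genome The annotated reference genome.
#' @param kappas TTR values to scan (default `c(1, 3, 5)`).
#' @param overlap Overlap policy for genome-wide site totals (see
#'   [genome_site_counts()]).
#' @param fallback Zero-synonymous fallback mode (see [gene_dnds()]).
#' @return `data.frame` with one row per scope (`"genome"` or ORF id)
#'   and TTR: observed counts, possible sites, `dn`, `ds`, `dnds`,
#'   `dids` (genome rows only), `s_approximated`. Genes with no
#'   observed substitutions are omitted (dN/dS undefined, "no data").
#' @export
selection_scan <- function(effects, genome, kappas = c(1, 3, 5),
                           overlap = c("longest", "per_orf"),
                           fallback = c("sites", "length")) {
  overlap <- match.arg(overlap)
  fallback <- match.arg(fallback)
  genome_obs <- observed_from_effects(effects)
  rows <- list()
  for (kappa in kappas) {
    scheme <- weight_scheme(kappa)
    gsites <- genome_site_counts(genome, scheme, overlap = overlap)
    g_dnds <- if (genome_obs$s_obs > 0L) dnds(genome_obs, gsites) else NA_real_
    g_dids <- if (genome_obs$s_obs > 0L) dids(genome_obs, gsites) else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      scope = "genome", kappa = kappa, n_obs = genome_obs$n_obs,
      s_obs = genome_obs$s_obs, i_obs = genome_obs$i_obs,
      n_poss = gsites$n_poss, s_poss = gsites$s_poss, i_poss = gsites$i_poss,
      dn = genome_obs$n_obs / gsites$n_poss,
      ds = genome_obs$s_obs / gsites$s_poss,
      dnds = g_dnds, dids = g_dids, s_approximated = FALSE)
    for (i in seq_len(nrow(genome$orfs))) {
      oid <- genome$orfs$orf_id[i]
      obs <- observed_from_effects(effects, orf_id = oid)
      if (obs$n_obs + obs$s_obs == 0L) next
      gene_sites <- region_site_counts(extract_cds(genome, genome$orfs[i, ]),
                                       scheme)
      res <- gene_dnds(obs, gene_sites, genome_obs, gsites,
                       fallback = fallback)
      rows[[length(rows) + 1L]] <- data.frame(
        scope = oid, kappa = kappa, n_obs = obs$n_obs, s_obs = obs$s_obs,
        i_obs = 0L, n_poss = gene_sites$n_poss, s_poss = gene_sites$s_poss,
        i_poss = 0, dn = res$dn, ds = res$ds, dnds = res$dnds,
        dids = NA_real_, s_approximated = res$s_approximated)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Report genes whose dN/dS exceeds a threshold at any TTR
#'
#' Reshapes a [selection_scan()] result into a per-gene table with one
#' dN/dS column per TTR (rounded to 3 decimals, the conventional table
#' presentation) and flags genes whose maximum over TTRs exceeds
#' `threshold`.
#'
#' @param scan Output of [selection_scan()].
#' @param threshold Flagging threshold (default 0.95).
#' @param genome Optional `annotated_genome` to add amino-acid lengths.
#' @param flagged_only If `TRUE` (default) only flagged genes are
#'   returned, plus the genome-wide rows.
#' @return `data.frame` in wide per-gene layout.
#' @export
selection_report <- function(scan, threshold = 0.95, genome = NULL,
                             flagged_only = TRUE) {
  if (!nrow(scan)) return(data.frame())
  kappas <- sort(unique(scan$kappa))
  scopes <- unique(scan$scope)
  rows <- lapply(scopes, function(sc) {
    sub <- scan[scan$scope == sc, , drop = FALSE]
    vals <- vapply(kappas, function(k) {
      v <- sub$dnds[sub$kappa == k]
      if (length(v)) v[1L] else NA_real_
    }, numeric(1))
    row <- data.frame(scope = sc, n_obs = sub$n_obs[1L], s_obs = sub$s_obs[1L])
    for (j in seq_along(kappas)) {
      row[[paste0("dnds_ttr", kappas[j])]] <- round(vals[j], 3L)
    }
    row$flagged <- any(vals > threshold, na.rm = TRUE)
    row
  })
  out <- do.call(rbind, rows)
  if (!is.null(genome)) {
    out$aa_length <- genome$orfs$aa_length[match(out$scope,
                                                 genome$orfs$orf_id)]
  }
  if (flagged_only) {
    out <- out[out$scope == "genome" | out$flagged, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Write a selection scan (or report) as TSV
#' @param x Data frame from [selection_scan()] or [selection_report()].
#' @param path Output file.
#' @export
write_selection_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export selection results as JSON
#' @param x Data frame from [selection_scan()].
#' @param path Output file.
#' @export
write_selection_json <- function(x, path) {
  jsonlite::write_json(x, path, dataframe = "rows", digits = NA,
                       na = "null", auto_unbox = TRUE)
  invisible(path)
}
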