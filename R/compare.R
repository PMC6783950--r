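# Pairwise genome comparison metrics and in-silico restriction-profile
# prediction.

#' Pairwise comparison metrics between two isolate genomes
#'
#' Both genomes are expressed in a common reference coordinate frame
#' (variant and large-deletion calls of one against the other, or both
#' against a shared reference). Identity is reported twice: over
#' non-deletion columns only (`identity_pct`) and counting
#' large-deletion columns as differences (`identity_with_dels_pct`).
#' SNP differences are split by coding-effect class.
#'
#' @param a,b `annotated_genome`s being compared.
#' @param effects Effect table ([classify_variants()]) of the SNP/MNP
#'   differences between the pair.
#' @param dels_a,dels_b Lists of `deletion_call`s for each operand
#'   (relative to the common frame).
#' @param large_threshold Deletions larger than this (bp) count as
#'   large (default 100).
#' @return `data.frame` (one row) with `identity_pct`,
#'   `identity_with_dels_pct`, `size_diff_bp`, `large_del_count_diff`,
#'   `syn_snp_diff`, `nonsyn_snp_diff`. All fields are symmetric in
#'   operand order.
#' @export
pairwise_metrics <- function(a, b, effects, dels_a = list(),
                             dels_b = list(), large_threshold = 100L) {
  L <- max(genome_length(a), genome_length(b))
  key <- function(d) sprintf("%d:%d", d$first_missing, d$last_missing)
  large <- function(dels) dels[vapply(dels, function(d)
    d$size > large_threshold, logical(1))]
  la <- large(dels_a); lb <- large(dels_b)
  ka <- vapply(la, key, ""); kb <- vapply(lb, key, "")
  # columns lost to a large deletion in either genome
  del_mask <- logical(L)
  for (d in c(la, lb)) del_mask[d$first_missing:d$last_missing] <- TRUE
  del_cols <- sum(del_mask)
  snp_eff <- effects[effects$var_class %in% c("SNP", "MNP"), , drop = FALSE]
  per_var <- snp_eff[order(snp_eff$variant_id,
                           snp_eff$effect != "nonsynonymous"), ]
  per_var <- per_var[!duplicated(per_var$variant_id), , drop = FALSE]
  syn <- sum(per_var$effect == "synonymous")
  nonsyn <- sum(per_var$effect == "nonsynonymous")
  n_diff_pos <- sum(nchar(per_var$ref))
  non_del <- L - del_cols
  out <- data.frame(
    identity_pct = 100 * (non_del - n_diff_pos) / non_del,
    identity_with_dels_pct = 100 * (L - del_cols - n_diff_pos) / L,
    size_diff_bp = abs(genome_length(a) - genome_length(b)),
    large_del_count_diff = length(setdiff(ka, kb)) +
      length(setdiff(kb, ka)),
    syn_snp_diff = syn, nonsyn_snp_diff = nonsyn)
  stopifnot(out$identity_with_dels_pct <= out$identity_pct + 1e-12)
  out
}

#' Predict a restriction fragment profile
#'
#' Finds all occurrences of the recognition site (including
#' origin-spanning occurrences on circular genomes) and cleaves after
#' `cut_offset` bases within the site (EcoRI G^AATTC: site `GAATTC`,
#' offset 1). The search is on the given strand only; for palindromic
#' sites such as EcoRI's the double-strand search would be redundant.
#'
#' @param genome An `annotated_genome`.
#' @param site Recognition sequence (default `"GAATTC"`).
#' @param cut_offset Cleavage offset within the site (default 1).
#' @return List with `enzyme_site`, `cut_offset`, `cut_positions`
#'   (position after which cleavage occurs) and `fragment_lengths`
#'   (sorted decreasing; sums to genome length).
#' @export
rflp_predict <- function(genome, site = "GAATTC", cut_offset = 1L) {
  if (grepl("[^ACGT]", site)) stop("site must be over ACGT")
  if (cut_offset < 0L || cut_offset > nchar(site)) {
    stop("cut_offset must be within the site")
  }
  s <- genome$sequence
  L <- genome_length(genome)
  w <- nchar(site)
  search_space <- if (genome$circular && w > 1L) {
    paste0(s, substr(s, 1L, w - 1L))
  } else s
  m <- gregexpr(site, search_space, fixed = TRUE)[[1L]]
  starts <- if (m[1L] == -1L) integer() else as.integer(m)
  starts <- starts[starts <= L]
  if (genome$circular) {
    cuts <- ((starts + cut_offset - 1L) %% L)
    cuts[cuts == 0L] <- L
    cuts <- sort(unique(cuts))
    frags <- if (length(cuts) == 0L) L
    else if (length(cuts) == 1L) L
    else c(diff(cuts), L - cuts[length(cuts)] + cuts[1L])
  } else {
    cuts <- starts + cut_offset - 1L
    cuts <- sort(unique(cuts[cuts >= 1L & cuts < L]))
    frags <- diff(c(0L, cuts, L))
  }
  frags <- sort(as.integer(frags), decreasing = TRUE)
  stopifnot(sum(frags) == L)
  list(enzyme_site = site, cut_offset = cut_offset,
       cut_positions = cuts, fragment_lengths = frags)
}
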