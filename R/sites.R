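# Possible-site counting under a transition:transversion-weighted
# single-substitution model. For every codon the nine single-nucleotide
# changes are enumerated; each change is weighted kappa if it is a
# transition (A<->G, C<->T) and 1 if a transversion. Under the default
# per-position normalisation the three weights at each codon position
# are divided by (kappa + 2), so every position contributes exactly one
# site and s + n = 3 per codon. These weighted totals are the
# denominators of dN, dS and dI.

#' Transition:transversion weighting scheme
#'
#' @param kappa Transition:transversion ratio (TTR), positive real.
#'   Typical assumed values are 1, 3 and 5.
#' @param normalization `"per_position"` (each genome position
#'   contributes one site in total; default) or `"raw"` (weights left
#'   unscaled). The choice cancels in dN/dS and dI/dS.
#' @param stop_changes How to count changes that turn a sense codon into
#'   a stop codon: `"nonsynonymous"` (default; they alter the protein)
#'   or `"exclude"` (contribute to neither class).
#' @return A `weight_scheme` object.
#' @export
weight_scheme <- function(kappa = 1,
                          normalization = c("per_position", "raw"),
                          stop_changes = c("nonsynonymous", "exclude")) {
  normalization <- match.arg(normalization)
  stop_changes <- match.arg(stop_changes)
  if (!is.numeric(kappa) || length(kappa) != 1L || kappa <= 0) {
    stop("kappa must be a positive number")
  }
  structure(list(kappa = kappa, normalization = normalization,
                 stop_changes = stop_changes), class = "weight_scheme")
}

.ALL_CODONS <- as.vector(outer(outer(c("A","C","G","T"), c("A","C","G","T"),
                                     paste0), c("A","C","G","T"), paste0))

.STOP_CODONS <- c("TAA", "TAG", "TGA")

# Per-codon, per-position weighted synonymous/nonsynonymous site tables.
# Returns list(S, N): 64 x 3 matrices (rownames = codons); stop-codon
# rows are NA.
.codon_site_tables <- function(scheme) {
  key <- paste(scheme$kappa, scheme$normalization, scheme$stop_changes)
  cache <- get0(".site_table_cache", envir = .virocomp_cache)
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  code <- .genetic_code()
  S <- N <- matrix(NA_real_, nrow = 64L, ncol = 3L,
                   dimnames = list(.ALL_CODONS, NULL))
  div <- if (scheme$normalization == "per_position") scheme$kappa + 2 else 1
  for (codon in .ALL_CODONS) {
    if (codon %in% .STOP_CODONS) next
    chars <- .s2c(codon)
    aa <- code[[codon]]
    for (j in 1:3) {
      s <- n <- 0
      for (b in setdiff(.BASES, chars[j])) {
        mut <- chars
        mut[j] <- b
        mutc <- paste(mut, collapse = "")
        w <- if (.is_transition(chars[j], b)) scheme$kappa else 1
        maa <- code[[mutc]]
        if (maa == "*") {
          if (scheme$stop_changes == "nonsynonymous") n <- n + w
        } else if (maa == aa) {
          s <- s + w
        } else {
          n <- n + w
        }
      }
      S[codon, j] <- s / div
      N[codon, j] <- n / div
    }
  }
  out <- list(S = S, N = N)
  if (is.null(cache)) cache <- list()
  cache[[key]] <- out
  assign(".site_table_cache", cache, envir = .virocomp_cache)
  out
}

.virocomp_cache <- new.env(parent = emptyenv())

#' Weighted possible synonymous/nonsynonymous sites of one codon
#'
#' Enumerates all nine single-nucleotide changes of the codon, weights
#' transitions by `kappa` and transversions by 1, and splits the total
#' into synonymous and nonsynonymous site counts.
#'
#' @param codon 3-letter string over ACGT; must not be a stop codon.
#' @param scheme A [weight_scheme()].
#' @return Named numeric vector `c(s_sites, n_sites)`; under
#'   per-position normalisation `s_sites + n_sites == 3` (when
#'   stop-producing changes are counted as nonsynonymous).
#' @export
codon_site_counts <- function(codon, scheme = weight_scheme()) {
  if (!is.character(codon) || nchar(codon) != 3L || grepl("[^ACGT]", codon)) {
    stop("codon must be a 3-mer over ACGT")
  }
  if (codon %in% .STOP_CODONS) stop("stop codons are excluded from site tallies")
  tabs <- .codon_site_tables(scheme)
  c(s_sites = sum(tabs$S[codon, ]), n_sites = sum(tabs$N[codon, ]))
}

.new_site_counts <- function(n_poss, s_poss, i_poss, codons_counted, scheme) {
  structure(list(n_poss = n_poss, s_poss = s_poss, i_poss = i_poss,
                 codons_counted = codons_counted, scheme = scheme),
            class = "site_counts")
}

#' @export
print.site_counts <- function(x, ...) {
  cat(sprintf(paste0("<site_counts> kappa=%g (%s): N_poss=%.2f S_poss=%.2f ",
                     "I_poss=%.2f over %d codons\n"),
              x$scheme$kappa, x$scheme$normalization,
              x$n_poss, x$s_poss, x$i_poss, x$codons_counted))
  invisible(x)
}

#' Possible-site totals of a coding region
#'
#' Tallies codon usage in a coding sequence and sums the weighted
#' per-codon site counts. The terminal stop codon is excluded; internal
#' stop codons are skipped with a warning.
#'
#' @param cds Coding nucleotide string (length a multiple of 3).
#' @param scheme A [weight_scheme()].
#' @return A `site_counts` object (with `i_poss = 0`).
#' @export
region_site_counts <- function(cds, scheme = weight_scheme()) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("CDS length not a multiple of 3")
  if (n == 0L) return(.new_site_counts(0, 0, 0, 0L, scheme))
  codons <- substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
  k <- length(codons)
  if (codons[k] %in% .STOP_CODONS) codons <- codons[-k]
  internal <- codons %in% .STOP_CODONS
  if (any(internal)) {
    warning(sum(internal), " internal stop codon(s) skipped in site tally")
    codons <- codons[!internal]
  }
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  if (length(codons) == 0L) return(.new_site_counts(0, 0, 0, 0L, scheme))
  tabs <- .codon_site_tables(scheme)
  usage <- table(factor(codons, levels = .ALL_CODONS))
  sS <- rowSums(tabs$S)
  sN <- rowSums(tabs$N)
  keep <- !(.ALL_CODONS %in% .STOP_CODONS)
  u <- as.numeric(usage)[keep]
  .new_site_counts(n_poss = sum(u * sN[keep]),
                   s_poss = sum(u * sS[keep]),
                   i_poss = 0,
                   codons_counted = length(codons), scheme = scheme)
}

#' Possible intergenic sites
#'
#' Every intergenic position admits one transition and two
#' transversions; under per-position normalisation the weighting cancels
#' and each intergenic position contributes exactly one possible site.
#'
#' @param genome An `annotated_genome`.
#' @param scheme A [weight_scheme()].
#' @return Weighted possible intergenic site total (numeric).
#' @export
intergenic_site_counts <- function(genome, scheme = weight_scheme()) {
  n_int <- length(intergenic_positions(genome))
  if (scheme$normalization == "per_position") n_int
  else n_int * (scheme$kappa + 2)
}

# Position ownership for overlapping ORFs: each coding position is
# attributed to the longest ORF containing it (ties: first in
# annotation order after sorting by span).
.orf_owner <- function(genome) {
  L <- genome_length(genome)
  owner <- integer(L)
  o <- genome$orfs
  if (!nrow(o)) return(owner)
  span <- .span_length(o$first, o$last, L)
  for (i in order(span)) {           # longer ORFs overwrite shorter ones
    owner[orf_positions(genome, o[i, ])] <- i
  }
  owner
}

#' Genome-wide possible-site totals
#'
#' Aggregates weighted possible synonymous and nonsynonymous sites over
#' all annotated ORFs, plus possible intergenic sites.
#'
#' @param genome An `annotated_genome`.
#' @param scheme A [weight_scheme()].
#' @param overlap Policy for positions inside two or more overlapping
#'   ORFs: `"longest"` (default; each position counted once, attributed
#'   to the longest containing ORF) or `"per_orf"` (each ORF tallied
#'   independently, overlaps counted twice).
#' @return A `site_counts` object including `i_poss`.
#' @export
genome_site_counts <- function(genome, scheme = weight_scheme(),
                               overlap = c("longest", "per_orf")) {
  overlap <- match.arg(overlap)
  o <- genome$orfs
  if (!nrow(o)) {
    return(.new_site_counts(0, 0, intergenic_site_counts(genome, scheme),
                            0L, scheme))
  }
  tabs <- .codon_site_tables(scheme)
  if (overlap == "per_orf") {
    n_poss <- s_poss <- 0
    codons <- 0L
    for (i in seq_len(nrow(o))) {
      rc <- region_site_counts(extract_cds(genome, o[i, ]), scheme)
      n_poss <- n_poss + rc$n_poss
      s_poss <- s_poss + rc$s_poss
      codons <- codons + rc$codons_counted
    }
  } else {
    owner <- .orf_owner(genome)
    n_poss <- s_poss <- 0
    owned_positions <- 0L
    seq_chars <- .s2c(genome$sequence)
    for (i in seq_len(nrow(o))) {
      pos <- orf_positions(genome, o[i, ])
      chars <- seq_chars[pos]
      if (o$strand[i] == "-") chars <- .complement(chars)
      k <- length(pos) %/% 3L
      codon_of <- rep(seq_len(k), each = 3L)
      codon_str <- vapply(split(chars, codon_of), paste, "", collapse = "")
      # drop terminal stop codon and any internal stops / ambiguous codons
      drop <- codon_str %in% .STOP_CODONS | grepl("N", codon_str, fixed = TRUE)
      if (k > 0L && codon_str[k] %in% .STOP_CODONS) drop[k] <- TRUE
      within <- rep(1:3, times = k)
      ok <- !drop[codon_of] & owner[pos] == i
      if (!any(ok)) next
      ci <- match(codon_str[codon_of[ok]], .ALL_CODONS)
      wj <- within[ok]
      s_poss <- s_poss + sum(tabs$S[cbind(ci, wj)])
      n_poss <- n_poss + sum(tabs$N[cbind(ci, wj)])
      owned_positions <- owned_positions + sum(ok)
    }
    codons <- as.integer(round(owned_positions / 3))
  }
  .new_site_counts(n_poss = n_poss, s_poss = s_poss,
                   i_poss = intergenic_site_counts(genome, scheme),
                   codons_counted = codons, scheme = scheme)
}

#' Per-gene possible-site table
#'
#' @param genome An `annotated_genome`.
#' @param kappas Numeric vector of TTR values.
#' @param ... Passed to [weight_scheme()].
#' @return `data.frame` with columns `region_id`, `kappa`, `codons`,
#'   `s_poss`, `n_poss`, `i_poss`.
#' @export
site_count_table <- function(genome, kappas = c(1, 3, 5), ...) {
  rows <- list()
  for (kappa in kappas) {
    scheme <- weight_scheme(kappa, ...)
    gsc <- genome_site_counts(genome, scheme)
    rows[[length(rows) + 1L]] <- data.frame(
      region_id = "genome", kappa = kappa, codons = gsc$codons_counted,
      s_poss = gsc$s_poss, n_poss = gsc$n_poss, i_poss = gsc$i_poss)
    for (i in seq_len(nrow(genome$orfs))) {
      rc <- region_site_counts(extract_cds(genome, genome$orfs[i, ]), scheme)
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = genome$orfs$orf_id[i], kappa = kappa,
        codons = rc$codons_counted, s_poss = rc$s_poss, n_poss = rc$n_poss,
        i_poss = 0)
    }
  }
  do.call(rbind, rows)
}

#' Write a site-count table as TSV
#' @param tab Output of [site_count_table()].
#' @param path Output file.
#' @export
write_site_counts_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
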