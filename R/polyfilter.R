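# Rule-based curation of within-isolate polymorphic variants. Deep
# read mappings call many low-frequency "heterozygous" variants that
# are artifacts of reads mapping onto repeat regions; the original
# workflow curated these manually. This module is an explicit,
# configurable automation of that triage: a frequency floor, a minimum
# supporting-read count, strand-balance bounds, and repeat-region
# flagging. The rule set is a declared proxy for manual inspection,
# not a reconstruction of it.

#' Variant frequency from read counts
#'
#' @param count Supporting reads.
#' @param coverage Total reads (> 0).
#' @return `count/coverage`, rounded to 4 decimals (the conventional
#'   table precision).
#' @export
variant_frequency <- function(count, coverage) {
  if (any(coverage <= 0)) stop("zero coverage")
  if (any(count < 0 | count > coverage)) stop("need 0 <= count <= coverage")
  round(count / coverage, 4L)
}

#' Is a position inside (or near) an annotated repeat region?
#'
#' @param positions Integer vector of genome positions.
#' @param genome An `annotated_genome`.
#' @param margin Extra bp on each side of every repeat (default 0).
#' @return Logical vector.
#' @export
in_repeat_region <- function(positions, genome, margin = 0L) {
  r <- genome$repeat_regions
  out <- logical(length(positions))
  for (i in seq_len(nrow(r))) {
    out <- out | (positions >= r$first[i] - margin &
                    positions <= r$last[i] + margin)
  }
  out
}

#' Curate polymorphic variants
#'
#' Applies the automated curation rules to each polymorphic variant:
#' frequency at least `min_freq`, supporting reads at least
#' `min_count`, forward-strand fraction within `strand_bounds`, and —
#' when `repeat_policy = "drop"` — not inside a repeat region. Every
#' rule outcome is recorded.
#'
#' @param variants A [variant_table()] data frame with `fixed = FALSE`
#'   rows and populated `count`, `coverage`, `forward_fraction`.
#' @param genome Optional `annotated_genome` used for the repeat rule.
#' @param min_freq Frequency floor (default 0.02).
#' @param strand_bounds Inclusive forward-fraction bounds
#'   (default `c(0.30, 0.70)`).
#' @param min_count Minimum supporting reads (default 10).
#' @param repeat_policy `"flag"` (default; repeat hits noted but kept)
#'   or `"drop"`.
#' @param repeat_margin Margin (bp) around repeats (default 0).
#' @return The input with added columns `frequency`, `in_repeat`,
#'   `keep`, and `reasons` (semicolon-joined `rule:pass|fail` labels).
#' @export
curate_polymorphisms <- function(variants, genome = NULL, min_freq = 0.02,
                                 strand_bounds = c(0.30, 0.70),
                                 min_count = 10L,
                                 repeat_policy = c("flag", "drop"),
                                 repeat_margin = 0L) {
  repeat_policy <- match.arg(repeat_policy)
  if (any(variants$fixed)) stop("curate_polymorphisms expects polymorphic variants")
  v <- variants
  v$frequency <- variant_frequency(v$count, v$coverage)
  v$in_repeat <- if (!is.null(genome)) {
    in_repeat_region(v$position, genome, repeat_margin)
  } else FALSE
  pass_freq <- v$frequency >= min_freq
  pass_count <- v$count >= min_count
  pass_strand <- v$forward_fraction >= strand_bounds[1L] &
    v$forward_fraction <= strand_bounds[2L]
  pass_repeat <- repeat_policy == "flag" | !v$in_repeat
  lab <- function(name, ok) paste0(name, ":", ifelse(ok, "pass", "fail"))
  v$keep <- pass_freq & pass_count & pass_strand & pass_repeat
  v$reasons <- paste(lab("min_freq", pass_freq), lab("min_count", pass_count),
                     lab("strand_balance", pass_strand),
                     lab("repeat", if (repeat_policy == "flag")
                       !v$in_repeat else pass_repeat),
                     sep = ";")
  v
}

#' Format / parse compact mutation labels
#'
#' The compact label dialect writes the reference allele, the position
#' (optionally with thousands separators) and the alternate allele,
#' alleles in lower case: `c35,202t`.
#'
#' @param ref,position,alt Components of the label.
#' @return `format_mutation_label`: character labels.
#' @export
format_mutation_label <- function(ref, position, alt) {
  paste0(tolower(ref), position, tolower(alt))
}

#' @rdname format_mutation_label
#' @param label Labels such as `"c35,202t"`.
#' @return `parse_mutation_label`: data frame with `ref`, `position`,
#'   `alt`.
#' @export
parse_mutation_label <- function(label) {
  m <- regmatches(label, regexec("^([acgt])([0-9,]+)([acgt])$",
                                 tolower(label)))
  bad <- lengths(m) != 4L
  if (any(bad)) stop("unparseable mutation label: ", label[bad][1L])
  data.frame(ref = toupper(vapply(m, `[`, "", 2L)),
             position = as.integer(gsub(",", "", vapply(m, `[`, "", 3L),
                                        fixed = TRUE)),
             alt = toupper(vapply(m, `[`, "", 4L)))
}

#' Summarise kept polymorphisms
#'
#' Builds the conventional within-isolate polymorphism report: mutation
#' label, count/coverage, 4-decimal frequency, forward-strand
#' percentage, containing ORF and amino-acid change (via the effect
#' classifier; `"none"` outside ORFs or for synonymous changes).
#'
#' @param variants Curated [variant_table()] rows to report (typically
#'   the `keep` subset of [curate_polymorphisms()]).
#' @param genome The annotated genome for effect classification.
#' @return `data.frame` with columns `mutation`, `count_coverage`,
#'   `frequency`, `forward_pct`, `orf`, `aa_change`.
#' @export
polymorphism_summary <- function(variants, genome) {
  if (!nrow(variants)) {
    return(data.frame(mutation = character(), count_coverage = character(),
                      frequency = numeric(), forward_pct = character(),
                      orf = character(), aa_change = character()))
  }
  eff <- classify_variants(variants, genome)
  first_eff <- eff[!duplicated(eff$variant_id), , drop = FALSE]
  i <- match(variants$variant_id, first_eff$variant_id)
  data.frame(
    mutation = format_mutation_label(variants$ref, variants$position,
                                     variants$alt),
    count_coverage = paste0(variants$count, "/", variants$coverage),
    frequency = variant_frequency(variants$count, variants$coverage),
    forward_pct = sprintf("%.2f%%", 100 * variants$forward_fraction),
    orf = ifelse(is.na(first_eff$orf_id[i]), "none", first_eff$orf_id[i]),
    aa_change = ifelse(is.na(first_eff$aa_change[i]), "none",
                       first_eff$aa_change[i]))
}
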