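# Small-mutation representation and coding-effect classification.
# Variants are rows of a plain data.frame (one row per called event);
# classification is strand-aware on circular genomes and handles SNPs,
# MNPs (adjacent substituted bases treated as one event per affected
# codon) and short indels (< 100 bp, tallied separately from the
# substitution classes).

#' Infer the variant class from its alleles
#'
#' @param ref,alt Allele strings.
#' @return `"SNP"`, `"MNP"` or `"short_indel"`.
#' @export
variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  cls <- character(length(lr))
  same <- lr == la
  cls[same & lr == 1L] <- "SNP"
  cls[same & lr > 1L] <- "MNP"
  diff <- abs(lr - la)
  indel <- !same
  if (any(indel & (diff < 1L | diff > 99L))) {
    stop("indel length difference must be 1-99 bp (short indels); ",
         "larger events are deletion calls, not variant records")
  }
  cls[indel] <- "short_indel"
  if (any(same & lr == 1L & ref == alt)) stop("SNP alleles must differ")
  cls
}

#' Build a variant table
#'
#' @param position 1-based genome position of the first affected base.
#' @param ref,alt Reference and alternate allele strings (ACGT).
#' @param fixed Logical: fixed (consensus-level) vs polymorphic.
#' @param count,coverage Supporting / total read counts (optional).
#' @param forward_fraction Fraction of supporting reads mapped to the
#'   forward strand (optional).
#' @return `data.frame` with one row per variant, including a
#'   `variant_id` key and the inferred `var_class`.
#' @export
variant_table <- function(position, ref, alt, fixed = TRUE,
                          count = NA_integer_, coverage = NA_integer_,
                          forward_fraction = NA_real_) {
  n <- length(position)
  ref <- toupper(ref); alt <- toupper(alt)
  if (any(grepl("[^ACGT]", c(ref, alt)))) stop("alleles must be over ACGT")
  df <- data.frame(position = as.integer(position), ref = ref, alt = alt,
                   var_class = variant_class(ref, alt),
                   fixed = rep_len(fixed, n),
                   count = rep_len(as.integer(count), n),
                   coverage = rep_len(as.integer(coverage), n),
                   forward_fraction = rep_len(forward_fraction, n))
  if (any(!is.na(df$count) & !is.na(df$coverage) & df$count > df$coverage)) {
    stop("count exceeds coverage")
  }
  df$variant_id <- sprintf("%d%s>%s", df$position, df$ref, df$alt)
  df
}

# Per-position coding maps: owner ORF index (0 = intergenic), coding
# index within that ORF, plus a list of additional (orf, index) pairs
# for positions covered by several overlapping ORFs.
.coding_maps <- function(genome) {
  L <- genome_length(genome)
  owner <- integer(L)
  index <- integer(L)
  extra <- list()
  o <- genome$orfs
  for (i in seq_len(nrow(o))) {
    pos <- orf_positions(genome, o[i, ])
    idx <- seq_along(pos)
    taken <- owner[pos] != 0L
    if (any(taken)) {
      for (j in which(taken)) {
        key <- as.character(pos[j])
        extra[[key]] <- rbind(extra[[key]], c(i, idx[j]))
      }
    }
    owner[pos[!taken]] <- i
    index[pos[!taken]] <- idx[!taken]
  }
  list(owner = owner, index = index, extra = extra)
}

.orf_hits <- function(maps, p) {
  hits <- NULL
  if (maps$owner[p] != 0L) hits <- rbind(hits, c(maps$owner[p], maps$index[p]))
  ex <- maps$extra[[as.character(p)]]
  if (!is.null(ex)) hits <- rbind(hits, ex)
  hits
}

#' Classify the coding effect of variants
#'
#' SNPs and MNPs inside an ORF are applied to their codon(s) in the
#' coding frame (minus-strand ORFs complement the alleles), translated,
#' and compared with the reference codon. An MNP is classified jointly
#' per affected codon: the fully mutated codon is compared against the
#' reference codon and counted as one substitution event for that codon.
#' Variants inside several overlapping ORFs are reported against each
#' containing ORF. Short indels are labelled `indel` and carried through
#' without amino-acid interpretation.
#'
#' @param variants A [variant_table()] data frame.
#' @param genome An `annotated_genome`; `ref` alleles must match the
#'   genome sequence at their positions (strict check).
#' @param decompose_mnp If `TRUE`, MNPs are decomposed into their
#'   constituent SNPs and each classified separately.
#' @param mask_regions Optional `data.frame` with `first`,`last`
#'   columns; variants whose affected positions intersect a masked
#'   interval (e.g. large-deletion flanks) are dropped.
#' @return `data.frame` of effect records: one row per (variant,
#'   containing ORF, affected codon), or a single row with `orf_id = NA`
#'   for intergenic/indel events. Columns: `variant_id`, `position`,
#'   `ref`, `alt`, `var_class`, `fixed`, `effect`, `orf_id`,
#'   `codon_index`, `aa_change`.
#' @export
classify_variants <- function(variants, genome, decompose_mnp = FALSE,
                              mask_regions = NULL) {
  L <- genome_length(genome)
  seq_chars <- .s2c(genome$sequence)
  if (!is.null(mask_regions) && nrow(mask_regions)) {
    masked <- logical(L)
    for (i in seq_len(nrow(mask_regions))) {
      masked[mask_regions$first[i]:mask_regions$last[i]] <- TRUE
    }
    span_end <- variants$position + nchar(variants$ref) - 1L
    hit <- mapply(function(a, b) any(masked[a:b]), variants$position,
                  pmin(span_end, L))
    variants <- variants[!hit, , drop = FALSE]
  }
  maps <- .coding_maps(genome)
  code <- .genetic_code()
  o <- genome$orfs
  rows <- vector("list", nrow(variants) * 2L)
  nr <- 0L
  add <- function(v, effect, orf_id = NA_character_,
                  codon_index = NA_integer_, aa_change = "none") {
    nr <<- nr + 1L
    rows[[nr]] <<- data.frame(variant_id = v$variant_id,
                              position = v$position, ref = v$ref,
                              alt = v$alt, var_class = v$var_class,
                              fixed = v$fixed, effect = effect,
                              orf_id = orf_id, codon_index = codon_index,
                              aa_change = aa_change)
  }
  if (nrow(variants) && isTRUE(decompose_mnp)) {
    mnp <- variants$var_class == "MNP"
    if (any(mnp)) {
      dec <- do.call(rbind, lapply(which(mnp), function(i) {
        v <- variants[i, ]
        k <- nchar(v$ref)
        variant_table(v$position + 0:(k - 1L),
                      substring(v$ref, 1:k, 1:k),
                      substring(v$alt, 1:k, 1:k),
                      fixed = v$fixed, count = v$count,
                      coverage = v$coverage,
                      forward_fraction = v$forward_fraction)
      }))
      dec <- dec[dec$ref != dec$alt, , drop = FALSE]
      variants <- rbind(variants[!mnp, , drop = FALSE], dec)
    }
  }
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    span <- v$position:(v$position + nchar(v$ref) - 1L)
    if (any(span > L) || v$position < 1L) stop("variant position out of range")
    obs <- paste(seq_chars[span], collapse = "")
    if (obs != v$ref) {
      stop(sprintf("reference mismatch at %d: genome has %s, variant ref %s",
                   v$position, obs, v$ref))
    }
    if (v$var_class == "short_indel") {
      hits <- .orf_hits(maps, v$position)
      if (is.null(hits)) add(v, "indel")
      else for (r in seq_len(nrow(hits))) {
        add(v, "indel", orf_id = o$orf_id[hits[r, 1L]])
      }
      next
    }
    alt_chars <- .s2c(v$alt)
    ref_chars <- .s2c(v$ref)
    changed <- span[ref_chars != alt_chars]
    alt_of <- stats::setNames(alt_chars[ref_chars != alt_chars],
                              as.character(changed))
    per_orf <- list()  # orf index -> changed positions inside it
    intergenic_hit <- FALSE
    for (p in changed) {
      hits <- .orf_hits(maps, p)
      if (is.null(hits)) { intergenic_hit <- TRUE; next }
      for (r in seq_len(nrow(hits))) {
        key <- as.character(hits[r, 1L])
        per_orf[[key]] <- rbind(per_orf[[key]], c(p, hits[r, 2L]))
      }
    }
    if (intergenic_hit && length(per_orf) == 0L) add(v, "intergenic")
    for (key in names(per_orf)) {
      oi <- as.integer(key)
      orf <- o[oi, ]
      hit <- per_orf[[key]]
      codon_idx <- unique((hit[, 2L] - 1L) %/% 3L + 1L)
      opos <- orf_positions(genome, orf)
      for (ci in sort(codon_idx)) {
        cpos <- opos[(3L * (ci - 1L) + 1L):(3L * ci)]
        ref_cod <- seq_chars[cpos]
        alt_cod <- ref_cod
        for (j in 1:3) {
          a <- alt_of[as.character(cpos[j])]
          if (!is.na(a)) alt_cod[j] <- a
        }
        if (orf$strand == "-") {
          ref_cod <- .complement(ref_cod)
          alt_cod <- .complement(alt_cod)
        }
        ref_aa <- code[[paste(ref_cod, collapse = "")]]
        alt_aa <- code[[paste(alt_cod, collapse = "")]]
        if (ref_aa == alt_aa) {
          add(v, "synonymous", orf_id = orf$orf_id, codon_index = ci)
        } else {
          add(v, "nonsynonymous", orf_id = orf$orf_id, codon_index = ci,
              aa_change = paste0(ref_aa, ci, alt_aa))
        }
      }
    }
  }
  if (nr == 0L) {
    return(data.frame(variant_id = character(), position = integer(),
                      ref = character(), alt = character(),
                      var_class = character(), fixed = logical(),
                      effect = character(), orf_id = character(),
                      codon_index = integer(), aa_change = character()))
  }
  out <- do.call(rbind, rows[seq_len(nr)])
  rownames(out) <- NULL
  out
}

#' Partition fixed variants into shared and unique sets
#'
#' Two isolates called against the same reference: a variant is shared
#' when the identical (position, ref, alt) triple occurs in both sets,
#' otherwise it is unique to its isolate. The three output sets are
#' disjoint and cover the input union (asserted).
#'
#' @param set_a,set_b [variant_table()] data frames of fixed variants.
#' @return List with elements `shared`, `unique_a`, `unique_b`.
#' @export
partition_variants <- function(set_a, set_b) {
  if (any(!set_a$fixed) || any(!set_b$fixed)) {
    stop("partition_variants admits fixed variants only")
  }
  key <- function(x) paste(x$position, x$ref, x$alt, sep = ":")
  ka <- key(set_a); kb <- key(set_b)
  out <- list(shared = set_a[ka %in% kb, , drop = FALSE],
              unique_a = set_a[!(ka %in% kb), , drop = FALSE],
              unique_b = set_b[!(kb %in% ka), , drop = FALSE])
  ks <- key(out$shared); kua <- key(out$unique_a); kub <- key(out$unique_b)
  stopifnot(!anyDuplicated(c(ks, kua)), !anyDuplicated(c(ks, kub)),
            setequal(c(ks, kua, kub), union(ka, kb)))
  out
}

#' Tally SNP/MNP events per ORF
#'
#' Each variant event is counted once per containing ORF (an MNP that
#' spans two codons of an ORF still counts once); intergenic events are
#' reported in a separate `intergenic` bucket.
#'
#' @param effects Output of [classify_variants()].
#' @return `data.frame` with columns `orf_id` and `snps`.
#' @export
tally_per_orf <- function(effects) {
  eff <- effects[effects$var_class %in% c("SNP", "MNP"), , drop = FALSE]
  if (!nrow(eff)) return(data.frame(orf_id = character(), snps = integer()))
  bucket <- ifelse(is.na(eff$orf_id), "intergenic", eff$orf_id)
  u <- unique(data.frame(variant_id = eff$variant_id, bucket = bucket))
  tab <- table(u$bucket)
  data.frame(orf_id = names(tab), snps = as.integer(tab),
             row.names = NULL)
}

#' Count transitions and transversions among SNPs
#'
#' @param variants A [variant_table()] data frame of SNPs.
#' @return Named integer vector `c(transitions, transversions)`.
#' @export
ts_tv_tally <- function(variants) {
  if (nrow(variants) && any(variants$var_class != "SNP")) {
    stop("ts_tv_tally admits SNPs only")
  }
  if (!nrow(variants)) return(c(transitions = 0L, transversions = 0L))
  ts <- .is_transition(variants$ref, variants$alt)
  c(transitions = sum(ts), transversions = sum(!ts))
}

#' Write an effect table as TSV
#' @param effects Output of [classify_variants()].
#' @param path Output file.
#' @export
write_effect_table <- function(effects, path) {
  utils::write.table(effects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
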