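# Large (>100 bp) deletion mapping. Two evidence routes mirror the two
# sequencing analyses they emulate: (1) resequencing — runs of
# low/zero coverage in a per-position depth profile, with breakpoints
# refined by matching the soft-clipped read consensus at each flank
# against the sequence adjacent to the opposite edge; (2) de novo —
# unique k-mer anchor chaining of a consensus assembly against the
# reference, reporting gaps between collinear anchors. Deletion
# coordinates are 1-based inclusive first/last missing positions.

#' Read / write per-position depth profiles
#'
#' Two-column TSV `position<TAB>depth`, 1-based, one row per reference
#' position.
#'
#' @param path File path.
#' @return Integer vector of depths (length = reference length).
#' @export
read_depth_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("position", "depth") %in% names(d))) {
    stop("depth TSV needs columns position, depth")
  }
  d <- d[order(d$position), ]
  if (!identical(as.integer(d$position), seq_len(nrow(d)))) {
    stop("depth TSV must cover positions 1..L without gaps")
  }
  as.integer(d$depth)
}

#' @rdname read_depth_tsv
#' @param depth Integer vector of per-position depths.
#' @export
write_depth_tsv <- function(depth, path) {
  utils::write.table(data.frame(position = seq_along(depth), depth = depth),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Soft-clip evidence records
#'
#' @param anchor_position 1-based position where the mapped portion of
#'   the clipped reads ends (left flank) or starts (right flank).
#' @param side `"left_flank"` or `"right_flank"`.
#' @param consensus Consensus of the non-mapping read portions.
#' @return `data.frame` of clip evidence.
#' @export
clip_evidence <- function(anchor_position, side, consensus) {
  stopifnot(all(side %in% c("left_flank", "right_flank")))
  data.frame(anchor_position = as.integer(anchor_position), side = side,
             consensus = toupper(consensus))
}

#' @rdname clip_evidence
#' @param path File path (TSV with the three columns).
#' @export
read_clip_tsv <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         colClasses = c("integer", "character", "character"))
  clip_evidence(d$anchor_position, d$side, d$consensus)
}

#' @rdname clip_evidence
#' @param clips Clip evidence data frame.
#' @export
write_clip_tsv <- function(clips, path) {
  utils::write.table(clips, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Scan a depth profile for low-coverage runs
#'
#' Maximal runs of positions with depth below `threshold` and length at
#' least `min_run`; on circular genomes a run spanning the origin is
#' merged into one wrapped region.
#'
#' @param depth Integer vector of per-position depths.
#' @param threshold Depth below which a position is "low" (default 10).
#' @param min_run Minimum run length to report (default 20, suppressing
#'   isolated dropouts).
#' @param circular Merge runs across the origin (default `TRUE`).
#' @return `data.frame` with columns `first`, `last`, `length`; sorted,
#'   disjoint, maximal. A wrapped run has `first > last`.
#' @export
scan_low_coverage <- function(depth, threshold = 10L, min_run = 20L,
                              circular = TRUE) {
  L <- length(depth)
  low <- depth < threshold
  empty <- data.frame(first = integer(), last = integer(), length = integer())
  if (!any(low)) return(empty)
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(first = starts[r$values], last = ends[r$values])
  runs$length <- runs$last - runs$first + 1L
  wrapped <- FALSE
  if (circular && nrow(runs) > 1L &&
      runs$first[1L] == 1L && runs$last[nrow(runs)] == L) {
    n <- nrow(runs)
    merged <- data.frame(first = runs$first[n], last = runs$last[1L])
    merged$length <- runs$length[n] + runs$length[1L]
    runs <- rbind(runs[-c(1L, n), ], merged)
    wrapped <- TRUE
  } else if (circular && nrow(runs) == 1L && runs$length[1L] == L) {
    # fully uncovered genome
  }
  runs <- runs[runs$length >= min_run, , drop = FALSE]
  ord <- order(ifelse(runs$first > runs$last, runs$first, runs$first))
  runs <- runs[ord, , drop = FALSE]
  rownames(runs) <- NULL
  runs
}

#' Deletion size from first/last missing positions
#'
#' @param first_missing,last_missing 1-based inclusive coordinates of
#'   the first and last missing nucleotide.
#' @return Integer size `last - first + 1`.
#' @export
deletion_length <- function(first_missing, last_missing) {
  if (any(last_missing < first_missing)) {
    stop("inverted coordinates: last_missing < first_missing")
  }
  as.integer(last_missing - first_missing + 1L)
}

.new_deletion_call <- function(first, last, evidence, insert = "") {
  structure(list(first_missing = as.integer(first),
                 last_missing = as.integer(last),
                 size = deletion_length(first, last),
                 evidence = evidence, inserted_sequence = insert),
            class = "deletion_call")
}

#' @export
print.deletion_call <- function(x, ...) {
  cat(sprintf("<deletion_call> %d-%d (%d bp, %s)%s\n", x$first_missing,
              x$last_missing, x$size, x$evidence,
              if (nzchar(x$inserted_sequence))
                paste0(", ", nchar(x$inserted_sequence), " bp insert")
              else ""))
  invisible(x)
}

# exact seed match positions of `seed` within reference window
# [from, to]; returns genome positions of match starts.
.seed_matches <- function(refseq, seed, from, to) {
  from <- max(1L, from)
  to <- min(nchar(refseq), to)
  if (to - from + 1L < nchar(seed)) return(integer())
  window <- substr(refseq, from, to)
  m <- gregexpr(seed, window, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) return(integer())
  as.integer(m) + from - 1L
}

# verify an ungapped extension of the clip consensus beyond the seed,
# tolerating 1 mismatch per 50 nt
.extension_ok <- function(refseq, ref_start, query, q_start, direction = 1L) {
  n <- 0L
  mism <- 0L
  i <- ref_start
  j <- q_start
  Lr <- nchar(refseq)
  Lq <- nchar(query)
  while (i >= 1L && i <= Lr && j >= 1L && j <= Lq) {
    if (substr(refseq, i, i) != substr(query, j, j)) mism <- mism + 1L
    n <- n + 1L
    i <- i + direction
    j <- j + direction
  }
  n == 0L || mism <= max(1L, n %/% 50L)
}

#' Refine deletion breakpoints from clipped-read consensus
#'
#' For a low-coverage candidate region, the clipped (non-mapping)
#' portion of reads at each flank is matched exactly against the
#' reference sequence adjacent to the opposite edge: a left-flank clip
#' whose consensus matches just after the deletion pins the last
#' missing position (its anchor pins the first), and symmetrically for
#' a right-flank clip. A clipped prefix that does not map is recorded
#' as a novel inserted sequence at the junction. Without usable clips
#' the candidate bounds are returned as `coverage_only`.
#'
#' @param candidate One row from [scan_low_coverage()] (or a list with
#'   `first`, `last`).
#' @param clips [clip_evidence()] data frame.
#' @param reference The reference `annotated_genome`.
#' @param search_window Reference window (bp) beyond the opposite edge
#'   searched for the clip seed (default 2000).
#' @param seed_length Exact-match seed length (default 15).
#' @param anchor_tolerance Max distance (bp) between a clip's anchor and
#'   the candidate edge for the clip to be considered (default 150,
#'   about one read length).
#' @param junction_tolerance Max disagreement (bp) between
#'   left- and right-derived junctions before an ambiguity error
#'   (default 5).
#' @return A `deletion_call`.
#' @export
refine_breakpoints <- function(candidate, clips, reference,
                               search_window = 2000L, seed_length = 15L,
                               anchor_tolerance = 150L,
                               junction_tolerance = 5L) {
  refseq <- reference$sequence
  cand_first <- candidate$first
  cand_last <- candidate$last
  left_call <- right_call <- NULL
  if (!is.null(clips) && nrow(clips)) {
    lefts <- clips[clips$side == "left_flank" &
                     abs(clips$anchor_position - cand_first) <=
                       anchor_tolerance, , drop = FALSE]
    rights <- clips[clips$side == "right_flank" &
                      abs(clips$anchor_position - cand_last) <=
                        anchor_tolerance, , drop = FALSE]
    for (i in seq_len(nrow(lefts))) {
      cons <- lefts$consensus[i]
      anchor <- lefts$anchor_position[i]
      nmax <- nchar(cons) - seed_length
      if (nmax < 0L) next
      for (k in 0:nmax) {
        seed <- substr(cons, k + 1L, k + seed_length)
        hits <- .seed_matches(refseq, seed, cand_last - junction_tolerance,
                              cand_last + search_window)
        hits <- hits[hits > anchor]
        if (length(hits)) {
          hit <- hits[1L]
          if (!.extension_ok(refseq, hit + seed_length, cons,
                             k + seed_length + 1L)) next
          left_call <- list(first = anchor + 1L, last = hit - 1L,
                            insert = substr(cons, 1L, k))
          break
        }
      }
      if (!is.null(left_call)) break
    }
    for (i in seq_len(nrow(rights))) {
      cons <- rights$consensus[i]
      anchor <- rights$anchor_position[i]
      nc <- nchar(cons)
      nmax <- nc - seed_length
      if (nmax < 0L) next
      for (k in 0:nmax) {
        seed <- substr(cons, nc - k - seed_length + 1L, nc - k)
        hits <- .seed_matches(refseq, seed,
                              cand_first - search_window,
                              cand_first + junction_tolerance +
                                seed_length - 1L)
        hits <- hits[hits + seed_length - 1L < anchor]
        if (length(hits)) {
          hit <- hits[length(hits)]
          if (!.extension_ok(refseq, hit - 1L, cons,
                             nc - k - seed_length, direction = -1L)) next
          right_call <- list(first = hit + seed_length,
                             last = anchor - 1L,
                             insert = if (k > 0L)
                               substr(cons, nc - k + 1L, nc) else "")
          break
        }
      }
      if (!is.null(right_call)) break
    }
  }
  if (is.null(left_call) && is.null(right_call)) {
    return(.new_deletion_call(cand_first, cand_last, "coverage_only"))
  }
  if (!is.null(left_call) && !is.null(right_call)) {
    if (abs(left_call$first - right_call$first) > junction_tolerance ||
        abs(left_call$last - right_call$last) > junction_tolerance) {
      stop(sprintf(paste0("contradictory clip evidence: left junction ",
                          "%d-%d vs right junction %d-%d"),
                   left_call$first, left_call$last, right_call$first,
                   right_call$last))
    }
    insert <- if (nzchar(left_call$insert)) left_call$insert
              else right_call$insert
    return(.new_deletion_call(left_call$first, left_call$last,
                              "clip_confirmed", insert))
  }
  call <- if (!is.null(left_call)) left_call else right_call
  .new_deletion_call(call$first, call$last, "clip_confirmed", call$insert)
}

#' Detect large indels by unique k-mer anchor chaining
#'
#' Aligns a consensus assembly (`query`) against the reference by
#' anchoring k-mers that occur exactly once in each sequence, selecting
#' the longest collinear anchor chain, and reporting the coordinate gap
#' between adjacent anchors wherever the reference advances at least
#' `min_size` bp more than the query (a deletion in the query) or vice
#' versa (an insertion). Breakpoints are refined by exact forward and
#' backward extension from the bounding anchors. Circular queries are
#' rotated into the reference frame first.
#'
#' @param query,reference `annotated_genome`s (low divergence assumed).
#' @param k Anchor k-mer length (default 31).
#' @param min_size Minimum indel size to report (default 100; the
#'   conventional "large" threshold is > 100 bp).
#' @return List of `deletion_call`s (evidence `"alignment_gap"`);
#'   insertions are returned with `size = 0` spans encoded in
#'   `inserted_sequence` and `first_missing = last_missing + 1`
#'   convention avoided — instead each element carries a `type`
#'   attribute `"deletion"` or `"insertion"`.
#' @export
alignment_gap_indels <- function(query, reference, k = 31L,
                                 min_size = 100L) {
  rseq <- reference$sequence
  qseq0 <- query$sequence
  anchors0 <- .unique_kmer_anchors(qseq0, rseq, k)
  if (query$circular) {
    # rotate query so that its first shared anchor aligns with the
    # reference frame
    if (nrow(anchors0) == 0L) stop("no collinear anchor chain found")
    a0 <- anchors0[which.min(anchors0$rpos), ]
    Lq <- nchar(qseq0)
    shift <- (a0$qpos - a0$rpos) %% Lq
    if (shift > 0L) {
      qseq <- paste0(substr(qseq0, shift + 1L, Lq),
                     substr(qseq0, 1L, shift))
    } else qseq <- qseq0
  } else qseq <- qseq0
  anchors <- .unique_kmer_anchors(qseq, rseq, k)
  if (nrow(anchors) == 0L) stop("no collinear anchor chain found")
  anchors <- anchors[order(anchors$rpos), ]
  chain_idx <- .lis(anchors$qpos)
  anchors <- anchors[chain_idx, , drop = FALSE]
  # drop short offset-outlier runs flanked by agreeing runs: isolated
  # anchors that pair a repeat copy with the wrong counterpart survive
  # the collinearity filter but betray themselves by their offset
  offs <- anchors$rpos - anchors$qpos
  r <- rle(offs)
  if (length(r$lengths) >= 3L) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- rep(TRUE, nrow(anchors))
    for (j in 2:(length(r$lengths) - 1L)) {
      if (r$lengths[j] <= 2L && r$values[j - 1L] == r$values[j + 1L]) {
        keep[starts[j]:ends[j]] <- FALSE
      }
    }
    anchors <- anchors[keep, , drop = FALSE]
  }
  calls <- list()
  for (i in seq_len(nrow(anchors) - 1L)) {
    r1 <- anchors$rpos[i]; q1 <- anchors$qpos[i]
    r2 <- anchors$rpos[i + 1L]; q2 <- anchors$qpos[i + 1L]
    dr <- r2 - r1; dq <- q2 - q1
    if (abs(dr - dq) < min_size) next
    s0 <- abs(dr - dq)
    deletion <- dr > dq
    # optimal single-junction placement: minimise total mismatches over
    # every possible breakpoint between the bounding anchors (robust to
    # substitutions near the junction)
    if (deletion) {
      best <- .place_gap(rseq, r1 + k, qseq, q1 + k, dq - k, s0)
    } else {
      best <- .place_gap(qseq, q1 + k, rseq, r1 + k, dr - k, s0)
    }
    n_aligned <- if (deletion) dq - k else dr - k
    clean <- best$cost <= max(2L, as.integer(0.15 * n_aligned))
    if (!clean) {
      # a genuine junction insert forces ~0.75 mismatches per inserted
      # base under the pure-gap model; delimit it by tolerant extension
      # and fall back to pure placement when the residual is tiny
      f <- .match_len_tol(rseq, r1 + k, qseq, q1 + k, 1L,
                          max_steps = min(dr, dq) - k)
      b <- .match_len_tol(rseq, r2 - 1L, qseq, q2 - 1L, -1L,
                          max_steps = min(dr, dq) - k - f)
      ins_len <- min(dr, dq) - k - f - b
      if (ins_len < 10L) clean <- TRUE
    }
    if (clean && deletion) {
      first <- r1 + k + best$t
      last <- first + s0 - 1L
      # left-normalise placement through junction homology
      while (first > 1L &&
             substr(rseq, first - 1L, first - 1L) ==
               substr(rseq, last, last)) {
        first <- first - 1L
        last <- last - 1L
      }
      calls[[length(calls) + 1L]] <-
        structure(.new_deletion_call(first, last, "alignment_gap"),
                  type = "deletion")
    } else if (clean) {
      at <- r1 + k + best$t
      ins <- substr(qseq, q1 + k + best$t, q1 + k + best$t + s0 - 1L)
      call <- .new_deletion_call(at, at, "alignment_gap", ins)
      call$size <- 0L
      calls[[length(calls) + 1L]] <- structure(call, type = "insertion")
    } else {
      # replacement event (deletion with a novel junction insert):
      # delimit by tolerant extension from both anchors; the unmatched
      # query remainder is the inserted sequence
      f <- .match_len_tol(rseq, r1 + k, qseq, q1 + k, 1L,
                          max_steps = min(dr, dq) - k)
      b <- .match_len_tol(rseq, r2 - 1L, qseq, q2 - 1L, -1L,
                          max_steps = min(dr, dq) - k - f)
      first <- r1 + k + f
      last <- r2 - b - 1L
      qfirst <- q1 + k + f
      qlast <- q2 - b - 1L
      ins <- if (qlast >= qfirst) substr(qseq, qfirst, qlast) else ""
      dr_gap <- last - first + 1L
      if (dr_gap >= min_size) {
        calls[[length(calls) + 1L]] <-
          structure(.new_deletion_call(first, last, "alignment_gap", ins),
                    type = "deletion")
      } else if (nchar(ins) >= min_size) {
        call <- .new_deletion_call(first, first, "alignment_gap", ins)
        call$size <- 0L
        calls[[length(calls) + 1L]] <- structure(call, type = "insertion")
      }
    }
  }
  calls
}

# Optimal placement of a single gap of size s0 between two anchored
# flanks: `long` carries s0 extra bases relative to `short`. For every
# junction offset t in 0..n_aligned the cost is the number of
# mismatching aligned bases; returns the left-most minimiser.
.place_gap <- function(long, lstart, short, sstart, n_aligned, s0) {
  if (n_aligned <= 0L) return(list(t = 0L, cost = 0L))
  lc <- .s2c(substr(long, lstart, lstart + n_aligned + s0 - 1L))
  sc <- .s2c(substr(short, sstart, sstart + n_aligned - 1L))
  if (length(lc) < n_aligned + s0) {
    pad <- rep("?", n_aligned + s0 - length(lc))
    lc <- c(lc, pad)
  }
  pre <- cumsum(sc != lc[seq_len(n_aligned)])
  post_vec <- sc != lc[seq_len(n_aligned) + s0]
  post <- rev(cumsum(rev(post_vec)))
  cost <- c(post[1L], if (n_aligned > 1L)
    pre[seq_len(n_aligned - 1L)] + post[2:n_aligned] else NULL,
    pre[n_aligned])
  t <- which.min(cost) - 1L
  list(t = as.integer(t), cost = as.integer(cost[t + 1L]))
}

# extension allowing isolated substitutions: a mismatch is absorbed only
# when the next `lookahead` base pairs match exactly (beyond a deletion
# junction the sequences are unrelated, so a chance lookahead pass is
# ~4^-lookahead); returns the extension length trimmed to the last match
.match_len_tol <- function(a, ai, b, bi, direction, max_steps = Inf,
                           lookahead = 8L) {
  n <- 0L
  last_match <- 0L
  La <- nchar(a); Lb <- nchar(b)
  while (n < max_steps && ai >= 1L && ai <= La && bi >= 1L && bi <= Lb) {
    if (substr(a, ai, ai) == substr(b, bi, bi)) {
      last_match <- n + 1L
    } else {
      ok <- TRUE
      for (j in seq_len(lookahead)) {
        aj <- ai + direction * j
        bj <- bi + direction * j
        if (aj < 1L || aj > La || bj < 1L || bj > Lb ||
            substr(a, aj, aj) != substr(b, bj, bj)) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    n <- n + 1L
    ai <- ai + direction
    bi <- bi + direction
  }
  last_match
}

.unique_kmer_anchors <- function(qseq, rseq, k) {
  qk <- substring(qseq, seq_len(nchar(qseq) - k + 1L),
                  seq_len(nchar(qseq) - k + 1L) + k - 1L)
  rk <- substring(rseq, seq_len(nchar(rseq) - k + 1L),
                  seq_len(nchar(rseq) - k + 1L) + k - 1L)
  qu <- !(qk %in% qk[duplicated(qk)])
  ru <- !(rk %in% rk[duplicated(rk)])
  qtab <- stats::setNames(seq_along(qk)[qu], qk[qu])
  keep <- ru & (rk %in% names(qtab))
  data.frame(rpos = seq_along(rk)[keep],
             qpos = as.integer(qtab[rk[keep]]))
}

# longest strictly increasing subsequence; returns indices
.lis <- function(x) {
  n <- length(x)
  if (n == 0L) return(integer())
  tails <- integer(n)   # indices into x of smallest tail per length
  prev <- integer(n)
  len <- 0L
  for (i in seq_len(n)) {
    lo <- 1L; hi <- len
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      if (x[tails[mid]] < x[i]) lo <- mid + 1L else hi <- mid - 1L
    }
    prev[i] <- if (lo > 1L) tails[lo - 1L] else 0L
    tails[lo] <- i
    if (lo > len) len <- lo
  }
  out <- integer(len)
  j <- tails[len]
  for (p in len:1) { out[p] <- j; j <- prev[j] }
  out
}

.match_len <- function(a, ai, b, bi, direction) {
  n <- 0L
  La <- nchar(a); Lb <- nchar(b)
  while (ai >= 1L && ai <= La && bi >= 1L && bi <= Lb &&
         substr(a, ai, ai) == substr(b, bi, bi)) {
    n <- n + 1L
    ai <- ai + direction
    bi <- bi + direction
  }
  n
}

#' Extract large gaps from a pairwise alignment
#'
#' Alternative to anchor chaining when a precomputed aligned FASTA pair
#' is available: gap runs of at least `min_size` in either aligned row
#' are reported in ungapped reference coordinates.
#'
#' @param aln_query,aln_reference Aligned sequences of equal length
#'   (gaps as `-`).
#' @param min_size Minimum gap run to report (default 100).
#' @return List of `deletion_call`s (type attribute as in
#'   [alignment_gap_indels()]).
#' @export
gaps_from_alignment <- function(aln_query, aln_reference, min_size = 100L) {
  if (nchar(aln_query) != nchar(aln_reference)) {
    stop("aligned sequences must have equal length")
  }
  qc <- .s2c(aln_query)
  rc <- .s2c(aln_reference)
  rpos <- cumsum(rc != "-")
  calls <- list()
  r <- rle(qc == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values & r$lengths >= min_size)) {
    first <- rpos[starts[i]]
    last <- rpos[ends[i]]
    calls[[length(calls) + 1L]] <-
      structure(.new_deletion_call(first, last, "alignment_gap"),
                type = "deletion")
  }
  r2 <- rle(rc == "-")
  ends2 <- cumsum(r2$lengths)
  starts2 <- ends2 - r2$lengths + 1L
  for (i in which(r2$values & r2$lengths >= min_size)) {
    ins <- paste(qc[starts2[i]:ends2[i]], collapse = "")
    at <- rpos[max(1L, starts2[i] - 1L)] + 1L
    call <- .new_deletion_call(at, at, "alignment_gap", ins)
    call$size <- 0L
    calls[[length(calls) + 1L]] <- structure(call, type = "insertion")
  }
  calls
}

#' Annotate a deletion call against the reference features
#'
#' Lists each ORF and repeat region fully contained in (deleted) or
#' partially overlapped by (partial deletion) the call.
#'
#' @param call A `deletion_call`.
#' @param genome The annotated reference genome.
#' @return Character string of notes, e.g. `"ORF126 deleted"`.
#' @export
annotate_deletion <- function(call, genome) {
  notes <- character()
  span <- c(call$first_missing, call$last_missing)
  overlap_note <- function(first, last, label) {
    if (first >= span[1L] && last <= span[2L]) {
      paste(label, "deleted")
    } else if (first <= span[2L] && last >= span[1L]) {
      paste(label, "partial deletion")
    } else NA_character_
  }
  o <- genome$orfs
  for (i in seq_len(nrow(o))) {
    lo <- min(o$first[i], o$last[i]); hi <- max(o$first[i], o$last[i])
    n <- overlap_note(lo, hi, o$orf_id[i])
    if (!is.na(n)) notes <- c(notes, n)
  }
  r <- genome$repeat_regions
  for (i in seq_len(nrow(r))) {
    n <- overlap_note(r$first[i], r$last[i], r$label[i])
    if (!is.na(n)) notes <- c(notes, n)
  }
  if (!length(notes)) "intergenic" else paste(notes, collapse = "; ")
}

#' Write deletion calls as a BED-like TSV
#'
#' Emits both coordinate conventions: `bed_start`/`bed_end` (0-based
#' half-open) and `first_missing`/`last_missing` (1-based inclusive).
#'
#' @param calls List of `deletion_call`s.
#' @param path Output file.
#' @param genome Optional annotated genome for the notes column.
#' @export
write_deletions_tsv <- function(calls, path, genome = NULL) {
  rows <- lapply(calls, function(x) {
    data.frame(bed_start = x$first_missing - 1L, bed_end = x$last_missing,
               first_missing = x$first_missing,
               last_missing = x$last_missing, size = x$size,
               evidence = x$evidence,
               inserted_sequence = x$inserted_sequence,
               notes = if (is.null(genome)) "" else
                 annotate_deletion(x, genome))
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(bed_start = integer(), bed_end = integer(),
               first_missing = integer(), last_missing = integer(),
               size = integer(), evidence = character(),
               inserted_sequence = character(), notes = character())
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
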