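# Minimal VCF subset used to interchange variant calls:
# CHROM/POS/REF/ALT plus INFO keys AF (allele frequency), DP (total
# coverage), AC (supporting reads) and FF (forward-strand fraction of
# supporting reads, the strand-bias field). Fixed variants are written
# with AF=1; on reading, a variant is considered fixed when its AF is
# missing or >= `fixed_af`.

#' Write a variant table as VCF (subset)
#'
#' @param variants A [variant_table()] data frame.
#' @param path Output file.
#' @param chrom Reference sequence name (default `"ref"`).
#' @export
write_vcf <- function(variants, path, chrom = "ref") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
               "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total coverage\">",
               "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Supporting reads\">",
               "##INFO=<ID=FF,Number=1,Type=Float,Description=\"Forward fraction of supporting reads\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, ]
    af <- if (v$fixed) 1 else {
      if (!is.na(v$count) && !is.na(v$coverage)) v$count / v$coverage
      else NA_real_
    }
    info <- c(if (!is.na(af)) sprintf("AF=%.6f", af),
              if (!is.na(v$coverage)) sprintf("DP=%d", v$coverage),
              if (!is.na(v$count)) sprintf("AC=%d", v$count),
              if (!is.na(v$forward_fraction))
                sprintf("FF=%.4f", v$forward_fraction))
    if (!length(info)) info <- "."
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", chrom, v$position,
                       v$ref, v$alt, paste(info, collapse = ";")), con)
  }
  invisible(path)
}

#' Read a VCF (subset) into a variant table
#'
#' @param path VCF file.
#' @param fixed_af AF at or above which a variant is treated as fixed
#'   (default 0.95).
#' @return A [variant_table()] data frame; also carries a `chrom`
#'   attribute with the reference name(s) seen.
#' @export
read_vcf <- function(path, fixed_af = 0.95) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(body)]
  if (!length(body)) {
    out <- variant_table(integer(), character(), character())
    attr(out, "chrom") <- character()
    return(out)
  }
  parts <- strsplit(body, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 8L)
  if (length(bad)) {
    stop("malformed VCF line ", which(!startsWith(lines, "#"))[bad[1L]],
         " in ", path)
  }
  m <- do.call(rbind, lapply(parts, `[`, 1:8))
  info_get <- function(info, key) {
    val <- sub(paste0("^(.*;)?", key, "=([^;]+).*$"), "\\2", info)
    ifelse(grepl(paste0("(^|;)", key, "="), info), val, NA)
  }
  af <- as.numeric(info_get(m[, 8L], "AF"))
  dp <- as.integer(info_get(m[, 8L], "DP"))
  ac <- as.integer(info_get(m[, 8L], "AC"))
  ff <- as.numeric(info_get(m[, 8L], "FF"))
  fixed <- is.na(af) | af >= fixed_af
  out <- variant_table(as.integer(m[, 2L]), m[, 4L], m[, 5L],
                       fixed = fixed, count = ac, coverage = dp,
                       forward_fraction = ff)
  attr(out, "chrom") <- unique(m[, 1L])
  out
}
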