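#' Read a GWAS summary-statistics TSV
#'
#' Expects (or maps to) the canonical columns chrom, pos, rsid, ea,
#' nea, beta, se, p, n.  `col_map` renames source columns, e.g.
#' `c(chrom = "CHR", pos = "BP", p = "PVAL")`.
#'
#' @param path File path.
#' @param col_map Optional named character vector mapping canonical
#'   names to the file's column names.
#' @return data.frame with columns chrom, pos, id, ea, nea, beta, se,
#'   p, n.
#' @export
read_sumstats <- function(path, col_map = NULL) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(col_map)) {
    for (canon in names(col_map)) {
      src <- col_map[[canon]]
      if (!src %in% names(x)) stop("column '", src, "' not in file")
      names(x)[names(x) == src] <- canon
    }
  }
  if ("rsid" %in% names(x) && !"id" %in% names(x))
    names(x)[names(x) == "rsid"] <- "id"
  need <- c("chrom", "pos", "id", "ea", "nea", "beta", "se", "p", "n")
  missing <- setdiff(need, names(x))
  if (length(missing))
    stop("missing summary-statistic columns: ",
         paste(missing, collapse = ", "))
  message(sprintf("read %d summary records from %s", nrow(x), path))
  x[need]
}

#' Write a summary-statistics TSV
#'
#' Columns are written as chrom, pos, rsid, ea, nea, beta, se, p, n.
#'
#' @param records Summary table (canonical columns, `id` for rsid).
#' @param path Output path.
#' @export
write_sumstats <- function(records, path) {
  out <- records[, c("chrom", "pos", "id", "ea", "nea", "beta", "se",
                     "p", "n")]
  names(out)[names(out) == "id"] <- "rsid"
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("wrote %d summary records to %s", nrow(out), path))
  invisible(path)
}

#' Write a dosage matrix TSV
#'
#' One row per variant (chrom, pos, id, ref, alt, then one column per
#' sample holding the alt-allele count).
#'
#' @param panel A reference panel.
#' @param path Output path.
#' @export
write_dosage_tsv <- function(panel, path) {
  out <- cbind(panel$variants[, c("chrom", "pos", "id", "ref", "alt")],
               t(panel$dosages))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf("wrote %d variants x %d samples to %s",
                  nrow(out), panel$n_samples, path))
  invisible(path)
}

#' Write a minimal GT-only VCF for a panel
#'
#' Diploid genotypes are written unphased (`0/0`, `0/1`, `1/1`) from
#' the dosage matrix; no INFO or QUAL content.
#'
#' @param panel A reference panel.
#' @param path Output path (uncompressed `.vcf`).
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_code[panel$dosages + 1L], nrow = panel$n_samples)
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", rownames(panel$dosages)), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(v$chrom[i], v$pos[i], v$id[i], v$ref[i], v$alt[i], ".",
            "PASS", ".", "GT", gt[, i]), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  message(sprintf("wrote %d VCF records to %s", nrow(v), path))
  invisible(path)
}

#' Read a GT-only VCF into a panel-like object
#'
#' Parses a VCF (e.g. as written by [write_panel_vcf()]) via
#' \pkg{vcfR} and converts genotypes to alt-allele dosages.
#' Multi-allelic sites are rejected; missing genotypes are not
#' supported.
#'
#' @param path VCF path.
#' @return A `reference_panel`-shaped list (block ids all 1).
#' @export
read_panel_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (any(grepl(",", fix[, "ALT"])))
    stop("multi-allelic sites are not supported")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (anyNA(gt)) stop("missing genotypes are not supported")
  dosages <- t(apply(gt, 1, function(g)
    vapply(strsplit(g, "[/|]"),
           function(a) sum(as.integer(a)), 0L)))
  dosages <- t(dosages)  # samples x variants
  v <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    id = fix[, "ID"],
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    block = 1L,
    stringsAsFactors = FALSE
  )
  colnames(dosages) <- v$id
  v$af <- colMeans(dosages) / 2
  message(sprintf("read %d VCF records (%d samples) from %s",
                  nrow(v), nrow(dosages), path))
  structure(list(n_samples = nrow(dosages), variants = v,
                 dosages = dosages,
                 block = stats::setNames(v$block, v$id)),
            class = "reference_panel")
}

#' Read a BED file of intervals
#'
#' BED is 0-based half-open; intervals are converted to the package's
#' 1-based inclusive convention on input.
#'
#' @param path BED path (>= 3 columns; column 4, if present, is a
#'   name).
#' @return data.frame with chrom, start, end (1-based inclusive) and
#'   optional name.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(x) < 3) stop("BED file needs at least 3 columns")
  out <- data.frame(chrom = x[[1]],
                    start = x[[2]] + 1L,  # 0-based -> 1-based
                    end = x[[3]],         # half-open end == inclusive end
                    stringsAsFactors = FALSE)
  if (ncol(x) >= 4) out$name <- x[[4]]
  message(sprintf("read %d intervals from %s", nrow(out), path))
  out
}

#' Write intervals as BED
#'
#' Converts from 1-based inclusive to BED's 0-based half-open.
#'
#' @param intervals data.frame with chrom, start, end (1-based
#'   inclusive) and optional name.
#' @param path Output path.
#' @export
write_bed <- function(intervals, path) {
  out <- data.frame(chrom = intervals$chrom,
                    start = intervals$start - 1L,
                    end = intervals$end)
  if ("name" %in% names(intervals)) out$name <- intervals$name
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  message(sprintf("wrote %d intervals to %s", nrow(out), path))
  invisible(path)
}
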