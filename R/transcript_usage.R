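#' Classify transcripts into long and short promoter groups
#'
#' Splits a gene's transcripts at a breakpoint (e.g. the chromatin
#' contact locus with the highest interaction frequency) in a
#' strand-aware way: a transcript belongs to the *long* group when its
#' TSS lies upstream of the breakpoint in the gene's transcription
#' sense (plus strand: `TSS < breakpoint`; minus strand:
#' `TSS > breakpoint`), otherwise to the *short* group.  A TSS exactly
#' at the breakpoint is classified short, with a warning, as the
#' downstream-promoter side.
#'
#' @param annotations data.frame with columns transcript_id, gene,
#'   chrom, strand (`"+"`/`"-"`), tss (1-based).
#' @param breakpoint Breakpoint position (1-based) on `chrom`.
#' @param chrom Chromosome of the breakpoint; all transcripts must be
#'   on it.
#' @return Named character vector transcript_id -> `"long"`/`"short"`.
#' @export
classify_transcripts <- function(annotations, breakpoint, chrom = NULL) {
  need <- c("transcript_id", "strand", "tss")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns ", paste(need, collapse = ", "))
  if (!is.null(chrom) && "chrom" %in% names(annotations) &&
      any(annotations$chrom != chrom))
    stop("all transcripts must be on the breakpoint chromosome ", chrom)
  if (!all(annotations$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  at_bp <- annotations$tss == breakpoint
  if (any(at_bp))
    warning("TSS exactly at the breakpoint for ",
            paste(annotations$transcript_id[at_bp], collapse = ", "),
            "; classified short")
  upstream <- ifelse(annotations$strand == "+",
                     annotations$tss < breakpoint,
                     annotations$tss > breakpoint)
  stats::setNames(ifelse(upstream, "long", "short"),
                  annotations$transcript_id)
}

#' Aggregate transcript TPM into promoter-group TPM
#'
#' Sums per-transcript TPM within the long and short groups for each
#' sample.  Because the groups partition the transcripts, the two
#' group totals sum to the gene's total TPM.
#'
#' @param tpm Transcripts x samples TPM matrix with transcript ids as
#'   row names.
#' @param mapping Named vector transcript -> `"long"`/`"short"` (from
#'   [classify_transcripts()]); must cover every row of `tpm`.
#' @return data.frame with per-sample columns `long` and `short`.
#' @export
group_tpm <- function(tpm, mapping) {
  if (!is.matrix(tpm)) tpm <- as.matrix(tpm)
  ids <- rownames(tpm)
  if (is.null(ids)) stop("TPM matrix must have transcript row names")
  unmapped <- setdiff(ids, names(mapping))
  if (length(unmapped))
    stop("unmapped transcript(s): ", paste(unmapped, collapse = ", "))
  grp <- mapping[ids]
  long <- colSums(tpm[grp == "long", , drop = FALSE])
  short <- colSums(tpm[grp == "short", , drop = FALSE])
  data.frame(long = long, short = short)
}

#' Genotype association of a promoter-group expression phenotype
#'
#' Ordinary least-squares regression of a group's per-sample TPM on
#' alt-allele dosage: slope, SE, two-sided P and n.
#'
#' @param dosage Dosage vector (nonconstant, length >= 3).
#' @param expression Group expression vector (nonconstant).
#' @return A `usage_qtl_result` list: beta, se, p, n.
#' @export
usage_qtl <- function(dosage, expression) {
  n <- length(dosage)
  if (n < 3) stop("need at least 3 samples")
  if (length(expression) != n)
    stop("dosage and expression lengths differ")
  if (var(dosage) == 0) stop("constant dosage")
  if (var(expression) == 0) stop("constant expression")
  fit <- summary(lm(expression ~ dosage))$coefficients
  structure(list(beta = fit["dosage", "Estimate"],
                 se = fit["dosage", "Std. Error"],
                 p = fit["dosage", "Pr(>|t|)"],
                 n = n),
            class = "usage_qtl_result")
}

#' @export
print.usage_qtl_result <- function(x, ...) {
  cat(sprintf("usage QTL: beta = %.4g (SE %.3g), P = %.3g, n = %d\n",
              x$beta, x$se, x$p, x$n))
  invisible(x)
}
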