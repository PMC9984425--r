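#' Recover a standard error from an effect size and P value
#'
#' When a summary-statistics source reports beta and P but no SE, the
#' SE is reconstructed from the two-sided normal test that produced the
#' P value: `se = |beta| / Q(1 - p/2)` with `Q` the standard normal
#' quantile function.  The reconstructed `z = beta/se` reproduces the
#' input P under the same two-sided test.
#'
#' @param beta Nonzero effect size.
#' @param p Two-sided P value in (0, 1).
#' @return Positive standard error (vectorized over `beta`/`p`).
#' @examples
#' estimate_se_from_p(0.1, 0.05)  # ~0.051021
#' @export
estimate_se_from_p <- function(beta, p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("'p' must lie strictly in (0, 1)")
  if (any(!is.finite(beta)) || any(beta == 0))
    stop("'beta' must be finite and nonzero")
  # upper-tail form keeps precision for very small p
  abs(beta) / qnorm(p / 2, lower.tail = FALSE)
}

#' Convert an odds ratio to a log-scale beta and SE
#'
#' `beta = log(OR)`; the SE comes from the log-scale confidence bounds
#' when both are given, otherwise from the P value via
#' [estimate_se_from_p()].
#'
#' @param or Odds ratio (> 0).
#' @param ci_lower,ci_upper Optional confidence bounds of the OR.
#' @param p Optional two-sided P value (used when bounds are absent).
#' @param level Confidence level of the bounds (default 0.95).
#' @return List with `beta` and `se`.
#' @export
or_to_beta <- function(or, ci_lower = NULL, ci_upper = NULL, p = NULL,
                       level = 0.95) {
  if (any(or <= 0)) stop("'or' must be positive")
  beta <- log(or)
  if (!is.null(ci_lower) && !is.null(ci_upper)) {
    if (any(ci_lower <= 0) || any(ci_upper <= ci_lower))
      stop("confidence bounds must satisfy 0 < lower < upper")
    se <- (log(ci_upper) - log(ci_lower)) /
      (2 * qnorm((1 + level) / 2))
  } else if (!is.null(p)) {
    se <- estimate_se_from_p(beta, p)
  } else {
    stop("supply either confidence bounds or a P value")
  }
  list(beta = beta, se = se)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.is_palindromic <- function(a, b) {
  !is.na(a) & !is.na(b) & .complement[a] == b
}

.panel_site_index <- function(panel) {
  v <- panel$variants
  key <- paste(v$chrom, v$pos, sep = ":")
  if (anyDuplicated(key)) {
    dup <- unique(key[duplicated(key)])
    attr(key, "multiallelic") <- dup
  }
  key
}

#' Infer the non-effect allele from a biallelic reference panel
#'
#' Records reporting only an effect allele are completed from the panel
#' site at the same coordinate: if the biallelic site carries the
#' effect allele, the other allele becomes the non-effect allele;
#' records at absent or multi-allelic sites, or whose effect allele is
#' not one of the site's two alleles, are dropped.
#'
#' @param records Summary-statistics data.frame (columns chrom, pos,
#'   id, ea, nea, ...) where `nea` may be `NA`/empty.
#' @param panel A [simulate_reference_panel()]-style panel (or any list
#'   with a `variants` data.frame carrying chrom, pos, ref, alt).
#' @return List with `records` (completed rows only) and `dropped`
#'   (data.frame of rejected rows with a `reason` column).
#' @export
infer_noneffect_allele <- function(records, panel) {
  v <- panel$variants
  key <- paste(v$chrom, v$pos, sep = ":")
  multi <- unique(key[duplicated(key)])
  rkey <- paste(records$chrom, records$pos, sep = ":")
  hit <- match(rkey, key)
  needs <- is.na(records$nea) | records$nea == ""
  reason <- rep(NA_character_, nrow(records))
  for (i in which(needs)) {
    if (rkey[i] %in% multi) { reason[i] <- "multiallelic_site"; next }
    j <- hit[i]
    if (is.na(j)) { reason[i] <- "site_absent"; next }
    if (records$ea[i] == v$alt[j]) records$nea[i] <- v$ref[j]
    else if (records$ea[i] == v$ref[j]) records$nea[i] <- v$alt[j]
    else reason[i] <- "effect_allele_not_at_site"
  }
  keep <- is.na(reason)
  dropped <- records[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- reason[!keep]
  list(records = records[keep, , drop = FALSE], dropped = dropped)
}

#' Harmonize summary statistics to a reference panel orientation
#'
#' Aligns each record's alleles and effect sign to the panel's ref/alt
#' orientation, so that after harmonization every beta is expressed per
#' copy of the panel's *alt* allele.  Direct allele matches are kept
#' (sign-flipped when the reported effect allele is the panel ref);
#' complementary-strand matches are base-complemented first;
#' palindromic (A/T, C/G) records are dropped unconditionally since
#' strand cannot be resolved without frequency information; records at
#' sites absent from the panel, or with unresolvable alleles, are
#' dropped with a reason.
#'
#' @param records Summary-statistics data.frame with columns chrom,
#'   pos, id, ea, nea, beta, se, p, n (`nea` may be missing and is then
#'   inferred from the panel).
#' @param panel Reference panel with a `variants` table.
#' @return List with `records` (harmonized, alt-allele-oriented) and
#'   `report` (class `harmonization_report`): counts of kept,
#'   sign-flipped, strand-flipped and dropped records by reason;
#'   `kept + sum(dropped) == input`.
#' @export
harmonize_to_panel <- function(records, panel) {
  stopifnot(is.data.frame(records))
  n_in <- nrow(records)
  drop_reason <- rep(NA_character_, n_in)
  sign_flip <- strand_flip <- rep(FALSE, n_in)

  has_coord <- !is.na(records$chrom) & !is.na(records$pos)
  has_id <- !is.na(records$id) & records$id != ""
  drop_reason[!has_coord & !has_id] <- "missing_coordinates_and_id"
  drop_reason[!has_coord & has_id] <- "not_in_panel"

  rkey <- paste(records$chrom, records$pos, sep = ":")
  dup <- duplicated(rkey) | duplicated(rkey, fromLast = TRUE)
  dup <- dup & has_coord
  if (any(dup))
    stop("duplicate records at position(s): ",
         paste(unique(rkey[dup]), collapse = ", "))

  v <- panel$variants
  key <- paste(v$chrom, v$pos, sep = ":")
  hit <- match(rkey, key)
  live <- is.na(drop_reason)
  drop_reason[live & is.na(hit)] <- "not_in_panel"

  # complete missing non-effect alleles from the panel
  needs_nea <- is.na(records$nea) | records$nea == ""
  for (i in which(needs_nea & is.na(drop_reason))) {
    j <- hit[i]
    if (records$ea[i] == v$alt[j]) records$nea[i] <- v$ref[j]
    else if (records$ea[i] == v$ref[j]) records$nea[i] <- v$alt[j]
    else drop_reason[i] <- "undetermined_noneffect_allele"
  }

  bases <- c("A", "C", "G", "T")
  for (i in which(is.na(drop_reason))) {
    j <- hit[i]
    ea <- records$ea[i]; nea <- records$nea[i]
    if (!(ea %in% bases) || !(nea %in% bases)) {
      drop_reason[i] <- "undetermined_noneffect_allele"; next
    }
    if (.is_palindromic(ea, nea)) {
      drop_reason[i] <- "ambiguous_palindromic"; next
    }
    ref <- v$ref[j]; alt <- v$alt[j]
    if (ea == alt && nea == ref) {
      # already alt-oriented
    } else if (ea == ref && nea == alt) {
      sign_flip[i] <- TRUE
    } else if (.complement[[ea]] == alt && .complement[[nea]] == ref) {
      strand_flip[i] <- TRUE
    } else if (.complement[[ea]] == ref && .complement[[nea]] == alt) {
      strand_flip[i] <- TRUE; sign_flip[i] <- TRUE
    } else {
      drop_reason[i] <- "allele_mismatch"
    }
  }

  keep <- is.na(drop_reason)
  out <- records[keep, , drop = FALSE]
  ki <- which(keep)
  for (w in seq_along(ki)) {
    i <- ki[w]; j <- hit[i]
    out$ea[w] <- v$alt[j]
    out$nea[w] <- v$ref[j]
    if (sign_flip[i]) out$beta[w] <- -out$beta[w]
  }
  reasons <- c("missing_coordinates_and_id",
               "undetermined_noneffect_allele", "not_in_panel",
               "ambiguous_palindromic", "allele_mismatch")
  dropped <- vapply(reasons, function(r) sum(drop_reason == r,
                                             na.rm = TRUE), 0L)
  report <- structure(list(input = n_in, kept = sum(keep),
                           sign_flipped = sum(sign_flip[keep]),
                           strand_flipped = sum(strand_flip[keep]),
                           dropped = dropped),
                      class = "harmonization_report")
  list(records = out, report = report)
}

#' @export
print.harmonization_report <- function(x, ...) {
  cat(sprintf("harmonization: %d in, %d kept (%d sign-flipped, %d strand-flipped), %d dropped\n",
              x$input, x$kept, x$sign_flipped, x$strand_flipped,
              sum(x$dropped)))
  for (r in names(x$dropped))
    if (x$dropped[[r]] > 0) cat(sprintf("  dropped %s: %d\n", r, x$dropped[[r]]))
  invisible(x)
}
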