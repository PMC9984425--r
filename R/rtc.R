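#' Principal components of a genotype dosage matrix
#'
#' Top-k principal-component scores of the centered dosage matrix,
#' intended as ancestry/structure covariates for eQTL models.  Signs
#' are fixed deterministically by making each component's
#' largest-magnitude loading positive.
#'
#' @param dosages Samples x variants matrix.
#' @param k Number of components (default 3).
#' @return Samples x k score matrix (fewer columns, with a warning, if
#'   the matrix rank is below `k`).
#' @export
genotype_pcs <- function(dosages, k = 3) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  if (nrow(dosages) < k)
    stop("need at least k = ", k, " samples")
  pc <- prcomp(dosages, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  if (rank < k) {
    warning("matrix rank ", rank, " < k = ", k,
            "; returning ", rank, " components")
    k <- rank
  }
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    load <- pc$rotation[, j]
    if (load[which.max(abs(load))] < 0) scores[, j] <- -scores[, j]
  }
  scores
}

#' Rank-based inverse-normal transform
#'
#' Maps a vector to normal quantiles of its mid-ranks,
#' `qnorm((rank - 0.5)/n)`; standard practice for stabilizing eQTL
#' expression phenotypes.
#'
#' @param y Numeric vector.
#' @return Transformed vector.
#' @export
rank_inverse_normal <- function(y) {
  qnorm((rank(y, ties.method = "average") - 0.5) / length(y))
}

#' Residualize a response on a covariate matrix
#'
#' Least-squares residuals of `y` on `[1, X]`.  Collinear columns are
#' dropped (with a warning) via pivoted QR, so rank-deficient inputs
#' degrade gracefully; residuals are orthogonal to every retained
#' column.
#'
#' @param y Response vector.
#' @param X Covariate matrix (may have zero columns).
#' @return Residual vector.
#' @export
residualize <- function(y, X = NULL) {
  n <- length(y)
  M <- cbind(`(Intercept)` = rep(1, n), X)
  qr_m <- qr(M)
  if (qr_m$rank < ncol(M))
    warning("dropping ", ncol(M) - qr_m$rank,
            " collinear covariate column(s)")
  qr.resid(qr_m, y)
}

#' Regulatory trait concordance score
#'
#' Quantifies whether a GWAS sentinel variant and an eQTL share a
#' causal variant inside one recombination-hotspot interval.  For each
#' of the interval's `N_int` variants, expression is residualized on
#' the covariates plus that variant's dosage, and the residual
#' association (squared t statistic) of the eQTL lead variant is
#' recomputed.  Variants are ranked ascending by that statistic --- a
#' variant that better extinguishes the eQTL signal ranks earlier ---
#' with ties broken by interval order (genomic position).  With `Rank`
#' the sentinel's 0-based position, `RTC = (N_int - Rank) / N_int`;
#' scores at or above 0.9 are called colocalized.
#'
#' @param dosages Samples x interval-variants dosage matrix, columns
#'   named by variant id and ordered by genomic position.
#' @param expression Expression vector for the eGene.
#' @param covariates Covariate matrix (e.g. genotype PCs + expression
#'   factors); may be `NULL`.
#' @param sentinel GWAS sentinel variant id (must be a column).
#' @param lead eQTL lead variant id (must be a column).
#' @param rint Apply [rank_inverse_normal()] to expression first
#'   (default TRUE).
#' @return An `rtc_result`: list with `n_int`, `rank` (0-based),
#'   `rtc`, `sentinel`, `lead`, `stat` (per-variant residual
#'   statistics) and `colocalized` (at 0.9).
#' @export
rtc_score <- function(dosages, expression, covariates = NULL,
                      sentinel, lead, rint = TRUE) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  ids <- colnames(dosages)
  if (is.null(ids)) stop("dosage columns must be named by variant id")
  if (!sentinel %in% ids) stop("sentinel '", sentinel,
                               "' not among interval variants")
  if (!lead %in% ids) stop("eQTL lead '", lead,
                           "' not among interval variants")
  n <- nrow(dosages)
  y <- if (rint) rank_inverse_normal(expression) else expression
  x_lead <- dosages[, lead]
  n_int <- ncol(dosages)
  stat <- vapply(seq_len(n_int), function(s) {
    r <- residualize(y, cbind(covariates, dosages[, s]))
    xl <- x_lead - mean(x_lead)
    sxx <- sum(xl^2)
    if (sxx == 0) return(0)
    b <- sum(xl * r) / sxx
    rss <- sum(r^2) - b^2 * sxx
    # residual df: intercept + covariates + extinguisher + lead
    df <- n - 3 - (if (is.null(covariates)) 0 else ncol(covariates))
    if (rss <= 0) return(Inf)
    b^2 * sxx / (rss / df)   # squared t statistic
  }, numeric(1))
  ord <- order(stat, seq_len(n_int))  # ties by genomic order
  rank0 <- which(ids[ord] == sentinel) - 1L
  rtc <- (n_int - rank0) / n_int
  structure(list(n_int = n_int, rank = rank0, rtc = rtc,
                 sentinel = sentinel, lead = lead,
                 stat = stats::setNames(stat, ids),
                 colocalized = rtc >= 0.9),
            class = "rtc_result")
}

#' @export
print.rtc_result <- function(x, ...) {
  cat(sprintf("RTC: sentinel %s vs lead %s; N_int = %d, rank = %d, RTC = %.3f%s\n",
              x$sentinel, x$lead, x$n_int, x$rank, x$rtc,
              if (x$colocalized) " (colocalized)" else ""))
  invisible(x)
}

#' Colocalization call from an RTC result
#'
#' @param result An [rtc_score()] result.
#' @param threshold RTC threshold (default 0.9, inclusive).
#' @return Logical.
#' @export
colocalized <- function(result, threshold = 0.9) {
  stopifnot(inherits(result, "rtc_result"))
  result$rtc >= threshold
}
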