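#' Define an LD block
#'
#' An analysis unit for fine-mapping and pleiotropy: a genomic interval
#' with an ordered variant list and, optionally, its LD matrix.
#'
#' @param interval A [genomic_interval()].
#' @param ids Ordered character vector of variant ids.
#' @param ld Optional symmetric unit-diagonal LD (Pearson r) matrix
#'   matching `ids`.
#' @return An `ld_block` object.
#' @export
ld_block <- function(interval, ids, ld = NULL) {
  stopifnot(inherits(interval, "genomic_interval"),
            is.character(ids), length(ids) >= 1L)
  if (!is.null(ld)) {
    if (!is.matrix(ld) || nrow(ld) != length(ids) ||
        ncol(ld) != length(ids))
      stop("LD matrix dimensions must match the variant list")
    if (max(abs(ld - t(ld))) > 1e-8 || max(abs(diag(ld) - 1)) > 1e-8)
      stop("LD matrix must be symmetric with unit diagonal")
  }
  structure(list(interval = interval, ids = ids, ld = ld),
            class = "ld_block")
}

#' Select causal blocks by genome-wide significance
#'
#' Keeps blocks that contain at least one variant reaching the
#' genome-wide significance threshold in the supplied summary table.
#' Blocks with no summary records are dropped.
#'
#' @param blocks List of [ld_block()] objects.
#' @param sumstats Summary data.frame with columns `id` and `p`.
#' @param threshold Significance threshold in (0, 1); default `5e-8`.
#' @return The qualifying subset of `blocks` (possibly empty).
#' @export
select_causal_blocks <- function(blocks, sumstats, threshold = 5e-8) {
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must lie in (0, 1)")
  keep <- vapply(blocks, function(b) {
    p <- sumstats$p[sumstats$id %in% b$ids]
    length(p) > 0 && min(p, na.rm = TRUE) <= threshold
  }, logical(1))
  blocks[keep]
}

#' Compute a block-wise LD matrix
#'
#' Pairwise Pearson correlation of genotype dosages.  Monomorphic
#' variants are excluded (with a warning) before computation, since
#' their correlation is undefined.
#'
#' @param dosages Samples x variants dosage matrix (>= 2 samples).
#' @return Symmetric unit-diagonal correlation matrix over the retained
#'   variants.
#' @export
compute_ld_matrix <- function(dosages) {
  if (!is.matrix(dosages)) dosages <- as.matrix(dosages)
  if (nrow(dosages) < 2)
    stop("at least 2 samples are required to compute LD")
  v <- apply(dosages, 2, var)
  if (any(v == 0)) {
    warning("excluding ", sum(v == 0), " monomorphic variant(s): ",
            paste(colnames(dosages)[v == 0], collapse = ", "))
    dosages <- dosages[, v > 0, drop = FALSE]
  }
  if (ncol(dosages) == 0) stop("no polymorphic variants left")
  r <- cor(dosages)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Wakefield approximate Bayes factor (log scale)
#'
#' Single-variant evidence ratio of association vs null under a
#' normal effect-size prior with variance `W`: with `V = se^2` and
#' `z = beta/se`,
#' `ABF = sqrt(V/(V+W)) * exp(z^2 W / (2 (V+W)))`.
#' All arithmetic is kept in log space so that |z| of 40+ stays finite.
#'
#' @param beta Effect estimate(s).
#' @param se Standard error(s), > 0.
#' @param W Prior variance of the effect size (trait units squared),
#'   >= 0.  Default 0.04 (prior SD 0.2).
#' @return Log ABF (vectorized).  `W = 0` gives log ABF = 0.
#' @examples
#' exp(wakefield_log_abf(0, 0.1, W = 0.04))   # sqrt(0.01/0.05)
#' @export
wakefield_log_abf <- function(beta, se, W = 0.04) {
  if (any(se <= 0)) stop("'se' must be positive")
  if (any(W < 0)) stop("'W' must be >= 0")
  V <- se^2
  z <- beta / se
  0.5 * log(V / (V + W)) + z^2 / 2 * (W / (V + W))
}

#' Wakefield approximate Bayes factor
#'
#' Natural-scale convenience wrapper around [wakefield_log_abf()].
#'
#' @inheritParams wakefield_log_abf
#' @return ABF (may overflow to `Inf` for extreme z; prefer the log
#'   form in pipelines).
#' @export
wakefield_abf <- function(beta, se, W = 0.04) {
  exp(wakefield_log_abf(beta, se, W))
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Single-causal posterior probabilities from ABFs
#'
#' Under the single-causal-variant assumption with a uniform prior on
#' which variant is causal, `PP_i = ABF_i / sum_j ABF_j`.  Computed
#' with log-sum-exp normalization.
#'
#' @param abf Vector of ABFs (>= 0, at least one positive), or log
#'   ABFs when `log = TRUE`.
#' @param log Are the inputs on the log scale?
#' @return Posterior probability vector summing to 1.
#' @export
single_causal_posteriors <- function(abf, log = FALSE) {
  if (!log) {
    if (any(abf < 0)) stop("ABFs must be nonnegative")
    if (all(abf == 0)) stop("all-zero ABF vector")
    labf <- base::log(abf)
  } else labf <- abf
  exp(labf - log_sum_exp(labf))
}

#' Credible set of likely causal variants
#'
#' Sorts variants by descending posterior probability (ties broken by
#' input order) and takes the shortest prefix whose cumulative PP
#' reaches the credible level.
#'
#' @param pp Posterior probabilities summing to 1 (tolerance `1e-8`).
#' @param ids Variant ids matching `pp` (default: indices).
#' @param rho Credible level in (0, 1]; default 0.95.  `rho = 1`
#'   returns all variants with positive PP.
#' @return Character vector of member ids (in PP-descending order).
#' @export
credible_set <- function(pp, ids = as.character(seq_along(pp)),
                         rho = 0.95) {
  if (rho <= 0 || rho > 1) stop("'rho' must lie in (0, 1]")
  if (abs(sum(pp) - 1) > 1e-8)
    stop("posterior probabilities must sum to 1")
  ord <- order(-pp, seq_along(pp))  # stable: ties by input order
  cum <- cumsum(pp[ord])
  if (rho == 1) {
    take <- which(pp[ord] > 0)
  } else {
    take <- seq_len(which(cum >= rho)[1])
  }
  ids[ord[take]]
}

#' Fine-map one causal block
#'
#' Runs the single-causal pipeline on one block's harmonized summary
#' statistics: per-variant log ABFs, posterior probabilities, and the
#' 95% credible set.
#'
#' @param sumstats Harmonized summary data.frame for the block
#'   (columns id, beta, se).
#' @param W Effect-size prior variance (see [wakefield_log_abf()]).
#' @param rho Credible level (default 0.95).
#' @return An `abf_result`: data.frame (id, z, log_abf, pp,
#'   in_credible_set) plus attributes `rho` and `credible_set`.
#' @export
finemap_block <- function(sumstats, W = 0.04, rho = 0.95) {
  labf <- wakefield_log_abf(sumstats$beta, sumstats$se, W)
  pp <- single_causal_posteriors(labf, log = TRUE)
  cs <- credible_set(pp, ids = sumstats$id, rho = rho)
  out <- data.frame(id = sumstats$id,
                    z = sumstats$beta / sumstats$se,
                    log_abf = labf, pp = pp,
                    in_credible_set = sumstats$id %in% cs,
                    stringsAsFactors = FALSE)
  attr(out, "rho") <- rho
  attr(out, "credible_set") <- cs
  class(out) <- c("abf_result", "data.frame")
  out
}
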