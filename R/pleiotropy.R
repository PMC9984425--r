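#' Parse a MeSH tree number
#'
#' Splits a dotted Medical Subject Headings tree number (e.g.
#' `"C06.405.469.432.249"`) into its ordered components.
#'
#' @param x Tree-number string.
#' @return A `mesh_tree_number` (character vector of components).
#' @export
mesh_tree_number <- function(x) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x))
    stop("tree number must be a single non-empty string")
  comp <- strsplit(x, ".", fixed = TRUE)[[1]]
  if (length(comp) < 1L || any(!nzchar(comp)))
    stop("unparseable MeSH tree number: '", x, "'")
  structure(comp, class = "mesh_tree_number")
}

#' Relationship level of two diseases in the MeSH hierarchy
#'
#' The level is the length of the longest common prefix of the two
#' tree numbers' component lists, capped at 5.  Closely related
#' diseases (e.g. two inflammatory bowel diseases under one parent
#' node) share deep prefixes; unrelated ones share none.
#'
#' @param a,b Tree numbers (strings or [mesh_tree_number()] objects).
#' @return Integer level in 0..5.
#' @examples
#' mesh_relationship_level("C06.405.469.432.249",
#'                         "C06.405.469.432.500")  # 4
#' @export
mesh_relationship_level <- function(a, b) {
  if (!inherits(a, "mesh_tree_number")) a <- mesh_tree_number(a)
  if (!inherits(b, "mesh_tree_number")) b <- mesh_tree_number(b)
  k <- min(length(a), length(b), 5L)
  level <- 0L
  for (i in seq_len(k)) {
    if (a[i] == b[i]) level <- i else break
  }
  min(level, 5L)
}

#' Expected cohort-overlap correlation for a disease pair
#'
#' Maps a MeSH relationship level onto the expected null correlation
#' of the two traits' summary statistics.  Pairs from distinct cohorts
#' get 0; same-cohort (overlapping-sample) pairs follow the ladder
#' `0.09 * level`, i.e. 0.09, 0.18, 0.27, 0.36, 0.45 for levels 1-5.
#'
#' @param level MeSH relationship level (>= 0).
#' @param cohort `"same-cohort"` or `"distinct-cohort"`.
#' @return Expected correlation C.
#' @examples
#' expected_correlation(4, "same-cohort")  # 0.36
#' @export
expected_correlation <- function(level,
                                 cohort = c("same-cohort",
                                            "distinct-cohort")) {
  cohort <- match.arg(cohort)
  if (level < 0) stop("'level' must be >= 0")
  if (cohort == "distinct-cohort") return(0)
  0.09 * min(level, 5)
}

# log density of a bivariate normal N(0, [[a, c], [c, b]]) at (x, y)
.ldbvn <- function(x, y, a, b, c) {
  det <- a * b - c^2
  -log(2 * pi) - 0.5 * log(det) -
    0.5 * (b * x^2 - 2 * c * x * y + a * y^2) / det
}

#' Joint Bayes factor for one variant shared by two traits
#'
#' Evidence ratio that one variant is causal for *both* traits,
#' against the null of no association in either, allowing for
#' cohort-overlap correlation `C` between the two scans' null
#' Z scores.  In Z space the null is `N(0, Sigma)` with
#' `Sigma = [[1, C], [C, 1]]` and the shared-causal alternative adds
#' the prior variance ratios on the diagonal:
#' `N(0, Sigma + diag(W1/V1, W2/V2))`.  With `C = 0` this factorizes
#' into the product of the two marginal Wakefield ABFs.
#'
#' @param z1,z2 Per-trait Z scores (vectorized).
#' @param V1,V2 Squared standard errors, > 0.
#' @param C Expected overlap correlation, |C| < 1.
#' @param W1,W2 Per-trait effect-size prior variances.
#' @return Log joint Bayes factor.
#' @export
joint_log_abf_shared <- function(z1, z2, V1, V2, C = 0,
                                 W1 = 0.04, W2 = 0.04) {
  if (any(V1 <= 0) || any(V2 <= 0)) stop("'V1'/'V2' must be positive")
  if (abs(C) >= 1) stop("|C| must be < 1")
  .ldbvn(z1, z2, 1 + W1 / V1, 1 + W2 / V2, C) -
    .ldbvn(z1, z2, 1, 1, C)
}

#' Per-variant pleiotropy model priors
#'
#' Prior probabilities that any one variant in a block is causal for
#' trait 1 only, trait 2 only, both (shared), or that two distinct
#' variants are causal for the two traits.  These fixed defaults stand
#' in for a genome-wide empirical-Bayes fit, which cannot be estimated
#' from one or a few blocks; all four are configurable.
#'
#' @param pi1,pi2 Trait-specific causal priors (default `1e-4`).
#' @param pi3 Shared-causal prior (default `1e-5`).
#' @param pi4 Distinct-causal-pair prior (default `1e-6`).
#' @return A `pleiotropy_priors` list.
#' @export
pleiotropy_priors <- function(pi1 = 1e-4, pi2 = 1e-4, pi3 = 1e-5,
                              pi4 = 1e-6) {
  p <- c(pi1 = pi1, pi2 = pi2, pi3 = pi3, pi4 = pi4)
  if (any(p <= 0) || any(p >= 1))
    stop("all priors must lie in (0, 1)")
  structure(as.list(p), class = "pleiotropy_priors")
}

# log(exp(a) - exp(b)) for a >= b, -Inf-safe
log_diff_exp <- function(a, b) {
  if (!is.finite(a) || b == -Inf) return(a)
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Five-model pleiotropy posteriors for one block
#'
#' Combines per-variant log Bayes factors for trait 1, trait 2, and
#' the shared-causal model into block-level posteriors over the five
#' models \{0: no association, 1: trait 1 only, 2: trait 2 only,
#' 3: one shared causal variant, 4: two distinct causal variants\}.
#' Unnormalized block scores are
#' `S0 = 1`, `S1 = pi1 sum_i BF1_i`, `S2 = pi2 sum_i BF2_i`,
#' `S3 = pi3 sum_i BFj_i`, and
#' `S4 = pi4 sum_i sum_{j != i} BF1_i BF2_j`, all evaluated in log
#' space with log-sum-exp normalization.
#'
#' @param labf1,labf2 Per-variant log ABFs for each trait (equal
#'   length k >= 1).
#' @param labf_joint Per-variant log joint shared-causal BFs
#'   ([joint_log_abf_shared()]).
#' @param priors A [pleiotropy_priors()].
#' @return A `model_posteriors` object: numeric `pp0`..`pp4` summing
#'   to 1.
#' @export
block_model_posteriors <- function(labf1, labf2, labf_joint,
                                   priors = pleiotropy_priors()) {
  k <- length(labf1)
  if (k < 1 || length(labf2) != k || length(labf_joint) != k)
    stop("log-BF vectors must have equal positive length")
  stopifnot(inherits(priors, "pleiotropy_priors"))
  l1 <- log_sum_exp(labf1)
  l2 <- log_sum_exp(labf2)
  # sum over ordered pairs i != j of BF1_i * BF2_j
  l4core <- if (k == 1L) -Inf else
    log_diff_exp(l1 + l2, log_sum_exp(labf1 + labf2))
  ls <- c(0,
          log(priors$pi1) + l1,
          log(priors$pi2) + l2,
          log(priors$pi3) + log_sum_exp(labf_joint),
          log(priors$pi4) + l4core)
  pp <- exp(ls - log_sum_exp(ls))
  structure(as.list(stats::setNames(pp, paste0("pp", 0:4))),
            class = "model_posteriors")
}

#' @export
print.model_posteriors <- function(x, ...) {
  cat("block model posteriors:\n")
  lbl <- c("null", "trait1 only", "trait2 only", "shared causal",
           "two distinct causals")
  for (i in 0:4)
    cat(sprintf("  pp%d (%s): %.4g\n", i, lbl[i + 1],
                x[[paste0("pp", i)]]))
  invisible(x)
}

#' Shared-genetic-effect call
#'
#' A block is called pleiotropic (shared genetic effect) when the
#' shared-causal model's posterior reaches the threshold (inclusive).
#'
#' @param posteriors A [block_model_posteriors()] result.
#' @param threshold Posterior threshold (default 0.9).
#' @return Logical.
#' @export
is_shared_effect <- function(posteriors, threshold = 0.9) {
  stopifnot(inherits(posteriors, "model_posteriors"))
  posteriors$pp3 >= threshold
}

#' Pairwise pleiotropy scan of one block
#'
#' Convenience wrapper: from two harmonized summary tables restricted
#' to one LD block, computes per-variant marginal log ABFs, joint
#' shared-causal BFs under the supplied overlap correlation, and the
#' five-model posteriors.
#'
#' @param sumstats1,sumstats2 Harmonized summary data.frames with
#'   columns id, beta, se, aligned to the same panel (matched on id).
#' @param C Expected cohort-overlap correlation (see
#'   [expected_correlation()]).
#' @param W1,W2 Effect-size prior variances.
#' @param priors A [pleiotropy_priors()].
#' @return A `model_posteriors` with attribute `C`.
#' @export
pleiotropy_scan <- function(sumstats1, sumstats2, C = 0,
                            W1 = 0.04, W2 = 0.04,
                            priors = pleiotropy_priors()) {
  common <- intersect(sumstats1$id, sumstats2$id)
  if (!length(common)) stop("no shared variants between the two scans")
  a <- sumstats1[match(common, sumstats1$id), ]
  b <- sumstats2[match(common, sumstats2$id), ]
  labf1 <- wakefield_log_abf(a$beta, a$se, W1)
  labf2 <- wakefield_log_abf(b$beta, b$se, W2)
  labfj <- joint_log_abf_shared(a$beta / a$se, b$beta / b$se,
                                a$se^2, b$se^2, C, W1, W2)
  out <- block_model_posteriors(labf1, labf2, labfj, priors)
  attr(out, "C") <- C
  attr(out, "ids") <- common
  out
}
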