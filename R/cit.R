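#' Prefilter a cis/trans expression pair
#'
#' Triplets whose cis- and trans-gene expression traits are only
#' weakly correlated are removed before causal inference testing to
#' reduce the multiple-testing burden: the pair is kept iff the
#' Pearson correlation test P value is at or below `alpha`.
#'
#' @param G,T Cis and trans expression vectors (equal length).
#' @param alpha Correlation-test threshold (default 0.05).
#' @return Logical; `FALSE` (with a warning) for constant vectors.
#' @export
prefilter_triplet <- function(G, T, alpha = 0.05) {
  if (length(G) != length(T)) stop("'G' and 'T' must have equal length")
  if (sd(G) == 0 || sd(T) == 0) {
    warning("constant expression vector; triplet dropped")
    return(FALSE)
  }
  cor.test(G, T)$p.value <= alpha
}

# F-test p-value for adding column x to the linear model y ~ X0
.partial_f_p <- function(y, x, X0) {
  r_y <- residualize(y, X0)
  r_x <- residualize(x, X0)
  sxx <- sum(r_x^2)
  if (sxx == 0) stop("degenerate regression: zero-variance predictor")
  b <- sum(r_x * r_y) / sxx
  rss1 <- sum(r_y^2) - b^2 * sxx
  df2 <- length(y) - (if (is.null(X0)) 1 else ncol(as.matrix(X0)) + 1) - 1
  f <- b^2 * sxx / (rss1 / df2)
  pf(f, 1, df2, lower.tail = FALSE)
}

# observed F statistic for L in T ~ G + L, plus B permuted
# counterparts with L permuted within tertile bins of G (preserving
# the coarse L-G structure while breaking any direct L-T link)
.perm_f_stats <- function(L, G, T, B) {
  n <- length(L)
  X <- cbind(1, G)
  qx <- qr(X)
  rT <- qr.resid(qx, T)
  bins <- cut(G, breaks = quantile(G, probs = c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE, labels = FALSE)
  # occasional ties can collapse a bin; fall back to rank-based bins
  if (length(unique(bins)) < 2)
    bins <- as.integer(cut(rank(G, ties.method = "first"), 3))
  perms <- matrix(L, n, B)
  for (bin in unique(bins)) {
    idx <- which(bins == bin)
    if (length(idx) > 1)
      perms[idx, ] <- apply(perms[idx, , drop = FALSE], 2, sample)
  }
  fstat <- function(Lcol) {
    rL <- qr.resid(qx, Lcol)
    sxx <- sum(rL^2)
    if (sxx == 0) return(0)
    b <- sum(rL * rT) / sxx
    rss <- sum(rT^2) - b^2 * sxx
    b^2 * sxx / (rss / (n - 3))
  }
  list(observed = fstat(L),
       permuted = apply(perms, 2, fstat))
}

#' Component P values of the causal inference test
#'
#' For the direction `L -> G -> T` (variant to cis gene to trans
#' gene), four conditions are tested, all oriented so that a *small*
#' P value supports the causal model:
#' \enumerate{
#'   \item `p1`: L is associated with T (F test of L in `T ~ L`);
#'   \item `p2`: L is associated with G given T (F test of L in
#'     `G ~ L + T`);
#'   \item `p3`: G is associated with T given L (F test of G in
#'     `T ~ G + L`);
#'   \item `p4`: L is conditionally *independent* of T given G,
#'     assessed by an equivalence test: the observed F statistic for
#'     L in `T ~ G + L` is referred to a noncentral F whose
#'     noncentrality is the marginal L-T association strength (the
#'     test-1 F statistic) minus the leakage baseline estimated from
#'     `B` seeded permutations of L within tertile bins of G (which
#'     preserve the coarse L-G structure while destroying any direct
#'     L-T link).  `p4 = P(F_ncp <= F_obs)` is small when the
#'     conditional association is much weaker than the marginal one,
#'     i.e. when G fully mediates the L-T association.
#' }
#' The omnibus for a direction is the maximum of its four components
#' (see [cit_omnibus()]): all four conditions must hold for a causal
#' call.
#'
#' @param L Dosage vector (numeric additive coding).
#' @param G,T Cis and trans expression vectors.
#' @param B Number of permutations for the `p4` leakage baseline
#'   (default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return Named numeric `c(p1, p2, p3, p4)`.
#' @export
cit_components <- function(L, G, T, B = 1000L, seed = 1L) {
  n <- length(L)
  if (length(G) != n || length(T) != n)
    stop("L, G, T must have equal length")
  if (n < 10) stop("need at least 10 samples")
  if (sd(L) == 0 || sd(G) == 0 || sd(T) == 0)
    stop("degenerate regression: zero-variance input")
  p1 <- .partial_f_p(T, L, NULL)
  p2 <- .partial_f_p(G, L, cbind(T))
  p3 <- .partial_f_p(T, G, cbind(L))
  # marginal L-T F statistic: the dependence that must be mediated
  rT0 <- T - mean(T); rL0 <- L - mean(L)
  b0 <- sum(rL0 * rT0) / sum(rL0^2)
  rss0 <- sum(rT0^2) - b0^2 * sum(rL0^2)
  f_marg <- b0^2 * sum(rL0^2) / (rss0 / (n - 2))
  fs <- withr::with_seed(child_seed(seed, 71L),
                         .perm_f_stats(L, G, T, B))
  ncp <- max(f_marg - mean(fs$permuted), 0)
  p4 <- pf(fs$observed, 1, n - 3, ncp = ncp, lower.tail = TRUE)
  c(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
}

#' Intersection-union omnibus P value
#'
#' The omnibus P value of four oriented component tests is their
#' maximum: every condition must individually be rejected for the
#' model to be accepted.
#'
#' @param components Numeric vector of four oriented P values
#'   (small = supports the model in every component).
#' @return The maximum.
#' @export
cit_omnibus <- function(components) {
  if (length(components) != 4) stop("expected four component P values")
  max(components)
}

#' Classify a triplet from its two omnibus P values
#'
#' With Bonferroni level `alpha = 0.05 / n_tests`: causal iff the
#' causal-direction omnibus is below `alpha` while the reactive one is
#' not; reactive for the mirror image; otherwise (including both
#' significant) the independent model is retained.
#'
#' @param p_causal,p_reactive Omnibus P values of the two directions.
#' @param n_tests Number of tested triplets (>= 1) for the Bonferroni
#'   correction.
#' @return `"causal"`, `"reactive"` or `"independent"`.
#' @export
classify_triplet <- function(p_causal, p_reactive, n_tests = 1L) {
  if (n_tests < 1) stop("'n_tests' must be >= 1")
  alpha <- 0.05 / n_tests
  if (p_causal < alpha && p_reactive >= alpha) "causal"
  else if (p_reactive < alpha && p_causal >= alpha) "reactive"
  else "independent"
}

#' Run the causal inference test on one triplet
#'
#' Computes component and omnibus P values for both the causal
#' (`L -> G -> T`) and reactive (`L -> T -> G`) directions and
#' classifies the triplet.  The reactive direction is the causal test
#' with G and T exchanged, so swapping `G` and `T` in the input swaps
#' `p_causal` and `p_reactive` exactly.
#'
#' @param L Dosage vector.
#' @param G,T Cis and trans expression vectors.
#' @param n_tests Bonferroni denominator (number of triplets tested).
#' @param B Permutations for the conditional-independence component.
#' @param seed Integer seed.
#' @param ids Optional named list/vector with `variant`, `cis`,
#'   `trans` identifiers (carried into network assembly).
#' @return A `cit_result`: components for both directions, omnibus
#'   pair, `alpha`, `classification`, `ids`.
#' @export
cit_run <- function(L, G, T, n_tests = 1L, B = 1000L, seed = 1L,
                    ids = NULL) {
  comp_c <- cit_components(L, G, T, B = B, seed = seed)
  comp_r <- cit_components(L, T, G, B = B, seed = seed)
  p_causal <- cit_omnibus(comp_c)
  p_reactive <- cit_omnibus(comp_r)
  structure(list(components_causal = comp_c,
                 components_reactive = comp_r,
                 p_causal = p_causal, p_reactive = p_reactive,
                 alpha = 0.05 / n_tests,
                 classification = classify_triplet(p_causal, p_reactive,
                                                   n_tests),
                 ids = ids),
            class = "cit_result")
}

#' @export
print.cit_result <- function(x, ...) {
  cat(sprintf("CIT: p_causal = %.3g, p_reactive = %.3g (alpha = %.3g) -> %s\n",
              x$p_causal, x$p_reactive, x$alpha, x$classification))
  invisible(x)
}

#' Assemble the directed cis/trans regulatory network
#'
#' Builds a directed graph from classified triplets: a causal call
#' contributes `variant -> cis -> trans`; a reactive call contributes
#' `variant -> trans -> cis`; independent calls contribute nothing.
#' Genes are labeled `cis`, `trans`, or `cis/trans` when they appear
#' in both roles across triplets.
#'
#' @param results List of [cit_run()] results whose `ids` carry
#'   `variant`, `cis`, `trans` names.
#' @return List with `graph` (igraph), `node_class` (named character)
#'   and `counts` (table of node classes).
#' @export
build_regulatory_network <- function(results) {
  edges <- list()
  cis_genes <- character(0); trans_genes <- character(0)
  variants <- character(0)
  for (r in results) {
    if (is.null(r$ids)) stop("cit_result lacks ids")
    v <- r$ids$variant; g <- r$ids$cis; t <- r$ids$trans
    if (r$classification == "causal") {
      edges[[length(edges) + 1L]] <- data.frame(from = c(v, g),
                                                to = c(g, t))
      cis_genes <- c(cis_genes, g); trans_genes <- c(trans_genes, t)
      variants <- c(variants, v)
    } else if (r$classification == "reactive") {
      edges[[length(edges) + 1L]] <- data.frame(from = c(v, t),
                                                to = c(t, g))
      cis_genes <- c(cis_genes, g); trans_genes <- c(trans_genes, t)
      variants <- c(variants, v)
    }
  }
  edge_df <- if (length(edges)) unique(do.call(rbind, edges))
             else data.frame(from = character(0), to = character(0))
  genes <- union(cis_genes, trans_genes)
  node_class <- stats::setNames(rep("", length(genes)), genes)
  node_class[genes %in% cis_genes & !(genes %in% trans_genes)] <- "cis"
  node_class[!(genes %in% cis_genes) & genes %in% trans_genes] <- "trans"
  node_class[genes %in% cis_genes & genes %in% trans_genes] <- "cis/trans"
  node_class <- c(node_class,
                  stats::setNames(rep("variant", length(unique(variants))),
                                  unique(variants)))
  g <- igraph::graph_from_data_frame(edge_df, directed = TRUE,
                                     vertices = if (length(node_class))
                                       names(node_class) else NULL)
  list(graph = g, node_class = node_class,
       counts = table(node_class))
}
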