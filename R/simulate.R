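#' Simulate an LD-structured diploid reference panel
#'
#' Generates biallelic genotype dosages (alt-allele counts in \{0,1,2\})
#' for unrelated diploid samples, organised into LD blocks.  Each
#' haplotype is drawn from a latent multivariate normal with
#' block-constant correlation and thresholded at the block's allele
#' frequency; two independent haplotypes are paired into a diploid
#' dosage.  Because thresholding attenuates correlation, the latent
#' correlation is calibrated numerically so that the *genotype* (phi)
#' correlation within a block matches `within_block_ld` in expectation.
#' Variants in different blocks are independent.
#'
#' All variants within a block share one allele frequency, drawn from
#' `maf_range`; with distinct frequencies the requested LD can be
#' unattainable (the phi coefficient is bounded above by the frequency
#' mismatch), so a common frequency keeps the target honest.
#'
#' @param n_samples Number of diploid samples (>= 2).
#' @param blocks Integer vector of block sizes (numbers of variants).
#' @param within_block_ld Target pairwise genotype correlation within a
#'   block, in `[0, 1)`.
#' @param maf_range Length-2 numeric, the minor-allele-frequency
#'   interval to draw block frequencies from; must lie within (0, 0.5].
#' @param seed Integer seed; the panel is a pure function of its
#'   arguments and this seed.
#' @return An object of class `reference_panel`: list with `n_samples`,
#'   `variants` (data.frame: chrom, pos, id, ref, alt, block, af),
#'   `dosages` (samples x variants integer matrix, columns named by
#'   variant id), and `block` (variant id -> block id vector).
#' @examples
#' p <- simulate_reference_panel(200, blocks = c(5, 5),
#'                               within_block_ld = 0.6, seed = 1)
#' dim(p$dosages)
#' @export
simulate_reference_panel <- function(n_samples, blocks,
                                     within_block_ld = 0,
                                     maf_range = c(0.05, 0.5),
                                     seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 2)
    stop("'n_samples' must be >= 2")
  if (!is.numeric(blocks) || length(blocks) < 1L || any(blocks < 1))
    stop("'blocks' must be a vector of positive block sizes")
  if (!is.numeric(within_block_ld) || within_block_ld < 0 ||
      within_block_ld >= 1)
    stop("'within_block_ld' must lie in [0, 1)")
  if (length(maf_range) != 2L || maf_range[1] <= 0 ||
      maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("'maf_range' must be an interval within (0, 0.5]")
  n_samples <- as.integer(n_samples)
  blocks <- as.integer(blocks)

  withr::with_seed(as.integer(seed), {
    n_hap <- 2L * n_samples
    cols <- vector("list", length(blocks))
    afs <- numeric(0)
    for (b in seq_along(blocks)) {
      k <- blocks[b]
      f <- runif(1, maf_range[1], maf_range[2])
      lam <- .latent_ld(within_block_ld, f)
      q <- qnorm(f)
      # haplotype alleles: shared block factor + idiosyncratic noise
      draw_block <- function() {
        u <- rnorm(n_hap)
        x <- sqrt(lam) * u + sqrt(1 - lam) *
          matrix(rnorm(n_hap * k), n_hap, k)
        h <- (x < q) + 0L
        h[seq_len(n_samples), , drop = FALSE] +
          h[n_samples + seq_len(n_samples), , drop = FALSE]
      }
      g <- draw_block()
      # redraw monomorphic columns: the panel excludes fixed sites
      for (tries in 1:50) {
        mono <- apply(g, 2, function(v) length(unique(v)) == 1L)
        if (!any(mono)) break
        g2 <- draw_block()
        g[, mono] <- g2[, mono, drop = FALSE]
      }
      if (any(apply(g, 2, function(v) length(unique(v)) == 1L)))
        stop("could not generate polymorphic variants; ",
             "increase n_samples or maf_range")
      cols[[b]] <- g
      afs <- c(afs, rep(f, k))
    }
    dosages <- do.call(cbind, cols)
    m <- ncol(dosages)
    # non-palindromic ref/alt pairs so harmonization keeps every site
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                   c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
    pick <- sample.int(nrow(pairs), m, replace = TRUE)
    block_id <- rep(seq_along(blocks), times = blocks)
    pos <- 1e6 * block_id + 1e3 * stats::ave(block_id, block_id,
                                             FUN = seq_along)
    variants <- data.frame(
      chrom = "chr1",
      pos = as.integer(pos),
      id = paste0("v", seq_len(m)),
      ref = pairs[pick, 1],
      alt = pairs[pick, 2],
      block = block_id,
      af = afs,
      stringsAsFactors = FALSE
    )
    colnames(dosages) <- variants$id
    rownames(dosages) <- paste0("s", seq_len(n_samples))
    structure(list(n_samples = n_samples, variants = variants,
                   dosages = dosages,
                   block = stats::setNames(block_id, variants$id)),
              class = "reference_panel")
  })
}

# Solve for the latent-normal correlation giving a target genotype
# (phi) correlation at threshold frequency f.  P(X<q, Y<q) under
# correlation lam is evaluated by one-dimensional quadrature.
.latent_ld <- function(target, f) {
  if (target == 0) return(0)
  q <- qnorm(f)
  p11 <- function(lam) {
    integrate(function(x) dnorm(x) * pnorm((q - lam * x) / sqrt(1 - lam^2)),
              -Inf, q, rel.tol = 1e-10)$value
  }
  phi <- function(lam) (p11(lam) - f^2) / (f * (1 - f))
  uniroot(function(l) phi(l) - target, c(1e-9, 1 - 1e-6),
          tol = 1e-9)$root
}

#' @export
print.reference_panel <- function(x, ...) {
  cat(sprintf("reference_panel: %d samples, %d variants in %d blocks\n",
              x$n_samples, nrow(x$variants), length(unique(x$block))))
  invisible(x)
}

#' Simulation specification for a paired GWAS
#'
#' Describes the causal configuration of a two-trait quantitative GWAS
#' simulated on a shared-sample cohort.
#'
#' @param config One of `"null"`, `"trait1_only"`, `"trait2_only"`,
#'   `"shared"`, `"distinct"`.
#' @param causal1,causal2 Variant ids of the causal variants for trait 1
#'   and trait 2 (`shared` uses `causal1` for both; `distinct` requires
#'   two different ids).
#' @param effect1,effect2 Per-alt-allele effect sizes on the trait scale.
#' @param n Per-trait sample size (the cohorts fully overlap).
#' @param overlap_cor Cohort-overlap correlation `C` in `[-1, 1]`:
#'   the trait-noise correlation on the shared samples, which equals the
#'   null Z-score correlation between the two scans.
#' @param seed Integer seed.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(config = c("null", "trait1_only", "trait2_only",
                                       "shared", "distinct"),
                            causal1 = NULL, causal2 = NULL,
                            effect1 = 0, effect2 = 0,
                            n = 1000L, overlap_cor = 0, seed = 1L) {
  config <- match.arg(config)
  if (n < 2) stop("'n' must be >= 2")
  if (abs(overlap_cor) > 1) stop("'overlap_cor' must lie in [-1, 1]")
  if (config == "shared") {
    if (is.null(causal1)) stop("shared configuration needs 'causal1'")
    causal2 <- causal1
  }
  if (config == "distinct") {
    if (is.null(causal1) || is.null(causal2) ||
        identical(causal1, causal2))
      stop("distinct configuration needs two different causal ids")
  }
  structure(list(config = config, causal1 = causal1, causal2 = causal2,
                 effect1 = effect1, effect2 = effect2,
                 n = as.integer(n), overlap_cor = overlap_cor,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

.panel_dose <- function(panel, id) {
  if (!id %in% colnames(panel$dosages))
    stop("causal variant '", id, "' not present in panel")
  panel$dosages[, id]
}

#' Marginal association scan of a phenotype over dosage columns
#'
#' Vectorized per-variant simple linear regression of a quantitative
#' phenotype on each dosage column: slope, SE, two-sided t-test P and
#' sample size, in column order.
#'
#' @param dosages Samples x variants dosage matrix.
#' @param y Phenotype vector.
#' @return data.frame with columns beta, se, p, n (one row per
#'   variant).
#' @export
marginal_scan <- function(dosages, y) {
  n <- length(y)
  xc <- scale(dosages, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(xc^2)
  sxy <- as.vector(crossprod(xc, yc))
  beta <- sxy / sxx
  rss <- sum(yc^2) - beta * sxy
  sigma2 <- pmax(rss, 0) / (n - 2)
  se <- sqrt(sigma2 / sxx)
  tval <- beta / se
  p <- 2 * pt(-abs(tval), df = n - 2)
  data.frame(beta = beta, se = se, p = p, n = n)
}

#' Simulate paired GWAS summary statistics on one panel
#'
#' Quantitative phenotypes for two traits are generated on fully shared
#' samples as `y_t = effect_t * dosage(causal_t) + e_t`, with the noise
#' pair drawn bivariate normal (unit variance, correlation
#' `overlap_cor`).  Each trait is then scanned by per-variant marginal
#' linear regression, yielding the usual beta/SE/P summary table with
#' the panel's alt allele as effect allele.
#'
#' @param panel A [simulate_reference_panel()] object.
#' @param spec A [simulation_spec()].
#' @return List of two data.frames (`trait1`, `trait2`), each with
#'   columns chrom, pos, id, ea, nea, beta, se, p, n.
#' @export
simulate_gwas_pair <- function(panel, spec) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(spec, "simulation_spec"))
  if (spec$n > panel$n_samples)
    stop("spec n (", spec$n, ") exceeds panel samples (",
         panel$n_samples, ")")
  idx <- seq_len(spec$n)
  withr::with_seed(child_seed(spec$seed, 11L), {
    g1 <- g2 <- rep(0, spec$n)
    if (spec$config %in% c("trait1_only", "shared", "distinct"))
      g1 <- spec$effect1 * .panel_dose(panel, spec$causal1)[idx]
    if (spec$config %in% c("trait2_only", "shared", "distinct"))
      g2 <- spec$effect2 * .panel_dose(panel, spec$causal2)[idx]
    C <- spec$overlap_cor
    e1 <- rnorm(spec$n)
    e2 <- C * e1 + sqrt(1 - C^2) * rnorm(spec$n)
    y1 <- g1 + e1
    y2 <- g2 + e2
    d <- panel$dosages[idx, , drop = FALSE]
    base <- panel$variants[, c("chrom", "pos", "id")]
    base$ea <- panel$variants$alt
    base$nea <- panel$variants$ref
    t1 <- cbind(base, marginal_scan(d, y1))
    t2 <- cbind(base, marginal_scan(d, y2))
    rownames(t1) <- rownames(t2) <- NULL
    list(trait1 = t1, trait2 = t2)
  })
}

#' Simulate a cis-eQTL study with explicit covariates
#'
#' Expression is generated as `effect * dosage(causal) + Z gamma +
#' noise` where `Z` is a matrix of `n_covariates` standard-normal
#' covariates with N(0, 0.5^2) effects and the noise is standard
#' normal.  Covariates are returned so downstream methods can adjust
#' for them explicitly.
#'
#' @param panel A reference panel.
#' @param causal_id Variant id of the causal eQTL (effect may be 0 for
#'   a null study).
#' @param effect Per-alt-allele effect on expression.
#' @param n_covariates Number of simulated covariates (>= 0).
#' @param seed Integer seed.
#' @param n Number of samples to use (default: all panel samples).
#' @return List with `dosages` (samples x variants), `expression`
#'   (vector), `covariates` (matrix, 0 columns allowed), `causal_id`.
#' @export
simulate_eqtl_study <- function(panel, causal_id, effect,
                                n_covariates = 3L, seed = 1L,
                                n = panel$n_samples) {
  stopifnot(inherits(panel, "reference_panel"))
  dose <- .panel_dose(panel, causal_id)
  if (n > panel$n_samples) stop("'n' exceeds panel samples")
  idx <- seq_len(n)
  withr::with_seed(child_seed(seed, 23L), {
    Z <- matrix(rnorm(n * n_covariates), n, n_covariates)
    gamma <- if (n_covariates > 0) rnorm(n_covariates, 0, 0.5) else numeric(0)
    expr <- effect * dose[idx] +
      (if (n_covariates > 0) as.vector(Z %*% gamma) else 0) + rnorm(n)
    list(dosages = panel$dosages[idx, , drop = FALSE],
         expression = expr,
         covariates = Z,
         causal_id = causal_id)
  })
}

#' Simulate a genotype / cis-gene / trans-gene triplet
#'
#' Generates one of the three mediation structures distinguished by the
#' causal inference test, with unit-variance Gaussian noise:
#' \describe{
#'   \item{causal}{`G = a L + e1`, `T = b G + e2` (variant acts on the
#'     trans gene through the cis gene).}
#'   \item{reactive}{`T = a L + e1`, `G = b T + e2` (cis expression
#'     reacts to the trans gene).}
#'   \item{independent}{`G = a L + e1`, `T = c L + e3` with independent
#'     noises (the variant affects both, no mediation).}
#' }
#'
#' @param panel A reference panel supplying the dosage vector.
#' @param model `"causal"`, `"reactive"` or `"independent"`.
#' @param effects Named list/vector with `a`, `b` (and `c` for the
#'   independent model).
#' @param variant_id Panel variant to use as `L` (default: first).
#' @param seed Integer seed.
#' @param n Samples to use (default all).
#' @return List with vectors `L`, `G`, `T` and the ids used.
#' @export
simulate_triplet <- function(panel, model = c("causal", "reactive",
                                              "independent"),
                             effects = list(a = 1, b = 1, c = 1),
                             variant_id = NULL, seed = 1L,
                             n = panel$n_samples) {
  stopifnot(inherits(panel, "reference_panel"))
  model <- match.arg(model)
  effects <- as.list(effects)
  for (nm in c("a", "b", "c"))
    if (!is.null(effects[[nm]]) && !is.finite(effects[[nm]]))
      stop("effect '", nm, "' must be finite")
  variant_id <- variant_id %||% panel$variants$id[1]
  L <- .panel_dose(panel, variant_id)[seq_len(n)]
  withr::with_seed(child_seed(seed, 37L), {
    a <- effects$a %||% 1; b <- effects$b %||% 1; cc <- effects$c %||% 1
    if (model == "causal") {
      G <- a * L + rnorm(n)
      Tv <- b * G + rnorm(n)
    } else if (model == "reactive") {
      Tv <- a * L + rnorm(n)
      G <- b * Tv + rnorm(n)
    } else {
      G <- a * L + rnorm(n)
      Tv <- cc * L + rnorm(n)
    }
    list(L = L, G = G, T = Tv, variant_id = variant_id, model = model)
  })
}

#' Simulate long/short promoter-group expression driven by genotype
#'
#' Emulates an alternative-promoter usage QTL: each alt-allele copy
#' shifts expression away from the long-transcript group and toward the
#' short-transcript group by `usage_effect` TPM, around the supplied
#' baselines, plus Gaussian noise.  The reciprocal structure means a
#' positive usage effect produces a positive short-group and negative
#' long-group dosage slope.
#'
#' @param dosages Numeric dosage vector in \{0,1,2\}.
#' @param usage_effect TPM shift per alt allele (>= 0 for the canonical
#'   short-up/long-down pattern).
#' @param baseline_tpm Named numeric `c(long = , short = )`, both >= 0.
#' @param noise_sd Residual SD in TPM units.
#' @param seed Integer seed.
#' @return data.frame with per-sample columns `long` and `short`.
#' @export
simulate_transcript_usage <- function(dosages, usage_effect,
                                      baseline_tpm = c(long = 50, short = 30),
                                      noise_sd = 5, seed = 1L) {
  if (any(baseline_tpm < 0)) stop("'baseline_tpm' must be >= 0")
  n <- length(dosages)
  withr::with_seed(child_seed(seed, 53L), {
    long <- baseline_tpm[["long"]] - usage_effect * dosages +
      rnorm(n, 0, noise_sd)
    short <- baseline_tpm[["short"]] + usage_effect * dosages +
      rnorm(n, 0, noise_sd)
    data.frame(long = long, short = short)
  })
}
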