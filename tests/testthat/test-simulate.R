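test_that("reference panel generation is deterministic and validates inputs", {
  p1 <- simulate_reference_panel(100, blocks = c(3, 2), seed = 5)
  p2 <- simulate_reference_panel(100, blocks = c(3, 2), seed = 5)
  expect_identical(p1$dosages, p2$dosages)
  expect_true(all(p1$dosages %in% 0:2))
  expect_false(any(duplicated(paste(p1$variants$chrom, p1$variants$pos))))
  # no monomorphic sites
  expect_true(all(apply(p1$dosages, 2, var) > 0))

  expect_error(simulate_reference_panel(1, blocks = 3), "n_samples")
  expect_error(simulate_reference_panel(10, blocks = 0), "blocks")
  expect_error(simulate_reference_panel(10, blocks = 3,
                                        maf_range = c(0, 0.6)),
               "maf_range")
})

test_that("within- and across-block LD match the generator's target", {
  p0 <- simulate_reference_panel(2000, blocks = c(5, 5),
                                 within_block_ld = 0, seed = 2)
  r <- cor(p0$dosages)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.1)

  p8 <- fixture_panel("ld08", 5000, blocks = c(5, 5),
                      within_block_ld = 0.8, seed = 3)
  within <- c(cor(p8$dosages[, 1:5])[upper.tri(diag(5))],
              cor(p8$dosages[, 6:10])[upper.tri(diag(5))])
  expect_lt(abs(mean(within) - 0.8), 0.1)
  across <- cor(p8$dosages[, 1:5], p8$dosages[, 6:10])
  expect_lt(mean(abs(across)), 0.1)
})

test_that("paired GWAS simulation is calibrated under the null", {
  panel <- fixture_panel("gwas", 2000, blocks = rep(10, 2),
                         within_block_ld = 0.3, seed = 42)
  ps <- unlist(lapply(1:25, function(s) {
    g <- simulate_gwas_pair(panel, simulation_spec("null", n = 2000,
                                                   seed = s))
    g$trait1$p
  }))
  expect_lt(abs(mean(ps < 0.05) - 0.05), 0.03)

  # cohort overlap: null Z-score correlation tracks C
  zz <- sapply(1:40, function(s) {
    g <- simulate_gwas_pair(panel, simulation_spec("null", n = 2000,
                                                   overlap_cor = 0.4,
                                                   seed = 100 + s))
    cbind(g$trait1$beta / g$trait1$se, g$trait2$beta / g$trait2$se)
  })
  z1 <- as.vector(zz[1:20, ]); z2 <- as.vector(zz[21:40, ])
  expect_lt(abs(cor(z1, z2) - 0.4), 0.1)
})

test_that("a shared causal variant dominates both scans", {
  panel <- fixture_panel("gwas", 2000, blocks = rep(10, 2),
                         within_block_ld = 0.3, seed = 42)
  hits <- sapply(1:20, function(s) {
    sp <- simulation_spec("shared", causal1 = "v5", effect1 = 0.5,
                          effect2 = 0.5, n = 2000, seed = s)
    g <- simulate_gwas_pair(panel, sp)
    which.min(g$trait1$p) == 5 && which.min(g$trait2$p) == 5
  })
  expect_gte(mean(hits), 0.9)
  expect_error(
    simulate_gwas_pair(panel, simulation_spec("shared", causal1 = "nope",
                                              effect1 = 1, n = 100)),
    "nope")
})

test_that("eQTL study recovers its causal variant and is seed-stable", {
  panel <- fixture_panel("eqtl", 500, blocks = rep(5, 3),
                         within_block_ld = 0.5, seed = 9)
  a <- simulate_eqtl_study(panel, "v8", effect = 1, seed = 4)
  b <- simulate_eqtl_study(panel, "v8", effect = 1, seed = 4)
  expect_identical(a$expression, b$expression)

  ok <- sapply(1:40, function(s) {
    st <- simulate_eqtl_study(panel, "v8", effect = 1, seed = s)
    scan <- marginal_scan(st$dosages, st$expression)
    lead <- panel$variants$id[which.min(scan$p)]
    if (lead == "v8") return(TRUE)
    cor(panel$dosages[, lead], panel$dosages[, "v8"])^2 > 0.8
  })
  expect_gte(mean(ok), 0.95)

  # null effect: causal-variant P is uniform across seeds
  pnull <- sapply(1:100, function(s) {
    st <- simulate_eqtl_study(panel, "v8", effect = 0, n_covariates = 0,
                              seed = 500 + s)
    marginal_scan(st$dosages[, "v8", drop = FALSE], st$expression)$p
  })
  expect_gt(suppressWarnings(ks.test(pnull, "punif"))$p.value, 0.01)
})

test_that("triplet generator matches its closed-form dependence structure", {
  panel <- fixture_panel("trip", 5000, blocks = 2, seed = 13)
  # zero effects: all three mutually independent
  t0 <- simulate_triplet(panel, "causal", list(a = 0, b = 0), seed = 1)
  expect_lt(abs(cor(t0$L, t0$G)), 0.05)
  expect_lt(abs(cor(t0$G, t0$T)), 0.05)
  expect_lt(abs(cor(t0$L, t0$T)), 0.05)

  # independent model: partial correlation of L and T given G stays
  # nonzero; oracle = closed form from the generating covariances
  ti <- simulate_triplet(panel, "independent", list(a = 1, c = 1), seed = 2)
  v <- var(ti$L)
  rLT <- v / sqrt(v * (v + 1)); rLG <- rLT
  rGT <- v / (v + 1)
  oracle <- (rLT - rLG * rGT) / sqrt((1 - rLG^2) * (1 - rGT^2))
  pc <- (cor(ti$L, ti$T) - cor(ti$L, ti$G) * cor(ti$G, ti$T)) /
    sqrt((1 - cor(ti$L, ti$G)^2) * (1 - cor(ti$G, ti$T)^2))
  expect_gt(oracle, 0.3)
  expect_lt(abs(pc - oracle), 0.05)

  expect_error(simulate_triplet(panel, "causal",
                                list(a = Inf, b = 1)), "finite")
})

test_that("transcript-usage generator shows the reciprocal dosage effect", {
  panel <- fixture_panel("usage", 200, blocks = 1, seed = 17)
  dose <- panel$dosages[, 1]
  a <- simulate_transcript_usage(dose, usage_effect = 5, seed = 3)
  b <- simulate_transcript_usage(dose, usage_effect = 5, seed = 3)
  expect_identical(a, b)

  flips <- sapply(1:30, function(s) {
    u <- simulate_transcript_usage(dose, usage_effect = 5, seed = s)
    coef(lm(u$short ~ dose))[2] > 0 && coef(lm(u$long ~ dose))[2] < 0
  })
  expect_gte(mean(flips), 0.9)

  pnull <- sapply(1:200, function(s) {
    u <- simulate_transcript_usage(dose, usage_effect = 0, seed = 1000 + s)
    usage_qtl(dose, u$short)$p
  })
  expect_gt(suppressWarnings(ks.test(pnull, "punif"))$p.value, 0.01)

  expect_error(simulate_transcript_usage(dose, 1,
                                         baseline_tpm = c(long = -1,
                                                          short = 2)),
               "baseline")
})
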