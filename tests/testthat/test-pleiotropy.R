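test_that("MeSH relationship level is the common tree-number prefix", {
  expect_equal(mesh_relationship_level("C06.405.469.432.249",
                                       "C06.405.469.432.500"), 4L)
  expect_equal(mesh_relationship_level("C06.405.469.432.249",
                                       "C06.405.469.432.249"), 5L)
  expect_equal(mesh_relationship_level("C06.405", "C17.800"), 0L)
  # cap at 5 even for deeper identical numbers
  deep <- "C06.405.469.432.249.100"
  expect_equal(mesh_relationship_level(deep, deep), 5L)
  expect_error(mesh_tree_number(""), "non-empty")
  expect_error(mesh_tree_number("C06..405"), "unparseable")
})

test_that("expected overlap correlation follows the 0.09-per-level ladder", {
  expect_equal(expected_correlation(4, "same-cohort"), 0.36)
  expect_equal(expected_correlation(0, "same-cohort"), 0)
  expect_equal(expected_correlation(5, "same-cohort"), 0.45)
  expect_equal(expected_correlation(7, "same-cohort"), 0.45)  # capped
  for (lvl in 0:5)
    expect_equal(expected_correlation(lvl, "distinct-cohort"), 0)
  expect_error(expected_correlation(-1), "level")
})

test_that("joint shared-effect BF factorizes at C = 0 and is symmetric", {
  set.seed(3)
  for (i in 1:10) {
    z1 <- rnorm(1, 0, 3); z2 <- rnorm(1, 0, 3)
    V1 <- runif(1, 1e-4, 0.05); V2 <- runif(1, 1e-4, 0.05)
    joint <- joint_log_abf_shared(z1, z2, V1, V2, C = 0)
    marg <- wakefield_log_abf(z1 * sqrt(V1), sqrt(V1)) +
      wakefield_log_abf(z2 * sqrt(V2), sqrt(V2))
    expect_equal(joint, marg, tolerance = 1e-10)
    # trait-order symmetry
    expect_equal(joint_log_abf_shared(z1, z2, V1, V2, 0.3, 0.04, 0.09),
                 joint_log_abf_shared(z2, z1, V2, V1, 0.3, 0.09, 0.04),
                 tolerance = 1e-12)
  }
  expect_equal(joint_log_abf_shared(0, 0, 0.01, 0.01, 0),
               2 * wakefield_log_abf(0, 0.1), tolerance = 1e-12)
  expect_error(joint_log_abf_shared(1, 1, 0.01, 0.01, C = 1), "C")
})

test_that("block posteriors favour the generating model", {
  k <- 8
  # all BFs equal 1: the null dominates under default priors
  flat <- block_model_posteriors(rep(0, k), rep(0, k), rep(0, k))
  expect_gt(flat$pp0, 0.99)
  expect_equal(flat$pp0 + flat$pp1 + flat$pp2 + flat$pp3 + flat$pp4, 1,
               tolerance = 1e-10)

  # one variant huge in both traits: shared model wins
  big <- rep(0, k); big[3] <- 30   # log BF scale of |z| near 8
  shared <- block_model_posteriors(big, big, 2 * big)
  pps <- unlist(shared)
  expect_equal(unname(which.max(pps)), 4L)  # pp3

  # two different variants huge in one trait each: distinct model wins
  b1 <- rep(0, k); b1[2] <- 30
  b2 <- rep(0, k); b2[6] <- 30
  joint <- pmin(b1, b2)  # no single variant strong in both
  distinct <- block_model_posteriors(b1, b2, joint)
  expect_equal(unname(which.max(unlist(distinct))), 5L)  # pp4

  expect_error(block_model_posteriors(numeric(0), numeric(0),
                                      numeric(0)), "length")
})

test_that("posterior normalization holds for fuzzed log-BF inputs", {
  set.seed(11)
  for (i in 1:25) {
    k <- sample(1:40, 1)
    post <- block_model_posteriors(rnorm(k, 0, 10), rnorm(k, 0, 10),
                                   rnorm(k, 0, 10))
    pps <- unlist(post)
    expect_equal(sum(pps), 1, tolerance = 1e-10)
    expect_true(all(pps >= 0 & pps <= 1))
  }
})

test_that("shared-effect call uses an inclusive 0.9 bound", {
  mk <- function(pp3) {
    rest <- (1 - pp3) / 4
    structure(list(pp0 = rest, pp1 = rest, pp2 = rest, pp3 = pp3,
                   pp4 = rest), class = "model_posteriors")
  }
  expect_true(is_shared_effect(mk(0.95)))
  expect_true(is_shared_effect(mk(0.9)))
  expect_false(is_shared_effect(mk(0.89)))
})

test_that("modelling the overlap correlation lowers the false shared rate", {
  # correlated null z-scores (C = 0.45, 100 independent variants);
  # liberal priors so that miscalibration produces observable false
  # positives at desk scale
  C <- 0.45; k <- 100; se <- 0.03
  pri <- pleiotropy_priors(1e-3, 1e-3, 5e-2, 5e-3)
  run <- function(seed, C_used) {
    set.seed(seed)
    z1 <- rnorm(k); z2 <- C * z1 + sqrt(1 - C^2) * rnorm(k)
    labf1 <- wakefield_log_abf(z1 * se, rep(se, k))
    labf2 <- wakefield_log_abf(z2 * se, rep(se, k))
    labfj <- joint_log_abf_shared(z1, z2, se^2, se^2, C_used)
    block_model_posteriors(labf1, labf2, labfj, pri)$pp3
  }
  miscal <- sapply(1:1000, function(s) run(s, 0))
  correct <- sapply(1:1000, function(s) run(s, C))
  expect_lt(mean(correct >= 0.5), mean(miscal >= 0.5))
  # paired per-seed dominance of the correction
  expect_gt(mean(correct <= miscal), 0.75)
})

test_that("pleiotropy_scan wires harmonized tables into posteriors", {
  panel <- fixture_panel("gwas", 2000, blocks = rep(10, 2),
                         within_block_ld = 0.3, seed = 42)
  sp <- simulation_spec("shared", causal1 = "v5", effect1 = 0.35,
                        effect2 = 0.35, n = 2000, seed = 4)
  g <- simulate_gwas_pair(panel, sp)
  post <- pleiotropy_scan(g$trait1, g$trait2)
  expect_true(is_shared_effect(post))
  expect_error(pleiotropy_scan(g$trait1[0, ], g$trait2), "shared")
})
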