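test_that("SE recovery from P inverts the two-sided normal test", {
  expect_equal(estimate_se_from_p(0.2, 0.3173105), 0.2, tolerance = 1e-6)
  # frozen from an independent quantile evaluation (scipy.stats.norm.ppf)
  expect_equal(estimate_se_from_p(0.1, 0.05), 0.0510213456924654,
               tolerance = 1e-12)
  expect_error(estimate_se_from_p(0.1, 1), "p")
  expect_error(estimate_se_from_p(0.1, 0), "p")
  expect_error(estimate_se_from_p(0, 0.05), "beta")

  # round trip p -> se -> z -> p across the full floating range
  p <- 10^seq(-300, log10(0.999), length.out = 60)
  se <- estimate_se_from_p(0.37, p)
  z <- 0.37 / se
  p_back <- 2 * pnorm(abs(z), lower.tail = FALSE)
  expect_equal(p_back, p, tolerance = 1e-10)
})

test_that("odds ratios convert to log-scale effects", {
  x <- or_to_beta(1.5, ci_lower = 1.2, ci_upper = 1.875)
  expect_equal(x$beta, log(1.5))
  expect_equal(x$se, (log(1.875) - log(1.2)) / (2 * qnorm(0.975)))
  y <- or_to_beta(1.5, p = 0.01)
  expect_equal(y$se, estimate_se_from_p(log(1.5), 0.01))
  expect_error(or_to_beta(-1, p = 0.5), "positive")
  expect_error(or_to_beta(1.5), "supply")
})

test_that("harmonization aligns alleles, flips signs/strands, drops the rest", {
  panel <- toy_panel()  # rs1 A/G, rs2 A/C, rs3 G/T, rs4 C/T, rs5 A/G
  rec <- rbind(
    toy_record(100, "G", "A", beta = 0.3),   # ea == alt: kept as is
    toy_record(200, "A", "C", beta = 0.3),   # ea == ref: sign flip
    toy_record(300, "A", "C", beta = 0.2),   # complement of T/G: strand flip
    toy_record(400, "G", "A", beta = 0.2),   # complement of C/T: strand+sign
    toy_record(500, "A", "T", beta = 0.1)    # palindromic: dropped
  )
  out <- harmonize_to_panel(rec, panel)
  expect_equal(out$report$kept + sum(out$report$dropped),
               out$report$input)
  expect_equal(out$report$kept, 4L)
  expect_equal(out$report$dropped[["ambiguous_palindromic"]], 1L)
  h <- out$records
  expect_equal(h$beta[h$pos == 100], 0.3)
  expect_equal(h$beta[h$pos == 200], -0.3)
  expect_equal(h$beta[h$pos == 300], 0.2)
  expect_equal(h$beta[h$pos == 400], -0.2)
  # all records now alt-oriented
  expect_equal(h$ea, panel$variants$alt[match(h$pos, panel$variants$pos)])

  # idempotence: re-harmonizing changes nothing
  out2 <- harmonize_to_panel(h, panel)
  expect_equal(out2$records$beta, h$beta)
  expect_equal(out2$report$sign_flipped, 0L)
  expect_equal(out2$report$strand_flipped, 0L)

  expect_error(harmonize_to_panel(rbind(toy_record(100, "G", "A"),
                                        toy_record(100, "A", "G")),
                                  panel),
               "duplicate")
})

test_that("harmonization report is conserved on fuzzed tables", {
  panel <- toy_panel()
  set.seed(1)
  for (i in 1:10) {
    k <- sample(2:5, 1)
    pos <- sample(c(100, 200, 300, 400, 500, 999), k)
    rec <- do.call(rbind, lapply(pos, function(p)
      toy_record(p, sample(c("A", "C", "G", "T"), 1),
                 sample(c("A", "C", "G", "T"), 1))))
    out <- harmonize_to_panel(rec, panel)
    expect_equal(out$report$kept + sum(out$report$dropped), k)
  }
})

test_that("non-effect alleles are inferred only at matching biallelic sites", {
  panel <- toy_panel()
  rec <- toy_record(100, "A", NA)            # A at A/G site -> nea G
  out <- infer_noneffect_allele(rec, panel)
  expect_equal(out$records$nea, "G")

  rec2 <- toy_record(100, "C", NA)           # C not at A/G site -> drop
  out2 <- infer_noneffect_allele(rec2, panel)
  expect_equal(nrow(out2$records), 0L)
  expect_equal(out2$dropped$reason, "effect_allele_not_at_site")

  # multi-allelic site: duplicate panel entry at one position
  panel2 <- panel
  extra <- panel$variants[1, ]; extra$alt <- "C"
  panel2$variants <- rbind(panel$variants, extra)
  out3 <- infer_noneffect_allele(toy_record(100, "A", NA), panel2)
  expect_equal(out3$dropped$reason, "multiallelic_site")
})

test_that("genomic intervals use 1-based inclusive arithmetic", {
  expect_equal(interval_length(genomic_interval("chr1", 5, 5)), 1L)
  expect_error(genomic_interval("chr1", 10, 5), "start")
  iv <- genomic_interval("chr2", 10, 20)
  expect_true(interval_contains(iv, "chr2", 10))
  expect_false(interval_contains(iv, "chr2", 21))
  expect_false(interval_contains(iv, "chr3", 15))
})

test_that("TSV/VCF/BED round trips preserve content and conventions", {
  panel <- simulate_reference_panel(30, blocks = c(3, 2), seed = 8)
  tmp <- withr::local_tempdir()

  f <- file.path(tmp, "ss.tsv")
  g <- simulate_gwas_pair(panel, simulation_spec("null", n = 30, seed = 1))
  suppressMessages(write_sumstats(g$trait1, f))
  back <- suppressMessages(read_sumstats(f))
  expect_equal(back$beta, g$trait1$beta)
  expect_equal(back$id, g$trait1$id)

  v <- file.path(tmp, "p.vcf")
  suppressMessages(write_panel_vcf(panel, v))
  pv <- suppressMessages(read_panel_vcf(v))
  expect_equal(unname(pv$dosages), unname(panel$dosages))
  expect_equal(pv$variants$ref, panel$variants$ref)

  b <- file.path(tmp, "iv.bed")
  iv <- data.frame(chrom = "chr7", start = 128573817, end = 128574098,
                   name = "reporter")
  suppressMessages(write_bed(iv, b))
  raw <- read.delim(b, header = FALSE)
  expect_equal(raw$V2, 128573816)  # 0-based start on disk
  bk <- suppressMessages(read_bed(b))
  expect_equal(bk$start, 128573817)
  expect_equal(bk$end, 128574098)

  d <- file.path(tmp, "dose.tsv")
  suppressMessages(write_dosage_tsv(panel, d))
  raw_d <- read.delim(d)
  expect_equal(nrow(raw_d), ncol(panel$dosages))
})
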