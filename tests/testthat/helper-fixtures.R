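# Shared synthetic fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

fixture_panel <- function(key, ...) {
  if (is.null(.fixture_cache[[key]]))
    .fixture_cache[[key]] <- simulate_reference_panel(...)
  .fixture_cache[[key]]
}

# tiny hand-built panel for harmonization tests: one chromosome,
# explicit ref/alt pairs
toy_panel <- function() {
  variants <- data.frame(
    chrom = "chr1",
    pos = c(100L, 200L, 300L, 400L, 500L),
    id = paste0("rs", 1:5),
    ref = c("A", "A", "G", "C", "A"),
    alt = c("G", "C", "T", "T", "G"),
    block = 1L,
    af = 0.3,
    stringsAsFactors = FALSE
  )
  dosages <- matrix(rep(c(0L, 1L, 2L, 1L), 5), nrow = 4,
                    dimnames = list(paste0("s", 1:4), variants$id))
  structure(list(n_samples = 4L, variants = variants,
                 dosages = dosages,
                 block = stats::setNames(variants$block, variants$id)),
            class = "reference_panel")
}

toy_record <- function(pos, ea, nea, beta = 0.1, id = paste0("rs", pos %/% 100)) {
  data.frame(chrom = "chr1", pos = pos, id = id, ea = ea, nea = nea,
             beta = beta, se = 0.02, p = 1e-6, n = 1000L,
             stringsAsFactors = FALSE)
}
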