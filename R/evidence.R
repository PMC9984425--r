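.regulomedb_vocab <- c("1a", "1b", "1c", "1d", "1e", "1f",
                       "2a", "2b", "2c", "3a", "3b", "4", "5", "6", "7")

#' Compare RegulomeDB categories on the evidence ladder
#'
#' RegulomeDB categories are ordered 1a (strongest regulatory
#' evidence) through 7 (weakest).  A variant passes a threshold when
#' its category is at least as strong as the threshold, i.e. its index
#' in the ladder is less than or equal to the threshold's (inclusive).
#'
#' @param category Observed category string.
#' @param threshold Threshold category (default `"2c"`).
#' @return Logical.
#' @export
regulomedb_at_least <- function(category, threshold = "2c") {
  i <- match(category, .regulomedb_vocab)
  j <- match(threshold, .regulomedb_vocab)
  if (any(is.na(i))) stop("unknown RegulomeDB category: ",
                          paste(category[is.na(i)], collapse = ", "))
  if (is.na(j)) stop("unknown RegulomeDB threshold: ", threshold)
  i <= j
}

#' Aggregate the four evidence conditions for candidate variants
#'
#' For each variant, four boolean flags are computed, all with
#' inclusive thresholds:
#' \enumerate{
#'   \item reproduced pleiotropy: shared-causal posterior `pp3 >= 0.9`
#'     for at least one trait pair;
#'   \item fine-mapped: membership in a 95\% credible set for at least
#'     one trait;
#'   \item colocalized: `RTC >= 0.9` for at least one eQTL dataset;
#'   \item regulatory: regBase PHRED `>= 15` and cepip combined
#'     `>= 0.6` and RegulomeDB category at least `2c`.
#' }
#' A variant absent from any evidence table simply fails that flag (a
#' logged gap, not an error).  Candidates are variants with all four
#' flags true; the shared-disease count is the number of distinct
#' diseases over the variant's pleiotropic (pp3-passing) pairs.
#'
#' @param variants data.frame with columns id, chrom, pos.
#' @param pleiotropy data.frame (id, disease1, disease2, pp3), one row
#'   per variant x trait pair.
#' @param finemap data.frame (id, trait, in_credible_set).
#' @param rtc data.frame (id, dataset, rtc).
#' @param scores data.frame (id, regbase_phred, cepip_combined,
#'   regulomedb).
#' @param pp3_threshold,rtc_threshold,phred_threshold,cepip_threshold,
#'   regulomedb_threshold Inclusive thresholds (defaults as printed
#'   above).
#' @return data.frame, one row per variant: the four flags,
#'   `shared_diseases`, and `candidate`.
#' @export
evidence_flags <- function(variants, pleiotropy, finemap, rtc, scores,
                           pp3_threshold = 0.9, rtc_threshold = 0.9,
                           phred_threshold = 15, cepip_threshold = 0.6,
                           regulomedb_threshold = "2c") {
  out <- variants[, c("id", "chrom", "pos")]
  n <- nrow(out)
  out$reproduced_pleiotropy <- logical(n)
  out$fine_mapped <- logical(n)
  out$colocalized <- logical(n)
  out$regulatory <- logical(n)
  out$shared_diseases <- integer(n)
  for (i in seq_len(n)) {
    id <- out$id[i]
    pl <- pleiotropy[pleiotropy$id == id & pleiotropy$pp3 >= pp3_threshold, ]
    out$reproduced_pleiotropy[i] <- nrow(pl) > 0
    out$shared_diseases[i] <-
      length(unique(c(pl$disease1, pl$disease2)))
    fm <- finemap[finemap$id == id, ]
    out$fine_mapped[i] <- nrow(fm) > 0 && any(fm$in_credible_set)
    rt <- rtc[rtc$id == id, ]
    out$colocalized[i] <- nrow(rt) > 0 && any(rt$rtc >= rtc_threshold)
    sc <- scores[scores$id == id, ]
    out$regulatory[i] <- nrow(sc) > 0 &&
      any(sc$regbase_phred >= phred_threshold &
          sc$cepip_combined >= cepip_threshold &
          regulomedb_at_least(sc$regulomedb, regulomedb_threshold))
  }
  missing <- vapply(list(pleiotropy, finemap, rtc, scores),
                    function(tb) sum(!out$id %in% tb$id), 0L)
  if (any(missing > 0))
    message("evidence gaps (variants absent from a table): ",
            paste(c("pleiotropy", "finemap", "rtc", "scores")[missing > 0],
                  missing[missing > 0], sep = "=", collapse = ", "))
  out$candidate <- out$reproduced_pleiotropy & out$fine_mapped &
    out$colocalized & out$regulatory
  out
}

#' Rank candidate causal regulatory variants
#'
#' Candidates (all four evidence flags true) are ranked by descending
#' shared-disease count, with ties broken by (chrom, pos) ascending
#' for determinism.
#'
#' @param profiles An [evidence_flags()] table.
#' @return The candidate rows in rank order (possibly zero rows).
#' @export
rank_candidates <- function(profiles) {
  cand <- profiles[profiles$candidate, , drop = FALSE]
  if (nrow(cand) == 0) return(cand)
  cand[order(-cand$shared_diseases, cand$chrom, cand$pos), ,
       drop = FALSE]
}

#' Assign target genes to a variant
#'
#' Union of three evidence routes, each tagged by source: bait genes
#' of promoter-capture Hi-C interaction regions overlapping the
#' variant with interaction score strictly above 5; eGenes of
#' colocalized eQTLs; and genes whose protein function or splicing the
#' variant alters directly.
#'
#' @param chrom,pos Variant coordinate (1-based).
#' @param regions data.frame of interaction regions (chrom, start,
#'   end, bait_gene, score), 1-based inclusive.
#' @param egenes Character vector of colocalized eGenes (may be
#'   empty).
#' @param consequence_genes Character vector of directly affected
#'   genes (may be empty).
#' @param score_threshold Strict lower bound on the interaction score
#'   (default 5).
#' @return data.frame (gene, source); zero rows when nothing applies.
#' @export
assign_target_genes <- function(chrom, pos, regions = NULL,
                                egenes = character(0),
                                consequence_genes = character(0),
                                score_threshold = 5) {
  genes <- character(0); src <- character(0)
  if (!is.null(regions) && nrow(regions)) {
    need <- c("chrom", "start", "end", "bait_gene", "score")
    if (!all(need %in% names(regions)))
      stop("malformed interaction regions: need columns ",
           paste(need, collapse = ", "))
    hit <- regions$chrom == chrom & regions$start <= pos &
      regions$end >= pos & regions$score > score_threshold
    genes <- c(genes, regions$bait_gene[hit])
    src <- c(src, rep("PCHi-C", sum(hit)))
  }
  genes <- c(genes, egenes, consequence_genes)
  src <- c(src, rep("eQTL", length(egenes)),
           rep("consequence", length(consequence_genes)))
  out <- unique(data.frame(gene = genes, source = src,
                           stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}
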