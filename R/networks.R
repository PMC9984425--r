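#' Build the pleiotropic variant-gene bipartite network
#'
#' One edge per distinct (variant, gene) pair; each variant carries
#' the set of diseases it is associated with.  Edges never connect two
#' variants or two genes.
#'
#' @param triples data.frame with columns variant, gene, disease (one
#'   row per association; duplicates collapse).
#' @return A `bipartite_network`: list with `edges` (variant, gene),
#'   `variants`, `genes`, and `diseases` (named list variant -> disease
#'   set).
#' @export
build_bipartite <- function(triples) {
  need <- c("variant", "gene", "disease")
  if (!is.data.frame(triples) || !all(need %in% names(triples)))
    stop("triples must be a data.frame with columns variant, gene, disease")
  bad <- !stats::complete.cases(triples[need]) |
    triples$variant == "" | triples$gene == "" | triples$disease == ""
  if (any(bad)) stop("malformed triple(s) at row(s): ",
                     paste(which(bad), collapse = ", "))
  edges <- unique(triples[, c("variant", "gene")])
  rownames(edges) <- NULL
  diseases <- lapply(split(triples$disease, triples$variant), unique)
  structure(list(edges = edges,
                 variants = unique(triples$variant),
                 genes = unique(triples$gene),
                 diseases = diseases),
            class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("bipartite network: %d variants, %d genes, %d edges\n",
              length(x$variants), length(x$genes), nrow(x$edges)))
  invisible(x)
}

#' Compress a variant-gene network into a disease-gene network
#'
#' All pleiotropic variants of one disease collapse into a single
#' disease node; a disease-gene edge exists when some variant of that
#' disease targets the gene, weighted by the number of such variants.
#'
#' @param net A [build_bipartite()] network.
#' @return A `disease_gene_network`: list with `edges` (disease, gene,
#'   weight), `diseases`, `genes`.
#' @export
compress_by_disease <- function(net) {
  stopifnot(inherits(net, "bipartite_network"))
  unlabeled <- setdiff(net$variants, names(net$diseases))
  if (length(unlabeled))
    stop("variant(s) without disease label: ",
         paste(unlabeled, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(net$edges))) {
    v <- net$edges$variant[i]; g <- net$edges$gene[i]
    for (d in net$diseases[[v]])
      rows[[length(rows) + 1L]] <- data.frame(disease = d, gene = g,
                                              variant = v)
  }
  if (!length(rows)) {
    edges <- data.frame(disease = character(0), gene = character(0),
                        weight = integer(0))
  } else {
    all_rows <- unique(do.call(rbind, rows))
    agg <- stats::aggregate(variant ~ disease + gene, all_rows, length)
    edges <- data.frame(disease = agg$disease, gene = agg$gene,
                        weight = agg$variant)
  }
  structure(list(edges = edges,
                 diseases = unique(edges$disease),
                 genes = net$genes),
            class = "disease_gene_network")
}

#' Gene-sharing summary of a disease-gene network
#'
#' Counts genes connected to at least `min_diseases` distinct diseases
#' and reports the share among all genes, as a percentage rounded to
#' two decimals.
#'
#' @param dg_net A [compress_by_disease()] network.
#' @param min_diseases Minimum disease degree (default 3).
#' @return List with `n_shared`, `n_total`, `percentage`.
#' @export
shared_gene_summary <- function(dg_net, min_diseases = 3) {
  stopifnot(inherits(dg_net, "disease_gene_network"))
  n_total <- length(dg_net$genes)
  if (n_total == 0) stop("empty gene set")
  deg <- table(unique(dg_net$edges[, c("disease", "gene")])$gene)
  n_shared <- sum(deg >= min_diseases)
  list(n_shared = n_shared, n_total = n_total,
       percentage = round(100 * n_shared / n_total, 2))
}

#' Force-directed layout of a disease-gene network
#'
#' Plain Fruchterman-Reingold iteration on the disease-gene graph:
#' all node pairs repel with force `k^2/d`, connected pairs attract
#' with force `d^2/k`, where `k = sqrt(1/n)` is the natural spring
#' length, under a linearly cooling displacement cap.  Deterministic
#' for a fixed seed; an isolated single node stays at the origin, and
#' an isolated connected pair settles near separation `k` (the
#' fixed point where attraction balances repulsion).
#'
#' @param dg_net A [compress_by_disease()] network.
#' @param iterations Iteration count (default 300).
#' @param seed Integer seed for the random initial placement.
#' @return data.frame (node, type, x, y).
#' @export
force_layout <- function(dg_net, iterations = 300L, seed = 1L) {
  stopifnot(inherits(dg_net, "disease_gene_network"))
  nodes <- c(dg_net$diseases, dg_net$genes)
  type <- c(rep("disease", length(dg_net$diseases)),
            rep("gene", length(dg_net$genes)))
  n <- length(nodes)
  if (n == 0) return(data.frame(node = character(0),
                                type = character(0),
                                x = numeric(0), y = numeric(0)))
  if (n == 1) return(data.frame(node = nodes, type = type, x = 0, y = 0))
  ei <- cbind(match(dg_net$edges$disease, nodes),
              match(dg_net$edges$gene, nodes))
  k <- sqrt(1 / n)
  pos <- withr::with_seed(as.integer(seed),
                          matrix(runif(2 * n, -0.5, 0.5), n, 2))
  t0 <- 0.1
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2)
    for (i in seq_len(n - 1)) {
      dx <- pos[i, 1] - pos[(i + 1):n, 1]
      dy <- pos[i, 2] - pos[(i + 1):n, 2]
      d2 <- pmax(dx^2 + dy^2, 1e-12)
      d <- sqrt(d2)
      f <- k^2 / d2   # repulsion / distance
      disp[i, ] <- disp[i, ] + c(sum(f * dx), sum(f * dy))
      disp[(i + 1):n, ] <- disp[(i + 1):n, ] - cbind(f * dx, f * dy)
    }
    if (nrow(ei)) {
      dx <- pos[ei[, 1], 1] - pos[ei[, 2], 1]
      dy <- pos[ei[, 1], 2] - pos[ei[, 2], 2]
      d <- pmax(sqrt(dx^2 + dy^2), 1e-12)
      f <- d / k      # attraction / distance
      for (e in seq_len(nrow(ei))) {
        disp[ei[e, 1], ] <- disp[ei[e, 1], ] - f[e] * c(dx[e], dy[e])
        disp[ei[e, 2], ] <- disp[ei[e, 2], ] + f[e] * c(dx[e], dy[e])
      }
    }
    temp <- t0 * (1 - (it - 1) / iterations)
    len <- pmax(sqrt(rowSums(disp^2)), 1e-12)
    step <- pmin(len, temp) / len
    pos <- pos + disp * step
  }
  data.frame(node = nodes, type = type, x = pos[, 1], y = pos[, 2])
}
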