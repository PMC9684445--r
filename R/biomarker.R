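#' Build the disease-specific miRNA-mRNA network
#'
#' Induces the bipartite targeting network on a set of differentially
#' expressed miRNAs: only edges whose miRNA endpoint is in `dems` are kept.
#' DEMs with no recorded targets are retained as isolated miRNAs.
#'
#' @param dems character vector of DEM miRNA ids (non-empty).
#' @param targets `edge_table` with relation `"targets"`.
#' @param tfs TF catalog: character vector of gene ids designated
#'   transcription factors.
#' @return list of class `mirna_mrna_network` with elements `mirnas`,
#'   `genes`, `edges` (data.frame `mirna`, `gene`), `tf_catalog` (the
#'   supplied TF universe) and `tf_flags` (the TF genes present in the
#'   network).
#' @export
build_disease_network <- function(dems, targets, tfs = character()) {
  if (!length(dems)) stop("empty DEM set")
  targets <- validate_edge_table(as.data.frame(targets))
  if (nrow(targets) && !all(targets$relation == "targets"))
    stop("targets table must have relation 'targets'")
  keep <- targets$source_id %in% dems
  edges <- unique(data.frame(mirna = targets$source_id[keep],
                             gene = targets$target_id[keep],
                             stringsAsFactors = FALSE))
  genes <- sort(unique(edges$gene))
  net <- list(mirnas = sort(unique(as.character(dems))),
              genes = genes,
              edges = edges,
              tf_catalog = unique(as.character(tfs)),
              tf_flags = intersect(genes, tfs))
  class(net) <- "mirna_mrna_network"
  net
}

#' Score miRNAs by single-line regulation and TF percentage
#'
#' For each miRNA in the disease network computes
#' \itemize{
#'   \item NSR, the number of single-line regulations: targets regulated by
#'     this miRNA alone (gene in-degree 1 in the bipartite network), with a
#'     permutation p-value under degree-preserving rewiring of the bipartite
#'     edges (checkerboard swaps), upper tail with pseudo-count
#'     (1 + #\{null >= observed\}) / (1 + permutations);
#'   \item TFP, the fraction of its targets that are transcription factors,
#'     with a hypergeometric upper-tail p-value for drawing its targets from
#'     the network's gene universe.
#' }
#' miRNAs with zero targets get NSR 0, TFP 0 and p-values 1.
#'
#' @param net a `mirna_mrna_network` from [build_disease_network()].
#' @param null_permutations permutation replicates for the NSR null
#'   (>= 100 when NSR p-values are wanted; 0 skips them, p_nsr = NA).
#' @param seed RNG seed for the rewiring null.
#' @param swaps_per_edge attempted checkerboard swaps per edge per
#'   replicate.
#' @param universe hypergeometric gene universe: `"network"` (genes in the
#'   disease network, the default) or a character vector of gene ids.
#' @return data.frame: `mirna_id`, `nsr`, `p_nsr`, `tfp`, `p_tfp`,
#'   `n_targets`, ordered by descending NSR.
#' @export
score_nsr_tfp <- function(net, null_permutations = 1000L, seed = 1L,
                          swaps_per_edge = 10L, universe = "network") {
  stopifnot(inherits(net, "mirna_mrna_network"))
  if (null_permutations > 0L && null_permutations < 100L)
    stop("null_permutations must be >= 100 (or 0 to skip NSR p-values)")
  mirnas <- net$mirnas
  edges <- net$edges

  nsr_of <- function(edges) {
    deg <- table(edges$gene)
    single <- names(deg)[deg == 1L]
    tab <- table(factor(edges$mirna[edges$gene %in% single],
                        levels = mirnas))
    as.numeric(tab)
  }
  obs_nsr <- nsr_of(edges)
  n_targets <- as.numeric(table(factor(edges$mirna, levels = mirnas)))

  ## TFP + hypergeometric tail
  if (is.character(universe) && length(universe) == 1L &&
      universe == "network") {
    gene_universe <- net$genes
  } else gene_universe <- unique(as.character(universe))
  tf_set <- intersect(net$tf_flags, gene_universe)
  n_tf_targets <- vapply(mirnas, function(m)
    length(intersect(edges$gene[edges$mirna == m], tf_set)), 1)
  tfp <- ifelse(n_targets > 0, n_tf_targets / n_targets, 0)
  if (length(net$tf_catalog) == 0L && any(n_targets > 0))
    stop("TFP requested with empty TF catalog")
  N <- length(gene_universe); K <- length(tf_set)
  p_tfp <- ifelse(n_targets > 0,
                  stats::phyper(n_tf_targets - 1, K, N - K, n_targets,
                                lower.tail = FALSE),
                  1)

  ## NSR permutation null: degree-preserving bipartite rewiring by
  ## checkerboard swaps ((m1,g1),(m2,g2) -> (m1,g2),(m2,g1) when neither
  ## replacement edge exists), preserving every miRNA out-degree and gene
  ## in-degree
  if (null_permutations > 0L && nrow(edges) > 1L) {
    withr_seed(seed)
    exceed <- numeric(length(mirnas))
    src <- match(edges$mirna, mirnas)
    gene_levels <- net$genes
    tgt <- match(edges$gene, gene_levels)
    n_edges <- length(src)
    n_genes <- length(gene_levels)
    n_swaps <- swaps_per_edge * n_edges
    code <- function(s, t) (s - 1L) * n_genes + t
    null_nsr_of <- function(s, t) {
      indeg <- tabulate(t, n_genes)
      tabulate(s[indeg[t] == 1L], length(mirnas))
    }
    for (r in seq_len(null_permutations)) {
      s <- src; t <- tgt
      present <- logical(length(mirnas) * n_genes)
      present[code(s, t)] <- TRUE
      i <- sample.int(n_edges, n_swaps, replace = TRUE)
      j <- sample.int(n_edges, n_swaps, replace = TRUE)
      for (k in seq_len(n_swaps)) {
        a <- i[k]; b <- j[k]
        if (a == b || s[a] == s[b] || t[a] == t[b]) next
        c1 <- code(s[a], t[b]); c2 <- code(s[b], t[a])
        if (present[c1] || present[c2]) next
        present[c(code(s[a], t[a]), code(s[b], t[b]))] <- FALSE
        present[c(c1, c2)] <- TRUE
        tmp <- t[a]; t[a] <- t[b]; t[b] <- tmp
      }
      exceed <- exceed + (null_nsr_of(s, t) >= obs_nsr)
    }
    p_nsr <- (1 + exceed) / (1 + null_permutations)
  } else {
    p_nsr <- rep(NA_real_, length(mirnas))
  }
  p_nsr[n_targets == 0] <- 1

  out <- data.frame(mirna_id = mirnas, nsr = obs_nsr, p_nsr = p_nsr,
                    tfp = tfp, p_tfp = p_tfp, n_targets = n_targets,
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$nsr, out$p_nsr, out$mirna_id), , drop = FALSE]
}

#' Rank candidate biomarkers by joint NSR/TFP significance
#'
#' Keeps miRNAs significant on both criteria (p_nsr < alpha and
#' p_tfp < alpha) and ranks them by descending NSR, breaking ties by
#' ascending p_nsr then id.
#'
#' @param scores output of [score_nsr_tfp()].
#' @param alpha significance level in (0, 1).
#' @return character vector of candidate biomarker miRNA ids, ranked.
#' @export
predict_biomarkers <- function(scores, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  keep <- !is.na(scores$p_nsr) & scores$p_nsr < alpha &
    scores$p_tfp < alpha
  s <- scores[keep, , drop = FALSE]
  s$mirna_id[order(-s$nsr, s$p_nsr, s$mirna_id)]
}
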