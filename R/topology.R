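#' Degree and betweenness centralities with iterative degree filtering
#'
#' Builds the undirected simple graph of an edge table, iteratively removes
#' nodes of degree < `min_degree` until stable (i.e. restricts to the
#' `min_degree`-core), and computes each surviving node's degree and
#' unnormalized shortest-path betweenness (no endpoint counting).
#'
#' @param edges `edge_table` (any relation; direction ignored).
#' @param min_degree degree cutoff (default 2, i.e. drop leaves and
#'   isolated nodes iteratively); 0 keeps everything.
#' @return data.frame: `node_id`, `degree`, `betweenness`.
#' @export
network_centralities <- function(edges, min_degree = 2L) {
  if (!nrow(edges)) stop("empty edge list")
  g <- igraph::simplify(igraph::graph_from_data_frame(
    data.frame(from = edges$source_id, to = edges$target_id),
    directed = FALSE))
  if (min_degree > 0L) {
    repeat {
      deg <- igraph::degree(g)
      drop <- names(deg)[deg < min_degree]
      if (!length(drop)) break
      g <- igraph::delete_vertices(g, drop)
    }
  }
  if (igraph::vcount(g) == 0L)
    return(data.frame(node_id = character(), degree = integer(),
                      betweenness = numeric()))
  data.frame(node_id = igraph::V(g)$name,
             degree = as.integer(igraph::degree(g)),
             betweenness = igraph::betweenness(g, directed = FALSE,
                                               normalized = FALSE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Group miRNAs by similarity of network-topology features
#'
#' Standardizes (degree, betweenness) to zero mean / unit sd, clusters by
#' single-linkage agglomeration on Euclidean distance, and cuts the tree
#' where the merge distance exceeds `tau`. A constant feature contributes 0
#' after standardization.
#'
#' @param stats data.frame with `node_id`, `degree`, `betweenness`
#'   (restricted to the miRNAs of interest; >= 2 rows).
#' @param tau merge-distance cut (standardized units; default 0.5).
#' @return list of character vectors (the groups), ordered by decreasing
#'   size then decreasing mean degree.
#' @export
group_mirnas_by_topology <- function(stats, tau = 0.5) {
  if (nrow(stats) < 2L) stop("need at least 2 miRNAs to group")
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x)
                   else rep(0, length(x))
  feats <- cbind(z(stats$degree), z(stats$betweenness))
  hc <- stats::hclust(stats::dist(feats), method = "single")
  cl <- stats::cutree(hc, h = tau)
  groups <- split(stats$node_id, cl)
  mean_deg <- vapply(groups, function(ids)
    mean(stats$degree[stats$node_id %in% ids]), 1)
  ord <- order(-lengths(groups), -mean_deg)
  unname(groups[ord])
}

#' Genes shared by several miRNAs
#'
#' Extracts genes targeted by at least `min_mirnas` distinct miRNAs from
#' the given set (e.g. "targets of at least two of the final biomarkers").
#'
#' @param targets `edge_table` with relation `"targets"`.
#' @param mirnas miRNA id set to count within.
#' @param min_mirnas minimum number of distinct targeting miRNAs (>= 1).
#' @return sorted character vector of gene ids.
#' @export
shared_target_genes <- function(targets, mirnas, min_mirnas = 2L) {
  stopifnot(min_mirnas >= 1L)
  keep <- targets$source_id %in% mirnas
  pairs <- unique(data.frame(mirna = targets$source_id[keep],
                             gene = targets$target_id[keep],
                             stringsAsFactors = FALSE))
  counts <- table(pairs$gene)
  sort(names(counts)[counts >= min_mirnas])
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric test of a query gene set against each set of a
#' collection, with Benjamini-Hochberg adjustment across sets. Sets are
#' intersected with the universe before testing; the query must be a subset
#' of the universe.
#'
#' @param query character vector of query gene ids.
#' @param sets a [gene_set_collection()].
#' @param universe character vector of background gene ids.
#' @return data.frame: `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p_value`, `adj_p`, ordered by p-value.
#' @export
ora_hypergeometric <- function(query, sets, universe) {
  universe <- unique(as.character(universe))
  query <- unique(as.character(query))
  if (!all(query %in% universe))
    stop("query contains gene(s) outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5), collapse = ", "))
  N <- length(universe); q <- length(query)
  res <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    k <- length(intersect(s, query))
    p <- stats::phyper(k - 1, length(s), N - length(s), q,
                       lower.tail = FALSE)
    data.frame(set_name = nm, overlap = k, set_size = length(s),
               query_size = q, universe_size = N, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adj_p <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value, out$set_name), , drop = FALSE]
}
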