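#' MCODE dense-module detection in a PPI network
#'
#' A faithful implementation of the MCODE complex-detection algorithm on a
#' confidence-filtered protein-protein interaction network.
#'
#' \strong{Stage 1 (vertex weighting).} For each vertex, take the graph
#' induced on its open neighborhood (the vertex itself excluded), find the
#' highest k-core of that neighborhood graph, and set the vertex weight to
#' the core number k times the density of that core. Vertices with degree
#' below `degree_cutoff` are weighted 0.
#'
#' \strong{Stage 2 (complex prediction).} Seeds are visited in decreasing
#' weight order (ties by id). From each unvisited seed, neighbors are
#' admitted breadth-first when their weight is at least
#' `seed_weight * (1 - node_score_cutoff)`; expansion is limited to
#' `max_depth` steps from the seed, and a vertex belongs to at most one
#' complex.
#'
#' \strong{Stage 3 (post-processing).} Complexes without a `k_core`-core
#' are discarded. With `haircut = TRUE` degree-1 members are removed; with
#' `fluff = TRUE` neighbors whose neighborhood density exceeds
#' `fluff_density` are appended (both off by default). The module score is
#' the density of the member-induced subgraph times the member count, and
#' modules are returned sorted by decreasing score.
#'
#' @param ppi `edge_table` of physical interactions with confidence in
#'   `score`.
#' @param confidence_min minimum edge confidence retained (default 0.4).
#' @param degree_cutoff minimum degree for a vertex to be weighted
#'   (default 2).
#' @param node_score_cutoff admission slack relative to the seed weight, in
#'   \[0, 1\] (default 0.2).
#' @param k_core required core of a reported complex (default 2).
#' @param max_depth breadth limit of seed expansion (default 100).
#' @param haircut,fluff,fluff_density optional post-processing toggles.
#' @return list of modules, each a list with `members` (sorted ids),
#'   `score`, `density`, `seed_vertex`; sorted by decreasing score (ties by
#'   seed id).
#' @export
mcode_cluster <- function(ppi, confidence_min = 0.4, degree_cutoff = 2L,
                          node_score_cutoff = 0.2, k_core = 2L,
                          max_depth = 100L,
                          haircut = FALSE, fluff = FALSE,
                          fluff_density = 0.5) {
  stopifnot(degree_cutoff > 0L, k_core > 0L, max_depth > 0L,
            node_score_cutoff >= 0, node_score_cutoff <= 1)
  ## unscored edges are kept: there is nothing to filter them on
  keep <- is.na(ppi$score) | ppi$score >= confidence_min
  if (!any(keep)) {
    warning("all edges below confidence_min; no modules")
    return(list())
  }
  g <- igraph::simplify(igraph::graph_from_data_frame(
    data.frame(from = ppi$source_id[keep], to = ppi$target_id[keep]),
    directed = FALSE))
  nm <- igraph::V(g)$name
  n <- length(nm)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, function(vs) as.integer(vs))
  deg <- lengths(adj)

  graph_density <- function(nv, ne) if (nv < 2L) 0 else 2 * ne / (nv * (nv - 1))

  ## stage 1: core-weight each vertex on its open neighborhood
  weight <- numeric(n)
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nb <- adj[[v]]
    sub <- igraph::induced_subgraph(g, nb)
    if (igraph::ecount(sub) == 0L) next
    core <- igraph::coreness(sub)
    kmax <- max(core)
    core_v <- which(core == kmax)
    core_sub <- igraph::induced_subgraph(sub, core_v)
    weight[v] <- kmax * graph_density(length(core_v),
                                      igraph::ecount(core_sub))
  }

  ## stage 2: greedy seeded expansion in decreasing weight order
  seen <- logical(n)
  complexes <- list()
  for (seed in order(-weight, nm)) {
    if (seen[seed] || weight[seed] <= 0) next
    thresh <- weight[seed] * (1 - node_score_cutoff)
    members <- seed
    seen[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[!seen[nxt] & weight[nxt] >= thresh]
      if (!length(nxt)) break
      seen[nxt] <- TRUE
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1L
    }
    complexes[[length(complexes) + 1L]] <- list(seed = seed,
                                                members = members)
  }

  ## stage 3: post-process, require a k_core-core, score by density x size
  out <- list()
  for (cx in complexes) {
    members <- cx$members
    sub <- igraph::induced_subgraph(g, members)
    if (igraph::ecount(sub) == 0L || max(igraph::coreness(sub)) < k_core)
      next
    if (haircut) {
      repeat {
        d1 <- igraph::degree(sub) < 2
        if (!any(d1) || all(d1)) break
        sub <- igraph::induced_subgraph(sub, which(!d1))
      }
      members <- match(igraph::V(sub)$name, nm)
    }
    if (fluff) {
      cand <- setdiff(unique(unlist(adj[members])), members)
      add <- cand[vapply(cand, function(v) {
        nb <- adj[[v]]
        s <- igraph::induced_subgraph(g, union(nb, v))
        graph_density(igraph::vcount(s), igraph::ecount(s)) > fluff_density
      }, TRUE)]
      members <- c(members, add)
      sub <- igraph::induced_subgraph(g, members)
    }
    nv <- length(members)
    dens <- graph_density(nv, igraph::ecount(sub))
    if (dens <= 0) next
    out[[length(out) + 1L]] <- list(members = sort(nm[members]),
                                    score = dens * nv,
                                    density = dens,
                                    seed_vertex = nm[cx$seed])
  }
  ord <- order(-vapply(out, `[[`, 1, "score"),
               vapply(out, `[[`, "", "seed_vertex"))
  out[ord]
}

#' Select high-scoring modules and associate them with miRNAs
#'
#' Keeps modules with score above `score_min`, counts for each miRNA how
#' many selected-module member genes it targets (summed over modules), and
#' defines the module-associated ("model 2") miRNA set as those whose
#' association count exceeds the chosen rule — by default, the median count
#' among the candidate miRNAs.
#'
#' @param modules output of [mcode_cluster()].
#' @param score_min module score threshold (> 0; modules with score
#'   strictly greater are kept).
#' @param targets `edge_table` with relation `"targets"`.
#' @param mirnas candidate miRNA ids.
#' @param rule `"above_median"` (default) or a numeric threshold: keep
#'   miRNAs with association strictly greater than the rule value.
#' @return list: `selected` (the retained modules), `association` (named
#'   count vector per miRNA) and `model2` (character vector of associated
#'   miRNAs, by decreasing association).
#' @export
select_top_modules_and_associate <- function(modules, score_min, targets,
                                             mirnas,
                                             rule = "above_median") {
  stopifnot(score_min > 0)
  selected <- Filter(function(m) m$score > score_min, modules)
  pairs <- unique(data.frame(mirna = targets$source_id,
                             gene = targets$target_id,
                             stringsAsFactors = FALSE))
  pairs <- pairs[pairs$mirna %in% mirnas, , drop = FALSE]
  association <- stats::setNames(numeric(length(mirnas)), mirnas)
  for (mod in selected) {
    hit <- pairs[pairs$gene %in% mod$members, , drop = FALSE]
    cnt <- table(factor(hit$mirna, levels = mirnas))
    association <- association + as.numeric(cnt)
  }
  cut <- if (identical(rule, "above_median")) stats::median(association)
         else as.numeric(rule)
  model2 <- names(association)[association > cut]
  model2 <- model2[order(-association[model2], model2)]
  list(selected = selected, association = association, model2 = model2)
}
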