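## Independent brute-force oracles used to check the implementations.
## These deliberately avoid the package's own code paths and igraph.

## Benjamini-Hochberg step-up by direct evaluation of the definition:
## adj_p(i) = min over j >= i in rank order of min(1, p_(j) * m / j)
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- pmin(1, p[o] * m / seq_len(m))
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- q
  out
}

## Unnormalized shortest-path betweenness (no endpoints) by exhaustive
## BFS path counting on an adjacency matrix.
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  dist <- matrix(Inf, n, n)
  sig <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); d[s] <- 0
    sg <- rep(0, n); sg[s] <- 1
    frontier <- s; level <- 0L
    while (length(frontier)) {
      level <- level + 1L
      nxt <- integer()
      for (v in frontier) for (w in which(adj[v, ] > 0)) {
        if (!is.finite(d[w])) { d[w] <- level; nxt <- c(nxt, w) }
        if (d[w] == level) sg[w] <- sg[w] + sg[v]
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d; sig[s, ] <- sg
  }
  btw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(dist[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (is.finite(dist[s, v]) && is.finite(dist[v, t]) &&
          dist[s, v] + dist[v, t] == dist[s, t])
        btw[v] <- btw[v] + sig[s, v] * sig[v, t] / sig[s, t]
    }
  }
  btw
}

## Exhaustive FFL triple scan applying the class definitions directly to a
## directed edge list. `kind` is a named vector over node ids.
ffl_triple_scan <- function(edges, kind) {
  key <- paste(edges$source_id, edges$target_id)
  has <- function(a, b) paste(a, b) %in% key
  tfs <- names(kind)[kind == "TF"]
  mirnas <- names(kind)[kind == "miRNA"]
  targets <- names(kind)[kind %in% c("TF", "gene")]
  out <- list()
  for (t in tfs) for (m in mirnas) for (g in targets) {
    if (g == t || g == m) next
    if (!has(t, g) || !has(m, g)) next
    t_m <- has(t, m); m_t <- has(m, t)
    cls <- if (t_m && m_t) "composite"
           else if (t_m) "TF-FFL"
           else if (m_t) "miRNA-FFL"
           else next
    out[[length(out) + 1L]] <- data.frame(tf = t, mirna = m, gene = g,
                                          ffl_class = cls,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), ffl_class = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

## AUC by exhaustive pair counting with half credit for ties.
auc_pair_oracle <- function(scores, is_case) {
  cs <- scores[is_case]; ct <- scores[!is_case]
  total <- 0
  for (a in cs) for (b in ct)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(cs) * length(ct))
}

## Upper-tail hypergeometric by direct summation of the pmf.
hyper_tail_oracle <- function(k_obs, n_white, n_black, n_draw) {
  ks <- k_obs:min(n_white, n_draw)
  sum(choose(n_white, ks) * choose(n_black, n_draw - ks)) /
    choose(n_white + n_black, n_draw)
}

## Random directed tri-partite regulatory network for FFL fuzzing.
random_coreg_network <- function(n_tf, n_mirna, n_gene, p = 0.15) {
  tfs <- paste0("T", seq_len(n_tf))
  ms <- paste0("m", seq_len(n_mirna))
  gs <- paste0("g", seq_len(n_gene))
  draw <- function(from, to) {
    grid <- expand.grid(source_id = from, target_id = to,
                        stringsAsFactors = FALSE)
    grid <- grid[grid$source_id != grid$target_id, , drop = FALSE]
    grid[stats::runif(nrow(grid)) < p, , drop = FALSE]
  }
  edges <- rbind(draw(tfs, ms), draw(tfs, gs), draw(tfs, tfs),
                 draw(ms, gs), draw(ms, tfs))
  if (!nrow(edges))
    edges <- data.frame(source_id = tfs[1], target_id = gs[1],
                        stringsAsFactors = FALSE)
  edges$sign <- ifelse(substr(edges$source_id, 1, 1) == "m",
                       "repress", "activate")
  edges$edge_kind <- "mixed"
  kind <- c(stats::setNames(rep("TF", n_tf), tfs),
            stats::setNames(rep("miRNA", n_mirna), ms),
            stats::setNames(rep("gene", n_gene), gs))
  nodes <- data.frame(id = names(kind), kind = unname(kind),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "coreg_network")
}

## Small convenience: a miRNA->gene targets table from parallel vectors.
toy_targets <- function(mirna, gene, origin = "toy",
                        evidence = "validated_strong", score = NA_real_) {
  edge_table(mirna, gene, "miRNA", "gene", "targets",
             evidence = evidence, origin = origin, score = score)
}
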