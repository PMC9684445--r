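#' Assemble the signed TF-miRNA-gene co-regulatory network
#'
#' Restricts the regulatory evidence to a kept miRNA set (the final
#' biomarkers) and a kept gene set (e.g. genes targeted by at least two
#' biomarkers), plus every TF connected to either. miRNA->TF edges are
#' derived from miRNA targeting records whose target is a TF. Signs follow
#' the standing assumption — miRNAs repress their targets, TFs activate
#' theirs — unless a source annotates otherwise; when sources disagree on
#' an edge the repress annotation wins and the conflict is reported via a
#' message.
#'
#' @param tf_mirna `edge_table` of TF->miRNA regulation (signed).
#' @param tf_gene `edge_table` of TF->gene regulation (signed).
#' @param mirna_gene `edge_table` of miRNA->gene targeting; targets that
#'   are TFs (per `tf_ids`) yield the derived miRNA->TF edges.
#' @param keep_mirnas,keep_genes non-empty id sets defining the network
#'   scope.
#' @param tf_ids TF universe; defaults to all TF->x source ids.
#' @return list of class `coreg_network`: `nodes` (data.frame `id`,
#'   `kind`), `edges` (data.frame `source_id`, `target_id`, `sign`,
#'   `edge_kind` in \{TF->miRNA, TF->gene, miRNA->gene, miRNA->TF\}).
#' @export
assemble_coregulatory_network <- function(tf_mirna, tf_gene, mirna_gene,
                                          keep_mirnas, keep_genes,
                                          tf_ids = NULL) {
  if (!length(keep_mirnas) || !length(keep_genes))
    stop("keep_mirnas and keep_genes must be non-empty")
  if (is.null(tf_ids))
    tf_ids <- unique(c(tf_mirna$source_id, tf_gene$source_id))

  sgn <- function(et, default_kind) {
    s <- et$sign
    s[is.na(s) | s == "unknown"] <- default_sign(default_kind)
    s
  }
  ## candidate edges before scope filtering
  e_tm <- data.frame(source_id = tf_mirna$source_id,
                     target_id = tf_mirna$target_id,
                     sign = sgn(tf_mirna, "TF"),
                     edge_kind = "TF->miRNA", stringsAsFactors = FALSE)
  e_tg <- data.frame(source_id = tf_gene$source_id,
                     target_id = tf_gene$target_id,
                     sign = sgn(tf_gene, "TF"),
                     edge_kind = "TF->gene", stringsAsFactors = FALSE)
  is_tf_target <- mirna_gene$target_id %in% tf_ids
  e_mg <- data.frame(source_id = mirna_gene$source_id,
                     target_id = mirna_gene$target_id,
                     sign = "repress",                 # standing assumption
                     edge_kind = ifelse(is_tf_target, "miRNA->TF",
                                        "miRNA->gene"),
                     stringsAsFactors = FALSE)

  ## scope: kept miRNAs, kept genes, TFs connected to either
  e_tm <- e_tm[e_tm$target_id %in% keep_mirnas, , drop = FALSE]
  e_tg <- e_tg[e_tg$target_id %in% keep_genes |
                 e_tg$target_id %in% tf_ids, , drop = FALSE]
  e_mg <- e_mg[e_mg$source_id %in% keep_mirnas &
                 (e_mg$target_id %in% keep_genes |
                    e_mg$target_id %in% tf_ids), , drop = FALSE]
  edges <- rbind(e_tm, e_tg, e_mg)

  connected_tfs <- unique(c(e_tm$source_id,
                            e_tg$source_id,
                            e_mg$target_id[e_mg$edge_kind == "miRNA->TF"]))
  connected_tfs <- intersect(connected_tfs, tf_ids)
  ## TF->gene / TF->TF edges only from TFs that touch the kept core
  core_touching <- unique(c(
    e_tm$source_id,
    e_mg$target_id[e_mg$edge_kind == "miRNA->TF"],
    e_tg$source_id[e_tg$target_id %in% keep_genes]))
  keep_tfs <- intersect(connected_tfs, core_touching)
  edges <- edges[
    (edges$source_id %in% keep_tfs | edges$source_id %in% keep_mirnas) &
      (edges$target_id %in% keep_mirnas | edges$target_id %in% keep_genes |
         edges$target_id %in% keep_tfs), , drop = FALSE]

  ## merge duplicate directed edges; an annotated repress wins over activate
  key <- paste(edges$source_id, edges$target_id, sep = "\r")
  if (anyDuplicated(key)) {
    conflict <- tapply(edges$sign, key, function(s) length(unique(s)) > 1)
    if (any(conflict))
      message("sign conflict on ", sum(conflict),
              " edge(s); keeping the repress annotation")
    merged <- do.call(rbind, lapply(split(edges, key), function(d) {
      d <- d[order(d$sign != "repress"), , drop = FALSE]  # repress first
      d[1L, , drop = FALSE]
    }))
    edges <- merged[order(match(unique(key), key)), , drop = FALSE]
  }
  rownames(edges) <- NULL

  node_ids <- unique(c(edges$source_id, edges$target_id))
  kind <- ifelse(node_ids %in% keep_mirnas, "miRNA",
                 ifelse(node_ids %in% keep_tfs, "TF", "gene"))
  structure(list(nodes = data.frame(id = node_ids, kind = kind,
                                    stringsAsFactors = FALSE),
                 edges = edges),
            class = "coreg_network")
}

#' Enumerate and classify feed-forward loops
#'
#' Scans every (TF, miRNA, target) triple of the co-regulatory network for
#' the three FFL classes, with composite taking precedence so that each
#' qualifying triple receives exactly one class:
#' \itemize{
#'   \item \strong{composite}: TF<->miRNA mutual regulation plus both
#'     TF->gene and miRNA->gene;
#'   \item \strong{TF-FFL}: TF->miRNA, TF->gene, miRNA->gene (TF is the
#'     main regulator);
#'   \item \strong{miRNA-FFL}: miRNA->TF, TF->gene, miRNA->gene (miRNA is
#'     the main regulator).
#' }
#' The target may itself be a TF node (TFs can take the gene role);
#' degenerate triples with target == TF are excluded.
#'
#' @param net a `coreg_network`.
#' @return data.frame: `tf`, `mirna`, `gene`, `ffl_class`, `edge_signs`
#'   (collapsed annotation of the participating signed edges).
#' @export
enumerate_and_classify_ffls <- function(net) {
  nodes <- net$nodes; edges <- net$edges
  key <- paste(edges$source_id, edges$target_id, sep = "\r")
  sign_by_key <- stats::setNames(edges$sign, key)
  out_nbrs <- split(edges$target_id, edges$source_id)
  sign_of <- function(a, b) unname(sign_by_key[paste(a, b, sep = "\r")])
  tfs <- nodes$id[nodes$kind == "TF"]
  mirnas <- nodes$id[nodes$kind == "miRNA"]
  target_ids <- nodes$id[nodes$kind %in% c("gene", "TF")]

  rec <- list()
  for (t in tfs) {
    t_out <- out_nbrs[[t]]
    if (is.null(t_out)) next
    t_targets <- intersect(t_out, target_ids)
    for (m in mirnas) {
      m_out <- out_nbrs[[m]]
      t_m <- m %in% t_out
      m_t <- !is.null(m_out) && t %in% m_out
      if (!t_m && !m_t) next
      if (is.null(m_out)) next
      shared <- setdiff(intersect(t_targets, m_out), c(t, m))
      if (!length(shared)) next
      cls <- if (t_m && m_t) "composite" else if (t_m) "TF-FFL"
             else "miRNA-FFL"
      for (g in shared) {
        signs <- c(
          if (t_m) paste0("TF->miRNA:", sign_of(t, m)),
          if (m_t) paste0("miRNA->TF:", sign_of(m, t)),
          paste0("TF->gene:", sign_of(t, g)),
          paste0("miRNA->gene:", sign_of(m, g)))
        rec[[length(rec) + 1L]] <-
          data.frame(tf = t, mirna = m, gene = g, ffl_class = cls,
                     edge_signs = paste(signs, collapse = ";"),
                     stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rec))
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), ffl_class = character(),
                      edge_signs = character(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rec)
  out <- out[order(out$tf, out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank hub nodes of the co-regulatory network
#'
#' Degree (in + out) hub ranking, separately for TF nodes and gene nodes,
#' plus the dual-role set: TFs that are themselves regulation targets
#' (>= 1 incoming edge). Ties broken by id.
#'
#' @param net a `coreg_network`.
#' @param top_k list length per ranking (>= 1).
#' @return list: `top_tfs`, `top_genes` (data.frames `id`, `degree`),
#'   `dual_role` (character vector).
#' @export
rank_hubs <- function(net, top_k = 5L) {
  stopifnot(top_k >= 1L)
  nodes <- net$nodes; edges <- net$edges
  deg <- table(factor(c(edges$source_id, edges$target_id),
                      levels = nodes$id))
  stats <- data.frame(id = nodes$id, kind = nodes$kind,
                      degree = as.integer(deg[nodes$id]),
                      stringsAsFactors = FALSE)
  pick <- function(kind) {
    s <- stats[stats$kind == kind, , drop = FALSE]
    s <- s[order(-s$degree, s$id), , drop = FALSE]
    utils::head(s[c("id", "degree")], top_k)
  }
  incoming <- unique(edges$target_id)
  dual <- sort(intersect(nodes$id[nodes$kind == "TF"], incoming))
  list(top_tfs = pick("TF"), top_genes = pick("gene"), dual_role = dual)
}
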