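#' Load an expression matrix from TSV, restricted to a sample sheet
#'
#' Reads a features-x-samples TSV (first column = feature id, header row =
#' sample ids, log2 intensities) and returns the matrix restricted to the
#' samples listed in `sheet`, in sheet order.
#'
#' @param path TSV file path.
#' @param sheet a [sample_sheet()].
#' @return numeric matrix (features x samples) passing
#'   [validate_expression_matrix()].
#' @export
load_expression <- function(path, sheet) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(raw) < 2L)
    stop("expression TSV needs a feature id column and >=1 sample column")
  feature_ids <- raw[[1L]]
  if (anyDuplicated(feature_ids))
    stop("duplicate feature row(s): ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "))
  missing <- setdiff(sheet$sample_id, names(raw)[-1L])
  if (length(missing))
    stop("sample(s) in sheet absent from expression file: ",
         paste(missing, collapse = ", "))
  vals <- raw[, sheet$sample_id, drop = FALSE]
  m <- matrix(NA_real_, nrow = nrow(vals), ncol = ncol(vals),
              dimnames = list(feature_ids, sheet$sample_id))
  for (j in seq_len(ncol(vals))) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(col) & !is.na(vals[[j]]) & vals[[j]] != "NA")
    if (length(bad))
      stop(sprintf("non-numeric value '%s' at feature '%s', sample '%s'",
                   vals[[j]][bad[1L]], feature_ids[bad[1L]],
                   sheet$sample_id[j]))
    m[, j] <- col
  }
  validate_expression_matrix(m)
  m
}

#' Write an expression matrix as TSV
#'
#' @param m expression matrix.
#' @param path output file.
#' @export
write_expression <- function(m, path) {
  validate_expression_matrix(m)
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load an edge table from TSV
#'
#' Expects the [edge_table()] columns as a header; `sign`, `score` and
#' `score_label` are optional (missing signs fall back to the default-sign
#' rule). Records whose `relation` differs from `expected_relation` are
#' rejected.
#'
#' @param path TSV file path.
#' @param expected_relation one of `"targets"`, `"regulates"`, `"interacts"`,
#'   or `NULL` to accept any relation.
#' @return an `edge_table`.
#' @export
load_edge_table <- function(path, expected_relation = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("source_id", "source_kind", "target_id", "target_kind",
                "relation", "evidence", "origin")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("edge TSV missing column(s): ", paste(missing_cols, collapse = ", "))
  if (!"sign" %in% names(df)) df$sign <- NA_character_
  if (!"score" %in% names(df)) df$score <- NA_real_
  if (!"score_label" %in% names(df)) df$score_label <- NA_character_
  if (!is.null(expected_relation)) {
    off <- unique(df$relation[df$relation != expected_relation])
    if (length(off))
      stop("expected relation '", expected_relation, "' but found: ",
           paste(off, collapse = ", "))
  }
  edge_table(source_id = df$source_id, target_id = df$target_id,
             source_kind = df$source_kind, target_kind = df$target_kind,
             relation = df$relation,
             sign = ifelse(is.na(df$sign) | df$sign == "", NA, df$sign),
             evidence = df$evidence, origin = df$origin,
             score = df$score, score_label = df$score_label)
}

#' Write an edge table as TSV
#' @param et an `edge_table`.
#' @param path output file.
#' @export
write_edge_table <- function(et, path) {
  utils::write.table(as.data.frame(et), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes.
#'
#' @param path GMT file.
#' @return a [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("malformed GMT line(s) (need name, description, >=1 gene): line ",
         paste(which(short), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets,
                      description = vapply(fields, `[[`, "", 2L))
}

#' Write gene sets to a GMT file
#' @param gsc a `gene_set_collection`.
#' @param path output file.
#' @export
write_gmt <- function(gsc, path) {
  desc <- attr(gsc, "description")
  if (is.null(desc)) desc <- stats::setNames(rep("", length(gsc)), names(gsc))
  lines <- vapply(names(gsc), function(nm) {
    paste(c(nm, desc[[nm]], gsc[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read per-origin consensus cutoff configuration
#'
#' YAML with one section per prediction database, e.g.
#' \preformatted{
#' miRDB:       {dir: ge, value: 84}
#' TargetScan:  {dir: le, value: -0.4}
#' mirDIP:      {dir: class, value: [very high]}
#' }
#' `dir` is `ge` (keep score >= value), `le` (keep score <= value) or
#' `class` (keep records whose score label is in `value`, compared after
#' whitespace trimming, case-insensitively).
#'
#' @param path YAML file.
#' @return named list of `list(dir=, value=)` cutoffs.
#' @export
read_cutoff_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (origin in names(cfg)) {
    cu <- cfg[[origin]]
    if (!is.list(cu) || is.null(cu$dir) || is.null(cu$value))
      stop("cutoff for origin '", origin, "' needs 'dir' and 'value'")
    if (!cu$dir %in% c("ge", "le", "class"))
      stop("cutoff dir for origin '", origin,
           "' must be one of ge, le, class")
  }
  cfg
}

#' Export a network as SIF (simple interaction format)
#'
#' One line per edge: `source <TAB> relation <TAB> target`, importable by
#' standard network viewers.
#'
#' @param edges data.frame with `source_id`, `target_id` and either a
#'   `relation` or `sign` column used as the interaction type.
#' @param path output file.
#' @param type_col column to use as the interaction type.
#' @export
write_sif <- function(edges, path, type_col = "relation") {
  type <- if (type_col %in% names(edges)) edges[[type_col]] else "interacts"
  writeLines(paste(edges$source_id, type, edges$target_id, sep = "\t"), path)
  invisible(path)
}

#' Export a network as GraphML via igraph
#'
#' @param edges data.frame with `source_id`, `target_id` and any extra edge
#'   attribute columns.
#' @param path output file.
#' @param directed logical.
#' @param node_kind optional named character vector of node kinds, attached
#'   as a vertex attribute.
#' @export
write_graphml <- function(edges, path, directed = TRUE, node_kind = NULL) {
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$source_id, to = edges$target_id,
               edges[setdiff(names(edges), c("source_id", "target_id"))],
               stringsAsFactors = FALSE),
    directed = directed)
  if (!is.null(node_kind))
    igraph::V(g)$kind <- unname(node_kind[igraph::V(g)$name])
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
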