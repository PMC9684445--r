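#' @keywords internal
"_PACKAGE"

## Controlled vocabularies shared across the data model.
NODE_KINDS <- c("miRNA", "TF", "gene")
RELATIONS  <- c("targets", "regulates", "interacts")
SIGNS      <- c("activate", "repress", "unknown")
EVIDENCE   <- c("validated_strong", "predicted", "physical")

EDGE_COLUMNS <- c("source_id", "source_kind", "target_id", "target_kind",
                  "relation", "sign", "evidence", "origin", "score")

#' Construct a validated regulatory/physical edge table
#'
#' The edge table is the shared container for every interaction source in the
#' pipeline: miRNA->gene targeting (validated or predicted), signed TF->miRNA
#' and TF->gene regulation, and protein-protein interactions with confidence
#' scores.
#'
#' @param source_id,target_id character vectors of interactor identifiers.
#' @param source_kind,target_kind node kinds, each one of `"miRNA"`, `"TF"`,
#'   `"gene"` (recycled if length 1).
#' @param relation interaction class: `"targets"` (miRNA->gene),
#'   `"regulates"` (TF->miRNA / TF->gene) or `"interacts"` (physical PPI).
#' @param sign regulation sign: `"activate"`, `"repress"` or `"unknown"`.
#'   When `NULL`, the default-sign rule is applied: miRNA sources repress,
#'   TF sources activate, anything else is unknown.
#' @param evidence one of `"validated_strong"`, `"predicted"`, `"physical"`.
#' @param origin free-text database label the record came from.
#' @param score numeric evidence score; required (non-`NA`) for every
#'   `"predicted"` record, optional otherwise.
#' @param score_label optional character class label (e.g. a score tier such
#'   as "very high") for origins that grade predictions categorically rather
#'   than numerically.
#'
#' @return A `data.frame` of class `edge_table` with one row per record.
#'
#' @details Invariants enforced: no self-loops for `targets`/`regulates`
#' relations; `(source_id, target_id, relation, origin)` unique; every
#' predicted record carries a numeric score or a score label.
#'
#' @export
edge_table <- function(source_id, target_id,
                       source_kind, target_kind,
                       relation, sign = NULL,
                       evidence = "predicted",
                       origin = "user",
                       score = NA_real_,
                       score_label = NA_character_) {
  n <- length(source_id)
  df <- data.frame(
    source_id   = as.character(source_id),
    source_kind = rep_len(as.character(source_kind), n),
    target_id   = as.character(target_id),
    target_kind = rep_len(as.character(target_kind), n),
    relation    = rep_len(as.character(relation), n),
    sign        = if (is.null(sign)) NA_character_ else
                    rep_len(as.character(sign), n),
    evidence    = rep_len(as.character(evidence), n),
    origin      = rep_len(as.character(origin), n),
    score       = rep_len(as.numeric(score), n),
    score_label = rep_len(as.character(score_label), n),
    stringsAsFactors = FALSE
  )
  missing_sign <- is.na(df$sign)
  if (any(missing_sign))
    df$sign[missing_sign] <- default_sign(df$source_kind[missing_sign])
  validate_edge_table(df)
}

#' Default regulation sign by source kind
#'
#' miRNAs are assumed to repress their targets and TFs to activate theirs
#' unless a source annotates otherwise; other sources get `"unknown"`.
#'
#' @param source_kind character vector of node kinds.
#' @return character vector of signs.
#' @export
default_sign <- function(source_kind) {
  ifelse(source_kind == "miRNA", "repress",
         ifelse(source_kind == "TF", "activate", "unknown"))
}

validate_edge_table <- function(df) {
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(EDGE_COLUMNS, names(df))
  if (length(missing_cols))
    stop("edge table is missing columns: ", paste(missing_cols, collapse = ", "))
  if (!"score_label" %in% names(df)) df$score_label <- NA_character_
  check_vocab <- function(x, vocab, what) {
    bad <- setdiff(unique(x), vocab)
    if (length(bad))
      stop("unknown ", what, " token(s): ", paste(bad, collapse = ", "))
  }
  check_vocab(df$source_kind, NODE_KINDS, "source_kind")
  check_vocab(df$target_kind, NODE_KINDS, "target_kind")
  check_vocab(df$relation, RELATIONS, "relation")
  check_vocab(df$sign, SIGNS, "sign")
  check_vocab(df$evidence, EVIDENCE, "evidence")
  loops <- df$relation %in% c("targets", "regulates") &
    df$source_id == df$target_id
  if (any(loops))
    stop("self-loop(s) in regulatory relation for: ",
         paste(unique(df$source_id[loops]), collapse = ", "))
  key <- paste(df$source_id, df$target_id, df$relation, df$origin, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (source, target, relation, origin) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  pred <- df$evidence == "predicted"
  scoreless <- pred & is.na(df$score) & is.na(df$score_label)
  if (any(scoreless))
    stop("predicted record(s) without score: ",
         paste(df$source_id[scoreless], df$target_id[scoreless],
               sep = "->", collapse = ", "))
  class(df) <- c("edge_table", "data.frame")
  df
}

#' Construct a sample sheet
#'
#' @param sample_id unique sample identifiers.
#' @param group `"case"` or `"control"` per sample.
#' @param cohort cohort (dataset) label per sample; defaults to a single
#'   cohort `"cohort1"`.
#' @return `data.frame` of class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, group, cohort = "cohort1") {
  df <- data.frame(sample_id = as.character(sample_id),
                   group = as.character(group),
                   cohort = rep_len(as.character(cohort), length(sample_id)),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id(s): ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad))
    stop("group must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  class(df) <- c("sample_sheet", "data.frame")
  df
}

#' Validate an expression matrix
#'
#' Expression data travel as a plain numeric matrix in log2 intensity units
#' with features as rownames and samples as colnames (the limma convention).
#' This checks the container invariants and returns the matrix invisibly.
#'
#' @param m numeric matrix, features x samples.
#' @return `m`, invisibly.
#' @export
validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("expression data must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("expression matrix must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(m)))
    stop("duplicate feature id(s): ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample id(s): ",
         paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", "))
  if (!all(is.finite(m)))
    stop("expression matrix contains non-finite values")
  invisible(m)
}

#' Construct a gene-set collection
#'
#' A named list of character vectors with an optional per-set description
#' kept in the `"description"` attribute — the in-memory form of a GMT file.
#'
#' @param sets named list of character vectors of gene ids.
#' @param description optional character vector of set descriptions.
#' @return list of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, description = NULL) {
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("all gene sets must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  if (any(lengths(sets) == 0L))
    stop("empty gene set(s): ",
         paste(names(sets)[lengths(sets) == 0L], collapse = ", "))
  sets <- lapply(sets, as.character)
  if (is.null(description)) description <- rep("", length(sets))
  attr(sets, "description") <- stats::setNames(as.character(description),
                                               names(sets))
  class(sets) <- c("gene_set_collection", "list")
  sets
}
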