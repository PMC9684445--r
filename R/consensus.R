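#' Consensus filtering of predicted miRNA-target interactions
#'
#' Combines computationally predicted miRNA->gene interactions, screened by
#' per-database score cutoffs and multi-database agreement, with
#' experimentally validated strong-evidence interactions. A predicted pair
#' survives when it passes its origin's cutoff in at least `min_sources`
#' distinct databases; every validated strong-evidence pair is kept
#' unconditionally. The output is deduplicated on (miRNA, gene) and labels
#' each pair as `validated`, `predicted`, or `both`.
#'
#' @param predicted `edge_table` of predicted miRNA->gene records, each with
#'   an `origin` and a numeric `score` (or categorical `score_label`).
#' @param validated `edge_table` of validated strong-evidence records; may
#'   have zero rows.
#' @param cutoffs named list of per-origin cutoffs as returned by
#'   [read_cutoff_config()]: `list(dir = "ge"|"le"|"class", value = ...)`.
#' @param min_sources minimum number of distinct databases a predicted pair
#'   must pass (>= 1).
#' @return an `edge_table` with one row per retained (miRNA, gene) pair and
#'   a `status` column in `{validated, predicted, both}`.
#' @export
consensus_target_filter <- function(predicted, validated, cutoffs,
                                    min_sources = 3L) {
  stopifnot(min_sources >= 1L)
  predicted <- validate_edge_table(as.data.frame(predicted))
  if (nrow(predicted)) {
    known <- unique(predicted$origin)
    unconfigured <- setdiff(known, names(cutoffs))
    if (length(unconfigured))
      stop("no cutoff configured for origin(s): ",
           paste(unconfigured, collapse = ", "))
    pass <- logical(nrow(predicted))
    for (origin in known) {
      idx <- predicted$origin == origin
      cu <- cutoffs[[origin]]
      pass[idx] <- switch(cu$dir,
        ge = !is.na(predicted$score[idx]) & predicted$score[idx] >= cu$value,
        le = !is.na(predicted$score[idx]) & predicted$score[idx] <= cu$value,
        class = {
          lab <- tolower(trimws(predicted$score_label[idx]))
          lab %in% tolower(trimws(unlist(cu$value)))
        })
    }
    kept <- predicted[pass, , drop = FALSE]
    key <- paste(kept$source_id, kept$target_id, sep = "\r")
    n_origins <- vapply(split(kept$origin, key),
                        function(o) length(unique(o)), 1L)
    consensus_keys <- names(n_origins)[n_origins >= min_sources]
  } else {
    consensus_keys <- character()
  }

  split_key <- function(k) do.call(rbind, strsplit(k, "\r", fixed = TRUE))
  pred_pairs <- if (length(consensus_keys)) {
    p <- split_key(consensus_keys)
    data.frame(source_id = p[, 1L], target_id = p[, 2L],
               stringsAsFactors = FALSE)
  } else data.frame(source_id = character(), target_id = character(),
                    stringsAsFactors = FALSE)

  val_pairs <- if (nrow(validated)) {
    unique(data.frame(source_id = validated$source_id,
                      target_id = validated$target_id,
                      stringsAsFactors = FALSE))
  } else data.frame(source_id = character(), target_id = character(),
                    stringsAsFactors = FALSE)

  pk <- paste(pred_pairs$source_id, pred_pairs$target_id, sep = "\r")
  vk <- paste(val_pairs$source_id, val_pairs$target_id, sep = "\r")
  all_keys <- union(vk, pk)
  if (!length(all_keys)) {
    out <- edge_table(character(), character(), "miRNA", "gene", "targets")
    out$status <- character()
    return(out)
  }
  all_keys <- sort(all_keys)
  p <- split_key(all_keys)
  status <- ifelse(all_keys %in% vk & all_keys %in% pk, "both",
                   ifelse(all_keys %in% vk, "validated", "predicted"))
  ## for pairs with predicted support, score = number of passing databases
  support <- rep(NA_real_, length(all_keys))
  if (length(consensus_keys))
    support[match(consensus_keys, all_keys)] <-
      as.numeric(n_origins[n_origins >= min_sources])
  out <- edge_table(source_id = p[, 1L], target_id = p[, 2L],
                    source_kind = "miRNA", target_kind = "gene",
                    relation = "targets",
                    evidence = ifelse(status == "validated",
                                      "validated_strong", "predicted"),
                    origin = "consensus",
                    score = support)
  out$status <- status
  rownames(out) <- NULL
  class(out) <- c("edge_table", "data.frame")
  out
}
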