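#' Quantile normalization
#'
#' Forces every sample (column) to share one value distribution: the
#' reference distribution is the vector of per-rank row means over the
#' column-sorted matrix, and each column's values are replaced by the
#' reference value at their within-column rank. Tied values within a column
#' receive the mean of the reference values across their tied rank span, so
#' the map is well defined and rank-preserving.
#'
#' @param m numeric expression matrix (features x samples).
#' @return matrix of the same shape; every column holds the same multiset
#'   of values.
#' @export
quantile_normalize <- function(m) {
  validate_expression_matrix(m)
  if (ncol(m) < 1L) stop("need at least one column")
  ref <- rowMeans(apply(m, 2L, sort))
  out <- m
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    assigned <- numeric(length(v))
    assigned[order(v)] <- ref
    # ties (equal values) get the mean reference over their rank span
    out[, j] <- stats::ave(assigned, match(v, v), FUN = mean)
  }
  out
}

#' Per-feature differential expression between case and control
#'
#' For each feature computes the log2 fold change (case mean minus control
#' mean on the log2-scale matrix) and a two-sided p-value from either an
#' empirical-Bayes moderated t-statistic or a Welch t-test, with
#' Benjamini-Hochberg adjustment across features.
#'
#' The moderated t shrinks each feature's pooled residual variance s^2
#' (d = n_case + n_control - 2 df) toward a prior s0^2 with prior df d0:
#' s_tilde^2 = (d0 s0^2 + d s^2) / (d0 + d), and refers
#' t = log2fc / (s_tilde sqrt(1/n1 + 1/n2)) to a t distribution on d0 + d
#' df. The hyperparameters (d0, s0^2) are estimated by moment matching on
#' the log sample variances (the standard scaled-F empirical Bayes fit);
#' if the fit degenerates the ordinary pooled t (d0 = 0) is used, and if
#' the log-variances underdisperse relative to trigamma(d/2) the prior
#' dominates completely (d0 = Inf, normal reference).
#'
#' @param m normalized expression matrix.
#' @param sheet [sample_sheet()] covering the columns of `m`.
#' @param method `"moderated_t"` or `"welch_t"`.
#' @param prior_df optional override of the moderated-t prior df d0 (used
#'   with `prior_var`); mainly for reproducing limit cases.
#' @param prior_var optional override of the prior variance s0^2.
#' @return data.frame with one row per feature: `feature_id`, `log2fc`,
#'   `t_stat`, `df`, `p_value`, `adj_p` (BH).
#' @export
differential_expression <- function(m, sheet,
                                    method = c("moderated_t", "welch_t"),
                                    prior_df = NULL, prior_var = NULL) {
  method <- match.arg(method)
  validate_expression_matrix(m)
  sheet <- sheet[match(colnames(m), sheet$sample_id), , drop = FALSE]
  if (any(is.na(sheet$sample_id)))
    stop("sheet does not cover all matrix columns")
  case <- sheet$group == "case"
  n1 <- sum(case); n2 <- sum(!case)
  if (n1 < 2L || n2 < 2L)
    stop("each group needs at least 2 samples (case: ", n1,
         ", control: ", n2, ")")

  x1 <- m[, case, drop = FALSE]; x2 <- m[, !case, drop = FALSE]
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  log2fc <- m1 - m2
  v1 <- apply(x1, 1L, stats::var); v2 <- apply(x2, 1L, stats::var)

  if (method == "welch_t") {
    se2 <- v1 / n1 + v2 / n2
    t_stat <- ifelse(se2 > 0, log2fc / sqrt(se2),
                     ifelse(log2fc == 0, 0, sign(log2fc) * Inf))
    df <- ifelse(se2 > 0,
                 se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))),
                 n1 + n2 - 2)
    p <- ifelse(se2 > 0, 2 * stats::pt(-abs(t_stat), df),
                ifelse(log2fc == 0, 1, 0))
  } else {
    d <- n1 + n2 - 2L
    s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / d
    if (is.null(prior_df)) {
      fit <- fit_variance_prior(s2, d)
      d0 <- fit$d0; s02 <- fit$s02
    } else {
      d0 <- prior_df
      s02 <- if (is.null(prior_var)) stats::median(s2) else prior_var
    }
    if (is.infinite(d0)) {
      s2_tilde <- rep(s02, length(s2))
      df <- rep(Inf, length(s2))
    } else {
      s2_tilde <- (d0 * s02 + d * s2) / (d0 + d)
      df <- rep(d0 + d, length(s2))
    }
    denom <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
    t_stat <- ifelse(denom > 0, log2fc / denom, 0)
    p <- ifelse(denom > 0, 2 * stats::pt(-abs(t_stat), df), 1)
    # zero shrunken variance can only arise from an all-zero-variance fit;
    # a zero difference there is a null feature by convention
    p[denom == 0 & log2fc == 0] <- 1
  }
  p[v1 == 0 & v2 == 0 & log2fc == 0] <- 1

  data.frame(feature_id = rownames(m), log2fc = log2fc, t_stat = t_stat,
             df = df, p_value = p,
             adj_p = stats::p.adjust(p, method = "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

## Moment-matching estimate of the scaled-F prior (d0, s0^2) from pooled
## per-feature variances s2 on d df, via the log-variance identity:
## E log s2 = log s0^2 + digamma(d/2) - log(d/2) - (digamma(d0/2) - log(d0/2))
## Var log s2 = trigamma(d/2) + trigamma(d0/2)
fit_variance_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L)
    return(list(d0 = 0, s02 = if (any(ok)) stats::median(s2[ok]) else 1))
  z <- log(s2[ok])
  e <- z - digamma(d / 2) + log(d / 2)
  evar <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(evar))
    return(list(d0 = 0, s02 = stats::median(s2[ok])))
  if (evar <= 0)                         # underdispersed: complete shrinkage
    return(list(d0 = Inf, s02 = exp(mean(e))))
  d0 <- 2 * trigamma_inverse(evar)
  s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s02 = s02)
}

## Newton inversion of trigamma (monotone decreasing on (0, Inf))
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Select differentially expressed miRNAs per cohort and intersect
#'
#' Per cohort: keep features with |log2fc| >= `lfc_min` and BH-adjusted
#' p < `adjp_max`; sort ascending by adjusted p (ties broken by descending
#' |log2fc|, then feature id); truncate to the `top_k` lowest; then
#' intersect the per-cohort lists.
#'
#' @param results_per_cohort named list of [differential_expression()]
#'   result data.frames (one per cohort).
#' @param lfc_min minimum absolute log2 fold change (> 0).
#' @param adjp_max adjusted-p threshold.
#' @param top_k per-cohort list size cap (>= 1).
#' @return list with `per_cohort` (named list of id vectors, each the
#'   ordered truncated DEM list), `n_dems` (per-cohort DEM totals before
#'   truncation) and `intersection` (character vector of common DEMs).
#' @export
select_and_intersect_dems <- function(results_per_cohort, lfc_min = 1,
                                      adjp_max = 0.01, top_k = 500L) {
  stopifnot(lfc_min > 0, top_k >= 1L)
  if (!length(results_per_cohort))
    stop("no cohort results supplied")
  per_cohort <- lapply(results_per_cohort, function(res) {
    keep <- abs(res$log2fc) >= lfc_min & res$adj_p < adjp_max
    res <- res[keep, , drop = FALSE]
    ord <- order(res$adj_p, -abs(res$log2fc), res$feature_id)
    utils::head(res$feature_id[ord], top_k)
  })
  n_dems <- vapply(results_per_cohort, function(res)
    sum(abs(res$log2fc) >= lfc_min & res$adj_p < adjp_max), 1L)
  list(per_cohort = per_cohort,
       n_dems = n_dems,
       intersection = Reduce(intersect, per_cohort))
}
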