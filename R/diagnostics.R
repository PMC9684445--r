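#' Single-marker ROC analysis with Youden-optimal cutoff
#'
#' AUC is computed by the rank (Mann-Whitney) formula with half credit for
#' ties. Orientation is fixed so that AUC >= 0.5: when the raw AUC for
#' "cases have higher values" falls below 0.5 the marker is flipped and the
#' recorded `direction` becomes `"<"` (controls higher). The standard error
#' is Hanley-McNeil with Q1 = A/(2-A), Q2 = 2A^2/(1+A); the 95% CI is
#' A +/- 1.96 se, clipped to \[0, 1\]. The optimal cutoff maximizes the
#' Youden index J = sensitivity + specificity - 1 over midpoints between
#' adjacent distinct observed values (plus -Inf/+Inf), ties resolved toward
#' the lower cutoff.
#'
#' @param scores numeric marker values, one per sample.
#' @param labels `"case"`/`"control"` per sample (or logical, TRUE = case).
#' @return list of class `roc_result`: `auc`, `se_auc`, `ci95`, `youden_j`,
#'   `cutoff`, `sensitivity`, `specificity`, `direction`, `n_case`,
#'   `n_control`, and `curve` (data.frame of ROC points).
#' @export
roc_analysis <- function(scores, labels) {
  if (is.logical(labels)) labels <- ifelse(labels, "case", "control")
  stopifnot(length(scores) == length(labels))
  is_case <- labels == "case"
  n1 <- sum(is_case); n0 <- sum(!is_case)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")

  r <- rank(scores, ties.method = "average")
  auc_raw <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  flipped <- auc_raw < 0.5
  direction <- if (flipped) "<" else ">"
  work <- if (flipped) -scores else scores
  auc <- if (flipped) 1 - auc_raw else auc_raw

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
                (n0 - 1) * (q2 - auc^2)) / (n1 * n0))
  ci95 <- pmin(1, pmax(0, auc + c(-1, 1) * 1.96 * se))

  ## candidate thresholds: midpoints between adjacent distinct values, +/-Inf
  v <- sort(unique(work))
  thr <- c(-Inf, if (length(v) > 1L) (v[-1L] + v[-length(v)]) / 2, Inf)
  sens <- vapply(thr, function(ct) mean(work[is_case] > ct), 1)
  spec <- vapply(thr, function(ct) mean(work[!is_case] <= ct), 1)
  j <- sens + spec - 1
  best <- which(j == max(j))[1L]            # ties -> lower threshold
  cutoff <- if (flipped) -thr[best] else thr[best]

  structure(list(auc = auc, se_auc = se, ci95 = ci95,
                 youden_j = j[best], cutoff = cutoff,
                 sensitivity = sens[best], specificity = spec[best],
                 direction = direction, n_case = n1, n_control = n0,
                 ci_method = "hanley-mcneil",
                 curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.4f (HM se %.4f, 95%% CI %.4f-%.4f)\n", x$auc, x$se_auc,
    x$ci95[1], x$ci95[2]))
  cat(sprintf(
    "  Youden J %.4f at cutoff %.4g (sens %.4f, spec %.4f, direction %s)\n",
    x$youden_j, x$cutoff, x$sensitivity, x$specificity, x$direction))
  cat(sprintf("  n_case %d, n_control %d\n", x$n_case, x$n_control))
  invisible(x)
}

#' Fit a multi-marker logistic diagnostic panel
#'
#' Fits case/control ~ markers by binomial logistic regression (iteratively
#' reweighted least squares via `glm`), then evaluates the panel by ROC
#' analysis of the fitted probabilities. When no held-out data are given
#' the ROC is in-sample, mirroring a fit-and-evaluate-per-dataset design.
#'
#' @param m expression matrix restricted to the member markers
#'   (features x samples, >= 2 members).
#' @param labels `"case"`/`"control"` per column of `m`.
#' @param max_iter IRLS iteration cap.
#' @param tol convergence tolerance on the deviance (passed to `glm`).
#' @param newdata,newlabels optional held-out matrix/labels; when supplied
#'   the panel ROC is computed on the held-out predictions instead.
#' @return list of class `panel_model`: `member_ids`, `coefficients`
#'   (intercept first, log-odds units), `fitted_scores`, `separation`
#'   (TRUE when perfect separation was detected; coefficients are the
#'   finite-iteration values), and `roc` (a `roc_result`).
#' @export
fit_panel <- function(m, labels, max_iter = 100L, tol = 1e-8,
                      newdata = NULL, newlabels = NULL) {
  validate_expression_matrix(m)
  if (nrow(m) < 2L) stop("a panel needs at least 2 member markers")
  if (is.logical(labels)) labels <- ifelse(labels, "case", "control")
  y <- as.integer(labels == "case")
  x <- t(m)
  const <- apply(x, 2L, function(col) stats::var(col) == 0)
  if (any(const))
    stop("constant-valued member(s): ",
         paste(rownames(m)[const], collapse = ", "))
  design <- cbind(`(Intercept)` = 1, x)
  if (qr(design)$rank < ncol(design))
    stop("singular design: collinear panel members")

  fit <- withCallingHandlers(
    stats::glm.fit(design, y, family = stats::binomial(),
                   control = list(maxit = max_iter, epsilon = tol)),
    warning = function(w) invokeRestart("muffleWarning"))
  prob <- fit$fitted.values
  separation <- any(prob > 1 - 1e-8) || any(prob < 1e-8) || !fit$converged

  if (!is.null(newdata)) {
    eta <- cbind(1, t(newdata[rownames(m), , drop = FALSE])) %*%
      fit$coefficients
    scores <- as.numeric(stats::plogis(eta))
    roc <- roc_analysis(scores, newlabels)
  } else {
    roc <- roc_analysis(prob, labels)
  }

  structure(list(member_ids = rownames(m),
                 coefficients = fit$coefficients,
                 fitted_scores = prob,
                 separation = separation,
                 roc = roc),
            class = "panel_model")
}

#' @export
print.panel_model <- function(x, ...) {
  cat("Logistic panel:", paste(x$member_ids, collapse = " + "), "\n")
  print(round(x$coefficients, 4))
  if (x$separation) cat("  [perfect separation flagged]\n")
  print(x$roc)
  invisible(x)
}
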