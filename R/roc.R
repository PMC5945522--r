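#' Area under the ROC curve
#'
#' The probability that a randomly chosen case outscores a randomly
#' chosen control, with ties counted one half — the normalized
#' Mann-Whitney U statistic. Computed exactly via midranks.
#'
#' @param scores numeric scores, higher = more case-like.
#' @param labels binary labels (0/1, logical, or a two-level factor whose
#'   second level is the case).
#' @return AUC in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  if (length(scores) != length(y))
    input_error("scores and labels differ in length")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    input_error("both classes must be present to compute an AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) return(as.numeric(labels == levels(labels)[2]))
  y <- as.numeric(labels)
  if (!all(y %in% c(0, 1))) input_error("labels must be binary")
  y
}

# Placement values: for each case, the fraction of controls it beats
# (V10), and for each control, the fraction of cases it loses to (V01).
placements <- function(scores, y) {
  s1 <- scores[y == 1]; s0 <- scores[y == 0]
  v10 <- vapply(s1, function(s) mean((s > s0) + 0.5 * (s == s0)),
                numeric(1))
  v01 <- vapply(s0, function(s) mean((s1 > s) + 0.5 * (s1 == s)),
                numeric(1))
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong confidence interval for a single AUC
#'
#' Nonparametric variance of the AUC from placement values, with a
#' normal-approximation interval on the AUC scale truncated to \[0, 1\].
#'
#' @inheritParams auc
#' @param level confidence level (default 0.95).
#' @return list with `auc`, `se`, `ci` (length-2 vector), `level`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  y <- as_binary_labels(labels)
  pl <- placements(scores, y)
  v <- stats::var(pl$v10) / length(pl$v10) +
    stats::var(pl$v01) / length(pl$v01)
  se <- sqrt(v)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * se, 0), 1)
  list(auc = pl$auc, se = se, ci = ci, level = level)
}

#' DeLong test for two paired (correlated) AUCs
#'
#' Compares the AUCs of two score vectors computed on the same samples
#' and labels. The covariance of the two AUCs is estimated from the
#' placement values of cases and controls under each scoring; the
#' two-sided p-value comes from the normal approximation of the
#' standardized AUC difference. If the estimated variance of the
#' difference is zero (e.g. identical score vectors) the p-value is 1 by
#' convention and the result is flagged `degenerate`.
#'
#' @param scores0,scores1 paired score vectors (same samples, same order).
#' @param labels binary labels shared by both scorings.
#' @return list with `auc0`, `auc1`, `diff`, `se_diff`, `z`, `p`,
#'   `degenerate`.
#' @export
delong_test <- function(scores0, scores1, labels) {
  y <- as_binary_labels(labels)
  if (length(scores0) != length(y) || length(scores1) != length(y))
    input_error("paired scores must cover the same samples")
  p0 <- placements(scores0, y)
  p1 <- placements(scores1, y)
  n1 <- length(p0$v10); n0 <- length(p0$v01)
  s10 <- stats::cov(cbind(p0$v10, p1$v10))
  s01 <- stats::cov(cbind(p0$v01, p1$v01))
  S <- s10 / n1 + s01 / n0
  vdiff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- p1$auc - p0$auc
  if (vdiff <= .Machine$double.eps) {
    return(list(auc0 = p0$auc, auc1 = p1$auc, diff = d,
                se_diff = 0, z = NA_real_, p = 1, degenerate = TRUE))
  }
  z <- d / sqrt(vdiff)
  list(auc0 = p0$auc, auc1 = p1$auc, diff = d, se_diff = sqrt(vdiff),
       z = z, p = 2 * stats::pnorm(-abs(z)), degenerate = FALSE)
}

#' Compare a risk-factor model with and without a miRNA panel
#'
#' Fits two logistic models of case status on the same samples: Model 0
#' with the traditional risk factors (age, smoking) and Model 1 with the
#' risk factors plus one expression covariate (`-dCt`, log2-abundance
#' scale) per panel miRNA. Both models are scored by fitted
#' probabilities (apparent AUC) and compared with the paired DeLong
#' test. Samples missing any panel assay are dropped listwise; the run
#' aborts if any panel assay is missing for more than `max_missing` of
#' samples.
#'
#' @param d a [delta_ct()] matrix (or any samples x assays expression
#'   matrix on the `-dCt` sign convention after negation).
#' @param meta a [cohort_metadata()] table.
#' @param panel miRNA/assay ids to add in Model 1.
#' @param case_classes classes counted as cases; default all cancer
#'   subtypes.
#' @param control_class reference class.
#' @param max_missing maximum tolerated fraction of samples missing a
#'   panel assay (default 0.2).
#' @return object of class `model_comparison`: list with `auc0`, `ci0`,
#'   `auc1`, `ci1`, `delong_p`, `n_cases`, `n_controls`, `n_dropped`,
#'   `models`.
#' @export
compare_models <- function(d, meta, panel,
                           case_classes = setdiff(BC_CLASSES, "control"),
                           control_class = "control", max_missing = 0.2) {
  miss <- setdiff(panel, colnames(d))
  if (length(miss))
    input_error(sprintf("panel assay '%s' not measured", miss[1]))
  grp <- qpcr_groups(d, meta, c(control_class, case_classes))
  y <- as.numeric(grp$class %in% case_classes)
  expr <- -grp$d[, panel, drop = FALSE]
  frac_missing <- colMeans(is.na(expr))
  if (any(frac_missing > max_missing))
    input_error(sprintf(
      "panel assay '%s' missing for %.0f%% of samples (max %.0f%%)",
      panel[which.max(frac_missing)], 100 * max(frac_missing),
      100 * max_missing))
  covar <- covariate_matrix(grp$meta)
  complete <- stats::complete.cases(expr) & stats::complete.cases(covar)
  n_dropped <- sum(!complete)
  y <- y[complete]
  if (all(y == 1) || all(y == 0))
    input_error("both cases and controls are needed")

  X0 <- cbind(1, covar[complete, , drop = FALSE])
  X1 <- cbind(X0, expr[complete, , drop = FALSE])
  fit0 <- suppressWarnings(stats::glm.fit(X0, y,
                                          family = stats::binomial(),
                                          control = list(maxit = 100)))
  fit1 <- suppressWarnings(stats::glm.fit(X1, y,
                                          family = stats::binomial(),
                                          control = list(maxit = 100)))
  dl <- delong_test(fit0$fitted.values, fit1$fitted.values, y)
  structure(list(auc0 = dl$auc0, ci0 = delong_ci(fit0$fitted.values, y)$ci,
                 auc1 = dl$auc1, ci1 = delong_ci(fit1$fitted.values, y)$ci,
                 delong_p = dl$p, delong_z = dl$z,
                 n_cases = sum(y == 1), n_controls = sum(y == 0),
                 n_dropped = n_dropped,
                 models = list(model0 = c("age", "smoking"),
                               model1 = c("age", "smoking", panel))),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    "Model 0 (age + smoking):      AUC = %.2f (95%% CI %.2f-%.2f)\n",
    x$auc0, x$ci0[1], x$ci0[2]))
  cat(sprintf(
    "Model 1 (+ %d-miRNA panel):    AUC = %.2f (95%% CI %.2f-%.2f)\n",
    length(x$models$model1) - 2, x$auc1, x$ci1[1], x$ci1[2]))
  cat(sprintf("DeLong test p = %.3g  (%d cases / %d controls)\n",
              x$delong_p, x$n_cases, x$n_controls))
  invisible(x)
}
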