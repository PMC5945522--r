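#' Construct a qPCR Ct matrix
#'
#' Raw cycle-threshold values, one row per sample and one column per
#' assay, with designated endogenous-control assays and an optional
#' spike-in. Ct values must lie in (0, 45); missing values are allowed
#' (undetected assays) and are flagged downstream.
#'
#' @param ct numeric matrix, samples x assays, with dimnames.
#' @param controls assay ids used as endogenous controls.
#' @param spike_in optional spike-in assay id (QC only, never used for
#'   normalization).
#' @return matrix of class `ct_matrix` with `controls` / `spike_in`
#'   attributes.
#' @export
ct_matrix <- function(ct, controls, spike_in = NULL) {
  if (!is.matrix(ct)) ct <- as.matrix(ct)
  if (is.null(rownames(ct)) || is.null(colnames(ct)))
    input_error("Ct matrix needs sample rownames and assay colnames")
  bad <- which(!is.na(ct) & (ct <= 0 | ct >= 45), arr.ind = TRUE)
  if (nrow(bad))
    input_error(sprintf("Ct value out of (0, 45) at sample '%s', assay '%s'",
                        rownames(ct)[bad[1, 1]], colnames(ct)[bad[1, 2]]))
  miss <- setdiff(c(controls, spike_in), colnames(ct))
  if (length(miss))
    input_error(sprintf("designated assay '%s' not present", miss[1]))
  structure(ct, controls = controls, spike_in = spike_in,
            class = c("ct_matrix", class(ct)))
}

#' Read a long-format Ct table
#'
#' Expects a TSV with columns `sample_id`, `assay_id`, `ct`.
#'
#' @param path input TSV path.
#' @param controls,spike_in passed to [ct_matrix()].
#' @export
read_ct <- function(path, controls, spike_in = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay_id", "ct")
  if (!all(need %in% names(df)))
    input_error("Ct TSV needs columns sample_id, assay_id, ct")
  samples <- unique(df$sample_id)
  assays <- unique(df$assay_id)
  ct <- matrix(NA_real_, length(samples), length(assays),
               dimnames = list(samples, assays))
  ct[cbind(match(df$sample_id, samples), match(df$assay_id, assays))] <-
    df$ct
  ct_matrix(ct, controls = controls, spike_in = spike_in)
}

#' Write a Ct matrix as a long-format TSV
#' @param ct a [ct_matrix()].
#' @param path output path.
#' @export
write_ct <- function(ct, path) {
  df <- data.frame(sample_id = rep(rownames(ct), times = ncol(ct)),
                   assay_id = rep(colnames(ct), each = nrow(ct)),
                   ct = as.vector(ct))
  df <- df[!is.na(df$ct), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Spike-in quality flag
#'
#' The spike-in enters every reverse-transcription reaction at a fixed
#' amount, so its Ct should be near-constant; a standard deviation above
#' `max_sd` cycles indicates technical drift between runs.
#'
#' @param ct a [ct_matrix()] with a designated spike-in.
#' @param max_sd flag threshold in Ct cycles (default 1.0).
#' @return list with the spike-in `sd` and logical `ok`.
#' @export
spike_in_qc <- function(ct, max_sd = 1.0) {
  sp <- attr(ct, "spike_in")
  if (is.null(sp)) input_error("no spike-in assay designated")
  s <- stats::sd(ct[, sp], na.rm = TRUE)
  list(sd = s, ok = s <= max_sd)
}

#' Delta-Ct normalization to endogenous controls
#'
#' For each sample, the mean Ct of the endogenous-control assays is
#' subtracted from every target assay's Ct:
#' `dCt = Ct(target) - mean(Ct(controls))`. Lower dCt means higher
#' expression. Samples missing any control measurement are excluded and
#' reported in the `"excluded_samples"` attribute.
#'
#' @param ct a [ct_matrix()] with designated control assays.
#' @return samples x target-assays matrix of dCt values (controls and
#'   spike-in removed), class `dct_matrix`.
#' @export
delta_ct <- function(ct) {
  controls <- attr(ct, "controls")
  if (is.null(controls) || length(controls) == 0)
    input_error("no endogenous-control assays designated")
  ctrl <- unclass(ct)[, controls, drop = FALSE]
  ok <- rowSums(is.na(ctrl)) == 0
  if (!all(ok))
    message(sum(!ok), " sample(s) excluded: missing endogenous-control Ct")
  targets <- setdiff(colnames(ct), c(controls, attr(ct, "spike_in")))
  d <- unclass(ct)[ok, targets, drop = FALSE] - rowMeans(ctrl[ok, , drop = FALSE])
  structure(d, excluded_samples = rownames(ct)[!ok],
            class = c("dct_matrix", "matrix", "array"))
}

#' Delta-delta-Ct log2 fold changes for one subtype
#'
#' `ddCt = mean dCt(subtype) - mean dCt(controls)`; the log2 fold change
#' is `-ddCt` (the usual 2^-ddCt quantification expressed in log2
#' units), so positive values mean up-regulation in the subtype.
#'
#' @param d a [delta_ct()] matrix.
#' @param meta a [cohort_metadata()] table.
#' @param subtype cancer class contrasted against `control_class`.
#' @param control_class reference class.
#' @return data.frame with `assay_id`, group mean dCts, `ddct`, `log2fc`.
#' @export
ddct_log2fc <- function(d, meta, subtype, control_class = "control") {
  grp <- qpcr_groups(d, meta, c(control_class, subtype))
  case <- grp$class == subtype
  if (!any(case) || all(case))
    input_error("both groups must be non-empty")
  dd <- colMeans(grp$d[case, , drop = FALSE], na.rm = TRUE) -
    colMeans(grp$d[!case, , drop = FALSE], na.rm = TRUE)
  data.frame(assay_id = colnames(grp$d),
             mean_dct_case = colMeans(grp$d[case, , drop = FALSE],
                                      na.rm = TRUE),
             mean_dct_control = colMeans(grp$d[!case, , drop = FALSE],
                                         na.rm = TRUE),
             ddct = dd, log2fc = -dd, row.names = NULL)
}

# Align a dCt matrix with metadata restricted to the given classes.
qpcr_groups <- function(d, meta, classes) {
  idx <- match(rownames(d), meta$sample_id)
  if (anyNA(idx))
    input_error("dCt samples missing from metadata")
  meta <- meta[idx, , drop = FALSE]
  keep <- meta$class %in% classes
  list(d = unclass(d)[keep, , drop = FALSE],
       meta = meta[keep, , drop = FALSE],
       class = as.character(meta$class[keep]))
}

#' Covariate-adjusted association between expression and case status
#'
#' For each assay, logistic regression of case status on the expression
#' level `-dCt`, adjusted for age and smoking (indicator contrasts
#' against never-smokers). The Wald p-value of the expression coefficient
#' is reported, BH-adjusted across the subtype's assay panel. Complete
#' separation is handled by a Firth-type penalized fit (flagged).
#' Constant-expression assays get a missing p-value.
#'
#' @inheritParams ddct_log2fc
#' @return data.frame with `assay_id`, `estimate` (log-odds per
#'   `-dCt` unit), `p`, `fdr`, `method` ("ml", "firth" or "none").
#' @export
association_test <- function(d, meta, subtype, control_class = "control") {
  grp <- qpcr_groups(d, meta, c(control_class, subtype))
  y <- as.numeric(grp$class == subtype)
  if (all(y == 1) || all(y == 0)) input_error("both groups must be present")
  covar <- covariate_matrix(grp$meta)
  res <- lapply(seq_len(ncol(grp$d)), function(i) {
    expr <- -grp$d[, i]
    ok <- !is.na(expr)
    logistic_wald(cbind(expr = expr, covar)[ok, , drop = FALSE], y[ok],
                  term = "expr")
  })
  out <- data.frame(assay_id = colnames(grp$d),
                    estimate = vapply(res, `[[`, numeric(1), "estimate"),
                    p = vapply(res, `[[`, numeric(1), "p"),
                    method = vapply(res, `[[`, character(1), "method"),
                    row.names = NULL)
  out$fdr <- bh_adjust(out$p)
  out[, c("assay_id", "estimate", "p", "fdr", "method")]
}

# age + smoking design columns (never-smoker reference), no intercept.
covariate_matrix <- function(meta) {
  sm <- factor(as.character(meta$smoking), levels = SMOKING_LEVELS)
  cbind(age = meta$age,
        smoking_former = as.numeric(sm == "former"),
        smoking_current = as.numeric(sm == "current"))
}

# Wald test for one coefficient of a logistic model with intercept.
# Falls back to a Firth-type penalized fit when the ML fit separates.
logistic_wald <- function(xmat, y, term) {
  keep <- apply(xmat, 2, function(col) stats::sd(col) > 0)
  if (!isTRUE(unname(keep[term])))
    return(list(estimate = NA_real_, p = NA_real_, method = "none"))
  X <- cbind(`(Intercept)` = 1, xmat[, keep, drop = FALSE])
  j <- which(colnames(X) == term)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 100)))
  p_hat <- fit$fitted.values
  separated <- !fit$converged || any(p_hat > 1 - 1e-8) || any(p_hat < 1e-8) ||
    any(abs(fit$coefficients) > 20)
  if (!separated) {
    v <- tryCatch(solve(crossprod(X * sqrt(fit$weights))),
                  error = function(e) NULL)
    if (!is.null(v) && v[j, j] > 0) {
      z <- fit$coefficients[j] / sqrt(v[j, j])
      return(list(estimate = unname(fit$coefficients[j]),
                  p = 2 * stats::pnorm(-abs(z)), method = "ml"))
    }
  }
  f <- firth_logistic(X, y)
  if (is.null(f))
    return(list(estimate = NA_real_, p = NA_real_, method = "none"))
  z <- f$coef[j] / f$se[j]
  list(estimate = unname(f$coef[j]), p = 2 * stats::pnorm(-abs(z)),
       method = "firth")
}

# Firth-penalized logistic regression (Jeffreys-prior score correction).
firth_logistic <- function(X, y, maxit = 100, tol = 1e-8) {
  beta <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    w <- pmax(p * (1 - p), 1e-10)
    XW <- X * sqrt(w)
    info <- crossprod(XW)
    inv <- tryCatch(solve(info), error = function(e) NULL)
    if (is.null(inv)) return(NULL)
    h <- rowSums((XW %*% inv) * XW)
    score <- drop(crossprod(X, y - p + h * (0.5 - p)))
    step <- drop(inv %*% score)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- drop(X %*% beta)
  p <- 1 / (1 + exp(-eta))
  w <- pmax(p * (1 - p), 1e-10)
  inv <- tryCatch(solve(crossprod(X * sqrt(w))), error = function(e) NULL)
  if (is.null(inv)) return(NULL)
  list(coef = beta, se = sqrt(diag(inv)))
}

#' Ordered-subtype trend test
#'
#' Tests for a monotone shift of expression across the ordered disease
#' states control < NMIBC G1+G2 < NMIBC G3 < MIBC. Expression (`-dCt`)
#' is regressed on the ordinal group score (0, 1, 2, ...), by default
#' adjusting for age and smoking; the two-sided p-value of the slope is
#' reported per assay. In cases-only mode the control group is dropped
#' and the remaining groups are re-scored consecutively.
#'
#' @param d a [delta_ct()] matrix.
#' @param meta a [cohort_metadata()] table.
#' @param cases_only drop controls and test the trend across cancer
#'   subtypes only.
#' @param adjust include age and smoking covariates (default `TRUE`).
#' @return data.frame with `assay_id`, `slope` (expression change per
#'   ordinal step), `trend_p`.
#' @export
trend_test <- function(d, meta, cases_only = FALSE, adjust = TRUE) {
  classes <- if (cases_only) setdiff(BC_CLASSES, "control") else BC_CLASSES
  grp <- qpcr_groups(d, meta, classes)
  present <- classes[classes %in% unique(grp$class)]
  if (length(present) < 2)
    input_error("need at least 2 ordered groups for a trend test")
  score <- match(grp$class, present) - 1
  covar <- if (adjust) covariate_matrix(grp$meta) else NULL
  res <- vapply(seq_len(ncol(grp$d)), function(i) {
    expr <- -grp$d[, i]
    ok <- !is.na(expr)
    X <- cbind(1, score = score, covar)[ok, , drop = FALSE]
    if (stats::sd(score[ok]) == 0 || stats::sd(expr[ok]) == 0)
      return(c(NA_real_, NA_real_))
    fit <- stats::lm.fit(X, expr[ok])
    rdf <- length(fit$residuals) - fit$rank
    if (rdf < 1) return(c(NA_real_, NA_real_))
    sigma2 <- sum(fit$residuals^2) / rdf
    xtxi <- tryCatch(solve(crossprod(X)), error = function(e) NULL)
    if (is.null(xtxi)) return(c(NA_real_, NA_real_))
    se <- sqrt(sigma2 * xtxi[2, 2])
    tval <- fit$coefficients[2] / se
    c(fit$coefficients[2], 2 * stats::pt(-abs(tval), rdf))
  }, numeric(2))
  data.frame(assay_id = colnames(grp$d),
             slope = res[1, ], trend_p = res[2, ], row.names = NULL)
}
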