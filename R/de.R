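#' Median-of-ratios size factors
#'
#' Per-sample depth multipliers estimated by the median-of-ratios
#' convention for negative-binomial count models: each sample's counts are
#' divided by the per-miRNA geometric mean over samples (restricted to
#' miRNAs with a strictly positive geometric mean, i.e. no zero in any
#' sample), and the sample's factor is the median of those ratios. Factors
#' are rescaled so their geometric mean is exactly 1, which anchors the
#' normalized scale.
#'
#' @param m a count matrix (miRNA x sample).
#' @return numeric vector of positive size factors named by sample, class
#'   `size_factors`.
#' @export
size_factors <- function(m) {
  if (nrow(m) == 0 || ncol(m) == 0)
    input_error("empty count matrix")
  logk <- log(m)
  loggeo <- rowMeans(logk)                       # -Inf when any zero
  use <- is.finite(loggeo)
  if (!any(use))
    input_error(paste("no miRNA has nonzero counts in every sample;",
                      "median-of-ratios is undefined (consider a",
                      "pseudo-reference fallback)"),
                class = "urimir_normalization_error")
  ratio <- exp(logk[use, , drop = FALSE] - loggeo[use])
  sf <- apply(ratio, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))                  # geometric mean 1
  structure(sf, names = colnames(m), class = "size_factors")
}

# Depth-normalized counts k_ij / s_j.
normalize_counts <- function(m, sf = NULL) {
  if (is.null(sf)) sf <- size_factors(m)
  sweep(unclass(m), 2, unclass(sf), "/")
}

#' Per-miRNA dispersion estimation with trend shrinkage
#'
#' Method-of-moments estimate of the negative-binomial dispersion
#' (`Var = mu + alpha * mu^2`) computed on depth-normalized counts within
#' design groups, pooled across groups by residual degrees of freedom,
#' then shrunk halfway (by default) towards a mean-dispersion trend
#' `alpha(mu) = a0 + a1/mu` fitted by least squares over all miRNAs.
#' Shrinkage towards the trend stabilises the noisy per-feature moment
#' estimates at the moderate sample sizes typical of discovery cohorts.
#'
#' @param m a count matrix.
#' @param group factor of design groups (e.g. the class labels of the
#'   samples in `m`).
#' @param sf size factors; computed from `m` when `NULL`.
#' @param trend_weight weight of the trend component in the final
#'   estimate (0 = pure moment estimate, 1 = pure trend). Default 0.5.
#' @return numeric vector `alpha_hat` named by miRNA, with the fitted
#'   trend coefficients in the `"trend"` attribute.
#' @export
estimate_dispersion <- function(m, group, sf = NULL, trend_weight = 0.5) {
  group <- droplevels(as.factor(group))
  if (length(group) != ncol(m))
    input_error("group length must match the number of samples")
  if (ncol(m) - nlevels(group) < 3)
    input_error("need at least 3 residual degrees of freedom")
  if (is.null(sf)) sf <- size_factors(m)
  x <- normalize_counts(m, sf)
  mu_all <- rowMeans(x)

  num <- rep(0, nrow(m)); den <- 0
  for (g in levels(group)) {
    sel <- group == g
    xg <- x[, sel, drop = FALSE]
    ng <- ncol(xg)
    if (ng < 2) next
    mg <- rowMeans(xg)
    vg <- rowSums((xg - mg)^2) / (ng - 1)
    # per-group MoM: Var(k/s) ~ mu * mean(1/s) + alpha * mu^2
    cg <- mean(1 / unclass(sf)[sel])
    ag <- ifelse(mg > 0, pmax(0, (vg - mg * cg) / mg^2), 0)
    num <- num + (ng - 1) * ag
    den <- den + (ng - 1)
  }
  alpha_mom <- num / den

  pos <- mu_all > 0
  if (sum(pos) < 10) {
    warning("fewer than 10 miRNAs; dispersion trend replaced by global mean")
    trend <- rep(mean(alpha_mom[pos]), nrow(m))
    coefs <- c(a0 = mean(alpha_mom[pos]), a1 = 0)
  } else {
    fit <- stats::lm.fit(cbind(1, 1 / mu_all[pos]), alpha_mom[pos])
    coefs <- c(a0 = fit$coefficients[[1]], a1 = fit$coefficients[[2]])
    trend <- rep(NA_real_, nrow(m))
    trend[pos] <- coefs[1] + coefs[2] / mu_all[pos]
    trend[!pos] <- 0
  }
  trend <- pmax(trend, 0)
  alpha_hat <- pmax((1 - trend_weight) * alpha_mom + trend_weight * trend,
                    1e-8)
  names(alpha_hat) <- rownames(m)
  attr(alpha_hat, "trend") <- coefs
  alpha_hat
}

#' Negative-binomial Wald test of a cancer subtype against controls
#'
#' For each miRNA, fits a negative-binomial generalized linear model with
#' log link, `log(size factor)` offsets and fixed per-miRNA dispersion by
#' iteratively reweighted least squares. The design is an intercept, the
#' subtype indicator and any surrogate-variable columns. The subtype
#' coefficient is reported in log2 units with a Wald p-value from the
#' normal approximation of `beta / SE`, and Benjamini-Hochberg adjusted
#' p-values are computed over all miRNAs tested in this comparison.
#'
#' miRNAs whose fit does not converge (including all-zero rows) are
#' flagged, their p-value set missing, and they are excluded from the
#' multiple-testing burden; the count of such rows is reported in the
#' `"n_failed"` attribute.
#'
#' @param m a count matrix covering (at least) the subtype and control
#'   samples.
#' @param meta a [cohort_metadata()] table.
#' @param subtype the cancer class to contrast against `control_class`.
#' @param sv optional surrogate-variable matrix (samples x components,
#'   rownames = sample ids) as returned by [estimate_sv()]; its rows for
#'   the comparison's samples enter the design.
#' @param sf,dispersions optional precomputed size factors / dispersions
#'   for the comparison's samples; computed internally when `NULL`.
#' @param control_class reference class, default `"control"`.
#' @param maxit IRLS iteration cap per miRNA.
#' @return a `data.frame` of class `de_result` with columns `mirna_id`,
#'   `mean_read_count`, `log2fc`, `dispersion`, `se`, `wald_stat`, `p`,
#'   `fdr`, `converged`.
#' @export
nb_wald_test <- function(m, meta, subtype, sv = NULL, sf = NULL,
                         dispersions = NULL, control_class = "control",
                         maxit = 50) {
  meta <- align_metadata(m, meta)
  if (!subtype %in% meta$class)
    input_error(sprintf("no '%s' samples present", subtype))
  if (!control_class %in% meta$class)
    input_error(sprintf("no '%s' samples present", control_class))
  keep <- meta$class %in% c(subtype, control_class)
  m2 <- m[, keep, drop = FALSE]
  meta2 <- meta[keep, , drop = FALSE]
  is_case <- as.numeric(meta2$class == subtype)

  if (is.null(sf)) sf <- size_factors(m2)
  if (is.null(dispersions))
    dispersions <- estimate_dispersion(m2, factor(is_case), sf = sf)

  X <- cbind(`(Intercept)` = 1, subtype = is_case)
  if (!is.null(sv)) {
    svm <- if (inherits(sv, "surrogate_variables")) sv$sv else sv
    if (!is.null(svm) && ncol(svm) > 0) {
      if (is.null(rownames(svm)))
        input_error("surrogate-variable matrix must have sample rownames")
      idx <- match(colnames(m2), rownames(svm))
      if (anyNA(idx))
        input_error("surrogate variables missing for some samples")
      X <- cbind(X, svm[idx, , drop = FALSE])
    }
  }
  off <- log(unclass(sf))

  p_mirna <- nrow(m2)
  log2fc <- se <- wald <- pval <- rep(NA_real_, p_mirna)
  conv <- rep(FALSE, p_mirna)
  ln2 <- log(2)
  for (i in seq_len(p_mirna)) {
    y <- m2[i, ]
    if (all(y == 0)) next
    theta <- min(1 / dispersions[i], 1e8)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, y,
                                      family = MASS::negative.binomial(theta),
                                      offset = off,
                                      control = list(maxit = maxit))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || anyNA(fit$coefficients)) next
    b <- fit$coefficients[2]
    w <- fit$weights
    xtwx <- crossprod(X * sqrt(w))
    v <- tryCatch(solve(xtwx), error = function(e) NULL)
    if (is.null(v) || v[2, 2] <= 0) next
    conv[i] <- TRUE
    log2fc[i] <- b / ln2
    se[i] <- sqrt(v[2, 2]) / ln2
    wald[i] <- log2fc[i] / se[i]
    pval[i] <- 2 * stats::pnorm(-abs(wald[i]))
  }

  out <- data.frame(mirna_id = rownames(m2),
                    mean_read_count = rowMeans(unclass(m2)),
                    log2fc = log2fc,
                    dispersion = as.numeric(dispersions),
                    se = se, wald_stat = wald, p = pval,
                    fdr = bh_adjust(pval),
                    converged = conv,
                    row.names = NULL)
  attr(out, "comparison") <- c(subtype = subtype, control = control_class)
  attr(out, "n_failed") <- sum(!conv)
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values mapped back to input order; missing values are
#' passed through and excluded from the multiple-testing burden.
#'
#' @param p numeric vector of p-values in \[0, 1\] (NAs allowed).
#' @return vector of BH-adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    input_error("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}
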