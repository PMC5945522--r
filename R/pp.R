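#' Per-miRNA predictive power
#'
#' Scores each miRNA by how well its expression level alone predicts the
#' case/control label. A single-covariate logistic model
#' `class ~ log2(1 + normalized count)` is fitted and scored as
#' classification accuracy, with the probability cutoff at the training
#' prevalence (0.5 for a balanced training set). The default scheme is
#' leave-one-out cross-validation (each sample predicted by a model
#' fitted without it), which guards against the optimism of in-sample
#' accuracy; `scheme = "apparent"` gives the in-sample figure.
#'
#' When the training data are completely separated (all case values above
#' all control values, or vice versa) the logistic MLE diverges but the
#' induced classifier is still well defined; a midpoint-threshold rule on
#' the covariate is used in that case. A constant covariate yields the
#' majority-class prediction, so its predictive power equals the majority
#' class proportion.
#'
#' @param m a count matrix covering the subtype and control samples.
#' @param meta a [cohort_metadata()] table.
#' @param subtype cancer class contrasted against `control_class`.
#' @param sf optional size factors for the comparison's samples.
#' @param scheme `"loocv"` (default) or `"apparent"`.
#' @param control_class reference class.
#' @return data.frame of class `pp_result` with columns `mirna_id`, `pp`,
#'   `pass_070`.
#' @export
predictive_power <- function(m, meta, subtype, sf = NULL,
                             scheme = c("loocv", "apparent"),
                             control_class = "control") {
  scheme <- match.arg(scheme)
  meta <- align_metadata(m, meta)
  keep <- meta$class %in% c(subtype, control_class)
  m2 <- m[, keep, drop = FALSE]
  y <- as.numeric(meta$class[keep] == subtype)
  if (sum(y == 1) == 0 || sum(y == 0) == 0)
    input_error("both classes must be present")
  if (scheme == "loocv" && (sum(y == 1) < 3 || sum(y == 0) < 3))
    input_error("leave-one-out scoring needs >= 3 samples per class")
  if (is.null(sf)) sf <- size_factors(m2)
  xmat <- log2(1 + normalize_counts(m2, sf))

  pp <- vapply(seq_len(nrow(xmat)), function(i) {
    x <- xmat[i, ]
    if (scheme == "apparent") {
      mean(classify_logistic(x, y, x) == y)
    } else {
      pred <- vapply(seq_along(y), function(j) {
        classify_logistic(x[-j], y[-j], x[j])
      }, numeric(1))
      mean(pred == y)
    }
  }, numeric(1))

  out <- data.frame(mirna_id = rownames(m2), pp = pp,
                    pass_070 = pp >= 0.70, row.names = NULL)
  attr(out, "comparison") <- c(subtype = subtype, control = control_class)
  class(out) <- c("pp_result", "data.frame")
  out
}

# Train a one-covariate logistic classifier on (x, y) and predict labels
# for xnew. The probability cutoff is the training prevalence (0.5 for a
# balanced fold): under leave-one-out the held-out sample is always the
# training fold's minority class, so a fixed 0.5 cutoff votes
# systematically against it and drives null predictive power far below
# one half. Falls back to a midpoint threshold under complete separation
# and to the majority class for a constant covariate.
classify_logistic <- function(x, y, xnew) {
  if (max(x) - min(x) < .Machine$double.eps^0.5) {
    maj <- as.numeric(mean(y) >= 0.5)
    return(rep(maj, length(xnew)))
  }
  x1 <- x[y == 1]; x0 <- x[y == 0]
  if (min(x1) > max(x0)) {
    thr <- (min(x1) + max(x0)) / 2
    return(as.numeric(xnew > thr))
  }
  if (max(x1) < min(x0)) {
    thr <- (max(x1) + min(x0)) / 2
    return(as.numeric(xnew < thr))
  }
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, x), y, family = stats::binomial(),
                   control = list(maxit = 50)))
  eta <- fit$coefficients[1] + fit$coefficients[2] * xnew
  cut <- stats::qlogis(mean(y))
  as.numeric(eta > cut)
}

#' miRNAs passing a predictive-power threshold
#'
#' @param r a [predictive_power()] result.
#' @param threshold inclusive lower bound, default 0.70.
#' @return character vector of miRNA ids with `pp >= threshold`.
#' @export
pp_threshold <- function(r, threshold = 0.70) {
  r$mirna_id[!is.na(r$pp) & r$pp >= threshold]
}
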