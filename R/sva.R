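#' Estimate surrogate variables for unwanted variation
#'
#' Captures latent structure (e.g. batch effects) not explained by the
#' known class design, so it can enter the differential-expression design
#' as adjustment covariates. The procedure:
#'
#' 1. transform counts to `log2(1 + depth-normalized counts)`;
#' 2. regress each miRNA on the known design (class indicators) and take
#'    residuals;
#' 3. singular value decomposition of the residual matrix;
#' 4. decide how many components are real by a permutation null
#'    (Buja-Eyuboglu style): each miRNA's residuals are permuted
#'    independently across samples `n_perm` times, and a component is kept
#'    while its observed variance share exceeds the 95th percentile of its
#'    permutation null, stopping at the first failure;
#' 5. rebuild each kept component from the unresidualized (gene-centred)
#'    data via its residual-space gene loadings, so that the surrogate
#'    retains any share of the latent factor that is correlated with the
#'    class design — without this step a class-confounded batch could
#'    never be adjusted away — and return the centred, orthonormalized
#'    per-sample scores.
#'
#' The returned columns have zero mean across samples and are mutually
#' orthogonal; they are deliberately *not* orthogonalized against the
#' class design.
#'
#' @param m a count matrix.
#' @param meta a [cohort_metadata()] table; its `class` column forms the
#'   known design.
#' @param max_sv maximum number of surrogate variables to return.
#' @param n_perm number of row-wise permutations for the component test.
#' @param seed RNG seed for the permutations.
#' @param sf optional size factors (computed from `m` when `NULL`).
#' @param quantile permutation quantile a component must exceed (0.95).
#' @return object of class `surrogate_variables`: list with `sv`
#'   (samples x n_sv matrix, sample ids as rownames), `n_sv`, the
#'   observed variance `shares` and the permutation `thresholds`.
#' @export
estimate_sv <- function(m, meta, max_sv = 5, n_perm = 100, seed = NULL,
                        sf = NULL, quantile = 0.95) {
  meta <- align_metadata(m, meta)
  cls <- droplevels(meta$class)
  if (nlevels(cls) < 2)
    input_error("need at least 2 classes to define the known design")
  if (min(table(cls)) < 2)
    input_error("each class needs at least 2 samples",
                class = "urimir_design_error")
  n <- ncol(m)
  if (is.null(sf)) sf <- size_factors(m)
  # log depth enters the known design: the log2(1 + x) transform leaves a
  # smooth depth-dependent bias in low-count miRNAs that would otherwise
  # surface as a spurious component
  X <- cbind(stats::model.matrix(~cls), logsf = log(unclass(sf)))
  if (n <= ncol(X) + 1)
    input_error("too few samples for the design")

  y <- log2(1 + normalize_counts(m, sf))
  # residuals of each miRNA (row) on the sample-level design
  H <- X %*% solve(crossprod(X), t(X))
  R <- y - y %*% H
  # equalize per-sample residual scale: counting noise makes low-depth
  # samples noisier on the log scale, which a raw SVD mistakes for a
  # latent factor
  col_scale <- pmax(apply(R, 2, stats::sd), 1e-12)
  R <- sweep(R, 2, col_scale, "/")
  attr(R, "col_scale") <- col_scale

  empty <- function() {
    sv <- matrix(numeric(0), nrow = n, ncol = 0,
                 dimnames = list(colnames(m), NULL))
    structure(list(sv = sv, n_sv = 0L, shares = numeric(0),
                   thresholds = numeric(0)),
              class = "surrogate_variables")
  }
  if (max_sv < 1) return(empty())

  sv_full <- svd(R)
  d2 <- sv_full$d^2
  shares <- d2 / sum(d2)
  kmax <- min(max_sv, length(shares))

  perm_shares <- with_seed(seed, {
    ps <- matrix(NA_real_, n_perm, kmax)
    for (b in seq_len(n_perm)) {
      # permute each miRNA's residuals across samples, then re-project
      # onto the residual space of the design so observed and null
      # matrices have the same rank
      Rp <- t(apply(R, 1, sample))
      Rp <- Rp - Rp %*% H
      dp <- svd(Rp, nu = 0, nv = 0)$d^2
      ps[b, ] <- (dp / sum(dp))[seq_len(kmax)]
    }
    ps
  })
  thresholds <- apply(perm_shares, 2, stats::quantile, probs = quantile)

  n_sv <- 0L
  for (k in seq_len(kmax)) {
    if (shares[k] > thresholds[k]) n_sv <- k else break
  }
  if (n_sv == 0L) return(empty())

  # Reconstruct each surrogate from the *original* (gene-centred) data
  # using the residual-space gene loadings. Residual right-singular
  # vectors are orthogonal to the design by construction, so they cannot
  # carry the design-correlated share of a confounded batch; projecting
  # the unresidualized data onto the batch-driven gene weights recovers
  # the full latent vector, which is what must enter the DE design to
  # de-bias it.
  u <- sv_full$u[, seq_len(n_sv), drop = FALSE]
  yc <- y - rowMeans(y)
  sv <- crossprod(sweep(yc, 2, attr(R, "col_scale"), "/"), u)
  sv <- qr.Q(qr(scale(sv, center = TRUE, scale = FALSE)))

  # Iteratively reweighted refinement: genes are weighted by the
  # strength of their association with the current surrogates (given the
  # design), and the surrogates re-extracted from the weighted,
  # unresidualized data. This concentrates the estimate on the genes the
  # latent factor actually drives and converges on the factor itself
  # rather than a noisy projection of it.
  for (it in 1:3) {
    X2 <- cbind(X, sv)
    q2 <- ncol(X2)
    if (n - q2 < 2) break
    xtxi <- tryCatch(solve(crossprod(X2)), error = function(e) NULL)
    if (is.null(xtxi)) break
    coefs <- yc %*% X2 %*% xtxi
    res <- yc - coefs %*% t(X2)
    sig2 <- pmax(rowSums(res^2) / (n - q2), 1e-12)
    jj <- (ncol(X) + 1):q2
    tstat <- abs(coefs[, jj, drop = FALSE]) /
      sqrt(outer(sig2, diag(xtxi)[jj]))
    w <- apply(tstat, 1, max)
    w <- w / max(w)
    vv <- svd(w * yc, nu = 0, nv = n_sv)$v
    sv <- qr.Q(qr(scale(vv, center = TRUE, scale = FALSE)))
  }
  rownames(sv) <- colnames(m)
  colnames(sv) <- paste0("SV", seq_len(n_sv))
  structure(list(sv = sv, n_sv = n_sv,
                 shares = shares[seq_len(kmax)], thresholds = thresholds),
            class = "surrogate_variables")
}

#' @export
print.surrogate_variables <- function(x, ...) {
  cat("surrogate variables: n_sv =", x$n_sv, "\n")
  if (length(x$shares))
    cat("variance shares:", signif(x$shares, 3),
        "\nperm thresholds:", signif(x$thresholds, 3), "\n")
  invisible(x)
}
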