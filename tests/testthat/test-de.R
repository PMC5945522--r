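test_that("size factors reproduce the hand-computed median-of-ratios", {
  m <- count_matrix(matrix(c(10L, 20L, 30L, 60L), 2, byrow = TRUE,
                           dimnames = list(c("a", "b"), c("s1", "s2"))))
  sf <- size_factors(m)
  # ratios are (1/sqrt(2), sqrt(2)) for both rows; geometric mean already 1
  expect_equal(unclass(sf), c(s1 = sqrt(0.5), s2 = sqrt(2)),
               tolerance = 1e-12)
  # identical samples are symmetric
  m2 <- count_matrix(matrix(c(5L, 5L, 9L, 9L), 2, byrow = TRUE,
                            dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_equal(unclass(size_factors(m2)), c(s1 = 1, s2 = 1))
})

test_that("size factors match a brute-force median-of-ratios oracle", {
  set.seed(1)
  m <- count_matrix(matrix(rpois(500, 40) + 1L, 50, 10,
                           dimnames = list(sprintf("m%02d", 1:50),
                                           sprintf("s%02d", 1:10))))
  sf <- size_factors(m)
  # oracle: explicit loops over the definition
  geo <- apply(m, 1, function(r) exp(mean(log(r))))
  raw <- vapply(seq_len(ncol(m)),
                function(j) median(m[, j] / geo), numeric(1))
  oracle <- raw / exp(mean(log(raw)))
  expect_equal(unname(unclass(sf)), oracle, tolerance = 1e-12)
  expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
})

test_that("size factors fail informatively when no miRNA covers all samples", {
  m <- count_matrix(matrix(c(0L, 5L, 7L, 0L), 2, byrow = TRUE,
                           dimnames = list(c("a", "b"), c("s1", "s2"))))
  expect_error(size_factors(m), "pseudo-reference",
               class = "urimir_normalization_error")
})

test_that("dispersion estimates are near zero on Poisson data", {
  set.seed(2)
  mu <- rep(c(50, 200, 800), length.out = 60)
  k <- t(vapply(mu, function(m) rpois(100, m), numeric(100)))
  storage.mode(k) <- "integer"
  m <- count_matrix(k, mirna_ids = sprintf("m%02d", 1:60),
                    sample_ids = sprintf("s%03d", 1:100))
  a <- estimate_dispersion(m, rep(c("x", "y"), each = 50))
  expect_lt(median(a), 0.05)
})

test_that("dispersion estimates recover a planted alpha", {
  set.seed(3)
  k <- t(replicate(80, rnbinom(100, mu = 500, size = 1 / 0.2)))
  storage.mode(k) <- "integer"
  m <- count_matrix(k, mirna_ids = sprintf("m%02d", 1:80),
                    sample_ids = sprintf("s%03d", 1:100))
  a <- estimate_dispersion(m, rep(c("x", "y"), each = 50))
  expect_gt(median(a), 0.1)
  expect_lt(median(a), 0.3)
})

test_that("constant counts within groups give zero moment dispersion", {
  k <- matrix(rep(c(10L, 30L), each = 6), 2, 6, byrow = TRUE,
              dimnames = list(c("a", "b"), sprintf("s%d", 1:6)))
  m <- count_matrix(k)
  expect_warning(
    a <- estimate_dispersion(m, rep("g", 6),
                             sf = structure(rep(1, 6),
                                            class = "size_factors"),
                             trend_weight = 0),
    "fewer than 10 miRNAs")
  expect_equal(as.numeric(a), rep(1e-8, 2))  # clamped floor, i.e. zero
})

test_that("the NB Wald test recovers a planted fold change at high abundance", {
  pl <- data.frame(mirna_id = "miR-30a-5p", class = "MIBC", log2fc = -1.8,
                   base_log2_mean = log2(19453))
  cfg <- two_class_config(n = 50, n_mirna = 200, seed = 17, planted_de = pl,
                          baseline = c(4, 12))
  coh <- generate_counts(cfg)
  de <- nb_wald_test(coh$counts, coh$metadata, "MIBC")
  row <- de[de$mirna_id == "miR-30a-5p", ]
  expect_lt(abs(row$log2fc - (-1.8)), 0.2)
  expect_lt(row$fdr, 0.05)
  expect_gt(row$mean_read_count, 300)
})

test_that("all-zero miRNAs are flagged and excluded from the BH burden", {
  cfg <- two_class_config(n = 10, n_mirna = 30, seed = 19,
                          baseline = c(5, 8))
  coh <- generate_counts(cfg)
  m <- unclass(coh$counts)
  m["miR-sim-0001", ] <- 0L
  m <- count_matrix(m)
  de <- nb_wald_test(m, coh$metadata, "MIBC")
  zrow <- de[de$mirna_id == "miR-sim-0001", ]
  expect_false(zrow$converged)
  expect_true(is.na(zrow$p) && is.na(zrow$fdr))
  expect_gte(attr(de, "n_failed"), 1)
  # BH burden = number of non-missing p-values
  ok <- !is.na(de$p)
  expect_equal(de$fdr[ok], p.adjust(de$p[ok], "BH"))
})

test_that("DE results are invariant to sample order", {
  cfg <- two_class_config(n = 12, n_mirna = 60, seed = 23,
                          baseline = c(5, 11))
  coh <- generate_counts(cfg)
  de1 <- nb_wald_test(coh$counts, coh$metadata, "MIBC")
  perm <- sample(ncol(coh$counts))
  de2 <- nb_wald_test(coh$counts[, perm], coh$metadata, "MIBC")
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 1e-8)
  expect_equal(de1$p, de2$p, tolerance = 1e-8)
})

test_that("size factors and fold changes agree with DESeq2 on a fixture", {
  suppressPackageStartupMessages({
    library(SummarizedExperiment)
    library(DESeq2)
  })
  pl <- data.frame(mirna_id = "tgt", class = "MIBC", log2fc = 1.5,
                   base_log2_mean = 9)
  cfg <- two_class_config(n = 20, n_mirna = 60, seed = 29, planted_de = pl,
                          baseline = c(5, 11))
  coh <- generate_counts(cfg)
  keep <- rowSums(coh$counts) > 0
  m <- coh$counts[keep, ]

  dds <- DESeqDataSetFromMatrix(unclass(m),
                                colData = data.frame(
                                  class = relevel(coh$metadata$class,
                                                  "control")),
                                design = ~class)
  dds <- suppressWarnings(DESeq(dds, fitType = "mean", quiet = TRUE))
  res <- results(dds)

  # same normalization convention up to a global rescaling (DESeq2 takes
  # the median of log ratios, which differs microscopically from the
  # ratio-scale median when the middle pair is averaged)
  ratio <- unclass(size_factors(m)) / sizeFactors(dds)
  expect_lt(sd(log(ratio)), 1e-3)

  de <- nb_wald_test(m, coh$metadata, "MIBC")
  expect_lt(abs(de$log2fc[de$mirna_id == "tgt"] -
                  res["tgt", "log2FoldChange"]), 0.2)
  # directional agreement on clearly significant calls
  sig <- !is.na(res$padj) & res$padj < 0.01 & !is.na(de$fdr) & de$fdr < 0.01
  if (any(sig))
    expect_true(all(sign(de$log2fc[sig]) ==
                      sign(res$log2FoldChange[sig])))
})

test_that("BH adjustment reproduces hand-worked and degenerate cases", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.2, 1.2)), "\\[0, 1\\]")
  p <- c(0.9, NA, 0.1)
  adj <- bh_adjust(p)
  expect_true(is.na(adj[2]))
  expect_equal(adj[c(1, 3)], p.adjust(p[c(1, 3)], "BH"))
})

test_that("BH adjustment equals the brute-force step-up oracle", {
  # oracle: adj p_(i) = min over j >= i of m * p_(j) / j, by explicit loops
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    ps <- p[o]
    adj <- numeric(m)
    for (i in seq_len(m)) {
      best <- Inf
      for (j in i:m) best <- min(best, m * ps[j] / j)
      adj[i] <- min(best, 1)
    }
    out <- numeric(m)
    out[o] <- adj
    out
  }
  set.seed(7)
  for (r in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})
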