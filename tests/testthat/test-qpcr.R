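toy_ct <- function() {
  ct <- matrix(c(25, 20, 22,
                 27, 21, 23,
                 24, 19, 21,
                 26, 20, 22,
                 28, 21, 23,
                 25, 20, 22),
               nrow = 6, byrow = TRUE,
               dimnames = list(sprintf("s%d", 1:6),
                               c("tgt", "ctl1", "ctl2")))
  ct_matrix(ct, controls = c("ctl1", "ctl2"))
}

toy_ct_meta <- function(classes = rep(c("control", "MIBC"), each = 3)) {
  cohort_metadata(data.frame(sample_id = sprintf("s%d", 1:6),
                             class = classes,
                             age = c(58, 63, 60, 66, 61, 64),
                             smoking = c("never", "former", "current",
                                         "former", "never", "current")))
}

test_that("dCt subtracts the per-sample mean of the control assays", {
  d <- delta_ct(toy_ct())
  expect_equal(d["s1", "tgt"], 25 - mean(c(20, 22)))  # = 4
  # single control equal to the target gives zero
  ct1 <- ct_matrix(matrix(c(20, 20), 1, 2,
                          dimnames = list("s1", c("tgt", "ctl"))),
                   controls = "ctl")
  expect_equal(unname(delta_ct(ct1)["s1", "tgt"]), 0)
})

test_that("dCt matches an explicit per-sample oracle loop on random tables", {
  set.seed(5)
  raw <- matrix(runif(60, 15, 35), 10, 6,
                dimnames = list(sprintf("s%02d", 1:10),
                                c(sprintf("a%d", 1:4), "c1", "c2")))
  ct <- ct_matrix(raw, controls = c("c1", "c2"))
  d <- delta_ct(ct)
  for (j in rownames(raw)) for (a in sprintf("a%d", 1:4))
    expect_equal(d[j, a], raw[j, a] - mean(raw[j, c("c1", "c2")]),
                 tolerance = 1e-12)
})

test_that("dCt is exactly invariant to per-sample Ct offsets", {
  ct <- toy_ct()
  shifted <- unclass(ct) + c(1.3, -0.7, 2.1, 0.4, -1.9, 0.8)
  ct2 <- ct_matrix(shifted, controls = attr(ct, "controls"))
  expect_identical(delta_ct(ct2)[, "tgt"], delta_ct(ct)[, "tgt"])
})

test_that("samples missing a control Ct are excluded and reported", {
  raw <- unclass(toy_ct())
  raw["s3", "ctl1"] <- NA
  ct <- ct_matrix(raw, controls = c("ctl1", "ctl2"))
  expect_message(d <- delta_ct(ct), "excluded")
  expect_false("s3" %in% rownames(d))
  expect_identical(attr(d, "excluded_samples"), "s3")
})

test_that("log2 fold change is minus ddCt with the documented sign", {
  d <- matrix(c(5, 5, 5, 3, 3, 3), ncol = 1,
              dimnames = list(sprintf("s%d", 1:6), "tgt"))
  fc <- ddct_log2fc(d, toy_ct_meta(), "MIBC")
  expect_equal(fc$ddct, -2)       # cases 3 minus controls 5
  expect_equal(fc$log2fc, 2)      # lower Ct = higher expression
  expect_identical(fc$log2fc, -fc$ddct)
  # identical groups give exactly zero
  d0 <- matrix(rep(4, 6), ncol = 1,
               dimnames = list(sprintf("s%d", 1:6), "tgt"))
  expect_equal(ddct_log2fc(d0, toy_ct_meta(), "MIBC")$log2fc, 0)
})

test_that("Ct values outside the plausible range are rejected", {
  expect_error(ct_matrix(matrix(c(50, 20), 1, 2,
                                dimnames = list("s1", c("a", "c"))),
                         controls = "c"),
               "out of \\(0, 45\\)")
  expect_error(ct_matrix(matrix(c(20, 20), 1, 2,
                                dimnames = list("s1", c("a", "c"))),
                         controls = "missing"),
               "not present")
})

test_that("association test finds a strong planted effect, adjusting for covariates", {
  set.seed(41)
  n <- 50
  cls <- rep(c("control", "MIBC"), each = n)
  dct <- c(rnorm(n, 6, 1), rnorm(n, 4, 1))   # cases 2 cycles lower
  d <- matrix(dct, ncol = 1,
              dimnames = list(sprintf("s%03d", 1:(2 * n)), "tgt"))
  meta <- cohort_metadata(data.frame(
    sample_id = rownames(d), class = cls,
    age = round(runif(2 * n, 45, 75)),
    smoking = sample(SMOKING_LEVELS, 2 * n, replace = TRUE)))
  res <- association_test(d, meta, "MIBC")
  expect_lt(res$p, 0.001)
  expect_gt(res$estimate, 0)                 # higher expression in cases
  expect_identical(res$method, "ml")
})

test_that("complete separation falls back to a flagged Firth fit", {
  n <- 40
  d <- matrix(c(rep(8, n / 2), rep(2, n / 2)) + rep(c(0, 0.3), n / 2),
              ncol = 1, dimnames = list(sprintf("s%02d", 1:n), "tgt"))
  meta <- cohort_metadata(data.frame(
    sample_id = rownames(d),
    class = rep(c("control", "MIBC"), each = n / 2),
    age = seq(50, 72, length.out = n),
    smoking = rep(c("never", "former"), n / 2)))
  res <- association_test(d, meta, "MIBC")
  expect_identical(res$method, "firth")
  expect_lt(res$p, 0.05)
  expect_true(is.finite(res$estimate))
})

test_that("a constant assay yields a missing p-value, not a crash", {
  d <- matrix(rep(5, 6), ncol = 1,
              dimnames = list(sprintf("s%d", 1:6), "tgt"))
  res <- association_test(d, toy_ct_meta(), "MIBC")
  expect_true(is.na(res$p))
  expect_identical(res$method, "none")
})

test_that("the trend test detects ordered group shifts and respects ordering", {
  set.seed(43)
  n <- 25
  classes <- rep(BC_CLASSES, each = n)
  expr <- rnorm(4 * n, mean = rep(c(0, 1, 2, 3), each = n), sd = 1)
  d <- matrix(-expr, ncol = 1,
              dimnames = list(sprintf("s%03d", 1:(4 * n)), "tgt"))
  meta <- cohort_metadata(data.frame(
    sample_id = rownames(d), class = classes,
    age = round(runif(4 * n, 45, 75)),
    smoking = sample(SMOKING_LEVELS, 4 * n, replace = TRUE)))
  res <- trend_test(d, meta)
  expect_gt(res$slope, 0)
  expect_lt(res$trend_p, 0.05)
  # cases-only mode drops controls and rescores
  res_cases <- trend_test(d, meta, cases_only = TRUE)
  expect_gt(res_cases$slope, 0)
  expect_lt(res_cases$trend_p, 0.05)
})

test_that("with two groups the unadjusted trend test is the equal-variance t-test", {
  set.seed(47)
  d <- matrix(rnorm(6, 5, 1), ncol = 1,
              dimnames = list(sprintf("s%d", 1:6), "tgt"))
  meta <- toy_ct_meta()
  res <- trend_test(d, meta, adjust = FALSE)
  tt <- t.test(-d[4:6, 1], -d[1:3, 1], var.equal = TRUE)
  expect_equal(res$trend_p, tt$p.value, tolerance = 1e-10)
  expect_equal(res$slope, unname(diff(rev(tt$estimate))), tolerance = 1e-10)
})

test_that("a single group cannot support a trend test", {
  d <- matrix(1:3, ncol = 1,
              dimnames = list(sprintf("s%d", 1:3), "tgt"))
  meta <- cohort_metadata(data.frame(
    sample_id = sprintf("s%d", 1:3), class = "MIBC",
    age = c(60, 62, 64), smoking = "never"))
  expect_error(trend_test(d, meta), "at least 2 ordered groups")
})

test_that("the spike-in QC flags drifting plates", {
  raw <- cbind(unclass(toy_ct()), UniSp6 = c(18, 18.1, 17.9, 18, 18.2, 18))
  ct <- ct_matrix(raw, controls = c("ctl1", "ctl2"), spike_in = "UniSp6")
  expect_true(spike_in_qc(ct)$ok)
  raw[, "UniSp6"] <- c(15, 21, 17, 23, 14, 20)
  ct2 <- ct_matrix(raw, controls = c("ctl1", "ctl2"), spike_in = "UniSp6")
  expect_false(spike_in_qc(ct2)$ok)
})
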