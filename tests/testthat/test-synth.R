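test_that("the generator is deterministic in (config, seed) and seed-sensitive", {
  cfg <- two_class_config(n = 10, n_mirna = 50, seed = 7)
  a <- generate_counts(cfg)
  b <- generate_counts(cfg)
  expect_identical(unclass(a$counts), unclass(b$counts))
  expect_identical(a$metadata, b$metadata)
  cfg2 <- two_class_config(n = 10, n_mirna = 50, seed = 8)
  expect_false(identical(unclass(a$counts),
                         unclass(generate_counts(cfg2)$counts)))
})

test_that("generated counts are non-negative integers", {
  coh <- generate_counts(two_class_config(n = 15, n_mirna = 100, seed = 3))
  expect_true(all(coh$counts >= 0))
  expect_identical(storage.mode(unclass(coh$counts)), "integer")
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(n_per_class = c(control = 0, MIBC = 5)),
               "positive")
  expect_error(simulation_config(n_mirna = 0), "positive")
  expect_error(simulation_config(
    planted_de = data.frame(mirna_id = "x", class = "MIBC", log2fc = 1),
    planted_stable = "x"), "disjoint")
  expect_error(simulation_config(
    planted_de = data.frame(mirna_id = "x", class = "control", log2fc = 1)),
    "cancer subtypes")
})

test_that("with nothing planted, depth-normalized class means are balanced", {
  cfg <- two_class_config(n = 40, n_mirna = 150, seed = 5,
                          baseline = c(6, 12))
  coh <- generate_counts(cfg)
  x <- sweep(unclass(coh$counts), 2, unclass(size_factors(coh$counts)), "/")
  case <- coh$metadata$class == "MIBC"
  ratio <- log2(rowMeans(x[, case]) / rowMeans(x[, !case]))
  # no systematic class effect: mean log-ratio near 0, no large outliers
  expect_lt(abs(mean(ratio)), 0.1)
  expect_lt(max(abs(ratio)), 1)
})

test_that("null counts are overdispersed relative to Poisson when alpha > 0", {
  cfg <- simulation_config(n_per_class = c(control = 1000),
                           n_mirna = 60, baseline_log2_mean_range = c(6, 10),
                           depth_factor_range = c(1, 1), batch_effect_sd = 0,
                           planted_de = NULL, planted_stable = character(),
                           seed = 9)
  coh <- generate_counts(cfg)
  k <- unclass(coh$counts)
  vmr <- apply(k, 1, var) / rowMeans(k)
  expect_true(all(vmr > 1.5))     # variance-to-mean well above Poisson's 1
})

test_that("noiseless Ct values are an exact linear function of expression", {
  # two samples, equal depth, one assay at ratio 2, one constant control
  cfg <- two_class_config(n = 2, n_mirna = 4, seed = 1, ct_noise_sd = 0)
  m <- count_matrix(matrix(c(200L, 400L, 100L, 100L, 50L, 50L, 400L, 200L),
                           nrow = 4, byrow = TRUE,
                           dimnames = list(c("tgt", "ctl", "m3", "m4"),
                                           c("s1", "s2"))))
  meta <- cohort_metadata(data.frame(
    sample_id = c("s1", "s2"), class = c("control", "MIBC"),
    age = c(60, 61), smoking = "never"))
  ct <- generate_ct(cfg, m, meta, assays = "tgt", controls = "ctl")
  # expression doubles from s1 to s2 -> Ct drops by |slope| exactly
  expect_equal(ct["s1", "tgt"] - ct["s2", "tgt"], abs(cfg$ct_slope) *
                 (log2(400) - log2(200)), tolerance = 1e-12)
  expect_true(all(c("ctl", "UniSp6") %in% colnames(ct)))
  expect_error(generate_ct(cfg, m, meta, assays = "absent"),
               "not present")
})

test_that("planted qPCR fold changes are recovered by the ddCt stage", {
  pl <- data.frame(mirna_id = "tgt", class = "MIBC", log2fc = 2,
                   base_log2_mean = 10)
  cfg <- two_class_config(n = 50, n_mirna = 60, seed = 11, planted_de = pl,
                          planted_stable = c("hk1", "hk2"),
                          baseline = c(6, 12))
  coh <- generate_counts(cfg)
  ct <- generate_ct(cfg, coh$counts, coh$metadata, assays = "tgt")
  fc <- ddct_log2fc(delta_ct(ct), coh$metadata, "MIBC")
  expect_equal(fc$log2fc[fc$assay_id == "tgt"], 2, tolerance = 0.25)
})

test_that("stable control assays show vanishing class dCt differences", {
  cfg <- two_class_config(n = 200, n_mirna = 50, seed = 13,
                          planted_stable = c("hk1", "hk2"),
                          baseline = c(6, 12))
  coh <- generate_counts(cfg)
  ct <- generate_ct(cfg, coh$counts, coh$metadata, assays = "hk1",
                    controls = "hk2")
  fc <- ddct_log2fc(delta_ct(ct), coh$metadata, "MIBC")
  expect_lt(abs(fc$log2fc), 0.15)   # law of large numbers at n = 200/group
})
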