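#' Configuration for the synthetic urinary-miRNA cohort generator
#'
#' Defines a cohort whose statistical structure mirrors what the analysis
#' stages assume: negative-binomial read counts with per-sample sequencing
#' depth, a latent two-level batch effect on the log2 scale, a small set of
#' planted subtype-specific fold changes, a set of planted invariant
#' (housekeeping-like) miRNAs, and qPCR Ct values linearly linked to latent
#' log2 expression with Gaussian measurement noise.
#'
#' Counts for miRNA i in sample j are drawn as
#' `NB(mean = depth_j * 2^(b_i + delta_i,class(j) + beta_i * batch_j),
#' dispersion alpha_i)` with `Var = mu + alpha * mu^2`. Dispersion follows
#' the trend `alpha(mu) = a0 + a1/mu` evaluated at the baseline mean.
#'
#' Defaults emulate the discovery cohort of a urinary small RNA-seq
#' bladder-cancer study: 114 samples (48 controls, 39 low-grade NMIBC, 17
#' high-grade NMIBC, 10 MIBC), 1822 miRNAs, baseline abundances spanning
#' sub-count noise to tens of thousands of reads, and planted fold changes
#' of the magnitudes reported for validated urinary biomarkers (roughly
#' -2.4 to +3.7 on the log2 scale). Age and smoking are generated
#' independently of class so that covariate-adjusted tests are null by
#' construction; batch is balanced across classes unless
#' `batch_confound` is moved away from 0.5.
#'
#' @param n_per_class named integer vector of sample counts per class
#'   (names from [BC_CLASSES]), or a single integer used for every class.
#' @param n_mirna total number of miRNAs (planted ones included).
#' @param baseline_log2_mean_range interval from which baseline log2 mean
#'   counts of unplanted miRNAs are drawn uniformly.
#' @param dispersion_model coefficients `c(a0, a1)` of the dispersion trend
#'   `alpha(mu) = a0 + a1/mu`.
#' @param depth_factor_range interval of per-sample depth multipliers.
#' @param batch_effect_sd SD of the per-miRNA log2 batch coefficient; 0
#'   disables the batch effect.
#' @param batch_confound probability that a cancer sample falls in batch
#'   "B2" (controls get the complementary probability); 0.5 = balanced.
#' @param planted_de data.frame with columns `mirna_id`, `class`,
#'   `log2fc` and optionally `base_log2_mean`: subtype-specific planted
#'   log2 fold changes relative to controls.
#' @param planted_stable character vector of invariant miRNA ids (no class
#'   or batch effect, minimal dispersion).
#' @param stable_dispersion,stable_log2_mean dispersion and baseline log2
#'   mean given to planted stable miRNAs.
#' @param ct_intercept,ct_slope,ct_noise_sd linear Ct link: Ct =
#'   intercept + slope * log2(expression) + N(0, ct_noise_sd^2). The
#'   nominal slope is -1 Ct per log2 unit (a doubling costs one cycle).
#' @param spike_in_ct,spike_in_sd constant Ct level and inter-well SD of
#'   the synthetic spike-in assay.
#' @param age_range,smoking_probs covariate generator settings.
#' @param seed integer RNG seed; identical configs with identical seeds
#'   produce identical cohorts.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_per_class = c(control = 48, NMIBC_G1G2 = 39,
                                              NMIBC_G3 = 17, MIBC = 10),
                              n_mirna = 1822,
                              baseline_log2_mean_range = c(-3, 14),
                              dispersion_model = c(a0 = 0.05, a1 = 2),
                              depth_factor_range = c(0.5, 2),
                              batch_effect_sd = 0.5,
                              batch_confound = 0.5,
                              planted_de = default_planted_de(),
                              planted_stable = c("miR-28-3p", "miR-361-3p"),
                              stable_dispersion = 0.001,
                              stable_log2_mean = 8,
                              ct_intercept = 35,
                              ct_slope = -1,
                              ct_noise_sd = 0.5,
                              spike_in_ct = 18,
                              spike_in_sd = 0.15,
                              age_range = c(42, 75),
                              smoking_probs = c(never = 0.1, former = 0.5,
                                                current = 0.4),
                              seed = 1L) {
  if (length(n_per_class) == 1 && is.null(names(n_per_class)))
    n_per_class <- stats::setNames(rep(n_per_class, length(BC_CLASSES)),
                                   BC_CLASSES)
  if (is.null(names(n_per_class)) ||
      !all(names(n_per_class) %in% BC_CLASSES))
    input_error("n_per_class must be named with class labels")
  if (any(n_per_class < 1) || n_mirna < 1)
    input_error("n_per_class and n_mirna must be positive")
  if (is.null(planted_de))
    planted_de <- data.frame(mirna_id = character(), class = character(),
                             log2fc = numeric())
  if (!all(c("mirna_id", "class", "log2fc") %in% names(planted_de)))
    input_error("planted_de needs columns mirna_id, class, log2fc")
  if (!all(planted_de$class %in% setdiff(BC_CLASSES, "control")))
    input_error("planted_de classes must be cancer subtypes")
  if (length(intersect(planted_de$mirna_id, planted_stable)))
    input_error("planted_de and planted_stable ids must be disjoint")
  n_planted <- length(unique(planted_de$mirna_id)) + length(planted_stable)
  if (n_planted > n_mirna)
    input_error("more planted miRNAs than n_mirna")
  cfg <- list(n_per_class = n_per_class, n_mirna = as.integer(n_mirna),
              baseline_log2_mean_range = baseline_log2_mean_range,
              dispersion_model = dispersion_model,
              depth_factor_range = depth_factor_range,
              batch_effect_sd = batch_effect_sd,
              batch_confound = batch_confound,
              planted_de = planted_de, planted_stable = planted_stable,
              stable_dispersion = stable_dispersion,
              stable_log2_mean = stable_log2_mean,
              ct_intercept = ct_intercept, ct_slope = ct_slope,
              ct_noise_sd = ct_noise_sd, spike_in_ct = spike_in_ct,
              spike_in_sd = spike_in_sd, age_range = age_range,
              smoking_probs = smoking_probs, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

#' Default planted fold changes
#'
#' A panel emulating validated urinary bladder-cancer biomarkers: three
#' miRNAs altered in all subtypes (down-regulated miR-30a-5p and
#' let-7c-5p, strongly up-regulated miR-486-5p) plus a few
#' subtype-specific effects, with log2 fold changes and abundances of the
#' magnitudes seen in such panels.
#'
#' @return data.frame with columns mirna_id, class, log2fc,
#'   base_log2_mean.
#' @export
default_planted_de <- function() {
  shared <- expand.grid(mirna_id = c("miR-30a-5p", "let-7c-5p", "miR-486-5p"),
                        class = c("NMIBC_G1G2", "NMIBC_G3", "MIBC"),
                        stringsAsFactors = FALSE)
  shared$log2fc <- rep(c(-1.80, -1.62, 3.68), times = 3)
  shared$base_log2_mean <- rep(c(14.2, 10.5, 9.7), times = 3)
  extra <- data.frame(
    mirna_id = c("miR-205-5p", "miR-21-5p", "miR-451a"),
    class = c("NMIBC_G1G2", "NMIBC_G3", "MIBC"),
    log2fc = c(2.97, 1.42, 3.40),
    base_log2_mean = c(8.6, 14.8, 10.0))
  rbind(shared, extra)
}

#' Generate a synthetic count matrix and cohort metadata
#'
#' Draws negative-binomial read counts and per-sample covariates under the
#' model described in [simulation_config()]. The returned object also
#' carries the simulation truth (depth factors, baseline means, batch
#' coefficients, dispersions) in the `"truth"` attribute for use in
#' parameter-recovery checks.
#'
#' @param config a [simulation_config()].
#' @return list with elements `counts` (a [count_matrix()]) and
#'   `metadata` (a [cohort_metadata()] including a `batch` column).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    npc <- config$n_per_class
    classes <- rep(names(npc), times = npc)
    n <- length(classes)
    sample_ids <- sprintf("S%03d", seq_len(n))

    planted <- config$planted_de
    planted_ids <- unique(planted$mirna_id)
    stable_ids <- config$planted_stable
    n_filler <- config$n_mirna - length(planted_ids) - length(stable_ids)
    filler_ids <- if (n_filler > 0)
      sprintf("miR-sim-%04d", seq_len(n_filler)) else character()
    mirna_ids <- c(planted_ids, stable_ids, filler_ids)
    p <- length(mirna_ids)

    rng <- config$baseline_log2_mean_range
    baseline <- stats::runif(p, rng[1], rng[2])
    names(baseline) <- mirna_ids
    if (length(planted_ids)) {
      bm <- planted$base_log2_mean
      if (is.null(bm)) bm <- rep(11, nrow(planted))
      baseline[planted_ids] <-
        bm[match(planted_ids, planted$mirna_id)]
    }
    baseline[stable_ids] <- config$stable_log2_mean

    a <- config$dispersion_model
    alpha <- a[[1]] + a[[2]] / 2^baseline
    alpha <- pmax(alpha, 1e-8)
    alpha[stable_ids] <- config$stable_dispersion

    # class effects Delta[i, class]
    delta <- matrix(0, p, length(BC_CLASSES),
                    dimnames = list(mirna_ids, BC_CLASSES))
    if (nrow(planted))
      delta[cbind(match(planted$mirna_id, mirna_ids),
                  match(planted$class, BC_CLASSES))] <- planted$log2fc

    # batch: two levels, cancer samples fall in B2 with prob batch_confound
    p_b2 <- ifelse(classes == "control",
                   1 - config$batch_confound, config$batch_confound)
    batch <- ifelse(stats::runif(n) < p_b2, "B2", "B1")
    beta <- stats::rnorm(p, 0, config$batch_effect_sd)
    beta[mirna_ids %in% stable_ids] <- 0

    depth <- stats::runif(n, config$depth_factor_range[1],
                          config$depth_factor_range[2])

    log2mu <- baseline +
      delta[, classes, drop = FALSE] +
      outer(beta, ifelse(batch == "B2", 0.5, -0.5))
    mu <- sweep(2^log2mu, 2, depth, "*")
    k <- matrix(stats::rnbinom(p * n, mu = mu, size = rep(1 / alpha, n)),
                nrow = p, dimnames = list(mirna_ids, sample_ids))

    meta <- cohort_metadata(data.frame(
      sample_id = sample_ids,
      class = classes,
      age = round(stats::runif(n, config$age_range[1], config$age_range[2]),
                  1),
      smoking = sample(SMOKING_LEVELS, n, replace = TRUE,
                       prob = config$smoking_probs),
      batch = batch,
      stringsAsFactors = FALSE))

    out <- list(counts = count_matrix(k), metadata = meta)
    attr(out, "truth") <- list(depth = stats::setNames(depth, sample_ids),
                               baseline = baseline, batch_coef = beta,
                               dispersion = alpha,
                               planted_de = planted,
                               planted_stable = stable_ids)
    class(out) <- "sim_cohort"
    out
  })
}

#' Generate a synthetic qPCR Ct table linked to sequencing counts
#'
#' For every requested assay, the Ct value of sample j is a linear
#' function of that sample's depth-normalized log2 read count (the latent
#' expression a well-behaved assay would measure) plus Gaussian
#' measurement noise: `Ct = intercept + slope * log2(expr) + eps`. A
#' constant-level spike-in assay ("UniSp6") is appended for QC.
#'
#' @param config a [simulation_config()].
#' @param counts,metadata a cohort generated by [generate_counts()].
#' @param assays miRNA ids to measure as targets.
#' @param controls miRNA ids to designate as endogenous-control assays.
#' @return a [ct_matrix()] (samples x assays) whose control assays and
#'   spike-in are recorded in attributes.
#' @export
generate_ct <- function(config, counts, metadata, assays,
                        controls = config$planted_stable) {
  stopifnot(inherits(config, "simulation_config"))
  all_assays <- unique(c(assays, controls))
  missing <- setdiff(all_assays, rownames(counts))
  if (length(missing))
    input_error(sprintf("assay '%s' not present in the count matrix",
                        missing[1]))
  sf <- size_factors(counts)
  with_seed(config$seed + 1L, {
    q <- t(log2(sweep(pmax(counts[all_assays, , drop = FALSE], 0.5),
                      2, sf, "/")))
    ct <- config$ct_intercept + config$ct_slope * q
    if (config$ct_noise_sd > 0)
      ct <- ct + stats::rnorm(length(ct), 0, config$ct_noise_sd)
    spike <- stats::rnorm(nrow(ct), config$spike_in_ct, config$spike_in_sd)
    ct <- cbind(ct, UniSp6 = spike)
    ct_matrix(ct, controls = controls, spike_in = "UniSp6")
  })
}

#' Write a full synthetic dataset to disk
#'
#' Produces the three tab-separated inputs of the pipeline: the count
#' matrix, the sample metadata and the long-format Ct table.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed).
#' @param assays target assays for the Ct table; defaults to the planted
#'   differentially expressed miRNAs.
#' @return invisibly, the list of written paths.
#' @export
write_simulated_dataset <- function(config, dir,
                                    assays = unique(config$planted_de$mirna_id)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- generate_counts(config)
  ct <- generate_ct(config, cohort$counts, cohort$metadata, assays)
  paths <- list(counts = file.path(dir, "counts.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                ct = file.path(dir, "ct.tsv"))
  write_counts(cohort$counts, paths$counts)
  write_metadata(cohort$metadata, paths$metadata)
  write_ct(ct, paths$ct)
  invisible(paths)
}
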