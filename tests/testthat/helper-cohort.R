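# Small cohort configurations reused across tests.

two_class_config <- function(n = 30, n_mirna = 200, seed = 1,
                             planted_de = NULL,
                             planted_stable = character(),
                             baseline = c(3, 12), batch_sd = 0, ...) {
  simulation_config(n_per_class = c(control = n, MIBC = n),
                    n_mirna = n_mirna,
                    baseline_log2_mean_range = baseline,
                    batch_effect_sd = batch_sd,
                    planted_de = planted_de,
                    planted_stable = planted_stable,
                    seed = seed, ...)
}

# Class-conditional SD of log2 depth-normalized counts under the
# generator's NB model (delta method): var(log2 k) ~ (1/mu + alpha)/ln2^2.
log2_count_sd <- function(mu, alpha) sqrt(1 / mu + alpha) / log(2)

# Tiny deterministic count fixture.
toy_counts <- function() {
  count_matrix(matrix(c(10L, 20L, 30L, 60L, 5L, 5L), nrow = 3, byrow = TRUE,
                      dimnames = list(c("m1", "m2", "m3"), c("s1", "s2"))))
}

toy_metadata <- function(n_case = 3, n_ctrl = 3) {
  cohort_metadata(data.frame(
    sample_id = sprintf("s%d", seq_len(n_case + n_ctrl)),
    class = rep(c("MIBC", "control"), c(n_case, n_ctrl)),
    age = seq(55, 70, length.out = n_case + n_ctrl),
    smoking = rep(c("never", "former", "current"), length.out = n_case + n_ctrl)))
}
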