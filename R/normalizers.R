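#' Select candidate endogenous-control miRNAs from sequencing counts
#'
#' Stability-based reference selection adapted from housekeeping-gene
#' screens: a miRNA qualifies as an endogenous-control candidate when
#'
#' 1. it has at least `min_reads` raw reads in every sample (a detection
#'    requirement, applied to unnormalized counts);
#' 2. the standard deviation across samples of its log2 depth-normalized
#'    expression is below `max_log2_sd`;
#' 3. no sample deviates from the miRNA's across-sample mean log2
#'    expression by less than `fc_low` or more than `fc_high` (no
#'    exceptional expression in any sample).
#'
#' Candidates are ranked by ascending log2 SD (most stable first), ties
#' broken lexicographically by id, and the top `top_k` are selected.
#'
#' @param m a count matrix.
#' @param sf optional size factors.
#' @param min_reads minimum raw count required in every sample (default 2).
#' @param max_log2_sd exclusive upper bound on the log2 SD (default 12).
#' @param fc_low,fc_high allowed range of per-sample log2 deviation from
#'   the miRNA mean (defaults -4 and 7).
#' @param top_k how many ranked candidates to select (default 2).
#' @return object of class `normalizer_set`: list with `selected` (ids,
#'   best first) and `stats` (per-miRNA data.frame with columns
#'   `mirna_id`, `min_count`, `log2_sd`, `min_dev`, `max_dev`, `pass`,
#'   `rank`).
#' @export
select_normalizers <- function(m, sf = NULL, min_reads = 2, max_log2_sd = 12,
                               fc_low = -4, fc_high = 7, top_k = 2) {
  if (nrow(m) == 0) input_error("empty count matrix")
  x <- log2(pmax(normalize_counts(m, sf), 0.5))
  ctr <- x - rowMeans(x)
  stats_df <- data.frame(
    mirna_id = rownames(m),
    min_count = apply(unclass(m), 1, min),
    log2_sd = apply(x, 1, stats::sd),
    min_dev = apply(ctr, 1, min),
    max_dev = apply(ctr, 1, max),
    row.names = NULL)
  stats_df$pass <- stats_df$min_count >= min_reads &
    stats_df$log2_sd < max_log2_sd &
    stats_df$min_dev >= fc_low & stats_df$max_dev <= fc_high

  ord <- order(!stats_df$pass, stats_df$log2_sd, stats_df$mirna_id)
  stats_df$rank <- NA_integer_
  n_pass <- sum(stats_df$pass)
  stats_df$rank[ord[seq_len(n_pass)]] <- seq_len(n_pass)
  selected <- stats_df$mirna_id[ord[seq_len(min(top_k, n_pass))]]
  if (length(selected) == 0)
    warning("no miRNA satisfies the endogenous-control criteria; ",
            "qPCR normalization will need an explicit control list")
  structure(list(selected = selected, stats = stats_df,
                 thresholds = c(min_reads = min_reads,
                                max_log2_sd = max_log2_sd,
                                fc_low = fc_low, fc_high = fc_high,
                                top_k = top_k)),
            class = "normalizer_set")
}

#' @export
print.normalizer_set <- function(x, ...) {
  cat("endogenous-control candidates (", sum(x$stats$pass), " pass, top ",
      length(x$selected), " selected):\n", sep = "")
  print(utils::head(x$stats[order(x$stats$rank), ], length(x$selected)))
  invisible(x)
}
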