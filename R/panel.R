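#' Build the candidate biomarker panel for one subtype comparison
#'
#' Combines the two discovery tracks. The differential-expression track
#' keeps miRNAs with BH-adjusted p (FDR) at most `fdr_max` and mean raw
#' read count at least `min_mean`; the predictive-power track keeps
#' miRNAs with predictive power at least `pp_min` (all bounds inclusive).
#' The panel lists the intersection of the two tracks first, then any
#' manually curated additions (tagged `"manual"`; plot-count inspection
#' and literature candidates are an explicit input, never computed).
#'
#' @param de a [nb_wald_test()] result.
#' @param pp a [predictive_power()] result on the same comparison.
#' @param fdr_max,min_mean,pp_min selection thresholds (defaults 0.05,
#'   300, 0.70).
#' @param manual character vector of manually added miRNA ids.
#' @return object of class `candidate_panel`: list with `subtype`,
#'   `members` (data.frame `mirna_id`, `source`), the track sets
#'   `de_mirnas` / `pp_mirnas`, their sizes and the thresholds used.
#' @export
build_panel <- function(de, pp, fdr_max = 0.05, min_mean = 300,
                        pp_min = 0.70, manual = character()) {
  if (!setequal(de$mirna_id, pp$mirna_id))
    input_error("DE and PP tracks cover different miRNA universes")
  cmp_de <- attr(de, "comparison")
  cmp_pp <- attr(pp, "comparison")
  if (!is.null(cmp_de) && !is.null(cmp_pp) && !identical(cmp_de, cmp_pp))
    input_error("DE and PP tracks come from different comparisons")

  de_set <- de$mirna_id[!is.na(de$fdr) & de$fdr <= fdr_max &
                          de$mean_read_count >= min_mean]
  pp_set <- pp$mirna_id[!is.na(pp$pp) & pp$pp >= pp_min]
  core <- de$mirna_id[de$mirna_id %in% intersect(de_set, pp_set)]
  manual <- setdiff(manual, core)
  members <- data.frame(
    mirna_id = c(core, manual),
    source = c(rep("DE&PP", length(core)), rep("manual", length(manual))),
    stringsAsFactors = FALSE)
  subtype <- if (!is.null(cmp_de)) unname(cmp_de["subtype"]) else
    NA_character_
  structure(list(subtype = subtype,
                 members = members,
                 de_mirnas = de_set, pp_mirnas = pp_set,
                 n_de = length(de_set), n_pp = length(pp_set),
                 n_overlap = length(core),
                 thresholds = c(fdr_max = fdr_max, min_mean = min_mean,
                                pp_min = pp_min)),
            class = "candidate_panel")
}

#' @export
print.candidate_panel <- function(x, ...) {
  cat(sprintf("candidate panel [%s]: |DE| = %d, |PP| = %d, |DE&PP| = %d\n",
              x$subtype %||% "?", x$n_de, x$n_pp, x$n_overlap))
  if (nrow(x$members)) print(x$members)
  invisible(x)
}

#' Overlap of candidate panels across subtypes
#'
#' Reports, by miRNA id, the pairwise intersections between panels and
#' the miRNAs common to all of them.
#'
#' @param panels list of [build_panel()] results (length >= 2).
#' @return list with `pairwise` (named list of id vectors), `counts`
#'   (matrix of pairwise intersection sizes), `all_way` (ids in every
#'   panel) and `union` (ids in any panel).
#' @export
cross_subtype_overlap <- function(panels) {
  if (length(panels) < 2) input_error("need at least 2 panels")
  sets <- lapply(panels, function(p)
    if (inherits(p, "candidate_panel")) p$members$mirna_id else
      as.character(p))
  labs <- names(sets) %||% paste0("panel", seq_along(sets))
  labs[labs == ""] <- paste0("panel", which(labs == ""))
  names(sets) <- labs
  np <- length(sets)
  counts <- matrix(0L, np, np, dimnames = list(labs, labs))
  pairwise <- list()
  for (i in seq_len(np)) for (j in seq_len(np)) {
    ids <- intersect(sets[[i]], sets[[j]])
    counts[i, j] <- length(ids)
    if (i < j) pairwise[[paste(labs[i], labs[j], sep = ":")]] <- ids
  }
  list(pairwise = pairwise, counts = counts,
       all_way = Reduce(intersect, sets),
       union = Reduce(union, sets))
}
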