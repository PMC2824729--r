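# HRC step: High Weight Elements (Wv > 0.5) are prioritized as plausible
# disease candidates (HWEc) when their local clustering coefficient in the
# domain interaction network is below 0.015 -- disease genes tend to avoid
# densely clustered network neighborhoods.

#' Prioritize candidates by weight value and clustering coefficient
#'
#' Applies the two strict thresholds: a candidate is an HWE iff
#' `wv > wv_threshold` and an HWEc iff additionally `ci < ci_threshold`.
#' Both comparisons are strict, so a candidate sitting exactly on a
#' threshold is not selected. Output is sorted by `wv` descending, then `ci`
#' ascending, then protein ID, for deterministic diffable lists.
#'
#' @param candidates `data.frame` with at least `protein`, `wv`, `ci`
#'   columns, as from [assign_protein_scores()].
#' @param wv_threshold HWE weight-value threshold (default 0.5).
#' @param ci_threshold HWEc clustering-coefficient cutoff (default 0.015,
#'   the reported average clustering coefficient of disease genes).
#' @return object of class `prioritization_result`: `candidates` (sorted,
#'   with `is_hwe`/`is_hwec` columns), `hwe_count`, `hwec_count`,
#'   `thresholds`.
#' @export
prioritize <- function(candidates, wv_threshold = 0.5, ci_threshold = 0.015) {
  stopifnot(all(c("protein", "wv", "ci") %in% names(candidates)))
  candidates$is_hwe <- candidates$wv > wv_threshold
  candidates$is_hwec <- candidates$is_hwe & candidates$ci < ci_threshold
  ord <- order(-candidates$wv, candidates$ci, candidates$protein)
  candidates <- candidates[ord, , drop = FALSE]
  rownames(candidates) <- NULL
  structure(list(candidates = candidates,
                 hwe_count = sum(candidates$is_hwe),
                 hwec_count = sum(candidates$is_hwec),
                 thresholds = c(wv_threshold = wv_threshold,
                                ci_threshold = ci_threshold)),
            class = "prioritization_result")
}

#' @export
print.prioritization_result <- function(x, ...) {
  cat(sprintf(paste0("prioritization: %d candidates, %d HWE (Wv > %g), ",
                     "%d HWEc (C_i < %g)\n"),
              nrow(x$candidates), x$hwe_count, x$thresholds[["wv_threshold"]],
              x$hwec_count, x$thresholds[["ci_threshold"]]))
  invisible(x)
}

#' HWEc subset of a prioritization
#' @param result a `prioritization_result`.
#' @return `data.frame` of prioritized (HWEc) candidates, in ranked order.
#' @export
hwec_candidates <- function(result) {
  stopifnot(inherits(result, "prioritization_result"))
  out <- result$candidates[result$candidates$is_hwec, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Regression check against the packaged benchmark gene table
#'
#' Runs [prioritize()] on the 19-gene comparison table shipped with the
#' package ([table3_fixture()]) and reports the HWE and HWEc counts plus
#' per-gene decisions next to the printed prioritization flags.
#'
#' @param fixture the 19-row table (default [table3_fixture()]).
#' @param wv_threshold,ci_threshold thresholds passed to [prioritize()].
#' @return list: `hwe_count`, `hwec_count`, `flags` (`data.frame` with
#'   `gene`, `wv`, `ci`, `is_hwe`, `is_hwec`, `published_flag`).
#' @export
table3_check <- function(fixture = table3_fixture(),
                         wv_threshold = 0.5, ci_threshold = 0.015) {
  cand <- data.frame(protein = fixture$gene, wv = fixture$wv,
                     ci = fixture$ci, stringsAsFactors = FALSE)
  res <- prioritize(cand, wv_threshold = wv_threshold,
                    ci_threshold = ci_threshold)
  m <- match(fixture$gene, res$candidates$protein)
  list(hwe_count = res$hwe_count,
       hwec_count = res$hwec_count,
       flags = data.frame(gene = fixture$gene, wv = fixture$wv,
                          ci = fixture$ci,
                          is_hwe = res$candidates$is_hwe[m],
                          is_hwec = res$candidates$is_hwec[m],
                          published_flag = fixture$prioritized,
                          stringsAsFactors = FALSE))
}
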