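# Packaged regression fixture: the published 19-gene benchmark comparison
# (genome-wide-association T2D genes scored by Wv and C_i, with the
# prioritization flag and the GeneWanderer random-walk rank).

#' The 19-gene benchmark comparison table
#'
#' Returns the published per-gene weight values, clustering coefficients,
#' prioritization flags and GeneWanderer random-walk ranks for the 19 known
#' T2D genes used for benchmarking. `prioritized` is `TRUE` for the genes
#' flagged as prioritized by the combined Wv + HRC method;
#' `genewanderer_rank` is `NA` where no rank was reported.
#'
#' @return `data.frame` with columns `gene`, `wv`, `ci`, `prioritized`,
#'   `genewanderer_rank` (19 rows).
#' @export
#' @examples
#' t3 <- table3_fixture()
#' nrow(t3)              # 19
#' sum(t3$wv > 0.5)      # High Weight Elements among the known genes
table3_fixture <- function() {
  data.frame(
    gene = c("ADAMTS9", "NOTCH2", "HNF1B", "PPARG", "KCNQ1", "CDKL1",
             "CAMK1D", "IGF2BP2", "LGR5", "CDKN2B", "CDKN2A", "HHEX",
             "TSPAN8", "TCF7L2", "CDC123", "MTNR1B", "SLC30A8", "HDAC2",
             "KCNJ11"),
    wv = c(1, 0.93, 0.87, 0.77, 0.73, 0.63, 0.63, 0.59, 0.56, 0.53, 0.53,
           0.53, 0.51, 0.48, 0.46, 0.44, 0.37, 0.21, 0),
    ci = c(0, 0, 1, 0.667, 0.033, 0.005, 0.005, 0.01, 0.286, 0.016, 0.016,
           0.053, 0, 0.03, 0, 0, 0.055, 0.067, 0),
    prioritized = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                    FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE,
                    FALSE, FALSE, FALSE),
    genewanderer_rank = c(35, 9, NA, 1, 4, 16, 30, 71, 41, 1, 3, 16, 10,
                          NA, 21, 1, 42, 9, NA),
    stringsAsFactors = FALSE
  )
}
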