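# End-to-end driver: score -> prioritize -> benchmark -> motifs, with fixed
# TSV layouts and a JSON run manifest recording inputs, settings and
# per-stage row counts.

.default_pipeline_options <- function() {
  list(min_confidence = 10, aggregation = "sum", normalization = "minmax",
       wv_threshold = 0.5, ci_threshold = 0.015,
       motif_size = 3, motif_iterations = 1000, motif_alpha = 0.01,
       seed = 1)
}

# Fixed-format TSV used for all pipeline outputs: floats at 6 significant
# digits, tab separated, LF endings.
.write_pipeline_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      out[[j]] <- formatC(signif(out[[j]], 6), format = "fg", digits = 6)
      out[[j]][is.na(df[[j]])] <- "NA"
    }
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(out), collapse = "\t"), con, sep = "\n")
  if (nrow(out) > 0L) {
    writeLines(do.call(paste, c(unname(out), sep = "\t")), con, sep = "\n")
  }
  path
}

#' Run the full prioritization pipeline
#'
#' Chains the stages on one input bundle: Wv scoring of every candidate
#' protein, HRC prioritization, benchmarking against the label files (when
#' present), and motif significance analysis of the domain network. Writes
#' `scores.tsv`, `hwec.tsv`, `report.tsv`, `motifs.tsv`,
#' `roc_points.tsv` and `manifest.json` into `outdir`. A stage failure
#' aborts with an error after writing a partial manifest naming the failed
#' stage.
#'
#' @param config either a named list or the path of a YAML file with an
#'   `inputs` section (file paths as accepted by [load_inputs()]) and
#'   optional settings: `min_confidence`, `aggregation`, `normalization`,
#'   `wv_threshold`, `ci_threshold`, `motif_size`, `motif_iterations`,
#'   `motif_alpha`, `seed`.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with the stage results (`bundle`, `scored`,
#'   `prioritized`, `benchmark`, `motifs`, `manifest`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      stop(structure(class = c("domprior_missing_input", "error", "condition"),
                     list(message = paste0("config file not found: ", config),
                          call = NULL)))
    }
    config <- yaml::read_yaml(config)
  }
  opts <- utils::modifyList(.default_pipeline_options(),
                            config[setdiff(names(config), "inputs")])
  inputs <- lapply(config$inputs, as.character)
  if (length(inputs) == 0L) {
    stop(structure(class = c("domprior_missing_input", "error", "condition"),
                   list(message = "config has no 'inputs' section",
                        call = NULL)))
  }
  absent <- names(inputs)[!vapply(inputs, file.exists, TRUE)]
  if (length(absent) > 0L) {
    stop(structure(class = c("domprior_missing_input", "error", "condition"),
                   list(message = paste0("missing input file(s): ",
                                         paste(absent, collapse = ", ")),
                        call = NULL)))
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    tool = "domprior", version = as.character(packageVersion("domprior")),
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = opts$seed,
    options = opts[setdiff(names(opts), "seed")],
    inputs = lapply(inputs, function(p) {
      list(path = p, md5 = unname(tools::md5sum(p)))
    }),
    stages = list())
  fail <- function(stage, err) {
    manifest$failed_stage <<- stage
    manifest$error <<- conditionMessage(err)
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(err),
         call. = FALSE)
  }

  bundle <- tryCatch(load_inputs(inputs, config = config),
                     error = function(e) fail("load", e))

  scored <- tryCatch({
    s <- score_bundle(bundle, min_confidence = opts$min_confidence,
                      aggregation = opts$aggregation,
                      normalization = opts$normalization)
    pr <- prioritize(s$candidates, wv_threshold = opts$wv_threshold,
                     ci_threshold = opts$ci_threshold)
    .write_pipeline_tsv(pr$candidates[, c("protein", "gene_symbol",
                                          "best_domain", "n_partners",
                                          "raw_wv", "wv", "ci", "is_hwe",
                                          "is_hwec")],
                        file.path(outdir, "scores.tsv"))
    .write_pipeline_tsv(hwec_candidates(pr)[, c("protein", "gene_symbol",
                                                "best_domain", "wv", "ci")],
                        file.path(outdir, "hwec.tsv"))
    list(scoring = s, prioritized = pr)
  }, error = function(e) fail("score", e))
  manifest$stages$score <- list(
    candidates = nrow(scored$scoring$candidates),
    excluded = length(attr(scored$scoring$candidates, "excluded")),
    hwe = scored$prioritized$hwe_count,
    hwec = scored$prioritized$hwec_count)

  bench <- NULL
  if (!is.null(bundle$labels)) {
    bench <- tryCatch({
      cand <- scored$prioritized$candidates
      scores_vec <- setNames(cand$wv, cand$protein)
      res <- benchmark_prediction(cand$protein[cand$is_hwec],
                                  bundle$labels, scores = scores_vec)
      report <- data.frame(
        metric = c("tp", "fp", "tn", "fn", "sensitivity", "specificity",
                   "accuracy", "enrichment", "auc"),
        value = c(res$matrix$tp, res$matrix$fp, res$matrix$tn,
                  res$matrix$fn, res$sensitivity, res$specificity,
                  res$accuracy, res$enrichment, res$auc),
        stringsAsFactors = FALSE)
      .write_pipeline_tsv(report, file.path(outdir, "report.tsv"))
      .write_pipeline_tsv(res$roc_points, file.path(outdir, "roc_points.tsv"))
      res
    }, error = function(e) fail("benchmark", e))
    manifest$stages$benchmark <- list(
      auc = bench$auc, sensitivity = bench$sensitivity,
      specificity = bench$specificity)
  }

  motifs <- tryCatch({
    mot <- motif_significance(scored$scoring$network, size = opts$motif_size,
                              iterations = opts$motif_iterations,
                              alpha = opts$motif_alpha, seed = opts$seed)
    .write_pipeline_tsv(mot, file.path(outdir, "motifs.tsv"))
    mot
  }, error = function(e) fail("motifs", e))
  manifest$stages$motifs <- list(
    classes = nrow(motifs), significant = sum(motifs$significant))

  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(bundle = bundle, scored = scored$scoring,
                 prioritized = scored$prioritized, benchmark = bench,
                 motifs = motifs, manifest = manifest))
}
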