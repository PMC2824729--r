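# Synthetic input worlds: a complete, self-consistent set of the six input
# files (domain interactions, domain-protein map, annotation, linked
# regions, class catalogs, benchmark labels) with a controllable number of
# planted high-evidence candidates, so the whole pipeline is testable
# without any external database.

#' Configuration for a synthetic input world
#'
#' Defaults describe the desk-scale study conditions the generator emulates:
#' a heterogeneous domain interaction graph with mean degree about 6.5,
#' confidence scores of which roughly a fifth fall below the cutoff of 10,
#' 1-3 domains per protein, 64 linked 10 Mb marker regions over a 22
#' chromosome genome, and evidence catalogs with totals T_a = 60, T_b = 15,
#' T_c = `n_markers`, T_d derived from a raw disease list of 1777 entries.
#' Planted candidates carry a dedicated parent domain wired to partner
#' domains that are members of the evidence classes (a/b-class domains and
#' c/d-class domains), while background partners are class-free up to a
#' small annotation-noise rate.
#'
#' @param n_domains number of Pfam-style domains in the world.
#' @param n_proteins number of positional candidate proteins.
#' @param n_markers number of linkage markers (one 10 Mb region each).
#' @param mean_degree target mean degree of the domain graph.
#' @param confidence_meanlog,confidence_sdlog lognormal parameters of edge
#'   confidence scores.
#' @param t_a class-a catalog size (padded with out-of-world domains).
#' @param t_b class-b GO process count.
#' @param t_d_raw raw class-d catalog size before class-a deduplication.
#' @param n_planted number of planted disease-like candidates.
#' @param n_evidence_ab,n_evidence_cd sizes of the a/b- and c/d-class
#'   evidence domain pools.
#' @param planted_ab_partners,planted_cd_partners evidence partners wired to
#'   each planted parent domain.
#' @param bg_classb_fraction fraction of ordinary domains mapped to a
#'   class-b process (default 0: background partners are free of the curated
#'   evidence classes; only positional class-c overlap arises naturally).
#' @param n_classd_background background candidate proteins listed in
#'   class d (annotation noise).
#' @param n_negatives control genes in the benchmark label file.
#' @param seed integer seed; identical seed and config give byte-identical
#'   output files.
#' @return object of class `world_config` (a validated list).
#' @export
world_config <- function(n_domains = 300, n_proteins = 500, n_markers = 64,
                         mean_degree = 6.5,
                         confidence_meanlog = log(20),
                         confidence_sdlog = 0.8,
                         t_a = 60, t_b = 15, t_d_raw = 1777,
                         n_planted = 10,
                         n_evidence_ab = 8, n_evidence_cd = 8,
                         planted_ab_partners = 6, planted_cd_partners = 6,
                         bg_classb_fraction = 0,
                         n_classd_background = 40,
                         n_negatives = 150, seed = 1) {
  cfg <- list(n_domains = n_domains, n_proteins = n_proteins,
              n_markers = n_markers, mean_degree = mean_degree,
              confidence_meanlog = confidence_meanlog,
              confidence_sdlog = confidence_sdlog,
              t_a = t_a, t_b = t_b, t_d_raw = t_d_raw,
              n_planted = n_planted,
              n_evidence_ab = n_evidence_ab, n_evidence_cd = n_evidence_cd,
              planted_ab_partners = planted_ab_partners,
              planted_cd_partners = planted_cd_partners,
              bg_classb_fraction = bg_classb_fraction,
              n_classd_background = n_classd_background,
              n_negatives = n_negatives, seed = as.integer(seed))
  counts <- unlist(cfg[c("n_domains", "n_proteins", "n_markers", "t_a",
                         "t_b", "t_d_raw")])
  if (any(counts <= 0)) stop("all counts must be positive", call. = FALSE)
  if (n_planted < 0 || n_planted > n_proteins) {
    stop("infeasible config: n_planted must be between 0 and n_proteins",
         call. = FALSE)
  }
  if (n_planted + n_evidence_ab + n_evidence_cd + 10 > n_domains) {
    stop("infeasible config: too few domains for the planted structure",
         call. = FALSE)
  }
  if (planted_ab_partners > n_evidence_ab ||
      planted_cd_partners > n_evidence_cd) {
    stop("infeasible config: planted partner counts exceed evidence pools",
         call. = FALSE)
  }
  if (t_a < n_evidence_ab) {
    stop("infeasible config: t_a smaller than the a/b evidence pool",
         call. = FALSE)
  }
  if (n_negatives > n_proteins - n_planted) {
    stop("infeasible config: not enough background proteins for negatives",
         call. = FALSE)
  }
  structure(cfg, class = "world_config")
}

# Synthetic genome: 22 chromosomes shrinking from 250 Mb to 61 Mb.
.world_chrom_lengths <- function() {
  setNames(as.integer(250e6 - (0:21) * 9e6), paste0("chr", 1:22))
}

#' Generate a synthetic input world
#'
#' Builds all inputs in memory (and optionally on disk, see [write_world()])
#' under the configured seed: a fitness-model random domain graph with
#' lognormal confidence scores, a domain-protein map with 1-3 domains per
#' candidate, gene coordinates on a synthetic genome, marker regions, the
#' four class catalogs and benchmark labels. Planted candidates are wired so
#' that their parent domain's partners hit the evidence classes, giving them
#' a separated upper mode of the weight-value distribution.
#'
#' @param config a [world_config()].
#' @param outdir optional directory; when given, the world is also written
#'   to disk via [write_world()].
#' @return object of class `domprior_world`: `bundle` (a `domprior_bundle`),
#'   `planted` (planted candidate proteins), `planted_parents` (their
#'   dedicated parent domains), `config`, and `paths` when written.
#' @export
generate_world <- function(config = world_config(), outdir = NULL) {
  stopifnot(inherits(config, "world_config"))
  world <- .with_seed(config$seed, .build_world(config))
  if (!is.null(outdir)) {
    world$paths <- write_world(world, outdir)
  }
  world
}

.build_world <- function(cfg) {
  domains <- sprintf("PF%05d", seq_len(cfg$n_domains))
  idx_parent <- seq_len(cfg$n_planted)
  idx_ab <- cfg$n_planted + seq_len(cfg$n_evidence_ab)
  idx_cd <- cfg$n_planted + cfg$n_evidence_ab + seq_len(cfg$n_evidence_cd)
  planted_parents <- domains[idx_parent]
  ab_pool <- domains[idx_ab]
  cd_pool <- domains[idx_cd]
  ordinary <- domains[-c(idx_parent, idx_ab, idx_cd)]

  # background interaction graph: fitness model targeting the mean degree
  m <- round(cfg$mean_degree * cfg$n_domains / 2)
  fit <- rlnorm(cfg$n_domains, 0, 0.8)
  g <- igraph::sample_fitness(m, fitness.out = fit, loops = FALSE,
                              multiple = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  conf <- round(rlnorm(nrow(el), cfg$confidence_meanlog,
                       cfg$confidence_sdlog), 2)
  edges <- data.frame(domain_a = domains[el[, 1L]],
                      domain_b = domains[el[, 2L]],
                      confidence = conf, stringsAsFactors = FALSE)

  # planted wiring: each planted parent interacts only with a sample of the
  # evidence pools (high-confidence edges, resampled above the cutoff), and
  # evidence domains do not interact with each other -- planted candidates
  # are peripheral, locally sparse nodes, the network signature of disease
  # genes the HRC filter selects for
  if (cfg$n_planted > 0L) {
    touched <- c(planted_parents, ab_pool, cd_pool)
    drop <- edges$domain_a %in% touched & edges$domain_b %in% touched |
      edges$domain_a %in% planted_parents |
      edges$domain_b %in% planted_parents
    edges <- edges[!drop, , drop = FALSE]
    pe <- do.call(rbind, lapply(seq_len(cfg$n_planted), function(i) {
      partners <- c(sample(ab_pool, cfg$planted_ab_partners),
                    sample(cd_pool, cfg$planted_cd_partners))
      data.frame(domain_a = planted_parents[i], domain_b = partners,
                 stringsAsFactors = FALSE)
    }))
    pconf <- round(rlnorm(nrow(pe), cfg$confidence_meanlog,
                          cfg$confidence_sdlog), 2)
    while (any(pconf < 10)) {
      low <- pconf < 10
      pconf[low] <- round(rlnorm(sum(low), cfg$confidence_meanlog,
                                 cfg$confidence_sdlog), 2)
    }
    pe$confidence <- pconf
    edges <- rbind(edges, pe)
  }
  edges <- make_edge_table(edges)

  # linked marker regions (10 Mb windows) on the synthetic genome
  chrom_len <- .world_chrom_lengths()
  mk_chrom <- sample(names(chrom_len), cfg$n_markers, replace = TRUE)
  mk_pos <- vapply(mk_chrom, function(ch) {
    round(runif(1, 5e6 + 1, chrom_len[[ch]] - 5e6))
  }, 0)
  regions <- regions_from_markers(data.frame(
    marker_id = sprintf("MRK%03d", seq_len(cfg$n_markers)),
    chrom = mk_chrom, pos = mk_pos, stringsAsFactors = FALSE))

  # candidate annotation: random gene intervals over the genome
  proteins <- sprintf("SYNP%04d", seq_len(cfg$n_proteins))
  pr_chrom <- sample(names(chrom_len), cfg$n_proteins, replace = TRUE)
  pr_len <- round(runif(cfg$n_proteins, 5e3, 2e5))
  pr_start <- vapply(seq_len(cfg$n_proteins), function(i) {
    round(runif(1, 1, chrom_len[[pr_chrom[i]]] - pr_len[i]))
  }, 0)
  annotation <- data.frame(protein = proteins,
                           gene_symbol = sprintf("GENE%04d",
                                                 seq_len(cfg$n_proteins)),
                           chrom = pr_chrom, start = pr_start,
                           end = pr_start + pr_len,
                           stringsAsFactors = FALSE)
  planted_proteins <- if (cfg$n_planted > 0L) {
    proteins[seq_len(cfg$n_planted)]
  } else character()
  background_proteins <- setdiff(proteins, planted_proteins)

  # domain-protein map: planted candidates harbor their parent (plus at most
  # one ordinary domain), background candidates 1-3 ordinary domains
  dm <- list()
  if (cfg$n_planted > 0L) {
    extra <- sample(c(TRUE, FALSE), cfg$n_planted, replace = TRUE)
    dm[[1L]] <- data.frame(domain = planted_parents,
                           protein = planted_proteins,
                           stringsAsFactors = FALSE)
    if (any(extra)) {
      dm[[2L]] <- data.frame(domain = sample(ordinary, sum(extra),
                                             replace = TRUE),
                             protein = planted_proteins[extra],
                             stringsAsFactors = FALSE)
    }
  }
  n_bg <- length(background_proteins)
  n_dom_per <- sample(1:3, n_bg, replace = TRUE)
  dm[[length(dm) + 1L]] <- data.frame(
    domain = sample(ordinary, sum(n_dom_per), replace = TRUE),
    protein = rep(background_proteins, n_dom_per),
    stringsAsFactors = FALSE)

  # harboring proteins for the evidence pools: a/b domains get ordinary
  # hosts; c/d domains get hosts placed inside linked regions and listed in
  # the disease catalog (and carrying no class-a domain, so they survive the
  # class-a deduplication)
  ab_hosts <- sprintf("SYNA%04d", seq_len(cfg$n_evidence_ab))
  ab_host_chrom <- sample(names(chrom_len), cfg$n_evidence_ab, replace = TRUE)
  ab_host_start <- vapply(ab_host_chrom, function(ch) {
    round(runif(1, 1, chrom_len[[ch]] - 5e4))
  }, 0)
  cd_hosts <- sprintf("SYNQ%04d", seq_len(cfg$n_evidence_cd))
  host_region <- sample(seq_len(nrow(regions)), cfg$n_evidence_cd,
                        replace = TRUE)
  cd_start <- round(regions$start[host_region] +
                      runif(cfg$n_evidence_cd, 1e5, 8e6))
  host_annot <- data.frame(
    protein = c(ab_hosts, cd_hosts),
    gene_symbol = c(sprintf("HOSTA%03d", seq_len(cfg$n_evidence_ab)),
                    sprintf("HOSTQ%03d", seq_len(cfg$n_evidence_cd))),
    chrom = c(ab_host_chrom, regions$chrom[host_region]),
    start = c(ab_host_start, cd_start),
    end = c(ab_host_start + 5e4, cd_start + 5e4),
    stringsAsFactors = FALSE)
  annotation <- rbind(annotation, host_annot)
  dm[[length(dm) + 1L]] <- data.frame(domain = c(ab_pool, cd_pool),
                                      protein = c(ab_hosts, cd_hosts),
                                      stringsAsFactors = FALSE)
  domain_map <- unique(do.call(rbind, dm))
  domain_map <- domain_map[order(domain_map$domain, domain_map$protein), ,
                           drop = FALSE]
  rownames(domain_map) <- NULL

  # class catalogs
  class_a <- c(ab_pool, sprintf("PF9%04d", seq_len(cfg$t_a - cfg$n_evidence_ab)))
  class_b <- sprintf("GO:%07d", 8000000 + seq_len(cfg$t_b))
  noise_go <- sprintf("GO:%07d", 7000000 + 1:25)
  n_bg_b <- round(cfg$bg_classb_fraction * length(ordinary))
  bg_b_domains <- if (n_bg_b > 0L) sample(ordinary, n_bg_b) else character()
  n_noise <- round(0.1 * length(ordinary))
  noise_domains <- if (n_noise > 0L) sample(ordinary, n_noise) else character()
  pfam2go <- unique(data.frame(
    domain = c(ab_pool, bg_b_domains, noise_domains),
    go_id = c(sample(class_b, cfg$n_evidence_ab, replace = TRUE),
              if (n_bg_b > 0L) sample(class_b, n_bg_b, replace = TRUE),
              if (n_noise > 0L) sample(noise_go, n_noise, replace = TRUE)),
    stringsAsFactors = FALSE))
  pfam2go <- pfam2go[order(pfam2go$domain, pfam2go$go_id), , drop = FALSE]
  rownames(pfam2go) <- NULL
  n_d_bg <- min(cfg$n_classd_background, length(background_proteins))
  class_d_raw <- c(cd_hosts,
                   if (n_d_bg > 0L) sample(background_proteins, n_d_bg),
                   head(ab_hosts, min(3L, cfg$n_evidence_ab)),
                   sprintf("OMIMP%04d",
                           seq_len(max(0L, cfg$t_d_raw - cfg$n_evidence_cd -
                                         n_d_bg - min(3L, cfg$n_evidence_ab)))))
  catalog <- class_catalog(class_a_domains = class_a,
                           class_b_processes = class_b,
                           pfam2go = pfam2go,
                           class_c_regions = regions,
                           class_d_proteins = class_d_raw,
                           domain_map = domain_map)

  positives <- if (cfg$n_planted > 0L) planted_proteins else
    sample(background_proteins, min(5L, length(background_proteins) - 1L))
  labels <- benchmark_labels(
    positives = positives,
    negatives = sample(setdiff(background_proteins, positives),
                       min(cfg$n_negatives,
                           length(setdiff(background_proteins, positives)))))
  bundle <- structure(list(edges = edges, domain_map = domain_map,
                           annotation = annotation, regions = regions,
                           catalog = catalog, labels = labels,
                           validation = character()),
                      class = "domprior_bundle")
  structure(list(bundle = bundle, planted = planted_proteins,
                 planted_parents = planted_parents,
                 class_a_raw = class_a, class_d_raw = sort(unique(class_d_raw)),
                 config = cfg, paths = NULL),
            class = "domprior_world")
}

#' @export
print.domprior_world <- function(x, ...) {
  cat(sprintf("synthetic world (seed %d): %d domains, %d candidates, %d planted\n",
              x$config$seed, x$config$n_domains, x$config$n_proteins,
              x$config$n_planted))
  print(x$bundle)
  invisible(x)
}

# Deterministic TSV writer: tab-separated, no quoting, LF line endings.
.write_tsv <- function(df, path, header = NULL) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(header)) {
    writeLines(paste0("#", paste(header, collapse = "\t")), con, sep = "\n")
  }
  for (j in seq_along(df)) {
    if (is.numeric(df[[j]])) df[[j]] <- format(df[[j]], scientific = FALSE,
                                               trim = TRUE)
  }
  writeLines(do.call(paste, c(unname(df), sep = "\t")), con, sep = "\n")
}

#' Write a synthetic world to disk
#'
#' Emits the full input bundle in the on-disk dialects read by
#' [load_inputs()]: `edges.tsv`, `domain_map.tsv`, `annotation.tsv`,
#' `regions.bed` (0-based half-open), `class_a.txt`,
#' `class_b_processes.txt`, `pfam2go.txt`, `class_d.txt`, `positives.txt`,
#' `negatives.txt`. The class-d file carries the raw (pre-deduplication)
#' catalog, as an OMIM-style list would.
#'
#' @param world a `domprior_world` from [generate_world()].
#' @param outdir output directory (created if needed).
#' @return named list of file paths (invisibly usable with [load_inputs()]).
#' @export
write_world <- function(world, outdir) {
  stopifnot(inherits(world, "domprior_world"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  b <- world$bundle
  paths <- list(
    edges = file.path(outdir, "edges.tsv"),
    domain_map = file.path(outdir, "domain_map.tsv"),
    annotation = file.path(outdir, "annotation.tsv"),
    regions = file.path(outdir, "regions.bed"),
    class_a = file.path(outdir, "class_a.txt"),
    class_b = file.path(outdir, "class_b_processes.txt"),
    pfam2go = file.path(outdir, "pfam2go.txt"),
    class_d = file.path(outdir, "class_d.txt"),
    positives = file.path(outdir, "positives.txt"),
    negatives = file.path(outdir, "negatives.txt"))
  .write_tsv(b$edges, paths$edges,
             header = c("domain_a", "domain_b", "confidence"))
  .write_tsv(b$domain_map, paths$domain_map, header = c("domain", "protein"))
  .write_tsv(b$annotation, paths$annotation,
             header = c("protein", "gene_symbol", "chrom", "start", "end"))
  bed <- data.frame(chrom = b$regions$chrom,
                    start = b$regions$start - 1,  # back to BED convention
                    end = b$regions$end,
                    marker_id = b$regions$marker_id,
                    stringsAsFactors = FALSE)
  .write_tsv(bed, paths$regions)
  writeLines(sort(world$class_a_raw), paths$class_a)
  writeLines(b$catalog$class_b_processes, paths$class_b)
  p2g <- b$catalog$pfam2go
  writeLines(sprintf("Pfam:%s %s > GO:process ; %s",
                     p2g$domain, tolower(p2g$domain), p2g$go_id),
             paths$pfam2go)
  writeLines(world$class_d_raw, paths$class_d)
  writeLines(sort(b$labels$positives), paths$positives)
  writeLines(sort(b$labels$negatives), paths$negatives)
  invisible(paths)
}
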