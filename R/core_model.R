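# Input data model: identifier normalization, the six tabular input dialects,
# interval arithmetic against linked marker regions, and bundle validation.

#' Normalize a domain or protein identifier
#'
#' Identifiers are upper-cased and stripped of surrounding whitespace so that
#' lookups are case-insensitive. The operation is idempotent.
#'
#' @param x character vector of identifiers.
#' @return character vector of normalized identifiers.
#' @export
#' @examples
#' normalize_id(c(" pf05277", "Pf00046 "))
normalize_id <- function(x) {
  toupper(trimws(as.character(x)))
}

# Split non-comment lines of a TSV into fields, keeping original line numbers
# so parse errors can point at the offending line.
.read_tsv_lines <- function(path) {
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep), path = path)
}

.parse_error <- function(path, lineno, what) {
  stop(sprintf("malformed line %d in %s: %s", lineno, path, what),
       call. = FALSE)
}

# TRUE if a field fails numeric conversion (used for header sniffing and
# per-line validation).
.not_numeric <- function(x) is.na(suppressWarnings(as.numeric(x)))

#' Read a domain interaction edge list
#'
#' Expects tab-separated columns `domain_a`, `domain_b`, `confidence`. Lines
#' starting with `#` are comments; a leading non-numeric header row is
#' skipped. Self-interactions are dropped (with a recorded count) and
#' duplicate pairs, including reversed order, are merged keeping the maximum
#' confidence: the interaction network is undirected and local clustering
#' coefficients are not defined on multigraphs with self-loops.
#'
#' @param path path to the edge TSV.
#' @return `data.frame` with columns `domain_a`, `domain_b`, `confidence`;
#'   attributes `n_self_loops` and `n_duplicates` record what ingest removed.
#' @export
read_edge_table <- function(path) {
  tsv <- .read_tsv_lines(path)
  fields <- tsv$fields
  if (length(fields) == 0L) {
    stop("empty mandatory file: ", path, call. = FALSE)
  }
  if (length(fields[[1L]]) >= 3L && .not_numeric(fields[[1L]][3L])) {
    fields <- fields[-1L]
    tsv$lineno <- tsv$lineno[-1L]
  }
  if (length(fields) == 0L) {
    stop("empty mandatory file (header only): ", path, call. = FALSE)
  }
  n <- length(fields)
  a <- character(n); b <- character(n); conf <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 3L) .parse_error(path, tsv$lineno[i], "expected 3 columns")
    if (.not_numeric(f[3L])) {
      .parse_error(path, tsv$lineno[i], "confidence is not numeric")
    }
    a[i] <- f[1L]; b[i] <- f[2L]; conf[i] <- as.numeric(f[3L])
  }
  if (any(conf < 0)) {
    bad <- which(conf < 0)[1L]
    .parse_error(path, tsv$lineno[bad], "confidence is negative")
  }
  make_edge_table(data.frame(domain_a = a, domain_b = b, confidence = conf,
                             stringsAsFactors = FALSE))
}

#' Construct a validated edge table from a data frame
#'
#' Applies the same ingest rules as [read_edge_table()]: identifier
#' normalization, self-loop removal and undirected duplicate merging (keeping
#' the maximum confidence).
#'
#' @param edges data.frame with columns `domain_a`, `domain_b`, `confidence`.
#' @return normalized edge `data.frame` with removal counts as attributes.
#' @export
make_edge_table <- function(edges) {
  a <- normalize_id(edges$domain_a)
  b <- normalize_id(edges$domain_b)
  conf <- as.numeric(edges$confidence)
  stopifnot(all(conf >= 0), all(nzchar(a)), all(nzchar(b)))
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; conf <- conf[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  n_dup <- sum(duplicated(key))
  if (n_dup > 0L) {
    conf <- tapply(conf, key, max)
    first <- !duplicated(key)
    ord <- key[first]
    out <- data.frame(domain_a = lo[first], domain_b = hi[first],
                      confidence = as.numeric(conf[ord]),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(domain_a = lo, domain_b = hi, confidence = conf,
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out <- out[order(out$domain_a, out$domain_b), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_self_loops") <- n_self
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Read a domain-to-protein mapping
#'
#' Expects tab-separated columns `domain`, `protein` (one pair per line,
#' SwissPfam style). Duplicate pairs are collapsed.
#'
#' @param path path to the mapping TSV.
#' @return `data.frame` with columns `domain`, `protein`.
#' @export
read_domain_map <- function(path) {
  tsv <- .read_tsv_lines(path)
  fields <- tsv$fields
  if (length(fields) == 0L) stop("empty mandatory file: ", path, call. = FALSE)
  if (identical(tolower(fields[[1L]][1L]), "domain")) {
    fields <- fields[-1L]; tsv$lineno <- tsv$lineno[-1L]
  }
  n <- length(fields)
  dom <- character(n); prot <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 2L) .parse_error(path, tsv$lineno[i], "expected 2 columns")
    dom[i] <- f[1L]; prot[i] <- f[2L]
  }
  out <- unique(data.frame(domain = normalize_id(dom),
                           protein = normalize_id(prot),
                           stringsAsFactors = FALSE))
  out <- out[order(out$domain, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a gene/protein annotation table
#'
#' Expects tab-separated columns `protein`, `gene_symbol`, `chrom`, `start`,
#' `end` with 1-based inclusive coordinates. Coordinates may be missing
#' (empty or `NA`) for unlocatable proteins; rows with coordinates must
#' satisfy `start <= end` and carry a chromosome.
#'
#' @param path path to the annotation TSV.
#' @return `data.frame` with the five columns; `start`/`end` numeric.
#' @export
read_annotation <- function(path) {
  tsv <- .read_tsv_lines(path)
  fields <- tsv$fields
  if (length(fields) == 0L) stop("empty mandatory file: ", path, call. = FALSE)
  if (length(fields[[1L]]) >= 4L && .not_numeric(fields[[1L]][4L]) &&
      !identical(fields[[1L]][4L], "NA") && !identical(fields[[1L]][4L], "")) {
    fields <- fields[-1L]; tsv$lineno <- tsv$lineno[-1L]
  }
  n <- length(fields)
  prot <- character(n); sym <- character(n); chrom <- character(n)
  start <- numeric(n); end <- numeric(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 5L) .parse_error(path, tsv$lineno[i], "expected 5 columns")
    prot[i] <- f[1L]; sym[i] <- f[2L]; chrom[i] <- f[3L]
    s <- suppressWarnings(as.numeric(f[4L]))
    e <- suppressWarnings(as.numeric(f[5L]))
    if ((is.na(s) && nzchar(f[4L]) && f[4L] != "NA") ||
        (is.na(e) && nzchar(f[5L]) && f[5L] != "NA")) {
      .parse_error(path, tsv$lineno[i], "coordinates are not numeric")
    }
    if (!is.na(s) && !is.na(e)) {
      if (s > e) .parse_error(path, tsv$lineno[i], "start > end")
      if (!nzchar(chrom[i]) || chrom[i] == "NA") {
        .parse_error(path, tsv$lineno[i], "coordinates without chromosome")
      }
    }
    start[i] <- s; end[i] <- e
  }
  out <- data.frame(protein = normalize_id(prot), gene_symbol = sym,
                    chrom = chrom, start = start, end = end,
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$protein)) {
    stop("duplicate protein identifiers in ", path, call. = FALSE)
  }
  out
}

#' Read linked marker regions from a BED-like file
#'
#' Expects tab-separated columns `chrom`, `start`, `end`, `marker_id` using
#' BED conventions (0-based half-open). Coordinates are converted to the
#' package's internal 1-based closed convention at ingest.
#'
#' @param path path to the BED-like TSV.
#' @return `data.frame` with columns `marker_id`, `chrom`, `start`, `end`
#'   (1-based, inclusive).
#' @export
read_regions <- function(path) {
  tsv <- .read_tsv_lines(path)
  fields <- tsv$fields
  if (length(fields) == 0L) stop("empty mandatory file: ", path, call. = FALSE)
  if (length(fields[[1L]]) >= 2L && .not_numeric(fields[[1L]][2L])) {
    fields <- fields[-1L]; tsv$lineno <- tsv$lineno[-1L]
  }
  n <- length(fields)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  marker <- character(n)
  for (i in seq_len(n)) {
    f <- fields[[i]]
    if (length(f) < 4L) .parse_error(path, tsv$lineno[i], "expected 4 columns")
    if (.not_numeric(f[2L]) || .not_numeric(f[3L])) {
      .parse_error(path, tsv$lineno[i], "coordinates are not numeric")
    }
    chrom[i] <- f[1L]
    start[i] <- as.numeric(f[2L]); end[i] <- as.numeric(f[3L])
    marker[i] <- f[4L]
    if (end[i] <= start[i]) {
      .parse_error(path, tsv$lineno[i], "region has non-positive width")
    }
  }
  data.frame(marker_id = marker, chrom = chrom,
             start = start + 1, end = end,  # BED 0-based half-open -> 1-based closed
             stringsAsFactors = FALSE)
}

#' Derive 10 Mb windows around linkage markers
#'
#' Builds the candidate-search regions from marker point positions: a window
#' of `flank` base pairs on each side of the marker (default 5 Mb, giving the
#' 10 Mb region encompassing each marker), clipped at position 1.
#'
#' @param markers data.frame with columns `marker_id`, `chrom`, `pos`.
#' @param flank half-window size in base pairs.
#' @return `data.frame` of regions in the internal 1-based closed convention.
#' @export
regions_from_markers <- function(markers, flank = 5e6) {
  data.frame(marker_id = as.character(markers$marker_id),
             chrom = as.character(markers$chrom),
             start = pmax(1, markers$pos - flank),
             end = markers$pos + flank,
             stringsAsFactors = FALSE)
}

#' Read a plain identifier list (one per line)
#'
#' Used for the class-a domain catalog, the class-b GO process list and the
#' class-d disease protein catalog. `#` comment lines and blanks are ignored.
#'
#' @param path path to the list file.
#' @param normalize normalize identifiers via [normalize_id()]?
#' @return character vector (duplicates preserved; catalog constructors
#'   deduplicate and record raw totals).
#' @export
read_id_list <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (normalize) normalize_id(lines) else lines
}

#' Read a Pfam2GO mapping file
#'
#' Parses lines of the curated Pfam-to-Gene-Ontology dialect:
#' `Pfam:PF00046 Homeobox > GO:DNA binding ; GO:0003677`. One GO term per
#' line; a domain may appear on several lines.
#'
#' @param path path to the mapping file.
#' @return `data.frame` with columns `domain`, `go_id`.
#' @export
read_pfam2go <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "!") &
                   !startsWith(trimws(lines), "#")]
  m <- regmatches(lines, regexec(
    "^Pfam:(\\S+).*;\\s*(GO:\\d+)\\s*$", lines))
  bad <- which(vapply(m, length, 1L) != 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed line %d in %s: not a Pfam2GO record",
                 bad[1L], path), call. = FALSE)
  }
  data.frame(domain = normalize_id(vapply(m, `[`, "", 2L)),
             go_id = vapply(m, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Build the four-class evidence catalog
#'
#' Assembles the membership sets for the four binary evidence classes and
#' records their totals `T_a..T_d`, the denominators of the per-partner score
#' components. Class d (proteins with any other known disease association) is
#' deduplicated against class a: proteins harboring a class-a domain are
#' removed, and both the raw and deduplicated totals are kept; scoring uses
#' the deduplicated total.
#'
#' @param class_a_domains character vector of class-a domain accessions.
#' @param class_b_processes character vector of disease-relevant GO process
#'   IDs (class b).
#' @param pfam2go data.frame `domain`, `go_id` mapping domains to processes.
#' @param class_c_regions region data.frame as from [read_regions()].
#' @param class_d_proteins character vector of disease-associated proteins.
#' @param domain_map optional domain-protein map used for the class-a/class-d
#'   deduplication; if omitted, class d is only made unique.
#' @return object of class `class_catalog` with members and totals.
#' @export
class_catalog <- function(class_a_domains, class_b_processes, pfam2go,
                          class_c_regions, class_d_proteins,
                          domain_map = NULL) {
  a <- unique(normalize_id(class_a_domains))
  b <- unique(as.character(class_b_processes))
  d_raw <- unique(normalize_id(class_d_proteins))
  t_d_raw <- length(d_raw)
  d <- d_raw
  if (!is.null(domain_map)) {
    class_a_proteins <- unique(domain_map$protein[domain_map$domain %in% a])
    d <- setdiff(d, class_a_proteins)
  }
  stopifnot(length(a) > 0L, length(b) > 0L,
            nrow(class_c_regions) > 0L, length(d) > 0L)
  structure(list(
    class_a_domains = a,
    class_b_processes = b,
    pfam2go = pfam2go,
    class_c_regions = class_c_regions,
    class_d_proteins = d,
    t_a = length(a), t_b = length(b), t_c = nrow(class_c_regions),
    t_d = length(d), t_d_raw = t_d_raw
  ), class = "class_catalog")
}

#' @export
print.class_catalog <- function(x, ...) {
  cat("Evidence class catalog\n")
  cat(sprintf("  class a (variant domains):   T_a = %d\n", x$t_a))
  cat(sprintf("  class b (GO processes):      T_b = %d\n", x$t_b))
  cat(sprintf("  class c (linked regions):    T_c = %d\n", x$t_c))
  cat(sprintf("  class d (disease proteins):  T_d = %d (raw %d)\n",
              x$t_d, x$t_d_raw))
  invisible(x)
}

#' Does a protein overlap any linked marker region?
#'
#' Closed-interval intersection on the same chromosome: a single shared
#' boundary base counts as overlap (1-based inclusive coordinates,
#' Ensembl convention). A protein without coordinates is reported as
#' non-overlapping with a warning (unlocatable).
#'
#' @param protein one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param regions region data.frame as from [read_regions()].
#' @return logical scalar.
#' @export
region_overlap <- function(protein, regions) {
  s <- protein$start; e <- protein$end; chrom <- protein$chrom
  if (is.null(s) || is.null(e) || is.na(s) || is.na(e) ||
      is.null(chrom) || is.na(chrom) || !nzchar(chrom)) {
    warning("protein without coordinates is unlocatable; scored as non-overlap")
    return(FALSE)
  }
  any(regions$chrom == chrom & regions$start <= e & regions$end >= s)
}

# Vectorized region membership for an annotation table: TRUE per row iff the
# gene interval intersects any region on its chromosome.
.proteins_in_regions <- function(annotation, regions) {
  hit <- logical(nrow(annotation))
  for (chr in unique(regions$chrom)) {
    reg <- regions[regions$chrom == chr, , drop = FALSE]
    idx <- which(annotation$chrom == chr & !is.na(annotation$start) &
                   !is.na(annotation$end))
    if (length(idx) == 0L) next
    for (j in seq_len(nrow(reg))) {
      hit[idx] <- hit[idx] | (annotation$start[idx] <= reg$end[j] &
                                annotation$end[idx] >= reg$start[j])
    }
  }
  hit
}

#' Load and cross-validate the full input bundle
#'
#' Reads the six input files of the method (edge list, domain-protein map,
#' annotation, linked regions, class catalogs, optional benchmark labels) and
#' cross-references the identifiers. Unknown identifiers (e.g. mapped
#' proteins absent from the annotation table) are logged in the validation
#' report, not fatal; malformed files are errors naming the file and line.
#'
#' @param paths named list of file paths: `edges`, `domain_map`, `annotation`,
#'   `regions`, `class_a`, `class_b`, `pfam2go`, `class_d`, and optionally
#'   `positives`, `negatives`.
#' @param config optional list; `dedupe_class_d = FALSE` skips the class-a
#'   overlap removal.
#' @return object of class `domprior_bundle`: `edges`, `domain_map`,
#'   `annotation`, `regions`, `catalog`, `labels` (or `NULL`) and a
#'   `validation` report (character vector of notes).
#' @export
load_inputs <- function(paths, config = list()) {
  required <- c("edges", "domain_map", "annotation", "regions",
                "class_a", "class_b", "pfam2go", "class_d")
  missing <- setdiff(required, names(paths))
  if (length(missing) > 0L) {
    stop("missing input paths: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  edges <- read_edge_table(paths$edges)
  domain_map <- read_domain_map(paths$domain_map)
  annotation <- read_annotation(paths$annotation)
  regions <- read_regions(paths$regions)
  pfam2go <- read_pfam2go(paths$pfam2go)
  dedupe <- !identical(config$dedupe_class_d, FALSE)
  catalog <- class_catalog(
    class_a_domains = read_id_list(paths$class_a),
    class_b_processes = read_id_list(paths$class_b, normalize = FALSE),
    pfam2go = pfam2go,
    class_c_regions = regions,
    class_d_proteins = read_id_list(paths$class_d),
    domain_map = if (dedupe) domain_map else NULL
  )
  labels <- NULL
  if (!is.null(paths$positives) && !is.null(paths$negatives)) {
    labels <- benchmark_labels(read_id_list(paths$positives),
                               read_id_list(paths$negatives))
  }
  notes <- character()
  if (attr(edges, "n_self_loops") > 0L) {
    notes <- c(notes, sprintf("dropped %d self-interaction(s) at ingest",
                              attr(edges, "n_self_loops")))
  }
  if (attr(edges, "n_duplicates") > 0L) {
    notes <- c(notes, sprintf("merged %d duplicate edge record(s) keeping max confidence",
                              attr(edges, "n_duplicates")))
  }
  unknown <- setdiff(unique(domain_map$protein), annotation$protein)
  if (length(unknown) > 0L) {
    notes <- c(notes, sprintf("%d mapped protein(s) absent from annotation (unannotated): %s%s",
                              length(unknown),
                              paste(head(unknown, 5L), collapse = ", "),
                              if (length(unknown) > 5L) ", ..." else ""))
  }
  structure(list(edges = edges, domain_map = domain_map,
                 annotation = annotation, regions = regions,
                 catalog = catalog, labels = labels, validation = notes),
            class = "domprior_bundle")
}

#' @export
print.domprior_bundle <- function(x, ...) {
  cat("domprior input bundle\n")
  cat(sprintf("  edges:      %d (filtered at network build time)\n", nrow(x$edges)))
  cat(sprintf("  domain map: %d pairs, %d domains, %d proteins\n",
              nrow(x$domain_map), length(unique(x$domain_map$domain)),
              length(unique(x$domain_map$protein))))
  cat(sprintf("  annotation: %d proteins\n", nrow(x$annotation)))
  cat(sprintf("  regions:    %d\n", nrow(x$regions)))
  print(x$catalog)
  if (length(x$validation) > 0L) {
    cat("  validation notes:\n")
    for (v in x$validation) cat("   -", v, "\n")
  }
  invisible(x)
}
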