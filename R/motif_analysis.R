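# Network motifs: census of connected 3- and 4-node induced subgraphs,
# degree-preserving randomization (double-edge swaps), over-representation
# p-values against the randomized ensemble, and Pfam2GO-based function
# prediction for motif members lacking annotation.

# Human-readable names for the connected undirected isomorphism classes, in
# igraph isomorphism-class numbering.
.motif_class_table <- function(size) {
  if (size == 3L) {
    data.frame(isoclass = c(2L, 3L),
               motif_id = c("path3", "triangle"),
               edges = c(2L, 3L), stringsAsFactors = FALSE)
  } else if (size == 4L) {
    data.frame(isoclass = c(4L, 6L, 7L, 8L, 9L, 10L),
               motif_id = c("star4", "path4", "paw4", "cycle4",
                            "diamond4", "clique4"),
               edges = c(3L, 3L, 4L, 4L, 5L, 6L), stringsAsFactors = FALSE)
  } else {
    stop("motif size must be 3 or 4", call. = FALSE)
  }
}

#' Census of connected induced subgraphs (motif candidates)
#'
#' Counts every connected induced subgraph of the given size exactly once,
#' grouped by isomorphism class, using the ESU enumeration behind
#' [igraph::motifs()]. Classes are named by shape: `path3`/`triangle` for
#' size 3; `star4`, `path4`, `paw4` (triangle with a pendant edge),
#' `cycle4`, `diamond4`, `clique4` for size 4.
#'
#' @param network a non-empty `domain_network`.
#' @param size subgraph size, 3 or 4.
#' @return `data.frame` with columns `motif_id`, `size`, `edges`, `count`.
#' @export
enumerate_subgraphs <- function(network, size = 3L) {
  size <- as.integer(size)
  classes <- .motif_class_table(size)
  g <- as_igraph(network)
  if (igraph::vcount(g) == 0L) stop("empty network", call. = FALSE)
  counts <- if (igraph::vcount(g) < size) {
    rep(0, nrow(classes))
  } else {
    m <- igraph::motifs(g, size = size)
    m[classes$isoclass + 1L]  # igraph classes are 0-based
  }
  counts[is.na(counts)] <- 0
  data.frame(motif_id = classes$motif_id, size = size,
             edges = classes$edges, count = as.numeric(counts),
             stringsAsFactors = FALSE)
}

# ESU enumeration of connected induced subgraph instances (node sets).
# adj: list of integer neighbor vectors. Returns list of integer vectors.
.esu_instances <- function(adj, size) {
  out <- list(); n_out <- 0L
  n <- length(adj)
  recurse <- function(sub, ext, root) {
    if (length(sub) == size) {
      n_out <<- n_out + 1L
      out[[n_out]] <<- sub
      return(invisible(NULL))
    }
    while (length(ext) > 0L) {
      w <- ext[1L]; ext <- ext[-1L]
      # exclusive neighborhood of w: neighbors beyond the root not already
      # in the subgraph or adjacent to it
      nb_sub <- unique(unlist(adj[sub], use.names = FALSE))
      cand <- adj[[w]]
      cand <- cand[cand > root & !(cand %in% sub) & !(cand %in% nb_sub)]
      recurse(c(sub, w), unique(c(ext, cand)), root)
    }
  }
  for (v in seq_len(n)) {
    ext0 <- adj[[v]][adj[[v]] > v]
    recurse(v, ext0, v)
  }
  out
}

#' Instances of connected induced subgraphs
#'
#' Enumerates the node sets of all connected induced subgraphs of the given
#' size (ESU enumeration, each instance exactly once) and labels each with
#' its isomorphism class. Intended for function prediction on instances of
#' significant motif classes; cost grows quickly with network density.
#'
#' @param network a `domain_network`.
#' @param size subgraph size, 3 or 4.
#' @param classes optional character vector of `motif_id`s to keep.
#' @return list with `instances` (list of character node vectors) and
#'   `motif_id` (character vector, parallel to `instances`).
#' @export
motif_instances <- function(network, size = 3L, classes = NULL) {
  size <- as.integer(size)
  class_tab <- .motif_class_table(size)
  g <- as_igraph(network)
  names_v <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  inst <- .esu_instances(adj, size)
  if (length(inst) == 0L) {
    return(list(instances = list(), motif_id = character()))
  }
  iso <- vapply(inst, function(ix) {
    igraph::isomorphism_class(igraph::induced_subgraph(g, ix))
  }, 0)
  ids <- class_tab$motif_id[match(iso, class_tab$isoclass)]
  keep <- if (is.null(classes)) seq_along(inst) else which(ids %in% classes)
  list(instances = lapply(inst[keep], function(ix) names_v[ix]),
       motif_id = ids[keep])
}

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. seed = NULL uses (and advances) the global stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Degree-preserving network randomization
#'
#' Produces a simple undirected graph with exactly the input's degree
#' sequence by repeated double-edge swaps (default 10 attempted swaps per
#' edge); swaps that would create a self-loop or multi-edge are rejected.
#' A fixed seed gives identical output across runs. Networks too small to
#' swap (< 2 edges) are returned unchanged with a warning.
#'
#' @param network a `domain_network`.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @param swaps_per_edge attempted swaps per edge.
#' @return a randomized `domain_network` with the same nodes and degrees.
#' @export
randomize_network <- function(network, seed = NULL, swaps_per_edge = 10) {
  g <- as_igraph(network)
  if (igraph::ecount(g) < 2L) {
    warning("network has fewer than 2 edges; returning an unchanged copy")
    return(network)
  }
  niter <- max(1L, as.integer(swaps_per_edge * igraph::ecount(g)))
  rg <- .with_seed(seed,
                   igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                            niter = niter)))
  structure(list(graph = rg, min_confidence = network$min_confidence),
            class = "domain_network")
}

#' Motif over-representation against randomized networks
#'
#' Compares the real census ([enumerate_subgraphs()]) with counts from
#' `iterations` degree-preserving randomizations. For each motif class the
#' one-sided over-representation p-value is
#' `(1 + #\{null count >= real count\}) / (iterations + 1)`; the z-score is
#' `(real - null mean) / null sd` (`NA` when the null sd is 0). A class is
#' significant iff `p <= alpha` (default 0.01).
#'
#' @param network a non-empty `domain_network`.
#' @param size motif size, 3 or 4.
#' @param iterations number of randomized networks (default 1000).
#' @param alpha significance level for the `significant` flag.
#' @param seed optional integer seed for the randomization ensemble.
#' @param swaps_per_edge attempted double-edge swaps per edge per
#'   randomization.
#' @return `data.frame`: `motif_id`, `size`, `real_count`, `null_mean`,
#'   `null_sd`, `z_score`, `p_value`, `significant`; the full null count
#'   matrix is attached as attribute `null_counts`.
#' @export
motif_significance <- function(network, size = 3L, iterations = 1000,
                               alpha = 0.01, seed = NULL,
                               swaps_per_edge = 10) {
  iterations <- as.integer(iterations)
  if (iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  real <- enumerate_subgraphs(network, size)
  null_counts <- .with_seed(seed, {
    vapply(seq_len(iterations), function(i) {
      rnet <- randomize_network(network, seed = NULL,
                                swaps_per_edge = swaps_per_edge)
      enumerate_subgraphs(rnet, size)$count
    }, numeric(nrow(real)))
  })
  null_counts <- matrix(null_counts, nrow = nrow(real))
  null_mean <- rowMeans(null_counts)
  null_sd <- apply(null_counts, 1L, sd)
  exceed <- rowSums(null_counts >= real$count)
  p <- (1 + exceed) / (iterations + 1)
  z <- ifelse(null_sd > 0, (real$count - null_mean) / null_sd, NA_real_)
  out <- data.frame(motif_id = real$motif_id, size = real$size,
                    real_count = real$count,
                    null_mean = null_mean, null_sd = null_sd,
                    z_score = z, p_value = p,
                    significant = p <= alpha,
                    stringsAsFactors = FALSE)
  attr(out, "null_counts") <- null_counts
  attr(out, "iterations") <- iterations
  out
}

#' Function prediction for a motif instance
#'
#' Resolves each member domain's biological-process labels from a Pfam2GO
#' mapping (optionally restricted to processes of interest) and predicts a
#' function for the instance's unlabeled members: the most frequent process
#' among the labeled members, with all tied labels reported. If no member is
#' labeled the prediction is `"unknown"`.
#'
#' @param instance character vector of member domains.
#' @param pfam2go `data.frame` with `domain`, `go_id` (and optionally a
#'   `process` name column used for display).
#' @param processes_of_interest optional character vector of GO IDs to which
#'   labels are restricted.
#' @return object of class `motif_annotation`: `instance`, `processes`
#'   (named list, `"unknown"` entries for unlabeled members),
#'   `predicted_function` (character vector, possibly several tied labels).
#' @export
annotate_motif <- function(instance, pfam2go, processes_of_interest = NULL) {
  instance <- normalize_id(instance)
  p2g <- pfam2go
  if (!is.null(processes_of_interest)) {
    p2g <- p2g[p2g$go_id %in% processes_of_interest, , drop = FALSE]
  }
  procs <- lapply(instance, function(d) {
    unique(p2g$go_id[p2g$domain == d])
  })
  names(procs) <- instance
  labeled <- lengths(procs) > 0L
  procs[!labeled] <- list("unknown")
  predicted <- "unknown"
  pool <- unlist(procs[labeled], use.names = FALSE)
  if (length(pool) > 0L) {
    tab <- table(pool)
    predicted <- sort(names(tab)[tab == max(tab)])
  }
  structure(list(instance = instance, processes = procs,
                 predicted_function = predicted),
            class = "motif_annotation")
}

#' @export
print.motif_annotation <- function(x, ...) {
  cat("motif instance:", paste(x$instance, collapse = ", "), "\n")
  for (d in names(x$processes)) {
    cat(sprintf("  %s: %s\n", d, paste(x$processes[[d]], collapse = "; ")))
  }
  cat("predicted function:", paste(x$predicted_function, collapse = "; "), "\n")
  invisible(x)
}
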