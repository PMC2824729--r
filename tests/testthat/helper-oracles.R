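# Independent brute-force oracles, written on plain adjacency matrices so
# they share no graph machinery with the implementation under test.

# Symmetric logical adjacency matrix from an edge data.frame.
adj_from_edges <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$domain_a, edges$domain_b)))
  n <- length(nodes)
  A <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(nrow(edges))) {
    a <- edges$domain_a[i]; b <- edges$domain_b[i]
    if (a != b) A[a, b] <- A[b, a] <- TRUE
  }
  A
}

# Random simple edge list on `n` labeled nodes (no igraph involved).
random_edges <- function(n, p, conf = 50, prefix = "D") {
  nodes <- sprintf("%s%03d", prefix, seq_len(n))
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  data.frame(domain_a = nodes[pairs[keep, 1]],
             domain_b = nodes[pairs[keep, 2]],
             confidence = conf, stringsAsFactors = FALSE)
}

# Local clustering coefficient by explicit neighbor-pair counting.
oracle_local_ci <- function(A, v) {
  nb <- which(A[v, ])
  k <- length(nb)
  if (k < 2) return(0)
  linked <- 0L
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      if (A[nb[i], nb[j]]) linked <- linked + 1L
    }
  }
  2 * linked / (k * (k - 1))
}

# All-pairs shortest paths by Floyd-Warshall; returns the mean distance over
# connected ordered pairs of the largest connected component.
oracle_path_length <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  comp_sizes <- integer(n)
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (is.na(comp[v])) {
      cid <- cid + 1L
      members <- which(is.finite(D[v, ]))
      comp[members] <- cid
      comp_sizes[cid] <- length(members)
    }
  }
  giant <- which(comp == which.max(comp_sizes))
  if (length(giant) < 2) return(NA_real_)
  sub <- D[giant, giant]
  mean(sub[upper.tri(sub)])
}

# Census of connected induced subgraphs by exhaustive subset enumeration;
# classes keyed by (edge count, sorted degree sequence), which identifies
# undirected isomorphism classes up to 4 nodes.
oracle_census <- function(A, size) {
  key_to_name <- c("2|112" = "path3", "3|222" = "triangle",
                   "3|1113" = "star4", "3|1122" = "path4",
                   "4|1223" = "paw4", "4|2222" = "cycle4",
                   "5|2233" = "diamond4", "6|3333" = "clique4")
  counts <- setNames(rep(0, length(key_to_name)), names(key_to_name))
  n <- nrow(A)
  if (n < size) return(counts)
  subsets <- combn(n, size)
  for (s in seq_len(ncol(subsets))) {
    idx <- subsets[, s]
    S <- A[idx, idx, drop = FALSE]
    # connectivity by breadth-first reachability
    seen <- c(1L); frontier <- c(1L)
    while (length(frontier) > 0) {
      nxt <- setdiff(which(apply(S[frontier, , drop = FALSE], 2, any)), seen)
      seen <- c(seen, nxt); frontier <- nxt
    }
    if (length(seen) < size) next
    key <- paste0(sum(S) / 2, "|", paste(sort(rowSums(S)), collapse = ""))
    counts[key] <- counts[key] + 1
  }
  counts <- setNames(counts, key_to_name)
  if (size == 3) counts[c("path3", "triangle")] else
    counts[c("star4", "path4", "paw4", "cycle4", "diamond4", "clique4")]
}

# AUC as the probability that a random positive outscores a random negative
# (ties count one half), by explicit pair enumeration.
oracle_auc <- function(scores, is_positive) {
  pos <- scores[is_positive]
  neg <- scores[!is_positive]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Interval overlap decision by direct closed-interval arithmetic.
oracle_overlap <- function(chrom, start, end, regions) {
  for (i in seq_len(nrow(regions))) {
    if (regions$chrom[i] == chrom && start <= regions$end[i] &&
        end >= regions$start[i]) {
      return(TRUE)
    }
  }
  FALSE
}

# Edge data.frame from an igraph object used purely as a graph source
# (e.g. the graph atlas); safe for edgeless graphs.
edges_from_igraph <- function(g, nodes) {
  el <- igraph::as_edgelist(g)
  data.frame(domain_a = nodes[el[, 1]], domain_b = nodes[el[, 2]],
             confidence = rep(50, nrow(el)), stringsAsFactors = FALSE)
}

# Small convenience: a domain_network from explicit high-confidence pairs.
net_from_pairs <- function(...) {
  pairs <- list(...)
  edges <- data.frame(domain_a = vapply(pairs, `[`, "", 1),
                      domain_b = vapply(pairs, `[`, "", 2),
                      confidence = 50, stringsAsFactors = FALSE)
  build_network(edges, min_confidence = 0)
}
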