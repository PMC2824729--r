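# Weight value (Wv) scoring: each partner domain D_j of a parent domain D_i
# is tested against four binary disease-evidence classes; indicators are
# normalized by the class totals and summed over partners, then Wv is min-max
# normalized over the run and assigned to proteins (max over their domains).

#' Score one partner domain against the four evidence classes
#'
#' Presence/absence is scored by a binary system: `D_ja = 1` iff the partner
#' is a class-a domain (domains found in proteins with disease-associated
#' non-synonymous variants); `D_jb = 1` iff the partner maps, via Pfam2GO, to
#' any class-b (disease-relevant) GO biological process; `P_jc = 1` iff at
#' least one protein harboring the partner lies in a linked chromosomal
#' region (class c); `P_jd = 1` iff at least one harboring protein is a known
#' disease protein (class d). Components are `indicator / class total`:
#' `a_j = D_ja/T_a`, ..., `d_j = P_jd/T_d`. Classes c and d evaluate all
#' harboring proteins with a logical OR.
#'
#' @param partner a partner domain accession.
#' @param catalog a [class_catalog()].
#' @param domain_map domain-protein map `data.frame` (`domain`, `protein`).
#' @param annotation annotation `data.frame` (used for class-c coordinates).
#' @return one-row `data.frame`: `partner`, indicators `d_ja`, `d_jb`,
#'   `p_jc`, `p_jd`, components `a_j`, `b_j`, `c_j`, `d_j`.
#' @export
score_partner <- function(partner, catalog, domain_map, annotation) {
  score_partners(partner, catalog, domain_map, annotation)
}

#' Score many partner domains at once
#'
#' Vectorized form of [score_partner()]; one row per input domain.
#'
#' @inheritParams score_partner
#' @param partners character vector of domain accessions.
#' @return `data.frame` with one row per partner.
#' @export
score_partners <- function(partners, catalog, domain_map, annotation) {
  stopifnot(inherits(catalog, "class_catalog"))
  partners <- normalize_id(partners)
  b_domains <- unique(catalog$pfam2go$domain[
    catalog$pfam2go$go_id %in% catalog$class_b_processes])
  in_region <- annotation$protein[
    .proteins_in_regions(annotation, catalog$class_c_regions)]
  d_ja <- as.integer(partners %in% catalog$class_a_domains)
  d_jb <- as.integer(partners %in% b_domains)
  prots_by_domain <- split(domain_map$protein, domain_map$domain)
  p_jc <- integer(length(partners))
  p_jd <- integer(length(partners))
  for (i in seq_along(partners)) {
    prots <- prots_by_domain[[partners[i]]]
    if (is.null(prots)) next  # unmapped partner: P_jc = P_jd = 0
    p_jc[i] <- as.integer(any(prots %in% in_region))
    p_jd[i] <- as.integer(any(prots %in% catalog$class_d_proteins))
  }
  data.frame(partner = partners,
             d_ja = d_ja, d_jb = d_jb, p_jc = p_jc, p_jd = p_jd,
             a_j = d_ja / catalog$t_a, b_j = d_jb / catalog$t_b,
             c_j = p_jc / catalog$t_c, d_j = p_jd / catalog$t_d,
             stringsAsFactors = FALSE)
}

#' Weight value of one parent domain
#'
#' Aggregates the four-class components of the parent's N distinct
#' interaction partners: `Wv_raw(D_i) = sum_j (a_j + b_j + c_j + d_j)` (the
#' default), or that sum divided by N under `aggregation = "mean"`. A parent
#' with no partners scores 0.
#'
#' @param parent a parent domain accession (a node of `network`, or isolated).
#' @param network a `domain_network`.
#' @inheritParams score_partner
#' @param aggregation `"sum"` (default) or `"mean"` over partners.
#' @return one-row `data.frame`: `domain`, `n_partners`, `raw`.
#' @export
weight_value <- function(parent, network, catalog, domain_map, annotation,
                         aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  compute_weight_values(network, catalog, domain_map, annotation,
                        parents = parent, aggregation = aggregation)
}

#' Weight values for a set of parent domains
#'
#' Computes raw Wv for every parent (default: every domain appearing in the
#' domain-protein map, isolated parents included with N = 0). Partner scores
#' are computed once per distinct domain and reused.
#'
#' @inheritParams weight_value
#' @param parents character vector of parent domains; default all mapped
#'   domains plus all network nodes.
#' @return `data.frame`: `domain`, `n_partners`, `raw`, one row per parent.
#' @export
compute_weight_values <- function(network, catalog, domain_map, annotation,
                                  parents = NULL,
                                  aggregation = c("sum", "mean")) {
  aggregation <- match.arg(aggregation)
  g <- as_igraph(network)
  if (is.null(parents)) {
    parents <- sort(unique(c(domain_map$domain, igraph::V(g)$name)))
  } else {
    parents <- normalize_id(parents)
  }
  all_partners <- unique(unlist(lapply(
    intersect(parents, igraph::V(g)$name),
    function(p) igraph::neighbors(g, p)$name), use.names = FALSE))
  ps <- score_partners(all_partners, catalog, domain_map, annotation)
  contrib <- setNames(ps$a_j + ps$b_j + ps$c_j + ps$d_j, ps$partner)
  n_partners <- integer(length(parents))
  raw <- numeric(length(parents))
  in_net <- parents %in% igraph::V(g)$name
  for (i in seq_along(parents)) {
    if (!in_net[i]) next
    nb <- igraph::neighbors(g, parents[i])$name
    n_partners[i] <- length(nb)
    if (length(nb) > 0L) {
      s <- sum(contrib[nb])
      raw[i] <- if (aggregation == "mean") s / length(nb) else s
    }
  }
  data.frame(domain = parents, n_partners = n_partners, raw = raw,
             stringsAsFactors = FALSE)
}

#' Normalize raw weight values to \[0, 1\]
#'
#' Default is min-max over the run's parent domains:
#' `Wv = (raw - min) / (max - min)`, so the best-scoring parent maps to
#' exactly 1 and the worst to exactly 0. The alternative `"maxratio"`
#' divides by the run maximum (`Wv = raw / max`), anchoring only the top.
#' If all raw values are equal, all normalized values are set to 0 with a
#' warning.
#'
#' @param wv_scores `data.frame` from [compute_weight_values()].
#' @param method `"minmax"` (default) or `"maxratio"`.
#' @return the input with a `normalized` column added.
#' @export
normalize_scores <- function(wv_scores, method = c("minmax", "maxratio")) {
  method <- match.arg(method)
  raw <- wv_scores$raw
  if (length(raw) == 0L) stop("no scores to normalize", call. = FALSE)
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warning("all raw weight values are equal; normalized scores set to 0")
    wv_scores$normalized <- rep(0, length(raw))
  } else if (method == "minmax") {
    wv_scores$normalized <- (raw - rng[1]) / (rng[2] - rng[1])
  } else {
    wv_scores$normalized <- raw / rng[2]
  }
  wv_scores
}

#' Assign weight values and clustering coefficients to proteins
#'
#' For a protein harboring more than one domain, the highest normalized Wv
#' among its domains is assigned to the protein; `best_domain` is the argmax
#' (ties broken by lower C_i, then lexicographic). The protein inherits the
#' best domain's local clustering coefficient, and `is_hwe` flags High Weight
#' Elements (`Wv > 0.5`, strict). Proteins with no mapped domain are excluded
#' and reported in the `excluded` attribute.
#'
#' @param annotation annotation `data.frame`.
#' @param domain_map domain-protein map `data.frame`.
#' @param wv_scores normalized scores from [normalize_scores()].
#' @param network the `domain_network` (source of C_i; domains absent from
#'   the network count as isolated, C_i = 0).
#' @param hwe_threshold Wv threshold for HWE status (strict, default 0.5).
#' @return `data.frame`: `protein`, `gene_symbol`, `best_domain`,
#'   `n_partners`, `raw_wv`, `wv`, `ci`, `is_hwe`; attribute `excluded`
#'   lists annotation proteins without domains.
#' @export
assign_protein_scores <- function(annotation, domain_map, wv_scores, network,
                                  hwe_threshold = 0.5) {
  if (is.null(wv_scores$normalized)) {
    stop("wv_scores lacks a 'normalized' column; run normalize_scores() first",
         call. = FALSE)
  }
  ci_all <- clustering_coefficient(network)
  dom_ci <- function(d) ifelse(d %in% names(ci_all), ci_all[d], 0)
  score_by_domain <- setNames(wv_scores$normalized, wv_scores$domain)
  raw_by_domain <- setNames(wv_scores$raw, wv_scores$domain)
  np_by_domain <- setNames(wv_scores$n_partners, wv_scores$domain)
  dm <- domain_map[domain_map$domain %in% names(score_by_domain), , drop = FALSE]
  doms_by_protein <- split(dm$domain, dm$protein)
  proteins <- annotation$protein
  has_domain <- proteins %in% names(doms_by_protein)
  excluded <- proteins[!has_domain]
  kept <- which(has_domain)
  n <- length(kept)
  best <- character(n); wv <- numeric(n); raw <- numeric(n)
  ci <- numeric(n); np <- integer(n)
  for (i in seq_len(n)) {
    doms <- doms_by_protein[[proteins[kept[i]]]]
    sc <- score_by_domain[doms]
    cand <- doms[sc == max(sc)]
    if (length(cand) > 1L) {  # ties: lowest C_i, then lexicographic
      cic <- vapply(cand, dom_ci, 0)
      cand <- sort(cand[cic == min(cic)])
    }
    b <- cand[1L]
    best[i] <- b
    wv[i] <- score_by_domain[[b]]
    raw[i] <- raw_by_domain[[b]]
    np[i] <- np_by_domain[[b]]
    ci[i] <- dom_ci(b)
  }
  out <- data.frame(protein = proteins[kept],
                    gene_symbol = annotation$gene_symbol[kept],
                    best_domain = best, n_partners = np,
                    raw_wv = raw, wv = wv, ci = ci,
                    is_hwe = wv > hwe_threshold,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' One-call scoring stage
#'
#' Convenience wrapper: builds the network from the bundle's edges, computes
#' and normalizes domain weight values, and assigns protein-level scores.
#'
#' @param bundle a `domprior_bundle` from [load_inputs()] or
#'   [generate_world()].
#' @param min_confidence edge confidence cutoff.
#' @param aggregation partner aggregation, `"sum"` or `"mean"`.
#' @param normalization `"minmax"` or `"maxratio"`.
#' @return list with `network`, `wv_scores` (domain level) and `candidates`
#'   (protein-level `data.frame`).
#' @export
score_bundle <- function(bundle, min_confidence = 10,
                         aggregation = "sum", normalization = "minmax") {
  network <- build_network(bundle$edges, min_confidence = min_confidence,
                           isolated_domains = unique(bundle$domain_map$domain))
  wv <- compute_weight_values(network, bundle$catalog, bundle$domain_map,
                              bundle$annotation, aggregation = aggregation)
  wv <- normalize_scores(wv, method = normalization)
  candidates <- assign_protein_scores(bundle$annotation, bundle$domain_map,
                                      wv, network)
  list(network = network, wv_scores = wv, candidates = candidates)
}
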