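# Weight value scoring: binary class components, partner aggregation,
# min-max normalization and protein-level assignment.

# A small hand-built scoring context. Domains PFA001 (class a), PFB001
# (maps to a class-b process), PFC001 (harbored by an in-region protein),
# PFD001 (harbored by a disease protein), PFX001..PFX003 (class-free).
make_test_context <- function(t_a = 60, t_b = 15, t_d = 1746) {
  regions <- data.frame(marker_id = sprintf("M%02d", 1:64),
                        chrom = "chr1",
                        start = seq(1, by = 2e6, length.out = 64),
                        stringsAsFactors = FALSE)
  regions$end <- regions$start + 1e6
  annotation <- data.frame(
    protein = c("PRC", "PRD", "PRX"),
    gene_symbol = c("GC", "GD", "GX"),
    chrom = c("chr1", "chr2", "chr2"),
    start = c(5e5, 100, 100), end = c(6e5, 200, 200),
    stringsAsFactors = FALSE)
  domain_map <- data.frame(
    domain = c("PFC001", "PFD001", "PFX001"),
    protein = c("PRC", "PRD", "PRX"),
    stringsAsFactors = FALSE)
  catalog <- class_catalog(
    class_a_domains = c("PFA001", sprintf("PAD%03d", seq_len(t_a - 1))),
    class_b_processes = sprintf("GO:%07d", seq_len(t_b)),
    pfam2go = data.frame(domain = "PFB001", go_id = "GO:0000001",
                         stringsAsFactors = FALSE),
    class_c_regions = regions,
    class_d_proteins = c("PRD", sprintf("DPAD%04d", seq_len(t_d - 1))))
  list(catalog = catalog, domain_map = domain_map, annotation = annotation)
}

test_that("each class component is the indicator over the class total", {
  ctx <- make_test_context()
  s <- score_partner("PFA001", ctx$catalog, ctx$domain_map, ctx$annotation)
  expect_equal(s$a_j, 1 / 60)
  expect_equal(s$b_j + s$c_j + s$d_j, 0)
  s <- score_partner("PFB001", ctx$catalog, ctx$domain_map, ctx$annotation)
  expect_equal(s$b_j, 1 / 15)
  s <- score_partner("PFC001", ctx$catalog, ctx$domain_map, ctx$annotation)
  expect_equal(s$c_j, 1 / 64)
  s <- score_partner("PFD001", ctx$catalog, ctx$domain_map, ctx$annotation)
  expect_equal(s$d_j, 1 / 1746)
  # absent from every class (and every mapping): the all-zero score
  s <- score_partner("PFNONE", ctx$catalog, ctx$domain_map, ctx$annotation)
  expect_equal(unlist(s[, c("a_j", "b_j", "c_j", "d_j")]),
               c(a_j = 0, b_j = 0, c_j = 0, d_j = 0))
})

test_that("partner components equal an independent set-membership oracle", {
  set.seed(41)
  regions <- data.frame(marker_id = "M1", chrom = "chr1",
                        start = 1e6, end = 2e6, stringsAsFactors = FALSE)
  doms <- sprintf("PF%05d", 1:50)
  prots <- sprintf("P%03d", 1:40)
  starts <- sample.int(3e6, 40)
  annotation <- data.frame(protein = prots, gene_symbol = prots,
                           chrom = "chr1", start = starts,
                           end = starts + 1e4, stringsAsFactors = FALSE)
  domain_map <- data.frame(domain = sample(doms, 120, replace = TRUE),
                           protein = sample(prots, 120, replace = TRUE),
                           stringsAsFactors = FALSE)
  class_a <- sample(doms, 8)
  class_b <- sprintf("GO:%07d", 1:6)
  p2g <- data.frame(domain = sample(doms, 20, replace = TRUE),
                    go_id = sample(sprintf("GO:%07d", 1:12), 20,
                                   replace = TRUE),
                    stringsAsFactors = FALSE)
  class_d <- sample(prots, 10)
  catalog <- class_catalog(class_a, class_b, p2g, regions, class_d)
  scores <- score_partners(doms, catalog, domain_map, annotation)
  in_region <- prots[starts <= 2e6 & starts + 1e4 >= 1e6]
  for (i in seq_along(doms)) {
    d <- doms[i]
    hosts <- domain_map$protein[domain_map$domain == d]
    expect_equal(scores$d_ja[i], as.integer(d %in% class_a))
    expect_equal(scores$d_jb[i],
                 as.integer(any(p2g$go_id[p2g$domain == d] %in% class_b)))
    expect_equal(scores$p_jc[i], as.integer(any(hosts %in% in_region)))
    expect_equal(scores$p_jd[i], as.integer(any(hosts %in% class_d)))
  }
})

test_that("weight value sums partner components (and can average them)", {
  ctx <- make_test_context()
  # parent wired to four single-class partners: the sum over partners is
  # the sum of the four class reciprocals
  net <- net_from_pairs(c("PFP001", "PFA001"), c("PFP001", "PFB001"),
                        c("PFP001", "PFC001"), c("PFP001", "PFD001"))
  wv <- weight_value("PFP001", net, ctx$catalog, ctx$domain_map,
                     ctx$annotation)
  expect_equal(wv$n_partners, 4L)
  expect_equal(wv$raw, 1 / 60 + 1 / 15 + 1 / 64 + 1 / 1746)
  wv_mean <- weight_value("PFP001", net, ctx$catalog, ctx$domain_map,
                          ctx$annotation, aggregation = "mean")
  expect_equal(wv_mean$raw, (1 / 60 + 1 / 15 + 1 / 64 + 1 / 1746) / 4)
  # no partners -> empty sum; class-free partners -> zero contributions
  iso <- build_network(data.frame(domain_a = "PFX002", domain_b = "PFX003",
                                  confidence = 50),
                       isolated_domains = "PFP009")
  expect_equal(weight_value("PFP009", iso, ctx$catalog, ctx$domain_map,
                            ctx$annotation)$raw, 0)
  expect_equal(weight_value("PFX002", iso, ctx$catalog, ctx$domain_map,
                            ctx$annotation)$raw, 0)
})

test_that("adding a scoring partner never decreases the raw weight value", {
  ctx <- make_test_context()
  base <- net_from_pairs(c("PFP001", "PFX001"), c("PFP001", "PFX002"))
  more <- net_from_pairs(c("PFP001", "PFX001"), c("PFP001", "PFX002"),
                         c("PFP001", "PFA001"))
  raw0 <- weight_value("PFP001", base, ctx$catalog, ctx$domain_map,
                       ctx$annotation)$raw
  raw1 <- weight_value("PFP001", more, ctx$catalog, ctx$domain_map,
                       ctx$annotation)$raw
  expect_gte(raw1, raw0)
  expect_equal(raw1 - raw0, 1 / 60)
})

test_that("min-max normalization anchors the extremes and preserves order", {
  wv <- data.frame(domain = c("A", "B", "C"), n_partners = 1L,
                   raw = c(0, 5, 10), stringsAsFactors = FALSE)
  norm <- normalize_scores(wv)
  expect_equal(norm$normalized, c(0, 0.5, 1))
  set.seed(43)
  raw <- runif(100, 0, 3)
  wv <- data.frame(domain = sprintf("D%03d", 1:100), n_partners = 1L,
                   raw = raw, stringsAsFactors = FALSE)
  norm <- normalize_scores(wv)
  expect_equal(norm$normalized[which.max(raw)], 1)
  expect_equal(norm$normalized[which.min(raw)], 0)
  expect_equal(order(norm$normalized), order(raw))
  expect_equal(cor(rank(norm$normalized), rank(raw)), 1)
  # affine transformation of raw scores leaves normalized scores unchanged
  wv2 <- wv; wv2$raw <- 7 * wv$raw + 3
  expect_equal(normalize_scores(wv2)$normalized, norm$normalized)
  # degenerate all-equal input
  wv3 <- wv; wv3$raw <- 1
  expect_warning(norm3 <- normalize_scores(wv3), "all raw weight values")
  expect_equal(norm3$normalized, rep(0, 100))
})

test_that("proteins take the maximum Wv over their domains, strict HWE rule", {
  net <- net_from_pairs(c("D1", "D2"), c("D3", "D4"))
  wv <- data.frame(domain = c("D1", "D3", "D5"), n_partners = c(1L, 1L, 0L),
                   raw = c(0.3, 0.7, 0.51), stringsAsFactors = FALSE)
  wv$normalized <- wv$raw
  annotation <- data.frame(protein = c("P1", "P2", "P3", "P4"),
                           gene_symbol = c("G1", "G2", "G3", "G4"),
                           chrom = "chr1", start = 1, end = 2,
                           stringsAsFactors = FALSE)
  domain_map <- data.frame(domain = c("D1", "D3", "D5", "D1"),
                           protein = c("P1", "P1", "P2", "P4"),
                           stringsAsFactors = FALSE)
  cand <- assign_protein_scores(annotation, domain_map, wv, net)
  p1 <- cand[cand$protein == "P1", ]
  expect_equal(p1$wv, 0.7)
  expect_equal(p1$best_domain, "D3")
  expect_true(p1$is_hwe)
  expect_true(cand$is_hwe[cand$protein == "P2"])   # 0.51 > 0.5
  expect_false(cand$is_hwe[cand$protein == "P4"])  # 0.3
  # proteins without domains are excluded and reported
  expect_false("P3" %in% cand$protein)
  expect_equal(attr(cand, "excluded"), "P3")
  # exactly 0.5 is not an HWE (strict inequality)
  wv$normalized <- c(0.5, 0.5, 0.5)
  cand <- assign_protein_scores(annotation, domain_map, wv, net)
  expect_false(any(cand$is_hwe))
})

test_that("planted parents outscore class-free background parents", {
  # purpose-built world: planted parents wired to partners hitting all
  # classes, background parents to class-free partners
  ctx <- make_test_context()
  set.seed(47)
  for (rep in 1:20) {
    planted <- sprintf("PLT%02d", 1:3)
    background <- sprintf("BGD%02d", 1:10)
    pairs <- list()
    for (p in planted) {
      for (partner in c("PFA001", "PFB001", "PFC001", "PFD001")) {
        pairs[[length(pairs) + 1L]] <- c(p, partner)
      }
    }
    free_partners <- sprintf("PFX%03d", 1:20)
    for (b in background) {
      for (partner in sample(free_partners, 3)) {
        pairs[[length(pairs) + 1L]] <- c(b, partner)
      }
    }
    net <- do.call(net_from_pairs, pairs)
    wv <- compute_weight_values(net, ctx$catalog, ctx$domain_map,
                                ctx$annotation,
                                parents = c(planted, background))
    wv <- normalize_scores(wv)
    expect_gt(min(wv$normalized[wv$domain %in% planted]),
              max(wv$normalized[wv$domain %in% background]))
  }
})
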