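# Input model: parsing dialects, identifier handling, interval overlap.

write_lines <- function(lines, file) {
  writeLines(lines, file)
  file
}

test_that("a minimal toy world parses into a one-edge bundle", {
  dir <- withr::local_tempdir()
  paths <- list(
    edges = write_lines(c("#domain_a\tdomain_b\tconfidence",
                          "PF00001\tPF00002\t25"),
                        file.path(dir, "edges.tsv")),
    domain_map = write_lines("PF00001\tP1", file.path(dir, "dm.tsv")),
    annotation = write_lines("P1\tGENE1\tchr1\t100\t200",
                             file.path(dir, "ann.tsv")),
    regions = write_lines("chr1\t0\t10000000\tM1", file.path(dir, "reg.bed")),
    class_a = write_lines("PF00002", file.path(dir, "a.txt")),
    class_b = write_lines("GO:0000001", file.path(dir, "b.txt")),
    pfam2go = write_lines("Pfam:PF00002 dom > GO:x ; GO:0000001",
                          file.path(dir, "p2g.txt")),
    class_d = write_lines("P9", file.path(dir, "d.txt")))
  bundle <- load_inputs(paths)
  expect_s3_class(bundle, "domprior_bundle")
  expect_equal(nrow(bundle$edges), 1L)
  expect_equal(bundle$edges$confidence, 25)
  expect_equal(bundle$catalog$t_a, 1L)
  # regions converted from BED to 1-based closed coordinates
  expect_equal(bundle$regions$start, 1)
  expect_equal(bundle$regions$end, 1e7)
})

test_that("edge ingest skips headers, drops self-loops and merges duplicates", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("domain_a\tdomain_b\tconfidence",  # bare (non-#) header
               "PF00001\tPF00002\t10",
               "PF00002\tPF00001\t30",            # reversed duplicate
               "PF00003\tPF00003\t99",            # self-interaction
               "pf00004\tPF00001\t5"), f)
  edges <- read_edge_table(f)
  expect_equal(nrow(edges), 2L)
  expect_equal(attr(edges, "n_self_loops"), 1L)
  expect_equal(attr(edges, "n_duplicates"), 1L)
  merged <- edges[edges$domain_a == "PF00001" & edges$domain_b == "PF00002", ]
  expect_equal(merged$confidence, 30)  # maximum kept
  expect_true("PF00004" %in% c(edges$domain_a, edges$domain_b))  # case-normalized
})

test_that("malformed and empty inputs fail with file and line information", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("PF00001\tPF00002\t12", "PF00003\tPF00004"), f)
  expect_error(read_edge_table(f), "line 2")
  # a leading non-numeric row is header-sniffed, so the malformed row must
  # not be first
  writeLines(c("PF00001\tPF00002\t12", "PF00001\tPF00003\tabc"), f)
  expect_error(read_edge_table(f), "not numeric")
  writeLines(character(), f)
  expect_error(read_edge_table(f), "empty mandatory file")
  g <- withr::local_tempfile(fileext = ".tsv")
  writeLines("P1\tG1\tchr1\t500\t100", g)
  expect_error(read_annotation(g), "start > end")
})

test_that("identifier normalization is idempotent", {
  set.seed(7)
  raw <- replicate(50, paste0(
    paste(sample(c(letters, LETTERS, 0:9, " "), 8, replace = TRUE),
          collapse = "")))
  once <- normalize_id(raw)
  expect_identical(normalize_id(once), once)
})

test_that("pfam2go dialect parses one mapping per line", {
  f <- withr::local_tempfile()
  writeLines(c("!version: test",
               "Pfam:PF05277 DUF718 > GO:electron transport ; GO:0006118",
               "Pfam:PF05277 DUF718 > GO:other ; GO:0009999"), f)
  p2g <- read_pfam2go(f)
  expect_equal(nrow(p2g), 2L)
  expect_equal(unique(p2g$domain), "PF05277")
  expect_setequal(p2g$go_id, c("GO:0006118", "GO:0009999"))
})

test_that("class-d catalog records raw and deduplicated totals", {
  dm <- data.frame(domain = c("PF00001", "PF00002"),
                   protein = c("P1", "P2"), stringsAsFactors = FALSE)
  cat <- class_catalog(
    class_a_domains = "PF00001",
    class_b_processes = "GO:0000001",
    pfam2go = data.frame(domain = character(), go_id = character()),
    class_c_regions = data.frame(marker_id = "M1", chrom = "chr1",
                                 start = 1, end = 10),
    class_d_proteins = c("P1", "P2", "P3", "P3"),  # P1 harbors a class-a domain
    domain_map = dm)
  expect_equal(cat$t_d_raw, 3L)
  expect_equal(cat$t_d, 2L)
  expect_setequal(cat$class_d_proteins, c("P2", "P3"))
})

test_that("region overlap follows closed-interval arithmetic per chromosome", {
  regions <- data.frame(marker_id = "M1", chrom = "chr3",
                        start = 150, end = 10000150,
                        stringsAsFactors = FALSE)
  expect_true(region_overlap(list(chrom = "chr3", start = 100, end = 200),
                             regions))
  expect_false(region_overlap(list(chrom = "chr4", start = 100, end = 200),
                              data.frame(marker_id = "M2", chrom = "chr4",
                                         start = 1e7, end = 2e7)))
  # shared boundary base counts as overlap
  expect_true(region_overlap(list(chrom = "chr3", start = 1, end = 150),
                             regions))
  expect_warning(
    ans <- region_overlap(list(chrom = NA, start = NA, end = NA), regions),
    "unlocatable")
  expect_false(ans)
})

test_that("overlap decisions match a brute-force all-pairs interval check", {
  set.seed(11)
  chroms <- paste0("chr", 1:4)
  regions <- data.frame(marker_id = sprintf("M%02d", 1:64),
                        chrom = sample(chroms, 64, replace = TRUE),
                        start = sample.int(1e6, 64),
                        stringsAsFactors = FALSE)
  regions$end <- regions$start + sample.int(5e4, 64)
  starts <- sample.int(1.1e6, 1000)
  prots <- data.frame(chrom = sample(chroms, 1000, replace = TRUE),
                      start = starts, end = starts + sample.int(2e4, 1000),
                      stringsAsFactors = FALSE)
  got <- vapply(seq_len(1000), function(i) {
    region_overlap(prots[i, ], regions)
  }, TRUE)
  want <- vapply(seq_len(1000), function(i) {
    oracle_overlap(prots$chrom[i], prots$start[i], prots$end[i], regions)
  }, TRUE)
  expect_identical(got, want)
})

test_that("a generated world survives a write-then-read round trip", {
  dir <- withr::local_tempdir()
  world <- generate_world(world_config(n_domains = 60, n_proteins = 50,
                                       n_markers = 10, t_a = 12, t_b = 5,
                                       t_d_raw = 40, n_planted = 3,
                                       n_evidence_ab = 4, n_evidence_cd = 4,
                                       planted_ab_partners = 3,
                                       planted_cd_partners = 3,
                                       n_classd_background = 8,
                                       n_negatives = 20, seed = 5),
                          outdir = dir)
  reloaded <- load_inputs(world$paths)
  b <- world$bundle
  expect_equal(reloaded$edges$domain_a, b$edges$domain_a)
  expect_equal(reloaded$edges$domain_b, b$edges$domain_b)
  expect_equal(reloaded$edges$confidence, b$edges$confidence)
  expect_equal(reloaded$domain_map, b$domain_map)
  expect_equal(reloaded$annotation$protein, b$annotation$protein)
  expect_equal(reloaded$annotation$start, b$annotation$start)
  expect_equal(reloaded$annotation$end, b$annotation$end)
  expect_equal(reloaded$regions$start, b$regions$start)
  expect_equal(reloaded$regions$end, b$regions$end)
  expect_equal(reloaded$catalog$t_a, b$catalog$t_a)
  expect_equal(reloaded$catalog$t_d, b$catalog$t_d)
  expect_setequal(reloaded$catalog$class_d_proteins,
                  b$catalog$class_d_proteins)
  expect_setequal(reloaded$labels$positives, b$labels$positives)
  expect_setequal(reloaded$labels$negatives, b$labels$negatives)
})
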