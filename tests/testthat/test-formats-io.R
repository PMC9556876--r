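# Readers/writers, ID mapping, and the sequence-identity fallback.

write_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("edge list parsing collapses duplicates and drops self-loops", {
  path <- write_lines(c("a\tb\t0.9", "b\ta\t0.7", "c\tc\t0.5"))
  expect_message(read_edge_list(path), "1 self-loop")
  g <- suppressMessages(read_edge_list(path))
  expect_equal(igraph::ecount(g), 1)
  expect_true(igraph::are_adjacent(g, "a", "b"))
  expect_equal(igraph::E(g)$weight, 0.9)
  expect_false("c" %in% igraph::V(g)$name)
})

test_that("edge list parse errors are informative", {
  expect_error(read_edge_list(write_lines(character(0))), "empty")
  expect_error(read_edge_list(write_lines(c("a\tb\t0.4", "a\tc\tNA_ish"))),
               "line 2")
  # header line is tolerated and named weight columns resolved
  path <- write_lines(c("protein_a\tprotein_b\tscore\textra",
                        "a\tb\t900\t1", "a\tc\t10\t2"))
  g <- read_edge_list(path, weight_column = "score")
  expect_equal(sort(igraph::E(g)$weight), c(10, 900))
  expect_error(read_edge_list(path, weight_column = "nope"), "no column")
})

test_that("edge lists round-trip through write and read, scores as given", {
  set.seed(7)
  edges <- data.frame(a = sprintf("p%d", 1:10),
                      b = sprintf("p%d", 2:11),
                      weight = sample(0:999, 10))
  g <- ppi_graph(edges)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(g, path)
  g2 <- read_edge_list(path)
  el1 <- igraph::as_data_frame(g)
  el2 <- igraph::as_data_frame(g2)
  key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
  expect_setequal(key(el1), key(el2))
  expect_equal(el2$weight[match(key(el1), key(el2))], el1$weight)
})

test_that("annotation tables deduplicate, count aspects and round-trip", {
  tab <- annotation_table(data.frame(
    protein_id = c("p1", "p1", "p1", "p2", "p2", "p3"),
    go_id = c("GO:1", "GO:1", "GO:2", "GO:3", "GO:4", "GO:5"),
    aspect = c("BP", "BP", "BP", "BP", "MF", "CC")))
  expect_equal(nrow(tab), 5)  # duplicate (p1, GO:1, BP) collapsed
  expect_equal(aspect_counts(tab), c(BP = 3L, MF = 1L, CC = 1L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(tab, path)
  back <- read_annotations(path)
  expect_setequal(do.call(paste, as.data.frame(tab)),
                  do.call(paste, as.data.frame(back)))
})

test_that("unknown aspect codes are rejected with a line number", {
  path <- write_lines(c("p1\tGO:1\tBP", "p2\tGO:2\tXX"))
  expect_error(read_annotations(path), "XX.*line 2")
})

test_that("FASTA records are parsed, validated and round-tripped", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1 some description", "MK", "WV", ">p2", "ACDEFGHIKLMNPQRSTVWY"), fa)
  seqs <- read_fasta(fa)
  expect_equal(seqs[["p1"]], "MKWV")
  expect_equal(names(seqs), c("p1", "p2"))
  out <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, out)
  expect_equal(read_fasta(out), seqs)
  bad <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">p1", "MKXZV"), bad)
  expect_error(read_fasta(bad), "'X' at position 3")
})

test_that("ID maps allow one-to-many and return empty for absent ids", {
  m <- idmap(c("s1", "s1", "s2", "s1"), c("u1", "u2", "u3", "u1"))
  expect_equal(nrow(m), 3)  # duplicate pair collapsed
  expect_setequal(idmap_lookup(m, "s1"), c("u1", "u2"))
  expect_equal(idmap_lookup(m, "absent"), character(0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_mapping(m, path)
  m2 <- read_mapping(path)
  expect_setequal(paste(m$source_id, m$target_id),
                  paste(m2$source_id, m2$target_id))
})

test_that("domain tables store DDI pairs canonically", {
  dt <- domain_tables(
    data.frame(p = c("p1", "p2"), d = c("d1", "d2")),
    data.frame(a = c("d2", "d1"), b = c("d1", "d2")),  # both orders, one pair
    data.frame(d = "d1", go = "GO:1"))
  expect_equal(nrow(dt$ddi), 1)
  expect_equal(dt$ddi$domain_a, "d1")
  expect_equal(dt$ddi$domain_b, "d2")
  paths <- replicate(3, withr::local_tempfile(fileext = ".tsv"))
  write_domain_tables(dt, paths[1], paths[2], paths[3])
  dt2 <- read_domain_tables(paths[1], paths[2], paths[3])
  expect_equal(dt2$protein_domains, dt$protein_domains)
  expect_equal(dt2$ddi, dt$ddi)
  expect_equal(dt2$domain_go, dt$domain_go)
})

test_that("sequence identity matches a hand alignment and the NW oracle", {
  expect_equal(seq_identity("MKWVT", "MKWVT"), 1.0)
  # 9/10 matches, no gaps: boundary case for the 90% threshold
  expect_equal(seq_identity("MKWVTAAAAA", "MKWVTAAAAC"), 0.9)
  # against the naive DP oracle on random short peptides, both orders
  set.seed(11)
  for (i in 1:12) {
    a <- paste(sample(c("A", "C", "D", "G", "K"), sample(4:9, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "D", "G", "K"), sample(4:9, 1),
                      replace = TRUE), collapse = "")
    expect_equal(seq_identity(a, b), oracle_nw_identity(a, b), tolerance = 1e-12)
    expect_equal(seq_identity(a, b), seq_identity(b, a))
    expect_equal(seq_identity(a, a), 1.0)
  }
})

test_that("identity fallback maps through the table first, then >=90% hits", {
  m <- idmap("s1", "u1")
  refs <- c(r1 = "MKWVTAAAAA", r2 = "MKWVTAAAAC", r3 = "GGGGGGGGGG")
  # table hit short-circuits: no sequences needed
  expect_equal(map_with_identity_fallback("s1", m), "u1")
  # threshold is inclusive: the 0.9-identity reference is kept
  hits <- map_with_identity_fallback("s9", m, "MKWVTAAAAA", refs)
  expect_equal(hits, c("r1", "r2"))
  # order-independent w.r.t. the reference list
  expect_equal(map_with_identity_fallback("s9", m, "MKWVTAAAAA",
                                          refs[c(3, 2, 1)]), hits)
  # unmappable: no table hit and no query sequence
  expect_equal(map_with_identity_fallback("s9", m), character(0))
})
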