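# Degree-seeded clustering in property space and sequence-based prediction.

# two property profiles far apart in every component
profile_seqs <- function() {
  c(t0 = "WWWWWAAAAA",
    a1 = "WWWWWWWWWW", a2 = "WWWWWWWWWW", a3 = "WWWWWWWWWW",
    b1 = "DDDDDDDDDD", b2 = "DDDDDDDDDD", b3 = "DDDDDDDDDD")
}

two_clique_world <- function() {
  edges <- rbind(
    expand.grid(a = c("a1", "a2", "a3"), b = c("a1", "a2", "a3"),
                stringsAsFactors = FALSE),
    expand.grid(a = c("b1", "b2", "b3"), b = c("b1", "b2", "b3"),
                stringsAsFactors = FALSE))
  edges <- edges[edges$a < edges$b, ]
  edges$weight <- 0.9
  edges <- rbind(edges, data.frame(a = "t0", b = c("a1", "b1"), weight = 0.9))
  g <- ppi_graph(edges)
  as_neighborhood(g, "t0")
}

test_that("two planted property cliques give exactly two clusters", {
  ng <- two_clique_world()
  props <- property_matrix(profile_seqs()[-1])
  cl <- build_clusters(ng, props, dist_threshold = 1)
  expect_length(cl, 2)
  sets <- lapply(cl, `[[`, "members")
  expect_setequal(sets[[1]], c("a1", "a2", "a3"))
  expect_setequal(sets[[2]], c("b1", "b2", "b3"))
  # clusters partition the non-target nodes
  expect_setequal(unlist(sets), setdiff(igraph::V(ng$graph)$name, "t0"))
  rep <- validate_clusters(cl)
  expect_length(rep$warnings, 0)
  expect_equal(unname(rep$max_intra), c(0, 0))
})

test_that("identical properties collapse into seed-absorbing clusters", {
  ng <- two_clique_world()
  seqs <- profile_seqs()
  seqs[] <- "AAAA"
  props <- property_matrix(seqs[-1])
  cl <- build_clusters(ng, props, dist_threshold = 0.5)
  # highest-degree node absorbs all its direct neighbors (distance 0)
  sizes <- vapply(cl, function(x) length(x$members), integer(1))
  seeds <- vapply(cl, `[[`, "", "seed")
  deg <- igraph::degree(ng$graph)
  expect_equal(sizes[1],
               length(intersect(
                 igraph::neighbors(ng$graph, seeds[1])$name,
                 setdiff(igraph::V(ng$graph)$name, "t0"))) + 1L)
  # partition always holds
  expect_setequal(unlist(lapply(cl, `[[`, "members")),
                  setdiff(igraph::V(ng$graph)$name, "t0"))
  expect_false(any(duplicated(unlist(lapply(cl, `[[`, "members")))))
})

test_that("clusters partition random refined neighborhoods", {
  for (s in 1:8) {
    g <- random_weighted_graph(12, 0.3, seed = 400 + s)
    target <- igraph::V(g)$name[1]
    ng <- as_neighborhood(g, target)
    nodes <- setdiff(igraph::V(g)$name, target)
    set.seed(500 + s)
    seqs <- vapply(nodes, function(n)
      paste(sample(c("A", "D", "K", "W"), 12, replace = TRUE), collapse = ""),
      "")
    cl <- build_clusters(ng, property_matrix(seqs))
    members <- unlist(lapply(cl, `[[`, "members"))
    expect_setequal(members, nodes)
    expect_false(any(duplicated(members)))
    for (c1 in cl) expect_equal(c1$members[1], c1$seed)
  }
})

test_that("missing property vectors are reported by node name", {
  ng <- two_clique_world()
  props <- property_matrix(profile_seqs()[c("a1", "a2")])
  expect_error(build_clusters(ng, props), "missing property vector for node 'a3'")
})

test_that("target assignment picks the nearest centroid, ties by seed id", {
  cl <- structure(list(
    list(seed = "s1", members = "s1", score_vector = rep(0, 7)),
    list(seed = "s2", members = "s2", score_vector = rep(1, 7))),
    class = "cluster_set")
  expect_equal(assign_target(rep(0.1, 7), cl)$seed, "s1")
  # exact centroid
  expect_equal(assign_target(rep(1, 7), cl)$seed, "s2")
  # equidistant: smaller seed id wins
  expect_equal(assign_target(rep(0.5, 7), cl)$seed, "s1")
})

test_that("prediction transfers the nearest annotated member's terms", {
  ng <- two_clique_world()
  seqs <- profile_seqs()
  ann <- annotation_table(data.frame(
    protein_id = c("a1", "a1", "a2", "b1", "b2"),
    go_id = c("tA", "tA2", "tA", "tB", "tB"),
    aspect = "BP"))
  pred <- sequence_predict("t0", ng, seqs, ann, dist_threshold = 1)
  # the target's composition is nearer the W-rich clique
  expect_setequal(pred$go_id, c("tA", "tA2"))
  # both terms share the single member-transfer score
  expect_equal(pred$score[1], pred$score[2])
  expect_true(all(pred$score > 0 & pred$score <= 1))
  # predictions never invent terms
  expect_true(all(pred$go_id %in% ann$go_id))
})

test_that("a zero-distance transfer source scores exactly 1", {
  ng <- two_clique_world()
  seqs <- profile_seqs()
  seqs["t0"] <- seqs[["a1"]]  # identical composition to a1
  ann <- annotation_table(data.frame(
    protein_id = "a1", go_id = "tA", aspect = "BP"))
  pred <- sequence_predict("t0", ng, seqs, ann, dist_threshold = 1)
  expect_equal(pred$go_id, "tA")
  expect_equal(pred$score, 1.0)
})

test_that("planted module terms are recovered through the cluster route", {
  w <- generate_world(seed = 31, annotation_noise = 0)
  t <- names(w$truth)[1]
  ref <- refine_neighborhood(w$network, t)
  pred <- suppressMessages(
    sequence_predict(t, ref, w$sequences, w$annotations))
  expect_gt(length(intersect(pred$go_id, w$truth[[t]])), 0)
})
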