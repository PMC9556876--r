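# Neighborhood construction, ECC, non-essential classification, pruning and
# the adaptive double filter.

path_graph <- function(ids, weight = 1) {
  ppi_graph(data.frame(a = ids[-length(ids)], b = ids[-1], weight = weight))
}

test_that("neighborhood collects level-1 and level-2 nodes with tags", {
  g <- path_graph(c("a", "b", "c", "d"))
  ng <- neighborhood(g, "a")
  expect_setequal(igraph::V(ng$graph)$name, c("a", "b", "c"))
  expect_equal(ng$level[["b"]], 1L)
  expect_equal(ng$level[["c"]], 2L)
  expect_error(neighborhood(g, "zz"), "not in network")
  # isolated target
  g2 <- igraph::make_empty_graph(directed = FALSE) |>
    igraph::add_vertices(1, name = "solo")
  ng2 <- neighborhood(g2, "solo")
  expect_equal(igraph::V(ng2$graph)$name, "solo")
})

test_that("neighborhood equals the brute-force distance-2 ball", {
  for (s in 1:5) {
    g <- random_weighted_graph(50, 0.06, seed = s)
    target <- igraph::V(g)$name[1]
    ng <- neighborhood(g, target)
    d <- igraph::distances(g, v = target, weights = NA)[1, ]
    expect_setequal(igraph::V(ng$graph)$name, names(d)[d <= 2])
    # induced edges are all retained, including level-2 <-> level-2
    sub <- igraph::induced_subgraph(g, names(d)[d <= 2])
    expect_equal(igraph::ecount(ng$graph), igraph::ecount(sub))
  }
})

test_that("ECC matches hand values on canonical small graphs", {
  tri <- ppi_graph(data.frame(a = c("a", "b", "c"), b = c("b", "c", "a"),
                              weight = 1))
  expect_equal(edge_clustering_coefficient(tri, "a", "b"), 1.0)
  ring <- ppi_graph(data.frame(a = c("a", "b", "c", "d"),
                               b = c("b", "c", "d", "a"), weight = 1))
  expect_equal(edge_clustering_coefficient(ring, "a", "b"), 0.0)
  g <- ppi_graph(data.frame(a = c("a", "b", "c", "c", "d"),
                            b = c("b", "c", "a", "d", "e"), weight = 1))
  expect_equal(edge_clustering_coefficient(g, "b", "c"), 1.0)
  expect_equal(edge_clustering_coefficient(g, "c", "d"), 0.0)
  expect_error(edge_clustering_coefficient(g, "a", "e"), "no edge")
})

test_that("vectorized ECC agrees with the per-edge function and the oracle", {
  for (s in 1:20) {
    g <- random_weighted_graph(15, 0.25, seed = 100 + s)
    if (igraph::ecount(g) == 0) next
    ec <- ecc_all(g)
    el <- igraph::as_edgelist(g)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    adj[adj > 0] <- 1
    idx <- stats::setNames(seq_len(nrow(adj)), rownames(adj))
    for (i in seq_len(nrow(el))) {
      expect_equal(ec[i], edge_clustering_coefficient(g, el[i, 1], el[i, 2]))
      expect_equal(ec[i], oracle_ecc(adj, idx[el[i, 1]], idx[el[i, 2]]))
    }
    expect_true(all(ec >= 0 & ec <= 1))
  }
})

test_that("non-essential classification follows bridge > fjord > shore", {
  # star: center is an articulation vertex when seen from a leaf target
  star <- ppi_graph(data.frame(a = "hub", b = c("t", "l1", "l2", "l3"),
                               weight = 1))
  ng <- as_neighborhood(star, "t")
  expect_equal(classify_nonessential(ng, "hub"), "bridge")
  expect_equal(classify_nonessential(ng, "l1"), "shore")
  expect_error(classify_nonessential(ng, "t"), "target")
  # fjord: degree >= 2, no triangles, yet not an articulation vertex
  # (4-cycle t-a-x-b: removing x leaves t-a and t-b connected)
  g <- ppi_graph(data.frame(
    a = c("t", "a", "x", "b"),
    b = c("a", "x", "b", "t"),
    weight = 1))
  ngf <- as_neighborhood(g, "t")
  adj <- as.matrix(igraph::as_adjacency_matrix(g))
  adj[adj > 0] <- 1
  idx <- stats::setNames(seq_len(nrow(adj)), rownames(adj))
  expect_false(oracle_is_articulation(adj, idx[["x"]]))
  expect_equal(oracle_triangles_through(adj, idx[["x"]]), 0)
  expect_gte(igraph::degree(g, "x"), 2)
  expect_equal(classify_nonessential(ngf, "x"), "fjord")
})

test_that("classification labels agree with independent predicates", {
  for (s in 1:10) {
    g <- random_weighted_graph(12, 0.25, seed = 200 + s)
    target <- igraph::V(g)$name[1]
    ng <- as_neighborhood(g, target)
    adj <- as.matrix(igraph::as_adjacency_matrix(g))
    adj[adj > 0] <- 1
    idx <- stats::setNames(seq_len(nrow(adj)), rownames(adj))
    for (v in setdiff(igraph::V(g)$name, target)) {
      expected <- if (oracle_is_articulation(adj, idx[[v]])) "bridge"
        else if (sum(adj[idx[[v]], ]) >= 2 &&
                 oracle_triangles_through(adj, idx[[v]]) == 0) "fjord"
        else if (sum(adj[idx[[v]], ]) == 1) "shore"
        else "none"
      expect_equal(classify_nonessential(ng, v), expected)
    }
  }
})

test_that("pruning removes labelled nodes simultaneously, never the target", {
  star <- ppi_graph(data.frame(a = "t", b = c("l1", "l2", "l3"), weight = 1))
  ng <- as_neighborhood(star, "t")
  pruned <- prune_nonessential(ng)
  expect_equal(igraph::V(pruned$graph)$name, "t")
  expect_equal(attr(pruned, "removed")[["shore"]], 3L)
  # a clique has no articulation points, no leaves, all triangles: unchanged
  cl <- igraph::make_full_graph(5)
  igraph::V(cl)$name <- letters[1:5]
  igraph::E(cl)$weight <- 1
  ngc <- as_neighborhood(cl, "a")
  expect_equal(igraph::vcount(prune_nonessential(ngc)$graph), 5)
})

test_that("adaptive threshold matches the closed form", {
  expect_equal(adaptive_threshold(c(2, 2, 2, 2)), 2)  # sigma = 0 -> mean
  # alpha 0.5, sigma 0.2: 0.5 + 0.6 * (1 - 1/1.04)
  expect_equal(adaptive_threshold(c(0.3, 0.7)),
               0.5 + 0.6 * (1 - 1 / 1.04), tolerance = 1e-12)
  # alpha 0, sigma 1: 3 * (1 - 0.5) = 1.5
  expect_equal(adaptive_threshold(c(-1, 1)), 1.5, tolerance = 1e-12)
  expect_error(adaptive_threshold(numeric(0)), "empty")
  # always >= mean, strictly above when sigma > 0 and k > 0
  set.seed(31)
  for (i in 1:25) {
    v <- stats::rnorm(sample(2:40, 1))
    expect_gte(adaptive_threshold(v), mean(v))
    if (pop_sd_for_test(v) > 0) expect_gt(adaptive_threshold(v), mean(v))
  }
})

test_that("double filter: uniform graphs are untouched, edges only removed", {
  cl <- igraph::make_full_graph(6)
  igraph::V(cl)$name <- letters[1:6]
  igraph::E(cl)$weight <- 0.7
  ng <- as_neighborhood(cl, "a")
  flt <- double_filter(ng)
  expect_equal(igraph::ecount(flt$graph), igraph::ecount(cl))
  expect_equal(igraph::vcount(flt$graph), 6)
})

test_that("double filter removes pendant chains off a heavy clique", {
  cl <- igraph::make_full_graph(5)
  igraph::V(cl)$name <- paste0("k", 1:5)
  igraph::E(cl)$weight <- 0.9
  chain <- data.frame(a = c("k1", "x1"), b = c("x1", "x2"), weight = 0.1)
  g <- igraph::graph_from_data_frame(
    rbind(igraph::as_data_frame(cl)[, c(1, 2, 3)] |>
            stats::setNames(c("a", "b", "weight")), chain),
    directed = FALSE)
  ng <- as_neighborhood(g, "k2")
  flt <- double_filter(ng)
  # manual oracle: chain edges have ECC 0, clique edges ECC 1; the ECC
  # threshold lies strictly between, so exactly the chain goes
  eccs <- ecc_all(ng$graph)
  thr <- adaptive_threshold(eccs)
  expect_true(all(eccs[eccs < thr] == 0))
  expect_setequal(igraph::V(flt$graph)$name, paste0("k", 1:5))
  expect_equal(igraph::ecount(flt$graph), 10)
})

test_that("prune then filter never drops the target and never adds", {
  for (s in 1:30) {
    g <- random_weighted_graph(sample(8:25, 1), stats::runif(1, 0.1, 0.4),
                               seed = 300 + s)
    target <- igraph::V(g)$name[1]
    ng <- neighborhood(g, target)
    pruned <- prune_nonessential(ng)
    flt <- double_filter(pruned)
    expect_true(target %in% igraph::V(flt$graph)$name)
    expect_lte(igraph::vcount(pruned$graph), igraph::vcount(ng$graph))
    expect_lte(igraph::vcount(flt$graph), igraph::vcount(pruned$graph))
    expect_lte(igraph::ecount(flt$graph), igraph::ecount(pruned$graph))
    # surviving edges are a subset of the input edges
    key <- function(gg) {
      el <- igraph::as_edgelist(gg)
      paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    }
    expect_true(all(key(flt$graph) %in% key(ng$graph)))
  }
})
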