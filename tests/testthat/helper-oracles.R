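# Independent oracles and fixture builders shared across the suite. Every
# oracle is a deliberately naive reimplementation (brute force, enumeration,
# closed form) kept free of the package's own code paths.

# Brute-force ECC from an adjacency matrix: count common neighbors by
# scanning all vertices.
oracle_ecc <- function(adj, i, j) {
  n <- nrow(adj)
  common <- 0L
  for (k in seq_len(n)) {
    if (k != i && k != j && adj[i, k] == 1 && adj[j, k] == 1) {
      common <- common + 1L
    }
  }
  denom <- min(sum(adj[i, ]) - 1, sum(adj[j, ]) - 1)
  if (denom <= 0) 0 else common / denom
}

# Naive Needleman-Wunsch (match 1, mismatch 0, linear gap -1) with full
# traceback; returns matches / alignment length.
oracle_nw_identity <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x)
  m <- length(y)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- -(0:n)
  S[1, ] <- -(0:m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + (x[i] == y[j]),
                             S[i, j + 1] - 1, S[i + 1, j] - 1)
    }
  }
  i <- n
  j <- m
  matches <- 0L
  len <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && S[i + 1, j + 1] == S[i, j] + (x[i] == y[j])) {
      matches <- matches + (x[i] == y[j])
      i <- i - 1
      j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    len <- len + 1L
  }
  matches / len
}

# Hypergeometric upper tail by exhaustive enumeration of all size-n draws
# from N items of which the first K are marked. Returns p for every x in
# 0..min(n, K) as a vector indexed by x + 1.
oracle_hyper_enum <- function(N, K, n) {
  if (n == 0) return(c(1, numeric(min(n, K))))
  draws <- utils::combn(N, n)
  marked <- colSums(draws <= K)
  vapply(0:min(n, K), function(x) mean(marked >= x), numeric(1))
}

# Hypergeometric upper tail by direct log-space summation of the mass
# function (independent of stats::phyper).
oracle_hyper_logsum <- function(x, n, K, N) {
  xs <- x:min(n, K)
  lp <- lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)
  mx <- max(lp)
  exp(mx) * sum(exp(lp - mx))
}

# Independent threshold-scan Fmax: plain double loop over the grid.
oracle_fmax <- function(predictions, truths, thresholds = seq(0, 1, 0.01)) {
  best <- 0
  targets <- names(truths)[lengths(truths) > 0]
  for (tau in thresholds) {
    ps <- c()
    rs <- c()
    for (t in targets) {
      p <- predictions[[t]]
      kept <- if (is.null(p) || nrow(p) == 0) character(0) else
        unique(p$go_id[p$score >= tau])
      tp <- length(intersect(kept, truths[[t]]))
      if (length(kept) > 0) ps <- c(ps, tp / length(kept))
      rs <- c(rs, tp / length(unique(truths[[t]])))
    }
    pm <- if (length(ps)) mean(ps) else 0
    rm <- mean(rs)
    f <- if (pm + rm > 0) 2 * pm * rm / (pm + rm) else 0
    if (f > best) best <- f
  }
  best
}

# Brute-force articulation test: removing v increases the number of
# connected components (computed by matrix-power reachability).
oracle_is_articulation <- function(adj, v) {
  count_components <- function(a) {
    n <- nrow(a)
    if (n == 0) return(0L)
    reach <- diag(n) + a
    for (i in seq_len(n)) reach <- sign(reach %*% (diag(n) + a))
    comp <- unique(apply(reach > 0, 1, paste, collapse = ""))
    length(comp)
  }
  before <- count_components(adj)
  after <- count_components(adj[-v, -v, drop = FALSE])
  after > before
}

oracle_triangles_through <- function(adj, v) {
  nb <- which(adj[v, ] == 1)
  cnt <- 0L
  if (length(nb) >= 2) {
    for (pair in utils::combn(nb, 2, simplify = FALSE)) {
      if (adj[pair[1], pair[2]] == 1) cnt <- cnt + 1L
    }
  }
  cnt
}

pop_sd_for_test <- function(x) sqrt(mean((x - mean(x))^2))

# Random weighted Erdos-Renyi graph as an igraph object.
random_weighted_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  if (igraph::ecount(g) > 0) {
    igraph::E(g)$weight <- round(stats::runif(igraph::ecount(g)), 3)
  }
  g
}

# A tiny deterministic annotation fixture.
tiny_annotations <- function() {
  annotation_table(data.frame(
    protein_id = c("p1", "p2", "p1", "p3", "p2", "p4"),
    go_id = c("GO:1", "GO:1", "GO:2", "GO:3", "GO:2", "GO:3"),
    aspect = c("BP", "BP", "MF", "CC", "MF", "CC")))
}

# Wrap a bare igraph as a target-rooted neighborhood for predictor tests.
as_neighborhood <- function(g, target) {
  lev <- igraph::distances(g, v = target, weights = NA)[1, ]
  lev <- ifelse(is.finite(lev), lev, NA)
  structure(list(target = target, graph = g,
                 level = stats::setNames(as.integer(lev), names(lev))),
            class = "neighborhood_graph")
}
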