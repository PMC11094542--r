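# Shared fixtures and independent brute-force oracles.

# small hand-readable trees
tree_abc <- function() ape::read.tree(text = "((a:1,b:1):1,c:2);")
tree_star <- function(b = 1, n = 4) {
  ape::read.tree(text = sprintf("(%s);",
    paste(sprintf("%s:%g", letters[seq_len(n)], b), collapse = ",")))
}

toy_counts <- function() {
  m <- matrix(c(5, 3, 0,
                2, 2, 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  m
}

toy_enzymes <- function() {
  tibble::tibble(sample_id = c("s1", "s2"),
                 AG = c(30, 28), BG = c(50, 60), XS = c(20, 25),
                 CB = c(10, 12), NAG = c(20, 30), LAP = c(10, 20),
                 AP = c(40, 90))
}

# independent betaMNTD oracle: explicit double loop over printed distances
bmntd_brute <- function(a, b, d, weighted = FALSE) {
  ia <- which(a > 0); ib <- which(b > 0)
  mins_a <- vapply(ia, function(i) min(d[i, ib]), numeric(1))
  mins_b <- vapply(ib, function(j) min(d[ia, j]), numeric(1))
  if (weighted) {
    fa <- a[ia] / sum(a[ia]); fb <- b[ib] / sum(b[ib])
    0.5 * (sum(fa * mins_a) + sum(fb * mins_b))
  } else {
    mean(c(mins_a, mins_b))  # pooled over both communities
  }
}

# brute-force patristic distance: shortest path over the tree's edge graph
patristic_brute <- function(tree) {
  g <- igraph::graph_from_edgelist(cbind(tree$edge[, 1], tree$edge[, 2]),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  n <- length(tree$tip.label)
  d <- igraph::distances(g, v = seq_len(n), to = seq_len(n))
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# all set partitions of 1..n (for the brute-force modularity oracle)
set_partitions <- function(n) {
  if (n == 1) return(list(list(1L)))
  out <- list()
  for (p in set_partitions(n - 1L)) {
    for (i in seq_along(p)) {
      q <- p; q[[i]] <- c(q[[i]], n)
      out[[length(out) + 1L]] <- q
    }
    p[[length(p) + 1L]] <- n
    out[[length(out) + 1L]] <- p
  }
  out
}

# maximum-modularity partition by exhaustive search (graphs <= 8 nodes)
modularity_brute <- function(g) {
  n <- igraph::vcount(g)
  best <- -Inf
  for (p in set_partitions(n)) {
    memb <- integer(n)
    for (i in seq_along(p)) memb[p[[i]]] <- i
    q <- igraph::modularity(g, memb)
    if (q > best) best <- q
  }
  best
}

# two r~0.9 blocks of 20 plus weak noise, as a correlation-like matrix
block_correlation <- function(seed, k = 40, block = 20, r_in = 0.9,
                              noise_sd = 0.12) {
  set.seed(seed)
  r <- matrix(stats::rnorm(k * k, 0, noise_sd), k, k)
  r <- (r + t(r)) / 2
  for (bl in list(seq_len(block), (block + 1):k))
    r[bl, bl] <- pmin(0.99, pmax(0.6, matrix(stats::rnorm(block^2, r_in, 0.03),
                                             block)))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(paste0("a", seq_len(k)), paste0("a", seq_len(k)))
  r
}

graph_fixtures <- function() {
  list(
    k4 = igraph::make_full_graph(4),
    p4 = igraph::make_graph(~ a - b, b - c, c - d),
    two_triangles = igraph::disjoint_union(igraph::make_full_graph(3),
                                           igraph::make_full_graph(3)),
    star5 = igraph::make_star(5, mode = "undirected"),
    cycle6 = igraph::make_ring(6),
    barbell = igraph::add_edges(
      igraph::disjoint_union(igraph::make_full_graph(4),
                             igraph::make_full_graph(4)), c(1, 5))
  )
}
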