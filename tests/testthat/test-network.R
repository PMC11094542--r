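test_that("prevalence filter keeps exactly the sufficiently-occupied ASVs", {
  m <- matrix(0, 36, 3, dimnames = list(paste0("s", 1:36),
                                        c("common", "patchy", "rare5")))
  m[, "common"] <- 1
  m[1:14, "patchy"] <- 2
  m[1:5, "rare5"] <- 3
  f <- prevalence_filter(asv_table(m), 1 / 3)
  expect_identical(colnames(f), c("common", "patchy"))  # 5/36 < 12/36
  expect_true(all(colnames(f) %in% colnames(m)))
  disj <- matrix(c(1, 1, 0, 0, 0, 0, 1, 1), 4, 2,
                 dimnames = list(paste0("s", 1:4), c("a", "b")))
  expect_error(prevalence_filter(asv_table(disj), 1), "removed all")
  expect_error(prevalence_filter(asv_table(m), 0), "min_fraction")
})

test_that("log correlations are symmetric, order invariant and near 1 for
           proportional lognormal counts", {
  set.seed(21)
  base <- rlnorm(40, 3, 1)
  m <- cbind(x = round(base), y = round(2 * base),
             z = round(rlnorm(40, 3, 1)))
  rownames(m) <- paste0("s", 1:40)
  r <- log_correlation(asv_table(m + 1))
  expect_equal(r, t(r))
  expect_equal(diag(r), c(x = 1, y = 1, z = 1))
  expect_gt(r["x", "y"], 0.99)
  perm <- sample(40)
  r2 <- log_correlation(asv_table(m[perm, ] + 1))
  expect_equal(r, r2, tolerance = 1e-12)

  mc <- cbind(m, const = 5)
  expect_warning(rc <- log_correlation(asv_table(mc + 1)), "constant")
  expect_false("const" %in% colnames(rc))
  expect_error(log_correlation(asv_table(m[1:3, ] + 1)), "4 samples")
})

test_that("the RMT threshold scan returns grid members and rejects
           degenerate spectra", {
  r <- block_correlation(1)
  t <- rmt_threshold(r)
  expect_true(t %in% seq(0.30, 0.90, by = 0.01))
  expect_gt(t, 0.2)
  ident <- diag(40)
  dimnames(ident) <- dimnames(r)
  expect_error(rmt_threshold(ident), "degenerate|widen")
})

test_that("thresholding a block matrix strips between-block edges", {
  ok <- 0
  for (s in 1:3) {
    r <- block_correlation(s)
    t <- rmt_threshold(r)
    between <- abs(r[1:20, 21:40])
    within <- c(abs(r[1:20, 1:20][upper.tri(diag(20))]),
                abs(r[21:40, 21:40][upper.tri(diag(20))]))
    if (mean(between >= t) <= 0.05 && mean(within >= t) >= 0.80) ok <- ok + 1
  }
  expect_gte(ok, 2)
})

test_that("network construction is monotone in the threshold", {
  r <- block_correlation(2)
  g9 <- build_conetwork(r, 0.9, drop_isolated = FALSE)
  g5 <- build_conetwork(r, 0.5, drop_isolated = FALSE)
  e9 <- igraph::as_edgelist(g9); e5 <- igraph::as_edgelist(g5)
  key <- function(e) paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  expect_true(all(key(e9) %in% key(e5)))
  expect_true(all(abs(igraph::E(g5)$r) >= 0.5))
  expect_true(all(igraph::E(g5)$sign %in% c("positive", "negative")))

  tri <- matrix(0.9, 3, 3); diag(tri) <- 1
  dimnames(tri) <- list(c("a", "b", "c"), c("a", "b", "c"))
  gt <- build_conetwork(tri, 0.8)
  expect_equal(igraph::ecount(gt), 3)
  expect_warning(build_conetwork(diag(3) + 0, 0.99), "empty")
})

test_that("topology metrics match hand values on printed toy graphs", {
  fx <- graph_fixtures()
  top_k4 <- network_topology(fx$k4, n_rewire_null = 0)
  expect_equal(top_k4$avg_degree, 3)
  expect_equal(top_k4$diameter, 1L)
  expect_equal(top_k4$avg_clustering, 1)

  top_p4 <- network_topology(fx$p4, n_rewire_null = 0)
  expect_equal(top_p4$avg_degree, 1.5)
  expect_equal(top_p4$diameter, 3L)
  expect_equal(top_p4$avg_clustering, 0)
  expect_gte(top_p4$diameter, floor(top_p4$avg_path_length))

  top_tt <- network_topology(fx$two_triangles, n_rewire_null = 0)
  expect_equal(top_tt$modularity, 0.5, tolerance = 1e-12)
  expect_equal(top_tt$avg_clustering, 1)
  expect_equal(top_tt$n_edges, 6L)
})

test_that("greedy modularity equals the exhaustive optimum on small graphs", {
  fx <- graph_fixtures()
  for (nm in names(fx)) {
    g <- fx[[nm]]
    q_greedy <- igraph::modularity(
      igraph::cluster_fast_greedy(g, weights = NULL))
    q_best <- modularity_brute(g)
    expect_equal(q_greedy, q_best, tolerance = 1e-9, info = nm)
  }
})

test_that("module assignment ranks by size and reports composition", {
  fx <- graph_fixtures()
  g <- fx$two_triangles
  igraph::V(g)$name <- paste0("t", 1:6)
  part <- tibble::tibble(asv_id = paste0("t", 1:6),
                         mean_rel_abund = c(0.02, rep(4e-4, 4), 0.005),
                         category = factor(
                           c("abundant", rep("rare", 4), "intermediate"),
                           levels = c("abundant", "intermediate", "rare")))
  mod <- network_modules(g, partition = part, min_large = 5)
  expect_equal(sort(mod$modules$size), c(3L, 3L))
  expect_false(any(mod$modules$large))
  expect_equal(mod$modules$size[mod$modules$module == 1], 3L)
  comp <- mod$modules
  m_of_t1 <- mod$membership$module[mod$membership$asv_id == "t1"]
  expect_equal(comp$frac_abundant[comp$module == m_of_t1], 1 / 3,
               tolerance = 1e-12)
  rowsums <- rowSums(comp[, grep("^frac_", names(comp))], na.rm = TRUE)
  expect_equal(unname(rowsums), rep(1, nrow(comp)), tolerance = 1e-12)

  mod2 <- network_modules(g, partition = part, min_large = 3)
  expect_true(all(mod2$modules$large))

  # determinism
  expect_identical(network_modules(g)$membership,
                   network_modules(g)$membership)
})

test_that("per-sample complexity is centred and ranks denser samples higher", {
  g <- igraph::make_graph(~ a - b, b - c, a - c, c - d, d - e)
  m <- rbind(s1 = c(1, 1, 1, 0, 0),   # triangle: dense
             s2 = c(1, 0, 1, 1, 1),   # path-like
             s3 = c(0, 0, 1, 1, 1))   # path
  colnames(m) <- letters[1:5]
  cx <- sample_complexity(g, asv_table(m))
  expect_equal(mean(cx$complexity, na.rm = TRUE), 0, tolerance = 1e-9)
  expect_gt(cx$complexity[cx$sample_id == "s1"],
            cx$complexity[cx$sample_id == "s3"])

  # a sample sharing no taxa with the network gets a missing score
  m2 <- rbind(m[, 1:5], s4 = c(0, 0, 0, 0, 1))
  g2 <- igraph::induced_subgraph(g, c("a", "b", "c", "d"))
  cx2 <- sample_complexity(g2, asv_table(m2))
  expect_true(all(c("s1", "s2", "s3") %in%
                    cx2$sample_id[!is.na(cx2$complexity)]))

  # identical composition everywhere: constant properties -> missing
  m3 <- rbind(s1 = c(1, 1, 1, 0, 0), s2 = c(1, 1, 1, 0, 0))
  colnames(m3) <- letters[1:5]
  cx3 <- suppressWarnings(sample_complexity(g, asv_table(m3)))
  expect_true(all(is.na(cx3$complexity)))
})

test_that("complexity-ratio regressions behave on constructed cases", {
  set.seed(31)
  cx <- tibble::tibble(sample_id = paste0("s", 1:12),
                       complexity = rnorm(12))
  ratios <- tibble::tibble(sample_id = paste0("s", 1:12),
                           cn = 2 * cx$complexity + 5,
                           cp = rnorm(12), np = rnorm(12))
  fit <- complexity_ratio_fit(cx, ratios, "cn")
  expect_equal(fit$r, 1, tolerance = 1e-9)
  expect_identical(sign(fit$slope), sign(fit$r))
  fit2 <- complexity_ratio_fit(cx, ratios, "cp")
  expect_identical(sign(fit2$slope), sign(fit2$r))
  expect_error(complexity_ratio_fit(cx, dplyr::mutate(ratios, cn = 1), "cn"),
               "constant")
  expect_named(glance(fit), c("slope", "r", "p.value", "n"))
})
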