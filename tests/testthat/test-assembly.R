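test_that("betaMNTD reproduces hand-computed toy cases", {
  d <- patristic_matrix(tree_abc())
  a <- c(a = 1, b = 0, c = 0); b <- c(a = 0, b = 1, c = 0)
  expect_equal(beta_mntd(a, b, d), 2)              # cherry tips, d = 2
  expect_equal(beta_mntd(a, b, d, weighted = TRUE), 2)
  expect_equal(beta_mntd(a, a, d), 0)              # identical communities

  # star tree: every inter-tip distance 2b regardless of abundances
  ds <- patristic_matrix(tree_star(b = 1.5))
  x <- c(a = 5, b = 2, c = 0, d = 0); y <- c(a = 0, b = 0, c = 7, d = 1)
  expect_equal(beta_mntd(x, y, ds), 3)
  expect_equal(beta_mntd(x, y, ds, weighted = TRUE), 3)
  expect_error(beta_mntd(x * 0, y, ds), "empty")
})

test_that("betaMNTD is symmetric and invariant to abundance rescaling", {
  set.seed(4)
  tr <- sim_tree(12, seed = 4)
  d <- patristic_matrix(tr)
  for (i in 1:10) {
    a <- setNames(rpois(12, 2), tr$tip.label)
    b <- setNames(rpois(12, 2), tr$tip.label)
    if (sum(a) == 0 || sum(b) == 0) next
    expect_equal(beta_mntd(a, b, d), beta_mntd(b, a, d), tolerance = 1e-12)
    expect_equal(beta_mntd(a * 7, b, d, weighted = TRUE),
                 beta_mntd(a, b, d, weighted = TRUE), tolerance = 1e-12)
  }
})

test_that("betaMNTD agrees with picante as an independent reference", {
  skip_if_not_installed("picante")
  set.seed(6)
  tr <- sim_tree(15, seed = 6)
  m <- matrix(rpois(6 * 15, 2), 6, 15,
              dimnames = list(paste0("s", 1:6), tr$tip.label))
  m[rowSums(m) == 0, 1] <- 1
  d <- patristic_matrix(tr)
  for (w in c(TRUE, FALSE)) {
    ref <- as.matrix(picante::comdistnt(m, d, abundance.weighted = w))
    for (i in 1:5) for (j in (i + 1):6) {
      expect_equal(beta_mntd(m[i, ], m[j, ], d, weighted = w), ref[i, j],
                   tolerance = 1e-12)
    }
  }
})

test_that("a shuffle-invariant tree gives an undefined betaNTI, not zero", {
  tr <- tree_star(b = 1, n = 6)
  m <- rbind(s1 = c(3, 2, 1, 0, 0, 0), s2 = c(0, 0, 0, 1, 2, 3))
  colnames(m) <- tr$tip.label
  pr <- suppressWarnings(assembly_pairs(asv_table(m), tr, n_null = 49,
                                        seed = 1))
  expect_true(is.na(pr$bnti))
  expect_identical(as.character(pr$process), "undefined")
})

test_that("the process classifier matches its five-way truth table", {
  # boundaries: |bnti| = 2 and |rc| = 0.95 are NOT selection/dispersal
  expect_identical(as.character(classify_process(2.5, 0.1)),
                   "heterogeneous_selection")
  expect_identical(as.character(classify_process(-2.5, 0.99)),
                   "homogeneous_selection")
  expect_identical(as.character(classify_process(0, 0.97)),
                   "dispersal_limitation")
  expect_identical(as.character(classify_process(0, -0.97)),
                   "homogenizing_dispersal")
  expect_identical(as.character(classify_process(-1, 0)), "undominated")
  expect_identical(as.character(classify_process(2, 0.99)),
                   "dispersal_limitation")
  expect_identical(as.character(classify_process(-2, -0.99)),
                   "homogenizing_dispersal")
  expect_identical(as.character(classify_process(0, 0.95)), "undominated")
  expect_identical(as.character(classify_process(0, -0.95)), "undominated")
  expect_identical(as.character(classify_process(NA, 0.5)), "undefined")
  expect_identical(as.character(classify_process(1, NA)), "undefined")
})

test_that("the classifier is exhaustive and mutually exclusive on a grid", {
  grid <- expand.grid(bnti = seq(-4, 4, by = 0.25),
                      rc = seq(-1, 1, by = 0.05))
  out <- classify_process(grid$bnti, grid$rc)
  expect_false(anyNA(out))
  expect_true(all(out != "undefined"))
  sel <- abs(grid$bnti) > 2
  expect_true(all(out[sel] %in% c("heterogeneous_selection",
                                  "homogeneous_selection")))
  expect_true(all(out[!sel & abs(grid$rc) <= 0.95] == "undominated"))
})

test_that("Raup-Crick respects its bounds and limiting cases", {
  set.seed(9)
  tr <- sim_tree(12, seed = 9)
  # identical ubiquitous communities: obs BC = 0 -> RC = -1
  m <- matrix(5, 4, 12, dimnames = list(paste0("s", 1:4), tr$tip.label))
  m[2, ] <- m[1, ]
  m[3, ] <- c(rep(8, 6), rep(2, 6)); m[4, ] <- c(rep(2, 6), rep(8, 6))
  for (s in 1:5) {
    pr <- assembly_pairs(asv_table(m), tr, n_null = 99, seed = s)
    expect_true(all(pr$rc_bray >= -1 & pr$rc_bray <= 1))
    rc12 <- pr$rc_bray[pr$sample_a == "s1" & pr$sample_b == "s2"]
    expect_equal(rc12, -1)
  }

  # disjoint samples of pool-rare taxa sit far above their null
  tr2 <- sim_tree(40, seed = 2)
  pool <- matrix(0, 4, 40, dimnames = list(paste0("s", 1:4), tr2$tip.label))
  for (i in 1:4) pool[i, ((i - 1) * 10 + 1):(i * 10)] <- 10
  rcs <- vapply(1:5, function(s) {
    pr <- assembly_pairs(asv_table(pool), tr2, n_null = 99, seed = s)
    pr$rc_bray[pr$sample_a == "s1" & pr$sample_b == "s2"]
  }, numeric(1))
  expect_true(median(rcs) > 0.8)
})

test_that("assembly fractions normalize over defined pairs", {
  pairs <- tibble::tibble(
    sample_a = c("s1", "s1", "s2", "s3"),
    sample_b = c("s2", "s3", "s3", "s4"),
    bmntd = 1, bnti = c(0, 0, 0, NA), rc_bray = c(0.99, 0.99, 0.99, NA),
    process = classify_process(c(0, 0, 0, NA), c(0.99, 0.99, 0.99, NA)))
  fr <- assembly_fractions(pairs)
  def <- dplyr::filter(fr, process != "undefined")
  expect_equal(sum(def$fraction), 1, tolerance = 1e-12)
  expect_equal(def$fraction[def$process == "dispersal_limitation"], 1)
  expect_equal(fr$n[fr$process == "undefined"], 1L)

  allna <- dplyr::mutate(pairs, bnti = NA_real_,
                         process = classify_process(NA_real_, rc_bray))
  expect_error(assembly_fractions(allna), "undefined")

  groups <- c(s1 = "A", s2 = "A", s3 = "B", s4 = "B")
  frg <- assembly_fractions(pairs, groups = groups)
  expect_true(all(frg$group %in% c("A", "B")))
})

test_that("Mantel tests behave on self-correlation and monotone transforms", {
  set.seed(13)
  ids <- paste0("s", 1:10)
  v <- rnorm(10)
  bn <- as.matrix(dist(v)) * 3
  dimnames(bn) <- list(ids, ids)
  meta <- tibble::tibble(sample_id = ids, pH = v, junk = rnorm(10))
  res <- mantel_env(bn, meta, c("pH"), n_perm = 199, seed = 1)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_equal(res$p, 1 / 200)

  # spearman r is invariant to a monotone transform of the variable distances
  rs1 <- mantel_env(bn, meta, "pH", n_perm = 49, seed = 1,
                    method = "spearman")$r
  meta2 <- dplyr::mutate(meta, pH = exp(pH / 2))
  # monotone on values is not monotone on distances in general; use a matrix
  bn2 <- bn^3
  dimnames(bn2) <- dimnames(bn)
  rs2 <- mantel_env(bn2, meta, "pH", n_perm = 49, seed = 1,
                    method = "spearman")$r
  expect_equal(rs1, rs2, tolerance = 1e-12)

  expect_error(mantel_env(bn, meta, "absent"), "absent")
  expect_error(mantel_env(bn, dplyr::mutate(meta, pH = 1), "pH"), "constant")
})

test_that("pairwise tibbles convert to symmetric matrices", {
  pairs <- tibble::tibble(sample_a = c("s1", "s1", "s2"),
                          sample_b = c("s2", "s3", "s3"),
                          bnti = c(1, 2, 3))
  m <- pairs_to_matrix(pairs, "bnti")
  expect_equal(m, t(m))
  expect_equal(m["s1", "s3"], 2)
  expect_true(all(diag(m) == 0))
})

test_that("assembly_pairs is deterministic and seed-sensitive", {
  b <- simulate_bundle(regime_spec("neutral", n_samples = 5, depth = 500,
                                   n_taxa = 25, seed = 2))
  p1 <- assembly_pairs(b$table, b$tree, n_null = 49, seed = 5)
  p2 <- assembly_pairs(b$table, b$tree, n_null = 49, seed = 5)
  p3 <- assembly_pairs(b$table, b$tree, n_null = 49, seed = 6)
  expect_identical(p1$bnti, p2$bnti)
  expect_identical(p1$rc_bray, p2$rc_bray)
  expect_false(identical(p1$bnti, p3$bnti))
})

test_that("each generator regime leaves its expected signature in betaNTI
           and Raup-Crick", {
  pooled <- function(rg) {
    dplyr::bind_rows(lapply(c(11, 12), function(s) {
      b <- simulate_bundle(regime_spec(rg, seed = s))
      assembly_pairs(b$table, b$tree, n_null = 99, seed = s)
    }))
  }
  hom <- pooled("homogeneous_selection")
  expect_lt(median(hom$bnti, na.rm = TRUE), -2)

  het <- pooled("heterogeneous_selection")
  expect_gt(median(het$bnti, na.rm = TRUE), 2)

  dl <- pooled("dispersal_limitation")
  expect_lte(abs(median(dl$bnti, na.rm = TRUE)), 2)
  expect_gt(median(dl$rc_bray), 0.95)

  hd <- pooled("homogenizing_dispersal")
  expect_lt(median(hd$rc_bray), -0.95)
})
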