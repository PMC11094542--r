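test_that("relative-abundance conversion is exact and idempotent", {
  tab <- asv_table(toy_counts())
  rel <- to_relative(tab)
  expect_equal(unclass(rel)["s2", ], c(a = 0.25, b = 0.25, c = 0.5))
  expect_true(is_relative(rel))
  expect_identical(unclass(to_relative(rel)), unclass(rel))
  bad <- toy_counts(); bad[1, ] <- 0
  expect_error(to_relative(bad), "all-zero")
})

test_that("abundance partition applies the strict printed cutoffs", {
  # engineered mean relative abundances: 0.02 / 0.005 / 0.0005
  m <- matrix(rep(c(0.02, 0.005, 0.0005, 0.9745), each = 3), nrow = 3,
              dimnames = list(paste0("s", 1:3), c("ab", "mid", "ra", "fill")))
  p <- partition_taxa(asv_table(m, is_relative = TRUE))
  expect_identical(as.character(p$category[p$asv_id == "ab"]), "abundant")
  expect_identical(as.character(p$category[p$asv_id == "mid"]),
                   "intermediate")
  expect_identical(as.character(p$category[p$asv_id == "ra"]), "rare")

  # boundary values are not abundant/rare under strict inequalities
  mb <- matrix(rep(c(0.01, 0.001, 0.989), each = 2), nrow = 2,
               dimnames = list(c("s1", "s2"), c("at_ab", "at_ra", "fill")))
  pb <- partition_taxa(asv_table(mb, is_relative = TRUE))
  expect_identical(as.character(pb$category[pb$asv_id == "at_ab"]),
                   "intermediate")
  expect_identical(as.character(pb$category[pb$asv_id == "at_ra"]),
                   "intermediate")
  expect_error(partition_taxa(asv_table(m, is_relative = TRUE),
                              rare_cut = 0.5, abund_cut = 0.1), "rare_cut")
})

test_that("lowering the rare cutoff never shrinks the abundant set", {
  set.seed(3)
  m <- matrix(rlnorm(10 * 60, 0, 2), nrow = 10,
              dimnames = list(paste0("s", 1:10), paste0("t", 1:60)))
  rel <- to_relative(asv_table(m))
  cuts <- c(0.005, 0.002, 0.001, 5e-4)
  sizes <- vapply(cuts, function(rc) {
    sum(partition_taxa(rel, rare_cut = rc)$category == "abundant")
  }, numeric(1))
  expect_true(all(diff(sizes) == 0))  # abundant set depends on abund_cut only
})

test_that("copiotroph:oligotroph ratios sum strategy abundances", {
  m <- matrix(c(0.6, 0.3, 0.1), nrow = 1,
              dimnames = list("s1", c("a", "b", "c")))
  tax <- tibble::tibble(asv_id = c("a", "b", "c"),
                        phylum = c("Proteobacteria", "Chloroflexi",
                                   "Myxococcota"))
  r <- copiotroph_ratio(asv_table(m, is_relative = TRUE), tax)
  expect_equal(r$ratio, 2)

  # relabelling the unclassified phylum never changes the ratio
  tax2 <- dplyr::mutate(tax,
                        phylum = ifelse(phylum == "Myxococcota",
                                        "SomethingElse", phylum))
  expect_equal(copiotroph_ratio(asv_table(m, is_relative = TRUE), tax2)$ratio,
               2)

  tax3 <- dplyr::mutate(tax, phylum = "Unknowable")
  r3 <- copiotroph_ratio(asv_table(m, is_relative = TRUE), tax3)
  expect_true(is.na(r3$ratio))
})

test_that("Shannon diversity matches closed forms", {
  m <- rbind(uniform = c(1, 1, 1, 1), single = c(7, 0, 0, 0),
             mixed = c(2, 1, 1, 0))
  colnames(m) <- paste0("t", 1:4)
  h <- shannon_diversity(asv_table(m))
  expect_equal(h$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(h$shannon[2], 0, tolerance = 1e-12)
  expect_equal(h$shannon[3], -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
})

test_that("Bray-Curtis dissimilarities match the formula", {
  m <- rbind(a = c(0.5, 0.5, 0), b = c(0, 0.5, 0.5), c = c(0.5, 0.5, 0))
  colnames(m) <- paste0("t", 1:3)
  d <- as.matrix(bray_curtis(asv_table(m, is_relative = TRUE)))
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "b"], 0.5, tolerance = 1e-12)
  disj <- rbind(x = c(1, 1, 0, 0), y = c(0, 0, 1, 1))
  colnames(disj) <- paste0("t", 1:4)
  expect_equal(as.vector(bray_curtis(asv_table(disj))), 1)
})

test_that("PCoA recovers known configurations", {
  # three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(paste0("s", 1:3), paste0("s", 1:3))
  ord <- pcoa_ordination(d3, k = 2)
  ev <- ord$eigenvalues[ord$eigenvalues > 1e-9]
  expect_length(ev, 2)
  expect_equal(ev[1], ev[2], tolerance = 1e-9)

  # collinear points: one positive eigenvalue recovers the line
  x <- c(0, 1, 3, 7)
  dl <- as.matrix(dist(x))
  dimnames(dl) <- list(paste0("s", 1:4), paste0("s", 1:4))
  expect_warning(ordl <- pcoa_ordination(dl, k = 2), "truncating")
  rec <- ordl$scores$Axis1
  expect_equal(as.matrix(dist(rec)), as.matrix(dist(x)), tolerance = 1e-9,
               ignore_attr = TRUE)

  # Euclidean input: recovered coordinates reproduce all distances
  set.seed(5)
  pts <- matrix(rnorm(12 * 4), 12, 4)
  de <- as.matrix(dist(pts))
  dimnames(de) <- list(paste0("s", 1:12), paste0("s", 1:12))
  orde <- pcoa_ordination(de, k = 4)
  coords <- as.matrix(orde$scores[, -1])
  expect_equal(as.matrix(dist(coords)), de, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(abs(colMeans(coords)) < 1e-9))
  expect_true(all(diff(orde$proportion_explained) < 1e-12))
})

test_that("PERMANOVA is relabelling invariant and detects separation", {
  set.seed(11)
  m <- matrix(rlnorm(16 * 25), 16, 25,
              dimnames = list(paste0("s", 1:16), paste0("t", 1:25)))
  d <- bray_curtis(asv_table(m))
  g <- rep(c("a", "b"), each = 8)
  f1 <- permanova_test(d, g, n_perm = 99, seed = 1)
  perm <- sample(16)
  d2 <- as.dist(as.matrix(d)[perm, perm])
  f2 <- permanova_test(d2, g[perm], n_perm = 99, seed = 1)
  expect_equal(f1$pseudo_F, f2$pseudo_F, tolerance = 1e-12)
  expect_equal(f1$R2, f2$R2, tolerance = 1e-12)

  # two clouds with disjoint support reach (almost) the minimal attainable
  # p; a random permutation can rediscover the split, hence the one-draw
  # allowance
  m2 <- matrix(0, 16, 25, dimnames = dimnames(m))
  m2[1:8, 1:12] <- rlnorm(8 * 12, 0, 0.2)
  m2[9:16, 13:25] <- rlnorm(8 * 13, 0, 0.2)
  dsep <- bray_curtis(asv_table(m2))
  fs <- permanova_test(dsep, g, n_perm = 199, seed = 2)
  expect_lte(fs$p, 2 / 200)

  expect_error(permanova_test(d, rep("a", 16)), "two groups")
  expect_error(permanova_test(d, c("a", rep("b", 15))), "at least two samples")
})

test_that("tidiers expose PERMANOVA and PCoA results as tibbles", {
  set.seed(2)
  m <- matrix(rlnorm(12 * 20), 12, 20,
              dimnames = list(paste0("s", 1:12), paste0("t", 1:20)))
  d <- bray_curtis(asv_table(m))
  fit <- permanova_test(d, rep(c("a", "b"), each = 6), n_perm = 99, seed = 3)
  expect_named(glance(fit), c("pseudo_F", "R2", "p.value", "n_perm"))
  expect_equal(tidy(fit)$R2, fit$R2)
  ord <- pcoa_ordination(d)
  expect_identical(tidy(ord), ord$scores)
  expect_equal(glance(ord)$n_samples, 12)
})
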