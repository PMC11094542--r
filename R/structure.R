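#' Partition ASVs into abundant, intermediate and rare taxa
#'
#' Mean relative abundance across all samples is compared with the printed
#' cutoffs: above `abund_cut` (default 1\%) is abundant, below `rare_cut`
#' (default 0.1\%) is rare, the closed interval between them is an explicit
#' intermediate class so the partition is total.
#'
#' @param rel relative-abundance table (use [to_relative()] on counts first).
#' @param rare_cut,abund_cut strict cutoffs in (0, 1), `rare_cut < abund_cut`.
#' @return tibble `asv_id`, `mean_rel_abund`, `category` (factor
#'   abundant/intermediate/rare).
#' @export
partition_taxa <- function(rel, rare_cut = 0.001, abund_cut = 0.01) {
  if (rare_cut <= 0 || abund_cut >= 1 || rare_cut >= abund_cut)
    stopf("need 0 < rare_cut < abund_cut < 1")
  m <- as_asv_matrix(to_relative(rel), is_relative = TRUE)
  mu <- colMeans(m)
  tibble::tibble(
    asv_id = colnames(m),
    mean_rel_abund = unname(mu),
    category = factor(
      dplyr::case_when(mu > abund_cut ~ "abundant",
                       mu < rare_cut ~ "rare",
                       TRUE ~ "intermediate"),
      levels = c("abundant", "intermediate", "rare"))
  )
}

#' Subset an ASV count table to one partition category
#'
#' @param table count table.
#' @param partition output of [partition_taxa()] on the matching relative
#'   table.
#' @param category `"abundant"`, `"intermediate"` or `"rare"`.
#' @return count `asv_table` restricted to the chosen taxa.
#' @export
subset_partition <- function(table, partition, category) {
  category <- match.arg(category, levels(partition$category))
  keep <- partition$asv_id[partition$category == category]
  m <- as_asv_matrix(table)
  if (!length(keep)) stopf("no taxa in category '%s'", category)
  sub <- m[, intersect(colnames(m), keep), drop = FALSE]
  empty <- rowSums(sub) == 0
  if (any(empty)) {
    warnf("dropping %d sample(s) with no %s taxa", sum(empty), category)
    sub <- sub[!empty, , drop = FALSE]
  }
  asv_table(sub)
}

#' Default phylum-level life-strategy map
#'
#' Editable stand-in assignment of major soil phyla to the copiotrophic
#' (fast-growing, resource-responsive) or oligotrophic (slow-growing)
#' strategy. Phyla not listed are `unclassified`. Override entirely by
#' passing your own tibble to [copiotroph_ratio()].
#'
#' @return tibble `phylum`, `strategy`.
#' @export
default_strategy_map <- function() {
  path <- system.file("extdata", "strategy_map.tsv", package = "crustassembly")
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Per-sample copiotroph:oligotroph abundance ratio
#'
#' Sums relative abundances of ASVs whose phylum maps to each strategy;
#' unclassified phyla enter neither sum. Samples with a zero oligotroph sum
#' get a missing ratio (never infinity).
#'
#' @param rel relative-abundance table.
#' @param taxonomy taxonomy tibble (`asv_id`, ..., `phylum`, ...).
#' @param strategy_map tibble `phylum`, `strategy` with strategy in
#'   copiotroph/oligotroph/unclassified; defaults to
#'   [default_strategy_map()].
#' @return tibble `sample_id`, `copiotroph`, `oligotroph`, `ratio`.
#' @export
copiotroph_ratio <- function(rel, taxonomy, strategy_map = default_strategy_map()) {
  m <- as_asv_matrix(to_relative(rel), is_relative = TRUE)
  stopifnot(all(c("phylum", "strategy") %in% names(strategy_map)))
  strat <- setNames(strategy_map$strategy, strategy_map$phylum)
  phy <- setNames(taxonomy$phylum, taxonomy$asv_id)[colnames(m)]
  asv_strat <- strat[phy]
  asv_strat[is.na(asv_strat)] <- "unclassified"
  cop <- rowSums(m[, asv_strat == "copiotroph", drop = FALSE])
  oli <- rowSums(m[, asv_strat == "oligotroph", drop = FALSE])
  tibble::tibble(
    sample_id = rownames(m),
    copiotroph = unname(cop),
    oligotroph = unname(oli),
    ratio = unname(ifelse(oli > 0, cop / oli, NA_real_))
  )
}

#' Shannon alpha-diversity per sample
#'
#' Natural-log Shannon index \eqn{H = -\sum p \ln p} over positive
#' proportions.
#'
#' @param table counts or relative abundances.
#' @return tibble `sample_id`, `shannon`.
#' @export
shannon_diversity <- function(table) {
  m <- as_asv_matrix(table, is_relative = is_relative_guess(table))
  tibble::tibble(
    sample_id = rownames(m),
    shannon = unname(vegan::diversity(m, index = "shannon"))
  )
}

#' Bray-Curtis dissimilarity matrix
#'
#' @param rel relative-abundance table (counts are converted first so the
#'   dissimilarity is composition-based).
#' @return a `dist` object over samples.
#' @export
bray_curtis <- function(rel) {
  m <- as_asv_matrix(to_relative(rel), is_relative = TRUE)
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Double-centers \eqn{-D^2/2} and eigendecomposes it; axes are ordered by
#' eigenvalue and the variance explained is reported over the positive
#' eigenvalues only. Axis signs are arbitrary.
#'
#' @param dist a `dist` or symmetric zero-diagonal matrix.
#' @param k number of axes (truncated with a warning if fewer positive
#'   eigenvalues exist).
#' @return object of class `crust_pcoa`: list with `scores` (tibble
#'   `sample_id`, `Axis1..Axisk`), `eigenvalues`, `proportion_explained`.
#' @export
pcoa_ordination <- function(dist, k = 2) {
  d <- stats::as.dist(dist)
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  ev <- fit$eig
  pos <- sum(ev > sqrt(.Machine$double.eps) * max(abs(ev)))
  if (k > pos) {
    warnf("only %d positive eigenvalue(s); truncating k from %d", pos, k)
    k <- pos
  }
  coords <- fit$points[, seq_len(k), drop = FALSE]
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(
    scores = tibble::as_tibble(coords, rownames = "sample_id"),
    eigenvalues = ev,
    proportion_explained = ev[seq_len(pos)] / sum(ev[seq_len(pos)])
  ), class = "crust_pcoa")
}

#' @export
print.crust_pcoa <- function(x, ...) {
  cat(sprintf("<crust_pcoa> %d samples, first axes explain %s\n",
              nrow(x$scores),
              paste(sprintf("%.1f%%", 100 * utils::head(x$proportion_explained,
                                                        ncol(x$scores) - 1)),
                    collapse = ", ")))
  invisible(x)
}

#' PERMANOVA (Adonis) on a dissimilarity matrix
#'
#' Permutational multivariate analysis of variance: the pseudo-F of
#' between-group vs within-group sums of squares of the (Gower-centered)
#' dissimilarity matrix, with a permutation p-value using the add-one
#' estimator \eqn{p = (1 + \#\{F_{perm} \ge F_{obs}\})/(1 + n_{perm})}.
#' Computed by `vegan::adonis2`.
#'
#' @param dist a `dist` over samples.
#' @param groups factor-like group labels aligned with the samples.
#' @param n_perm number of permutations.
#' @param seed optional integer seed for the permutations.
#' @return object of class `crust_permanova` with fields `pseudo_F`, `R2`,
#'   `p`, `df`, `n_perm`; has [tidy()] and [glance()] methods.
#' @export
permanova_test <- function(dist, groups, n_perm = 999, seed = NULL) {
  d <- stats::as.dist(dist)
  groups <- as.factor(groups)
  if (length(groups) != attr(d, "Size"))
    stopf("groups length (%d) does not match samples (%d)",
          length(groups), attr(d, "Size"))
  if (nlevels(droplevels(groups)) < 2) stopf("need at least two groups")
  if (any(table(droplevels(groups)) < 2))
    stopf("every group needs at least two samples")
  df <- data.frame(group = groups)
  fit <- with_seed(seed,
                   vegan::adonis2(d ~ group, data = df, permutations = n_perm))
  structure(list(
    pseudo_F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1],
    df = fit$Df[1], n_perm = n_perm, seed = seed
  ), class = "crust_permanova")
}

#' @export
print.crust_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R2 = %.3f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p, x$n_perm))
  invisible(x)
}
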