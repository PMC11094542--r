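#' Prevalence filter for network construction
#'
#' Keeps ASVs present (count > 0) in at least `min_fraction` of samples —
#' the usual pre-filter before correlation networks.
#'
#' @param table count table.
#' @param min_fraction required occupancy fraction in (0, 1].
#' @return filtered count `asv_table` (column subset of the input).
#' @export
prevalence_filter <- function(table, min_fraction) {
  if (min_fraction <= 0 || min_fraction > 1)
    stopf("min_fraction must be in (0, 1]")
  m <- as_asv_matrix(table)
  keep <- colMeans(m > 0) >= min_fraction
  if (!any(keep)) stopf("prevalence filter removed all ASVs")
  asv_table(m[, keep, drop = FALSE])
}

#' Pearson correlations of log-transformed abundances
#'
#' Computes the ASV-by-ASV Pearson correlation matrix of
#' \eqn{\ln(count + pseudo)}. ASVs constant after the transform carry no
#' correlation signal and are excluded with a warning.
#'
#' @param table count table with at least 4 samples.
#' @param pseudo pseudo-count added before the log (1 default).
#' @return symmetric correlation matrix with unit diagonal, dimnames = ASVs.
#' @export
log_correlation <- function(table, pseudo = 1) {
  m <- as_asv_matrix(table)
  if (nrow(m) < 4) stopf("need at least 4 samples for correlations")
  lm_ <- log(m + pseudo)
  keep <- apply(lm_, 2, function(x) stats::sd(x) > 0)
  if (!all(keep)) {
    warnf("excluding %d constant ASV(s) from the correlation matrix",
          sum(!keep))
    lm_ <- lm_[, keep, drop = FALSE]
  }
  stats::cor(lm_)
}

#' Random-matrix-theory correlation threshold
#'
#' Scans candidate cutoffs: at each `t` the correlation matrix is hard-
#' thresholded (entries with |r| < t zeroed, diagonal kept), its eigenvalue
#' spectrum is unfolded with a cubic smoothing spline fitted to the
#' cumulative spectral density (duplicate eigenvalues collapsed first), and
#' the nearest-neighbour spacing distribution is tested against the Poisson
#' law \eqn{e^{-s}} by a chi-square goodness-of-fit test (bins of width
#' `bin_width` up to `s_max`, pooled to expected counts >= 5). The smallest
#' `t` whose Poisson fit is not rejected at `alpha` is returned: the point
#' where correlated noise (Wigner-like spacings) has been stripped and
#' modular signal remains.
#'
#' @param corr symmetric correlation matrix (>= 30 taxa recommended).
#' @param t_grid candidate thresholds (default 0.30..0.90 by 0.01).
#' @param alpha goodness-of-fit level (0.05).
#' @param bin_width,s_max NNSD histogram bin width and upper edge.
#' @param min_spacings minimum usable spacings at a threshold; fewer makes
#'   that threshold untestable.
#' @return selected threshold (member of `t_grid`) with the scan table as
#'   attribute `"scan"`.
#' @export
rmt_threshold <- function(corr, t_grid = seq(0.30, 0.90, by = 0.01),
                          alpha = 0.05, bin_width = 0.1, s_max = 3,
                          min_spacings = 15) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  scan <- purrr::map_dfr(t_grid, function(t) {
    p <- nnsd_poisson_p(corr, t, bin_width, s_max, min_spacings)
    tibble::tibble(threshold = t, p_poisson = p)
  })
  ok <- which(!is.na(scan$p_poisson) & scan$p_poisson > alpha)
  if (!length(ok))
    stopf(paste("no threshold in the grid gives a Poisson-consistent spacing",
                "distribution; widen the grid or check the input (degenerate",
                "spectra are untestable)"))
  structure(t_grid[ok[1]], scan = scan)
}

# chi-square GOF p-value of the unfolded NNSD against exp(-s); NA if the
# spectrum at this threshold is too degenerate to test
nnsd_poisson_p <- function(corr, t, bin_width, s_max, min_spacings) {
  a <- corr
  a[abs(a) < t] <- 0
  diag(a) <- diag(corr)
  ev <- sort(eigen(a, symmetric = TRUE, only.values = TRUE)$values)
  ev <- ev[c(TRUE, diff(ev) > 1e-8)]  # collapse (near-)duplicates
  m <- length(ev)
  if (m < min_spacings + 1) return(NA_real_)
  # unfold: smooth the cumulative spectral density, map eigenvalues onto a
  # uniform scale, then take nearest-neighbour spacings
  cdf <- seq_len(m) / m
  sp <- tryCatch(stats::smooth.spline(ev, cdf, df = min(10, m - 1)),
                 error = function(e) NULL)
  if (is.null(sp)) return(NA_real_)
  unfolded <- m * stats::predict(sp, ev)$y
  s <- diff(sort(unfolded))
  s <- s[is.finite(s) & s >= 0]
  if (length(s) < min_spacings || mean(s) == 0) return(NA_real_)
  s <- s / mean(s)
  breaks <- c(seq(0, s_max, by = bin_width), Inf)
  obs <- as.vector(table(cut(s, breaks = breaks, right = FALSE)))
  expd <- length(s) * diff(stats::pexp(breaks))
  pooled <- pool_bins(obs, expd, min_expected = 5)
  if (length(pooled$obs) < 2) return(NA_real_)
  stat <- sum((pooled$obs - pooled$expd)^2 / pooled$expd)
  stats::pchisq(stat, df = length(pooled$obs) - 1, lower.tail = FALSE)
}

# merge adjacent histogram bins (left to right) until expected counts >= min
pool_bins <- function(obs, expd, min_expected = 5) {
  po <- numeric(0); pe <- numeric(0)
  co <- 0; ce <- 0
  for (i in seq_along(obs)) {
    co <- co + obs[i]; ce <- ce + expd[i]
    if (ce >= min_expected) {
      po <- c(po, co); pe <- c(pe, ce)
      co <- 0; ce <- 0
    }
  }
  if (ce > 0 && length(pe)) {  # fold the remainder into the last bin
    po[length(po)] <- po[length(po)] + co
    pe[length(pe)] <- pe[length(pe)] + ce
  }
  list(obs = po, expd = pe)
}

#' Build a signed co-occurrence network at a threshold
#'
#' One edge per ASV pair with |r| >= threshold, keeping the signed
#' correlation as edge attribute `r` and `sign`. Isolated nodes are dropped
#' by default.
#'
#' @param corr correlation matrix from [log_correlation()].
#' @param threshold cutoff in (0, 1), e.g. from [rmt_threshold()].
#' @param drop_isolated drop nodes with no edge (default TRUE).
#' @return an `igraph` graph with vertex attribute `name` and edge
#'   attributes `r`, `sign`; attribute `threshold` records the cutoff.
#' @export
build_conetwork <- function(corr, threshold, drop_isolated = TRUE) {
  if (threshold <= 0 || threshold > 1) stopf("threshold must be in (0, 1]")
  a <- corr
  diag(a) <- 0
  a[abs(a) < threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(abs(a) > 0, mode = "undirected",
                                           diag = FALSE)
  ends <- igraph::as_edgelist(g)
  if (nrow(ends) == 0) warnf("empty network at threshold %.2f", threshold)
  rvals <- a[cbind(match(ends[, 1], rownames(a)), match(ends[, 2], colnames(a)))]
  igraph::E(g)$r <- rvals
  igraph::E(g)$sign <- ifelse(rvals >= 0, "positive", "negative")
  if (drop_isolated)
    g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  g$threshold <- threshold
  g
}

greedy_communities <- function(g) {
  igraph::cluster_fast_greedy(g, weights = NULL)
}

#' Topological properties of a co-occurrence network
#'
#' Node/edge counts, average degree (2E/N), mean local clustering
#' coefficient (nodes of degree < 2 contribute 0), diameter and average
#' path length on the largest connected component, Newman modularity Q of
#' the deterministic greedy partition, and relative modularity
#' \eqn{(Q - \bar{Q}_{null})/\bar{Q}_{null}} against degree-preserving
#' edge-rewiring null graphs.
#'
#' @param g an `igraph` network.
#' @param n_rewire_null number of rewired null graphs for relative
#'   modularity (0 skips it).
#' @param seed integer seed for the rewiring nulls.
#' @return one-row tibble of topology metrics.
#' @export
network_topology <- function(g, n_rewire_null = 100, seed = 1) {
  n <- igraph::vcount(g)
  if (n < 2) stopf("need at least 2 nodes")
  e <- igraph::ecount(g)
  if (e < 1) {
    return(tibble::tibble(n_nodes = n, n_edges = 0L, avg_degree = 0,
                          diameter = NA_integer_, avg_path_length = NA_real_,
                          avg_clustering = NA_real_, modularity = NA_real_,
                          relative_modularity = NA_real_))
  }
  comp <- igraph::components(g)
  giant <- igraph::induced_subgraph(
    g, which(comp$membership == which.max(comp$csize)))
  cl <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cl[is.na(cl)] <- 0
  q_obs <- igraph::modularity(greedy_communities(g))
  rel_mod <- NA_real_
  if (n_rewire_null > 0) {
    q_null <- with_seed(seed, vapply(seq_len(n_rewire_null), function(i) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = max(100, e * 10)))
      igraph::modularity(greedy_communities(gr))
    }, numeric(1)))
    mq <- mean(q_null)
    rel_mod <- if (mq != 0) (q_obs - mq) / mq else NA_real_
  }
  tibble::tibble(
    n_nodes = n, n_edges = e, avg_degree = 2 * e / n,
    diameter = as.integer(igraph::diameter(giant, weights = NA)),
    avg_path_length = igraph::mean_distance(giant, weights = NA),
    avg_clustering = mean(cl),
    modularity = q_obs,
    relative_modularity = rel_mod
  )
}

#' Module detection and abundant/rare composition
#'
#' Deterministic greedy modularity communities; modules are ranked by size
#' (module 1 = largest) and annotated with their composition over an
#' abundant/intermediate/rare taxon partition. Modules with at least
#' `min_large` nodes carry `large = TRUE`.
#'
#' @param g an `igraph` network with ASV names as vertex names.
#' @param partition optional [partition_taxa()] result for composition
#'   fractions.
#' @param min_large minimum node count for a "large" module (5 default).
#' @return list with `membership` (tibble `asv_id`, `module`) and `modules`
#'   (tibble `module`, `size`, `large`, and per-category fractions when a
#'   partition is supplied).
#' @export
network_modules <- function(g, partition = NULL, min_large = 5) {
  if (igraph::ecount(g) < 1) stopf("module detection needs at least one edge")
  comm <- greedy_communities(g)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  rank <- setNames(seq_along(sizes), names(sizes))
  membership <- tibble::tibble(asv_id = igraph::V(g)$name,
                               module = unname(rank[as.character(memb)]))
  modules <- membership |>
    dplyr::count(.data$module, name = "size") |>
    dplyr::arrange(.data$module) |>
    dplyr::mutate(large = .data$size >= min_large)
  if (!is.null(partition)) {
    comp <- membership |>
      dplyr::left_join(partition[, c("asv_id", "category")], by = "asv_id") |>
      dplyr::mutate(category = as.character(.data$category)) |>
      dplyr::mutate(category = tidyr::replace_na(.data$category, "unknown")) |>
      dplyr::count(.data$module, .data$category) |>
      dplyr::group_by(.data$module) |>
      dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
      dplyr::ungroup() |>
      dplyr::select(-"n") |>
      tidyr::pivot_wider(names_from = "category", values_from = "fraction",
                         values_fill = 0, names_prefix = "frac_")
    modules <- dplyr::left_join(modules, comp, by = "module")
  }
  list(membership = membership, modules = modules)
}

#' Per-sample network-complexity z-scores
#'
#' Induces, for each sample, the subgraph on ASVs present (count > 0) in
#' that sample, computes the chosen topological properties, z-scores each
#' property across samples (population SD; properties constant across
#' samples are dropped with a warning), and averages them into a composite
#' complexity score with mean 0.
#'
#' @param g network whose vertex names are ASV ids.
#' @param table count table aligned with the network's source data.
#' @param properties any of `"avg_degree"`, `"avg_clustering"`, `"n_edges"`.
#' @return tibble `sample_id`, one raw column per property, and `complexity`
#'   (NA for samples whose induced subgraph is empty).
#' @export
sample_complexity <- function(g, table,
                              properties = c("avg_degree", "avg_clustering",
                                             "n_edges")) {
  properties <- match.arg(properties, several.ok = TRUE)
  m <- as_asv_matrix(table)
  nodes <- igraph::V(g)$name
  raw <- purrr::map_dfr(rownames(m), function(s) {
    present <- colnames(m)[m[s, ] > 0]
    sub <- igraph::induced_subgraph(g, intersect(nodes, present))
    nv <- igraph::vcount(sub); ne <- igraph::ecount(sub)
    if (nv == 0)
      return(tibble::tibble(sample_id = s, avg_degree = NA_real_,
                            avg_clustering = NA_real_, n_edges = NA_real_))
    cl <- igraph::transitivity(sub, type = "localundirected",
                               isolates = "zero")
    cl[is.na(cl)] <- 0
    tibble::tibble(sample_id = s,
                   avg_degree = 2 * ne / nv,
                   avg_clustering = if (nv > 0) mean(cl) else NA_real_,
                   n_edges = as.numeric(ne))
  })
  usable <- character(0)
  z <- list()
  ok <- stats::complete.cases(raw[, properties, drop = FALSE])
  for (p in properties) {
    x <- raw[[p]][ok]
    if (length(x) >= 2 && sd_pop(x) > 0) {
      usable <- c(usable, p)
      z[[p]] <- zscore_pop(x)
    } else {
      warnf("property '%s' is constant across samples; dropped", p)
    }
  }
  raw$complexity <- NA_real_
  if (length(usable))
    raw$complexity[ok] <- rowMeans(do.call(cbind, z))
  raw[, c("sample_id", properties, "complexity")]
}

sd_pop <- function(x) sqrt(mean((x - mean(x))^2))

#' Regress network complexity on an enzyme stoichiometry ratio
#'
#' Ordinary least squares of the composite complexity score on one of the
#' log enzyme ratios, with the Pearson correlation and its two-sided t-test.
#'
#' @param complexity output of [sample_complexity()].
#' @param ratios output of [stoich_ratios()].
#' @param which ratio to use: `"cn"`, `"cp"` or `"np"`.
#' @return object of class `crust_fit` with `slope`, `intercept`, `r`, `p`,
#'   `n`; has [tidy()]/[glance()] methods.
#' @export
complexity_ratio_fit <- function(complexity, ratios,
                                 which = c("cn", "cp", "np")) {
  which <- match.arg(which)
  df <- dplyr::inner_join(complexity, ratios, by = "sample_id") |>
    dplyr::filter(is.finite(.data$complexity), is.finite(.data[[which]]))
  if (nrow(df) < 3) stopf("need at least 3 paired non-missing values")
  x <- df[[which]]
  if (stats::sd(x) == 0) stopf("constant predictor")
  fit <- stats::lm(df$complexity ~ x)
  ct <- stats::cor.test(x, df$complexity)
  structure(list(ratio = which, slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r = unname(ct$estimate), p = ct$p.value, n = nrow(df),
                 data = df), class = "crust_fit")
}

#' @export
print.crust_fit <- function(x, ...) {
  cat(sprintf("complexity ~ %s: slope = %.3f, r = %.3f, p = %.4g (n = %d)\n",
              x$ratio, x$slope, x$r, x$p, x$n))
  invisible(x)
}
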