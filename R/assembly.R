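PROCESSES <- c("heterogeneous_selection", "homogeneous_selection",
               "dispersal_limitation", "homogenizing_dispersal",
               "undominated", "undefined")

#' Between-community mean nearest taxon distance
#'
#' For each taxon in one community, the patristic distance to its nearest
#' relative in the other community (0 if the taxon itself is present there),
#' averaged — either over taxa (incidence, the default) or
#' abundance-weighted:
#' \deqn{0.5\left[\sum_{i \in A} f_i \min_j d_{ij} + \sum_{j \in B} f_j \min_i d_{ij}\right]}
#' with \eqn{f} the within-sample relative abundances over present taxa.
#'
#' @param a,b abundance vectors named by taxon, or aligned with `dist`.
#' @param dist patristic distance matrix whose dimnames cover the taxa.
#' @param weighted abundance-weighted mean, or incidence-based (the
#'   default, as in picante).
#' @return the betaMNTD value (non-negative scalar).
#' @export
beta_mntd <- function(a, b, dist, weighted = FALSE) {
  taxa <- colnames(dist)
  if (!is.null(names(a))) a <- a[match(taxa, names(a))]
  if (!is.null(names(b))) b <- b[match(taxa, names(b))]
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  if (length(a) != nrow(dist) || length(b) != nrow(dist))
    stopf("abundance vectors do not align with the distance matrix")
  if (sum(a > 0) == 0 || sum(b > 0) == 0) stopf("empty community")
  cpp_bmntd(as.numeric(a), as.numeric(b), as.matrix(dist), weighted)
}

#' Pairwise community-assembly statistics (betaNTI and Raup-Crick)
#'
#' For every sample pair: observed betaMNTD; the taxa-shuffle null (labels of
#' the patristic matrix permuted `n_null` times) giving
#' \eqn{\beta NTI = (obs - \bar{null})/sd(null)}; and the Raup-Crick
#' Bray-Curtis score from a null that reassembles each community at its
#' observed richness (taxa drawn by pool occupancy) and total reads
#' (distributed by metacommunity relative abundance), scaled to \[-1, 1\].
#' Pairs whose null betaMNTD spread is zero are flagged `undefined`.
#'
#' @param table ASV count table (samples x ASVs).
#' @param tree rooted phylogeny covering the ASVs (extras in the table are
#'   dropped with a warning).
#' @param n_null null draws for both nulls (999 default).
#' @param seed integer seed; all randomness in the run derives from it.
#' @param weighted abundance-weighted betaMNTD, or incidence (the default;
#'   at moderate richness the abundance-weighted statistic concentrates on
#'   one or two dominant taxa, which blunts the selection signal).
#' @param null_scope `"tree"` (default; shuffle across every tip of the
#'   supplied phylogeny — the regional species pool), `"pool"` (only taxa
#'   present in the table) or `"union"` (only each pair's union of present
#'   taxa). Prune the tree to your dataset first if you want the pool to be
#'   the observed taxa.
#' @param rc_pool optional count table defining the species pool for the
#'   Raup-Crick null; defaults to `table` itself.
#' @return tibble with one row per unordered sample pair: `sample_a`,
#'   `sample_b`, `bmntd`, `bnti`, `rc_bray`, `process`, plus the seed as an
#'   attribute.
#' @export
assembly_pairs <- function(table, tree, n_null = 999, seed = 1,
                           weighted = FALSE,
                           null_scope = c("tree", "pool", "union"),
                           rc_pool = NULL) {
  null_scope <- match.arg(null_scope)
  tab <- align_table_tree(table, tree)
  m <- unclass_matrix(tab)
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (ncol(m) < 2) stopf("need at least two taxa across the table")
  scope_taxa <- if (null_scope == "tree") tree$tip.label else colnames(m)
  mfull <- matrix(0, nrow(m), length(scope_taxa),
                  dimnames = list(rownames(m), scope_taxa))
  mfull[, colnames(m)] <- m
  m <- mfull
  k <- ncol(m)
  dmat <- patristic_matrix(tree)[colnames(m), colnames(m)]
  pool <- if (is.null(rc_pool)) m else as_asv_matrix(rc_pool)
  occ <- colMeans(pool[, colnames(m), drop = FALSE] > 0)
  meta <- colSums(pool[, colnames(m), drop = FALSE])
  meta <- meta / sum(meta)

  samples <- rownames(m)
  idx <- utils::combn(length(samples), 2)
  with_seed(seed, {
    res <- purrr::map_dfr(seq_len(ncol(idx)), function(p) {
      i <- idx[1, p]; j <- idx[2, p]
      a <- m[i, ]; b <- m[j, ]
      obs <- cpp_bmntd(a, b, dmat, weighted)
      perms <- make_null_perms(k, n_null, scope = null_scope,
                               union_idx = which(a > 0 | b > 0))
      nulls <- cpp_bmntd_nulls(a, b, dmat, perms, weighted)
      sd_null <- stats::sd(nulls)
      bnti <- if (is.na(sd_null) || sd_null == 0) NA_real_
              else (obs - mean(nulls)) / sd_null
      rc <- raup_crick_pair(a, b, occ, meta, n_null)
      tibble::tibble(sample_a = samples[i], sample_b = samples[j],
                     bmntd = obs, bnti = bnti, rc_bray = rc)
    })
    res$process <- classify_process(res$bnti, res$rc_bray)
    attr(res, "seed") <- seed
    attr(res, "n_null") <- n_null
    res
  })
}

# permutation matrix for the taxa-shuffle null: k x n_null, 0-based
make_null_perms <- function(k, n_null, scope = "pool", union_idx = NULL) {
  if (scope %in% c("tree", "pool")) {
    perms <- vapply(seq_len(n_null), function(i) sample.int(k), integer(k))
  } else {
    base <- seq_len(k)
    perms <- vapply(seq_len(n_null), function(i) {
      p <- base
      p[union_idx] <- union_idx[sample.int(length(union_idx))]
      p
    }, integer(k))
  }
  perms - 1L
}

# Raup-Crick score for one pair against the occupancy/abundance null
raup_crick_pair <- function(a, b, occ, meta, n_null, tol = 1e-10) {
  na_ <- sum(a); sa <- sum(a > 0)
  nb_ <- sum(b); sb <- sum(b > 0)
  obs <- 1 - 2 * sum(pmin(a, b)) / (na_ + nb_)
  nulls <- cpp_rc_nulls(as.integer(na_), as.integer(sa),
                        as.integer(nb_), as.integer(sb),
                        occ, meta, as.integer(n_null))
  less <- sum(nulls < obs - tol)
  ties <- sum(abs(nulls - obs) <= tol)
  2 * ((less + 0.5 * ties) / n_null - 0.5)
}

#' Classify a sample pair into an assembly process
#'
#' Stegen-style five-process partition: betaNTI beyond +/-2 indicates
#' deterministic selection (sign separates heterogeneous from homogeneous);
#' otherwise the Raup-Crick score beyond +/-0.95 separates dispersal
#' limitation (positive) from homogenizing dispersal (negative), and the
#' remainder is undominated. Boundary values fall inside the
#' non-selection/non-dispersal bands; missing inputs give `undefined`.
#'
#' @param bnti,rc_bray numeric vectors (recycled pairwise).
#' @return factor with levels heterogeneous_selection, homogeneous_selection,
#'   dispersal_limitation, homogenizing_dispersal, undominated, undefined.
#' @export
classify_process <- function(bnti, rc_bray) {
  out <- dplyr::case_when(
    !is.finite(bnti) | !is.finite(rc_bray) ~ "undefined",
    bnti > 2 ~ "heterogeneous_selection",
    bnti < -2 ~ "homogeneous_selection",
    rc_bray > 0.95 ~ "dispersal_limitation",
    rc_bray < -0.95 ~ "homogenizing_dispersal",
    TRUE ~ "undominated"
  )
  factor(out, levels = PROCESSES)
}

#' Assembly-process fractions
#'
#' Relative contribution of each process over the defined pairs, optionally
#' within groups (pairs whose two samples share a group label).
#'
#' @param pairs output of [assembly_pairs()].
#' @param groups optional named vector (sample id -> group label).
#' @return tibble `group` (if given), `process`, `n`, `fraction`;
#'   fractions sum to 1 over defined pairs within each group. Undefined
#'   pairs are reported with `fraction = NA`.
#' @export
assembly_fractions <- function(pairs, groups = NULL) {
  df <- tibble::as_tibble(pairs)
  if (!is.null(groups)) {
    df$group <- ifelse(groups[df$sample_a] == groups[df$sample_b],
                       as.character(groups[df$sample_a]), NA_character_)
    df <- dplyr::filter(df, !is.na(.data$group))
  } else {
    df$group <- "all"
  }
  out <- df |>
    dplyr::count(.data$group, process = .data$process, .drop = FALSE) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(
      fraction = dplyr::if_else(
        .data$process == "undefined", NA_real_,
        .data$n / pmax(sum(.data$n[.data$process != "undefined"]), 1L))) |>
    dplyr::ungroup()
  if (sum(out$n[out$process != "undefined"]) == 0)
    stopf("all pairs undefined; no process fractions available")
  out
}

#' Square matrix from a pairwise tibble
#'
#' @param pairs tibble with `sample_a`, `sample_b` and a value column.
#' @param value name of the value column (e.g. `"bnti"`).
#' @return symmetric matrix with zero diagonal.
#' @export
pairs_to_matrix <- function(pairs, value = "bnti") {
  ids <- sort(unique(c(pairs$sample_a, pairs$sample_b)))
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  m[cbind(pairs$sample_a, pairs$sample_b)] <- pairs[[value]]
  m[cbind(pairs$sample_b, pairs$sample_a)] <- pairs[[value]]
  m
}

#' Mantel tests of betaNTI against environmental distance
#'
#' Correlates the pairwise betaNTI matrix with the per-variable Euclidean
#' distance matrix of each soil variable, with a permutation p-value
#' (add-one estimator), via `vegan::mantel`.
#'
#' @param pairs output of [assembly_pairs()] (or a square matrix).
#' @param metadata per-sample metadata tibble (`sample_id` + variables).
#' @param variables character vector of metadata columns to test.
#' @param n_perm permutations per test.
#' @param seed optional seed.
#' @param method `"pearson"` or `"spearman"`.
#' @return tibble `variable`, `r`, `p`, `n_perm`.
#' @export
mantel_env <- function(pairs, metadata, variables, n_perm = 999, seed = NULL,
                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  m <- if (is.matrix(pairs)) pairs else pairs_to_matrix(pairs, "bnti")
  if (anyNA(m)) stopf("betaNTI matrix contains undefined pairs")
  ids <- rownames(m)
  meta <- metadata[match(ids, metadata$sample_id), , drop = FALSE]
  with_seed(seed, purrr::map_dfr(variables, function(v) {
    x <- meta[[v]]
    if (is.null(x)) stopf("variable '%s' absent from metadata", v)
    dv <- stats::dist(x)
    if (stats::sd(as.vector(dv)) == 0) stopf("constant distance matrix for '%s'", v)
    fit <- vegan::mantel(stats::as.dist(m), dv, method = method,
                         permutations = n_perm)
    tibble::tibble(variable = v, r = unname(fit$statistic),
                   p = fit$signif, n_perm = n_perm)
  }))
}
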