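REGIMES <- c("homogeneous_selection", "heterogeneous_selection",
             "dispersal_limitation", "homogenizing_dispersal", "neutral")

PHYLUM_POOL <- c("Proteobacteria", "Bacteroidota", "Firmicutes",
                 "Actinobacteriota", "Acidobacteriota", "Chloroflexi",
                 "Verrucomicrobiota", "Planctomycetota", "Desulfobacterota",
                 "Myxococcota")

#' Specify a synthetic community-assembly regime
#'
#' Bundles the generator settings for one simulated data set: the named
#' assembly regime, community sizes, sequencing depth and the regime's
#' mechanism parameters. Unset mechanism parameters get regime-specific
#' defaults (see below), which are the package's reference study conditions.
#'
#' @param regime one of homogeneous_selection, heterogeneous_selection,
#'   dispersal_limitation, homogenizing_dispersal, neutral.
#' @param n_samples number of samples (>= 2).
#' @param depth reads per sample (>= 100); 2000 default.
#' @param n_taxa metacommunity richness (>= 10).
#' @param selection_strength Gaussian niche-filter strength (>= 0); defaults
#'   to 2 under homogeneous selection (broad filter around one derived
#'   optimum) and 10 under heterogeneous selection (sharper filter swept
#'   along the niche axis).
#' @param drift_sd lognormal sd of a per-sample, per-taxon demographic
#'   lottery multiplying the selection weights (default 1 for heterogeneous
#'   selection, 0 otherwise).
#' @param dropout per-sample probability that a taxon fails to establish
#'   regardless of fit (default 0.5 under homogeneous selection, 0
#'   otherwise); this is the within-clade turnover that makes replicate
#'   selected communities differ in membership.
#' @param env_values per-sample environmental values; defaults to the focal
#'   clade's derived optimum (homogeneous selection) or an even quantile
#'   spread of the realized optima (heterogeneous selection).
#' @param seed integer seed expanded into per-stage child seeds.
#' @param sad_sigma lognormal species-abundance-distribution sigma of the
#'   metacommunity (1.5 default).
#' @param bm_sigma Brownian-motion rate for the per-taxon environmental
#'   optima (phylogenetic signal; 1 default on a unit-depth tree).
#' @param conservatism depth exponent for the optima simulation (see
#'   [sim_optima_bm()]); 0.3 default.
#' @param jump_size derived-niche trait jump (in units of `bm_sigma`) given
#'   to the focal clade under homogeneous selection; 5 default.
#' @param pool_fraction fraction of taxa reachable by one sample under
#'   dispersal limitation (0.2 default).
#' @param founding_factor size of the shared founding community under
#'   homogenizing dispersal, as a multiple of `depth` (2.5 default).
#' @return a `regime_spec` list.
#' @export
regime_spec <- function(regime, n_samples = 20, depth = 2000, n_taxa = 100,
                        selection_strength = NULL, drift_sd = NULL,
                        dropout = NULL, env_values = NULL, seed = 1,
                        sad_sigma = 1.5, bm_sigma = 1, conservatism = 0.3,
                        jump_size = 5, pool_fraction = 0.2,
                        founding_factor = 2.5) {
  regime <- match.arg(regime, REGIMES)
  if (n_samples < 2) stopf("n_samples must be >= 2")
  if (depth < 100) stopf("depth must be >= 100")
  if (n_taxa < 10) stopf("n_taxa must be >= 10")
  # regime-conditional defaults: the homogeneous regime uses a broad filter
  # around one derived optimum with establishment lottery dropout; the
  # heterogeneous regime uses a sharper filter swept across the niche axis
  if (is.null(selection_strength))
    selection_strength <- if (regime == "homogeneous_selection") 2 else 10
  if (is.null(drift_sd))
    drift_sd <- if (regime == "heterogeneous_selection") 1 else 0
  if (is.null(dropout))
    dropout <- if (regime == "homogeneous_selection") 0.5 else 0
  if (selection_strength < 0) stopf("selection_strength must be >= 0")
  if (drift_sd < 0) stopf("drift_sd must be >= 0")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  if (!is.null(env_values) && length(env_values) != n_samples)
    stopf("env_values must have one value per sample")
  structure(list(regime = regime, n_samples = as.integer(n_samples),
                 depth = as.integer(depth), n_taxa = as.integer(n_taxa),
                 selection_strength = selection_strength,
                 drift_sd = drift_sd, dropout = dropout,
                 env_values = env_values, seed = as.integer(seed),
                 sad_sigma = sad_sigma, bm_sigma = bm_sigma,
                 conservatism = conservatism, jump_size = jump_size,
                 pool_fraction = pool_fraction,
                 founding_factor = founding_factor),
            class = "regime_spec")
}

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Constant-rate birth process with exponential waiting times, rescaled so
#' every root-to-tip path length is exactly 1 (ultrametric, unit depth).
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed (deterministic output for a fixed seed).
#' @return rooted ultrametric `phylo` with tips `t1..tn`.
#' @export
sim_tree <- function(n_tips, seed = 1) {
  if (n_tips < 2) stopf("n_tips must be >= 2")
  tree <- with_seed(seed, ape::rphylo(n_tips, birth = 1, death = 0))
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- paste0("t", seq_len(n_tips))
  tree
}

#' Simulate environmental optima by Brownian motion along a tree
#'
#' Trait evolution from a root value of 0 with rate `sigma`, so a tip's
#' marginal variance is `sigma^2` times its root-to-tip path length and
#' close relatives get similar optima (phylogenetic niche signal).
#'
#' With `conservatism < 1` the tree's node depths are raised to that
#' exponent before simulating (an early-burst transform): trait variance
#' concentrates on deep branches, so trait clusters coincide with deep
#' clades. On an ultrametric unit-depth tree the marginal tip variance is
#' unchanged. `conservatism = 1` is plain Brownian motion.
#'
#' @param tree a `phylo` with branch lengths.
#' @param sigma Brownian rate (> 0).
#' @param seed integer seed.
#' @param conservatism depth exponent in (0, 1]; 0.3 default.
#' @return named numeric vector of per-tip optima.
#' @export
sim_optima_bm <- function(tree, sigma = 1, seed = 1, conservatism = 0.3) {
  if (sigma <= 0) stopf("sigma must be > 0")
  if (conservatism <= 0 || conservatism > 1)
    stopf("conservatism must be in (0, 1]")
  check_tree(tree)
  tr <- tree
  if (conservatism < 1) {
    h <- ape::node.depth.edgelength(tree)
    H <- max(h)
    if (H > 0) {
      hn <- (h / H)^conservatism
      tr$edge.length <- (hn[tree$edge[, 2]] - hn[tree$edge[, 1]]) * H
    }
  }
  with_seed(seed,
            ape::rTraitCont(tr, model = "BM", sigma = sigma, root.value = 0))
}

#' Simulate communities under a named assembly regime
#'
#' A lognormal metacommunity over the tree tips is sampled into per-sample
#' multinomial counts under the regime's mechanism. Selection regimes weight
#' taxa by a Gaussian niche filter \eqn{\exp(-s\,(optimum - env)^2)} (with
#' an establishment floor cutting negligibly-fit taxa): under homogeneous
#' selection every sample's environment matches the derived optimum of a
#' focal clade (a trait innovation on one lineage) and an establishment
#' lottery (`dropout`) turns over clade membership between samples; under
#' heterogeneous selection the environments sweep the realized niche axis so
#' different samples favour different clades. Dispersal limitation confines
#' each sample to a small independently-placed arc of a randomized taxon
#' ring (strong between-sample segregation); homogenizing dispersal draws
#' all samples from one shared realized founding community; neutral samples
#' the metacommunity directly.
#'
#' @param spec a [regime_spec()].
#' @param tree phylogeny with at least `spec$n_taxa` tips.
#' @param optima per-tip optima (defaults to [sim_optima_bm()] under the
#'   spec's child seed); required only by selection regimes.
#' @return count `asv_table` (rows sum to `spec$depth` exactly) with the
#'   generating truth attached as attribute `"truth"`.
#' @export
sim_communities <- function(spec, tree, optima = NULL) {
  stopifnot(inherits(spec, "regime_spec"))
  if (length(tree$tip.label) < spec$n_taxa)
    stopf("tree has fewer tips than n_taxa")
  taxa <- tree$tip.label[seq_len(spec$n_taxa)]
  seeds <- stage_seeds(spec$seed)
  n <- spec$n_samples; k <- spec$n_taxa
  selection <- spec$regime %in% c("homogeneous_selection",
                                  "heterogeneous_selection")
  focal_clade <- NULL
  if (selection && is.null(optima)) {
    optima <- sim_optima_bm(tree, sigma = spec$bm_sigma, seed = seeds$optima,
                            conservatism = spec$conservatism)
    if (spec$regime == "homogeneous_selection") {
      # derived niche: one mid-size clade carries a trait innovation, so the
      # shared environment selects a phylogenetically coherent set
      focal_clade <- pick_focal_clade(tree, taxa)
      optima[focal_clade] <- optima[focal_clade] +
        spec$jump_size * spec$bm_sigma
    }
  }
  env <- spec$env_values
  if (selection && is.null(env)) {
    opt_taxa <- optima[taxa]
    env <- if (spec$regime == "homogeneous_selection")
      rep(mean(optima[focal_clade]), n)
    else unname(stats::quantile(opt_taxa, seq(0.05, 0.95, length.out = n)))
  }
  counts <- with_seed(seeds$communities, {
    meta <- stats::rlnorm(k, meanlog = 0, sdlog = spec$sad_sigma)
    meta <- meta / sum(meta)
    draw <- function(w, depth = spec$depth) {
      w <- w / sum(w)
      as.integer(stats::rmultinom(1, depth, w))
    }
    m <- switch(spec$regime,
      neutral = t(vapply(seq_len(n), function(s) draw(meta), integer(k))),
      homogeneous_selection = ,
      heterogeneous_selection = {
        opt <- optima[taxa]
        t(vapply(seq_len(n), function(s) {
          filt <- exp(-spec$selection_strength * (opt - env[s])^2)
          filt[filt < 0.01] <- 0  # establishment floor: no straggler reads
          w <- meta * filt
          if (spec$drift_sd > 0) w <- w * stats::rlnorm(k, 0, spec$drift_sd)
          if (spec$dropout > 0) w[stats::runif(k) < spec$dropout] <- 0
          if (sum(w) == 0) w <- meta
          draw(w)
        }, integer(k)))
      },
      dispersal_limitation = {
        ring <- sample.int(k)
        m_pool <- max(2L, as.integer(round(spec$pool_fraction * k)))
        t(vapply(seq_len(n), function(s) {
          start <- sample.int(k, 1)
          pool <- ring[(start + seq_len(m_pool) - 2L) %% k + 1L]
          w <- numeric(k); w[pool] <- meta[pool]
          draw(w)
        }, integer(k)))
      },
      homogenizing_dispersal = {
        founding <- as.integer(round(spec$founding_factor * spec$depth))
        shared <- as.numeric(stats::rmultinom(1, founding, meta))
        t(vapply(seq_len(n), function(s) draw(shared), integer(k)))
      }
    )
    dimnames(m) <- list(paste0("s", seq_len(n)), taxa)
    m
  })
  tab <- asv_table(counts)
  attr(tab, "truth") <- list(spec = unclass(spec), env_values = env,
                             optima = if (selection) unname(optima[taxa]),
                             focal_clade = focal_clade)
  tab
}

# first internal node whose clade holds 15-30% of the analysed taxa
pick_focal_clade <- function(tree, taxa, lower = 0.15, upper = 0.30) {
  k <- length(taxa)
  nt <- length(tree$tip.label)
  best <- NULL
  for (node in (nt + 1L):(nt + tree$Nnode)) {
    tips <- tryCatch(ape::extract.clade(tree, node)$tip.label,
                     error = function(e) NULL)
    tips <- intersect(tips, taxa)
    if (length(tips) >= lower * k && length(tips) <= upper * k)
      return(tips)
    if (is.null(best) || abs(length(tips) - 0.2 * k) <
        abs(length(best) - 0.2 * k)) best <- tips
  }
  if (length(best) < 2) stopf("no usable focal clade in the tree")
  best
}

#' Simulate soil metadata and enzyme activities
#'
#' Soil variables are drawn around field-realistic baselines with
#' multiplicative lognormal noise; enzyme activities are constructed so the
#' expected allocation-vector angle sits below 45 degrees for
#' `limitation = "N"`, above for `"P"`, and exactly at 45 for `"balanced"`,
#' then jittered with the same multiplicative noise.
#'
#' @param sample_ids character vector of sample ids (or an ASV table whose
#'   row names are used).
#' @param limitation `"N"`, `"P"` or `"balanced"` — the ground-truth
#'   microbial nutrient limitation.
#' @param noise_sd lognormal sd of the multiplicative jitter (>= 0).
#' @param seed integer seed.
#' @param n_sites number of site labels (A, B, ...) assigned in contiguous
#'   blocks.
#' @return list with `metadata` and `enzymes` tibbles.
#' @export
sim_soil_enzymes <- function(sample_ids, limitation = c("balanced", "N", "P"),
                             noise_sd = 0.05, seed = 1, n_sites = 3) {
  limitation <- match.arg(limitation)
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is.character(sample_ids)) sample_ids <- rownames(as_asv_matrix(sample_ids))
  n <- length(sample_ids)
  site <- LETTERS[ceiling(seq_len(n) / ceiling(n / n_sites))]
  # baselines loosely matching subtropical biocrust topsoils
  soil_base <- c(pH = 7.6, EC = 180, SWC = 12, SOC = 45, TN = 4,
                 NH4_N = 40, NO3_N = 16, TP = 0.8, AP_avail = 45, AK = 250)
  # enzyme baselines: BG+CB = 80; AP and NAG+LAP set by the target angle
  enz_base <- switch(limitation,
    balanced = c(AG = 30, BG = 60, XS = 25, CB = 20, NAG = 60, LAP = 40,
                 AP = 100),                     # NAG+LAP = AP -> 45 degrees
    N = c(AG = 30, BG = 60, XS = 25, CB = 20, NAG = 72, LAP = 48,
          AP = 76.2),                           # angle ~ 38 degrees
    P = c(AG = 30, BG = 60, XS = 25, CB = 20, NAG = 45.7, LAP = 30.5,
          AP = 120)                             # angle ~ 52 degrees
  )
  with_seed(seed, {
    jitter <- function(base, nr) {
      vapply(base, function(b) b * exp(stats::rnorm(nr, 0, noise_sd)),
             numeric(nr))
    }
    soil <- jitter(soil_base, n)
    metadata <- tibble::tibble(sample_id = sample_ids, site = site) |>
      dplyr::bind_cols(tibble::as_tibble(soil)) |>
      derive_soil_ratios()
    enz <- jitter(enz_base, n)
    enzymes <- tibble::tibble(sample_id = sample_ids) |>
      dplyr::bind_cols(tibble::as_tibble(enz))
    list(metadata = metadata, enzymes = enzymes)
  })
}

#' Simulate a taxonomy table with a declared strategy split
#'
#' Random phylum labels from a fixed 10-phylum list (8 of which carry a
#' copiotroph/oligotroph assignment in [default_strategy_map()]), with blank
#' lower ranks.
#'
#' @param asv_ids character vector of ASV ids.
#' @param seed integer seed.
#' @return taxonomy tibble (`asv_id`, kingdom..genus).
#' @export
sim_taxonomy <- function(asv_ids, seed = 1) {
  with_seed(seed, {
    phy <- sample(PHYLUM_POOL, length(asv_ids), replace = TRUE)
    tibble::tibble(asv_id = asv_ids, kingdom = "Bacteria", phylum = phy,
                   class = "", order = "", family = "", genus = "")
  })
}

#' Simulate a complete five-input analysis bundle with known truth
#'
#' Generates tree, counts, taxonomy, metadata and enzyme activities from one
#' seed (expanded into per-stage child seeds), with the generating truth
#' recorded so every downstream stage can be checked against ground truth.
#'
#' @param spec a [regime_spec()].
#' @param limitation enzyme-scenario ground truth (see [sim_soil_enzymes()]).
#' @param noise_sd enzyme/soil jitter sd.
#' @return a `crust_bundle` list: `table`, `tree`, `taxonomy`, `metadata`,
#'   `enzymes`, `truth`.
#' @export
simulate_bundle <- function(spec, limitation = "balanced", noise_sd = 0.05) {
  seeds <- stage_seeds(spec$seed)
  tree <- sim_tree(spec$n_taxa, seed = seeds$tree)
  table <- sim_communities(spec, tree)
  soil <- sim_soil_enzymes(rownames(table), limitation = limitation,
                           noise_sd = noise_sd, seed = seeds$soil)
  taxonomy <- sim_taxonomy(colnames(table), seed = seeds$tree)
  truth <- c(attr(table, "truth"),
             list(limitation = limitation, noise_sd = noise_sd,
                  seeds = seeds))
  structure(list(table = table, tree = tree, taxonomy = taxonomy,
                 metadata = soil$metadata, enzymes = soil$enzymes,
                 truth = truth),
            class = "crust_bundle")
}

#' @export
print.crust_bundle <- function(x, ...) {
  cat(sprintf("<crust_bundle> regime=%s: %d samples x %d taxa, depth %d\n",
              x$truth$spec$regime, nrow(x$table), ncol(x$table),
              x$truth$spec$depth))
  invisible(x)
}

#' Write a bundle to a directory of plain-text files
#'
#' Emits `asv_table.tsv`, `taxonomy.tsv`, `tree.nwk`, `metadata.tsv`,
#' `enzymes.tsv` and `truth.json`.
#'
#' @param bundle a `crust_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asv_table(bundle$table, file.path(dir, "asv_table.tsv"))
  readr::write_tsv(bundle$taxonomy, file.path(dir, "taxonomy.tsv"))
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  readr::write_tsv(bundle$metadata, file.path(dir, "metadata.tsv"))
  readr::write_tsv(bundle$enzymes, file.path(dir, "enzymes.tsv"))
  jsonlite::write_json(bundle$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a bundle directory written by [write_bundle()]
#' @param dir bundle directory.
#' @return a `crust_bundle` (truth present if `truth.json` exists).
#' @export
read_bundle <- function(dir) {
  truth_path <- file.path(dir, "truth.json")
  structure(list(
    table = read_asv_table(file.path(dir, "asv_table.tsv")),
    tree = read_tree(file.path(dir, "tree.nwk")),
    taxonomy = read_taxonomy(file.path(dir, "taxonomy.tsv")),
    metadata = read_metadata(file.path(dir, "metadata.tsv")),
    enzymes = read_enzymes(file.path(dir, "enzymes.tsv")),
    truth = if (file.exists(truth_path)) jsonlite::read_json(truth_path,
                                                             simplifyVector = TRUE)
  ), class = "crust_bundle")
}
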