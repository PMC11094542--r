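SOIL_VARS <- c("pH", "EC", "SWC", "SOC", "TN", "NH4_N", "NO3_N", "TP",
               "AP_avail", "AK")
ENZYMES <- c("AG", "BG", "XS", "CB", "NAG", "LAP", "AP")
TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

read_id_table <- function(path, delim = "\t") {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

#' Read an ASV abundance table
#'
#' Delimited text with a header row; the first column is the ID column.
#' `orientation` declares whether rows are samples or ASVs; the returned
#' table is always samples x ASVs.
#'
#' @param path file path.
#' @param orientation `"samples"` (rows are samples, default) or `"asvs"`.
#' @param delim field delimiter, tab by default.
#' @param is_relative logical; set `TRUE` if the file stores relative
#'   abundances.
#' @return an [asv_table()].
#' @export
read_asv_table <- function(path, orientation = c("samples", "asvs"),
                           delim = "\t", is_relative = FALSE) {
  orientation <- match.arg(orientation)
  df <- read_id_table(path, delim)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- colnames(df[-1])[!vapply(df[-1], is.numeric, logical(1))][1]
    stopf("non-numeric values in column '%s' of %s", bad, path)
  }
  rownames(m) <- ids
  if (orientation == "asvs") m <- t(m)
  asv_table(m, is_relative = is_relative)
}

#' Write an ASV table
#' @param table table in any accepted form.
#' @param path output path.
#' @param delim field delimiter.
#' @return `path`, invisibly.
#' @export
write_asv_table <- function(table, path, delim = "\t") {
  tab <- asv_table(table, is_relative = is_relative_guess(table))
  readr::write_delim(as_tibble(tab), path, delim = delim)
  invisible(path)
}

#' Read a taxonomy table (ASV to kingdom..genus)
#'
#' Missing ranks may be empty strings (treated as unassigned).
#'
#' @inheritParams read_asv_table
#' @return tibble with columns `asv_id`, `kingdom`, `phylum`, `class`,
#'   `order`, `family`, `genus`.
#' @export
read_taxonomy <- function(path, delim = "\t") {
  df <- read_id_table(path, delim)
  names(df)[1] <- "asv_id"
  missing <- setdiff(TAX_RANKS, names(df))
  for (r in missing) df[[r]] <- ""
  df <- dplyr::select(df, "asv_id", dplyr::all_of(TAX_RANKS))
  df <- dplyr::mutate(df, dplyr::across(dplyr::all_of(TAX_RANKS),
                                        ~ tidyr::replace_na(as.character(.x), "")))
  if (anyDuplicated(df$asv_id)) stopf("duplicate ASV IDs in taxonomy")
  df
}

#' Read sample metadata with soil physicochemical variables
#'
#' Expects `sample_id`, `site` and the soil variables pH, EC, SWC, SOC, TN,
#' NH4_N, NO3_N, TP, AP_avail, AK. Derives the elemental ratios
#' `C_N = SOC/TN` and `C_P = SOC/TP`.
#'
#' @inheritParams read_asv_table
#' @return tibble of per-sample metadata including derived `C_N`, `C_P`.
#' @export
read_metadata <- function(path, delim = "\t") {
  df <- read_id_table(path, delim)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample IDs in metadata")
  present <- intersect(SOIL_VARS, names(df))
  for (v in present) {
    if (any(df[[v]] < 0, na.rm = TRUE) && v != "pH")
      stopf("negative concentration in metadata column '%s'", v)
  }
  derive_soil_ratios(df)
}

derive_soil_ratios <- function(df) {
  if (all(c("SOC", "TN") %in% names(df)) && !"C_N" %in% names(df)) {
    if (any(df$TN <= 0, na.rm = TRUE)) stopf("TN must be > 0 to derive C_N")
    df$C_N <- df$SOC / df$TN
  }
  if (all(c("SOC", "TP") %in% names(df)) && !"C_P" %in% names(df)) {
    if (any(df$TP <= 0, na.rm = TRUE)) stopf("TP must be > 0 to derive C_P")
    df$C_P <- df$SOC / df$TP
  }
  tibble::as_tibble(df)
}

#' Read per-sample enzyme activities
#'
#' Expects `sample_id` plus the seven hydrolases AG, BG, XS, CB
#' (carbon-acquiring), NAG, LAP (nitrogen-acquiring) and AP
#' (phosphorus-acquiring), in the activity units supplied.
#'
#' @inheritParams read_asv_table
#' @return tibble of per-sample activities.
#' @export
read_enzymes <- function(path, delim = "\t") {
  df <- read_id_table(path, delim)
  names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  missing <- setdiff(ENZYMES, names(df))
  if (length(missing))
    stopf("enzyme table lacks column(s): %s", paste(missing, collapse = ", "))
  for (e in ENZYMES)
    if (any(df[[e]] < 0, na.rm = TRUE)) stopf("negative activity in '%s'", e)
  tibble::as_tibble(df[, c("sample_id", ENZYMES)])
}

#' Read a rooted phylogeny from a Newick file
#'
#' The tree must carry branch lengths; absent or negative branch lengths are
#' errors, never defaulted.
#'
#' @param path Newick file path.
#' @return an [ape::phylo] object (rooted).
#' @export
read_tree <- function(path) {
  tree <- tryCatch(suppressWarnings(ape::read.tree(path)),
                   error = function(e) stopf("unparseable Newick: %s",
                                             conditionMessage(e)))
  if (is.null(tree)) stopf("unparseable Newick file: %s", path)
  check_tree(tree)
  tree
}

check_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("not a phylogenetic tree")
  if (is.null(tree$edge.length))
    stopf("tree has no branch lengths; they are required, not defaulted")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stopf("tree has missing or negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stopf("duplicate tip labels in tree")
  invisible(tree)
}

#' Patristic (cophenetic) distance matrix of a tree
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric matrix of tip-to-tip path-length distances.
#' @export
patristic_matrix <- function(tree) {
  check_tree(tree)
  stats::cophenetic(tree)
}

#' Cross-check the five inputs of an analysis bundle
#'
#' Reports ASVs absent from the tree or taxonomy and samples absent from the
#' metadata or enzyme table. Missing samples always abort a pipeline run;
#' ASVs missing from the tree are dropped (with a warning) or raised,
#' depending on `missing_asv`.
#'
#' @param table ASV table (any accepted form).
#' @param taxonomy taxonomy tibble (or `NULL`).
#' @param tree phylogeny (or `NULL`).
#' @param metadata sample metadata tibble (or `NULL`).
#' @param enzymes enzyme-activity tibble (or `NULL`).
#' @param missing_asv `"drop"` (default) or `"error"` for ASVs absent from
#'   the tree.
#' @return a `validation_report` list with character vectors
#'   `asvs_not_in_tree`, `asvs_not_in_taxonomy`, `samples_not_in_metadata`,
#'   `samples_not_in_enzymes` and logical `ok`.
#' @export
validate_bundle <- function(table, taxonomy = NULL, tree = NULL,
                            metadata = NULL, enzymes = NULL,
                            missing_asv = c("drop", "error")) {
  missing_asv <- match.arg(missing_asv)
  tab <- asv_table(table, is_relative = is_relative_guess(table))
  asvs <- colnames(tab)
  samples <- rownames(tab)
  rep <- list(
    asvs_not_in_tree = if (is.null(tree)) character(0)
                       else setdiff(asvs, tree$tip.label),
    asvs_not_in_taxonomy = if (is.null(taxonomy)) character(0)
                           else setdiff(asvs, taxonomy$asv_id),
    samples_not_in_metadata = if (is.null(metadata)) character(0)
                              else setdiff(samples, metadata$sample_id),
    samples_not_in_enzymes = if (is.null(enzymes)) character(0)
                             else setdiff(samples, enzymes$sample_id)
  )
  rep$ok <- length(rep$samples_not_in_metadata) == 0 &&
    length(rep$samples_not_in_enzymes) == 0 &&
    (missing_asv == "drop" || length(rep$asvs_not_in_tree) == 0)
  if (missing_asv == "error" && length(rep$asvs_not_in_tree))
    stopf("%d ASV(s) absent from the tree (e.g. '%s')",
          length(rep$asvs_not_in_tree), rep$asvs_not_in_tree[1])
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report>", if (x$ok) "consistent" else "INCONSISTENT", "\n")
  for (f in setdiff(names(x), "ok"))
    if (length(x[[f]]))
      cat(sprintf("  %s: %s\n", f, paste(x[[f]], collapse = ", ")))
  invisible(x)
}

# drop table ASVs absent from the tree (warn), per the validation contract
align_table_tree <- function(table, tree) {
  tab <- asv_table(table, is_relative = is_relative_guess(table))
  missing <- setdiff(colnames(tab), tree$tip.label)
  if (length(missing)) {
    warnf("dropping %d ASV(s) absent from the tree", length(missing))
    keep <- unclass_matrix(tab)[, setdiff(colnames(tab), missing), drop = FALSE]
    tab <- asv_table(keep, is_relative = FALSE)
  }
  tab
}
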