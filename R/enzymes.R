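#' Z-score enzyme activities across samples
#'
#' Standardizes each enzyme's activity column to mean 0 and population
#' standard deviation 1 (divisor n; set `bessel = TRUE` for the n-1 form).
#'
#' @param enzymes per-sample enzyme tibble (`sample_id` + activity columns).
#' @param bessel logical; use the n-1 denominator instead of n.
#' @return tibble of the same shape with standardized activities.
#' @export
enzyme_zscore <- function(enzymes, bessel = FALSE) {
  stopifnot(is.data.frame(enzymes))
  num <- names(enzymes)[vapply(enzymes, is.numeric, logical(1))]
  out <- enzymes
  for (v in num) {
    x <- out[[v]]
    if (bessel) {
      s <- stats::sd(x)
      if (is.na(s) || s == 0) stopf("constant vector in column '%s'", v)
      out[[v]] <- (x - mean(x)) / s
    } else {
      out[[v]] <- zscore_pop(x)
    }
  }
  tibble::as_tibble(out)
}

#' Eco-enzymatic stoichiometry ratios
#'
#' Per-sample log-ratio indices of enzymatic carbon, nitrogen and phosphorus
#' acquisition:
#' \deqn{C:N = \ln(BG)/\ln(LAP+NAG)}
#' \deqn{C:P = \ln(BG)/\ln(AP)}
#' \deqn{N:P = \ln(LAP+NAG)/\ln(AP)}
#' Each log argument must be strictly positive and no denominator activity
#' may be exactly 1 (log of 1 gives an undefined ratio).
#'
#' @param enzymes per-sample tibble with at least `BG`, `NAG`, `LAP`, `AP`.
#' @return tibble `sample_id`, `cn`, `cp`, `np`.
#' @export
stoich_ratios <- function(enzymes) {
  e <- check_enzyme_df(enzymes, c("BG", "NAG", "LAP", "AP"))
  nn <- e$LAP + e$NAG
  if (any(e$BG <= 0) || any(nn <= 0) || any(e$AP <= 0))
    stopf("log-ratio arguments must be > 0 (BG, LAP+NAG, AP)")
  if (any(log(nn) == 0) || any(log(e$AP) == 0))
    stopf("undefined ratio: denominator activity exactly 1")
  tibble::tibble(
    sample_id = e$sample_id,
    cn = log(e$BG) / log(nn),
    cp = log(e$BG) / log(e$AP),
    np = log(nn) / log(e$AP)
  )
}

#' Enzyme-allocation vector length and angle
#'
#' Summarizes relative C vs nutrient acquisition as a point
#' \eqn{x = (BG+CB)/(BG+CB+AP)}, \eqn{y = (BG+CB)/(BG+CB+NAG+LAP)};
#' `length` = \eqn{\sqrt{x^2+y^2}} indexes relative carbon limitation and
#' `angle_deg` is the polar angle of (x, y) from the positive x-axis in
#' degrees (the spreadsheet ATAN2(X, Y) convention, i.e. atan(y/x)). Angles
#' below 45 degrees indicate nitrogen limitation, above 45 phosphorus
#' limitation.
#'
#' @param enzymes per-sample tibble with `BG`, `CB`, `NAG`, `LAP`, `AP`.
#' @return tibble `sample_id`, `x`, `y`, `length`, `angle_deg`.
#' @export
enzyme_vectors <- function(enzymes) {
  e <- check_enzyme_df(enzymes, c("BG", "CB", "NAG", "LAP", "AP"))
  cc <- e$BG + e$CB
  dx <- cc + e$AP
  dy <- cc + e$NAG + e$LAP
  if (any(dx == 0) || any(dy == 0))
    stopf("zero denominator in vector metrics (all relevant activities zero)")
  x <- cc / dx
  y <- cc / dy
  tibble::tibble(
    sample_id = e$sample_id,
    x = x, y = y,
    length = sqrt(x^2 + y^2),
    angle_deg = atan2(y, x) * 180 / pi
  )
}

#' Quadrant classification of enzymatic stoichiometry
#'
#' Scatter-plot classifier with `x = (LAP+NAG)/AP` and `y = BG/(LAP+NAG)`;
#' deviation of each axis from 1 splits samples into four resource-limitation
#' categories. Boundary values (exactly 1) fall in the non-carbon-limited
#' class.
#'
#' @param x,y positive reals (vectorized).
#' @param tol boundary tolerance; values within `tol` of 1 count as 1.
#' @return character vector in `{"C_and_N","C_and_P","N","P"}`.
#' @export
classify_quadrant <- function(x, y, tol = 0) {
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(x <= 0) || any(y <= 0))
    stopf("quadrant axes must be finite and > 0")
  gx <- x > 1 + tol
  gy <- y > 1 + tol
  dplyr::case_when(
    gy & !gx ~ "C_and_N",
    gy & gx ~ "C_and_P",
    !gy & !gx ~ "N",
    TRUE ~ "P"
  )
}

#' Nutrient-limitation call from the vector angle
#'
#' @param angle_deg vector angles in degrees.
#' @param tol half-width of the balanced band around 45 degrees.
#' @return character vector in `{"N_limited","balanced","P_limited"}`.
#' @export
classify_vector <- function(angle_deg, tol = 0) {
  dplyr::case_when(
    angle_deg < 45 - tol ~ "N_limited",
    angle_deg > 45 + tol ~ "P_limited",
    TRUE ~ "balanced"
  )
}

#' Full per-sample nutrient-limitation summary
#'
#' Chains [stoich_ratios()], [enzyme_vectors()], the quadrant classifier
#' (on `(LAP+NAG)/AP` vs `BG/(LAP+NAG)`) and the vector-angle classifier into
#' one tidy per-sample table.
#'
#' @param enzymes per-sample enzyme tibble.
#' @param tol balanced-band half width for the vector call.
#' @return tibble with ratios, vector metrics, `quadrant` and `vector_call`.
#' @export
enzyme_limitation <- function(enzymes, tol = 0) {
  e <- check_enzyme_df(enzymes, c("BG", "CB", "NAG", "LAP", "AP"))
  ratios <- stoich_ratios(e)
  vec <- enzyme_vectors(e)
  qx <- (e$LAP + e$NAG) / e$AP
  qy <- e$BG / (e$LAP + e$NAG)
  dplyr::left_join(ratios, vec, by = "sample_id") |>
    dplyr::mutate(
      quad_x = qx, quad_y = qy,
      quadrant = classify_quadrant(qx, qy),
      vector_call = classify_vector(.data$angle_deg, tol = tol)
    )
}

check_enzyme_df <- function(enzymes, need) {
  stopifnot(is.data.frame(enzymes))
  if (!"sample_id" %in% names(enzymes)) {
    enzymes <- dplyr::rename(enzymes, sample_id = 1)
  }
  missing <- setdiff(need, names(enzymes))
  if (length(missing))
    stopf("enzyme table lacks column(s): %s", paste(missing, collapse = ", "))
  if (any(vapply(enzymes[need], function(v) any(v < 0), logical(1))))
    stopf("enzyme activities must be non-negative")
  tibble::as_tibble(enzymes)
}
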