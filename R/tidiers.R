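#' @rdname permanova_test
#' @param x a `crust_permanova` object.
#' @param ... unused.
#' @export
tidy.crust_permanova <- function(x, ...) {
  tibble::tibble(term = "group", df = x$df, pseudo_F = x$pseudo_F,
                 R2 = x$R2, p.value = x$p)
}

#' @rdname permanova_test
#' @export
glance.crust_permanova <- function(x, ...) {
  tibble::tibble(pseudo_F = x$pseudo_F, R2 = x$R2, p.value = x$p,
                 n_perm = x$n_perm)
}

#' @rdname pcoa_ordination
#' @param x a `crust_pcoa` object.
#' @param ... unused.
#' @export
tidy.crust_pcoa <- function(x, ...) x$scores

#' @rdname pcoa_ordination
#' @export
glance.crust_pcoa <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$scores),
    n_positive_eig = length(x$proportion_explained),
    prop_axis1 = x$proportion_explained[1],
    prop_axis2 = if (length(x$proportion_explained) > 1)
      x$proportion_explained[2] else NA_real_
  )
}

#' @rdname complexity_ratio_fit
#' @param x a `crust_fit` object.
#' @param ... unused.
#' @export
tidy.crust_fit <- function(x, ...) {
  tibble::tibble(term = c("(Intercept)", x$ratio),
                 estimate = c(x$intercept, x$slope))
}

#' @rdname complexity_ratio_fit
#' @export
glance.crust_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, r = x$r, p.value = x$p, n = x$n)
}
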