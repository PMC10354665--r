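# broom-style tidiers for the fitted/result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.ecc_size_profile <- function(x, ...) {
  x$peaks
}

#' @export
glance.ecc_size_profile <- function(x, ...) {
  tibble(
    n = length(x$sizes), median = x$median,
    peak1 = x$peaks$size[1], peak2 = x$peaks$size[2],
    q90_boundary = size_quantile_boundary(x, 0.9)
  )
}

#' @export
tidy.ecc_repeat_profile <- function(x, ...) {
  x$by_size_bin
}

#' @export
glance.ecc_repeat_profile <- function(x, ...) {
  tibble(n = length(x$repeat_len), fraction_ge2 = x$fraction_ge2,
         fraction_ge4 = x$fraction_ge4)
}

#' @export
tidy.ecc_enhancer_test <- function(x, ...) {
  x$scores
}

#' @export
glance.ecc_enhancer_test <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores), statistic = x$test$value,
    p_value = x$p_value, min_attainable_p = x$min_attainable_p,
    exact = x$test$exact
  )
}

#' @export
tidy.ecc_gene_abundance <- function(x, ...) {
  x$normalized |>
    pivot_longer(-"gene_id", names_to = "sample_id", values_to = "cpm") |>
    left_join(
      x$raw |>
        pivot_longer(-"gene_id", names_to = "sample_id", values_to = "raw"),
      by = c("gene_id", "sample_id")
    )
}

#' @export
glance.ecc_gene_abundance <- function(x, ...) {
  tibble(n_genes = nrow(x$raw), n_samples = length(x$totals),
         total_split_reads = sum(x$totals))
}
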