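#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy per-repeat cross-validation results
#'
#' @param x A [cv_r2()] object.
#' @param ... Unused.
#' @return A tibble with one row per repeat (`repeat_id`, `r2`).
#' @method tidy cv_r2
#' @export
tidy.cv_r2 <- function(x, ...) {
  tibble(repeat_id = seq_along(x$r2), r2 = x$r2)
}

#' One-row cross-validation summary
#'
#' @param x A [cv_r2()] object.
#' @param ... Unused.
#' @return A one-row tibble: `mean_r2`, `sd_r2`, `k`, `repeats`, `n`,
#'   `predictor`.
#' @method glance cv_r2
#' @export
glance.cv_r2 <- function(x, ...) {
  tibble(
    mean_r2 = mean(x$r2), sd_r2 = stats::sd(x$r2),
    k = x$k, repeats = x$repeats, n = x$n, predictor = x$predictor
  )
}

#' Tidy the junction table of a construct report
#'
#' @param x A `construct_report` from [assemble_construct()].
#' @param ... Unused.
#' @return The per-junction overlap tibble.
#' @method tidy construct_report
#' @export
tidy.construct_report <- function(x, ...) {
  x$junctions
}

#' One-row construct summary
#'
#' @param x A `construct_report` from [assemble_construct()].
#' @param ... Unused.
#' @return A one-row tibble: `status`, `construct_length`, `n_segments`.
#' @method glance construct_report
#' @export
glance.construct_report <- function(x, ...) {
  tibble(
    status = x$status,
    construct_length = if (is.na(x$construct)) NA_integer_ else nchar(x$construct),
    n_segments = nrow(x$segments)
  )
}
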