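#' Tidy a rank test result
#'
#' @param x A `rank_test` from [mann_whitney()] or [wilcoxon_signed_rank()].
#' @param ... Unused.
#' @return A one-row tibble: `test`, `statistic`, `statistic_z`, `p_value`,
#'   `n1`, `n2`.
#' @export
tidy.rank_test <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    statistic = x$statistic_u %||% x$statistic_v,
    statistic_z = x$statistic_z,
    p_value = x$p_value,
    n1 = x$n1, n2 = x$n2
  )
}

#' @rdname tidy.rank_test
#' @export
glance.rank_test <- function(x, ...) tidy(x, ...)

#' Tidy a permutation test result
#'
#' @param x A `perm_test` from [permutation_diff_test()].
#' @param ... Unused.
#' @return A one-row tibble: `observed_diff`, `p_value`, `n_perm`, `n_a`,
#'   `n_b`.
#' @export
tidy.perm_test <- function(x, ...) {
  tibble::tibble(observed_diff = x$observed_diff, p_value = x$p_value,
                 n_perm = x$n_perm, n_a = x$n_a, n_b = x$n_b)
}

#' Tidy a Mantel connectivity result
#'
#' @param x A `mantel_result` from [mantel_connectivity()].
#' @param ... Unused.
#' @return A one-row tibble: `r_mantel`, `ci_low`, `ci_high`, `n_birds`,
#'   `n_boot`.
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(r_mantel = x$r_mantel, ci_low = x$ci_low, ci_high = x$ci_high,
                 n_birds = x$n_birds, n_boot = x$n_boot)
}

#' @rdname tidy.mantel_result
#' @export
glance.mantel_result <- function(x, ...) tidy(x, ...)

#' Grid cells of a utilization distribution as a tibble
#'
#' @param x A `ud_grid`.
#' @param ... Unused.
#' @return A tibble: `x_km`, `y_km`, `density`, one row per grid cell.
#' @export
tidy.ud_grid <- function(x, ...) {
  tibble::tibble(
    x_km = rep(x$x, times = length(x$y)),
    y_km = rep(x$y, each = length(x$x)),
    density = as.vector(x$density)
  )
}
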