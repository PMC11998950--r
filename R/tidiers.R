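#' Tidy a Bland-Altman result
#'
#' @param x A `bland_altman` object.
#' @param ... Unused.
#' @return One row per agreement line (`mean_diff`, `loa_low`, `loa_high`).
#' @export
tidy.bland_altman <- function(x, ...) {
  tibble::tibble(
    term = c("mean_diff", "loa_low", "loa_high"),
    estimate = c(x$mean_diff, x$loa_low, x$loa_high)
  )
}

#' @rdname tidy.bland_altman
#' @return `glance()`: a one-row summary.
#' @export
glance.bland_altman <- function(x, ...) {
  tibble::tibble(mean_diff = x$mean_diff, sd_diff = x$sd_diff,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 good_agreement = x$good_agreement,
                 threshold = x$threshold, n = x$n)
}

#' Tidy an ICC reliability result
#'
#' @param x An `icc_reliability` object.
#' @param ... Unused.
#' @export
tidy.icc_reliability <- function(x, ...) {
  tibble::tibble(
    term = c("icc", "typical_error"),
    estimate = c(x$icc, x$typical_error),
    conf_low = c(x$conf_low, NA_real_),
    conf_high = c(x$conf_high, NA_real_)
  )
}

#' @rdname tidy.icc_reliability
#' @export
glance.icc_reliability <- function(x, ...) {
  tibble::tibble(icc = x$icc, conf_low = x$conf_low, conf_high = x$conf_high,
                 typical_error = x$typical_error, design = x$design,
                 type = x$type, n = x$n, k = x$k, degenerate = x$degenerate)
}

#' Tidy a validity simulation
#'
#' One row per capture condition with its Bland-Altman agreement against
#' the nadir reference.
#'
#' @param x A `validity_simulation` object.
#' @param ... Unused.
#' @export
tidy.validity_simulation <- function(x, ...) {
  purrr::map_dfr(names(x$bland_altman), function(m) {
    g <- glance(x$bland_altman[[m]])
    dplyr::bind_cols(tibble::tibble(method = m, reference = x$reference), g)
  })
}

#' @rdname tidy.validity_simulation
#' @export
glance.validity_simulation <- function(x, ...) {
  worst <- which.max(abs(purrr::map_dbl(x$bland_altman, "mean_diff")))
  tibble::tibble(
    n_samples = length(unique(x$measurements$sample_id)),
    n_conditions = length(x$conditions),
    anova_f = x$anova$statistic, anova_p = x$anova$p_value,
    partial_eta_sq = x$anova$partial_eta_sq,
    worst_condition = names(x$bland_altman)[worst],
    worst_mean_diff = x$bland_altman[[worst]]$mean_diff,
    seed = x$seed
  )
}
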