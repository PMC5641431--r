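#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the trace of a posterior sample
#'
#' One row per post-burn-in sample per run: generation, run id, log
#' likelihood, log prior and the sampled scalar parameters.
#' @param x a `posterior_sample`.
#' @param ... unused.
#' @export
tidy.posterior_sample <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$runs), function(r) {
    dplyr::mutate(x$runs[[r]]$trace, run = r, .before = 1)
  }))
}

#' @rdname tidy.posterior_sample
#' @export
glance.posterior_sample <- function(x, ...) {
  tr <- tidy.posterior_sample(x)
  tibble::tibble(
    n_runs = length(x$runs),
    n_samples = nrow(tr),
    mean_lnL = mean(tr$lnL),
    sdsf = if (length(x$runs) >= 2) as.numeric(sdsf(x)) else NA_real_,
    constrained = !is.null(x$constraints))
}

#' Tidy a marginal-likelihood estimate
#'
#' Per-step rows: the beta interval, sample count and contribution.
#' @param x a `marginal_likelihood`.
#' @param ... unused.
#' @export
tidy.marginal_likelihood <- function(x, ...) x$contributions

#' @rdname tidy.marginal_likelihood
#' @export
glance.marginal_likelihood <- function(x, ...) {
  tibble::tibble(log_ml = x$log_ml, se = x$se, steps = x$steps)
}

#' Plot the stepping-stone path
#'
#' Per-step mean sampled log-likelihood against the rung power beta; the
#' near-linear decay toward the prior is a quick sanity check that the
#' rungs bridge posterior and prior smoothly.
#' @param object a `marginal_likelihood`.
#' @param ... unused.
#' @export
autoplot.marginal_likelihood <- function(object, ...) {
  d <- object$contributions
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_low, y = .data$mean_lnL)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = expression(beta), y = "mean sampled lnL",
                  title = sprintf("stepping stone: log ML = %.2f (SE %.2f)",
                                  object$log_ml, object$se)) +
    ggplot2::theme_minimal()
}

#' Plot a homoplasy report
#'
#' Histogram of per-character homoplasy indices, colored by gonopod
#' region.
#' @param object a `homoplasy_report`.
#' @param ... unused.
#' @export
autoplot.homoplasy_report <- function(object, ...) {
  d <- object[!is.na(object$hi), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hi, fill = .data$region)) +
    ggplot2::geom_histogram(bins = 20, boundary = 0) +
    ggplot2::labs(x = "homoplasy index (HI)", y = "characters") +
    ggplot2::theme_minimal()
}

#' Plot a hypothesis comparison
#'
#' Bar chart of `2 delta ln` divergence from the molecular-tree baseline.
#' @param object a `hypothesis_comparison`.
#' @param ... unused.
#' @export
autoplot.hypothesis_comparison <- function(object, ...) {
  d <- object$table[object$table$hypothesis != "MOT", ]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$hypothesis,
                                                     .data$two_delta_ln_vs_MOT),
                                  y = .data$two_delta_ln_vs_MOT)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 10, linetype = 2) +
    ggplot2::labs(x = NULL, y = "2Δln vs molecular tree") +
    ggplot2::theme_minimal()
}

#' Export a homoplasy report as TSV
#' @param report a `homoplasy_report`.
#' @param path output file.
#' @export
write_homoplasy_tsv <- function(report, path) {
  d <- report
  d$dwell <- vapply(d$dwell, function(w) {
    paste(sprintf("%s:%.4f", names(w), w), collapse = ";")
  }, character(1))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @importFrom rlang .data
NULL
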