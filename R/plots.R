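# ggplot2 views of the package's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Labeled-fraction time courses of a simulation
#'
#' @param object a `label_simulation`.
#' @param pools pools to show (default: all tracked).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.label_simulation <- function(object, pools = object$program$pools, ...) {
  pr <- object$program
  df <- dplyr::bind_rows(lapply(pools, function(p) {
    i <- match(p, pr$pools)
    block <- object$state[, pr$offsets[[p]] + seq_len(pr$sizes[i]), drop = FALSE]
    tot <- rowSums(block)
    tibble::tibble(time = object$times, pool = p,
                   labeled = 1 - block[, 1] / pmax(tot, 1e-12))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$labeled)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::facet_wrap(~pool, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "fraction of molecules carrying 13C",
                  title = "Label wash-in by metabolite pool") +
    ggplot2::theme_minimal()
}

#' Concentration time courses of a totals trajectory
#'
#' @param object a `totals_trajectory`.
#' @param pools pools to show (default all).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.totals_trajectory <- function(object, pools = colnames(object$conc), ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(time = object$times, object$conc[, pools, drop = FALSE])),
    -"time", names_to = "pool", values_to = "conc")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$conc)) +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::facet_wrap(~pool, scales = "free_y") +
    ggplot2::labs(x = "time (min)", y = "concentration (mM, suspension volume)") +
    ggplot2::theme_minimal()
}

#' Per-metabolite chi-square contributions
#'
#' @param object a `chi_square_report`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.chi_square_report <- function(object, ...) {
  df <- object$per_group |>
    dplyr::mutate(block = paste(.data$metabolite, .data$fragment))
  ggplot2::ggplot(df, ggplot2::aes(.data$block, .data$chi2)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = expression(chi^2),
                  title = sprintf("Total chi-square %.3g over %d points",
                                  object$total, object$n)) +
    ggplot2::theme_minimal()
}

#' Measured versus simulated observables of a fit
#'
#' Points are measured means with error bars of one standard deviation; the
#' identity line marks perfect agreement.
#'
#' @param object a `fit_result`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fit_result <- function(object, ...) {
  if (is.null(object$reports)) stop("fit_result carries no chi-square reports")
  df <- dplyr::bind_rows(lapply(object$reports, function(r) r$rows)) |>
    dplyr::filter(.data$quantity != "conc")
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$mean)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0, color = "grey60") +
    ggplot2::geom_point(ggplot2::aes(color = .data$metabolite)) +
    ggplot2::labs(x = "simulated fraction", y = "measured fraction",
                  title = sprintf("Best fit, chi-square = %.3g", object$chi2)) +
    ggplot2::theme_minimal()
}

#' Flux confidence intervals on a log scale
#'
#' @param object a `flux_ensemble`.
#' @param level confidence level.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.flux_ensemble <- function(object, level = 0.99, ...) {
  ci <- confidence_intervals(object, level = level)
  ci <- ci[ci$best > 0, ]
  ggplot2::ggplot(ci, ggplot2::aes(stats::reorder(.data$reaction, .data$best),
                                   .data$best)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = pmax(.data$lo, 1e-12),
                                          ymax = .data$hi),
                             color = "steelblue", size = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "flux (mM/min)",
                  title = sprintf("%d%% confidence envelopes", round(level * 100))) +
    ggplot2::theme_minimal()
}
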