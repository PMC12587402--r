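#' Plot a campaign
#'
#' @param object A `formubo_campaign`.
#' @param type `"hypervolume"` for the convergence trace, `"objectives"`
#'   for the measured objective values by iteration, `"mae"` for the
#'   out-of-sample prediction-error trace.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot formubo_campaign
#' @export
autoplot.formubo_campaign <- function(object,
                                      type = c("hypervolume", "objectives",
                                               "mae"),
                                      ...) {
  type <- match.arg(type)
  if (type == "hypervolume") {
    hv <- hypervolume_trace(object)
    return(
      ggplot2::ggplot(hv, ggplot2::aes(.data$iteration, .data$hypervolume)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::labs(x = "iteration",
                      y = "hypervolume (standardized objectives)")
    )
  }
  if (type == "mae") {
    mae <- prediction_mae_trace(object)
    return(
      ggplot2::ggplot(mae, ggplot2::aes(.data$iteration, .data$mae)) +
        ggplot2::geom_line() + ggplot2::geom_point() +
        ggplot2::facet_wrap(~objective, scales = "free_y") +
        ggplot2::labs(x = "iteration", y = "mean absolute error (raw units)")
    )
  }
  led <- measured_rows(object$ledger, object$config$objectives)
  long <- tidyr::pivot_longer(led, dplyr::all_of(object$config$objectives),
                              names_to = "objective")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$iteration), .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$route)) +
    ggplot2::facet_wrap(~objective, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = "measured objective")
}

#' Plot a surrogate Pareto front
#'
#' Pairwise scatter of the predicted objective values of the candidates on
#' the front.
#'
#' @param front A tibble from [nsga2_front()].
#' @return A ggplot object.
#' @export
plot_pareto_front <- function(front) {
  objs <- setdiff(names(front), u_cols(front))
  if (length(objs) < 2L) {
    abort("front needs at least two objective columns",
          class = "formubo_config_error")
  }
  pairs <- utils::combn(objs, 2L, simplify = FALSE)
  long <- purrr::map_dfr(pairs, function(p) {
    tibble::tibble(pair = paste(p[1], "vs", p[2]),
                   x = front[[p[1]]], y = front[[p[2]]])
  })
  ggplot2::ggplot(long, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~pair, scales = "free") +
    ggplot2::labs(x = "predicted objective (first of pair)",
                  y = "predicted objective (second of pair)")
}

#' Plot a melt curve with its derivative maximum
#'
#' @param curve A [melt_curve()] tibble.
#' @param ... Passed to [tm_from_curve()].
#' @return A ggplot object with the estimated Tm as a vertical line.
#' @export
plot_melt_curve <- function(curve, ...) {
  tm <- tryCatch(tm_from_curve(curve, ...), error = function(e) NA_real_)
  p <- ggplot2::ggplot(curve,
                       ggplot2::aes(.data$temperature_C, .data$ratio)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "temperature (°C)", y = "350/330 nm ratio")
  if (is.finite(tm)) {
    p <- p + ggplot2::geom_vline(xintercept = tm, linetype = "dashed")
  }
  p
}
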