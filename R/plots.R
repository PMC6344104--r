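#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_ribbon
#'   geom_col facet_wrap labs theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Plot bootstrap one-step-ahead predictions against observations
#'
#' One panel per variable: observed series (points and line), bootstrap
#' mean prediction, and the 95% interval (mean +- 1.96 sd) as a ribbon.
#'
#' @param object A `dbn_eval` from [evaluate_model()].
#' @param variables Optional subset of variables to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dbn_eval
#' @export
autoplot.dbn_eval <- function(object, variables = NULL, ...) {
  d <- object$predictions
  if (!is.null(variables)) d <- d[d$variable %in% variables, , drop = FALSE]
  ggplot(d, aes(x = .data$year)) +
    geom_ribbon(aes(ymin = .data$lo95, ymax = .data$hi95), fill = "grey80") +
    geom_line(aes(y = .data$boot_mean), colour = "steelblue") +
    geom_point(aes(y = .data$observed), shape = 1) +
    facet_wrap(~variable, scales = "free_y") +
    labs(x = "year", y = "standardized value") +
    theme_minimal()
}

#' Plot the model-comparison SSE table
#'
#' @param object A `dbn_comparison` from [compare_models()].
#' @param ... Unused.
#' @return A ggplot object: grouped bars of per-variable SSE by model.
#' @method autoplot dbn_comparison
#' @export
autoplot.dbn_comparison <- function(object, ...) {
  d <- tidy(object)
  ggplot(d, aes(x = .data$variable, y = .data$sse, fill = .data$model)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "bootstrap mean SSE", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot scenario responses
#'
#' @param object A `dbn_scenario` from [run_scenario()], or a list of them
#'   passed to [plot_scenarios()].
#' @param ... Unused.
#' @return A ggplot object: per-variable mean difference bars.
#' @method autoplot dbn_scenario
#' @export
autoplot.dbn_scenario <- function(object, ...) {
  d <- object$summary
  d$label <- object$spec$label
  scenario_bars(d)
}

#' Compare several press scenarios in one figure
#'
#' @param scenarios List of `dbn_scenario` objects (e.g. the 1.0, 1.5 and
#'   3.0 degree presses).
#' @return A ggplot object.
#' @export
plot_scenarios <- function(scenarios) {
  d <- purrr::map_dfr(scenarios, function(s) {
    out <- s$summary
    out$label <- s$spec$label
    out
  })
  scenario_bars(d)
}

scenario_bars <- function(d) {
  ggplot(d, aes(x = .data$variable, y = .data$mean_diff, fill = .data$label)) +
    geom_col(position = position_dodge()) +
    labs(x = NULL, y = "mean difference (scenario - baseline)", fill = NULL) +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
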