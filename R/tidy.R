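# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a steady-state distribution
#'
#' @param x A [solve_steady_state()] result.
#' @param ... Unused.
#' @return Tibble with `state` and `probability`.
#' @export
tidy.cpp_steady <- function(x, ...) {
  tibble::tibble(state = seq_len(x$n_states), probability = x$pi)
}

#' @rdname tidy.cpp_steady
#' @export
glance.cpp_steady <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, residual = x$residual, method = x$method)
}

#' Tidy a transition system
#'
#' @param x A `cpp_ts` (or aggregated `cpp_agg`) object.
#' @param ... Unused.
#' @return The labelled edge list as a tibble.
#' @export
tidy.cpp_ts <- function(x, ...) x$edges

#' @rdname tidy.cpp_ts
#' @export
glance.cpp_ts <- function(x, ...) {
  tibble::tibble(n_states = x$n_states, n_transitions = nrow(x$edges),
                 n_groups = nrow(x$groups),
                 aggregated = inherits(x, "cpp_agg"))
}

#' Tidy a solved pathway
#'
#' @param x A [solve_pathway()] result.
#' @param ... Unused.
#' @return The performance report tibble.
#' @export
tidy.cpp_solution <- function(x, ...) x$report

#' @rdname tidy.cpp_solution
#' @export
glance.cpp_solution <- function(x, ...) {
  tibble::tibble(n_states = x$ts$n_states, full_states = x$full_states,
                 residual = x$steady$residual,
                 throughput = x$report$value[x$report$measure == "throughput"])
}

#' Tidy a fluid steady state
#'
#' @param x A [fluid_steady_state()] result.
#' @param ... Unused.
#' @return Tibble with `group`, `local`, `count`.
#' @export
tidy.cpp_fluid_ss <- function(x, ...) {
  tibble::tibble(group = x$vars$group, local = x$vars$local,
                 count = as.numeric(x$counts))
}

#' @rdname tidy.cpp_fluid_ss
#' @export
glance.cpp_fluid_ss <- function(x, ...) {
  tibble::tibble(converged = x$converged, time = x$time, residual = x$residual)
}

#' Plot fluid trajectories
#'
#' @param object A [integrate_odes()] result.
#' @param locals Optional subset of local-state names to show.
#' @param ... Unused.
#' @return A ggplot object: counts over time, coloured by local state.
#' @export
autoplot.cpp_fluid <- function(object, locals = NULL, ...) {
  d <- object
  if (!is.null(locals)) d <- dplyr::filter(d, .data$local %in% locals)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$count,
                                  colour = .data$local)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)", y = "expected count", colour = NULL)
}

#' Plot a passage-time distribution
#'
#' @param object A `cpp_cdf` from [passage_time_cdf()].
#' @param ... Unused.
#' @return A ggplot object of the CDF.
#' @export
autoplot.cpp_cdf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$cdf)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "time (days)", y = "P(discharged by t)")
}

#' Plot a resource sweep
#'
#' @param object A [scenario_resource_sweep()] result.
#' @param x,facets Resource names for the x axis and facet rows/columns;
#'   default the last and remaining swept resources.
#' @param ... Unused.
#' @return A ggplot object: throughput against the x resource, faceted by
#'   the others.
#' @export
autoplot.cpp_sweep <- function(object, x = NULL, facets = NULL, ...) {
  rs <- attr(object, "resources")
  x <- x %||% rs[length(rs)]
  facets <- facets %||% setdiff(rs, x)
  p <- ggplot2::ggplot(object, ggplot2::aes(.data[[x]], .data$throughput)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = x, y = "throughput (patients/day)")
  if (length(facets))
    p <- p + ggplot2::facet_grid(
      rows = if (length(facets) > 1) ggplot2::vars(.data[[facets[2]]]),
      cols = ggplot2::vars(.data[[facets[1]]]), labeller = "label_both")
  p
}

#' Plot a saturation curve
#'
#' @param object A [scenario_max_input()] result.
#' @param ... Unused.
#' @return A ggplot object: throughput against mean input, with the
#'   capacity bound.
#' @export
autoplot.cpp_saturation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$input, .data$throughput)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = attr(object, "capacity"),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean input (patients/day)",
                  y = "throughput (patients/day)")
}
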