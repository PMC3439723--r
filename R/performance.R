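# Steady-state performance measures: resource utilisation and throughput.

resolve_resource <- function(ts, resource) {
  meta <- ts$model$meta
  if (!is.null(meta$resources) && resource %in% meta$resources$resource) {
    r <- meta$resources[meta$resources$resource == resource, ]
    cp <- ts$groups$copies[ts$groups$group == r$group[1]]
    return(list(group = r$group[1], busy = r$busy[1], copies = cp))
  }
  # heuristic: a group one of whose local states is the `_busy` derivative
  # matching the resource name
  for (gi in seq_len(nrow(ts$groups))) {
    g <- ts$groups$group[gi]
    locs <- ts$local_names[[g]]
    hit <- locs[grepl("_busy", locs, fixed = TRUE) &
                  startsWith(locs, resource)]
    if (length(hit))
      return(list(group = g, busy = hit[1], copies = ts$groups$copies[gi]))
  }
  abort(sprintf("unknown resource '%s' (no group with a matching busy state)", resource))
}

#' Steady-state resource utilisation
#'
#' The expected number of busy copies of a resource divided by its number
#' of copies: for a single copy, the summed probability of the states in
#' which its busy derivative is occupied.
#'
#' @param pi A [solve_steady_state()] result, or a bare probability vector.
#' @param ts The transition system (full or aggregated) `pi` was solved on.
#' @param resource Resource name as declared in the model metadata (for
#'   generated pathway models, the department's resource, e.g. `"Bed"`), or
#'   any name whose `_busy` derivative identifies the group.
#' @return Utilisation in `[0, 1]`.
#' @export
resource_utilisation <- function(pi, ts, resource) {
  if (inherits(pi, "cpp_steady")) pi <- pi$pi
  stopifnot(length(pi) == ts$n_states)
  r <- resolve_resource(ts, resource)
  busy <- local_counts(ts, r$group, r$busy)
  sum(pi * busy) / r$copies
}

#' Steady-state action flux
#'
#' Expected number of completions of an action per day: the steady-state
#' probability of each state weighted by the total rate of that action's
#' transitions enabled there.
#'
#' @inheritParams resource_utilisation
#' @param action Action label.
#' @return Flux in 1/day.
#' @export
action_flux <- function(pi, ts, action) {
  if (inherits(pi, "cpp_steady")) pi <- pi$pi
  e <- ts$edges[ts$edges$action == action, ]
  if (!nrow(e)) abort(sprintf("action '%s' is not present in the model", action))
  out <- tapply(e$rate, e$src, sum)
  sum(pi[as.integer(names(out))] * out)
}

#' System throughput
#'
#' The rate of patient discharges per day: the discharge rate times the
#' expected number of busy copies of the final resource (whose release is
#' the discharge activity). This equals the steady-state flux of the
#' discharge action.
#'
#' @inheritParams resource_utilisation
#' @param discharge_action,discharge_rate,final_resource The activity that
#'   frees the final resource, its rate (1/day) and that resource's name;
#'   defaults are taken from the model metadata when present.
#' @return Throughput in patients/day.
#' @export
throughput <- function(pi, ts, discharge_action = NULL, discharge_rate = NULL,
                       final_resource = NULL) {
  d <- ts$model$meta$discharge
  discharge_action <- discharge_action %||% d$action
  discharge_rate <- discharge_rate %||% d$rate
  final_resource <- final_resource %||% d$resource
  if (is.null(discharge_action) || is.null(discharge_rate) || is.null(final_resource))
    abort("discharge action, rate and final resource must be given or present in model metadata")
  if (!discharge_action %in% ts$edges$action)
    abort(sprintf("action '%s' is not present in the model", discharge_action))
  if (inherits(pi, "cpp_steady")) pi <- pi$pi
  r <- resolve_resource(ts, final_resource)
  busy <- local_counts(ts, r$group, r$busy)
  discharge_rate * sum(pi * busy)
}

#' Performance report of a solved pathway
#'
#' @inheritParams resource_utilisation
#' @return A tibble with one row per declared resource (`measure =
#'   "utilisation"`, with `copies`) and a final `throughput` row
#'   (patients/day).
#' @export
performance_report <- function(pi, ts) {
  res <- ts$model$meta$resources
  if (is.null(res)) abort("model metadata declares no resources; use resource_utilisation() directly")
  rows <- purrr::map_dfr(res$resource, function(rn) {
    r <- resolve_resource(ts, rn)
    tibble::tibble(measure = "utilisation", resource = rn,
                   copies = as.integer(r$copies),
                   value = resource_utilisation(pi, ts, rn))
  })
  dplyr::bind_rows(rows, tibble::tibble(
    measure = "throughput", resource = NA_character_, copies = NA_integer_,
    value = throughput(pi, ts)))
}

#' Solve a pathway model end to end
#'
#' Explores the state space, optionally lumps replicas, solves the steady
#' state and computes the performance report.
#'
#' @param model A [cpp_model()] (typically from [assemble_system()]).
#' @param aggregate Lump replica groups before solving (the measures are
#'   invariant under the abstraction).
#' @param max_states State budget for exploration.
#' @return An object of class `cpp_solution`: list with `ts`, `steady`,
#'   `report` and `full_states` (the unlumped count).
#' @export
#' @examples
#' sol <- solve_pathway(assemble_system(simple_pathway_config()))
#' sol$report
solve_pathway <- function(model, aggregate = TRUE, max_states = 1e6) {
  ts <- explore_state_space(model, max_states = max_states)
  full_states <- ts$n_states
  if (aggregate) ts <- aggregate_states(ts)
  st <- solve_steady_state(ts)
  structure(list(ts = ts, steady = st,
                 report = performance_report(st, ts),
                 full_states = full_states), class = "cpp_solution")
}

#' @export
print.cpp_solution <- function(x, ...) {
  cat(sprintf("<cpp_solution> %d states solved (%d before aggregation)\n",
              x$ts$n_states, x$full_states))
  print(x$report)
  invisible(x)
}

#' Write a performance report
#'
#' @param report Tibble from [performance_report()].
#' @param path Output path; format chosen by extension (`.csv` or `.json`).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(report, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}
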