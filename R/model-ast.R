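#' @useDynLib cpepa, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom rlang abort .data `%||%`
#' @importFrom methods as
#' @import tibble
NULL

# ---- activity and process expressions -------------------------------------

#' Create an activity
#'
#' An activity pairs an action label with an exponential completion rate.
#' The rate is the reciprocal of the mean duration, in units of 1/day.
#'
#' @param action Character action label, e.g. `"do_FAST"`.
#' @param rate Positive completion rate (1/day).
#' @return An object of class `cpp_activity`.
#' @export
#' @examples
#' cpp_activity("scan", 8)
cpp_activity <- function(action, rate) {
  stopifnot(is.character(action), length(action) == 1L, nzchar(action))
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    abort(sprintf("activity '%s': rate must be a positive finite number", action))
  structure(list(action = action, rate = as.numeric(rate)), class = "cpp_activity")
}

#' Process-expression constructors
#'
#' Bodies of sequential components are built from prefixes
#' (`(action, rate).Continuation`), binary choice (`+`), and references to
#' named components. A weighted prefix scales the rate by a branch
#' probability, so a routing choice is an ordinary choice over scaled
#' prefixes.
#'
#' @param activity A [cpp_activity()].
#' @param continuation,name Component name referred to.
#' @param left,right Process expressions.
#' @param weight Branch probability in (0, 1]; the effective rate of the
#'   prefix is `weight * rate`.
#' @return A process-expression node (classes `cpp_prefix`, `cpp_choice`,
#'   `cpp_ref`).
#' @name process-expr
NULL

#' @rdname process-expr
#' @export
cpp_prefix <- function(activity, continuation, weight = NULL) {
  stopifnot(inherits(activity, "cpp_activity"))
  if (is.character(continuation)) continuation <- cpp_ref(continuation)
  stopifnot(inherits(continuation, "cpp_ref"))
  if (!is.null(weight)) {
    stopifnot(is.numeric(weight), length(weight) == 1L, weight > 0, weight <= 1)
    weight <- as.numeric(weight)
  }
  structure(list(activity = activity, continuation = continuation, weight = weight),
            class = "cpp_prefix")
}

#' @rdname process-expr
#' @export
cpp_choice <- function(left, right) {
  stopifnot(is_process_expr(left), is_process_expr(right))
  structure(list(left = left, right = right), class = "cpp_choice")
}

#' @rdname process-expr
#' @export
cpp_ref <- function(name) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  structure(list(name = name), class = "cpp_ref")
}

is_process_expr <- function(x) {
  inherits(x, "cpp_prefix") || inherits(x, "cpp_choice") || inherits(x, "cpp_ref")
}

# ---- component definitions -------------------------------------------------

#' Define a sequential component
#'
#' A defining equation `name = body`, where `body` is a process expression.
#' Components are either patient-state components (places where patients are
#' treated) or resource components (idle/busy pairs of staff, equipment or
#' waiting rooms).
#'
#' @param name Component name.
#' @param body Process expression.
#' @param kind `"state"` or `"resource"`.
#' @return An object of class `cpp_component`.
#' @export
cpp_component <- function(name, body, kind = c("state", "resource")) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name), is_process_expr(body))
  kind <- match.arg(kind)
  structure(list(name = name, body = body, kind = kind), class = "cpp_component")
}

# ---- system expressions ----------------------------------------------------

#' System-expression constructors
#'
#' The system description composes component instances by cooperation over a
#' set of shared action labels. `cpp_parallel()` is cooperation over the
#' empty set (interleaving), and `cpp_replicate()` stands for `Name[N]`, N
#' interleaved copies of a component.
#'
#' @param left,right System expressions (or component names, taken as
#'   single instances).
#' @param sync Character vector of shared action labels.
#' @param component Component name to replicate.
#' @param copies Positive integer number of copies.
#' @return A system-expression node (classes `cpp_coop`, `cpp_rep`,
#'   `cpp_inst`).
#' @name system-expr
NULL

#' @rdname system-expr
#' @export
cpp_coop <- function(left, right, sync = character()) {
  left <- as_system_expr(left); right <- as_system_expr(right)
  stopifnot(is.character(sync))
  structure(list(left = left, right = right, sync = sync), class = "cpp_coop")
}

#' @rdname system-expr
#' @export
cpp_parallel <- function(left, right) cpp_coop(left, right, character())

#' @rdname system-expr
#' @export
cpp_replicate <- function(component, copies) {
  stopifnot(is.character(component), length(component) == 1L)
  copies <- as.integer(copies)
  if (is.na(copies) || copies < 1L) abort("replication copies must be >= 1")
  structure(list(component = component, copies = copies), class = "cpp_rep")
}

#' @rdname system-expr
#' @export
cpp_instance <- function(component) {
  stopifnot(is.character(component), length(component) == 1L)
  structure(list(component = component), class = "cpp_inst")
}

as_system_expr <- function(x) {
  if (is.character(x)) return(cpp_instance(x))
  if (inherits(x, c("cpp_coop", "cpp_rep", "cpp_inst"))) return(x)
  abort("not a system expression")
}

# ---- the model -------------------------------------------------------------

#' Assemble a clinical-pathway process-algebra model
#'
#' A model is a five-part object: patient-state components, resource
#' components, the set of activities (implied by the defining equations),
#' the resource constraints attached to activities (implied by the shared
#' action labels of the system expression), and the rate rule for shared
#' activities (cooperation proceeds at the minimum of the participants'
#' apparent rates). `meta` carries reporting metadata: which local state of
#' each resource is its busy state, and the discharge action/rate.
#'
#' @param components List of [cpp_component()] objects.
#' @param system System expression composing them.
#' @param meta Named list of metadata; recognised entries are
#'   `busy_states` (named character, resource group -> busy local state),
#'   `discharge` (list with `action`, `rate`, `resource`), and
#'   `entry` (list with `action`, `rate`).
#' @param validate Check well-formedness (default `TRUE`).
#' @return An object of class `cpp_model`.
#' @seealso [parse_model()], [assemble_system()], [stroke_model()]
#' @export
cpp_model <- function(components, system, meta = list(), validate = TRUE) {
  stopifnot(is.list(components), all(vapply(components, inherits, TRUE, "cpp_component")))
  names(components) <- vapply(components, `[[`, "", "name")
  m <- structure(list(components = components, system = as_system_expr(system),
                      meta = meta), class = "cpp_model")
  if (validate) validate_model(m)
  m
}

#' @export
print.cpp_model <- function(x, ...) {
  cat(sprintf("<cpp_model> %d components, %d activities\n",
              length(x$components), nrow(model_activities(x))))
  cat(unparse_model(x))
  invisible(x)
}

# Flatten a component body into its prefix table: one row per enabled prefix.
prefixes_of <- function(expr) {
  if (inherits(expr, "cpp_prefix")) {
    w <- expr$weight %||% 1
    return(tibble::tibble(action = expr$activity$action,
                          rate = expr$activity$rate * w,
                          base_rate = expr$activity$rate,
                          weight = w,
                          target = expr$continuation$name))
  }
  if (inherits(expr, "cpp_choice"))
    return(dplyr::bind_rows(prefixes_of(expr$left), prefixes_of(expr$right)))
  if (inherits(expr, "cpp_ref"))
    abort("a bare component reference cannot stand as a defining body")
  abort("not a process expression")
}

#' Prefix table of a component
#'
#' One row per enabled prefix of the defining equation of `name`: action
#' label, effective rate (branch weight times base rate) and target
#' component.
#'
#' @param model A [cpp_model()].
#' @param name Component name.
#' @return A tibble with columns `action`, `rate`, `base_rate`, `weight`,
#'   `target`.
#' @export
component_prefixes <- function(model, name) {
  comp <- model$components[[name]]
  if (is.null(comp)) abort(sprintf("unknown component '%s'", name))
  prefixes_of(comp$body)
}

#' Activities of a model
#'
#' @param model A [cpp_model()].
#' @return Tibble with one row per (action, rate) pair appearing in any
#'   defining equation.
#' @export
model_activities <- function(model) {
  purrr::map_dfr(model$components, function(cmp) prefixes_of(cmp$body)) |>
    dplyr::distinct(.data$action, .data$base_rate) |>
    dplyr::rename(rate = "base_rate") |>
    dplyr::arrange(.data$action)
}

#' Derivative set of a component
#'
#' All local states a sequential component can reach by following its
#' prefixes and choices transitively, including the component itself. For a
#' resource idle/busy pair this is the two-element set of its states.
#'
#' @param model A [cpp_model()].
#' @param name Component name.
#' @return Character vector of component names, in breadth-first order from
#'   `name`.
#' @export
#' @examples
#' m <- parse_model("P = (a, 1).Q; Q = (b, 2).P; P[1]")
#' derivative_set(m, "P")
derivative_set <- function(model, name) {
  if (is.null(model$components[[name]])) abort(sprintf("unknown component '%s'", name))
  seen <- character(); queue <- name
  while (length(queue)) {
    nm <- queue[[1]]; queue <- queue[-1]
    if (nm %in% seen) next
    seen <- c(seen, nm)
    tg <- component_prefixes(model, nm)$target
    queue <- c(queue, setdiff(tg, seen))
  }
  seen
}

# ---- apparent rates --------------------------------------------------------

#' Apparent rate of an action
#'
#' The total rate at which an expression can perform a given action: the
#' sum of the rates of its enabled prefixes of that action. For system
#' expressions the rate is evaluated in the initial configuration —
#' additive over parallel composition and replication, and the minimum of
#' the two operands' apparent rates for an action in a cooperation set.
#'
#' @param model A [cpp_model()] providing the defining equations.
#' @param expr A process or system expression, or a component name.
#' @param action Action label.
#' @return Nonnegative apparent rate (1/day); 0 if the action is not
#'   enabled.
#' @export
apparent_rate <- function(model, expr, action) {
  if (is.character(expr)) expr <- cpp_ref(expr)
  app <- function(e) {
    if (inherits(e, "cpp_ref")) return(app_local(model, e$name, action))
    if (inherits(e, "cpp_prefix"))
      return(if (e$activity$action == action) e$activity$rate * (e$weight %||% 1) else 0)
    if (inherits(e, "cpp_choice")) return(app(e$left) + app(e$right))
    if (inherits(e, "cpp_inst")) return(app_local(model, e$component, action))
    if (inherits(e, "cpp_rep")) return(e$copies * app_local(model, e$component, action))
    if (inherits(e, "cpp_coop")) {
      l <- app(e$left); r <- app(e$right)
      if (action %in% e$sync) return(min(l, r)) else return(l + r)
    }
    abort("not an expression")
  }
  app(expr)
}

app_local <- function(model, name, action) {
  pf <- component_prefixes(model, name)
  sum(pf$rate[pf$action == action])
}

# ---- validation ------------------------------------------------------------

system_leaves <- function(sys) {
  if (inherits(sys, "cpp_coop")) return(c(system_leaves(sys$left), system_leaves(sys$right)))
  list(sys)
}

# action labels appearing syntactically in the derivative closure of a
# system expression's components
syntactic_actions <- function(model, sys) {
  comps <- vapply(system_leaves(sys), `[[`, "", "component")
  locals <- unique(unlist(lapply(unique(comps), derivative_set, model = model)))
  unique(unlist(lapply(locals, function(nm) component_prefixes(model, nm)$action)))
}

#' Validate a model
#'
#' Checks: unique component names; every referenced continuation defined;
#' all rates positive; branch weights of each choice summing to at most 1
#' per action where weights are used; replication counts at least one; and
#' each cooperation-set action occurring syntactically in both operands.
#'
#' @param model A [cpp_model()].
#' @return `model`, invisibly; errors describe the first violation found.
#' @export
validate_model <- function(model) {
  nms <- vapply(model$components, `[[`, "", "name")
  if (anyDuplicated(nms)) abort(sprintf("duplicate component definition '%s'",
                                        nms[duplicated(nms)][1]))
  for (cmp in model$components) {
    pf <- prefixes_of(cmp$body)
    bad <- setdiff(pf$target, nms)
    if (length(bad)) abort(sprintf("component '%s' refers to undefined component '%s'",
                                   cmp$name, bad[1]))
    if (any(pf$rate <= 0)) abort(sprintf("component '%s' has a nonpositive rate", cmp$name))
  }
  check_sys <- function(sys) {
    if (inherits(sys, "cpp_coop")) {
      la <- syntactic_actions(model, sys$left)
      ra <- syntactic_actions(model, sys$right)
      bad <- setdiff(sys$sync, intersect(la, ra))
      if (length(bad))
        abort(sprintf("cooperation action '%s' does not occur in both operands", bad[1]))
      check_sys(sys$left); check_sys(sys$right)
    } else {
      if (is.null(model$components[[sys$component]]))
        abort(sprintf("system refers to undefined component '%s'", sys$component))
      if (inherits(sys, "cpp_rep") && sys$copies < 1L) abort("replication copies must be >= 1")
    }
    invisible(NULL)
  }
  check_sys(model$system)
  invisible(model)
}
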