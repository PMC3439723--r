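# Stochastic probes: a NotFinished/Finished observer fused onto the patient
# component, synchronised on a trigger action, so that the fraction of
# probes in the Finished state approximates the cumulative distribution of
# the time to the first completion of that action.

probe_sep <- "__"

#' Attach a passage-time probe to the patient component
#'
#' Replaces the probed replica group's component by its synchronised
#' product with the two-state probe: `NotFinished` turns into the absorbing
#' `Finished` on the first completion of the trigger action, and every
#' other activity leaves the probe untouched. Because the probe is fused
#' into the component (its rates are the trigger's own), all non-probe
#' marginals are exactly those of the original model. The probed group
#' starts at `start`, which also sets the clock origin of the measured
#' passage: starting at the first treatment state excludes the at-home
#' waiting stage.
#'
#' @param model A [cpp_model()].
#' @param start Component name the probed patients start in.
#' @param trigger Action label whose first completion ends the passage.
#' @return A [cpp_model()] whose metadata records the probe (`meta$probe`).
#' @export
#' @examples
#' m <- stroke_model(num_patients = 1)
#' pm <- attach_probe(m, "Patient_LAS", "treat_HASU")
attach_probe <- function(model, start, trigger) {
  if (is.null(model$components[[start]]))
    abort(sprintf("unknown start component '%s'", start))
  locals <- derivative_set(model, start)
  acts <- unique(unlist(lapply(locals, function(s) component_prefixes(model, s)$action)))
  if (!trigger %in% acts)
    abort(sprintf("trigger action '%s' is not reachable from '%s'", trigger, start))

  leaves <- system_leaves(model$system)
  leaf_i <- which(vapply(leaves, function(l) start %in%
                           derivative_set(model, l$component), TRUE))
  if (!length(leaf_i)) abort(sprintf("'%s' does not occur in the system expression", start))
  leaf_i <- leaf_i[1]

  pname <- function(s, p) paste0(s, probe_sep, p)
  probed <- list()
  for (s in locals) {
    pf <- component_prefixes(model, s)
    for (p in c("NotFinished", "Finished")) {
      prefs <- purrr::pmap(pf, function(action, rate, base_rate, weight, target) {
        p2 <- if (p == "Finished" || action == trigger) "Finished" else p
        cpp_prefix(cpp_activity(action, base_rate), pname(target, p2),
                   weight = if (weight != 1) weight else NULL)
      })
      nm <- pname(s, p)
      probed[[nm]] <- cpp_component(nm, purrr::reduce(prefs, cpp_choice), "state")
    }
  }

  keep <- model$components[setdiff(names(model$components), locals)]
  comps <- c(keep, probed)

  k <- 0L
  rewrite <- function(sys) {
    if (inherits(sys, "cpp_coop"))
      return(cpp_coop(rewrite(sys$left), rewrite(sys$right), sys$sync))
    k <<- k + 1L
    if (k != leaf_i) return(sys)
    if (inherits(sys, "cpp_rep"))
      cpp_replicate(pname(start, "NotFinished"), sys$copies)
    else cpp_instance(pname(start, "NotFinished"))
  }
  system <- rewrite(model$system)

  out <- cpp_model(comps, system, meta = model$meta, validate = FALSE)
  grp <- model_groups(out)
  if (!is.null(out$meta$resources))
    out$meta$resources$group <- grp$group[match(
      sub("_busy$", "_idle", out$meta$resources$busy), grp$component)]
  out$meta$probe <- list(trigger = trigger, start = start,
                         group = grp$group[leaf_i],
                         copies = grp$copies[leaf_i])
  validate_model(out)
  out
}

is_finished_local <- function(local) grepl(paste0(probe_sep, "Finished$"), local)

#' Passage-time distribution via the fluid probe
#'
#' Integrates the fluid equations of a probe-augmented model and reports
#' the Finished fraction of the probed population on the requested time
#' grid — an approximation of the cumulative distribution function of the
#' time from the probed start state to the first completion of the trigger
#' action. The curve is clamped to `[0, 1]` and made nondecreasing (the
#' analytical curve is; this removes integration noise at the tolerance
#' level).
#'
#' @param probed A model from [attach_probe()].
#' @param grid Time points (days).
#' @param rtol,atol Integration tolerances.
#' @return A `cpp_cdf` tibble with columns `time` and `cdf`.
#' @export
passage_time_cdf <- function(probed, grid, rtol = 1e-8, atol = 1e-10) {
  if (is.null(probed$meta$probe)) abort("model carries no probe; see attach_probe()")
  grid <- sort(unique(c(0, grid)))
  odes <- derive_odes(probed)
  traj <- integrate_odes(odes, times = grid, rtol = rtol, atol = atol)
  g <- probed$meta$probe$group
  fin <- traj |>
    dplyr::filter(.data$group == g, is_finished_local(.data$local)) |>
    dplyr::group_by(.data$time) |>
    dplyr::summarise(cdf = sum(.data$count) / probed$meta$probe$copies,
                     .groups = "drop")
  fin$cdf <- cummax(pmin(pmax(fin$cdf, 0), 1))
  structure(fin, class = c("cpp_cdf", class(fin)), probe = probed$meta$probe)
}
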