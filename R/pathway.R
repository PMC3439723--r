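# Generating pathway models from clinical configuration tables.
#
# A pathway is an ordered sequence of departments.  Each department has a
# service activity (rate = 24 / duration-in-hours, per day) and optionally
# a resource (idle/busy pair) acquired either directly on the action by
# which patients arrive, or through a fast waiting-room relay that decouples
# the hand-off so that arriving patients are never blocked by a busy
# resource.  Patients cycle Home -> departments -> Home (the discharge
# returns them to Home), which keeps the chain irreducible.

#' Build a pathway configuration
#'
#' @param departments Data frame with one row per department, columns:
#'   `department` (name), `activity` (service action label), `hours` (mean
#'   service duration, hours) or `rate` (1/day; wins if both given),
#'   `resource` (resource name, `NA` for an unlimited resource such as
#'   ambulances), `copies` (resource copies), `waiting_room` (logical:
#'   insert a fast waiting-room relay in front of the resource). Optional
#'   columns `wait_room` and `wait_action` override the generated names.
#' @param num_patients Patient population (parallel patient copies).
#' @param r_income Admission rate per patient at home (1/day); the mean
#'   daily input is `num_patients * r_income`.
#' @param entry_action Action label of the admission activity.
#' @param r_wait Waiting-room coupling rate (1/day); must be much larger
#'   than every service rate so the relay is effectively instantaneous.
#' @param num_wait_rooms Copies of each waiting room; must be at least
#'   `num_patients` so an idle room is always available.
#' @param home Name suffix of the at-home patient state.
#' @param routing Optional list of branch specifications, each a list with
#'   `from` (department), `to` (character vector of destination departments
#'   or `"Home"`), `prob` (probabilities summing to 1). The department's
#'   service rate is split across the branches by rate scaling.
#' @return A `cpp_pathway_config` object (a validated list).
#' @export
pathway_config <- function(departments, num_patients, r_income,
                           entry_action = "have_stroke", r_wait = 1000,
                           num_wait_rooms = num_patients, home = "Home",
                           routing = NULL) {
  d <- tibble::as_tibble(departments)
  if (!"rate" %in% names(d)) d$rate <- NA_real_
  if ("hours" %in% names(d)) d$rate <- ifelse(is.na(d$rate), 24 / d$hours, d$rate)
  if (!"resource" %in% names(d)) d$resource <- NA_character_
  if (!"copies" %in% names(d)) d$copies <- 1L
  if (!"waiting_room" %in% names(d)) d$waiting_room <- FALSE
  if (!"wait_room" %in% names(d)) d$wait_room <- NA_character_
  if (!"wait_action" %in% names(d)) d$wait_action <- NA_character_
  d$wait_room <- ifelse(d$waiting_room & is.na(d$wait_room),
                        paste0("Wait_", d$department), d$wait_room)
  d$wait_action <- ifelse(d$waiting_room & is.na(d$wait_action),
                          paste0("wait_", d$department), d$wait_action)
  stopifnot(nrow(d) >= 1, all(d$rate > 0), all(is.na(d$resource) | d$copies >= 1))
  if (num_patients < 1) abort("num_patients must be >= 1")
  if (r_income <= 0) abort("r_income must be positive")
  if (any(d$waiting_room) && num_wait_rooms < num_patients)
    abort(sprintf("waiting-room count %d is below the patient count %d",
                  num_wait_rooms, num_patients))
  if (!is.null(routing)) {
    for (b in routing) {
      stopifnot(b$from %in% d$department, length(b$to) == length(b$prob))
      if (abs(sum(b$prob) - 1) > 1e-12)
        abort(sprintf("routing probabilities at '%s' sum to %g, not 1",
                      b$from, sum(b$prob)))
      bad <- setdiff(b$to, c(d$department, "Home"))
      if (length(bad)) abort(sprintf("unknown routing destination '%s'", bad[1]))
    }
  }
  structure(list(departments = d, num_patients = as.integer(num_patients),
                 r_income = r_income, entry_action = entry_action,
                 r_wait = r_wait, num_wait_rooms = as.integer(num_wait_rooms),
                 home = home, routing = routing),
            class = "cpp_pathway_config")
}

patient_state <- function(config, place) {
  if (place == "Home") paste0("Patient_", config$home) else paste0("Patient_", place)
}

#' Patient state chain of a pathway
#'
#' One state component per place (home plus each department), connected in
#' a cycle: admission moves the patient from home into the first
#' department, each service activity moves it on, and the final discharge
#' returns it home. Routing branches become rate-scaled prefixes of a
#' choice.
#'
#' @param config A [pathway_config()].
#' @return Named list of [cpp_component()] state components.
#' @export
build_patient_chain <- function(config) {
  d <- config$departments
  chain <- list()
  nxt <- function(i) if (i == nrow(d)) "Home" else d$department[i + 1]
  # home state: admission
  chain[[patient_state(config, "Home")]] <- cpp_component(
    patient_state(config, "Home"),
    cpp_prefix(cpp_activity(config$entry_action, config$r_income),
               patient_state(config, d$department[1])),
    kind = "state")
  for (i in seq_len(nrow(d))) {
    nm <- patient_state(config, d$department[i])
    branch <- NULL
    for (b in config$routing %||% list()) if (b$from == d$department[i]) branch <- b
    body <- if (is.null(branch)) {
      cpp_prefix(cpp_activity(d$activity[i], d$rate[i]),
                 patient_state(config, nxt(i)))
    } else {
      pre <- purrr::map2(branch$to, branch$prob, function(to, p)
        cpp_prefix(cpp_activity(d$activity[i], d$rate[i]),
                   patient_state(config, to), weight = p))
      purrr::reduce(pre, cpp_choice)
    }
    chain[[nm]] <- cpp_component(nm, body, kind = "state")
  }
  chain
}

#' Resource and waiting-room components of a pathway
#'
#' For each resourced department, an idle/busy pair: the resource is seized
#' on the action by which patients arrive (the previous department's
#' service activity, or the admission activity for the first department)
#' and released by its own service activity. Where the configuration asks
#' for a waiting room, a fast relay pair is inserted: the room is seized on
#' the arrival action and hands over to the resource through the
#' waiting-coupling activity, so a busy resource never blocks the hand-off.
#'
#' @param config A [pathway_config()].
#' @return Named list of [cpp_component()] resource components.
#' @export
build_resource_pairs <- function(config) {
  d <- config$departments
  out <- list()
  arrival_action <- c(config$entry_action, d$activity[-nrow(d)])
  arrival_rate <- c(config$r_income, d$rate[-nrow(d)])
  for (i in seq_len(nrow(d))) {
    if (is.na(d$resource[i])) next
    res <- d$resource[i]
    idle <- paste0(res, "_idle"); busy <- paste0(res, "_busy")
    if (d$waiting_room[i]) {
      w <- d$wait_room[i]
      wi <- paste0(w, "_idle"); wb <- paste0(w, "_busy")
      out[[wi]] <- cpp_component(wi, cpp_prefix(
        cpp_activity(arrival_action[i], arrival_rate[i]), wb), "resource")
      out[[wb]] <- cpp_component(wb, cpp_prefix(
        cpp_activity(d$wait_action[i], config$r_wait), wi), "resource")
      seize <- cpp_activity(d$wait_action[i], config$r_wait)
    } else {
      seize <- cpp_activity(arrival_action[i], arrival_rate[i])
    }
    out[[idle]] <- cpp_component(idle, cpp_prefix(seize, busy), "resource")
    out[[busy]] <- cpp_component(busy, cpp_prefix(
      cpp_activity(d$activity[i], d$rate[i]), idle), "resource")
  }
  out
}

#' Assemble the full pathway model
#'
#' Builds the patient chain and resource pairs, wires the system expression
#' (patients cooperating with the nested resource-side composition over the
#' syntactically shared action labels), and records the reporting metadata:
#' each resource's busy state, and the discharge activity that frees the
#' final resource.
#'
#' @param config A [pathway_config()].
#' @return A validated [cpp_model()].
#' @export
#' @examples
#' m <- assemble_system(simple_pathway_config())
#' explore_state_space(m)$n_states  # 10
assemble_system <- function(config) {
  d <- config$departments
  comps <- c(build_patient_chain(config), build_resource_pairs(config))

  # resource-side leaves, pathway order: waiting room then resource per dept
  side <- list()
  for (i in seq_len(nrow(d))) {
    if (is.na(d$resource[i])) next
    if (d$waiting_room[i])
      side[[length(side) + 1L]] <- cpp_replicate(paste0(d$wait_room[i], "_idle"),
                                                 config$num_wait_rooms)
    side[[length(side) + 1L]] <- cpp_replicate(paste0(d$resource[i], "_idle"),
                                               d$copies[i])
  }
  patients <- cpp_replicate(patient_state(config, "Home"), config$num_patients)

  comp_actions <- function(nm) {
    model_tmp <- structure(list(components = comps), class = "cpp_model")
    locals <- derivative_set(model_tmp, nm)
    unique(unlist(lapply(locals, function(l) component_prefixes(model_tmp, l)$action)))
  }
  leaf_actions <- lapply(side, function(l) comp_actions(l$component))

  if (length(side)) {
    sys_side <- side[[length(side)]]
    acts_right <- leaf_actions[[length(side)]]
    if (length(side) > 1L) {
      for (i in rev(seq_len(length(side) - 1L))) {
        sync <- intersect(leaf_actions[[i]], acts_right)
        sys_side <- cpp_coop(side[[i]], sys_side, sync)
        acts_right <- union(leaf_actions[[i]], acts_right)
      }
    }
    pat_actions <- comp_actions(patient_state(config, "Home"))
    system <- cpp_coop(patients, sys_side, intersect(pat_actions, acts_right))
  } else {
    system <- patients
  }

  model <- cpp_model(comps, system, validate = FALSE)
  grp <- model_groups(model)
  res_rows <- d[!is.na(d$resource), ]
  resources <- tibble::tibble(
    resource = res_rows$resource,
    group = grp$group[match(paste0(res_rows$resource, "_idle"), grp$component)],
    busy = paste0(res_rows$resource, "_busy"),
    copies = as.integer(res_rows$copies))
  last_res <- utils::tail(which(!is.na(d$resource)), 1)
  discharge <- if (length(last_res))
    list(action = d$activity[last_res], rate = d$rate[last_res],
         resource = d$resource[last_res])
  model$meta <- list(
    resources = resources,
    discharge = discharge,
    entry = list(action = config$entry_action, rate = config$r_income),
    patient_group = grp$group[1],
    config = config)
  validate_model(model)
  model
}

#' Configuration of the two-patient illustrative pathway
#'
#' A single treatment place fed through a waiting room: patients move from
#' place0 to place1 on the `beta` activity (seizing a waiting room), the
#' room hands over to the single resource through the fast `gamma`
#' coupling, and service `alpha` returns the patient to place0. With 2
#' patients, 2 waiting rooms and 1 resource the chain has 10 states; with
#' 8, 8 and 3 it has 75582.
#'
#' @param num_patients,num_rooms,copies Population and resource counts.
#' @param beta,alpha,gamma Activity rates (1/day).
#' @return A [pathway_config()].
#' @export
simple_pathway_config <- function(num_patients = 2, num_rooms = 2, copies = 1,
                                  beta = 1, alpha = 3, gamma = 1000) {
  pathway_config(
    departments = tibble::tibble(
      department = "place1", activity = "alpha", rate = alpha,
      resource = "Resource_place1", copies = copies, waiting_room = TRUE,
      wait_room = "Wait_room0", wait_action = "gamma"),
    num_patients = num_patients, num_wait_rooms = num_rooms,
    r_income = beta, entry_action = "beta", r_wait = gamma, home = "place0")
}

#' Configuration and model of the stroke clinical pathway
#'
#' The simplified main-stream stroke pathway: ambulance FAST test (1 h,
#' unlimited ambulances), A&E stroke investigation (0.75 h, stroke teams),
#' CT scan (3 h, scanners, behind a waiting room), and HASU rehabilitation
#' (48 h, beds, behind a waiting room). Default resources are 3 teams, 3
#' scanners and 20 beds; the default population of 1000 patients at an
#' admission rate of 0.004/day gives a mean input of 4 patients/day.
#'
#' @param teams,scanners,beds Resource copies.
#' @param num_patients Patient population.
#' @param r_income Per-patient admission rate (1/day).
#' @param r_wait Waiting-room coupling rate (1/day).
#' @return `stroke_config()` returns a [pathway_config()]; `stroke_model()`
#'   the assembled [cpp_model()].
#' @export
#' @examples
#' m <- stroke_model()
#' m$meta$resources
stroke_config <- function(teams = 3, scanners = 3, beds = 20,
                          num_patients = 1000, r_income = 0.004, r_wait = 1000) {
  pathway_config(
    departments = tibble::tibble(
      department = c("LAS", "A_E_Resus", "CT_scan", "Normal_treat"),
      activity = c("do_FAST", "assess_and_investigate", "scan", "treat_HASU"),
      hours = c(1, 0.75, 3, 48),
      resource = c(NA, "Stroke_team", "Scanner", "Bed"),
      copies = c(1L, as.integer(teams), as.integer(scanners), as.integer(beds)),
      waiting_room = c(FALSE, FALSE, TRUE, TRUE),
      wait_room = c(NA, NA, "Wait_room1", "Wait_room2"),
      wait_action = c(NA, NA, "wait_scan", "wait_bed")),
    num_patients = num_patients, r_income = r_income,
    entry_action = "have_stroke", r_wait = r_wait)
}

#' @rdname stroke_config
#' @export
stroke_model <- function(teams = 3, scanners = 3, beds = 20,
                         num_patients = 1000, r_income = 0.004, r_wait = 1000) {
  assemble_system(stroke_config(teams, scanners, beds, num_patients,
                                r_income, r_wait))
}

# ---- routing estimation ----------------------------------------------------

#' HASU activity table
#'
#' Admission counts by category, used to estimate routing probabilities.
#'
#' @param strokes,mimics,tia,direct Nonnegative integer admission counts
#'   (confirmed strokes, stroke mimics, transient ischaemic attacks, direct
#'   HASU admissions).
#' @return A one-row tibble.
#' @export
activity_table <- function(strokes, mimics, tia, direct = 0L) {
  stopifnot(strokes >= 0, mimics >= 0, tia >= 0, direct >= 0)
  tibble::tibble(strokes = as.integer(strokes), mimics = as.integer(mimics),
                 tia = as.integer(tia), direct = as.integer(direct))
}

#' Estimate a routing probability from admission counts
#'
#' Branch probabilities of the pathway's decision points, estimated as the
#' branch count over the applicable total: patients leaving A&E for the
#' referral branch are the mimics among all assessed admissions
#' (strokes + mimics + TIA); patients leaving CT for the referral branch
#' are the TIAs among those scanned (strokes + mimics).
#'
#' @param table An [activity_table()] (or data frame with the same
#'   columns).
#' @param branch `"ae_referral"` or `"ct_referral"`.
#' @return A tibble with `branch`, `numerator`, `denominator`,
#'   `probability`, and `percent` (rounded to a whole percent for
#'   reporting).
#' @export
#' @examples
#' estimate_routing(activity_table(116, 27, 15), "ae_referral")  # 17%
estimate_routing <- function(table, branch = c("ae_referral", "ct_referral")) {
  branch <- match.arg(branch)
  t1 <- tibble::as_tibble(table)[1, ]
  num_den <- switch(branch,
    ae_referral = c(t1$mimics, t1$strokes + t1$tia + t1$mimics),
    ct_referral = c(t1$tia, t1$strokes + t1$mimics))
  if (num_den[2] <= 0) abort("zero denominator: no applicable admissions")
  tibble::tibble(branch = branch, numerator = as.integer(num_den[1]),
                 denominator = as.integer(num_den[2]),
                 probability = num_den[1] / num_den[2],
                 percent = round(100 * num_den[1] / num_den[2]))
}

# ---- configuration files ---------------------------------------------------

#' Read or write a pathway configuration file
#'
#' Configurations are stored as YAML (`.yaml`/`.yml`, requires the yaml
#' package) or JSON. The document has the fields of [pathway_config()]:
#' `departments` (a list of records with `department`, `activity`,
#' `hours` or `rate`, `resource`, `copies`, `waiting_room`, and optional
#' `wait_room`/`wait_action`), `num_patients`, `r_income`, and optionally
#' `entry_action`, `r_wait`, `num_wait_rooms`, `home`, `routing`.
#'
#' @param path File path.
#' @param config A [pathway_config()].
#' @return `read_pathway_config()` returns a validated [pathway_config()];
#'   `write_pathway_config()` returns `path` invisibly.
#' @export
read_pathway_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("reading YAML configurations requires the yaml package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  dep <- tibble::as_tibble(raw$departments)
  if (!is.data.frame(raw$departments) && is.list(raw$departments))
    dep <- dplyr::bind_rows(lapply(raw$departments, tibble::as_tibble))
  args <- list(departments = dep, num_patients = raw$num_patients,
               r_income = raw$r_income)
  for (f in c("entry_action", "r_wait", "num_wait_rooms", "home"))
    if (!is.null(raw[[f]])) args[[f]] <- raw[[f]]
  if (!is.null(raw$routing)) args$routing <- raw$routing
  do.call(pathway_config, args)
}

#' @rdname read_pathway_config
#' @export
write_pathway_config <- function(config, path) {
  doc <- list(departments = as.data.frame(config$departments),
              num_patients = config$num_patients,
              r_income = config$r_income,
              entry_action = config$entry_action,
              r_wait = config$r_wait,
              num_wait_rooms = config$num_wait_rooms,
              home = config$home)
  if (!is.null(config$routing)) doc$routing <- config$routing
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      abort("writing YAML configurations requires the yaml package")
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, na = "null")
  }
  invisible(path)
}
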