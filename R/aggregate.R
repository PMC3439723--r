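# Replica-counting abstraction: states that differ only by a permutation of
# the copies inside a replica group are strongly equivalent and can be
# lumped into one class described by per-group counts of local states.

#' Aggregate a transition system by counting abstraction
#'
#' Global states with identical per-group local-state count vectors are
#' merged into one class. The lumped rate from a class to another is the
#' total rate from any one member into the target class; because the
#' members of a replica group are exact copies of one component, every
#' member of a class has the same lumped outgoing rates (checked, and
#' reported as an error if violated). Class ordering follows the first
#' appearance of each class in the BFS state order, so the initial class is
#' class 1.
#'
#' @param ts A transition system from [explore_state_space()].
#' @param groups Character vector of replica-group ids to lump over;
#'   defaults to all groups. Instances of groups not listed keep their
#'   identity.
#' @param check Verify lumpability across all class members (default
#'   `TRUE`).
#' @param tol Relative tolerance of the lumpability check.
#' @return An aggregated system (classes `cpp_agg`, `cpp_ts`): list with
#'   `n_states` (classes), `counts` (class-by-variable count matrix, one
#'   variable per (group, local state)), `edges`, `members` (class sizes),
#'   `map` (full state -> class), `groups`, `initial`.
#' @export
aggregate_states <- function(ts, groups = NULL, check = TRUE, tol = 1e-9) {
  stopifnot(inherits(ts, "cpp_ts"), !is.null(ts$states))
  groups <- groups %||% ts$groups$group
  stopifnot(all(groups %in% ts$groups$group))

  # count-vector signature per state: for lumped groups, counts of each
  # local state; for others, the raw per-instance local state
  vars <- list(); cols <- list()
  for (g in ts$groups$group) {
    idx <- which(ts$instances$group == g)
    locs <- ts$local_names[[g]]
    if (g %in% groups) {
      for (li in seq_along(locs)) {
        cnt <- if (length(idx) == 1L) as.integer(ts$states[, idx] == li)
        else as.integer(rowSums(ts$states[, idx, drop = FALSE] == li))
        cols[[length(cols) + 1L]] <- cnt
        vars[[length(vars) + 1L]] <- tibble::tibble(group = g, local = locs[li])
      }
    } else {
      for (i in idx) {
        cols[[length(cols) + 1L]] <- ts$states[, i]
        vars[[length(vars) + 1L]] <- tibble::tibble(group = g,
                                                    local = sprintf("instance_%d", i))
      }
    }
  }
  counts <- do.call(cbind, cols)
  var_info <- dplyr::bind_rows(vars)
  key <- apply(counts, 1, paste, collapse = ",")
  first <- !duplicated(key)
  class_key <- key[first]
  map <- match(key, class_key)
  n_class <- length(class_key)
  members <- tabulate(map, n_class)
  repr <- which(first)

  # lumped transitions, from each class representative
  e <- ts$edges
  keep <- e$src %in% repr
  agg_edges <- tibble::tibble(src = map[e$src[keep]], tgt = map[e$tgt[keep]],
                              action = e$action[keep], rate = e$rate[keep]) |>
    dplyr::group_by(.data$src, .data$tgt, .data$action) |>
    dplyr::summarise(rate = sum(.data$rate), .groups = "drop") |>
    dplyr::arrange(.data$src, .data$tgt, .data$action)

  if (check) {
    all_l <- tibble::tibble(src = map[e$src], tgt = map[e$tgt],
                            action = e$action, rate = e$rate,
                            member = e$src) |>
      dplyr::group_by(.data$member, .data$src, .data$tgt, .data$action) |>
      dplyr::summarise(rate = sum(.data$rate), .groups = "drop")
    ok <- all_l |>
      dplyr::group_by(.data$src, .data$tgt, .data$action) |>
      dplyr::summarise(spread = max(.data$rate) - min(.data$rate),
                       n_members = dplyr::n_distinct(.data$member),
                       base = max(abs(.data$rate)), .groups = "drop")
    full_members <- members[ok$src]
    if (any(ok$n_members != full_members) ||
        any(ok$spread > tol * pmax(ok$base, 1)))
      abort("lumpability violation: class members disagree on lumped rates")
  }

  structure(list(
    model = ts$model,
    n_states = n_class,
    counts = counts[repr, , drop = FALSE],
    var_info = var_info,
    edges = agg_edges,
    members = members,
    map = map,
    groups = ts$groups,
    local_names = ts$local_names,
    actions = ts$actions,
    initial = map[ts$initial]), class = c("cpp_agg", "cpp_ts"))
}

# expected number of instances of `group` sitting in local state `local`,
# per global state / class — shared accessor for performance measures
local_counts <- function(ts, group, local) {
  if (inherits(ts, "cpp_agg")) {
    j <- which(ts$var_info$group == group & ts$var_info$local == local)
    if (!length(j)) return(rep(0, ts$n_states))
    return(as.numeric(ts$counts[, j]))
  }
  idx <- which(ts$instances$group == group)
  li <- match(local, ts$local_names[[group]])
  if (is.na(li) || !length(idx)) return(rep(0, ts$n_states))
  if (length(idx) == 1L) as.numeric(ts$states[, idx] == li)
  else as.numeric(rowSums(ts$states[, idx, drop = FALSE] == li))
}
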