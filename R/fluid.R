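# Mean-field (fluid) approximation: the expected count of each local state
# of each replica group evolves under ODEs whose shared-action terms take
# the minimum of the participating groups' apparent count-rates, the
# continuous counterpart of the cooperation rule.

#' Derive the fluid ODE system of a model
#'
#' One count variable per (replica group, local state). The drift of a
#' variable is the inflow minus the outflow of its transitions, where the
#' total rate of an action is evaluated over the cooperation tree: at a
#' group, the count-weighted sum of its enabled prefix rates; at a
#' cooperation, the minimum of the operands for a shared action and the sum
#' for an interleaved one. The total is apportioned to individual
#' transitions in proportion to their contribution to the group's apparent
#' rate.
#'
#' @param model A [cpp_model()].
#' @return An object of class `cpp_odes`: list with `vars` (tibble `group`,
#'   `local`, `init`), `rhs` (the derivative function), `actions`, and the
#'   compiled coupling structure.
#' @export
#' @examples
#' odes <- derive_odes(assemble_system(simple_pathway_config()))
#' odes$vars
derive_odes <- function(model) {
  validate_model(model)
  groups <- model_groups(model)
  locals <- lapply(groups$component, derivative_set, model = model)
  vars <- dplyr::bind_rows(purrr::map2(groups$group, locals, function(g, ls)
    tibble::tibble(group = g, local = ls)))
  vars$init <- 0
  var_id <- stats::setNames(seq_len(nrow(vars)), paste(vars$group, vars$local))
  for (gi in seq_len(nrow(groups)))
    vars$init[var_id[paste(groups$group[gi], groups$component[gi])]] <- groups$copies[gi]

  actions <- sort(unique(unlist(lapply(names(model$components), function(nm)
    component_prefixes(model, nm)$action))))

  # per-group flat prefix list: source var, action id, rate, target var
  gpref <- purrr::map(seq_len(nrow(groups)), function(gi) {
    g <- groups$group[gi]
    purrr::map_dfr(locals[[gi]], function(s) {
      pf <- component_prefixes(model, s)
      tibble::tibble(src = as.integer(var_id[paste(g, s)]),
                     action = match(pf$action, actions),
                     rate = pf$rate,
                     tgt = as.integer(var_id[paste(g, pf$target)]))
    })
  })

  # group-level cooperation tree (leaves are groups, in flatten order)
  nodes <- list()
  add <- function(kind, a, b = NA_integer_, sync = integer()) {
    nodes[[length(nodes) + 1L]] <<- list(kind = kind, a = a, b = b, sync = sync)
    length(nodes)
  }
  gi <- 0L
  build <- function(sys) {
    if (inherits(sys, "cpp_coop")) {
      l <- build(sys$left); r <- build(sys$right)
      return(add("coop", l, r, sync = match(sys$sync, actions)))
    }
    gi <<- gi + 1L
    add("leaf", gi)
  }
  root <- build(model$system)
  n_nodes <- length(nodes)
  n_act <- length(actions)

  rhs_r <- function(t, N, parms = NULL) {
    app <- matrix(0, n_nodes, n_act)
    for (ni in seq_len(n_nodes)) {
      nd <- nodes[[ni]]
      if (nd$kind == "leaf") {
        pf <- gpref[[nd$a]]
        if (nrow(pf))
          app[ni, ] <- rowsum(c(pf$rate * N[pf$src], numeric(n_act)),
                              c(pf$action, seq_len(n_act)))[, 1]
      } else {
        s <- app[nd$a, ] + app[nd$b, ]
        if (length(nd$sync))
          s[nd$sync] <- pmin(app[nd$a, nd$sync], app[nd$b, nd$sync])
        app[ni, ] <- s
      }
    }
    dN <- numeric(length(N))
    alloc <- function(ni, a, total) {
      if (total <= 0) return(invisible(NULL))
      nd <- nodes[[ni]]
      if (nd$kind == "leaf") {
        pf <- gpref[[nd$a]]
        sel <- which(pf$action == a)
        ag <- app[ni, a]
        if (ag > 0) for (k in sel) {
          fl <- total * pf$rate[k] * N[pf$src[k]] / ag
          dN[pf$src[k]] <<- dN[pf$src[k]] - fl
          dN[pf$tgt[k]] <<- dN[pf$tgt[k]] + fl
        }
        return(invisible(NULL))
      }
      if (a %in% nd$sync) {
        alloc(nd$a, a, total); alloc(nd$b, a, total)
      } else {
        al <- app[nd$a, a]; ar <- app[nd$b, a]
        if (al + ar > 0) {
          alloc(nd$a, a, total * al / (al + ar))
          alloc(nd$b, a, total * ar / (al + ar))
        }
      }
      invisible(NULL)
    }
    for (a in seq_len(n_act)) alloc(root, a, app[root, a])
    list(dN)
  }

  # compiled drift evaluation (identical semantics to rhs_r, which is kept
  # for inspection and cross-checking); the compiled object is rebuilt
  # lazily if the external pointer does not survive serialisation
  spec <- list(n_vars = nrow(vars), n_actions = n_act, root = root,
               leaf_pref = lapply(gpref, function(p)
                 list(src = p$src, action = p$action, rate = p$rate, tgt = p$tgt)),
               nodes = nodes)
  env <- new.env(parent = emptyenv())
  rhs <- function(t, N, parms = NULL) {
    if (is.null(env$ptr) || !.ptr_valid_cpp(env$ptr))
      env$ptr <- .fluid_compile_cpp(spec)
    list(.fluid_rhs_cpp(env$ptr, N))
  }

  structure(list(model = model, vars = vars, groups = groups, rhs = rhs,
                 rhs_r = rhs_r, actions = actions, nodes = nodes, root = root,
                 gpref = gpref),
            class = "cpp_odes")
}

# apparent rate of an action at the tree root for given counts (the total
# fluid rate of that action)
fluid_action_rate <- function(odes, N, action) {
  a <- match(action, odes$actions)
  if (is.na(a)) abort(sprintf("action '%s' is not present in the model", action))
  app_node <- function(ni) {
    nd <- odes$nodes[[ni]]
    if (nd$kind == "leaf") {
      pf <- odes$gpref[[nd$a]]
      sel <- pf$action == a
      return(sum(pf$rate[sel] * N[pf$src[sel]]))
    }
    l <- app_node(nd$a); r <- app_node(nd$b)
    if (a %in% nd$sync) min(l, r) else l + r
  }
  app_node(odes$root)
}

#' Symbolic form of the fluid equations
#'
#' @param x A [derive_odes()] result.
#' @param ... Unused.
#' @return Character vector, one readable equation per count variable.
#' @export
format.cpp_odes <- function(x, ...) {
  n_act <- length(x$actions)
  sym <- matrix("", length(x$nodes), n_act)
  for (ni in seq_along(x$nodes)) {
    nd <- x$nodes[[ni]]
    for (a in seq_len(n_act)) {
      if (nd$kind == "leaf") {
        pf <- x$gpref[[nd$a]]
        sel <- which(pf$action == a)
        if (length(sel))
          sym[ni, a] <- paste(sprintf("%s*N(%s)", fmt_num(pf$rate[sel]),
                                      x$vars$local[pf$src[sel]]), collapse = " + ")
      } else {
        l <- sym[nd$a, a]; r <- sym[nd$b, a]
        sym[ni, a] <-
          if (!nzchar(l)) r
          else if (!nzchar(r)) l
          else if (a %in% nd$sync) sprintf("min(%s, %s)", l, r)
          else sprintf("%s + %s", l, r)
      }
    }
  }
  # net drift text per variable: shares within a group are left implicit
  # when a group has several enabled prefixes of one action
  terms <- vector("list", nrow(x$vars))
  for (gi in seq_along(x$gpref)) {
    pf <- x$gpref[[gi]]
    for (k in seq_len(nrow(pf))) {
      e <- sym[x$root, pf$action[k]]
      terms[[pf$src[k]]] <- c(terms[[pf$src[k]]], paste0("- ", e))
      terms[[pf$tgt[k]]] <- c(terms[[pf$tgt[k]]], paste0("+ ", e))
    }
  }
  vapply(seq_len(nrow(x$vars)), function(v)
    sprintf("N(%s)' = %s", x$vars$local[v],
            if (length(terms[[v]])) paste(terms[[v]], collapse = " ") else "0"), "")
}

#' @export
print.cpp_odes <- function(x, ...) {
  cat(sprintf("<cpp_odes> %d count variables in %d groups\n",
              nrow(x$vars), nrow(x$groups)))
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Integrate the fluid equations
#'
#' Stiff-capable integration (lsoda) with dense output on the requested
#' grid. The model mixes day-scale service rates with the fast
#' waiting-room couplings, so tight tolerances are used by default.
#'
#' @param odes A [derive_odes()] result.
#' @param horizon Final time (days), or `times` for an explicit grid.
#' @param times Output time grid; default 200 points over `[0, horizon]`.
#' @param init Initial counts; defaults to the replication counts of the
#'   model.
#' @param rtol,atol Relative and absolute integration tolerances.
#' @return A `cpp_fluid` object: tibble of trajectories in long form
#'   (`time`, `group`, `local`, `count`) with the solution matrix as
#'   attribute `solution`.
#' @export
integrate_odes <- function(odes, horizon = NULL, times = NULL, init = NULL,
                           rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(odes, "cpp_odes"))
  if (is.null(times)) {
    stopifnot(!is.null(horizon), horizon > 0)
    times <- seq(0, horizon, length.out = 200)
  }
  y0 <- init %||% odes$vars$init
  sol <- deSolve::ode(y = y0, times = times, func = odes$rhs,
                      method = "lsoda", rtol = rtol, atol = atol, maxsteps = 100000)
  if (attr(sol, "istate")[1] < 0)
    abort(paste("fluid integration failed;",
                "solver diagnostics:", paste(attr(sol, "istate"), collapse = " ")))
  m <- unname(sol[, -1, drop = FALSE])
  out <- tidyr::expand_grid(time = sol[, 1],
                            var = seq_len(nrow(odes$vars)))
  out$group <- odes$vars$group[out$var]
  out$local <- odes$vars$local[out$var]
  out$count <- as.numeric(t(m))
  out <- out[, c("time", "group", "local", "count")]
  structure(tibble::as_tibble(out), solution = sol, vars = odes$vars,
            odes = odes, class = c("cpp_fluid", class(out)))
}

#' Fluid steady state
#'
#' Integrates the fluid equations in growing chunks until the largest
#' drift falls below `tol`, or the horizon cap is reached (returned with a
#' convergence flag rather than an error).
#'
#' @param odes A [derive_odes()] result.
#' @param tol Convergence threshold on `max |dN/dt|` (1/day).
#' @param t_max Horizon cap (days).
#' @param init Starting counts (defaults to the model's initial counts).
#' @param rtol,atol Integration tolerances.
#' @return A `cpp_fluid_ss` object: list with `counts` (named vector),
#'   `vars`, `converged`, `time`, `residual`.
#' @export
fluid_steady_state <- function(odes, tol = 1e-8, t_max = 1e5, init = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  y <- init %||% odes$vars$init
  t <- 0; chunk <- 10; resid <- Inf
  # Convergence accepts either a vanishing instantaneous drift or a
  # vanishing windowed mean drift |N(t2)-N(t1)|/(t2-t1): at a capacity
  # boundary the minimum terms switch ("slide") and the pointwise drift
  # chatters at a small finite value although the counts are stationary.
  repeat {
    resid <- max(abs(odes$rhs(t, y)[[1]]))
    if (resid < tol || t >= t_max) break
    upto <- min(t + chunk, t_max)
    sol <- deSolve::lsoda(y = y, times = c(t, upto), func = odes$rhs,
                          rtol = rtol, atol = atol, maxsteps = 100000)
    y2 <- as.numeric(sol[nrow(sol), -1])
    windowed <- max(abs(y2 - y)) / (upto - t)
    y <- y2; t <- upto
    chunk <- min(chunk * 2, 2000)
    if (windowed < tol) { resid <- windowed; break }
  }
  structure(list(counts = stats::setNames(y, paste(odes$vars$group,
                                                   odes$vars$local, sep = ".")),
                 vars = odes$vars, odes = odes,
                 converged = resid < tol, time = t, residual = resid),
            class = "cpp_fluid_ss")
}

#' @export
print.cpp_fluid_ss <- function(x, ...) {
  cat(sprintf("<cpp_fluid_ss> %sconverged at t = %g days (max drift %.2e)\n",
              if (x$converged) "" else "NOT ", x$time, x$residual))
  print(round(x$counts, 4))
  invisible(x)
}

fluid_count_of <- function(ss, group, local) {
  sel <- ss$vars$group == group & ss$vars$local == local
  if (!any(sel)) 0 else sum(ss$counts[sel])
}

#' Fluid performance report
#'
#' Utilisation and throughput measured on a fluid steady state, the
#' large-population counterpart of [performance_report()].
#'
#' @param ss A [fluid_steady_state()] result.
#' @return Tibble with one utilisation row per declared resource and a
#'   throughput row.
#' @export
fluid_report <- function(ss) {
  model <- ss$odes$model
  res <- model$meta$resources
  if (is.null(res)) abort("model metadata declares no resources")
  grp <- ss$odes$groups
  rows <- purrr::map_dfr(seq_len(nrow(res)), function(i) {
    copies <- grp$copies[grp$group == res$group[i]]
    tibble::tibble(measure = "utilisation", resource = res$resource[i],
                   copies = as.integer(copies),
                   value = fluid_count_of(ss, res$group[i], res$busy[i]) / copies)
  })
  d <- model$meta$discharge
  busy <- fluid_count_of(ss, res$group[res$resource == d$resource],
                         res$busy[res$resource == d$resource])
  dplyr::bind_rows(rows, tibble::tibble(measure = "throughput",
                                        resource = NA_character_,
                                        copies = NA_integer_,
                                        value = d$rate * busy))
}

#' Fluid throughput of a model
#'
#' Convenience wrapper: derives the ODEs, runs to the fluid steady state
#' and reports the discharge rate times the expected number of busy copies
#' of the final resource.
#'
#' @param model A pathway [cpp_model()] with discharge metadata.
#' @param ... Passed to [fluid_steady_state()].
#' @return List with `throughput`, `report`, and the `steady` object.
#' @export
fluid_throughput <- function(model, ...) {
  ss <- fluid_steady_state(derive_odes(model), ...)
  rep <- fluid_report(ss)
  list(throughput = rep$value[rep$measure == "throughput"],
       report = rep, steady = ss)
}
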