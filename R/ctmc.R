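# Deriving and solving the underlying continuous-time Markov chain.

# Flatten the system expression into replica groups: one group per leaf of
# the cooperation tree, carrying its component and copy count.
model_groups <- function(model) {
  leaves <- system_leaves(model$system)
  tibble::tibble(
    group = vapply(seq_along(leaves), function(i) {
      cmp <- leaves[[i]]$component
      paste0("g", i, ":", cmp)
    }, ""),
    component = vapply(leaves, `[[`, "", "component"),
    copies = vapply(leaves, function(l)
      if (inherits(l, "cpp_rep")) l$copies else 1L, 1L))
}

# Compile a model into the flat integer structures used by the C++ engine
# and the R-side bookkeeping (instances, local-state tables).
compile_model <- function(model) {
  validate_model(model)
  groups <- model_groups(model)
  acts <- sort(unique(unlist(lapply(names(model$components), function(nm)
    component_prefixes(model, nm)$action))))
  act_id <- stats::setNames(seq_along(acts), acts)

  # one component type per distinct initial component
  type_names <- unique(groups$component)
  locals <- lapply(type_names, derivative_set, model = model)
  names(locals) <- type_names
  types <- lapply(type_names, function(tn) {
    ls <- locals[[tn]]
    lid <- stats::setNames(seq_along(ls), ls)
    pf <- lapply(ls, function(nm) component_prefixes(model, nm))
    list(
      prefix_action = lapply(pf, function(p) as.integer(act_id[p$action]) - 1L),
      prefix_rate = lapply(pf, function(p) as.numeric(p$rate)),
      prefix_target = lapply(pf, function(p) as.integer(lid[p$target]) - 1L))
  })

  # instances, in group order
  inst_group <- rep.int(seq_len(nrow(groups)), groups$copies)
  inst_type <- match(groups$component[inst_group], type_names)
  inst_init <- rep.int(1L, length(inst_group))  # each group starts at its component
  instances <- cbind(type = inst_type - 1L, init = inst_init - 1L)

  # cooperation tree, with replications expanded to balanced parallel trees
  nodes <- list()
  add_node <- function(kind, a, b = -1L, sync = integer()) {
    nodes[[length(nodes) + 1L]] <<- list(kind = kind, a = as.integer(a),
                                         b = as.integer(b), sync = as.integer(sync))
    length(nodes) - 1L
  }
  inst_of_group <- split(seq_along(inst_group) - 1L, inst_group)
  balanced <- function(idx) {
    if (length(idx) == 1L) return(add_node(0L, idx))
    h <- length(idx) %/% 2L
    l <- balanced(idx[seq_len(h)]); r <- balanced(idx[-seq_len(h)])
    add_node(1L, l, r)
  }
  gi <- 0L
  build <- function(sys) {
    if (inherits(sys, "cpp_coop")) {
      l <- build(sys$left); r <- build(sys$right)
      return(add_node(1L, l, r, sync = act_id[sys$sync] - 1L))
    }
    gi <<- gi + 1L
    balanced(inst_of_group[[gi]])
  }
  root <- build(model$system)

  list(types = types, instances = instances, tree = nodes, root = root,
       n_actions = length(acts), actions = acts, type_names = type_names,
       locals = locals, groups = groups, inst_group = inst_group)
}

#' Explore the reachable state space of a model
#'
#' Breadth-first closure from the initial global state (every instance in
#' its defining component) under the cooperation semantics: a shared action
#' proceeds at the minimum of the operands' apparent rates, split across the
#' enabled source combinations in proportion to their contribution;
#' non-shared actions interleave. State ordering is the deterministic BFS
#' discovery order, so generator matrices and reports are reproducible.
#'
#' @param model A [cpp_model()].
#' @param max_states State budget; exploration stops with an error (never a
#'   silent truncation) if the reachable set exceeds it.
#' @return A transition system (class `cpp_ts`): a list with `n_states`,
#'   `states` (integer matrix of per-instance local states), `edges`
#'   (tibble `src`, `tgt`, `action`, `rate`), `instances`, `groups`,
#'   `local_names`, and `initial = 1`.
#' @export
#' @examples
#' m <- parse_model("P = (a, 1).Q; Q = (b, 2).P; P[1]")
#' explore_state_space(m)$n_states
explore_state_space <- function(model, max_states = 1e6) {
  cm <- compile_model(model)
  res <- .explore_cpp(cm[c("types", "instances", "tree", "root", "n_actions")],
                      as.numeric(max_states))
  edges <- tibble::tibble(src = res$src, tgt = res$tgt,
                          action = cm$actions[res$action], rate = res$rate)
  structure(list(
    model = model,
    n_states = nrow(res$states),
    states = res$states,
    edges = edges,
    instances = tibble::tibble(
      instance = seq_along(cm$inst_group),
      group = cm$groups$group[cm$inst_group],
      component = cm$groups$component[cm$inst_group]),
    groups = cm$groups,
    local_names = stats::setNames(cm$locals[cm$groups$component], cm$groups$group),
    actions = cm$actions,
    initial = 1L), class = "cpp_ts")
}

#' @export
print.cpp_ts <- function(x, ...) {
  cat(sprintf("<%s> %d states, %d transitions, %d instances in %d groups\n",
              class(x)[1], x$n_states, nrow(x$edges),
              if (!is.null(x$instances)) nrow(x$instances) else NA_integer_,
              nrow(x$groups)))
  invisible(x)
}

#' Global states as tuples of local-state names
#'
#' @param ts A transition system from [explore_state_space()].
#' @return Character matrix, one row per global state, one column per
#'   instance.
#' @export
state_tuples <- function(ts) {
  stopifnot(inherits(ts, "cpp_ts"), !is.null(ts$states))
  out <- matrix("", ts$n_states, ncol(ts$states))
  for (j in seq_len(ncol(ts$states))) {
    nm <- ts$local_names[[ts$instances$group[j]]]
    out[, j] <- nm[ts$states[, j]]
  }
  colnames(out) <- ts$instances$group
  out
}

#' Assemble the infinitesimal generator
#'
#' Off-diagonal entries sum the rates of all transitions between a pair of
#' distinct states; each diagonal entry is the negative sum of the other
#' entries of its row, so rows sum to zero. Self-loop transitions (which do
#' not change the global state) do not contribute.
#'
#' @param ts A transition system, or an aggregated system from
#'   [aggregate_states()].
#' @return A sparse `dgCMatrix` of dimension `n_states`, units 1/day.
#' @export
build_generator <- function(ts) {
  n <- ts$n_states
  e <- ts$edges[ts$edges$src != ts$edges$tgt, ]
  if (nrow(e)) {
    e <- dplyr::summarise(dplyr::group_by(e, .data$src, .data$tgt),
                          rate = sum(.data$rate), .groups = "drop")
    Q <- Matrix::sparseMatrix(i = e$src, j = e$tgt, x = e$rate, dims = c(n, n))
  } else {
    Q <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(), dims = c(n, n))
  }
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  Q
}

# Strongly-connected-component check; returns NULL if irreducible, else a
# description of the offending components.
scc_check <- function(Q) {
  n <- nrow(Q)
  if (n == 1L) return(NULL)
  tr <- Matrix::summary(methods::as(Matrix::drop0(Q), "generalMatrix"))
  off <- tr[tr$i != tr$j & tr$x > 0, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    data.frame(from = off$i, to = off$j),
    directed = TRUE, vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g, mode = "strong")
  if (comp$no == 1L) return(NULL)
  sizes <- table(comp$membership)
  sprintf("chain is reducible: %d strongly connected components (sizes %s)",
          comp$no, paste(as.integer(sizes), collapse = ", "))
}

#' Solve for the steady-state distribution
#'
#' Solves the global balance equations `pi Q = 0` with the normalisation
#' condition `sum(pi) = 1`, as a least-squares solve of the transposed
#' generator augmented with the normalisation row. The chain must be
#' irreducible; reducibility is detected by strongly-connected-component
#' analysis and reported as an error.
#'
#' @param Q Generator matrix (square; rows summing to zero), or a
#'   transition system, in which case the generator is built first.
#' @param tol Acceptance tolerance on the residual `max |pi Q|`.
#' @return An object of class `cpp_steady`: list with `pi`, `residual`,
#'   `n_states`, `method`.
#' @export
#' @examples
#' Q <- matrix(c(-7, 7, 6, -6), 2, 2, byrow = TRUE)
#' solve_steady_state(Q)$pi
solve_steady_state <- function(Q, tol = 1e-10) {
  if (inherits(Q, "cpp_ts")) Q <- build_generator(Q)
  n <- nrow(Q)
  stopifnot(n == ncol(Q))
  bad <- scc_check(Q)
  if (!is.null(bad)) abort(bad)
  b <- c(rep(0, n), 1)
  if (n <= 4096) {
    A <- rbind(t(as.matrix(Q)), rep(1, n))
    pi <- qr.coef(qr(A), b)
    method <- "dense-qr"
  } else {
    A <- rbind(Matrix::t(Q), Matrix::sparseMatrix(i = rep(1L, n), j = seq_len(n),
                                                  x = 1, dims = c(1L, n)))
    pi <- as.numeric(Matrix::solve(Matrix::crossprod(A), Matrix::crossprod(A, b)))
    method <- "sparse-normal-equations"
  }
  pi <- pmax(as.numeric(pi), 0)
  pi <- pi / sum(pi)
  resid <- max(abs(as.numeric(pi %*% Q)))
  if (resid > tol)
    abort(sprintf("steady-state residual %.3g exceeds tolerance %.3g", resid, tol))
  structure(list(pi = pi, residual = resid, n_states = n, method = method),
            class = "cpp_steady")
}

#' @export
print.cpp_steady <- function(x, ...) {
  cat(sprintf("<cpp_steady> %d states, residual %.2e (%s)\n",
              x$n_states, x$residual, x$method))
  print(utils::head(x$pi, 10))
  invisible(x)
}

#' Simulate the chain by Gillespie's direct method
#'
#' Event-level stochastic simulation on an explored transition system,
#' used as an independent check of the analytic steady state and of the
#' fluid approximation. Reproducible under `set.seed()`.
#'
#' @param ts A transition system.
#' @param n_events Number of transition firings.
#' @param init Initial state index.
#' @return List with `occupancy` (time-weighted state probabilities),
#'   `time` (total simulated time), `firings` (named per-action counts) and
#'   `final_state`.
#' @export
simulate_ctmc <- function(ts, n_events, init = ts$initial) {
  acts <- ts$actions %||% sort(unique(ts$edges$action))
  res <- .simulate_ts_cpp(ts$n_states, ts$edges$src, ts$edges$tgt,
                          match(ts$edges$action, acts), ts$edges$rate,
                          length(acts), init, as.numeric(n_events))
  total <- sum(res$occupancy)
  list(occupancy = res$occupancy / total, time = total,
       firings = stats::setNames(res$firings, acts), final_state = res$final_state)
}

# ---- exports ---------------------------------------------------------------

#' Export a transition system or generator
#'
#' `write_edges_csv()` writes the labelled edge list; `write_dot()` writes a
#' GraphViz digraph of the state transition diagram; `write_generator_mtx()`
#' writes the generator in MatrixMarket sparse format.
#'
#' @param ts A transition system.
#' @param Q A generator matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @name ts-export
NULL

#' @rdname ts-export
#' @export
write_edges_csv <- function(ts, path) {
  utils::write.csv(as.data.frame(ts$edges), path, row.names = FALSE)
  invisible(path)
}

#' @rdname ts-export
#' @export
write_dot <- function(ts, path) {
  lab <- if (!is.null(ts$states)) {
    apply(state_tuples(ts), 1, paste, collapse = ",")
  } else {
    apply(ts$counts, 1, function(r) paste(r, collapse = ","))
  }
  lines <- c("digraph ts {",
             sprintf("  s%d [label=\"S%d\\n(%s)\"];", seq_len(ts$n_states),
                     seq_len(ts$n_states), lab),
             sprintf("  s%d -> s%d [label=\"%s, %.4g\"];",
                     ts$edges$src, ts$edges$tgt, ts$edges$action, ts$edges$rate),
             "}")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname ts-export
#' @export
write_generator_mtx <- function(Q, path) {
  Matrix::writeMM(methods::as(Q, "generalMatrix"), path)
  invisible(path)
}
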