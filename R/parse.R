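# Textual model language.
#
# Defining equations and one system statement, each terminated by ';':
#
#   Patient_place0 = (beta, 1).Patient_place1;
#   Patient_place1 = (alpha, 3).Patient_place0;
#   Wait_room0_idle = (beta, 1).Wait_room0_busy;
#   Wait_room0_busy = (gamma, 1000).Wait_room0_idle;
#   Resource_idle_place1 = (gamma, 1000).Resource_busy_place1;
#   Resource_busy_place1 = (alpha, 3).Resource_idle_place1;
#   Patient_place0[2] <beta, alpha> (Wait_room0_idle[2] <gamma> Resource_idle_place1[1]);
#
# Rates may be written as a product `p * r` to express a routing probability
# scaling a base rate.  '||' composes with an empty cooperation set.
# Comments run from '#' or '//' to end of line.  Whitespace is free.

tokenize_model <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- list()
  pat <- paste0(
    "^(\\s+)|^(#[^\n]*|//[^\n]*)|",
    "^([A-Za-z][A-Za-z0-9_]*)|",
    "^([0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?|\\.[0-9]+([eE][+-]?[0-9]+)?)|",
    "^(\\|\\||[=+.,;*<>()\\[\\]])")
  for (ln in seq_along(lines)) {
    s <- lines[[ln]]; col <- 1L
    while (nzchar(s)) {
      m <- regmatches(s, regexpr(pat, s, perl = TRUE))
      if (!length(m) || !nzchar(m)) {
        abort(sprintf("syntax error at line %d, column %d: unexpected character '%s'",
                      ln, col, substr(s, 1, 1)))
      }
      type <- if (grepl("^\\s", m)) "ws"
      else if (grepl("^(#|//)", m)) "ws"
      else if (grepl("^[A-Za-z]", m)) "name"
      else if (grepl("^[0-9.]", m)) "num"
      else "punct"
      if (type != "ws")
        toks[[length(toks) + 1L]] <- list(type = type, value = m, line = ln, col = col)
      col <- col + nchar(m)
      s <- substr(s, nchar(m) + 1L, nchar(s))
    }
  }
  toks
}

#' Parse a model from its textual description
#'
#' Reads defining equations (`Name = (action, rate).Name + ...;`) and a
#' single system statement (cooperation sets in angle brackets, `||` for
#' interleaving, `Name[N]` for N parallel copies), validates the result and
#' returns a model. Parsing composed with [unparse_model()] is idempotent.
#'
#' @param text Model description (single string; may span lines).
#' @param meta Optional metadata list passed to [cpp_model()].
#' @return A validated [cpp_model()].
#' @export
#' @examples
#' parse_model("P = (a, 1).P; P[2]")
parse_model <- function(text, meta = list()) {
  toks <- tokenize_model(text)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NULL
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  fail <- function(msg, tok = peek()) {
    where <- if (is.null(tok)) "at end of input"
    else sprintf("at line %d, column %d (near '%s')", tok$line, tok$col, tok$value)
    abort(sprintf("syntax error %s: %s", where, msg))
  }
  expect <- function(value) {
    t <- take()
    if (is.null(t) || t$value != value) fail(sprintf("expected '%s'", value), t)
    t
  }
  at <- function(value) { t <- peek(); !is.null(t) && t$value == value }

  parse_number <- function() {
    t <- take()
    if (is.null(t) || t$type != "num") fail("expected a number", t)
    as.numeric(t$value)
  }
  parse_prefix <- function() {
    expect("(")
    a <- take()
    if (is.null(a) || a$type != "name") fail("expected an action label", a)
    expect(",")
    r1 <- parse_number()
    w <- NULL; rate <- r1
    if (at("*")) { take(); rate <- parse_number(); w <- r1 }
    if (rate <= 0 || (!is.null(w) && w <= 0))
      fail(sprintf("nonpositive rate for action '%s'", a$value), a)
    expect(")"); expect(".")
    tgt <- take()
    if (is.null(tgt) || tgt$type != "name") fail("expected a continuation component", tgt)
    cpp_prefix(cpp_activity(a$value, rate), cpp_ref(tgt$value), weight = w)
  }
  parse_body <- function() {
    e <- parse_prefix()
    while (at("+")) { take(); e <- cpp_choice(e, parse_prefix()) }
    e
  }
  parse_sys_term <- function() {
    if (at("(")) { take(); e <- parse_sys(); expect(")"); return(e) }
    t <- take()
    if (is.null(t) || t$type != "name") fail("expected a component name", t)
    if (at("[")) {
      take(); n <- parse_number(); expect("]")
      if (n != as.integer(n) || n < 1) fail("replication count must be a positive integer", t)
      return(cpp_replicate(t$value, as.integer(n)))
    }
    cpp_instance(t$value)
  }
  parse_sys <- function() {
    e <- parse_sys_term()
    repeat {
      if (at("||")) {
        take(); e <- cpp_parallel(e, parse_sys_term())
      } else if (at("<")) {
        take()
        sync <- character()
        if (!at(">")) {
          repeat {
            t <- take()
            if (is.null(t) || t$type != "name") fail("expected an action label", t)
            sync <- c(sync, t$value)
            if (at(",")) take() else break
          }
        }
        expect(">")
        e <- cpp_coop(e, parse_sys_term(), sync)
      } else break
    }
    e
  }

  comps <- list(); sys <- NULL
  while (!is.null(peek())) {
    t <- peek()
    is_def <- t$type == "name" && pos + 1L <= length(toks) && toks[[pos + 1L]]$value == "="
    if (is_def) {
      nm <- take()$value; take()  # '='
      if (!is.null(comps[[nm]]))
        fail(sprintf("duplicate definition of '%s'", nm), t)
      body <- parse_body()
      kind <- if (grepl("(_idle|_busy)($|_)", nm)) "resource" else "state"
      comps[[nm]] <- cpp_component(nm, body, kind)
    } else {
      if (!is.null(sys)) fail("more than one system statement", t)
      sys <- parse_sys()
    }
    expect(";")
  }
  if (is.null(sys)) abort("model has no system statement")
  if (!length(comps)) abort("model has no defining equations")
  cpp_model(comps, sys, meta = meta)
}

fmt_num <- function(x) {
  s <- trimws(formatC(x, format = "g", digits = 15))
  sub("e([+-])0+([0-9])", "e\\1\\2", s)
}

unparse_expr <- function(e) {
  if (inherits(e, "cpp_prefix")) {
    r <- if (is.null(e$weight) || e$weight == 1) fmt_num(e$activity$rate)
    else paste0(fmt_num(e$weight), "*", fmt_num(e$activity$rate))
    sprintf("(%s, %s).%s", e$activity$action, r, e$continuation$name)
  } else if (inherits(e, "cpp_choice")) {
    paste(unparse_expr(e$left), "+", unparse_expr(e$right))
  } else if (inherits(e, "cpp_ref")) e$name
  else abort("not a process expression")
}

unparse_sys <- function(s) {
  if (inherits(s, "cpp_inst")) return(s$component)
  if (inherits(s, "cpp_rep")) return(sprintf("%s[%d]", s$component, s$copies))
  op <- if (length(s$sync)) sprintf("<%s>", paste(s$sync, collapse = ", ")) else "||"
  right <- unparse_sys(s$right)
  if (inherits(s$right, "cpp_coop")) right <- paste0("(", right, ")")
  left <- unparse_sys(s$left)
  if (inherits(s$left, "cpp_coop")) left <- paste0("(", left, ")")
  paste(left, op, right)
}

#' Serialise a model to its textual form
#'
#' @param model A [cpp_model()].
#' @return A single string in the grammar accepted by [parse_model()].
#' @export
unparse_model <- function(model) {
  defs <- vapply(model$components, function(cmp)
    sprintf("%s = %s;", cmp$name, unparse_expr(cmp$body)), "")
  paste0(paste(defs, collapse = "\n"), "\n", unparse_sys(model$system), ";\n")
}

#' Read a model from a file
#'
#' @param path Path to a UTF-8 model file.
#' @param meta Optional metadata list.
#' @return A validated [cpp_model()].
#' @export
read_model <- function(path, meta = list()) {
  parse_model(paste(readLines(path, warn = FALSE), collapse = "\n"), meta = meta)
}

#' Write a model to a file
#'
#' @param model A [cpp_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  writeLines(unparse_model(model), path)
  invisible(path)
}
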