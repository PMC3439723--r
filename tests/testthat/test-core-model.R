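test_that("defining equations parse into the expected structure", {
  m <- parse_model(paste(
    "Patient_LAS = (do_FAST, 24).Patient_A_E_Resus;",
    "Patient_A_E_Resus = (assess, 32).Patient_LAS;",
    "Patient_LAS[1];", sep = "\n"))
  cmp <- m$components[["Patient_LAS"]]
  expect_s3_class(cmp$body, "cpp_prefix")
  expect_equal(cmp$body$activity$action, "do_FAST")
  expect_equal(cmp$body$activity$rate, 24)
  expect_equal(cmp$body$continuation$name, "Patient_A_E_Resus")

  # smallest cyclic model: a self-loop
  m2 <- parse_model("P = (a, 1).P; P[1];")
  expect_equal(derivative_set(m2, "P"), "P")
})

test_that("rate products express branch probabilities", {
  m <- parse_model(paste(
    "P = (a, 0.3*10).Q + (a, 0.7*10).R;",
    "Q = (b, 1).P; R = (c, 1).P;",
    "P[1];", sep = "\n"))
  pf <- component_prefixes(m, "P")
  expect_equal(sort(pf$rate), c(3, 7))
  expect_equal(pf$weight[order(pf$rate)], c(0.3, 0.7))
  expect_equal(sum(pf$rate), 10)  # branch rates sum to the parent rate
})

test_that("parse errors carry positions and name the problem", {
  expect_error(parse_model("P = (a, 1).Q; P[1];"), "undefined component 'Q'")
  expect_error(parse_model("P = (a, 0).P; P[1];"), "nonpositive rate")
  expect_error(parse_model("P = (a, 1).P; P = (b, 1).P; P[1];"),
               "duplicate definition")
  expect_error(parse_model("P = (a, 1).P"), "expected ';'")
  expect_error(parse_model("P = (a 1).P; P[1];"), "line 1")
  expect_error(parse_model("P = (a, 1).P;"), "no system statement")
  expect_error(parse_model("P = (a,1).P; Q = (b,1).Q; P[1] <b> Q[1];"),
               "does not occur in both operands")
})

test_that("parse/unparse round-trip is idempotent on generated models", {
  for (s in 1:50) {
    m <- assemble_system(generate_fixture(s))
    u1 <- unparse_model(m)
    u2 <- unparse_model(parse_model(u1))
    expect_identical(u1, u2)
    u3 <- unparse_model(parse_model(u2))
    expect_identical(u2, u3)
  }
})

test_that("model files read back into equivalent chains", {
  path <- system.file("extdata", "simple_pathway.txt", package = "cpepa")
  m <- read_model(path)
  expect_identical(unparse_model(m), unparse_model(simple_model()))
  expect_equal(explore_state_space(m)$n_states, 10)
  out <- withr::local_tempfile(fileext = ".txt")
  write_model(m, out)
  expect_identical(unparse_model(read_model(out)), unparse_model(m))
})

test_that("derivative sets close over prefixes and choices", {
  # an idle/busy resource pair has exactly its two states
  m <- assemble_system(simple_pathway_config())
  expect_setequal(derivative_set(m, "Resource_place1_idle"),
                  c("Resource_place1_idle", "Resource_place1_busy"))
  expect_length(derivative_set(m, "Wait_room0_idle"), 2)
  # the stroke patient chain has five places
  sm <- stroke_model()
  ds <- derivative_set(sm, "Patient_Home")
  expect_length(ds, 5)
  expect_setequal(ds, c("Patient_Home", "Patient_LAS", "Patient_A_E_Resus",
                        "Patient_CT_scan", "Patient_Normal_treat"))
  # fixed point: the derivative set of any member is the same set
  for (nm in ds) expect_setequal(derivative_set(sm, nm), ds)
  expect_error(derivative_set(sm, "NoSuch"), "unknown component")
})

test_that("apparent rates sum over enabled prefixes and respect cooperation", {
  m <- parse_model(paste(
    "P = (a, 3).P;",
    "Q = (a, 0.5).Q2 + (a, 0.5).Q3; Q2 = (b, 1).Q; Q3 = (b, 1).Q;",
    "P[1] || Q[1];", sep = "\n"))
  expect_equal(apparent_rate(m, "P", "a"), 3)        # single prefix
  expect_equal(apparent_rate(m, "Q", "a"), 1)        # additive over choice
  expect_equal(apparent_rate(m, "Q", "c"), 0)        # not enabled
  # additive over parallel replicas: two patients each enabling beta at 1
  sm <- simple_model()
  expect_equal(apparent_rate(m, cpp_replicate("P", 2), "a"), 6)
  expect_equal(apparent_rate(sm, sm$system$left, "beta"), 2)
  # cooperation takes the minimum of the operands over shared actions
  expect_equal(apparent_rate(sm, sm$system, "beta"), 2)
  expect_equal(apparent_rate(sm, sm$system, "gamma"), 0)  # rooms all idle
})

test_that("model validation enforces the structural invariants", {
  expect_error(cpp_activity("a", -1), "positive")
  expect_error(cpp_replicate("P", 0), ">= 1")
  m <- simple_model()
  expect_silent(validate_model(m))
  # a cooperation set action must occur syntactically on both sides
  bad <- cpp_model(m$components,
                   cpp_coop(cpp_replicate("Patient_place0", 2),
                            cpp_replicate("Resource_place1_idle", 1),
                            sync = "beta"),
                   validate = FALSE)
  expect_error(validate_model(bad), "beta")
})
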