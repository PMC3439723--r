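test_that("reachability matches the hand-derivable state spaces", {
  ts <- simple_ts()
  expect_equal(ts$n_states, 10)
  # the initial state is the all-idle, all-home five-tuple
  expect_equal(unname(state_tuples(ts)[1, ]),
               c("Patient_place0", "Patient_place0", "Wait_room0_idle",
                 "Wait_room0_idle", "Resource_place1_idle"))
  # structural invariant of the pathway: patients in treatment equal
  # busy waiting rooms plus busy resources, in every reachable state
  tup <- state_tuples(ts)
  p1 <- rowSums(tup[, 1:2] == "Patient_place1")
  wb <- rowSums(tup[, 3:4] == "Wait_room0_busy")
  rb <- (tup[, 5] == "Resource_place1_busy") + 0
  expect_equal(p1, wb + rb)

  # one patient, one directly-coupled resource: a 2-cycle
  cfg <- pathway_config(
    tibble::tibble(department = "place1", activity = "alpha", rate = 3,
                   resource = "Res", copies = 1, waiting_room = FALSE),
    num_patients = 1, r_income = 1, entry_action = "beta")
  ts2 <- explore_state_space(assemble_system(cfg))
  expect_equal(ts2$n_states, 2)
  expect_setequal(ts2$edges$action, c("beta", "alpha"))
})

test_that("the state budget is an explicit error, never a truncation", {
  expect_error(explore_state_space(simple_model(), max_states = 5),
               "state budget exceeded")
})

test_that("cooperation splits shared rates across source combinations", {
  ts <- simple_ts()
  # from the initial state, the shared beta proceeds at min(2, 2) = 2,
  # split equally over the four patient-room combinations
  e1 <- ts$edges[ts$edges$src == 1, ]
  expect_equal(nrow(e1), 4)
  expect_equal(unique(e1$action), "beta")
  expect_equal(e1$rate, rep(0.5, 4))
  expect_equal(sum(e1$rate), 2)
})

test_that("generator rows sum to zero and match a brute-force assembly", {
  # two-state chain with rates 7 and 6
  m <- parse_model("S1 = (f, 7).S2; S2 = (g, 6).S1; S1[1];")
  Q <- as.matrix(build_generator(explore_state_space(m)))
  expect_equal(unname(Q), matrix(c(-7, 7, 6, -6), 2, 2, byrow = TRUE))

  # a pure self-loop yields the 1x1 zero generator
  m1 <- parse_model("P = (a, 1).P; P[1];")
  expect_equal(as.matrix(build_generator(explore_state_space(m1))),
               matrix(0, 1, 1), ignore_attr = TRUE)

  for (s in 1:20) {
    ts <- explore_state_space(assemble_system(generate_fixture(s)))
    Q <- build_generator(ts)
    expect_lt(max(abs(Matrix::rowSums(Q))), 1e-12)
    offdiag <- Q - Matrix::Diagonal(x = Matrix::diag(Q))
    expect_gte(min(offdiag), 0)
    expect_equal(unname(as.matrix(Q)), dense_generator(ts))
  }
})

test_that("steady states satisfy balance and reproduce the worked chains", {
  st <- solve_steady_state(matrix(c(-7, 7, 6, -6), 2, 2, byrow = TRUE))
  expect_equal(round(st$pi, 2), c(0.46, 0.54))
  expect_equal(solve_steady_state(matrix(c(-2, 2, 2, -2), 2, 2))$pi,
               c(0.5, 0.5))

  # flux balance per state, on fixtures
  for (s in 1:20) {
    ts <- explore_state_space(assemble_system(generate_fixture(s)))
    Q <- build_generator(ts)
    st <- solve_steady_state(Q)
    expect_gte(min(st$pi), 0)
    expect_equal(sum(st$pi), 1)
    out_rate <- -Matrix::diag(Q)
    influx <- as.numeric(st$pi %*% (Q - Matrix::Diagonal(x = Matrix::diag(Q))))
    expect_lt(max(abs(st$pi * out_rate - influx)), 1e-10)
  }
})

test_that("reducible chains are refused with a diagnosis", {
  Q <- matrix(c(-1, 1, 0, 0), 2, 2, byrow = TRUE)  # absorbing second state
  expect_error(solve_steady_state(Q), "strongly connected components")
})

test_that("analytic steady state agrees with long-run simulation", {
  ts <- simple_ts()
  st <- solve_steady_state(ts)
  set.seed(2024)
  nb <- 5
  occ <- replicate(nb, simulate_ctmc(ts, 2e5)$occupancy)
  mean_occ <- rowMeans(occ)
  se <- apply(occ, 1, stats::sd) / sqrt(nb)
  z <- (st$pi - mean_occ) / pmax(se, 1e-12)
  expect_lt(max(abs(z[st$pi > 1e-4])), 3)
})
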