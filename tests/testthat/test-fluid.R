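test_that("the fluid system of the illustrative model has the documented shape", {
  odes <- derive_odes(simple_model())
  expect_equal(nrow(odes$vars), 6)
  eq <- format(odes)
  # patient drift couples to the waiting room through a minimum term and
  # regains mass from the busy resource
  p0 <- eq[grepl("N\\(Patient_place0\\)'", eq)]
  expect_match(p0, "min(", fixed = TRUE)
  expect_match(p0, "Patient_place0")
  expect_match(p0, "Wait_room0_idle")
  expect_match(p0, "Resource_place1_busy")
  # the fast coupling appears at its configured rate
  expect_match(paste(eq, collapse = " "), "1000", fixed = TRUE)
  # initial conditions are the replication counts
  expect_equal(odes$vars$init, c(2, 0, 2, 0, 1, 0))
})

test_that("an isolated cyclic component yields linear equations", {
  odes <- derive_odes(parse_model("P = (a, 2).Q; Q = (b, 5).P; P[4];"))
  expect_false(any(grepl("min(", format(odes), fixed = TRUE)))
  # linear system: analytic steady state 4 * (5, 2) / 7
  ss <- fluid_steady_state(odes)
  expect_true(ss$converged)
  expect_equal(unname(ss$counts), 4 * c(5, 2) / 7, tolerance = 1e-6)
})

test_that("fluid drift at t = 0 equals the exact CTMC expected drift", {
  for (s in 1:20) {
    m <- assemble_system(generate_fixture(s))
    ts <- explore_state_space(m)
    odes <- derive_odes(m)
    expect_equal(odes$rhs(0, odes$vars$init)[[1]],
                 ctmc_expected_drift(ts, odes, 1L), tolerance = 1e-12)
  }
})

test_that("compiled and reference drift evaluations agree", {
  set.seed(11)
  for (s in c(2, 4, 20)) {
    odes <- derive_odes(assemble_system(generate_fixture(s)))
    for (k in 1:5) {
      N <- odes$vars$init + stats::runif(nrow(odes$vars))
      expect_equal(odes$rhs(0, N)[[1]], odes$rhs_r(0, N)[[1]], tolerance = 1e-14)
    }
  }
})

test_that("group totals are conserved along trajectories", {
  odes <- derive_odes(simple_model())
  traj <- integrate_odes(odes, horizon = 5)
  totals <- traj |>
    dplyr::group_by(.data$time, .data$group) |>
    dplyr::summarise(n = sum(.data$count), .groups = "drop") |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(spread = max(.data$n) - min(.data$n))
  expect_lt(max(totals$spread), 1e-7)
})

test_that("the busy-resource count peaks within about two days", {
  odes <- derive_odes(simple_model())
  traj <- integrate_odes(odes, horizon = 5)
  busy <- traj[traj$local == "Resource_place1_busy", ]
  expect_equal(busy$count[busy$time == 0], 0)
  peak <- max(busy$count)
  expect_gte(max(busy$count[busy$time <= 2]), 0.99 * peak)
})

test_that("fluid trajectories track the simulated mean within Monte-Carlo error", {
  m <- assemble_system(simple_pathway_config(6, 6, 3))
  ts <- explore_state_space(m)
  odes <- derive_odes(m)
  cks <- c(0.25, 0.5, 1, 2, 4)
  fl <- subset(integrate_odes(odes, times = c(0, cks)),
               local == "Resource_place1_busy")
  fl <- as.numeric(tapply(fl$count, fl$time, sum))[-1]
  busy <- rowSums(state_tuples(ts)[, ts$instances$group == ts$groups$group[3],
                                   drop = FALSE] == "Resource_place1_busy")
  set.seed(7)
  sim <- gillespie_at(ts, busy, cks, nrep = 500)
  z <- (fl - colMeans(sim)) / (apply(sim, 2, stats::sd) / sqrt(nrow(sim)))
  expect_lt(max(abs(z)), 3)
})

test_that("the fluid fixed point satisfies the drift balance", {
  for (s in c(1, 3, 9)) {
    odes <- derive_odes(assemble_system(generate_fixture(s)))
    ss <- fluid_steady_state(odes, tol = 1e-9)
    expect_true(ss$converged)
    expect_lt(max(abs(odes$rhs(ss$time, as.numeric(ss$counts))[[1]])), 1e-6)
  }
  # a pathway with no admissions stays at its initial state: zero drift at
  # an all-home configuration with idle resources everywhere
  odes <- derive_odes(simple_model())
  y0 <- odes$vars$init
  y0 <- ifelse(odes$vars$local == "Patient_place0", 0, y0)  # no patients at all
  expect_equal(max(abs(odes$rhs(0, y0)[[1]])), 0)
})
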