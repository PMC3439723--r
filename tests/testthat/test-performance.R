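test_that("utilisation sums busy-state probabilities over copies", {
  ts <- simple_ts()
  st <- solve_steady_state(ts)
  u <- resource_utilisation(st, ts, "Resource_place1")
  expect_equal(round(u, 2), 0.47)
  # with no probability mass on busy states the utilisation is zero
  pi0 <- c(1, rep(0, ts$n_states - 1))
  expect_equal(resource_utilisation(pi0, ts, "Resource_place1"), 0)
  expect_error(resource_utilisation(st, ts, "NoSuchResource"), "unknown resource")
})

test_that("multi-copy utilisation equals mean busy count over copies", {
  for (s in c(4, 7, 24)) {  # fixtures with at least one 2-copy resource
    m <- assemble_system(generate_fixture(s))
    ts <- explore_state_space(m)
    st <- solve_steady_state(ts)
    for (i in seq_len(nrow(m$meta$resources))) {
      rn <- m$meta$resources$resource[i]
      busy_nm <- m$meta$resources$busy[i]
      # independent counting pass over the state tuples
      tup <- state_tuples(ts)
      cols <- which(ts$instances$group == m$meta$resources$group[i])
      busy_count <- rowSums(tup[, cols, drop = FALSE] == busy_nm)
      expect_equal(resource_utilisation(st, ts, rn),
                   sum(st$pi * busy_count) / length(cols))
    }
  }
})

test_that("throughput is discharge rate times expected busy copies", {
  ts <- simple_ts()
  st <- solve_steady_state(ts)
  expect_equal(round(throughput(st, ts), 2), 1.41)
  expect_equal(throughput(st, ts),
               3 * resource_utilisation(st, ts, "Resource_place1"))
  # zero utilisation implies zero throughput
  pi0 <- c(1, rep(0, ts$n_states - 1))
  expect_equal(throughput(pi0, ts), 0)
  expect_error(throughput(st, ts, discharge_action = "nope",
                          discharge_rate = 1, final_resource = "Resource_place1"),
               "not present")
})

test_that("throughput equals the steady-state flux of the discharge action", {
  for (s in 1:20) {
    m <- assemble_system(generate_fixture(s))
    ts <- explore_state_space(m)
    st <- solve_steady_state(ts)
    expect_equal(throughput(st, ts),
                 action_flux(st, ts, m$meta$discharge$action), tolerance = 1e-10)
    # conservation: discharges balance admissions in the cyclic pathway
    expect_equal(action_flux(st, ts, m$meta$discharge$action),
                 action_flux(st, ts, m$meta$entry$action), tolerance = 1e-8)
  }
})

test_that("performance measures are invariant under aggregation", {
  for (s in 1:20) {
    m <- assemble_system(generate_fixture(s))
    ts <- explore_state_space(m)
    st <- solve_steady_state(ts)
    ag <- aggregate_states(ts)
    sa <- solve_steady_state(ag)
    for (rn in m$meta$resources$resource)
      expect_equal(resource_utilisation(sa, ag, rn),
                   resource_utilisation(st, ts, rn), tolerance = 1e-9)
    expect_equal(throughput(sa, ag), throughput(st, ts), tolerance = 1e-9)
  }
})

test_that("reports are tidy tables and round-trip through files", {
  sol <- solve_pathway(simple_model())
  expect_s3_class(sol$report, "tbl_df")
  expect_equal(sol$report$measure, c("utilisation", "throughput"))
  expect_equal(glance(sol)$throughput, 1.41, tolerance = 1e-2)
  expect_equal(nrow(tidy(sol$steady)), sol$ts$n_states)

  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_report(sol$report, csv)
  write_report(sol$report, js)
  back <- utils::read.csv(csv)
  expect_equal(back$value, sol$report$value)
  expect_true(jsonlite::validate(paste(readLines(js), collapse = "")))
})
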