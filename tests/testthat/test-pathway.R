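test_that("the stroke model encodes the configured departments and rates", {
  m <- stroke_model()
  acts <- model_activities(m)
  rate_of <- function(a) acts$rate[acts$action == a]
  expect_equal(rate_of("do_FAST"), 24)          # 1 h
  expect_equal(rate_of("assess_and_investigate"), 32)  # 0.75 h
  expect_equal(rate_of("scan"), 8)              # 3 h
  expect_equal(rate_of("treat_HASU"), 0.5)      # 48 h
  expect_length(derivative_set(m, "Patient_Home"), 5)
  # ten resource defining equations: team, two waiting rooms, scanner, bed
  res <- Filter(function(cmp) cmp$kind == "resource", m$components)
  expect_length(res, 10)
  expect_equal(m$meta$resources$copies, c(3L, 3L, 20L))
  expect_equal(m$meta$discharge,
               list(action = "treat_HASU", rate = 0.5, resource = "Bed"))
  # mean daily admissions: population times per-patient rate
  expect_equal(m$meta$entry$rate * m$meta$config$num_patients, 4)
  # the unlimited ambulance stage carries no resource component
  expect_false(any(grepl("Ambulance", names(m$components))))
})

test_that("hours convert to daily rates by the 24/h rule", {
  cfg <- pathway_config(
    tibble::tibble(department = "d", activity = "serve", hours = 3,
                   resource = "R", copies = 1, waiting_room = FALSE),
    num_patients = 1, r_income = 1)
  expect_equal(cfg$departments$rate, 8)
})

test_that("routing branches split the service rate by probability", {
  cfg <- pathway_config(
    tibble::tibble(department = c("ae", "ct"),
                   activity = c("assess", "scan"), rate = c(32, 8),
                   resource = c("Team", "Scanner"), copies = c(1, 1),
                   waiting_room = FALSE),
    num_patients = 2, r_income = 0.5,
    routing = list(list(from = "ae", to = c("ct", "Home"),
                        prob = c(0.83, 0.17))))
  chain <- build_patient_chain(cfg)
  m <- assemble_system(cfg)
  pf <- component_prefixes(m, "Patient_ae")
  expect_equal(nrow(pf), 2)
  expect_equal(sum(pf$rate), 32)  # effective branch rates sum to the rate
  expect_equal(sort(pf$rate / 32), c(0.17, 0.83))
  expect_setequal(pf$target, c("Patient_ct", "Patient_Home"))
  expect_error(pathway_config(cfg$departments, num_patients = 1, r_income = 1,
                              routing = list(list(from = "ae",
                                                  to = c("ct", "Home"),
                                                  prob = c(0.6, 0.6)))),
               "sum to")
})

test_that("waiting rooms insert the fast relay pair", {
  m <- assemble_system(simple_pathway_config())
  # Wait room: seized on beta, released by the fast coupling
  wi <- component_prefixes(m, "Wait_room0_idle")
  expect_equal(wi$action, "beta"); expect_equal(wi$rate, 1)
  wb <- component_prefixes(m, "Wait_room0_busy")
  expect_equal(wb$action, "gamma"); expect_equal(wb$rate, 1000)
  ri <- component_prefixes(m, "Resource_place1_idle")
  expect_equal(ri$action, "gamma")
  rb <- component_prefixes(m, "Resource_place1_busy")
  expect_equal(rb$action, "alpha"); expect_equal(rb$rate, 3)
  # direct coupling blocks admission instead: the entry action is shared
  # with the resource itself
  cfg <- pathway_config(
    tibble::tibble(department = "place1", activity = "alpha", rate = 3,
                   resource = "Res", copies = 1, waiting_room = FALSE),
    num_patients = 2, r_income = 1, entry_action = "beta")
  m2 <- assemble_system(cfg)
  expect_equal(component_prefixes(m2, "Res_idle")$action, "beta")
  ts2 <- explore_state_space(m2)
  # with one resource busy and no waiting room, the second admission waits:
  # no state has two patients in treatment
  tup <- state_tuples(ts2)
  expect_lte(max(rowSums(tup[, 1:2] == "Patient_place1")), 1)
})

test_that("waiting-room counts below the population are rejected", {
  expect_error(simple_pathway_config(num_patients = 3, num_rooms = 2),
               "below the patient count")
})

test_that("generated pathway models are cyclic and irreducible", {
  for (s in 1:50) {
    m <- assemble_system(generate_fixture(s))
    expect_silent(validate_model(m))
  }
  for (s in 1:10) {
    ts <- explore_state_space(assemble_system(generate_fixture(s)))
    # solve_steady_state errors on reducible chains; success implies one SCC
    expect_s3_class(solve_steady_state(ts), "cpp_steady")
  }
})

test_that("routing probabilities are estimated from admission counts", {
  t1 <- activity_table(strokes = 116, mimics = 27, tia = 15, direct = 156)
  ae <- estimate_routing(t1, "ae_referral")
  expect_equal(ae$numerator, 27L)
  expect_equal(ae$denominator, 158L)
  expect_equal(ae$percent, 17)
  ct <- estimate_routing(t1, "ct_referral")
  expect_equal(ct$denominator, 143L)
  expect_equal(ct$percent, 10)
  # degenerate cases
  expect_equal(estimate_routing(activity_table(0, 5, 0), "ae_referral")$probability, 1)
  expect_error(estimate_routing(activity_table(0, 0, 0), "ae_referral"),
               "zero denominator")
})

test_that("models survive a text round trip with identical dynamics", {
  m <- stroke_model(num_patients = 2)
  m2 <- parse_model(unparse_model(m))
  expect_setequal(names(m2$components), names(m$components))
  expect_identical(unparse_model(m2), unparse_model(m))
})
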