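test_that("the probe product has the observer structure", {
  m <- stroke_model(num_patients = 1)
  pm <- attach_probe(m, "Patient_LAS", "treat_HASU")
  # every patient place exists in both probe states
  expect_true(all(c("Patient_Normal_treat__NotFinished",
                    "Patient_Normal_treat__Finished",
                    "Patient_Home__NotFinished") %in% names(pm$components)))
  # the trigger flips NotFinished to Finished at the trigger's own rate
  pf <- component_prefixes(pm, "Patient_Normal_treat__NotFinished")
  expect_equal(pf$action, "treat_HASU")
  expect_equal(pf$rate, 0.5)
  expect_equal(pf$target, "Patient_Home__Finished")
  # Finished is absorbing for the probe: the trigger self-reenters Finished
  pff <- component_prefixes(pm, "Patient_Normal_treat__Finished")
  expect_equal(pff$target, "Patient_Home__Finished")
  # resources are untouched
  expect_true("Bed_idle" %in% names(pm$components))
  expect_error(attach_probe(m, "Patient_LAS", "no_such_action"),
               "not reachable")
})

test_that("the probe does not perturb the non-probe marginals", {
  m <- simple_model()
  pm <- attach_probe(m, "Patient_place0", "alpha")
  t_grid <- seq(0, 4, by = 0.5)
  base <- integrate_odes(derive_odes(m), times = t_grid)
  probed <- integrate_odes(derive_odes(pm), times = t_grid)
  for (loc in c("Resource_place1_busy", "Wait_room0_busy")) {
    b <- base$count[base$local == loc]
    p <- probed$count[probed$local == loc]
    expect_equal(p, b, tolerance = 1e-7)
  }
  # patient marginals: summing the two probe states recovers the original
  for (loc in c("Patient_place0", "Patient_place1")) {
    b <- base$count[base$local == loc]
    p <- probed |>
      dplyr::filter(grepl(paste0("^", loc, "__"), .data$local)) |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(n = sum(.data$count), .groups = "drop")
    expect_equal(p$n, b, tolerance = 1e-7)
  }
})

test_that("a trigger enabled at the start makes Finished grow immediately", {
  cfg <- pathway_config(
    tibble::tibble(department = "ward", activity = "treat", rate = 2,
                   resource = NA_character_, copies = 1, waiting_room = FALSE),
    num_patients = 3, r_income = 5, entry_action = "admit")
  pm <- attach_probe(assemble_system(cfg), "Patient_ward", "treat")
  cdf <- passage_time_cdf(pm, grid = c(0.01, 0.1, 0.5))
  expect_gt(cdf$cdf[cdf$time == 0.01], 0)
  expect_true(all(diff(cdf$cdf) > 0))
})

test_that("a single uncontended exponential stage gives 1 - exp(-rt)", {
  cfg <- pathway_config(
    tibble::tibble(department = "ward", activity = "treat", rate = 2,
                   resource = NA_character_, copies = 1, waiting_room = FALSE),
    num_patients = 1, r_income = 5, entry_action = "admit")
  m <- assemble_system(cfg)
  pm <- attach_probe(m, "Patient_ward", "treat")
  grid <- seq(0.1, 3, by = 0.1)
  cdf <- passage_time_cdf(pm, grid)
  expect_equal(cdf$cdf[-1], 1 - exp(-2 * grid), tolerance = 1e-3)
})

test_that("an uncontended multi-stage pathway matches the hypoexponential", {
  cdf <- scenario_passage_time(stroke_config(1, 1, 8), grid = seq(0.25, 5, by = 0.25))
  expect_equal(cdf$cdf[-1], hypoexp_cdf(seq(0.25, 5, by = 0.25), c(24, 32, 8, 0.5)),
               tolerance = 2e-3)
})

test_that("passage CDFs are monotone, bounded, and approach one", {
  grid <- seq(0, 12, by = 0.5)
  cdf <- scenario_passage_time(stroke_config(), grid)
  expect_true(all(diff(cdf$cdf) >= 0))
  expect_gte(min(cdf$cdf), 0)
  expect_lte(max(cdf$cdf), 1)
  expect_equal(cdf$cdf[cdf$time == 0], 0)
  expect_gt(max(cdf$cdf), 0.99)
})
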