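test_that("defaults carry the base-case inputs", {
  p <- parameter_set()
  expect_equal(p$pretest_prob, 0.02635)
  expect_equal(p$start_age, 60L)
  expect_equal(p$horizon_cycles, 20L)
  expect_equal(p$discount_rate, 0.03)
  expect_equal(p$detection_schedule, c(0.15, 0.40, 1.00))
  s <- default_strategies(p)
  expect_equal(s$ct$sensitivity, 0.779)
  expect_equal(s$ct$specificity, 0.877)
  expect_equal(s$ct_ai$sensitivity, 0.977)
  expect_equal(s$ct_ai$specificity, 0.984)
  expect_equal(s$ct$screen_cost, 161)
  expect_equal(s$ct_ai$screen_cost, 161)
  expect_equal(s$ct_ai$ai_cost, 0)
})

test_that("every base-case input maps to exactly one field", {
  # completeness: the full set of model inputs, enumerated once
  p <- parameter_set()
  expected <- c(
    "pretest_prob", "start_age", "horizon_cycles", "discount_rate", "wtp",
    "cost_fp_followup", "cost_resection", "cost_post_resection_annual",
    "cost_palliative_annual", "cost_undetected",
    "utility_no_bc", "utility_fp", "utility_resection_year1",
    "utility_post_resection", "utility_undetected", "utility_palliative",
    "utility_dead",
    "p_resect_early", "p_resect_delayed", "p_death_post_resection",
    "p_recurrence", "p_death_palliative", "p_death_fp_procedural",
    "detection_schedule", "p_verify_fp_as_no_bc"
  )
  expect_setequal(names(p), expected)
  expect_equal(anyDuplicated(names(p)), 0L)
})

test_that("validation rejects out-of-range values naming the field", {
  expect_error(parameter_set(p_resect_early = 1.2), "p_resect_early")
  expect_error(parameter_set(utility_palliative = -0.1), "utility_palliative")
  expect_error(parameter_set(cost_resection = -5), "cost_resection")
  expect_error(parameter_set(discount_rate = -0.01), "discount_rate")
  expect_error(parameter_set(horizon_cycles = 0), "horizon_cycles")
  expect_error(parameter_set(detection_schedule = c(0.15, 0.4, 0.9)),
               "detection_schedule")
  expect_error(strategy("x", sensitivity = 1.2, specificity = 0.9),
               "sensitivity")
  # boundary: zero discount rate is a valid setting
  expect_equal(parameter_set(discount_rate = 0)$discount_rate, 0)
})

test_that("config files load, honour percent units, and round-trip", {
  cfg <- system.file("extdata", "base_case.yaml", package = "lcscreen")
  p <- load_parameters(cfg)
  expect_s3_class(p, "lcs_parameters")
  expect_equal(p$pretest_prob, 0.02635)
  strategies <- attr(p, "strategies")
  expect_named(strategies, c("ct", "ct_ai"))
  expect_equal(strategies$ct_ai$specificity, 0.984)

  pct <- tempfile(fileext = ".yaml")
  writeLines(c("probability_units: percent", "pretest_prob: 2.635",
               "utility_palliative: 63"), pct)
  pp <- load_parameters(pct)
  expect_equal(pp$pretest_prob, 0.02635)
  expect_equal(pp$utility_palliative, 0.63)

  # round-trip (strategy definitions live in the config, not the writer)
  bare <- p
  attr(bare, "strategies") <- NULL
  for (ext in c(".yaml", ".json")) {
    f <- tempfile(fileext = ext)
    write_parameters(bare, f)
    expect_equal(unclass(load_parameters(f)), unclass(bare))
  }
})

test_that("malformed configs fail with a parse/validation diagnostic", {
  bad <- tempfile(fileext = ".yaml")
  writeLines("pretest_prob: [unclosed", bad)
  expect_error(load_parameters(bad), "parse")
  oob <- tempfile(fileext = ".yaml")
  writeLines("p_death_palliative: 1.5", oob)
  expect_error(load_parameters(oob), "p_death_palliative")
  unk <- tempfile(fileext = ".yaml")
  writeLines("not_a_parameter: 3", unk)
  expect_error(load_parameters(unk), "not_a_parameter")
  expect_error(load_parameters(tempfile()), "not found")
})

test_that("per-screen acute cost is additive in screen and AI cost", {
  s <- strategy("ct_ai", 0.977, 0.984, screen_cost = 161, ai_cost = 68)
  d <- initial_distribution(s, parameter_set())
  expect_equal(d$acute_cost, 229)
})
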