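test_that("degenerate one-way range reproduces the base-case ICER", {
  p <- parameter_set()
  s <- default_strategies()
  lt <- default_life_table()
  bc <- run_base_case(p, s, lt)
  ow <- one_way("pretest_prob", p$pretest_prob, p$pretest_prob, p, s, lt)
  expect_equal(ow$icer_at_low, bc$comparison$icer, tolerance = 1e-10)
  expect_equal(ow$icer_at_high, ow$icer_at_low)
  expect_equal(ow$spread, 0)
})

test_that("unknown parameter paths fail listing the valid ones", {
  expect_error(one_way("no_such_param", 0, 1), "valid paths")
  expect_error(one_way("ct.frobnicate", 0, 1), "valid paths")
  expect_error(one_way("p_resect_early", 0.5, 1.5), "validity range")
  expect_error(one_way("p_resect_early", 0.9, 0.1), "low > high")
})

test_that("strategy and indexed paths resolve and modify the model", {
  p <- parameter_set()
  s <- default_strategies()
  lt <- flat_lt(0.01)
  base <- one_way("ct.sensitivity", 0.779, 0.779, p, s, lt)
  moved <- one_way("ct.sensitivity", 0.5, 0.9, p, s, lt)
  expect_gt(moved$spread, 0)
  det <- one_way("detection_schedule[1]", 0.05, 0.5, p, s, lt)
  expect_gt(det$spread, 0)
  expect_equal(base$spread, 0)
})

test_that("tornado entries are ranked by spread", {
  tor <- tornado(parameters = c("pretest_prob", "cost_fp_followup",
                                "ct_ai.specificity"),
                 params = parameter_set(), strategies = default_strategies(),
                 lt = flat_lt(0.01))
  expect_equal(nrow(tor), 3)
  expect_true(all(diff(tor$spread) <= 0))
  expect_true(all(tor$low_value <= tor$high_value))
})

test_that("AI-cost threshold: closed form agrees with bisection", {
  p <- parameter_set()
  s <- default_strategies()
  lt <- default_life_table()
  for (target in c(0, 50000, 100000)) {
    closed <- threshold_ai_cost(target, p, s, lt, check = FALSE)
    checked <- threshold_ai_cost(target, p, s, lt, check = TRUE)
    expect_equal(closed, checked)  # check = TRUE errors if bisection deviates
  }
  # randomized synthetic parameter sets
  for (seed in 1:8) {
    pp <- perturb_parameters(p, 0.25, seed)
    inc <- tryCatch(threshold_ai_cost(100000, pp, s, lt, check = TRUE),
                    error = function(e) e)
    if (!inherits(inc, "error")) expect_true(is.finite(inc))
  }
})

test_that("threshold requires a QALY gain", {
  p <- parameter_set()
  lt <- default_life_table()
  same <- list(ct = strategy("ct", 0.9, 0.9), ct_ai = strategy("ct_ai", 0.9, 0.9))
  expect_error(threshold_ai_cost(0, p, same, lt), "delta_qaly")
  # with a forced sensitivity bump the threshold at target 0 is -delta_cost0
  bumped <- list(ct = strategy("ct", 0.9, 0.9),
                 ct_ai = strategy("ct_ai", 0.95, 0.9))
  inc <- lcscreen:::pair_increments(p, bumped, lt, markov_convention())
  expect_equal(threshold_ai_cost(0, p, bumped, lt, check = FALSE),
               -inc[["delta_cost"]])
})

test_that("WTP-to-AI-cost table is affine with slope delta_qaly", {
  p <- parameter_set()
  s <- default_strategies()
  lt <- default_life_table()
  tab <- wtp_cost_table(seq(0, 200000, by = 20000), p, s, lt)
  expect_true(all(diff(tab$ai_cost) > 0))
  # two points determine the line; every other point lies on it to $0.01
  slope <- (tab$ai_cost[2] - tab$ai_cost[1]) / (tab$wtp[2] - tab$wtp[1])
  pred <- tab$ai_cost[1] + slope * (tab$wtp - tab$wtp[1])
  expect_true(all(abs(pred - tab$ai_cost) <= 0.01))
  # the slope is the base-case QALY increment
  bc <- run_base_case(p, s, lt)
  expect_equal(slope, bc$comparison$delta_qaly, tolerance = 1e-9)
})

test_that("zero-variance PSA degenerates to the base case", {
  p <- parameter_set()
  s <- default_strategies()
  lt <- flat_lt(0.015)
  specs <- lapply(psa_default_specs(p, s), function(sp) {
    sp$family <- "fixed"
    sp
  })
  r <- psa(specs, n_iterations = 5, seed = 9, params = p, strategies = s,
           lt = lt)
  bc <- run_base_case(p, s, lt)
  expect_equal(r$samples$delta_cost, rep(bc$comparison$delta_cost, 5),
               tolerance = 1e-12)
  expect_equal(r$samples$delta_qaly, rep(bc$comparison$delta_qaly, 5),
               tolerance = 1e-12)
  # dispersion -> 0 converges to the base-case increments
  tight <- psa(psa_default_specs(p, s, rel_se = 1e-5), n_iterations = 50,
               seed = 9, params = p, strategies = s, lt = lt)
  expect_equal(mean(tight$samples$delta_cost), bc$comparison$delta_cost,
               tolerance = 1e-2)
  expect_equal(mean(tight$samples$delta_qaly), bc$comparison$delta_qaly,
               tolerance = 1e-4)
})

test_that("PSA is reproducible from its seed", {
  p <- parameter_set()
  s <- default_strategies()
  lt <- flat_lt(0.015)
  a <- psa(n_iterations = 40, seed = 123, params = p, strategies = s, lt = lt)
  b <- psa(n_iterations = 40, seed = 123, params = p, strategies = s, lt = lt)
  expect_identical(a$samples, b$samples)
  expect_identical(a$frac_cost_effective, b$frac_cost_effective)
  c <- psa(n_iterations = 40, seed = 124, params = p, strategies = s, lt = lt)
  expect_false(identical(a$samples$delta_cost, c$samples$delta_cost))
})

test_that("PSA sampling respects parameter ranges", {
  p <- parameter_set()
  s <- default_strategies()
  r <- psa(n_iterations = 200, seed = 5, params = p, strategies = s,
           lt = flat_lt(0.015))
  draws <- r$samples[, !(names(r$samples) %in% c("delta_cost", "delta_qaly"))]
  probcols <- grep("sensitivity|specificity|^p_|utility|detection",
                   names(draws), value = TRUE)
  for (cn in probcols) {
    expect_true(all(draws[[cn]] >= 0 & draws[[cn]] <= 1))
  }
  costcols <- grep("^cost", names(draws), value = TRUE)
  for (cn in costcols) expect_true(all(draws[[cn]] >= 0))
})
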