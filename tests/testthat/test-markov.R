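test_that("transition rows reproduce the disease pathway", {
  p <- parameter_set()
  lt <- default_life_table()
  # palliative: 36% annual mortality regardless of age
  row <- transition_row("palliative", 65, p, lt)
  expect_equal(unname(row[c("palliative", "dead")]), c(0.64, 0.36))
  # dead is absorbing
  expect_equal(unname(transition_row("dead", 70, p, lt)["dead"]), 1)
  # last undetected year drains completely when background mortality is 0
  row3 <- transition_row("undetected_y3", 65, p, immortal_lt())
  expect_equal(unname(row3[c("after_resection_y1", "palliative")]),
               c(0.26, 0.74))
  # suspicious nodule: additive procedural excess on the life table
  q <- annual_death_prob(lt, 62)
  rfp <- transition_row("no_bc_suspicious", 62, p, lt)
  expect_equal(unname(rfp["dead"]), q + 0.001)
  expect_equal(unname(rfp["no_bc"]), 1 - q - 0.001)
  # post-resection: total state mortality, recurrence among survivors
  rr <- transition_row("after_resection_y1", 68, p, lt)
  expect_equal(unname(rr["dead"]), 0.047)
  expect_equal(unname(rr["palliative"]), 0.953 * 0.098)
  expect_equal(unname(rr["after_resection_later"]), 0.953 * 0.902)
})

test_that("transition rows always sum to 1, also under perturbation", {
  lt <- default_life_table()
  for (seed in 1:20) {
    p <- perturb_parameters(parameter_set(), 0.4, seed)
    for (conv in list(markov_convention(),
                      markov_convention(detection_timing = "cycle_start"))) {
      for (age in c(60, 70, 79)) {
        M <- transition_matrix(age, p, lt, conv)
        expect_equal(unname(rowSums(M)), rep(1, 9), tolerance = 1e-12)
        expect_true(all(M >= 0))
      }
    }
  }
})

test_that("cohort conserves probability and death is monotone absorbing", {
  lt <- default_life_table()
  s <- default_strategies()
  for (seed in 1:25) {
    p <- perturb_parameters(parameter_set(), 0.3, seed)
    tr <- run_cohort(if (seed %% 2) s$ct else s$ct_ai, p, lt)
    expect_equal(unname(rowSums(tr$occupancy)), rep(1, 21), tolerance = 1e-10)
    expect_true(all(tr$occupancy >= -1e-15))
    expect_true(all(diff(tr$occupancy[, "dead"]) >= -1e-15))
  }
  # with any positive background mortality death strictly increases while
  # living mass remains
  tr <- run_cohort(s$ct, parameter_set(), flat_lt(0.02))
  expect_true(all(diff(tr$occupancy[, "dead"]) > 0))
})

test_that("cohort occupancy equals the matrix-power solution", {
  p <- parameter_set()
  lt <- default_life_table()
  s <- default_strategies()$ct
  tr <- run_cohort(s, p, lt)
  occ <- entry_states(initial_distribution(s, p), p)$occupancy
  for (t in 1:20) {
    occ <- as.vector(occ %*% transition_matrix(60 + t - 1, p, lt))
    expect_equal(unname(tr$occupancy[t + 1, ]), occ, tolerance = 1e-10)
  }
})

test_that("utility-1, immortal, undiscounted limit accrues exactly the horizon", {
  p <- parameter_set(pretest_prob = 0, discount_rate = 0)
  ce <- accrue(run_cohort(free_perfect_screen(), p, immortal_lt()))
  expect_identical(ce$total_qaly, 20)
  expect_identical(ce$total_cost, 0)
  # with the scan billed, cost is the screen cost only
  ce2 <- accrue(run_cohort(strategy("ct", 1, 1), p, immortal_lt()))
  expect_equal(ce2$total_cost, 161)
})

test_that("all-palliative cohort matches the geometric closed form", {
  p <- all_palliative_params(discount_rate = 0)
  ce <- accrue(run_cohort(free_perfect_screen(), p, immortal_lt()))
  expect_equal(ce$total_qaly, sum(0.63 * 0.64^(1:20)), tolerance = 1e-12)
  expect_equal(ce$total_cost, sum(60000 * 0.64^(1:20)), tolerance = 1e-12)
  # discounted variant: each year's accrual carries (1+r)^-t
  r <- 0.03
  pd <- all_palliative_params(discount_rate = r)
  ced <- accrue(run_cohort(free_perfect_screen(), pd, immortal_lt()))
  expect_equal(ced$total_qaly, sum(0.63 * 0.64^(1:20) / (1 + r)^(1:20)),
               tolerance = 1e-12)
})

test_that("discounting weights a cycle's accrual by (1+r)^-t", {
  # a healthy, immortal cohort accrues utility 1/(1.03)^t in cycle t
  p <- parameter_set(pretest_prob = 0, discount_rate = 0.03)
  tr <- run_cohort(free_perfect_screen(), p, immortal_lt())
  expect_equal(tr$qaly_per_cycle[6], 1 / 1.03^5, tolerance = 1e-12)
  expect_equal(sum(tr$qaly_per_cycle), sum(1 / 1.03^(1:20)), tolerance = 1e-12)
})

test_that("raising sensitivity never decreases an arm's total QALYs", {
  p <- parameter_set()
  lt <- default_life_table()
  sens <- seq(0.5, 1, by = 0.1)
  q <- vapply(sens, function(x)
    accrue(run_cohort(strategy("s", x, 0.877), p, lt))$total_qaly, numeric(1))
  expect_true(all(diff(q) >= -1e-12))
})

test_that("accrual conventions behave as documented", {
  p <- parameter_set(pretest_prob = 0, discount_rate = 0)
  s <- free_perfect_screen()
  # cycle-0 accrual adds one extra utility year
  ce0 <- accrue(run_cohort(s, p, immortal_lt(),
                           markov_convention(cycle0_accrual = TRUE)))
  expect_equal(ce0$total_qaly, 21)
  # discount shift leaves the first annual payment undiscounted
  pr <- parameter_set(pretest_prob = 0, discount_rate = 0.03)
  tr <- run_cohort(s, pr, immortal_lt(),
                   markov_convention(discount_shift = 1L))
  expect_equal(tr$qaly_per_cycle[2], 1)
  # half-cycle accrual averages start and end occupancy
  pp <- all_palliative_params()
  ceh <- accrue(run_cohort(free_perfect_screen(), pp, immortal_lt(),
                           markov_convention(accrual = "half")))
  expect_equal(ceh$total_qaly,
               sum(0.63 * (0.64^(0:19) + 0.64^(1:20)) / 2), tolerance = 1e-12)
})

test_that("false-positive follow-up is charged once, in the suspicious year", {
  # disease-free cohort, specificity 0: everyone is a false positive
  p <- parameter_set(pretest_prob = 0, discount_rate = 0)
  tr <- run_cohort(strategy("s", 1, 0, screen_cost = 0), p, immortal_lt())
  expect_equal(tr$cost_per_cycle[2], 2256)
  expect_equal(sum(tr$cost_per_cycle), 2256)
  # the follow-up year is lived at utility 0.98 (survivors), 1 afterwards
  expect_equal(tr$qaly_per_cycle[2], (1 - 0.001) * 1 - (1 - 0.001) * 0.02)
  expect_equal(tr$qaly_per_cycle[3], 1 - 0.001)
})
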