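test_that("screen outcomes are the product of prevalence and test performance", {
  p <- parameter_set()
  d <- initial_distribution(default_strategies(p)$ct_ai, p)
  expect_equal(d$p_tp, 0.02635 * 0.977)
  expect_equal(d$p_fn, 0.02635 * (1 - 0.977))
  expect_equal(d$p_tn, 0.97365 * 0.984)
  expect_equal(d$p_fp, 0.97365 * 0.016)
  expect_equal(d$p_tp + d$p_fn + d$p_tn + d$p_fp, 1, tolerance = 1e-12)
  expect_equal(d$acute_cost, 161)

  # perfect test
  dp <- initial_distribution(strategy("perfect", 1, 1), p)
  expect_equal(dp$p_tp, p$pretest_prob)
  expect_equal(dp$p_tn, 1 - p$pretest_prob)
  expect_equal(dp$p_fn, 0)
  expect_equal(dp$p_fp, 0)

  # disease-free population
  d0 <- initial_distribution(default_strategies(p)$ct,
                             parameter_set(pretest_prob = 0))
  expect_equal(d0$p_tp + d0$p_fn, 0)
  expect_equal(d0$p_tn + d0$p_fp, 1)
})

test_that("entry resolution routes each outcome to its Markov state", {
  p <- parameter_set()
  # all true positive: transient early-detection node splits by resectability
  e_tp <- entry_states(initial_distribution(strategy("s", 1, 1,
                                                     screen_cost = 0),
                                            parameter_set(pretest_prob = 1)),
                       p)
  expect_equal(unname(e_tp$occupancy["after_resection_y1"]), 0.75)
  expect_equal(unname(e_tp$occupancy["palliative"]), 0.25)
  expect_equal(e_tp$onetime_cost, 0.75 * 36305)

  # all true negative
  e_tn <- entry_states(initial_distribution(strategy("s", 1, 1),
                                            parameter_set(pretest_prob = 0)),
                       p)
  expect_equal(unname(e_tn$occupancy["no_bc"]), 1)

  # all false negative: undetected tunnel entry, no treatment cost
  e_fn <- entry_states(initial_distribution(strategy("s", 0, 1,
                                                     screen_cost = 0),
                                            parameter_set(pretest_prob = 1)),
                       p)
  expect_equal(unname(e_fn$occupancy["undetected_y1"]), 1)
  expect_equal(e_fn$onetime_cost, 0)

  # all false positive
  e_fp <- entry_states(initial_distribution(strategy("s", 1, 0),
                                            parameter_set(pretest_prob = 0)),
                       p)
  expect_equal(unname(e_fp$occupancy["no_bc_suspicious"]), 1)
})

test_that("entry occupancy sums to 1 and cycle-0 cost follows the tree", {
  p <- parameter_set()
  set.seed(42)
  for (seed in 1:10) {
    pp <- perturb_parameters(p, 0.3, seed)
    s <- strategy("s", runif(1), runif(1), ai_cost = runif(1, 0, 100))
    d <- initial_distribution(s, pp)
    e <- entry_states(d, pp)
    expect_equal(sum(e$occupancy), 1, tolerance = 1e-12)
    expect_true(all(e$occupancy >= 0))
    expect_equal(e$onetime_cost,
                 d$acute_cost + d$p_tp * pp$p_resect_early * pp$cost_resection)
  }
})
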