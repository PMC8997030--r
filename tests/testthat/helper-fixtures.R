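# shared fixtures, built in code

base_params <- function(...) parameter_set(...)

# immortal background: isolates disease dynamics and closed forms
immortal_lt <- function() make_life_table(55:85, model = "flat", q = 0)

flat_lt <- function(q = 0.02) make_life_table(55:85, model = "flat", q = q)

# a ce_result literal, for cea unit tests
ce_result <- function(cost, qaly, strategy = "x") {
  structure(list(total_cost = cost, total_qaly = qaly, strategy = strategy),
            class = "lcs_ce_result")
}

# cohort that starts 100% in palliative care: perfect test, no resectability
all_palliative_params <- function(discount_rate = 0) {
  parameter_set(pretest_prob = 1, p_resect_early = 0,
                discount_rate = discount_rate)
}

free_perfect_screen <- function() strategy("free", 1, 1, screen_cost = 0)
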