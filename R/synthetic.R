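#' Generate a synthetic life table
#'
#' Two mortality models: a flat annual death probability, or an
#' exponential-in-age (Gompertz-type) hazard
#' `q(a) = q0 * exp(g * (a - a0))`. Useful for closed-form test oracles
#' (flat tables give exact geometric survival) and for plausible senescent
#' mortality without external data.
#'
#' @param ages Integer ages covered.
#' @param model `"flat"` or `"gompertz"`.
#' @param q Flat annual death probability (model `"flat"`).
#' @param q0,g,a0 Gompertz level, log-slope per year, and anchor age.
#' @param source_label Provenance label.
#' @return An [life_table()].
#' @examples
#' make_life_table(60:80, model = "flat", q = 0.02)
#' make_life_table(55:85, model = "gompertz", q0 = 0.011, g = 0.09, a0 = 60)
#' @export
make_life_table <- function(ages = 55:85, model = c("flat", "gompertz"),
                            q = 0.01, q0 = 0.011, g = 0.09, a0 = 60,
                            source_label = NULL) {
  model <- match.arg(model)
  qx <- switch(model,
               flat = rep(q, length(ages)),
               gompertz = q0 * exp(g * (ages - a0)))
  if (any(qx > 1)) {
    stop(sprintf("synthetic mortality exceeds 1 at age %d",
                 ages[which(qx > 1)[1L]]), call. = FALSE)
  }
  if (is.null(source_label)) {
    source_label <- switch(model,
      flat = sprintf("synthetic flat q = %g", q),
      gompertz = sprintf("synthetic Gompertz q0 = %g, g = %g, a0 = %g",
                         q0, g, a0))
  }
  life_table(data.frame(age = ages, qx = qx), source_label = source_label)
}

#' Per-patient microsimulation oracle
#'
#' Simulates each patient's stochastic walk through the same decision tree
#' and transition rows as [run_cohort()], accruing the same discounted costs
#' and utilities under the same convention, and returns means with Monte
#' Carlo standard errors. By the law of large numbers the means converge to
#' the cohort-model totals; the test suite checks agreement within three
#' standard errors.
#'
#' @param strat An [strategy()].
#' @param params An [parameter_set()].
#' @param lt An [life_table()].
#' @param n_patients Number of simulated patients.
#' @param seed Integer RNG seed.
#' @param convention An [markov_convention()]; accrual options `"end"`
#'   (default) and `"start"`, with or without cycle-0 accrual, are supported.
#' @return Object of class `lcs_microsim`: `n_patients`, `mean_cost`,
#'   `se_cost`, `mean_qaly`, `se_qaly`, `seed`.
#' @export
microsimulate <- function(strat, params, lt, n_patients = 10000L, seed = 1L,
                          convention = markov_convention()) {
  stopifnot(n_patients >= 1L)
  validate_parameters(params)
  check_life_table_coverage(lt, params)
  if (convention$accrual == "half") {
    stop("microsimulate does not support half-cycle accrual", call. = FALSE)
  }
  H <- params$horizon_cycles
  n <- as.integer(n_patients)
  scost <- unname(state_costs(params))
  sutil <- unname(state_utilities(params))
  r <- params$discount_rate
  dist <- initial_distribution(strat, params)

  withr_seed(seed, {
    # entry: draw TP/FN/TN/FP then resolve the transient early-detection node
    u <- stats::runif(n)
    cuts <- cumsum(c(dist$p_tp, dist$p_fn, dist$p_tn, dist$p_fp))
    outcome <- pmin(findInterval(u, cuts) + 1L, 4L)  # 1 TP, 2 FN, 3 TN, 4 FP
    state <- integer(n)
    cost <- rep(dist$acute_cost, n)
    qaly <- numeric(n)
    tp <- outcome == 1L
    resected <- tp & (stats::runif(n) < params$p_resect_early)
    state[resected] <- 6L
    state[tp & !resected] <- 8L
    state[outcome == 2L] <- 3L
    state[outcome == 3L] <- 1L
    state[outcome == 4L] <- 2L
    cost[resected] <- cost[resected] + params$cost_resection
    if (convention$cycle0_accrual) {
      cost <- cost + scost[state]
      qaly <- qaly + sutil[state]
    }
    for (t in seq_len(H)) {
      age <- params$start_age + t - 1L
      M <- transition_matrix(age, params, lt, convention)
      disc <- (1 + r)^(-(t - convention$discount_shift))
      prev <- state
      if (convention$accrual == "start") {
        cost <- cost + disc * scost[prev]
        qaly <- qaly + disc * sutil[prev]
      }
      cum <- t(apply(unname(M), 1L, cumsum))
      u <- stats::runif(n)
      nxt <- integer(n)
      for (s in unique(prev)) {
        idx <- prev == s
        nxt[idx] <- pmin(findInterval(u[idx], cum[s, ], left.open = TRUE) + 1L,
                         9L)
      }
      state <- nxt
      # event accruals, matching the cohort engine
      entered_res <- prev %in% 3:5 & state == 6L
      cost[entered_res] <- cost[entered_res] + disc * params$cost_resection
      was_fp <- prev == 2L
      cost[was_fp] <- cost[was_fp] + disc * params$cost_fp_followup
      if (convention$accrual == "end") {
        if (!convention$cycle0_accrual) {
          verified <- was_fp & state == 1L
          qaly[verified] <- qaly[verified] -
            disc * (params$utility_no_bc - params$utility_fp)
        }
        cost <- cost + disc * scost[state]
        qaly <- qaly + disc * sutil[state]
      }
    }
    structure(
      list(n_patients = n,
           mean_cost = mean(cost), se_cost = stats::sd(cost) / sqrt(n),
           mean_qaly = mean(qaly), se_qaly = stats::sd(qaly) / sqrt(n),
           seed = seed),
      class = "lcs_microsim"
    )
  })
}

#' Randomly perturb a parameter set
#'
#' Each continuous numeric field is independently scaled by a factor drawn
#' uniformly from `[1 - relative_width, 1 + relative_width]` and clamped to
#' its validity range; the final detection-schedule entry stays 1 so the
#' undetected tunnel always drains. Structural integers (`start_age`,
#' `horizon_cycles`) and the willingness-to-pay are left unchanged. Used as a
#' fuzz source for property tests.
#'
#' @param params An [parameter_set()].
#' @param relative_width Fraction in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @return A validated, perturbed `lcs_parameters`.
#' @export
perturb_parameters <- function(params, relative_width = 0.2, seed = 1L) {
  stopifnot(relative_width >= 0, relative_width < 1)
  validate_parameters(params)
  withr_seed(seed, {
    fields <- c(.lcs_prob_fields, .lcs_utility_fields, .lcs_cost_fields,
                "discount_rate")
    for (f in fields) {
      fac <- stats::runif(1L, 1 - relative_width, 1 + relative_width)
      v <- params[[f]] * fac
      if (f %in% c(.lcs_prob_fields, .lcs_utility_fields)) v <- min(v, 1)
      params[[f]] <- max(v, 0)
    }
    fac <- stats::runif(2L, 1 - relative_width, 1 + relative_width)
    ds <- params$detection_schedule
    ds[1:2] <- pmin(pmax(ds[1:2] * fac, 0), 1)
    ds[3L] <- 1
    params$detection_schedule <- ds
    validate_parameters(params)
    params
  })
}

#' @export
print.lcs_microsim <- function(x, ...) {
  cat(sprintf("<lcs_microsim> %d patients (seed %d)\n", x$n_patients, x$seed))
  cat(sprintf("  cost %.2f (SE %.2f) USD, QALY %.4f (SE %.4f)\n",
              x$mean_cost, x$se_cost, x$mean_qaly, x$se_qaly))
  invisible(x)
}
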