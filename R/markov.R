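#' Expanded Markov state space
#'
#' The six clinical states of the model, with tunnel expansions for
#' duration-dependent values: the undetected-BC state is split into three
#' year-indexed copies (staged clinical detection of a missed cancer at
#' 15\%/40\%/100\% per year) and the post-resection state into a first year
#' (utility 0.79) and later years (utility 0.933).
#'
#' @return Character vector of the nine expanded states, in canonical order.
#' @export
markov_states <- function() {
  c("no_bc", "no_bc_suspicious",
    "undetected_y1", "undetected_y2", "undetected_y3",
    "after_resection_y1", "after_resection_later",
    "palliative", "dead")
}

empty_occupancy <- function() {
  stats::setNames(numeric(9L), markov_states())
}

#' Accrual and timing conventions of the cohort engine
#'
#' The analysis the model reproduces does not state its reward-accrual
#' conventions, so they are explicit, documented options here. The default is
#' the package's reference convention: state rewards accrue for cycles
#' `1..horizon` based on occupancy *after* each transition, discounted by
#' `(1+r)^-t`; cycle-0 one-time costs (screen, AI, entry resections) are
#' undiscounted; no half-cycle correction. See the methods vignette for the
#' calibration grid over these options and [replication_convention()] for the
#' combination that reproduces the published base-case totals.
#'
#' @param accrual How state membership during a cycle is counted: `"end"`
#'   (occupancy after the transition), `"start"` (occupancy before it), or
#'   `"half"` (their average, a half-cycle correction).
#' @param cycle0_accrual If `TRUE`, the entry-state occupancy additionally
#'   accrues one undiscounted year of state costs and utilities at cycle 0
#'   (giving `horizon + 1` accrual points).
#' @param discount_shift Integer 0 or 1. Cycle `t` is discounted by
#'   `(1+r)^-(t - discount_shift)`; with 1, discounting starts at cycle 0 and
#'   the first annual payment is undiscounted.
#' @param detection_timing `"cycle_boundary"` (default): clinical detection of
#'   an undetected BC resolves at the cycle boundary and the destination
#'   state's hazards apply from the following cycle. `"cycle_start"`:
#'   detection occurs at the start of the cycle and the destination state's
#'   annual hazards (post-resection or palliative mortality, recurrence) apply
#'   already within the detection year.
#' @return Object of class `lcs_convention`.
#' @export
markov_convention <- function(accrual = c("end", "start", "half"),
                              cycle0_accrual = FALSE,
                              discount_shift = 0L,
                              detection_timing = c("cycle_boundary", "cycle_start")) {
  accrual <- match.arg(accrual)
  detection_timing <- match.arg(detection_timing)
  if (!discount_shift %in% c(0L, 1L)) {
    stop("discount_shift must be 0 or 1", call. = FALSE)
  }
  structure(
    list(accrual = accrual, cycle0_accrual = isTRUE(cycle0_accrual),
         discount_shift = as.integer(discount_shift),
         detection_timing = detection_timing),
    class = "lcs_convention"
  )
}

#' Convention reproducing the published base-case totals
#'
#' The member of the convention grid (see the methods vignette) under which
#' the model, with the bundled life table, reproduces the published per-arm
#' discounted totals: end-of-cycle accrual with an additional cycle-0 accrual
#' and discounting starting at cycle 0, keeping the default cycle-boundary
#' detection timing.
#'
#' @return An `lcs_convention`.
#' @export
replication_convention <- function() {
  markov_convention(accrual = "end", cycle0_accrual = TRUE,
                    discount_shift = 1L)
}

#' One row of the annual transition matrix
#'
#' Background mortality `q` is the life-table probability at `age`. Death is
#' resolved first; detection, verification and recurrence apply to survivors
#' (under the default cycle-boundary detection timing):
#' \itemize{
#'   \item no BC: dies with `q`, otherwise stays.
#'   \item suspicious nodule: dies with `min(1, q + p_death_fp_procedural)`;
#'     survivors are verified as benign and return to no BC.
#'   \item undetected year k: dies with `q`; surviving cancers are detected
#'     with `detection_schedule[k]` and split `p_resect_delayed` to the first
#'     post-resection year (resection cost charged on entry) versus
#'     palliative; undetected survivors advance along the tunnel.
#'   \item post-resection (both tunnel years): dies with
#'     `p_death_post_resection` (total state mortality); surviving recurrences
#'     (`p_recurrence`) move to palliative; the rest settle in the later
#'     post-resection state.
#'   \item palliative: dies with `p_death_palliative`, otherwise stays.
#'   \item dead: absorbing.
#' }
#'
#' @param state One of [markov_states()].
#' @param age Integer age during the cycle; must be covered by `lt`.
#' @param params An [parameter_set()].
#' @param lt An [life_table()].
#' @param convention An [markov_convention()]; only `detection_timing` affects
#'   the rows.
#' @return Named probability vector over [markov_states()], summing to 1.
#' @export
transition_row <- function(state, age, params, lt,
                           convention = markov_convention()) {
  M <- transition_matrix(age, params, lt, convention)
  if (!state %in% rownames(M)) {
    stop("unknown state '", state, "'", call. = FALSE)
  }
  M[state, ]
}

#' Full annual transition matrix at a given age
#'
#' @inheritParams transition_row
#' @return 9 x 9 row-stochastic matrix over [markov_states()].
#' @export
transition_matrix <- function(age, params, lt,
                              convention = markov_convention()) {
  q <- annual_death_prob(lt, age)
  st <- markov_states()
  M <- matrix(0, 9L, 9L, dimnames = list(st, st))
  M["no_bc", "dead"] <- q
  M["no_bc", "no_bc"] <- 1 - q

  qfp <- min(1, q + params$p_death_fp_procedural)
  M["no_bc_suspicious", "dead"] <- qfp
  # verification resolves the suspicious nodule; survivors return to no BC
  M["no_bc_suspicious", "no_bc"] <- (1 - qfp) * params$p_verify_fp_as_no_bc
  M["no_bc_suspicious", "no_bc_suspicious"] <-
    (1 - qfp) * (1 - params$p_verify_fp_as_no_bc)

  det <- params$detection_schedule
  for (k in 1:3) {
    s <- paste0("undetected_y", k)
    d <- det[k]
    if (convention$detection_timing == "cycle_boundary") {
      M[s, "dead"] <- q
      M[s, "after_resection_y1"] <- (1 - q) * d * params$p_resect_delayed
      M[s, "palliative"] <- (1 - q) * d * (1 - params$p_resect_delayed)
      if (k < 3) M[s, paste0("undetected_y", k + 1)] <- (1 - q) * (1 - d)
    } else {
      # detection at cycle start: detected cases face their destination
      # state's annual hazards already within the detection year
      pr <- (1 - q) * d * params$p_resect_delayed
      pp <- (1 - q) * d * (1 - params$p_resect_delayed)
      M[s, "dead"] <- q + pr * params$p_death_post_resection +
        pp * params$p_death_palliative
      M[s, "after_resection_y1"] <-
        pr * (1 - params$p_death_post_resection) * (1 - params$p_recurrence)
      M[s, "palliative"] <- pp * (1 - params$p_death_palliative) +
        pr * (1 - params$p_death_post_resection) * params$p_recurrence
      if (k < 3) M[s, paste0("undetected_y", k + 1)] <- (1 - q) * (1 - d)
    }
  }

  for (s in c("after_resection_y1", "after_resection_later")) {
    M[s, "dead"] <- params$p_death_post_resection
    M[s, "palliative"] <- (1 - params$p_death_post_resection) * params$p_recurrence
    M[s, "after_resection_later"] <-
      (1 - params$p_death_post_resection) * (1 - params$p_recurrence)
  }
  M["palliative", "dead"] <- params$p_death_palliative
  M["palliative", "palliative"] <- 1 - params$p_death_palliative
  M["dead", "dead"] <- 1

  bad <- which(abs(rowSums(M) - 1) > 1e-12)
  if (length(bad) > 0L) {
    stop("internal consistency error: transition row '", st[bad[1L]],
         "' sums to ", format(rowSums(M)[bad[1L]], digits = 17), call. = FALSE)
  }
  M
}

# internal: per-state annual cost and utility vectors
state_costs <- function(params) {
  stats::setNames(
    c(0, 0,
      params$cost_undetected, params$cost_undetected, params$cost_undetected,
      params$cost_post_resection_annual, params$cost_post_resection_annual,
      params$cost_palliative_annual, 0),
    markov_states())
}

state_utilities <- function(params) {
  stats::setNames(
    c(params$utility_no_bc, params$utility_fp,
      params$utility_undetected, params$utility_undetected,
      params$utility_undetected,
      params$utility_resection_year1, params$utility_post_resection,
      params$utility_palliative, params$utility_dead),
    markov_states())
}

#' Run the annual-cycle cohort simulation for one strategy
#'
#' Starts from the decision-tree entry occupancy, applies the age-specific
#' transition matrix for each of `horizon_cycles` annual cycles (ages
#' `start_age + 0 .. horizon-1`), and accrues discounted costs and QALYs per
#' cycle under the chosen [markov_convention()]. Event costs are charged when
#' they occur: resections on entry to the post-resection state (undiscounted
#' at cycle 0, discounted at the cycle of delayed detection) and the
#' false-positive follow-up cost once per person for the single year spent in
#' the suspicious-nodule state. Under the default end-of-cycle accrual the
#' follow-up year's utility decrement (`utility_no_bc - utility_fp`) is
#' likewise applied as a one-off event to verified survivors, since the
#' suspicious state is never occupied at an accrual point.
#'
#' @param strat An [strategy()].
#' @param params An [parameter_set()].
#' @param lt An [life_table()] covering `start_age .. start_age + horizon`.
#' @param convention An [markov_convention()].
#' @return Object of class `lcs_trace`: `occupancy` matrix
#'   (`horizon+1` rows, cycles 0..horizon), `cost_per_cycle` and
#'   `qaly_per_cycle` (discounted, length `horizon+1`, cycle 0 first),
#'   `age_per_cycle`, `strategy`, `convention`.
#' @examples
#' tr <- run_cohort(default_strategies()$ct_ai, parameter_set(),
#'                  default_life_table())
#' accrue(tr)
#' @export
run_cohort <- function(strat, params, lt, convention = markov_convention()) {
  validate_parameters(params)
  check_life_table_coverage(lt, params)
  entry <- entry_states(initial_distribution(strat, params), params)
  H <- params$horizon_cycles
  st <- markov_states()
  scost <- state_costs(params)
  sutil <- state_utilities(params)

  occ <- matrix(0, nrow = H + 1L, ncol = 9L,
                dimnames = list(paste0("cycle", 0:H), st))
  occ[1L, ] <- entry$occupancy
  cost <- numeric(H + 1L)
  qaly <- numeric(H + 1L)
  cost[1L] <- entry$onetime_cost
  if (convention$cycle0_accrual) {
    cost[1L] <- cost[1L] + sum(entry$occupancy * scost)
    qaly[1L] <- sum(entry$occupancy * sutil)
  }
  und <- c("undetected_y1", "undetected_y2", "undetected_y3")
  r <- params$discount_rate
  for (t in seq_len(H)) {
    age <- params$start_age + t - 1L
    M <- transition_matrix(age, params, lt, convention)
    prev <- occ[t, ]
    cur <- as.vector(prev %*% M)
    names(cur) <- st
    occ[t + 1L, ] <- cur
    disc <- (1 + r)^(-(t - convention$discount_shift))

    # event costs during cycle t
    if (convention$detection_timing == "cycle_boundary") {
      res_entry <- sum(prev[und] * M[und, "after_resection_y1"])
    } else {
      # resection attempted by all detected survivors of background death,
      # including those who die of post-resection mortality the same year
      qv <- annual_death_prob(lt, age)
      res_entry <- sum(prev[und] * (1 - qv) * params$detection_schedule *
                         params$p_resect_delayed)
    }
    ev_cost <- res_entry * params$cost_resection +
      prev["no_bc_suspicious"] * params$cost_fp_followup
    ev_qaly <- 0
    if (convention$accrual == "end" && !convention$cycle0_accrual) {
      ev_qaly <- -prev["no_bc_suspicious"] * M["no_bc_suspicious", "no_bc"] *
        (params$utility_no_bc - params$utility_fp)
    }
    w <- switch(convention$accrual,
                end = cur, start = prev, half = (cur + prev) / 2)
    cost[t + 1L] <- disc * (sum(w * scost) + ev_cost)
    qaly[t + 1L] <- disc * (sum(w * sutil) + ev_qaly)
  }

  sums <- rowSums(occ)
  if (any(abs(sums - 1) > 1e-10)) {
    stop("cohort trace lost probability mass (max deviation ",
         format(max(abs(sums - 1))), ")", call. = FALSE)
  }
  if (any(diff(occ[, "dead"]) < -1e-12)) {
    stop("dead occupancy decreased between cycles", call. = FALSE)
  }
  structure(
    list(occupancy = occ, cost_per_cycle = cost, qaly_per_cycle = qaly,
         age_per_cycle = params$start_age + 0:H,
         strategy = strat$name, convention = convention),
    class = "lcs_trace"
  )
}

#' Total discounted cost and effectiveness of a trace
#'
#' @param trace An `lcs_trace` from [run_cohort()].
#' @return Object of class `lcs_ce_result` with `total_cost` (discounted USD),
#'   `total_qaly` (discounted QALYs) and `strategy`.
#' @export
accrue <- function(trace) {
  stopifnot(inherits(trace, "lcs_trace"))
  structure(
    list(total_cost = sum(trace$cost_per_cycle),
         total_qaly = sum(trace$qaly_per_cycle),
         strategy = trace$strategy),
    class = "lcs_ce_result"
  )
}

#' Run both arms and compare them
#'
#' Convenience wrapper: runs [run_cohort()] for each strategy in `strategies`
#' and, when exactly two are given, also returns their [icer()].
#'
#' @param params An [parameter_set()].
#' @param strategies Named list of [strategy()] objects (intervention last, as
#'   in [default_strategies()], where `ct_ai` is compared against `ct`).
#' @param lt An [life_table()].
#' @param convention An [markov_convention()].
#' @return List with `results` (named list of `lcs_ce_result`) and, for two
#'   strategies, `comparison` (an `lcs_icer` of the second versus the first).
#' @export
run_base_case <- function(params = parameter_set(),
                          strategies = default_strategies(params),
                          lt = default_life_table(),
                          convention = markov_convention()) {
  results <- lapply(strategies, function(s)
    accrue(run_cohort(s, params, lt, convention)))
  comparison <- NULL
  if (length(results) == 2L) {
    comparison <- icer(results[[2L]], results[[1L]], wtp = params$wtp)
  }
  list(results = results, comparison = comparison)
}

#' @export
print.lcs_trace <- function(x, ...) {
  n <- nrow(x$occupancy)
  cat(sprintf("<lcs_trace> strategy '%s', %d cycles (ages %d-%d)\n",
              x$strategy, n - 1L, x$age_per_cycle[1L], x$age_per_cycle[n]))
  cat(sprintf("  discounted totals: cost %.2f USD, %.4f QALYs\n",
              sum(x$cost_per_cycle), sum(x$qaly_per_cycle)))
  cat(sprintf("  final occupancy: %.4f dead, %.4f no BC\n",
              x$occupancy[n, "dead"], x$occupancy[n, "no_bc"]))
  invisible(x)
}

#' @export
print.lcs_ce_result <- function(x, ...) {
  cat(sprintf("<lcs_ce_result> %s: %.2f USD, %.4f QALYs (discounted)\n",
              x$strategy, x$total_cost, x$total_qaly))
  invisible(x)
}
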