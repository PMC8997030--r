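#' Diagnostic outcome distribution at the baseline screen
#'
#' Applies a strategy's sensitivity and specificity to the pre-test probability
#' of BC, splitting the cohort into true positives, false negatives, true
#' negatives and false positives, with the acute per-screen cost
#' (scan + AI).
#'
#' @param strat An [strategy()] definition.
#' @param params An [parameter_set()].
#' @return Object of class `lcs_initial_distribution` with fields `p_tp`,
#'   `p_fn`, `p_tn`, `p_fp` (summing to 1) and `acute_cost` (USD per cohort
#'   member).
#' @examples
#' d <- initial_distribution(default_strategies()$ct_ai, parameter_set())
#' d$p_tp  # 0.02635 * 0.977
#' @export
initial_distribution <- function(strat, params) {
  stopifnot(inherits(strat, "lcs_strategy"))
  validate_parameters(params)
  pt <- params$pretest_prob
  d <- list(
    p_tp = pt * strat$sensitivity,
    p_fn = pt * (1 - strat$sensitivity),
    p_tn = (1 - pt) * strat$specificity,
    p_fp = (1 - pt) * (1 - strat$specificity),
    acute_cost = strat$screen_cost + strat$ai_cost
  )
  s <- d$p_tp + d$p_fn + d$p_tn + d$p_fp
  if (abs(s - 1) > 1e-12) {
    stop("internal error: outcome probabilities sum to ", format(s),
         call. = FALSE)
  }
  structure(d, class = "lcs_initial_distribution")
}

#' Resolve screen outcomes into cycle-0 Markov occupancy
#'
#' True positives pass through the transient "early detection" node within
#' cycle 0: a fraction `p_resect_early` undergoes resection (one-time
#' `cost_resection` charged at entry) and starts in the first post-resection
#' tunnel year; the remainder starts in palliative care. False negatives start
#' the first undetected tunnel year, true negatives start in "no BC", and
#' false positives start in "no BC, suspicious nodule". Transient nodes never
#' occupy a full cycle.
#'
#' @param dist An `lcs_initial_distribution`.
#' @param params An [parameter_set()].
#' @return Object of class `lcs_entry`: `occupancy` (named vector over the
#'   expanded state space, summing to 1) and `onetime_cost` (USD per cohort
#'   member at cycle 0: acute screen cost plus entry resections).
#' @export
entry_states <- function(dist, params) {
  stopifnot(inherits(dist, "lcs_initial_distribution"))
  occ <- empty_occupancy()
  occ["no_bc"] <- dist$p_tn
  occ["no_bc_suspicious"] <- dist$p_fp
  occ["undetected_y1"] <- dist$p_fn
  occ["after_resection_y1"] <- dist$p_tp * params$p_resect_early
  occ["palliative"] <- dist$p_tp * (1 - params$p_resect_early)
  onetime <- dist$acute_cost +
    dist$p_tp * params$p_resect_early * params$cost_resection
  if (abs(sum(occ) - 1) > 1e-12) {
    stop("internal error: entry occupancy sums to ", format(sum(occ)),
         call. = FALSE)
  }
  structure(list(occupancy = occ, onetime_cost = onetime),
            class = "lcs_entry")
}

#' @export
print.lcs_initial_distribution <- function(x, ...) {
  cat(sprintf(
    "<lcs_initial_distribution> TP %.5f | FN %.5f | TN %.5f | FP %.5f | acute cost %.2f USD\n",
    x$p_tp, x$p_fn, x$p_tn, x$p_fp, x$acute_cost))
  invisible(x)
}
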