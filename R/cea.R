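#' Incremental cost-effectiveness of an intervention versus a comparator
#'
#' Computes incremental cost and effectiveness, the ICER where defined, a
#' dominance classification, and whether the intervention is cost-effective at
#' the willingness-to-pay threshold. A negative ICER is sign-ambiguous, so the
#' headline result is the classification: `"dominant"` (cheaper and at least
#' as effective, one strictly), `"dominated"` (the mirror case), `"tie"`
#' (identical totals) or `"tradeoff"`; the raw ratio remains available in
#' `icer`.
#'
#' For a trade-off in the north-east quadrant (costlier, more effective) the
#' intervention is cost-effective iff `icer <= wtp`; in the south-west quadrant
#' (cheaper, less effective) iff `icer >= wtp`, i.e. the saving per QALY
#' forgone exceeds the threshold.
#'
#' @param intervention,comparator `lcs_ce_result` objects from [accrue()],
#'   produced under the same parameters and life table.
#' @param wtp Willingness-to-pay, USD per QALY.
#' @return Object of class `lcs_icer` with `delta_cost`, `delta_qaly`, `icer`
#'   (`NA` when `delta_qaly == 0`), `classification` and
#'   `cost_effective_at_wtp`.
#' @examples
#' bc <- run_base_case()
#' bc$comparison$classification
#' @export
icer <- function(intervention, comparator, wtp = 100000) {
  stopifnot(inherits(intervention, "lcs_ce_result"),
            inherits(comparator, "lcs_ce_result"))
  dc <- intervention$total_cost - comparator$total_cost
  de <- intervention$total_qaly - comparator$total_qaly
  ratio <- if (de != 0) dc / de else NA_real_
  classification <-
    if (dc == 0 && de == 0) "tie"
    else if (dc <= 0 && de >= 0) "dominant"
    else if (dc >= 0 && de <= 0) "dominated"
    else "tradeoff"
  ce <- switch(classification,
    dominant = TRUE,
    dominated = FALSE,
    tie = FALSE,
    tradeoff = if (de > 0) ratio <= wtp else ratio >= wtp
  )
  structure(
    list(delta_cost = dc, delta_qaly = de, icer = ratio,
         classification = classification, cost_effective_at_wtp = ce,
         wtp = wtp,
         intervention = intervention$strategy,
         comparator = comparator$strategy),
    class = "lcs_icer"
  )
}

#' Net monetary benefit
#'
#' `NMB = wtp * total_qaly - total_cost`. For trade-off comparisons,
#' `NMB(intervention) > NMB(comparator)` is equivalent to the intervention
#' being cost-effective at `wtp` (checked by a property test).
#'
#' @param result An `lcs_ce_result`.
#' @param wtp Willingness-to-pay, USD per QALY; must be non-negative.
#' @return Net monetary benefit in USD.
#' @export
net_monetary_benefit <- function(result, wtp = 100000) {
  stopifnot(inherits(result, "lcs_ce_result"))
  if (wtp < 0) stop("wtp must be >= 0", call. = FALSE)
  wtp * result$total_qaly - result$total_cost
}

#' @export
print.lcs_icer <- function(x, ...) {
  cat(sprintf("<lcs_icer> %s vs %s at WTP %s USD/QALY\n",
              x$intervention, x$comparator, format(x$wtp, big.mark = ",")))
  cat(sprintf("  incremental cost %.2f USD, incremental effectiveness %.5f QALY\n",
              x$delta_cost, x$delta_qaly))
  if (x$classification == "tradeoff") {
    cat(sprintf("  ICER %.2f USD/QALY -> %scost-effective\n", x$icer,
                if (x$cost_effective_at_wtp) "" else "not "))
  } else {
    cat(sprintf("  classification: %s (raw ratio %s)\n", x$classification,
                if (is.na(x$icer)) "undefined" else sprintf("%.2f", x$icer)))
  }
  invisible(x)
}
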