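#' Model parameters for the screening cost-effectiveness model
#'
#' Constructs the full, validated set of model inputs: pre-test probability of
#' bronchial cancer (BC) in the screened cohort, cohort start age, Markov
#' horizon, discount rate, willingness-to-pay, per-state annual costs and
#' utilities, one-time event costs, and the transition probabilities of the
#' disease pathway. All probabilities and utilities are stored as fractions in
#' \[0, 1\]; costs are USD.
#'
#' Defaults are the base-case inputs of the screening analysis the package
#' re-implements: a 60-year-old cohort of high-risk smokers with a BC
#' prevalence of 2.635\% at the baseline scan, a 20-year annual-cycle horizon,
#' 3\% discounting, and a willingness-to-pay of USD 100,000 per QALY.
#'
#' @param pretest_prob Prevalence of BC in the screened cohort at the baseline
#'   scan (fraction).
#' @param start_age Age (integer years) of the cohort at the screen.
#' @param horizon_cycles Number of annual Markov cycles.
#' @param discount_rate Annual discount rate (fraction) applied to both costs
#'   and QALYs; 0 disables discounting.
#' @param wtp Willingness-to-pay threshold, USD per QALY.
#' @param cost_fp_followup One-time cost (USD) of the follow-up work-up of a
#'   false-positive finding (follow-up CT, possible bronchoscopy/biopsy).
#' @param cost_resection One-time cost (USD) of curative resection, charged on
#'   entry to the post-resection state.
#' @param cost_post_resection_annual Annual cost (USD/year) of the
#'   post-resection state.
#' @param cost_palliative_annual Annual cost (USD/year) of palliative care.
#' @param cost_undetected Annual cost (USD/year) of undetected BC.
#' @param utility_no_bc,utility_fp,utility_resection_year1,utility_post_resection,utility_undetected,utility_palliative,utility_dead
#'   QALY weights in \[0, 1\] for the respective states; `utility_fp` applies
#'   to the single year spent under false-positive follow-up and
#'   `utility_resection_year1` to the first year after resection.
#' @param p_resect_early Probability that an early-detected (screen-detected)
#'   BC is resectable.
#' @param p_resect_delayed Probability that a delayed-detected BC is resectable.
#' @param p_death_post_resection Annual death probability in the post-resection
#'   states (used as the state's total mortality, not added to the life table).
#' @param p_recurrence Annual probability of recurrence after resection;
#'   recurrent disease moves to palliative care.
#' @param p_death_palliative Annual death probability under palliative care
#'   (total mortality of the state).
#' @param p_death_fp_procedural Excess death probability from invasive
#'   diagnostics in the false-positive year, added on top of background
#'   life-table mortality.
#' @param detection_schedule Conditional annual probabilities that an initially
#'   undetected BC is clinically detected in the 1st, 2nd and 3rd year after
#'   the screen; the final entry must be 1 so the tunnel drains.
#' @param p_verify_fp_as_no_bc Probability that a suspicious nodule is verified
#'   as benign within the follow-up year.
#'
#' @return An object of class `lcs_parameters` (a validated named list).
#' @seealso [load_parameters()], [default_strategies()], [run_cohort()]
#' @examples
#' p <- parameter_set()
#' p$pretest_prob
#' @export
parameter_set <- function(pretest_prob = 0.02635,
                          start_age = 60L,
                          horizon_cycles = 20L,
                          discount_rate = 0.03,
                          wtp = 100000,
                          cost_fp_followup = 2256,
                          cost_resection = 36305,
                          cost_post_resection_annual = 4283,
                          cost_palliative_annual = 60000,
                          cost_undetected = 0,
                          utility_no_bc = 1,
                          utility_fp = 0.98,
                          utility_resection_year1 = 0.79,
                          utility_post_resection = 0.933,
                          utility_undetected = 1,
                          utility_palliative = 0.63,
                          utility_dead = 0,
                          p_resect_early = 0.75,
                          p_resect_delayed = 0.26,
                          p_death_post_resection = 0.047,
                          p_recurrence = 0.098,
                          p_death_palliative = 0.36,
                          p_death_fp_procedural = 0.001,
                          detection_schedule = c(0.15, 0.40, 1.00),
                          p_verify_fp_as_no_bc = 1.0) {
  p <- list(
    pretest_prob = pretest_prob,
    start_age = as.integer(start_age),
    horizon_cycles = as.integer(horizon_cycles),
    discount_rate = discount_rate,
    wtp = wtp,
    cost_fp_followup = cost_fp_followup,
    cost_resection = cost_resection,
    cost_post_resection_annual = cost_post_resection_annual,
    cost_palliative_annual = cost_palliative_annual,
    cost_undetected = cost_undetected,
    utility_no_bc = utility_no_bc,
    utility_fp = utility_fp,
    utility_resection_year1 = utility_resection_year1,
    utility_post_resection = utility_post_resection,
    utility_undetected = utility_undetected,
    utility_palliative = utility_palliative,
    utility_dead = utility_dead,
    p_resect_early = p_resect_early,
    p_resect_delayed = p_resect_delayed,
    p_death_post_resection = p_death_post_resection,
    p_recurrence = p_recurrence,
    p_death_palliative = p_death_palliative,
    p_death_fp_procedural = p_death_fp_procedural,
    detection_schedule = as.numeric(detection_schedule),
    p_verify_fp_as_no_bc = p_verify_fp_as_no_bc
  )
  class(p) <- "lcs_parameters"
  validate_parameters(p)
}

# field groups used for validation, perturbation and PSA
.lcs_prob_fields <- c(
  "pretest_prob", "p_resect_early", "p_resect_delayed",
  "p_death_post_resection", "p_recurrence", "p_death_palliative",
  "p_death_fp_procedural", "p_verify_fp_as_no_bc"
)
.lcs_utility_fields <- c(
  "utility_no_bc", "utility_fp", "utility_resection_year1",
  "utility_post_resection", "utility_undetected", "utility_palliative",
  "utility_dead"
)
.lcs_cost_fields <- c(
  "cost_fp_followup", "cost_resection", "cost_post_resection_annual",
  "cost_palliative_annual", "cost_undetected"
)

#' Validate a parameter set
#'
#' Checks the range invariants of every field: probabilities and utilities in
#' \[0, 1\], non-negative costs and discount rate, horizon of at least one
#' cycle, and a detection schedule whose final entry is exactly 1 (the
#' undetected tunnel must drain). The first violated bound is reported with the
#' field name.
#'
#' @param params An `lcs_parameters` object (or plain named list with the same
#'   fields).
#' @return `params`, invisibly classed, if valid; otherwise an error.
#' @export
validate_parameters <- function(params) {
  required <- c(
    .lcs_prob_fields, .lcs_utility_fields, .lcs_cost_fields,
    "start_age", "horizon_cycles", "discount_rate", "wtp",
    "detection_schedule"
  )
  missing <- setdiff(required, names(params))
  if (length(missing) > 0L) {
    stop("parameter set is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  chk01 <- function(field, value) {
    if (!is.numeric(value) || anyNA(value) || any(value < 0) || any(value > 1)) {
      stop(sprintf("parameter '%s' must lie in [0, 1] (got %s)",
                   field, paste(format(value), collapse = ", ")), call. = FALSE)
    }
  }
  for (f in c(.lcs_prob_fields, .lcs_utility_fields)) chk01(f, params[[f]])
  chk01("detection_schedule", params$detection_schedule)
  for (f in c(.lcs_cost_fields, "wtp")) {
    v <- params[[f]]
    if (!is.numeric(v) || is.na(v) || v < 0) {
      stop(sprintf("parameter '%s' must be a non-negative cost (got %s)",
                   f, format(v)), call. = FALSE)
    }
  }
  if (!is.numeric(params$discount_rate) || params$discount_rate < 0) {
    stop("parameter 'discount_rate' must be >= 0", call. = FALSE)
  }
  if (params$horizon_cycles < 1L) {
    stop("parameter 'horizon_cycles' must be >= 1", call. = FALSE)
  }
  if (length(params$detection_schedule) != 3L) {
    stop("parameter 'detection_schedule' must have 3 annual entries",
         call. = FALSE)
  }
  if (params$detection_schedule[3L] != 1) {
    stop("parameter 'detection_schedule' must end in 1 (undetected state must drain)",
         call. = FALSE)
  }
  class(params) <- "lcs_parameters"
  invisible(params)
}

#' Screening strategy definition
#'
#' A screening arm is its diagnostic performance at the baseline scan plus its
#' acute per-screen costs. The AI cost is the additional per-screen cost of the
#' AI system (0 in the base case) and is the quantity varied by
#' [threshold_ai_cost()].
#'
#' @param name Strategy label.
#' @param sensitivity,specificity Test performance for BC at the baseline scan,
#'   fractions in \[0, 1\].
#' @param screen_cost Acute cost of the scan, USD per screen.
#' @param ai_cost Additional per-screen cost of AI support, USD.
#' @return An object of class `lcs_strategy`.
#' @examples
#' strategy("ct_ai", sensitivity = 0.977, specificity = 0.984)
#' @export
strategy <- function(name, sensitivity, specificity,
                     screen_cost = 161, ai_cost = 0) {
  if (!is.numeric(sensitivity) || sensitivity < 0 || sensitivity > 1) {
    stop("strategy field 'sensitivity' must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(specificity) || specificity < 0 || specificity > 1) {
    stop("strategy field 'specificity' must lie in [0, 1]", call. = FALSE)
  }
  if (screen_cost < 0 || ai_cost < 0) {
    stop("strategy costs 'screen_cost' and 'ai_cost' must be >= 0",
         call. = FALSE)
  }
  structure(
    list(name = as.character(name), sensitivity = sensitivity,
         specificity = specificity, screen_cost = screen_cost,
         ai_cost = ai_cost),
    class = "lcs_strategy"
  )
}

#' Base-case screening strategies
#'
#' The two modelled arms: conventional low-dose CT read by radiologists
#' (sensitivity 77.9\%, specificity 87.7\%) and CT with AI support
#' (sensitivity 97.7\%, specificity 98.4\%). Both arms share the same scan cost
#' (USD 161); the AI cost defaults to USD 0 so the base case isolates the
#' effect of diagnostic performance.
#'
#' @param params An `lcs_parameters` object (reserved for future
#'   parameterisation; strategies are currently independent of it).
#' @param ai_cost Additional per-screen AI cost of the CT+AI arm, USD.
#' @return Named list with elements `ct` and `ct_ai`, each an `lcs_strategy`.
#' @examples
#' s <- default_strategies()
#' s$ct_ai$sensitivity
#' @export
default_strategies <- function(params = parameter_set(), ai_cost = 0) {
  list(
    ct = strategy("ct", sensitivity = 0.779, specificity = 0.877,
                  screen_cost = 161, ai_cost = 0),
    ct_ai = strategy("ct_ai", sensitivity = 0.977, specificity = 0.984,
                     screen_cost = 161, ai_cost = ai_cost)
  )
}

#' Load a parameter configuration from YAML or JSON
#'
#' Reads a structured config file and returns a validated [parameter_set()].
#' Keys missing from the file are filled with base-case defaults. Probabilities
#' and utilities may be given as percentages by setting the top-level key
#' `probability_units: percent` (values are divided by 100 on load); the
#' default is `fraction`.
#'
#' The optional top-level key `strategies:` may hold a named map of strategy
#' definitions (`sensitivity`, `specificity`, `screen_cost`, `ai_cost`); it is
#' returned in the `"strategies"` attribute.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `lcs_parameters` object; strategies defined in the file
#'   are attached as attribute `"strategies"`.
#' @seealso [write_parameters()] for the round-trip writer.
#' @export
load_parameters <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- tryCatch(
    {
      if (grepl("\\.json$", path, ignore.case = TRUE)) {
        jsonlite::read_json(path, simplifyVector = TRUE)
      } else {
        yaml::read_yaml(path)
      }
    },
    error = function(e) {
      stop("failed to parse config '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  if (!is.list(raw)) stop("config '", path, "' did not parse to a mapping",
                          call. = FALSE)
  units <- raw$probability_units %||% "fraction"
  if (!units %in% c("fraction", "percent")) {
    stop("config key 'probability_units' must be 'fraction' or 'percent'",
         call. = FALSE)
  }
  strategies_raw <- raw$strategies
  raw$probability_units <- NULL
  raw$strategies <- NULL

  known <- names(formals(parameter_set))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (units == "percent") {
    for (f in intersect(names(raw), c(.lcs_prob_fields, .lcs_utility_fields))) {
      raw[[f]] <- raw[[f]] / 100
    }
    if ("detection_schedule" %in% names(raw)) {
      raw$detection_schedule <- raw$detection_schedule / 100
    }
  }
  params <- do.call(parameter_set, raw)
  if (!is.null(strategies_raw)) {
    strategies <- lapply(names(strategies_raw), function(nm) {
      do.call(strategy, c(list(name = nm), strategies_raw[[nm]]))
    })
    names(strategies) <- names(strategies_raw)
    attr(params, "strategies") <- strategies
  }
  params
}

#' Write a parameter set to YAML or JSON
#'
#' Serialises a parameter set (fractions, never percent) such that
#' `load_parameters(write_parameters(p, f))` reproduces `p` exactly.
#'
#' @param params An `lcs_parameters` object.
#' @param path Output path ending in `.yaml`, `.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  x <- unclass(params)
  attr(x, "strategies") <- NULL
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path, precision = 15L)
  }
  invisible(path)
}

#' @export
print.lcs_parameters <- function(x, ...) {
  cat("<lcs_parameters>\n")
  cat(sprintf("  cohort: start age %d, horizon %d annual cycles, pre-test probability %.5f\n",
              x$start_age, x$horizon_cycles, x$pretest_prob))
  cat(sprintf("  economics: discount %.1f%%/yr, WTP %s USD/QALY\n",
              100 * x$discount_rate, format(x$wtp, big.mark = ",")))
  cat(sprintf("  detection of missed BC: %s per year\n",
              paste(format(x$detection_schedule), collapse = "/")))
  invisible(x)
}

#' @export
print.lcs_strategy <- function(x, ...) {
  cat(sprintf("<lcs_strategy> %s: sens %.3f, spec %.3f, screen cost %.2f + AI %.2f USD\n",
              x$name, x$sensitivity, x$specificity, x$screen_cost, x$ai_cost))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
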