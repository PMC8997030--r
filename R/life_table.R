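#' Construct a life table
#'
#' A life table maps integer age to the annual probability of death `qx` used
#' as background (non-disease) mortality in the Markov engine. Ages must be
#' strictly increasing and every `qx` must lie in \[0, 1\]. No interpolation is
#' performed: cycles are annual and lookups are by integer age.
#'
#' @param data A data frame with columns `age` (integer years) and `qx`
#'   (annual death probability).
#' @param source_label Free-text provenance label carried in reports.
#' @return An object of class `lcs_life_table`.
#' @seealso [load_life_table()], [annual_death_prob()], [make_life_table()]
#' @export
life_table <- function(data, source_label = "user") {
  if (!is.data.frame(data) || !all(c("age", "qx") %in% names(data))) {
    stop("life table needs columns 'age' and 'qx'", call. = FALSE)
  }
  age <- as.integer(data$age)
  qx <- as.numeric(data$qx)
  if (anyNA(age) || anyNA(qx)) stop("life table contains missing values",
                                    call. = FALSE)
  if (any(diff(age) <= 0L)) {
    stop("life table ages must be strictly increasing", call. = FALSE)
  }
  bad <- which(qx < 0 | qx > 1)
  if (length(bad) > 0L) {
    stop(sprintf("life table qx outside [0, 1] at age %d (qx = %s)",
                 age[bad[1L]], format(qx[bad[1L]])), call. = FALSE)
  }
  structure(
    list(entries = data.frame(age = age, qx = qx),
         source_label = as.character(source_label)),
    class = "lcs_life_table"
  )
}

#' Load a life table from a delimited text file
#'
#' Expects a CSV (or any `read.csv`-readable file) with columns `age` and `qx`
#' (a header is allowed and recognised); alternatively the first two columns
#' are taken as age and qx.
#'
#' @param path Path to the file.
#' @param source_label Provenance label; defaults to the file name.
#' @return An `lcs_life_table`.
#' @export
load_life_table <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("life table file not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("age", "qx") %in% names(df))) {
    if (ncol(df) < 2L) stop("life table file needs two columns (age, qx)",
                            call. = FALSE)
    names(df)[1:2] <- c("age", "qx")
  }
  life_table(df[, c("age", "qx")], source_label = source_label)
}

#' Bundled synthetic US-style life table
#'
#' Returns the life table shipped with the package:
#' `extdata/life_table_us_synthetic.csv`, a *synthetic* unisex table for ages
#' 55--85 obtained by log-linear (Gompertz-type) interpolation through
#' US-magnitude anchor values at five-year ages. It stands in for a published
#' national life table, which is deliberately swappable via
#' [load_life_table()]; all reproduction results quoted in the package
#' documentation depend on this fixture.
#'
#' @return An `lcs_life_table` covering ages 55--85.
#' @export
default_life_table <- function() {
  path <- system.file("extdata", "life_table_us_synthetic.csv",
                      package = "lcscreen", mustWork = TRUE)
  load_life_table(path, source_label = "bundled synthetic US-style table (ages 55-85)")
}

#' Annual background death probability at an integer age
#'
#' @param lt An `lcs_life_table`.
#' @param age Integer age in years; must be covered by the table.
#' @return The annual death probability `qx` at that age.
#' @export
annual_death_prob <- function(lt, age) {
  stopifnot(inherits(lt, "lcs_life_table"))
  i <- match(as.integer(age), lt$entries$age)
  if (anyNA(i)) {
    stop(sprintf("age %s not covered by life table '%s' (ages %d-%d)",
                 paste(age[is.na(i)], collapse = ", "), lt$source_label,
                 min(lt$entries$age), max(lt$entries$age)), call. = FALSE)
  }
  lt$entries$qx[i]
}

# internal: check that lt covers [start_age, start_age + horizon]
check_life_table_coverage <- function(lt, params) {
  need <- params$start_age + 0:params$horizon_cycles
  missing <- setdiff(need, lt$entries$age)
  if (length(missing) > 0L) {
    stop(sprintf("life table '%s' does not cover required age(s) %s",
                 lt$source_label, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.lcs_life_table <- function(x, ...) {
  cat(sprintf("<lcs_life_table> %s: ages %d-%d, qx %.5f-%.5f\n",
              x$source_label, min(x$entries$age), max(x$entries$age),
              min(x$entries$qx), max(x$entries$qx)))
  invisible(x)
}
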