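# Measurement data model, natural-abundance correction, and the chi-square
# objective comparing simulated observables with measured tables.
#
# CSV dialect: columns experiment, metabolite, fragment ("C1-C6", "C1-C4",
# ...), quantity ("m0".."m6" or "conc"), mean, sd, units ("fraction", "mM",
# "mg_per_mL"). One row per measured quantity.

MEASUREMENT_COLS <- c("experiment", "metabolite", "fragment", "quantity",
                      "mean", "sd", "units")

#' Load a measurement table from CSV
#'
#' Reads the package's measurement CSV dialect and validates it: required
#' columns present, `sd > 0` on every row, isotopologue means in `[0, 1]`.
#' Malformed rows are reported with their line numbers.
#'
#' @param path CSV file path.
#' @return a tibble with columns `experiment, metabolite, fragment, quantity,
#'   mean, sd, units`.
#' @export
load_measurements <- function(path) {
  if (!file.exists(path)) stop("load_measurements: no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  missing <- setdiff(MEASUREMENT_COLS, names(df))
  if (length(missing)) {
    stop("load_measurements: missing columns: ", paste(missing, collapse = ", "))
  }
  tb <- tibble::as_tibble(df[MEASUREMENT_COLS])
  validate_measurements(tb, context = path)
  tb
}

#' Write a measurement table to CSV
#'
#' Inverse of [load_measurements()]; the round trip is lossless.
#'
#' @param table measurement tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(table, path) {
  validate_measurements(table)
  utils::write.csv(as.data.frame(table[MEASUREMENT_COLS]), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

validate_measurements <- function(tb, context = "measurement table") {
  bad_sd <- which(!is.finite(tb$sd) | tb$sd <= 0)
  if (length(bad_sd)) {
    stop(context, ": sd must be > 0; offending row(s): ",
         paste(bad_sd, collapse = ", "))
  }
  frac <- grepl("^m[0-9]+$", tb$quantity)
  bad_mean <- which(frac & (tb$mean < 0 | tb$mean > 1))
  if (length(bad_mean)) {
    stop(context, ": isotopologue means must lie in [0,1]; row(s): ",
         paste(bad_mean, collapse = ", "))
  }
  invisible(tb)
}

#' Chi-square of simulated observables against a measurement table
#'
#' Computes \eqn{\chi^2 = \sum_i [(y_i - f_i)/\sigma_i]^2} over all rows of
#' the measurement table, grouped per metabolite/fragment block the way the
#' study tables group them, plus the total and the number of points used.
#'
#' @param simulated tibble of simulated observables with columns
#'   `metabolite, fragment, quantity, value` (an `experiment` column, if
#'   present, is matched too).
#' @param table measurement tibble as from [load_measurements()].
#' @return object of class `chi_square_report`: list with `total`, `n`, and
#'   `per_group` tibble (`metabolite, fragment, chi2, n`).
#' @export
chi_square <- function(simulated, table) {
  validate_measurements(table)
  keys <- c("metabolite", "fragment", "quantity")
  if ("experiment" %in% names(simulated) &&
      length(unique(table$experiment)) > 1L) {
    keys <- c("experiment", keys)
  }
  joined <- dplyr::left_join(table, simulated, by = keys,
                             relationship = "one-to-one")
  if (anyNA(joined$value)) {
    miss <- joined[is.na(joined$value), keys]
    stop("chi_square: no simulated observable for row(s): ",
         paste(utils::capture.output(print(as.data.frame(miss))), collapse = "\n"))
  }
  joined$contrib <- ((joined$mean - joined$value) / joined$sd)^2
  per_group <- joined |>
    dplyr::group_by(.data$metabolite, .data$fragment) |>
    dplyr::summarise(chi2 = sum(.data$contrib), n = dplyr::n(),
                     .groups = "drop")
  structure(
    list(total = sum(joined$contrib), n = nrow(joined),
         per_group = per_group, rows = joined),
    class = "chi_square_report")
}

#' @export
print.chi_square_report <- function(x, ...) {
  cat(sprintf("chi-square report: total = %.4g over %d points\n", x$total, x$n))
  print(x$per_group, n = Inf)
  invisible(x)
}

#' @export
tidy.chi_square_report <- function(x, ...) x$per_group

#' @export
glance.chi_square_report <- function(x, ...) {
  tibble::tibble(chi2 = x$total, n = x$n)
}

#' Forward natural-abundance convolution matrix
#'
#' `M[j+1, k+1] = C(n-k, j-k) p^(j-k) (1-p)^(n-j)`: the probability that a
#' molecule with `k` tracer-labeled skeleton carbons out of `n` appears at
#' mass `m_j` once natural 13C at abundance `p` decorates the remaining
#' `n - k` positions.
#'
#' @param n_carbons number of skeleton carbons.
#' @param p13c natural 13C abundance (default 0.0107).
#' @return `(n+1) x (n+1)` lower-triangular matrix mapping corrected -> raw.
#' @export
natural_abundance_matrix <- function(n_carbons, p13c = 0.0107) {
  stopifnot(n_carbons >= 1, p13c >= 0, p13c < 0.5)
  n <- n_carbons
  m <- matrix(0, n + 1, n + 1)
  for (k in 0:n) {
    for (j in k:n) {
      m[j + 1, k + 1] <- choose(n - k, j - k) * p13c^(j - k) * (1 - p13c)^(n - j)
    }
  }
  m
}

#' Correct a measured mass-isotopologue distribution for natural abundance
#'
#' Inverts the binomial skeleton-carbon convolution: measured (raw) fractions
#' are modeled as `raw = M %*% corrected` with `M` from
#' [natural_abundance_matrix()]. Small negative inversion artifacts
#' (`> -1e-9`) are clipped to zero and the result renormalized to sum 1.
#'
#' @param raw_fractions numeric vector `m0..mn` summing to 1.
#' @param n_carbons number of skeleton carbons (`length(raw_fractions) - 1`).
#' @param p13c natural 13C abundance.
#' @return corrected fractions summing to 1.
#' @export
correct_natural_abundance <- function(raw_fractions, n_carbons = length(raw_fractions) - 1L,
                                      p13c = 0.0107) {
  stopifnot(length(raw_fractions) == n_carbons + 1L)
  if (abs(sum(raw_fractions) - 1) > 1e-6) {
    stop("correct_natural_abundance: raw fractions must sum to 1")
  }
  m <- natural_abundance_matrix(n_carbons, p13c)
  corrected <- solve(m, raw_fractions)
  if (any(corrected < -1e-6)) {
    warning("correct_natural_abundance: large negative artifacts after inversion")
  }
  corrected[corrected < 0] <- 0
  corrected / sum(corrected)
}

#' Apply natural abundance to a tracer-only distribution
#'
#' Forward counterpart of [correct_natural_abundance()].
#'
#' @inheritParams correct_natural_abundance
#' @param fractions tracer-only (skeleton) fractions `m0..mn`.
#' @return raw fractions as a mass spectrometer would report them.
#' @export
convolve_natural_abundance <- function(fractions, n_carbons = length(fractions) - 1L,
                                       p13c = 0.0107) {
  stopifnot(length(fractions) == n_carbons + 1L)
  as.vector(natural_abundance_matrix(n_carbons, p13c) %*% fractions)
}

#' Packaged measured isotopologue tables from the hepatocyte tracer study
#'
#' Returns the packaged measured (mean, sd) tables: `"glucose_only"` for the
#' 2-h incubation with 20 mM glucose enriched 50% in [1,2-13C2]glucose
#' (22 whole-molecule rows plus 6 glycogen-fragment rows), or
#' `"glucose_lactate"` for the paired experiments with glucose + 9 mM lactate
#' + 1 mM pyruvate, labeled either in glucose or in lactate.
#'
#' @param which `"glucose_only"` or `"glucose_lactate"`.
#' @return measurement tibble.
#' @export
study_measurements <- function(which = c("glucose_only", "glucose_lactate")) {
  which <- match.arg(which)
  f <- c(glucose_only = "table1_measurements.csv",
         glucose_lactate = "table2_measurements.csv")[[which]]
  load_measurements(system.file("extdata", f, package = "labelflux",
                                mustWork = TRUE))
}

#' Packaged best-fit simulated isotopologue values
#'
#' The simulated observables reported alongside the measurements for the two
#' model variants: `"B"` (channeled hexose phosphate pool) and `"A"`
#' (well-mixed single pool).
#'
#' @param which study, as in [study_measurements()].
#' @return tibble with columns `model, experiment, metabolite, fragment,
#'   quantity, value`.
#' @export
study_simulated <- function(which = c("glucose_only", "glucose_lactate")) {
  which <- match.arg(which)
  f <- c(glucose_only = "table1_simulated.csv",
         glucose_lactate = "table2_simulated.csv")[[which]]
  path <- system.file("extdata", f, package = "labelflux", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE,
                                    comment.char = "#"))
}
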