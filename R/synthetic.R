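# Synthetic measurement generator: fixtures with the statistical structure
# of the hepatocyte tracer study from known ground-truth parameters, for
# parameter-recovery and topology-recovery studies.

# Quantities reported per metabolite/fragment in synthetic study tables
# (mirrors the layout of the study's printed tables).
.study_rows <- function() {
  tibble::tribble(
    ~metabolite, ~fragment, ~quantity,
    "glucose", "C1-C6", "m0", "glucose", "C1-C6", "m1",
    "glucose", "C1-C6", "m2", "glucose", "C1-C6", "m3",
    "glucose", "C1-C6", "conc",
    "lactate", "C1-C3", "m0", "lactate", "C1-C3", "m1",
    "lactate", "C1-C3", "m2", "lactate", "C1-C3", "m3",
    "lactate", "C1-C3", "conc",
    "glutamate", "C2-C5", "m0", "glutamate", "C2-C5", "m1",
    "glutamate", "C2-C5", "m2",
    "glutamate", "C2-C4", "m0", "glutamate", "C2-C4", "m1",
    "glutamate", "C2-C4", "m2",
    "glycogen", "C1-C6", "m0", "glycogen", "C1-C6", "m1",
    "glycogen", "C1-C6", "m2", "glycogen", "C1-C6", "m3",
    "glycogen", "C1-C6", "m4", "glycogen", "C1-C6", "m5",
    "glycogen", "C1-C6", "conc",
    "glycogen", "C1-C4", "m0", "glycogen", "C1-C4", "m1",
    "glycogen", "C1-C4", "m2",
    "glycogen", "C3-C6", "m0", "glycogen", "C3-C6", "m1",
    "glycogen", "C3-C6", "m2")
}

#' Default measurement-noise profile
#'
#' Standard deviations with the magnitudes of the study's tables: for
#' isotopologue fractions 5% of the mean, floored at 0.005 and capped at
#' 0.05; for concentrations 10% of the mean.
#'
#' @param quantity `"m0"`..`"m6"` or `"conc"`.
#' @param mean simulated mean value.
#' @return standard deviation (strictly positive).
#' @export
default_noise_sd <- function(quantity, mean) {
  ifelse(quantity == "conc", pmax(0.1 * mean, 1e-3),
         pmin(pmax(0.05 * mean, 0.005), 0.05))
}

#' Describe a synthetic tracer study
#'
#' @param truth_variant scheme variant generating the data (`"A"` or `"B"`).
#' @param truth_params ground-truth parameters (default
#'   [default_params()] of the truth scheme).
#' @param experiments list of [experiment()] objects (default: the
#'   glucose-only incubation).
#' @param noise_sd function `(quantity, mean) -> sd`.
#' @param seed RNG seed recorded in the output.
#' @return object of class `synthetic_study`.
#' @export
synthetic_study <- function(truth_variant = "B", truth_params = NULL,
                            experiments = list(experiment_glucose_only()),
                            noise_sd = default_noise_sd, seed = 1L) {
  scheme <- build_scheme(truth_variant)
  structure(
    list(truth_variant = truth_variant, scheme = scheme,
         truth_params = truth_params %||% default_params(scheme),
         experiments = experiments, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_study")
}

#' Generate a synthetic measurement table from ground truth
#'
#' Simulates the study's observables at the ground-truth parameters, then
#' draws independent Gaussian noise per measured channel using the noise
#' profile; noisy fractions are clipped at zero and each fragment's full
#' distribution renormalized to sum 1 before the measured channels are
#' extracted. The truth record (parameters, noiseless observables, mean
#' fluxes) is returned alongside.
#'
#' @param study a [synthetic_study()].
#' @param sim_args simulation settings (defaults mirror fitting-grade runs).
#' @return list with `table` (measurement tibble), `truth` (list with
#'   `params`, `observables`, `fluxes`), and `seed`.
#' @export
generate_measurements <- function(study,
                                  sim_args = list(grid = seq(0, 120, by = 10),
                                                  rtol = 1e-6, atol = 1e-9)) {
  stopifnot(inherits(study, "synthetic_study"))
  set.seed(study$seed)
  layout <- .study_rows()
  tables <- list()
  truth_obs <- list()
  truth_flux <- list()
  for (ex in study$experiments) {
    sim <- do.call(simulate_labeling,
                   c(list(scheme = study$scheme, params = study$truth_params,
                          experiment = ex), sim_args))
    obs <- observables(sim)
    truth_obs[[ex$id]] <- obs
    truth_flux[[ex$id]] <- mean_fluxes(sim)
    # noise fractions per fragment on the full distribution, then renormalize
    noisy <- obs |>
      dplyr::group_by(.data$metabolite, .data$fragment) |>
      dplyr::group_modify(function(df, key) {
        is_frac <- df$quantity != "conc"
        sd <- study$noise_sd(df$quantity, pmax(df$value, 0))
        val <- df$value + stats::rnorm(nrow(df), 0, sd)
        val[is_frac] <- pmax(val[is_frac], 0)
        if (any(is_frac)) val[is_frac] <- val[is_frac] / sum(val[is_frac])
        df$value <- val
        df$sd <- sd
        df
      }) |>
      dplyr::ungroup()
    tab <- dplyr::inner_join(layout, noisy,
                             by = c("metabolite", "fragment", "quantity")) |>
      dplyr::transmute(experiment = ex$id, .data$metabolite, .data$fragment,
                       .data$quantity, mean = .data$value, sd = .data$sd,
                       .data$units)
    tables[[ex$id]] <- tab
  }
  table <- dplyr::bind_rows(tables)
  validate_measurements(table)
  list(table = table,
       truth = list(variant = study$truth_variant,
                    params = study$truth_params,
                    observables = dplyr::bind_rows(truth_obs),
                    fluxes = truth_flux),
       seed = study$seed)
}

#' One topology-recovery trial
#'
#' Generates a synthetic study from the truth topology, fits each candidate
#' topology to the generated table (annealing from log-normally perturbed
#' default parameters), and reports the discrimination statistics per
#' candidate.
#'
#' @param truth_variant generating topology.
#' @param fit_variants candidate topologies to fit.
#' @param seed trial seed (controls noise, starts, and annealing).
#' @param schedule annealing schedule (reduced-budget default).
#' @param start_spread log-sd of the multiplicative perturbation applied to
#'   the starting parameters.
#' @param sim_args simulation settings.
#' @return list with `reports` (tibble of N, P_eff, F, chi2, Q, verdict per
#'   variant), `fits`, and the generated `data`.
#' @export
topology_recovery_trial <- function(truth_variant = "B",
                                    fit_variants = c("A", "B"),
                                    seed = 1L,
                                    schedule = list(steps = 60,
                                                    polish_sweeps = 1),
                                    start_spread = 0.25,
                                    sim_args = list(grid = seq(0, 120, by = 10),
                                                    rtol = 1e-6, atol = 1e-9)) {
  study <- synthetic_study(truth_variant, seed = seed)
  data <- generate_measurements(study, sim_args = sim_args)
  fits <- list()
  reports <- list()
  for (v in fit_variants) {
    scheme <- build_scheme(v)
    base <- default_params(scheme)
    free <- fit_free_params(scheme)
    set.seed(seed * 1000L + match(v, c("A", "B")))
    start <- base[free] * exp(stats::rnorm(length(free), 0, start_spread))
    res <- fit_and_discriminate(
      scheme, study$experiments, data$table, base_params = base, free = free,
      start = start, schedule = schedule, seed = seed * 1000L + 500L + match(v, c("A", "B")),
      sim_args = sim_args)
    fits[[v]] <- res
    reports[[v]] <- tidy(res$report)
  }
  list(reports = dplyr::bind_rows(reports), fits = fits, data = data,
       seed = seed)
}
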