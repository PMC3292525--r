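# Global stochastic minimization of chi-square over parameters, joint
# multi-experiment fitting with shared parameters, and chi-square-threshold
# confidence intervals on fluxes.

#' Chi-square objective for one or several experiments
#'
#' Builds the function minimized by [anneal()]: for a free-parameter vector
#' it simulates every experiment with the shared parameter set, aggregates
#' the observables, and sums the chi-square against the measurement table.
#' Simulation failures yield an infinite objective (the annealer treats the
#' move as rejected).
#'
#' @param scheme a `network_scheme`.
#' @param experiments list of [experiment()] objects whose ids match the
#'   `experiment` column of `table`.
#' @param table measurement tibble covering all experiments.
#' @param base_params full named parameter vector; free parameters override
#'   entries of it.
#' @param free character vector of parameter names being fitted.
#' @param sim_args list of [simulate_labeling()] settings used during
#'   fitting (coarser grid/tolerances than reporting runs).
#' @return function `theta -> list(chi2, reports, predicted, fluxes)`, with
#'   `predicted` aligned to the rows of `table`.
#' @export
fit_objective <- function(scheme, experiments, table, base_params, free,
                          sim_args = list(grid = seq(0, 120, by = 10),
                                          rtol = 1e-6, atol = 1e-9)) {
  stopifnot(length(experiments) >= 1, all(free %in% names(base_params)))
  validate_measurements(table)
  exp_ids <- vapply(experiments, `[[`, "", "id")
  stopifnot(all(table$experiment %in% exp_ids))
  function(theta) {
    stopifnot(length(theta) == length(free))
    params <- base_params
    params[free] <- theta
    sims <- tryCatch(
      lapply(experiments, function(ex) {
        do.call(simulate_labeling,
                c(list(scheme = scheme, params = params, experiment = ex),
                  sim_args))
      }),
      error = function(e) e)
    if (inherits(sims, "error")) {
      return(list(chi2 = Inf, reports = NULL, predicted = NULL,
                  fluxes = NULL, error = conditionMessage(sims)))
    }
    obs <- dplyr::bind_rows(lapply(sims, observables))
    reports <- lapply(exp_ids, function(id) {
      chi_square(obs[obs$experiment == id, ],
                 table[table$experiment == id, ])
    })
    names(reports) <- exp_ids
    predicted <- unlist(lapply(reports, function(r) r$rows$value),
                        use.names = FALSE)
    fluxes <- rowMeans(vapply(sims, function(s) mean_fluxes(s)$flux,
                              numeric(length(scheme$reactions))))
    names(fluxes) <- names(scheme$reactions)
    list(chi2 = sum(vapply(reports, `[[`, 1.0, "total")),
         reports = reports, predicted = predicted, fluxes = fluxes)
  }
}

#' Simulated annealing with coordinate-descent polish
#'
#' Global stochastic minimization: multiplicative log-normal proposals on one
#' randomly chosen free parameter at a time (parameters span several orders
#' of magnitude), Metropolis acceptance under a geometrically cooled
#' temperature, followed by a coordinate-descent polish around the best
#' visited point. Fully reproducible given the seed.
#'
#' @param objective function from [fit_objective()] (or any function
#'   returning `list(chi2 = ...)`).
#' @param start named numeric vector of free-parameter starting values.
#' @param lower,upper bounds on the free parameters.
#' @param schedule list: `t0` initial temperature (default: scaled to the
#'   starting objective), `alpha` geometric cooling factor per step,
#'   `steps` number of annealing moves, `step_size` log-sd of proposals,
#'   `polish_sweeps` coordinate-descent sweeps, `polish_factor`
#'   multiplicative trial step of the polish.
#' @param seed RNG seed.
#' @return object of class `fit_result`: best parameters, chi-square
#'   breakdown, time-averaged fluxes, the accepted-move trace, and the seed.
#' @export
anneal <- function(objective, start, lower = start / 100, upper = start * 100,
                   schedule = list(), seed = 1L) {
  sch <- utils::modifyList(
    list(t0 = NULL, alpha = 0.95, steps = 120, step_size = 0.5,
         polish_sweeps = 1, polish_factor = 1.2),
    schedule)
  set.seed(seed)
  free <- names(start)
  lower <- rep_len(lower, length(start)); upper <- rep_len(upper, length(start))
  cur <- pmin(pmax(start, lower), upper)
  ev <- objective(cur)
  n_eval <- 1L
  trace <- list(list(step = 0L, chi2 = ev$chi2, params = cur,
                     fluxes = ev$fluxes, accepted = TRUE))
  best <- list(theta = cur, ev = ev)
  t0 <- sch$t0 %||% max(ev$chi2 / 10, 1)
  cur_chi2 <- ev$chi2
  temp <- t0
  for (s in seq_len(sch$steps)) {
    j <- sample(length(cur), 1L)
    prop <- cur
    prop[j] <- min(max(cur[j] * exp(stats::rnorm(1, 0, sch$step_size)),
                       lower[j]), upper[j])
    pe <- objective(prop)
    n_eval <- n_eval + 1L
    acc <- is.finite(pe$chi2) &&
      (pe$chi2 <= cur_chi2 ||
         stats::runif(1) < exp((cur_chi2 - pe$chi2) / temp))
    if (acc) {
      cur <- prop
      cur_chi2 <- pe$chi2
      if (pe$chi2 < best$ev$chi2) best <- list(theta = prop, ev = pe)
    }
    trace[[length(trace) + 1L]] <-
      list(step = s, chi2 = pe$chi2, params = prop, fluxes = pe$fluxes,
           accepted = acc)
    temp <- temp * sch$alpha
  }
  # coordinate descent around the best visited point, with a step factor
  # that halves (in log scale) on sweeps without improvement
  cur <- best$theta
  fac <- sch$polish_factor
  for (sweep in seq_len(sch$polish_sweeps)) {
    improved <- FALSE
    for (j in seq_along(cur)) {
      for (f in c(fac, 1 / fac)) {
        prop <- cur
        prop[j] <- min(max(cur[j] * f, lower[j]), upper[j])
        if (prop[j] == cur[j]) next
        pe <- objective(prop)
        n_eval <- n_eval + 1L
        trace[[length(trace) + 1L]] <-
          list(step = NA_integer_, chi2 = pe$chi2, params = prop,
               fluxes = pe$fluxes, accepted = pe$chi2 < best$ev$chi2)
        if (is.finite(pe$chi2) && pe$chi2 < best$ev$chi2) {
          best <- list(theta = prop, ev = pe)
          cur <- prop
          improved <- TRUE
          break
        }
      }
    }
    if (!improved) {
      fac <- exp(log(fac) / 2)
      if (fac < 1.0005) break
    }
  }
  structure(
    list(theta = best$theta, free = free, chi2 = best$ev$chi2,
         reports = best$ev$reports, fluxes = best$ev$fluxes,
         predicted = best$ev$predicted, trace = trace, seed = seed,
         n_eval = n_eval, schedule = sch),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result: chi2 = %.4g after %d evaluations (%d free parameters, seed %d)\n",
              x$chi2, x$n_eval, length(x$free), x$seed))
  invisible(x)
}

#' @export
tidy.fit_result <- function(x, ...) {
  tibble::tibble(reaction = names(x$fluxes), flux = unname(x$fluxes))
}

#' @export
glance.fit_result <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, p_free = length(x$free), n_eval = x$n_eval,
                 seed = x$seed)
}

#' Ensemble of fits for confidence-interval estimation
#'
#' Collects several optimization runs (and their annealing traces) into one
#' object; the chi-square threshold procedure draws flux intervals from it.
#'
#' @param fits list of `fit_result` objects.
#' @return object of class `flux_ensemble`.
#' @export
flux_ensemble <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "fit_result")))
  chi2s <- vapply(fits, `[[`, 1.0, "chi2")
  structure(list(fits = fits, chi2_min = min(chi2s)), class = "flux_ensemble")
}

# All visited points of an ensemble as (chi2, flux matrix).
.ensemble_points <- function(ensemble) {
  pts <- unlist(lapply(ensemble$fits, function(f) {
    c(f$trace, list(list(chi2 = f$chi2, fluxes = f$fluxes)))
  }), recursive = FALSE)
  pts <- Filter(function(p) is.finite(p$chi2) && !is.null(p$fluxes), pts)
  chi2 <- vapply(pts, `[[`, 1.0, "chi2")
  fl <- do.call(rbind, lapply(pts, `[[`, "fluxes"))
  list(chi2 = chi2, fluxes = fl)
}

#' Chi-square-threshold confidence interval for a flux
#'
#' The envelope (min, max) of a flux over all parameter sets visited by the
#' ensemble whose chi-square lies within `qchisq(level, 1)` of the ensemble
#' minimum — the profile-likelihood-style threshold (6.63 at the 99% level).
#'
#' @param ensemble a [flux_ensemble()].
#' @param flux_id reaction id(s); default all.
#' @param level confidence level (default 0.99).
#' @param min_members warn when fewer qualifying points than this support
#'   the interval.
#' @return tibble `reaction, best, lo, hi, n_members`.
#' @export
confidence_intervals <- function(ensemble, flux_id = NULL, level = 0.99,
                                 min_members = 5L) {
  stopifnot(inherits(ensemble, "flux_ensemble"))
  pts <- .ensemble_points(ensemble)
  thr <- ensemble$chi2_min + stats::qchisq(level, df = 1)
  keep <- pts$chi2 <= thr
  if (sum(keep) < min_members) {
    warning("confidence_intervals: only ", sum(keep),
            " qualifying ensemble points; intervals may under-cover")
  }
  best_fit <- ensemble$fits[[which.min(vapply(ensemble$fits, `[[`, 1.0, "chi2"))]]
  ids <- flux_id %||% colnames(pts$fluxes)
  fl <- pts$fluxes[keep, ids, drop = FALSE]
  tibble::tibble(
    reaction = ids,
    best = unname(best_fit$fluxes[ids]),
    lo = unname(apply(fl, 2, min)),
    hi = unname(apply(fl, 2, max)),
    n_members = sum(keep))
}

#' Fit a topology variant and run the model discrimination test
#'
#' Convenience pipeline: anneal the free parameters against the measurement
#' table, then count effective parameters from the SVD of the Gauss-Newton
#' Hessian at the optimum and assemble the acceptance statistics (N, P_eff,
#' F, chi-square, Q, verdict).
#'
#' @param scheme a `network_scheme`.
#' @param experiments list of [experiment()] objects.
#' @param table measurement tibble.
#' @param base_params full parameter vector (default [default_params()]).
#' @param free free-parameter names (default [fit_free_params()]).
#' @param start starting values for the free parameters (default: the base
#'   values).
#' @param schedule annealing schedule, see [anneal()].
#' @param seed RNG seed.
#' @param sim_args simulation settings during fitting.
#' @param hessian_step relative finite-difference step for the Hessian.
#' @param cond_threshold reciprocal-condition threshold for the effective
#'   parameter count.
#' @return list with `fit` (a `fit_result`), `hessian`
#'   (`hessian_analysis`), and `report` (`discrimination_report`).
#' @export
fit_and_discriminate <- function(scheme, experiments, table,
                                 base_params = default_params(scheme),
                                 free = fit_free_params(scheme),
                                 start = NULL, schedule = list(), seed = 1L,
                                 sim_args = list(grid = seq(0, 120, by = 10),
                                                 rtol = 1e-6, atol = 1e-9),
                                 hessian_step = 1e-4,
                                 cond_threshold = 1e-10) {
  obj <- fit_objective(scheme, experiments, table, base_params, free, sim_args)
  start <- start %||% base_params[free]
  fit <- anneal(obj, start, lower = start / 100, upper = start * 100,
                schedule = schedule, seed = seed)
  predict_fn <- function(theta) {
    ev <- obj(theta)
    if (!is.finite(ev$chi2)) stop("prediction failed during Hessian evaluation")
    ev$predicted
  }
  hess <- gauss_newton_hessian(predict_fn, fit$theta, sd = table$sd,
                               step = hessian_step)
  eff <- effective_parameter_count(hess, cond_threshold)
  report <- discrimination_report(nrow(table), eff$p_eff, fit$chi2,
                                  model = scheme$variant)
  list(fit = fit, hessian = hess, effective = eff, report = report)
}

#' Default free-parameter set for topology fitting
#'
#' The rate constants governing the fluxes that differ most between the
#' well-mixed and channeled topologies: glucose entry/exit, the
#' phosphofructokinase / fructose-bisphosphatase recycling, glycogen
#' synthesis, lactate output, triose-phosphate exchange and the hexose-triose
#' half-exchange; variant B adds the channel's own four reactions.
#'
#' @param scheme a `network_scheme`.
#' @return character vector of parameter names.
#' @export
fit_free_params <- function(scheme) {
  base <- c("k_hk1", "k_g6pase1", "k_pfk1", "k_fbpase1", "k_gs", "k_lacout",
            "k_aldex_f", "k_f6p_g3p")
  if (scheme$variant == "B") {
    c(base, "k_hk2", "k_g6pase2", "k_pfk2", "k_fbpase2")
  } else {
    base
  }
}
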