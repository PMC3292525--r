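# Rate laws and the ODE system for total metabolite concentrations.
#
# Units: time in minutes; concentrations in mM per volume of cell suspension
# (medium metabolites and intracellular pools share this volume base, so no
# medium/cell scaling factor enters the balance equations); fluxes in
# mM min^-1. Glycogen is tracked in mM glucosyl-unit equivalents
# (162 mg/mmol converts to mg/mL for reporting).

#' Evaluate a single rate law
#'
#' @param rate_law_id `"mass_action"` (k times the product of substrate
#'   concentrations) or `"michaelis_menten"` (Vmax S / (Km + S),
#'   unimolecular).
#' @param params named list/vector with the law's parameters (`k`, or `vmax`
#'   and `km`).
#' @param conc named vector of substrate concentrations.
#' @return nonnegative finite rate.
#' @examples
#' reaction_rate("mass_action", c(k = 0.1), c(S = 2))        # 0.2
#' reaction_rate("michaelis_menten", c(vmax = 1, km = 1), c(S = 1))  # 0.5
#' @export
reaction_rate <- function(rate_law_id, params, conc) {
  conc <- pmax(conc, 0)
  p <- as.list(params)
  switch(rate_law_id,
    mass_action = {
      if (is.null(p$k)) stop("reaction_rate: mass_action needs parameter 'k'")
      p$k * prod(conc)
    },
    michaelis_menten = {
      if (is.null(p$vmax) || is.null(p$km)) {
        stop("reaction_rate: michaelis_menten needs 'vmax' and 'km'")
      }
      if (length(conc) != 1L) {
        stop("reaction_rate: michaelis_menten is unimolecular")
      }
      unname(p$vmax * conc / (p$km + conc))
    },
    stop("reaction_rate: unknown rate law '", rate_law_id, "'"))
}

# Aldolase elementary rates from shared parameters and concentrations.
.aldolase_rates <- function(params, conc) {
  elementary_rates(
    v1 = params[["ald_k1"]] * max(conc[["fbp"]], 0),
    v2 = params[["ald_k2"]],
    v3 = params[["ald_k3"]],
    vm1 = params[["ald_km1"]],
    vm2 = params[["ald_km2"]] * max(conc[["g3p"]], 0),
    vm3 = params[["ald_km3"]] * max(conc[["dhap"]], 0))
}

#' All reaction fluxes of a scheme at given concentrations
#'
#' Mass-action and Michaelis-Menten reactions use their own parameters
#' (`k_<id>`, or `vmax_<id>`/`km_<id>`); the three aldolase-derived fluxes
#' (net forward `aldf`, net reverse `aldr`, half-molecule exchange `aldhex`)
#' are resolved jointly from the shared elementary-step parameters via
#' [exchange_fluxes()], so that `aldf - aldr` is the net aldolase chemical
#' flux at every instant.
#'
#' @param scheme a `network_scheme`.
#' @param params named parameter vector.
#' @param conc named concentration vector (clamped at zero).
#' @return named vector of fluxes, one per reaction.
#' @export
compute_fluxes <- function(scheme, params, conc) {
  flux_evaluator(scheme, params)(conc)
}

#' Precompiled flux evaluator
#'
#' Resolves parameter and substrate lookups once and returns a fast
#' `function(conc) -> named flux vector`, used by both ODE stages.
#'
#' @inheritParams compute_fluxes
#' @return function of a concentration vector.
#' @export
flux_evaluator <- function(scheme, params) {
  rxs <- scheme$reactions
  nr <- length(rxs)
  pool_ids <- names(scheme$pools)
  law <- vapply(rxs, `[[`, "", "rate_law")
  role <- vapply(rxs, function(rx) rx$role %||% "", "")
  k <- rep(NA_real_, nr)
  s1 <- rep(NA_integer_, nr)
  s2 <- rep(NA_integer_, nr)
  vmax <- rep(NA_real_, nr)
  km <- rep(NA_real_, nr)
  for (j in seq_len(nr)) {
    rx <- rxs[[j]]
    subs <- match(rx$substrates, pool_ids)
    if (length(subs) > 2) stop("flux_evaluator: > 2 substrates in ", rx$id)
    s1[j] <- subs[1]
    if (length(subs) > 1) s2[j] <- subs[2]
    if (law[j] == "mass_action") {
      kj <- params[[paste0("k_", rx$id)]]
      if (is.null(kj)) stop("flux_evaluator: missing parameter k_", rx$id)
      k[j] <- kj
    } else if (law[j] == "michaelis_menten") {
      vmax[j] <- params[[paste0("vmax_", rx$id)]]
      km[j] <- params[[paste0("km_", rx$id)]]
    }
  }
  is_ma <- law == "mass_action"
  is_mm <- law == "michaelis_menten"
  is_ald <- law == "aldolase"
  has_ald <- any(is_ald)
  i_fbp <- match("fbp", pool_ids)
  i_g3p <- match("g3p", pool_ids)
  i_dhap <- match("dhap", pool_ids)
  ald_par <- if (has_ald) {
    c(params[["ald_k1"]], params[["ald_k2"]], params[["ald_k3"]],
      params[["ald_km1"]], params[["ald_km2"]], params[["ald_km3"]])
  } else NULL
  rx_names <- names(rxs)
  function(conc) {
    conc <- pmax(conc, 0)
    v <- numeric(nr)
    c1 <- conc[s1]
    c2 <- ifelse(is.na(s2), 1, conc[s2])
    v[is_ma] <- k[is_ma] * c1[is_ma] * c2[is_ma]
    if (any(is_mm)) {
      v[is_mm] <- vmax[is_mm] * c1[is_mm] / (km[is_mm] + c1[is_mm])
    }
    if (has_ald) {
      d <- ald_par[2] * ald_par[1] * conc[i_fbp] +
        ald_par[6] * conc[i_dhap] * ald_par[1] * conc[i_fbp] +
        ald_par[6] * conc[i_dhap] * ald_par[5] * conc[i_g3p]
      if (d <= 0) {
        v[is_ald] <- 0
      } else {
        v1 <- ald_par[1] * conc[i_fbp]; v2 <- ald_par[2]; v3 <- ald_par[3]
        vm1 <- ald_par[4]; vm2 <- ald_par[5] * conc[i_g3p]
        vm3 <- ald_par[6] * conc[i_dhap]
        vf <- v1 * v2 * v3 / d
        vr <- vm1 * vm2 * vm3 / d
        vfg <- if (v1 + vm2 > 0) v1 * v2 / (v1 + vm2) else 0
        vgf <- if (vm2 + v2 > 0) vm3 * vm2 / (vm2 + v2) else 0
        v[is_ald & role == "vf"] <- vf
        v[is_ald & role == "vr"] <- vr
        v[is_ald & role == "vhalf"] <- vfg + vgf
      }
    }
    names(v) <- rx_names
    v
  }
}

#' Stoichiometry matrix of a scheme
#'
#' @param scheme a `network_scheme`.
#' @return pools x reactions matrix of net stoichiometric coefficients;
#'   exchange-only reactions have all-zero columns.
#' @export
stoichiometry <- function(scheme) {
  pools <- names(scheme$pools)
  s <- matrix(0, length(pools), length(scheme$reactions),
              dimnames = list(pools, names(scheme$reactions)))
  for (j in seq_along(scheme$reactions)) {
    rx <- scheme$reactions[[j]]
    for (p in rx$substrates) s[p, j] <- s[p, j] - 1
    for (p in rx$products) s[p, j] <- s[p, j] + 1
  }
  s
}

#' Right-hand side of the totals ODE system
#'
#' `d conc / dt = S v(conc)` with `S` the stoichiometry matrix and `v` the
#' rate-law fluxes. Negative input concentrations are evaluated as zero (the
#' clamp count is accumulated in `diag_env$clamps` when supplied).
#'
#' @param scheme a `network_scheme`.
#' @param params named parameter vector.
#' @param diag_env optional environment collecting integration diagnostics.
#' @return function `(t, conc, ...)` suitable for [deSolve::ode()].
#' @export
totals_rhs <- function(scheme, params, diag_env = NULL) {
  s <- stoichiometry(scheme)
  fe <- flux_evaluator(scheme, params)
  function(t, conc, ...) {
    if (any(conc < 0) && !is.null(diag_env)) {
      diag_env$clamps <- (diag_env$clamps %||% 0L) + 1L
    }
    list(as.vector(s %*% fe(conc)))
  }
}

#' Integrate total concentrations over an incubation
#'
#' Implicit stiff (BDF) integration of the totals ODE over the experiment
#' duration, returning dense concentration and flux series on the output
#' grid for the isotopomer layer.
#'
#' @param scheme a `network_scheme`.
#' @param params named parameter vector (see [default_params()]).
#' @param experiment an [experiment()] description.
#' @param grid output time grid in minutes; default 1-min spacing over the
#'   experiment duration.
#' @param rtol,atol solver tolerances.
#' @param method a [deSolve::ode()] method; default `"bdf"`.
#' @return object of class `totals_trajectory`: list with `times`, `conc`
#'   (times x pools), `flux` (times x reactions), and the inputs.
#' @export
integrate_totals <- function(scheme, params, experiment = experiment_glucose_only(),
                             grid = NULL, rtol = 1e-8, atol = 1e-10,
                             method = "bdf") {
  stopifnot(experiment$duration > 0)
  if (is.null(grid)) grid <- seq(0, experiment$duration, by = 1)
  conc0 <- initial_concentrations(scheme, experiment)
  dg <- new.env(parent = emptyenv())
  sol <- deSolve::ode(y = conc0, times = grid,
                      func = totals_rhs(scheme, params, dg),
                      method = method, rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("integrate_totals: solver failed (istate = ", attr(sol, "istate")[1], ")")
  }
  if (!is.null(dg$clamps) && dg$clamps > 0) {
    warning("integrate_totals: ", dg$clamps,
            " rate evaluations clamped negative concentrations to zero")
  }
  conc <- sol[, -1, drop = FALSE]
  fe <- flux_evaluator(scheme, params)
  flux <- matrix(0, nrow(conc), length(scheme$reactions),
                 dimnames = list(NULL, names(scheme$reactions)))
  for (i in seq_len(nrow(conc))) flux[i, ] <- fe(conc[i, ])
  structure(list(times = grid, conc = conc, flux = flux, scheme = scheme,
                 params = params, experiment = experiment),
            class = "totals_trajectory")
}

#' Initial concentration vector for an experiment
#'
#' Scheme defaults overridden by the experiment's `conc0` entries.
#'
#' @param scheme a `network_scheme`.
#' @param experiment an [experiment()].
#' @return named concentration vector over the scheme's pools.
#' @export
initial_concentrations <- function(scheme, experiment) {
  conc0 <- vapply(scheme$pools, `[[`, 1.0, "conc0")
  for (p in names(experiment$conc0)) {
    if (!p %in% names(conc0)) stop("experiment: unknown pool '", p, "'")
    conc0[p] <- experiment$conc0[[p]]
  }
  conc0
}

# ---- experiments ------------------------------------------------------------

#' Describe a tracer incubation experiment
#'
#' @param id experiment identifier (matched against measurement tables).
#' @param duration incubation length in minutes.
#' @param conc0 named list of initial-concentration overrides (mM).
#' @param tracers list of tracer descriptions: each
#'   `list(pool =, carbons =, fraction =)` places `fraction` of the pool's
#'   initial amount in the positional isotopomer labeled at `carbons`.
#' @return object of class `tracer_experiment`.
#' @export
experiment <- function(id, duration = 120, conc0 = list(), tracers = list()) {
  for (tr in tracers) {
    stopifnot(is.character(tr$pool), tr$fraction >= 0, tr$fraction <= 1)
  }
  structure(list(id = id, duration = duration, conc0 = conc0,
                 tracers = tracers),
            class = "tracer_experiment")
}

#' 2-h incubation with 20 mM glucose, 50% [1,2-13C2]glucose
#'
#' @param glc initial glucose (mM).
#' @param enrichment tracer molar fraction of the glucose.
#' @param duration minutes.
#' @return a `tracer_experiment`.
#' @export
experiment_glucose_only <- function(glc = 20, enrichment = 0.5, duration = 120) {
  experiment("glucose_only", duration = duration,
             conc0 = list(glc_med = glc, lac_med = 1e-4, pyr = 0.01),
             tracers = list(list(pool = "glc_med", carbons = c(1, 2),
                                 fraction = enrichment)))
}

#' 2-h incubation with 20 mM glucose + 9 mM lactate + 1 mM pyruvate
#'
#' Label either 50% [1,2-13C2] in glucose (`label = "glucose"`) or 50%
#' [U-13C3] in lactate (`label = "lactate"`).
#'
#' @param label which substrate carries the tracer.
#' @param duration minutes.
#' @return a `tracer_experiment`.
#' @export
experiment_glucose_lactate <- function(label = c("glucose", "lactate"),
                                       duration = 120) {
  label <- match.arg(label)
  tr <- if (label == "glucose") {
    list(list(pool = "glc_med", carbons = c(1, 2), fraction = 0.5))
  } else {
    list(list(pool = "lac_med", carbons = c(1, 2, 3), fraction = 0.5))
  }
  experiment(paste0(if (label == "glucose") "glc" else "lac", "_labeled"),
             duration = duration,
             conc0 = list(glc_med = 20, lac_med = 9, pyr = 1),
             tracers = tr)
}

# ---- default parameters -----------------------------------------------------

# Flux magnitudes (mM min^-1, suspension volume) the default rate constants
# reproduce at the canonical initial concentrations. Glycolytic and glycogen
# fluxes follow the best-fit values reported for hepatocytes on glucose alone;
# TCA-cycle fluxes sit between the two reported incubation conditions so that
# glutamate labeling is informative; the pentose phosphate exchange set keeps
# the classic 3:2:1 non-oxidative stoichiometry. The set is balanced so every
# intracellular pool starts near metabolic (not isotopic) steady state.
.flux_targets_B <- c(
  hk1 = 0.0027, hk2 = 0.00214, g6pase1 = 5.5e-5, g6pase2 = 2.1e-5,
  pfk1 = 0.00306, pfk2 = 0.00047, fbpase1 = 0.00044, fbpase2 = 0.00055,
  gs = 0.00222, gp = 1e-5,
  aldex_f = 0.045, aldex_r = 0.0425,
  g3pep = 0.00633, pepg3 = 0.0013, pk = 0.00523, lacout = 0.00473,
  pdh = 3e-4, pc = 2e-4, pepck = 2e-4, cs = 3e-4, citmal = 3e-4,
  maloa = 5e-4, oamal = 2e-4,
  g6pdh = 9e-5, tk1f = 6.3e-4, tk1r = 6.0e-4, tk2f = 3.3e-4, tk2r = 3.0e-4,
  taf = 7.8e-4, tar = 7.5e-4,
  p5p_g3p = 6.2e-4, f6p_g3p = 0.0075, s7p_e4p = 3e-4, f6p_s7p = 1.5e-5,
  p5p_s7p = 0.0023, s7p_f6p = 0.0015)

.flux_targets_A <- local({
  t <- .flux_targets_B
  t[["hk1"]] <- t[["hk1"]] + t[["hk2"]]
  t[["g6pase1"]] <- t[["g6pase1"]] + t[["g6pase2"]]
  t[["pfk1"]] <- t[["pfk1"]] + t[["pfk2"]]
  t[["fbpase1"]] <- t[["fbpase1"]] + t[["fbpase2"]]
  t[!names(t) %in% c("hk2", "g6pase2", "pfk2", "fbpase2")]
})

#' Default parameter values for a scheme
#'
#' Mass-action rate constants derived from the documented default flux
#' magnitudes at the canonical initial concentrations (`k = flux /
#' prod(conc0)`), plus the aldolase elementary-step constants (chosen to give
#' forward/reverse whole-cycle fluxes near 0.019/0.017 mM/min at those
#' concentrations) and the lactate-uptake constant scaled to reproduce the
#' reported lactate influx at 9 mM medium lactate.
#'
#' @param scheme a `network_scheme`.
#' @return named numeric parameter vector.
#' @export
default_params <- function(scheme) {
  conc0 <- vapply(scheme$pools, `[[`, 1.0, "conc0")
  targets <- if (scheme$variant == "B") .flux_targets_B else .flux_targets_A
  out <- c(ald_k1 = 40 / 3, ald_k2 = 0.2, ald_k3 = 0.036,
           ald_km1 = 0.05, ald_km2 = 50, ald_km3 = 12.5,
           k_lacin = 0.0257)
  for (id in names(targets)) {
    rx <- scheme$reactions[[id]]
    if (is.null(rx)) stop("default_params: no reaction '", id, "' in scheme")
    out[[paste0("k_", id)]] <- targets[[id]] / prod(conc0[rx$substrates])
  }
  out
}

#' Construct a parameter set with bounds and frozen entries
#'
#' @param values named numeric vector of parameter values (all positive:
#'   proposals are multiplicative).
#' @param lower,upper named or scalar bounds; defaults two orders of
#'   magnitude around `values`.
#' @param frozen character vector of parameter names excluded from fitting.
#' @return object of class `parameter_set`.
#' @export
parameter_set <- function(values, lower = NULL, upper = NULL, frozen = character(0)) {
  stopifnot(all(values > 0))
  if (is.null(lower)) lower <- values / 100
  if (is.null(upper)) upper <- values * 100
  lower <- rep_len(lower, length(values))
  upper <- rep_len(upper, length(values))
  names(lower) <- names(upper) <- names(values)
  stopifnot(all(lower > 0), all(values >= lower), all(values <= upper),
            all(frozen %in% names(values)))
  structure(list(values = values, lower = lower, upper = upper,
                 frozen = frozen),
            class = "parameter_set")
}

#' Time-averaged net fluxes of a trajectory
#'
#' Flux integrated over the incubation divided by its duration, the
#' convention used for reporting fitted flux values.
#'
#' @param traj a `totals_trajectory` (or `label_simulation`).
#' @return tibble with columns `reaction, flux`.
#' @export
mean_fluxes <- function(traj) {
  if (inherits(traj, "label_simulation")) traj <- traj$totals
  stopifnot(inherits(traj, "totals_trajectory"))
  tibble::tibble(reaction = colnames(traj$flux),
                 flux = colMeans(traj$flux))
}
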