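# Isotopomer dynamics on top of the totals trajectory, and aggregation into
# mass-isotopologue distributions of whole molecules and GC/MS fragments.

#' Compile a scheme into an isotopomer transition program
#'
#' Builds the flat operation list executed by the compiled right-hand side:
#' per reaction, one consume unit per substrate occurrence and, per scramble
#' variant and product, a produce unit whose parts are the substrates
#' contributing carbons to that product. Product isotopomer distributions are
#' OR-convolutions of independent parts, which is exact because every product
#' carbon receives exactly one source.
#'
#' @param scheme a `network_scheme`.
#' @return program list (`pools`, `offsets`, `sizes`, `units`).
#' @keywords internal
#' @export
compile_isotopomer_program <- function(scheme) {
  tracked <- names(scheme$pools)[vapply(scheme$pools, `[[`, TRUE, "is_tracked")]
  ncarb <- vapply(scheme$pools[tracked], `[[`, 1L, "n_carbons")
  sizes <- as.integer(2^ncarb)
  offsets <- as.integer(cumsum(c(0L, sizes[-length(sizes)])))
  names(offsets) <- tracked
  pool_idx <- stats::setNames(seq_along(tracked), tracked)
  units <- list()
  co2_tracked <- scheme$track_co2 && "co2" %in% tracked

  for (r in seq_along(scheme$reactions)) {
    rx <- scheme$reactions[[r]]
    for (si in seq_along(rx$substrates)) {
      p <- rx$substrates[si]
      if (p %in% tracked) {
        units[[length(units) + 1L]] <-
          list(kind = 0L, pool = pool_idx[[p]], rate = r, weight = 1.0)
      }
    }
    for (v in rx$variants) {
      m <- v$map
      for (pi in seq_along(rx$products)) {
        p <- rx$products[pi]
        if (!p %in% tracked) next
        rows <- m[m[, "pi"] == pi, , drop = FALSE]
        parts <- list()
        for (s in unique(rows[, "si"])) {
          rs <- rows[rows[, "si"] == s, , drop = FALSE]
          mask <- as.integer(sum(2^(rs[, "pc"] - 1L)))
          if (s == 0L) {
            parts[[length(parts) + 1L]] <-
              list(src = 0L, proj = integer(0), mask = mask, q = 0.0)
          } else {
            sp <- rx$substrates[s]
            if (!sp %in% tracked) {        # untracked substrate: unlabeled
              parts[[length(parts) + 1L]] <-
                list(src = 0L, proj = integer(0), mask = mask, q = 0.0)
              next
            }
            nsz <- 2^scheme$pools[[sp]]$n_carbons
            idx <- 0:(nsz - 1L)
            proj <- integer(nsz)
            for (k in seq_len(nrow(rs))) {
              proj <- proj + bitwShiftL(
                as.integer(bitwAnd(idx, bitwShiftL(1L, rs[k, "sc"] - 1L)) > 0L),
                rs[k, "pc"] - 1L)
            }
            parts[[length(parts) + 1L]] <-
              list(src = pool_idx[[sp]], proj = as.integer(proj),
                   mask = mask, q = 0.0)
          }
        }
        units[[length(units) + 1L]] <-
          list(kind = 1L, pool = pool_idx[[p]], rate = r,
               weight = v$prob, parts = parts)
      }
      if (co2_tracked) {
        rel <- m[m[, "pi"] == 0L & m[, "si"] > 0L, , drop = FALSE]
        for (k in seq_len(nrow(rel))) {
          sp <- rx$substrates[rel[k, "si"]]
          if (!sp %in% tracked) next
          nsz <- 2^scheme$pools[[sp]]$n_carbons
          idx <- 0:(nsz - 1L)
          proj <- as.integer(bitwAnd(idx, bitwShiftL(1L, rel[k, "sc"] - 1L)) > 0L)
          units[[length(units) + 1L]] <-
            list(kind = 1L, pool = pool_idx[["co2"]], rate = r,
                 weight = v$prob,
                 parts = list(list(src = pool_idx[[sp]], proj = proj,
                                   mask = 1L, q = 0.0)))
        }
      }
    }
  }
  list(pools = tracked, ncarb = ncarb, offsets = offsets, sizes = sizes,
       units = units, flat = .flatten_program(units), n_state = sum(sizes))
}

# Flatten the unit list into plain vectors for the compiled right-hand side.
.flatten_program <- function(units) {
  u_kind <- vapply(units, `[[`, 0L, "kind")
  u_pool <- vapply(units, `[[`, 0L, "pool") - 1L
  u_rate <- vapply(units, `[[`, 0L, "rate") - 1L
  u_weight <- vapply(units, `[[`, 0, "weight")
  parts <- unlist(lapply(units, function(u) {
    if (u$kind == 1L) u$parts else list()
  }), recursive = FALSE)
  u_nparts <- vapply(units, function(u) {
    if (u$kind == 1L) length(u$parts) else 0L
  }, 0L)
  u_part0 <- as.integer(cumsum(c(0L, u_nparts[-length(u_nparts)])))
  p_src <- vapply(parts, function(p) as.integer(p$src) - 1L, 0L)  # -1 Bernoulli
  p_mask <- vapply(parts, `[[`, 0L, "mask")
  p_q <- vapply(parts, `[[`, 0, "q")
  projs <- lapply(parts, `[[`, "proj")
  plen <- vapply(projs, length, 0L)
  p_proj0 <- as.integer(cumsum(c(0L, plen[-length(plen)])))
  list(u_kind = u_kind, u_pool = u_pool, u_rate = u_rate,
       u_weight = u_weight, u_part0 = u_part0, u_nparts = u_nparts,
       p_src = p_src, p_mask = p_mask, p_q = p_q, p_proj0 = p_proj0,
       proj_all = as.integer(unlist(projs)))
}

#' Initial isotopomer state for an experiment
#'
#' Every pool starts at its initial concentration with the unlabeled
#' isotopomer; each tracer places the stated molar fraction of its pool in
#' the positional isotopomer labeled at the given carbons.
#'
#' @param scheme a `network_scheme`.
#' @param experiment a `tracer_experiment`.
#' @param program compiled program (recompiled when omitted).
#' @return numeric state vector.
#' @export
initial_isotopomer_state <- function(scheme, experiment,
                                     program = compile_isotopomer_program(scheme)) {
  conc0 <- initial_concentrations(scheme, experiment)
  y <- numeric(program$n_state)
  for (p in program$pools) {
    y[program$offsets[[p]] + 1L] <- conc0[[p]]
  }
  for (tr in experiment$tracers) {
    if (!tr$pool %in% program$pools) stop("tracer pool not tracked: ", tr$pool)
    off <- program$offsets[[tr$pool]]
    mask <- sum(2^(tr$carbons - 1L))
    tot <- conc0[[tr$pool]]
    y[off + 1L] <- tot * (1 - tr$fraction)
    y[off + mask + 1L] <- tot * tr$fraction
  }
  y
}

#' Right-hand side of the isotopomer system at fixed fluxes
#'
#' Exposed mainly for testing; [simulate_labeling()] drives it with the
#' time-interpolated fluxes of a totals trajectory.
#'
#' @param scheme a `network_scheme`.
#' @param fluxes named vector of reaction fluxes.
#' @param state isotopomer state vector.
#' @param program optional precompiled program.
#' @return derivative vector `d state / dt`.
#' @export
isotopomer_rhs <- function(scheme, fluxes, state,
                           program = compile_isotopomer_program(scheme)) {
  isotopomer_rhs_cpp(state, as.numeric(fluxes[names(scheme$reactions)]), program)
}

#' Simulate the isotopomer dynamics of a tracer experiment
#'
#' Two-stage integration: total concentrations and fluxes first
#' ([integrate_totals()]), then the isotopomer system driven by the
#' interpolated flux series, both with an implicit stiff scheme. The state
#' carries isotopomer concentrations, so per-pool sums track the totals
#' trajectory; glycogen accumulates deposited glucosyl units so its
#' composition is the time-integrated record of what glycogen synthase saw.
#'
#' @param scheme a `network_scheme`.
#' @param params named parameter vector.
#' @param experiment a `tracer_experiment`.
#' @param grid output times (minutes); defaults to 1-min spacing.
#' @param rtol,atol isotopomer-solver tolerances.
#' @param method [deSolve::ode()] method for the label stage.
#' @param totals optionally, a precomputed `totals_trajectory`.
#' @param flux_mode `"rate_laws"` (default) re-evaluates the rate laws at the
#'   label stage's own pool totals, which keeps per-pool isotopomer sums
#'   exactly consistent with the kinetic layer; `"interpolate"` drives the
#'   label system with fluxes interpolated from the totals trajectory.
#' @return object of class `label_simulation`: `times`, `state` (times x
#'   isotopomers), the `program`, and the underlying `totals`.
#' @export
simulate_labeling <- function(scheme, params, experiment = experiment_glucose_only(),
                              grid = NULL, rtol = 1e-7, atol = 1e-10,
                              method = "lsodes", totals = NULL,
                              flux_mode = c("rate_laws", "interpolate")) {
  flux_mode <- match.arg(flux_mode)
  if (is.null(grid)) grid <- seq(0, experiment$duration, by = 1)
  if (is.null(totals)) {
    totals <- integrate_totals(scheme, params, experiment, grid = grid)
  }
  program <- compile_isotopomer_program(scheme)
  y0 <- initial_isotopomer_state(scheme, experiment, program)
  rhs <- if (flux_mode == "interpolate") {
    ft <- totals$times
    fm <- totals$flux
    function(t, y, ...) {
      i <- findInterval(t, ft, all.inside = TRUE)
      w <- (t - ft[i]) / (ft[i + 1L] - ft[i])
      v <- fm[i, ] * (1 - w) + fm[i + 1L, ] * w
      list(isotopomer_rhs_cpp(y, v, program))
    }
  } else {
    fe <- flux_evaluator(scheme, params)
    # indicator matrix: isotopomer state -> pool totals
    npool_all <- length(scheme$pools)
    conc_static <- initial_concentrations(scheme, experiment)
    msum <- matrix(0, program$n_state, npool_all,
                   dimnames = list(NULL, names(scheme$pools)))
    for (i in seq_along(program$pools)) {
      p <- program$pools[i]
      msum[program$offsets[[p]] + seq_len(program$sizes[i]), p] <- 1
    }
    untracked <- colSums(msum) == 0
    function(t, y, ...) {
      conc <- pmax(as.vector(crossprod(msum, y)), 0)
      conc[untracked] <- conc_static[untracked]
      names(conc) <- names(conc_static)
      v <- fe(conc)
      list(isotopomer_rhs_cpp(y, v, program))
    }
  }
  # default lsodes: BDF with an internally detected sparse Jacobian, which
  # suits the block-sparse coupling between isotopomer blocks
  sol <- deSolve::ode(y = y0, times = grid, func = rhs, method = method,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0) {
    stop("simulate_labeling: label-stage solver failed (istate = ",
         attr(sol, "istate")[1], ")")
  }
  structure(list(times = grid, state = sol[, -1, drop = FALSE],
                 program = program, totals = totals, scheme = scheme,
                 params = params, experiment = experiment),
            class = "label_simulation")
}

#' @export
print.label_simulation <- function(x, ...) {
  cat(sprintf("label_simulation: scheme %s, experiment %s, %d isotopomers, t in [%g, %g] min\n",
              x$scheme$variant, x$experiment$id, ncol(x$state),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Isotopomer vector of one pool at one time
#'
#' @param sim a `label_simulation`.
#' @param pool pool id.
#' @param time time point (must be on the output grid; default endpoint).
#' @return numeric vector of isotopomer concentrations (length `2^n`).
#' @export
pool_isotopomers <- function(sim, pool, time = max(sim$times)) {
  i <- match(time, sim$times)
  if (is.na(i)) stop("pool_isotopomers: time ", time, " not on the output grid")
  off <- sim$program$offsets[[pool]]
  if (is.null(off)) stop("pool_isotopomers: pool not tracked: ", pool)
  sz <- sim$program$sizes[[match(pool, sim$program$pools)]]
  unname(sim$state[i, off + seq_len(sz)])
}

#' Aggregate isotopomers into a fragment mass-isotopologue distribution
#'
#' `m_k` is the summed fractional abundance of all isotopomers carrying
#' exactly `k` labels within the fragment's carbon range.
#'
#' @param isotopomers isotopomer concentration vector (length `2^n`).
#' @param fragment integer carbon range, e.g. `1:6` or `3:6`.
#' @return numeric vector `m0..m_len(fragment)` summing to 1.
#' @export
to_isotopologues <- function(isotopomers, fragment = seq_len(round(log2(length(isotopomers))))) {
  n <- round(log2(length(isotopomers)))
  stopifnot(2^n == length(isotopomers), all(fragment >= 1), all(fragment <= n))
  tot <- sum(isotopomers)
  if (tot <= 0) stop("to_isotopologues: empty pool (total concentration 0)")
  idx <- 0:(2^n - 1L)
  counts <- integer(2^n)
  for (c in fragment) {
    counts <- counts + as.integer(bitwAnd(idx, bitwShiftL(1L, c - 1L)) > 0L)
  }
  as.vector(tapply(isotopomers / tot, factor(counts, levels = 0:length(fragment)),
                   sum, default = 0))
}

# Reported observable layout: pool, reported name, fragments, conc unit.
.observable_layout <- function() {
  list(
    list(pool = "glc_med", metabolite = "glucose",
         fragments = list(`C1-C6` = 1:6), conc_units = "mM"),
    list(pool = "lac_med", metabolite = "lactate",
         fragments = list(`C1-C3` = 1:3), conc_units = "mM"),
    list(pool = "glu", metabolite = "glutamate",
         fragments = list(`C2-C5` = 2:5, `C2-C4` = 2:4), conc_units = NA),
    list(pool = "glycogen", metabolite = "glycogen",
         fragments = list(`C1-C6` = 1:6, `C1-C4` = 1:4, `C3-C6` = 3:6),
         conc_units = "mg_per_mL"))
}

#' Endpoint observables of a simulation
#'
#' The isotopologue fractions and concentrations that the tracer study
#' reports: medium glucose (whole molecule), medium lactate, glutamate
#' fragments C2-C5 and C2-C4, and glycogen glucose with its C1-C4 and C3-C6
#' GC/MS fragments; glucose and lactate concentrations in mM, glycogen in
#' mg/mL (162 mg per mmol glucosyl units).
#'
#' @param sim a `label_simulation`.
#' @param time reporting time (default: end of incubation).
#' @return tibble with columns `experiment, metabolite, fragment, quantity,
#'   value, units`.
#' @export
observables <- function(sim, time = max(sim$times)) {
  rows <- list()
  for (ob in .observable_layout()) {
    iso <- pool_isotopomers(sim, ob$pool, time)
    for (fr in names(ob$fragments)) {
      frac <- to_isotopologues(iso, ob$fragments[[fr]])
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metabolite = ob$metabolite, fragment = fr,
        quantity = paste0("m", seq_along(frac) - 1L),
        value = frac, units = "fraction")
    }
    if (!is.na(ob$conc_units)) {
      conc <- sum(iso)
      if (ob$conc_units == "mg_per_mL") {
        conc <- conc * sim$scheme$config$glycogen_mg_per_mmol / 1000
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        metabolite = ob$metabolite,
        fragment = if (ob$metabolite == "lactate") "C1-C3" else "C1-C6",
        quantity = "conc", value = conc, units = ob$conc_units)
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::mutate(experiment = sim$experiment$id, .before = 1)
}

#' Total 13C content of the state (label balance audit)
#'
#' @param sim a `label_simulation`.
#' @param pools subset of pools (default: all tracked).
#' @return tibble `time, label_mM`: summed 13C concentration over the pools.
#' @export
label_content <- function(sim, pools = sim$program$pools) {
  pr <- sim$program
  out <- numeric(length(sim$times))
  for (p in pools) {
    i <- match(p, pr$pools)
    sz <- pr$sizes[i]
    idx <- 0:(sz - 1L)
    pop <- integer(sz)
    for (c in seq_len(pr$ncarb[i])) {
      pop <- pop + as.integer(bitwAnd(idx, bitwShiftL(1L, c - 1L)) > 0L)
    }
    block <- sim$state[, pr$offsets[[p]] + seq_len(sz), drop = FALSE]
    out <- out + as.vector(block %*% pop)
  }
  tibble::tibble(time = sim$times, label_mM = out)
}
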