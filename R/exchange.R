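# Steady-state partition of an enzyme's elementary-step rates into
# forward-cycle, reverse-cycle, and half-molecule isotope-exchange fluxes.
#
# The three-step aldolase cycle: E + fbp -> E-fbp (v1), E-fbp -> E-dhap + g3p
# (v2), E-dhap -> E + dhap (v3), with reverse steps vm1, vm2 (g3p binding),
# vm3 (dhap binding). The same treatment carries over to transketolase /
# transaldolase with the donor half-molecule in fbp's role.

#' Elementary rates of a three-step enzyme cycle
#'
#' @param v1,v2,v3 forward elementary rates (substrate binding, cleavage,
#'   product release).
#' @param vm1,vm2,vm3 reverse elementary rates.
#' @return named list of class `elementary_rates`.
#' @export
elementary_rates <- function(v1, v2, v3, vm1, vm2, vm3) {
  r <- list(v1 = v1, v2 = v2, v3 = v3, vm1 = vm1, vm2 = vm2, vm3 = vm3)
  if (any(unlist(r) < 0)) stop("elementary_rates: rates must be nonnegative")
  structure(r, class = "elementary_rates")
}

.cycle_denominator <- function(r) {
  r$v2 * r$v1 + r$vm3 * r$v1 + r$vm3 * r$vm2
}

#' Steady-state origin fractions of the enzyme-bound intermediates
#'
#' The fraction of each bound intermediate that originated from the upper
#' (fbp) substrate rather than from the free triose pools, expressed as the
#' ratio of fbp-originated input to total input at steady state:
#' `Pf_Edhap = v1 v2 / (v2 v1 + vm3 v1 + vm3 vm2)`,
#' `Pf_Efbp = (vm2 Pf_Edhap + v1) / (v1 + vm2)`, and the single-binding
#' fraction `Pfg_Efbp = v1 / (v1 + vm2)` relevant for the half-molecule
#' exchange.
#'
#' @param rates an [elementary_rates()] object.
#' @return named numeric vector `c(pf_edhap, pf_efbp, pfg_efbp)`, all in
#'   `[0, 1]`.
#' @export
partition_fractions <- function(rates) {
  stopifnot(inherits(rates, "elementary_rates"))
  d <- .cycle_denominator(rates)
  if (d <= 0 || rates$v1 + rates$vm2 <= 0) {
    stop("partition_fractions: denominator is zero (all-zero rate cycle)")
  }
  pf_edhap <- rates$v2 * rates$v1 / d
  pf_efbp <- (rates$vm2 * pf_edhap + rates$v1) / (rates$v1 + rates$vm2)
  pfg_efbp <- rates$v1 / (rates$v1 + rates$vm2)
  c(pf_edhap = pf_edhap, pf_efbp = pf_efbp, pfg_efbp = pfg_efbp)
}

#' Isotope-exchange fluxes of the three-step cycle
#'
#' Resolves the cycle into the four pool-level label fluxes: the forward
#' whole-cycle flux `vf = v1 v2 v3 / D`, the reverse whole-cycle flux
#' `vr = vm1 vm2 vm3 / D` (with `D = v2 v1 + vm3 v1 + vm3 vm2`), the forward
#' half-molecule exchange `vfg = v1 v2 / (v1 + vm2)` that swaps the cleaved
#' half of the bound substrate with the free triose pool without completing
#' the cycle, and its reverse-path counterpart `vgf = vm3 vm2 / (vm2 + v2)`.
#' `vf - vr` equals the net chemical flux of the cycle.
#'
#' @param rates an [elementary_rates()] object.
#' @return named numeric vector `c(vf, vr, vfg, vgf)`.
#' @export
exchange_fluxes <- function(rates) {
  stopifnot(inherits(rates, "elementary_rates"))
  d <- .cycle_denominator(rates)
  if (d <= 0) stop("exchange_fluxes: zero cycle denominator")
  vf <- rates$v1 * rates$v2 * rates$v3 / d
  vr <- rates$vm1 * rates$vm2 * rates$vm3 / d
  vfg <- if (rates$v1 + rates$vm2 > 0) rates$v1 * rates$v2 / (rates$v1 + rates$vm2) else 0
  vgf <- if (rates$vm2 + rates$v2 > 0) rates$vm3 * rates$vm2 / (rates$vm2 + rates$v2) else 0
  c(vf = vf, vr = vr, vfg = vfg, vgf = vgf)
}

#' Single-molecule Monte-Carlo oracle for the exchange fluxes
#'
#' Validates the analytic partition by direct simulation of molecule origins.
#' Each bound intermediate's origin is resolved by walking the input-branching
#' chain backwards: an E-dhap molecule arrived via cleavage (probability
#' `v2/(v2+vm3)`) or via dhap binding; a cleavage-derived molecule inherits
#' the origin of the E-fbp it came from, which in turn arrived via fbp binding
#' (`v1/(v1+vm2)`) or via g3p re-binding from an E-dhap, recursively.
#' Empirical origin fractions times the exit rates estimate `vf`, `vr`,
#' `vfg`.
#'
#' @param rates an [elementary_rates()] object.
#' @param n_molecules number of simulated molecules per intermediate.
#' @param seed RNG seed.
#' @return list with empirical fluxes (`vf`, `vr`, `vfg`, `vgf`), their
#'   binomial Monte-Carlo standard errors, and the empirical origin
#'   fractions.
#' @export
stochastic_exchange_oracle <- function(rates, n_molecules = 1e5, seed = 1L) {
  stopifnot(inherits(rates, "elementary_rates"), n_molecules >= 1)
  set.seed(seed)
  v <- rates
  # Resolve the origin (TRUE = fbp) of one E-dhap / E-fbp molecule by
  # stochastic recursion on the input branches; iterative to avoid deep
  # recursion when re-binding loops many times.
  origin_edhap <- function() {
    state <- "edhap"
    repeat {
      if (state == "edhap") {
        if (v$v2 + v$vm3 == 0) return(NA)
        if (stats::runif(1) < v$v2 / (v$v2 + v$vm3)) state <- "efbp" else return(FALSE)
      } else {                       # efbp
        if (v$v1 + v$vm2 == 0) return(NA)
        if (stats::runif(1) < v$v1 / (v$v1 + v$vm2)) return(TRUE) else state <- "edhap"
      }
    }
  }
  origin_efbp <- function() {
    if (v$v1 + v$vm2 == 0) return(NA)
    if (stats::runif(1) < v$v1 / (v$v1 + v$vm2)) TRUE else origin_edhap()
  }
  n <- as.integer(n_molecules)
  ed <- if (v$v3 > 0) mean(replicate(n, origin_edhap())) else NA_real_
  ef <- if (v$vm1 > 0) mean(replicate(n, origin_efbp())) else NA_real_
  # Half-exchange: lower-part origin of E-fbp is a single binomial branch.
  pfg <- if (v$v1 + v$vm2 > 0) {
    mean(stats::runif(n) < v$v1 / (v$v1 + v$vm2))
  } else NA_real_
  se <- function(p) if (is.na(p)) NA_real_ else sqrt(max(p * (1 - p), 1e-12) / n)
  list(
    vf = if (is.na(ed)) 0 else v$v3 * ed,
    vr = if (is.na(ef)) 0 else v$vm1 * (1 - ef),
    vfg = if (is.na(pfg)) 0 else v$v2 * pfg,
    vgf = exchange_fluxes(rates)[["vgf"]],
    se_vf = if (is.na(ed)) 0 else v$v3 * se(ed),
    se_vr = if (is.na(ef)) 0 else v$vm1 * se(ef),
    se_vfg = if (is.na(pfg)) 0 else v$v2 * se(pfg),
    n = n,
    fractions = c(pf_edhap = ed, pf_efbp = ef, pfg_efbp = pfg))
}
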