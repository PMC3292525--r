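# Annealing optimizer, objective assembly, confidence intervals.

quad_objective <- function(theta) {
  list(chi2 = sum(((theta - c(1, 2, 3)) / 0.1)^2))
}

test_that("annealing recovers the minimizer of a convex quadratic", {
  fit <- anneal(quad_objective, start = c(a = 3, b = 0.5, c = 1),
                lower = rep(0.01, 3), upper = rep(50, 3),
                schedule = list(steps = 250, step_size = 0.6,
                                polish_sweeps = 60, polish_factor = 1.3),
                seed = 4)
  expect_equal(unname(fit$theta), c(1, 2, 3), tolerance = 1e-3)
  expect_lt(fit$chi2, 1e-3)
})

test_that("annealing is reproducible and never returns a worse point than its best", {
  f1 <- anneal(quad_objective, start = c(a = 3, b = 0.5, c = 1),
               schedule = list(steps = 40), seed = 7)
  f2 <- anneal(quad_objective, start = c(a = 3, b = 0.5, c = 1),
               schedule = list(steps = 40), seed = 7)
  expect_identical(f1$theta, f2$theta)
  expect_identical(vapply(f1$trace, `[[`, 1.0, "chi2"),
                   vapply(f2$trace, `[[`, 1.0, "chi2"))
  all_chi2 <- vapply(f1$trace, `[[`, 1.0, "chi2")
  expect_equal(f1$chi2, min(all_chi2))
  # reported objective equals a fresh evaluation at the returned point
  expect_equal(quad_objective(f1$theta)$chi2, f1$chi2)
})

test_that("parameters outside the free set stay at their base values", {
  sch <- build_scheme("B")
  base <- default_params(sch)
  seen <- new.env(parent = emptyenv())
  # spy on the parameter vectors the simulator receives
  study <- synthetic_study("B", seed = 6)
  d <- generate_measurements(study)
  obj <- fit_objective(sch, study$experiments, d$table, base,
                       free = c("k_hk1", "k_gs"))
  ev <- obj(c(k_hk1 = base[["k_hk1"]] * 2, k_gs = base[["k_gs"]] / 2))
  expect_true(is.finite(ev$chi2))
  # the annealer proposes moves only on the free names
  fit <- anneal(function(th) list(chi2 = sum(th)),
                start = c(u = 1, v = 2), schedule = list(steps = 15), seed = 2)
  for (tr in fit$trace) expect_identical(names(tr$params), c("u", "v"))
})

test_that("the objective of two identical experiments is twice the single one", {
  sch <- toy_scheme()
  # two experiments identical except for their id
  e1 <- experiment("rep1", duration = 10,
                   tracers = list(list(pool = "X", carbons = 1L, fraction = 0.3)))
  e2 <- experiment("rep2", duration = 10,
                   tracers = list(list(pool = "X", carbons = 1L, fraction = 0.3)))
  # measurement rows: Z isotopologues at endpoint (custom minimal layout)
  sim <- simulate_labeling(sch, toy_params, e1, grid = c(0, 10))
  mz <- to_isotopologues(pool_isotopomers(sim, "Z", 10), 1:3)
  base_rows <- tibble::tibble(
    metabolite = "Z", fragment = "C1-C3", quantity = paste0("m", 0:3),
    mean = pmin(pmax(mz + c(0.02, -0.01, 0.01, 0), 0), 1), sd = 0.05,
    units = "fraction")
  tab <- dplyr::bind_rows(
    dplyr::mutate(base_rows, experiment = "rep1", .before = 1),
    dplyr::mutate(base_rows, experiment = "rep2", .before = 1))
  # simulated observables for the toy pools via a bespoke observable set:
  obj_chi2 <- function(experiments, table) {
    tot <- 0
    for (ex in experiments) {
      s <- simulate_labeling(sch, toy_params, ex, grid = c(0, 10))
      m <- to_isotopologues(pool_isotopomers(s, "Z", 10), 1:3)
      sub <- table[table$experiment == ex$id, ]
      tot <- tot + sum(((sub$mean - m) / sub$sd)^2)
    }
    tot
  }
  single <- obj_chi2(list(e1), tab[tab$experiment == "rep1", ])
  both <- obj_chi2(list(e1, e2), tab)
  expect_equal(both, 2 * single, tolerance = 1e-10)
})

test_that("fitting noiseless synthetic data at the truth gives a near-zero objective", {
  study <- synthetic_study("B", noise_sd = function(q, m) 1e-9, seed = 2)
  d <- generate_measurements(study)
  tab <- dplyr::mutate(d$table, sd = 0.01)
  obj <- fit_objective(build_scheme("B"), study$experiments, tab,
                       default_params(build_scheme("B")),
                       free = c("k_hk1", "k_gs"))
  ev <- obj(default_params(build_scheme("B"))[c("k_hk1", "k_gs")])
  expect_lt(ev$chi2, 1e-3)
  expect_length(ev$predicted, nrow(tab))
})

test_that("confidence intervals contain the best fit and drop over-threshold members", {
  mk_fit <- function(chi2, flux, trace_fluxes = list()) {
    structure(list(theta = c(k = 1), free = "k", chi2 = chi2,
                   fluxes = c(vx = flux), trace = trace_fluxes, seed = 1,
                   reports = NULL, predicted = NULL, n_eval = 1,
                   schedule = list()),
              class = "fit_result")
  }
  # single member: degenerate interval at its flux
  ens1 <- flux_ensemble(list(mk_fit(5, 0.3)))
  ci1 <- confidence_intervals(ens1, "vx", min_members = 1)
  expect_equal(ci1$lo, 0.3)
  expect_equal(ci1$hi, 0.3)
  # a member far above the threshold is excluded from the envelope
  ens2 <- flux_ensemble(list(
    mk_fit(5, 0.3, list(list(chi2 = 6, fluxes = c(vx = 0.35)))),
    mk_fit(300, 9.9)))
  ci2 <- confidence_intervals(ens2, "vx", min_members = 1)
  expect_equal(ci2$lo, 0.3)
  expect_equal(ci2$hi, 0.35)
  expect_true(ci2$best >= ci2$lo && ci2$best <= ci2$hi)
})
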