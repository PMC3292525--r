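# Shared fixtures and independent oracles.

# Brute-force isotopomer derivative by direct enumeration of substrate
# isotopomer tuples -- deliberately independent of the compiled
# OR-convolution engine.
brute_isotopomer_rhs <- function(scheme, fluxes, state) {
  tracked <- names(scheme$pools)[vapply(scheme$pools, `[[`, TRUE, "is_tracked")]
  ncarb <- vapply(scheme$pools[tracked], `[[`, 1L, "n_carbons")
  sizes <- 2^ncarb
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  names(offsets) <- tracked
  frac_of <- function(p) {
    block <- state[offsets[[p]] + seq_len(sizes[[p]])]
    tot <- sum(block)
    if (tot > 1e-12) block / tot else c(1, rep(0, sizes[[p]] - 1L))
  }
  dx <- numeric(length(state))
  for (r in seq_along(scheme$reactions)) {
    rx <- scheme$reactions[[r]]
    v <- fluxes[[rx$id]]
    if (v == 0) next
    for (var in rx$variants) {
      w <- var$prob * v
      m <- var$map
      # consume
      for (si in seq_along(rx$substrates)) {
        p <- rx$substrates[si]
        if (!p %in% tracked) next
        dx[offsets[[p]] + seq_len(sizes[[p]])] <-
          dx[offsets[[p]] + seq_len(sizes[[p]])] - w * frac_of(p)
      }
      # produce: enumerate all substrate isotopomer tuples
      subs <- rx$substrates
      sub_sizes <- vapply(subs, function(p) {
        if (p %in% tracked) as.integer(sizes[[p]]) else 1L
      }, 1L)
      fr <- lapply(subs, function(p) if (p %in% tracked) frac_of(p) else 1)
      tuples <- expand.grid(lapply(sub_sizes, function(n) 0:(n - 1L)))
      for (ti in seq_len(nrow(tuples))) {
        s_iso <- as.integer(tuples[ti, ])
        prob <- prod(vapply(seq_along(subs), function(i) fr[[i]][s_iso[i] + 1L], 1.0))
        if (prob == 0) next
        for (pi in seq_along(rx$products)) {
          p <- rx$products[pi]
          if (!p %in% tracked) next
          rows <- m[m[, "pi"] == pi, , drop = FALSE]
          mask <- 0L
          for (k in seq_len(nrow(rows))) {
            si <- rows[k, "si"]
            if (si == 0L) next  # unlabeled source
            bit <- bitwAnd(bitwShiftR(s_iso[si], rows[k, "sc"] - 1L), 1L)
            mask <- mask + bitwShiftL(bit, rows[k, "pc"] - 1L)
          }
          dx[offsets[[p]] + mask + 1L] <- dx[offsets[[p]] + mask + 1L] + w * prob
        }
      }
    }
  }
  dx
}

# 3-pool toy network: condensation, split, and a scrambling exchange.
toy_scheme <- function(order = c("X", "Y", "Z")) {
  pools <- list(
    X = pool("X", 2, "cytosol", 0.4),
    Y = pool("Y", 1, "cytosol", 0.3),
    Z = pool("Z", 3, "cytosol", 0.2))
  rxs <- list(
    reaction("condense", c("X", "Y"), "Z",
             rbind(labelflux:::m_span(1, 1:2, 1, 1:2),
                   labelflux:::m_span(2, 1, 1, 3))),
    reaction("split", "Z", c("X", "Y"),
             rbind(labelflux:::m_span(1, 1:2, 1, 1:2),
                   labelflux:::m_span(1, 3, 2, 1))),
    reaction("scramble", "Z", "Z", kind = "exchange", variants = list(
      list(prob = 0.5, map = labelflux:::m_ident(3)),
      list(prob = 0.5, map = labelflux:::m_rev(3)))))
  new_scheme(pools[order], rxs, variant = "toy")
}

toy_params <- c(k_condense = 2, k_split = 1.5, k_scramble = 4)

toy_experiment <- function() {
  experiment("toy", duration = 10,
             tracers = list(list(pool = "X", carbons = 1L, fraction = 0.3)))
}

# Brute-force integration of the toy system with the default lsoda solver.
brute_simulate <- function(scheme, params, experiment, grid) {
  prog <- compile_isotopomer_program(scheme)
  y0 <- initial_isotopomer_state(scheme, experiment, prog)
  fe <- flux_evaluator(scheme, params)
  tracked <- prog$pools
  rhs <- function(t, y, ...) {
    tot <- vapply(tracked, function(p) {
      i <- match(p, prog$pools)
      sum(y[prog$offsets[[p]] + seq_len(prog$sizes[i])])
    }, 1.0)
    conc <- vapply(names(scheme$pools), function(p) {
      if (p %in% tracked) max(tot[[p]], 0) else scheme$pools[[p]]$conc0
    }, 1.0)
    fluxes <- fe(conc)
    list(brute_isotopomer_rhs(scheme, fluxes, y))
  }
  sol <- deSolve::ode(y = y0, times = grid, func = rhs, method = "lsoda",
                      rtol = 1e-9, atol = 1e-12)
  list(times = grid, state = sol[, -1, drop = FALSE], program = prog)
}
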