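# Metabolite pools, reactions with carbon atom-transition maps, and the two
# hexose-phosphate topology variants.
#
# Carbon indexing is 1-based biochemical numbering (glucose C1 = aldehyde
# carbon). Isotopomers of an n-carbon pool are indexed 0..2^n-1; bit i-1 of
# the index encodes carbon i (0 = 12C, 1 = 13C).
#
# An atom map is an integer matrix with columns (si, sc, pi, pc): substrate
# position si (within the reaction's substrate list; 0 = untracked unlabeled
# source such as medium CO2), substrate carbon sc, product position pi (0 =
# released to an untracked sink), product carbon pc. Reactions with symmetric
# intermediates carry several map variants with probabilities summing to 1.

# ---- atom-map construction helpers -----------------------------------------

m_span <- function(si, sc, pi, pc) {
  cbind(si = as.integer(si), sc = as.integer(sc),
        pi = as.integer(pi), pc = as.integer(pc))
}
m_ident <- function(n, si = 1L, pi = 1L) m_span(si, seq_len(n), pi, seq_len(n))
m_rev <- function(n, si = 1L, pi = 1L) m_span(si, seq_len(n), pi, rev(seq_len(n)))
m_rel <- function(si, sc) m_span(si, sc, 0L, 0L)
m_unlab <- function(pi, pc) m_span(0L, 0L, pi, pc)

#' Define a metabolite pool
#'
#' @param id short pool name.
#' @param n_carbons carbon count (>= 1).
#' @param location one of `"medium"`, `"cytosol"`, `"channel"`,
#'   `"mito-lumped"`.
#' @param conc0 default initial concentration, mM per volume of cell
#'   suspension (glycogen in glucosyl-unit mM equivalents).
#' @param is_tracked whether isotopomers are simulated for this pool.
#' @return a `pool` list.
#' @export
pool <- function(id, n_carbons, location, conc0, is_tracked = TRUE) {
  stopifnot(n_carbons >= 1, conc0 >= 0,
            location %in% c("medium", "cytosol", "channel", "mito-lumped"))
  structure(list(id = id, n_carbons = as.integer(n_carbons),
                 location = location, conc0 = conc0,
                 is_tracked = isTRUE(is_tracked)),
            class = "pool")
}

#' Define a reaction with its atom map
#'
#' @param id flux name.
#' @param substrates character vector of substrate pool ids (repeat an id for
#'   stoichiometry 2; order defines the substrate positions of the map).
#' @param products character vector of product pool ids.
#' @param map atom-map matrix (columns si, sc, pi, pc), or `NULL` when
#'   `variants` is given.
#' @param variants list of `list(prob =, map =)` for scrambling reactions.
#' @param rate_law rate-law id: `"mass_action"`, `"michaelis_menten"`, or
#'   `"aldolase"` (flux derived from the shared elementary-step parameters;
#'   the `role` field then selects vf, vr or the half-exchange).
#' @param kind `"net"` or `"exchange"` (exchange-only reactions leave all
#'   total concentrations unchanged).
#' @param role for `rate_law = "aldolase"`: `"vf"`, `"vr"` or `"vhalf"`.
#' @return a `reaction` list.
#' @export
reaction <- function(id, substrates, products, map = NULL, variants = NULL,
                     rate_law = "mass_action", kind = "net", role = NULL) {
  if (is.null(variants)) {
    stopifnot(!is.null(map))
    variants <- list(list(prob = 1, map = map))
  }
  structure(list(id = id, substrates = substrates, products = products,
                 variants = variants, rate_law = rate_law, kind = kind,
                 role = role),
            class = "reaction")
}

# ---- scheme construction ----------------------------------------------------

.base_pools <- function() {
  list(
    pool("glc_med", 6, "medium", 20),
    pool("hexP", 6, "cytosol", 0.005),
    pool("fbp", 6, "cytosol", 0.003),
    pool("dhap", 3, "cytosol", 0.004),
    pool("g3p", 3, "cytosol", 0.002),
    pool("pep", 3, "cytosol", 0.002),
    pool("pyr", 3, "cytosol", 0.01),
    pool("lac_med", 3, "medium", 1e-4),
    pool("accoa", 2, "mito-lumped", 0.002),
    pool("oaa", 4, "mito-lumped", 0.001),
    pool("mal", 4, "mito-lumped", 0.002),
    pool("glu", 5, "mito-lumped", 0.02),
    pool("glycogen", 6, "cytosol", 0.005),
    pool("p5p", 5, "cytosol", 0.002),
    pool("s7p", 7, "cytosol", 0.001),
    pool("e4p", 4, "cytosol", 0.001),
    pool("co2", 1, "mito-lumped", 25, is_tracked = FALSE))
}

# Scrambled 4-carbon identity (fumarate symmetry): 0.5 direct / 0.5 reversed.
.scramble4 <- function() {
  list(list(prob = 0.5, map = m_ident(4)),
       list(prob = 0.5, map = m_rev(4)))
}

.base_reactions <- function(hex_glycogen) {
  # hex_glycogen: pool feeding glycogen synthase / receiving phosphorylase
  # flux ("hexP" in the well-mixed scheme, "hexP_chan" in the channeled one).
  list(
    # upper glycolysis / gluconeogenesis
    reaction("hk1", "glc_med", "hexP", m_ident(6)),
    reaction("g6pase1", "hexP", "glc_med", m_ident(6)),
    reaction("pfk1", "hexP", "fbp", m_ident(6)),
    reaction("fbpase1", "fbp", "hexP", m_ident(6)),
    reaction("gs", hex_glycogen, "glycogen", m_ident(6)),
    reaction("gp", "glycogen", hex_glycogen, m_ident(6)),
    # aldolase: fbp C1-C3 -> dhap, C4-C6 -> g3p; fluxes resolved from the
    # elementary-step cycle (exchange module)
    reaction("aldf", "fbp", c("dhap", "g3p"),
             rbind(m_span(1, 1:3, 1, 1:3), m_span(1, 4:6, 2, 1:3)),
             rate_law = "aldolase", role = "vf"),
    reaction("aldr", c("dhap", "g3p"), "fbp",
             rbind(m_span(1, 1:3, 1, 1:3), m_span(2, 1:3, 1, 4:6)),
             rate_law = "aldolase", role = "vr"),
    # half-molecule exchange: swaps the lower half of bound fbp with the g3p
    # pool without completing the cycle
    reaction("aldhex", c("fbp", "g3p"), c("fbp", "g3p"),
             rbind(m_span(1, 1:3, 1, 1:3), m_span(2, 1:3, 1, 4:6),
                   m_span(1, 4:6, 2, 1:3)),
             rate_law = "aldolase", role = "vhalf", kind = "exchange"),
    # triose phosphate isomerase, carbon order reversed
    reaction("aldex_f", "dhap", "g3p", m_rev(3)),
    reaction("aldex_r", "g3p", "dhap", m_rev(3)),
    # lower glycolysis (lumped) and lactate exchange with the medium
    reaction("g3pep", "g3p", "pep", m_ident(3)),
    reaction("pepg3", "pep", "g3p", m_ident(3)),
    reaction("pk", "pep", "pyr", m_ident(3)),
    reaction("lacout", "pyr", "lac_med", m_ident(3)),
    reaction("lacin", "lac_med", "pyr", m_ident(3)),
    # pyruvate entries into the TCA cycle
    reaction("pdh", "pyr", "accoa",
             rbind(m_rel(1, 1), m_span(1, 2, 1, 1), m_span(1, 3, 1, 2))),
    reaction("pc", "pyr", "oaa",
             rbind(m_span(1, 1:3, 1, 1:3), m_unlab(1, 4))),
    reaction("pepck", "oaa", "pep",
             rbind(m_span(1, 1:3, 1, 1:3), m_rel(1, 4))),
    # citrate synthase + aconitase/IDH lumped to 2-oxoglutarate == glutamate
    reaction("cs", c("oaa", "accoa"), "glu",
             rbind(m_span(1, 4:2, 1, 1:3), m_span(2, 2, 1, 4),
                   m_span(2, 1, 1, 5), m_rel(1, 1))),
    # akg -> malate through symmetric succinate/fumarate
    reaction("citmal", "glu", "mal", variants = list(
      list(prob = 0.5, map = rbind(m_rel(1, 1), m_span(1, 2:5, 1, 1:4))),
      list(prob = 0.5, map = rbind(m_rel(1, 1), m_span(1, 2:5, 1, 4:1))))),
    reaction("maloa", "mal", "oaa", variants = .scramble4()),
    reaction("oamal", "oaa", "mal", variants = .scramble4()),
    # oxidative pentose phosphate branch (lumped)
    reaction("g6pdh", "hexP", "p5p",
             rbind(m_rel(1, 1), m_span(1, 2:6, 1, 1:5))),
    # transketolase 1: 2 p5p <-> s7p + g3p (donor gives C1-C2)
    reaction("tk1f", c("p5p", "p5p"), c("s7p", "g3p"),
             rbind(m_span(1, 1:2, 1, 1:2), m_span(1, 3:5, 2, 1:3),
                   m_span(2, 1:5, 1, 3:7))),
    reaction("tk1r", c("s7p", "g3p"), c("p5p", "p5p"),
             rbind(m_span(1, 1:2, 1, 1:2), m_span(2, 1:3, 1, 3:5),
                   m_span(1, 3:7, 2, 1:5))),
    # transketolase 2: p5p + e4p <-> f6p + g3p
    reaction("tk2f", c("p5p", "e4p"), c("hexP", "g3p"),
             rbind(m_span(1, 1:2, 1, 1:2), m_span(2, 1:4, 1, 3:6),
                   m_span(1, 3:5, 2, 1:3))),
    reaction("tk2r", c("hexP", "g3p"), c("p5p", "e4p"),
             rbind(m_span(1, 1:2, 1, 1:2), m_span(2, 1:3, 1, 3:5),
                   m_span(1, 3:6, 2, 1:4))),
    # transaldolase: s7p + g3p <-> f6p + e4p (donor gives C1-C3)
    reaction("taf", c("s7p", "g3p"), c("hexP", "e4p"),
             rbind(m_span(1, 1:3, 1, 1:3), m_span(2, 1:3, 1, 4:6),
                   m_span(1, 4:7, 2, 1:4))),
    reaction("tar", c("hexP", "e4p"), c("s7p", "g3p"),
             rbind(m_span(1, 1:3, 1, 1:3), m_span(2, 1:4, 1, 4:7),
                   m_span(1, 4:6, 2, 1:3))),
    # half-reaction isotope-exchange fluxes of tk/ta (no net conversion)
    reaction("p5p_g3p", c("p5p", "g3p"), c("p5p", "g3p"),
             rbind(m_span(1, 1:2, 1, 1:2), m_span(2, 1:3, 1, 3:5),
                   m_span(1, 3:5, 2, 1:3)), kind = "exchange"),
    reaction("f6p_g3p", c("hexP", "g3p"), c("hexP", "g3p"),
             rbind(m_span(1, 1:3, 1, 1:3), m_span(2, 1:3, 1, 4:6),
                   m_span(1, 4:6, 2, 1:3)), kind = "exchange"),
    reaction("s7p_e4p", c("s7p", "e4p"), c("s7p", "e4p"),
             rbind(m_span(1, 1:3, 1, 1:3), m_span(2, 1:4, 1, 4:7),
                   m_span(1, 4:7, 2, 1:4)), kind = "exchange"),
    reaction("f6p_s7p", c("hexP", "s7p"), c("hexP", "s7p"),
             rbind(m_span(2, 1:2, 1, 1:2), m_span(1, 3:6, 1, 3:6),
                   m_span(1, 1:2, 2, 1:2), m_span(2, 3:7, 2, 3:7)),
             kind = "exchange"),
    reaction("p5p_s7p", c("p5p", "s7p"), c("p5p", "s7p"),
             rbind(m_span(2, 1:2, 1, 1:2), m_span(1, 3:5, 1, 3:5),
                   m_span(1, 1:2, 2, 1:2), m_span(2, 3:7, 2, 3:7)),
             kind = "exchange"),
    reaction("s7p_f6p", c("s7p", "hexP"), c("s7p", "hexP"),
             rbind(m_span(2, 1:3, 1, 1:3), m_span(1, 4:7, 1, 4:7),
                   m_span(1, 1:3, 2, 1:3), m_span(2, 4:6, 2, 4:6)),
             kind = "exchange"))
}

#' Build a network scheme
#'
#' Constructs one of the two hepatocyte central-carbon topologies: variant
#' `"A"` has a single well-mixed hexose phosphate pool common to glycolysis,
#' gluconeogenesis and glycogen turnover; variant `"B"` adds a channeled
#' hexose phosphate pool (`hexP_chan`) with its own hexokinase (`hk2`),
#' glucose-6-phosphatase (`g6pase2`), fructose bisphosphatase (`fbpase2`) and
#' phosphofructokinase (`pfk2`), and routes glycogen synthesis exclusively
#' from that pool.
#'
#' @param variant `"A"` (well-mixed) or `"B"` (channeled).
#' @param track_co2 simulate CO2/bicarbonate labeling explicitly? Default
#'   `FALSE`: released carbons leave to an untracked sink and carboxylation
#'   introduces unlabeled carbon, reflecting the dominance of the unlabeled
#'   bicarbonate buffer.
#' @return object of class `network_scheme`.
#' @examples
#' sch <- build_scheme("B")
#' setdiff(names(build_scheme("B")$pools), names(build_scheme("A")$pools))
#' @export
build_scheme <- function(variant = c("A", "B"), track_co2 = FALSE) {
  variant <- match.arg(variant)
  pools <- .base_pools()
  if (variant == "B") {
    pools <- append(pools, list(pool("hexP_chan", 6, "channel", 0.002)), after = 2)
    reactions <- c(.base_reactions("hexP_chan"), list(
      reaction("hk2", "glc_med", "hexP_chan", m_ident(6)),
      reaction("g6pase2", "hexP_chan", "glc_med", m_ident(6)),
      reaction("pfk2", "hexP_chan", "fbp", m_ident(6)),
      reaction("fbpase2", "fbp", "hexP_chan", m_ident(6))))
  } else {
    reactions <- .base_reactions("hexP")
  }
  names(pools) <- vapply(pools, `[[`, "", "id")
  if (track_co2) pools$co2$is_tracked <- TRUE
  new_scheme(pools, reactions, variant = variant,
             fast_equilibrium_groups = list(
               hexP = c("g6p", "f6p"), p5p = c("r5p", "xu5p", "ru5p"),
               glu = c("akg", "glu")),
             track_co2 = track_co2)
}

#' Assemble a network scheme from pools and reactions
#'
#' Low-level constructor behind [build_scheme()], also useful for toy
#' networks in tests and examples. Validates all atom maps.
#'
#' @param pools list of [pool()] objects.
#' @param reactions list of [reaction()] objects.
#' @param variant label for the scheme.
#' @param fast_equilibrium_groups named list documenting lumped pools.
#' @param track_co2 whether CO2 labeling is simulated.
#' @param config list of reporting constants.
#' @return a validated `network_scheme`.
#' @export
new_scheme <- function(pools, reactions, variant = "custom",
                       fast_equilibrium_groups = list(),
                       track_co2 = FALSE,
                       config = list(glycogen_mg_per_mmol = 162, t_end = 120)) {
  names(pools) <- vapply(pools, `[[`, "", "id")
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(names(pools))) stop("new_scheme: duplicate pool ids")
  if (anyDuplicated(names(reactions))) stop("new_scheme: duplicate reaction ids")
  for (rx in reactions) {
    missing <- setdiff(c(rx$substrates, rx$products), names(pools))
    if (length(missing)) {
      stop("new_scheme: reaction ", rx$id, " references unknown pool(s): ",
           paste(missing, collapse = ", "))
    }
  }
  scheme <- structure(
    list(variant = variant, pools = pools, reactions = reactions,
         fast_equilibrium_groups = fast_equilibrium_groups,
         track_co2 = track_co2, config = config),
    class = "network_scheme")
  v <- validate_atom_maps(scheme)
  if (length(v)) stop("new_scheme: invalid atom maps:\n",
                      paste(v, collapse = "\n"))
  scheme
}

#' @export
print.network_scheme <- function(x, ...) {
  cat(sprintf("network_scheme variant %s: %d pools, %d reactions\n",
              x$variant, length(x$pools), length(x$reactions)))
  invisible(x)
}

#' Validate carbon conservation of every atom map in a scheme
#'
#' Checks, for every reaction and every scramble variant, that each substrate
#' carbon has exactly one fate (a product carbon or release), that each
#' product carbon has exactly one source (a substrate carbon or an untracked
#' input), that carbon counts balance (substrate carbons = mapped product
#' carbons + released), and that variant probabilities sum to 1.
#'
#' @param scheme a `network_scheme`.
#' @return character vector of violations; empty when the scheme is valid.
#' @export
validate_atom_maps <- function(scheme) {
  out <- character(0)
  for (rx in scheme$reactions) {
    nsub <- vapply(rx$substrates, function(p) scheme$pools[[p]]$n_carbons, 1L)
    nprod <- vapply(rx$products, function(p) scheme$pools[[p]]$n_carbons, 1L)
    probs <- vapply(rx$variants, `[[`, 1, "prob")
    if (abs(sum(probs) - 1) > 1e-9) {
      out <- c(out, sprintf("%s: variant probabilities sum to %.4g != 1",
                            rx$id, sum(probs)))
    }
    for (vi in seq_along(rx$variants)) {
      m <- rx$variants[[vi]]$map
      tag <- if (length(rx$variants) > 1) sprintf("%s[variant %d]", rx$id, vi) else rx$id
      # substrate side: every (si, sc) exactly once
      need <- unlist(lapply(seq_along(nsub), function(i) {
        paste(i, seq_len(nsub[i]))
      }))
      have <- paste(m[, "si"], m[, "sc"])[m[, "si"] > 0]
      for (k in setdiff(need, have)) {
        out <- c(out, sprintf("%s: substrate carbon (%s) of %s unmapped", tag,
                              k, rx$substrates[as.integer(sub(" .*", "", k))]))
      }
      dup <- have[duplicated(have)]
      for (k in unique(dup)) {
        out <- c(out, sprintf("%s: substrate carbon (%s) mapped more than once", tag, k))
      }
      # product side: every (pi, pc) exactly once
      needp <- unlist(lapply(seq_along(nprod), function(i) {
        paste(i, seq_len(nprod[i]))
      }))
      havep <- paste(m[, "pi"], m[, "pc"])[m[, "pi"] > 0]
      for (k in setdiff(needp, havep)) {
        out <- c(out, sprintf("%s: product carbon (%s) of %s receives no source",
                              tag, k, rx$products[as.integer(sub(" .*", "", k))]))
      }
      dupp <- havep[duplicated(havep)]
      for (k in unique(dupp)) {
        out <- c(out, sprintf("%s: product carbon (%s) receives two sources", tag, k))
      }
      # carbon balance: tracked inputs = mapped-to-products + released
      n_in <- sum(nsub)
      n_mapped <- sum(m[, "si"] > 0 & m[, "pi"] > 0)
      n_rel <- sum(m[, "si"] > 0 & m[, "pi"] == 0)
      if (n_in != n_mapped + n_rel) {
        out <- c(out, sprintf("%s: carbon count not conserved (%d in, %d mapped + %d released)",
                              tag, n_in, n_mapped, n_rel))
      }
    }
    if (rx$kind == "exchange") {
      if (!identical(sort(rx$substrates), sort(rx$products))) {
        out <- c(out, sprintf("%s: exchange-only reaction changes pool totals", rx$id))
      }
    }
  }
  out
}

#' Pools reachable by label from a tracer pool
#'
#' Transitive closure over the atom maps: a pool is reachable when some chain
#' of reactions can carry a tracer carbon from `tracer_pool` into it.
#'
#' @param scheme a `network_scheme`.
#' @param tracer_pool starting pool id.
#' @return character vector of reachable pool ids (includes the start).
#' @export
reachable_labeling <- function(scheme, tracer_pool) {
  stopifnot(tracer_pool %in% names(scheme$pools))
  edges <- unique(do.call(rbind, lapply(scheme$reactions, function(rx) {
    do.call(rbind, lapply(rx$variants, function(v) {
      m <- v$map
      keep <- m[, "si"] > 0 & m[, "pi"] > 0
      if (!any(keep)) return(NULL)
      cbind(from = rx$substrates[m[keep, "si"]],
            to = rx$products[m[keep, "pi"]])
    }))
  })))
  reach <- tracer_pool
  repeat {
    new <- unique(edges[edges[, "from"] %in% reach, "to"])
    new <- setdiff(new, reach)
    if (!length(new)) break
    reach <- c(reach, new)
  }
  reach
}

#' Serialize a scheme to JSON
#'
#' @param scheme a `network_scheme`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  ser <- list(
    variant = scheme$variant,
    track_co2 = scheme$track_co2,
    config = scheme$config,
    fast_equilibrium_groups = scheme$fast_equilibrium_groups,
    pools = lapply(unname(scheme$pools), function(p) p[c(
      "id", "n_carbons", "location", "conc0", "is_tracked")]),
    reactions = lapply(unname(scheme$reactions), function(rx) {
      list(id = rx$id, substrates = rx$substrates, products = rx$products,
           rate_law = rx$rate_law, kind = rx$kind, role = rx$role,
           variants = lapply(rx$variants, function(v) {
             list(prob = v$prob, map = unname(v$map))
           }))
    }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a scheme from JSON
#'
#' @param path file written by [write_scheme()].
#' @return a `network_scheme`.
#' @export
read_scheme <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  pools <- lapply(ser$pools, function(p) {
    pool(p$id, p$n_carbons, p$location, p$conc0, isTRUE(p$is_tracked))
  })
  names(pools) <- vapply(pools, `[[`, "", "id")
  reactions <- lapply(ser$reactions, function(rx) {
    variants <- lapply(rx$variants, function(v) {
      m <- do.call(rbind, lapply(v$map, function(row) as.integer(unlist(row))))
      colnames(m) <- c("si", "sc", "pi", "pc")
      list(prob = v$prob, map = m)
    })
    reaction(rx$id, unlist(rx$substrates), unlist(rx$products),
             variants = variants, rate_law = rx$rate_law, kind = rx$kind,
             role = rx$role)
  })
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  scheme <- structure(
    list(variant = ser$variant, pools = pools, reactions = reactions,
         fast_equilibrium_groups = lapply(ser$fast_equilibrium_groups, unlist),
         track_co2 = isTRUE(ser$track_co2),
         config = lapply(ser$config, unlist)),
    class = "network_scheme")
  v <- validate_atom_maps(scheme)
  if (length(v)) stop("read_scheme: invalid atom maps:\n", paste(v, collapse = "\n"))
  scheme
}
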