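#' Lattice-model coupling parameters and schedule constants
#'
#' All energies are dimensionless (units of kT).  Sign conventions:
#' `v_p > 0` is a repulsive monomer-monomer contact energy, `mu_p` a
#' per-monomer chemical potential, `mu_b` a *per-molecule* bulk chemical
#' potential, `j_bulk` the on-site cross-species attraction of the molecular
#' bulk (or the nearest-neighbour coupling of the minimal lattice gas),
#' `j_nn` a weak nearest-neighbour coupling of total bulk density, and
#' `j_int` the on-site polymer / species-1 binding energy, one value per
#' monomer type (attractive when positive; a non-interacting segment type
#' has `j_int = 0`).
#'
#' @param mu_p per-monomer polymer chemical potential.
#' @param v_p monomer-monomer contact energy (positive = repulsive).
#' @param n_max exclusive upper bound for the polymer length `N_p`.
#' @param p_kink kink proposal probability, in `[0, 1)`.
#' @param mu_b bulk chemical potential per molecule.
#' @param j_bulk bulk-bulk attraction (see above).
#' @param j_nn nearest-neighbour bulk coupling.
#' @param j_int polymer binding energy per monomer type (vector).
#' @param n_b bulk molecule length, at least 2.
#' @param delta per-segment length tolerance for multi-component chains.
#' @return an object of class `model_params`.
#' @export
model_params <- function(mu_p = 0, v_p = 0, n_max = 1500L, p_kink = 0.2,
                         mu_b = 0, j_bulk = 0, j_nn = 0, j_int = 0,
                         n_b = 20L, delta = 12L) {
  n_b <- as.integer(n_b)
  n_max <- as.integer(n_max)
  delta <- as.integer(delta)
  if (n_b < 2) stop("n_b must be at least 2")
  if (delta < 0) stop("delta must be >= 0")
  if (p_kink < 0 || p_kink >= 1) stop("p_kink must lie in [0, 1)")
  if (n_max < 3) stop("n_max too small")
  structure(list(mu_p = mu_p, v_p = v_p, n_max = n_max, p_kink = p_kink,
                 mu_b = mu_b, j_bulk = j_bulk, j_nn = j_nn,
                 j_int = as.numeric(j_int), n_b = n_b, delta = delta),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("model parameters (kT units):\n")
  cat(sprintf("  polymer: mu_p=%g v_p=%g n_max=%d p_kink=%g\n",
              x$mu_p, x$v_p, x$n_max, x$p_kink))
  cat(sprintf("  bulk:    mu_b=%g j_bulk=%g j_nn=%g n_b=%d\n",
              x$mu_b, x$j_bulk, x$j_nn, x$n_b))
  cat(sprintf("  coupling: j_int=%s delta=%d\n",
              paste(x$j_int, collapse = ","), x$delta))
  invisible(x)
}

#' Full system state on the lattice
#'
#' Bundles a polymer chain with a bulk configuration: either a minimal
#' lattice gas (`gas`, an m x 3 matrix of occupied sites, playing the role
#' of species 1 in the polymer coupling) or a list of bulk `molecules`
#' (`list(species =, sites =)`).
#'
#' @param geometry a [lattice_geometry()].
#' @param chain optional [polymer_chain()].
#' @param gas optional occupied-site matrix of the minimal bulk.
#' @param molecules list of bulk molecules.
#' @export
lattice_state <- function(geometry, chain = NULL, gas = NULL,
                          molecules = list()) {
  if (!is.null(gas)) {
    gas <- matrix(as.integer(gas), ncol = 3)
    if (length(molecules)) stop("use either a lattice gas or molecules")
  }
  structure(list(geometry = geometry, chain = chain, gas = gas,
                 molecules = molecules), class = "lattice_state")
}

# indicator vectors (length V) for the bulk species of a state
bulk_indicators <- function(state) {
  V <- prod(state$geometry$dims)
  s1 <- integer(V)
  s2 <- integer(V)
  if (!is.null(state$gas) && nrow(state$gas) > 0)
    s1[site_index(state$gas, state$geometry) + 1L] <- 1L
  for (m in state$molecules) {
    w <- site_index(m$sites, state$geometry) + 1L
    if (m$species == 1) s1[w] <- 1L else s2[w] <- 1L
  }
  list(s1 = s1, s2 = s2)
}

# +axis neighbour index matrix: V x 3, entry (i, a) is the 0-based index of
# the +a neighbour of 0-based site i-1
plus_neighbours <- function(geometry) {
  d <- geometry$dims
  co <- site_coords(seq_len(prod(d)) - 1L, geometry)
  cbind(site_index(co + rep(c(1L, 0L, 0L), each = nrow(co)), geometry),
        site_index(co + rep(c(0L, 1L, 0L), each = nrow(co)), geometry),
        site_index(co + rep(c(0L, 0L, 1L), each = nrow(co)), geometry))
}

#' Polymer energy
#'
#' `H_poly = -(mu_p + v_p) N_p + v_p * C` where `N_p` is the number of
#' occupied sites and `C` the number of nearest-neighbour pairs of occupied
#' sites (sequential pairs included: the `-v_p` per-monomer shift offsets
#' them, up to an O(1) end effect).
#'
#' @param state a [lattice_state()].
#' @param params a [model_params()].
#' @return energy in kT.
#' @export
energy_polymer <- function(state, params) {
  if (is.null(state$chain)) return(0)
  occ <- occupancy_vector(state$chain, state$geometry) > 0
  np <- n_polymer(state$chain)
  nb <- plus_neighbours(state$geometry)
  contacts <- sum(occ & occ[nb[, 1] + 1L]) + sum(occ & occ[nb[, 2] + 1L]) +
    sum(occ & occ[nb[, 3] + 1L])
  -(params$mu_p + params$v_p) * np + params$v_p * contacts
}

#' Bulk energy
#'
#' For a molecular bulk: `-mu_b (n_1 + n_2) - j_bulk * (doubly occupied
#' sites) - j_nn * sum_<ij> (s1_i + s2_i)(s1_j + s2_j)` (the cross term of
#' the nearest-neighbour sum symmetrized over species, counted once per
#' unordered pair).  For a minimal lattice gas:
#' `-mu_b sum_i s_i - j_bulk sum_<ij> s_i s_j`.
#'
#' @inheritParams energy_polymer
#' @export
energy_bulk <- function(state, params) {
  nb <- plus_neighbours(state$geometry)
  ind <- bulk_indicators(state)
  if (!is.null(state$gas)) {
    s <- ind$s1
    pairs <- sum(s * s[nb[, 1] + 1L]) + sum(s * s[nb[, 2] + 1L]) +
      sum(s * s[nb[, 3] + 1L])
    return(-params$mu_b * sum(s) - params$j_bulk * pairs)
  }
  if (!length(state$molecules)) return(0)
  n <- ind$s1 + ind$s2
  pairs <- sum(n * n[nb[, 1] + 1L]) + sum(n * n[nb[, 2] + 1L]) +
    sum(n * n[nb[, 3] + 1L])
  -params$mu_b * length(state$molecules) -
    params$j_bulk * sum(ind$s1 * ind$s2) - params$j_nn * pairs
}

#' Polymer-bulk interaction energy
#'
#' `H_int = -sum_t j_int[t] * (sites where species 1 co-occupies a type-t
#' monomer)`.  Species 2 does not couple to the polymer.
#'
#' @inheritParams energy_polymer
#' @export
energy_interaction <- function(state, params) {
  if (is.null(state$chain)) return(0)
  ind <- bulk_indicators(state)
  w <- site_index(occupied_coords(state$chain), state$geometry) + 1L
  tp <- chain_types(state$chain)[seq_along(w)]
  j <- params$j_int
  jt <- ifelse(tp >= 1 & tp <= length(j), j[pmax(tp, 1)], 0)
  -sum(jt * ind$s1[w])
}

#' Total energy of a state
#' @inheritParams energy_polymer
#' @export
energy_total <- function(state, params) {
  energy_polymer(state, params) + energy_bulk(state, params) +
    energy_interaction(state, params)
}

#' Local energy difference of a move proposal
#'
#' Computes `E(after) - E(before)` from local terms only: each removed or
#' added occupied site contributes its per-site chemical-potential term plus
#' couplings to its six neighbours and any on-site bulk occupancy, applied
#' sequentially so simultaneous changes are handled exactly.  Supported
#' proposals: polymer moves from [classify_move()], a minimal-bulk spin flip
#' `list(kind = "flip", site =)`, or `list(kind = "none")`.
#'
#' @param state a [lattice_state()].
#' @param proposal a proposal object.
#' @param params a [model_params()].
#' @return the energy difference in kT; an exact integer combination of the
#'   couplings (no accumulated floating error).
#' @export
energy_delta <- function(state, proposal, params) {
  if (proposal$kind == "none") return(0)
  geometry <- state$geometry
  ind <- bulk_indicators(state)
  if (proposal$kind == "flip") {
    if (is.null(state$gas)) stop("spin flips apply to a minimal-bulk state")
    w <- site_index(proposal$site, geometry)
    nbs <- site_index(neighbors(wrap_site(proposal$site, geometry), geometry),
                      geometry)
    k <- sum(ind$s1[nbs + 1L])
    jt <- 0
    if (!is.null(state$chain)) {
      occ <- occupancy_vector(state$chain, geometry)
      if (occ[w + 1L] > 0) {
        wsites <- site_index(occupied_coords(state$chain), geometry)
        tp <- chain_types(state$chain)[match(w, wsites)]
        jt <- params$j_int[tp]
      }
    }
    e_on <- -params$mu_b - params$j_bulk * k - jt
    return(if (ind$s1[w + 1L] > 0) -e_on else e_on)
  }
  # polymer move: sequential removal then addition of occupied sites
  chain <- state$chain
  occ <- occupancy_vector(chain, geometry) > 0
  delta <- 0
  site_terms <- function(coord, tp, occ) {
    nbs <- site_index(neighbors(wrap_site(coord, geometry), geometry),
                      geometry)
    contacts <- sum(occ[nbs + 1L])
    w <- site_index(coord, geometry)
    jt <- if (tp >= 1 && tp <= length(params$j_int)) params$j_int[tp] else 0
    -(params$mu_p + params$v_p) + params$v_p * contacts - jt * ind$s1[w + 1L]
  }
  if (!is.null(proposal$removed) && proposal$kind != "kink") {
    for (m in proposal$removed + 1L) {
      coord <- chain$coords[m, ]
      w <- site_index(coord, geometry)
      occ[w + 1L] <- FALSE
      delta <- delta - site_terms(coord, chain$types[m], occ)
    }
  }
  if (proposal$kind == "kink") {
    m <- proposal$mover + 1L
    coord <- chain$coords[m, ]
    w <- site_index(coord, geometry)
    occ[w + 1L] <- FALSE
    delta <- delta - site_terms(coord, chain$types[m], occ)
    target <- proposal$new_coords[m, ]
    delta <- delta + site_terms(target, chain$types[m], occ)
    return(delta)
  }
  if (!is.null(proposal$added)) {
    s <- proposal$bond + 1L
    tps <- chain$types[c(s, s + 1L)]
    for (i in seq_len(nrow(proposal$added))) {
      coord <- proposal$added[i, ]
      delta <- delta + site_terms(coord, tps[i], occ)
      occ[site_index(coord, geometry) + 1L] <- TRUE
    }
  }
  delta
}
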