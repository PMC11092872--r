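#' Self-avoiding lattice polymer chain
#'
#' A chain is an ordered list of monomer positions in *unwrapped* integer
#' coordinates: consecutive monomers differ by one unit step, and the walk may
#' leave the primary box (periodic images are taken when occupancy or
#' energies are evaluated).  Self-avoidance holds on wrapped sites, with one
#' sanctioned exception: when the first and last monomers are periodic images
#' of each other the chain spans the box with winding number 1 and the two
#' terminal monomers share a single wrapped site, counted once, so that the
#' polymer length is `N_p = monomers - 1` and a straight spanning chain has
#' `N_p = L`.  Under the bond-translation move set the terminal monomers can
#' never be displaced, so both endpoints stay pinned for free.
#'
#' @param coords n x 3 integer matrix of unwrapped monomer coordinates.
#' @param geometry a [lattice_geometry()].
#' @param types optional integer vector (1-based type ids, one per monomer);
#'   defaults to a single type.
#' @param type_labels optional character labels, one per type id.
#' @param validate check bonds and self-avoidance (default TRUE).
#' @return an object of class `polymer_chain`.
#' @export
polymer_chain <- function(coords, geometry, types = NULL, type_labels = NULL,
                          validate = TRUE) {
  coords <- matrix(as.integer(coords), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  n <- nrow(coords)
  if (n < 2) stop("a chain needs at least 2 monomers")
  if (is.null(types)) types <- rep(1L, n)
  types <- as.integer(types)
  if (length(types) != n) stop("types must have one entry per monomer")
  if (is.null(type_labels)) type_labels <- as.character(seq_len(max(types)))
  w <- site_index(coords, geometry)
  shared <- (w[1] == w[n]) && !all(coords[1, ] == coords[n, ])
  if (validate) {
    steps <- abs(diff(coords))
    if (any(rowSums(steps) != 1))
      stop("consecutive monomers must be lattice nearest neighbours")
    wd <- if (shared) w[-n] else w
    if (anyDuplicated(wd))
      stop("chain is not self-avoiding on wrapped sites")
  }
  structure(list(coords = coords, geometry = geometry, types = types,
                 type_labels = type_labels, shared_ends = shared,
                 seg_id = NULL, seg_min = NULL, seg_max = NULL),
            class = "polymer_chain")
}

#' @export
print.polymer_chain <- function(x, ...) {
  cat("polymer chain: ", n_polymer(x), " occupied sites (",
      nrow(x$coords), " monomers", if (x$shared_ends) ", spanning", ")\n",
      sep = "")
  if (!is.null(x$seg_id))
    cat("segments: ",
        paste(sprintf("%s[%d]", x$type_labels[x$types[!duplicated(x$seg_id)]],
                      tabulate(x$seg_id + 1L)), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Number of occupied lattice sites of a chain
#' @param chain a [polymer_chain()].
#' @export
n_polymer <- function(chain) nrow(chain$coords) - as.integer(chain$shared_ends)

# coordinates of the distinct monomers (drops the terminal image of a
# spanning chain)
occupied_coords <- function(chain) {
  if (chain$shared_ends) chain$coords[-nrow(chain$coords), , drop = FALSE]
  else chain$coords
}

chain_types <- function(chain) chain$types

#' Straight chain spanning the box once in z
#'
#' The production initial condition: endpoints pinned at
#' `(L_x/2, L_y/2, 0)` and its periodic image `(L_x/2, L_y/2, L_z)`, the
#' chain winding once around the z axis.
#'
#' @param geometry a [lattice_geometry()].
#' @return a [polymer_chain()] with `N_p = L_z`.
#' @export
straight_spanning_chain <- function(geometry) {
  d <- geometry$dims
  x0 <- d[1] %/% 2L
  y0 <- d[2] %/% 2L
  polymer_chain(cbind(x0, y0, 0:d[3]), geometry)
}

#' Segment layout for a multi-component polymer
#'
#' Contiguous blocks of monomer types along the contour.  Moves may change
#' the number of monomers in each segment by at most `delta` relative to the
#' nominal count (and a segment never shrinks below one monomer).
#'
#' @param types character vector of block type labels (labels may repeat).
#' @param counts integer vector of nominal monomer counts per block.
#' @param delta allowed deviation per segment (integer >= 0), default 12.
#' @export
segment_spec <- function(types, counts, delta = 12L) {
  counts <- as.integer(counts)
  delta <- as.integer(delta)
  if (length(types) != length(counts)) stop("types and counts must align")
  if (any(counts < 1)) stop("nominal counts must be positive")
  if (delta < 0) stop("delta must be >= 0")
  structure(list(types = as.character(types), counts = counts, delta = delta),
            class = "segment_spec")
}

#' Impose a segment layout on a chain
#'
#' Labels the distinct monomers with contiguous blocks in the order given by
#' the spec.  Realized per-block counts start from the nominal counts and the
#' difference to the current chain length is distributed round-robin across
#' blocks, staying inside every `nominal +/- delta` window; an error is
#' raised when no such split exists.  The terminal image monomer of a
#' spanning chain inherits the first monomer's label.
#'
#' @param chain a [polymer_chain()].
#' @param spec a [segment_spec()].
#' @return the typed chain, with realized counts in attribute
#'   `"realized_counts"`.
#' @export
assign_segments <- function(chain, spec) {
  np <- n_polymer(chain)
  k <- length(spec$counts)
  lo <- pmax(1L, spec$counts - spec$delta)
  hi <- spec$counts + spec$delta
  if (np < sum(lo) || np > sum(hi))
    stop(sprintf("chain length %d cannot satisfy segment windows [%d, %d]",
                 np, sum(lo), sum(hi)))
  realized <- spec$counts
  need <- np - sum(realized)
  step <- if (need > 0) 1L else -1L
  i <- 1L
  guard <- 0L
  while (need != 0L) {
    cand <- realized[i] + step
    if (cand >= lo[i] && cand <= hi[i]) {
      realized[i] <- cand
      need <- need - step
    }
    i <- if (i == k) 1L else i + 1L
    guard <- guard + 1L
    if (guard > 10L * k * (abs(need) + 1L))
      stop("could not distribute monomers across segment windows")
  }
  labels <- unique(spec$types)
  type_ids <- match(spec$types, labels)
  types <- rep.int(type_ids, realized)
  seg <- rep.int(seq_len(k) - 1L, realized)
  if (chain$shared_ends) {
    types <- c(types, types[1])
    seg <- c(seg, seg[1])
  }
  chain$types <- as.integer(types)
  chain$type_labels <- labels
  chain$seg_id <- as.integer(seg)
  chain$seg_min <- lo
  chain$seg_max <- hi
  attr(chain, "realized_counts") <- realized
  chain
}

#' Proposal probabilities for the three polymer move classes
#'
#' The default proposal schedule for bond addition, removal and kink moves:
#' `P_add = (N_p + 2) / (2 (1 + N_p)) (1 - P_kink)`,
#' `P_rem = N_p / (2 (1 + N_p)) (1 - P_kink)`, and `P_kink` held constant.
#' The three probabilities sum to one.  Detailed balance does not rely on
#' any identity between these weights: the engine multiplies the Metropolis
#' ratio by the exact reverse/forward proposal ratio (Hastings factor)
#' computed from this schedule and the bond counts.
#'
#' @param n_p current polymer length (occupied sites), at least 2.
#' @param p_kink kink-move probability in `[0, 1)`.
#' @return named numeric vector `c(add, rem, kink)`.
#' @export
proposal_probabilities <- function(n_p, p_kink = 0.2) {
  if (p_kink < 0 || p_kink >= 1) stop("p_kink must lie in [0, 1)")
  if (n_p < 2) stop("n_p must be at least 2")
  add <- (n_p + 2) / (2 * (1 + n_p)) * (1 - p_kink)
  rem <- n_p / (2 * (1 + n_p)) * (1 - p_kink)
  c(add = add, rem = rem, kink = p_kink)
}

#' Classify a bond-translation move
#'
#' Every polymer move is the translation of one bond in a direction
#' orthogonal to it.  The move class is fully determined by whether the
#' translated bond intersects the two monomers flanking the bond along the
#' contour: neither intersected gives *addition* (two monomers inserted),
#' both gives *removal* (the bond's two monomers deleted), exactly one gives
#' a *kink* that re-threads the corner, relocating one interior monomer.  A
#' missing flank (terminal bond) counts as not intersected, which is why the
#' terminal monomers are never displaced by any move class.
#'
#' @param chain a [polymer_chain()].
#' @param bond_index 0-based bond index in `[0, monomers - 2]`.
#' @param direction unit integer vector orthogonal to the bond.
#' @return a proposal: `list(kind, bond, direction, mover, new_coords,
#'   added, removed)` where `mover`/`removed` are 0-based monomer indices,
#'   `added` holds inserted unwrapped coordinates and `new_coords` the full
#'   chain after the move.
#' @export
classify_move <- function(chain, bond_index, direction) {
  co <- chain$coords
  n <- nrow(co)
  if (bond_index < 0 || bond_index > n - 2) stop("bond index out of range")
  s <- bond_index + 1L # 1-based row of the first bond monomer
  b <- co[s + 1L, ] - co[s, ]
  direction <- as.integer(direction)
  if (sum(abs(direction)) != 1 || sum(b * direction) != 0)
    stop("direction must be a unit vector orthogonal to the bond")
  t1 <- co[s, ] + direction
  t2 <- co[s + 1L, ] + direction
  iL <- s > 1 && all(t1 == co[s - 1L, ])
  iR <- s + 2L <= n && all(t2 == co[s + 2L, ])
  if (iL && iR) {
    new_coords <- co[-c(s, s + 1L), , drop = FALSE]
    list(kind = "removal", bond = bond_index, direction = direction,
         mover = NA_integer_, new_coords = new_coords, added = NULL,
         removed = c(s, s + 1L) - 1L)
  } else if (!iL && !iR) {
    new_coords <- rbind(co[seq_len(s), , drop = FALSE], t1, t2,
                        co[seq.int(s + 1L, n), , drop = FALSE])
    list(kind = "addition", bond = bond_index, direction = direction,
         mover = NA_integer_, new_coords = new_coords, added = rbind(t1, t2),
         removed = NULL)
  } else {
    mover <- if (iL) s else s + 1L
    target <- if (iL) t2 else t1
    new_coords <- co
    new_coords[mover, ] <- target
    list(kind = "kink", bond = bond_index, direction = direction,
         mover = mover - 1L, new_coords = new_coords,
         added = matrix(target, 1), removed = mover - 1L)
  }
}

# the four unit directions orthogonal to a unit bond vector
orthogonal_directions <- function(bond) {
  axes <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L))
  out <- NULL
  for (a in which(bond == 0)) out <- rbind(out, axes[a, ], -axes[a, ])
  out
}

#' Attempt one Metropolis-Hastings polymer move
#'
#' Reference R implementation of a single Monte-Carlo step (the compiled
#' engine repeats the identical procedure in its inner loop): draw a move
#' class from [proposal_probabilities()], a bond and an orthogonal direction
#' uniformly; reject on class/geometry mismatch, self-avoidance violation,
#' the length window `N_p < n_max`, or a segment-window violation; otherwise
#' accept with probability `min(1, H * exp(-dE))` where `H` is the exact
#' reverse/forward proposal ratio.  Uses R's RNG stream.
#'
#' @param chain a [polymer_chain()].
#' @param params a [model_params()].
#' @param bulk optional bulk occupancy for the interaction energy, as in
#'   [lattice_state()] (`gas` matrix or `molecules` list).
#' @return `list(accepted, chain, proposal)`.
#' @export
attempt_polymer_move <- function(chain, params, bulk = NULL) {
  n <- nrow(chain$coords)
  np <- n_polymer(chain)
  probs <- proposal_probabilities(np, params$p_kink)
  cls <- c("addition", "removal", "kink")[
    findInterval(runif(1), cumsum(c(0, probs[1], probs[2]))[-1]) + 1L]
  bond <- sample.int(n - 1L, 1L) - 1L
  b <- chain$coords[bond + 2L, ] - chain$coords[bond + 1L, ]
  dirs <- orthogonal_directions(b)
  prop <- classify_move(chain, bond, dirs[sample.int(4L, 1L), ])
  reject <- list(accepted = FALSE, chain = chain, proposal = prop)
  if (prop$kind != cls) return(reject)

  geometry <- chain$geometry
  occ <- occupancy_vector(chain, geometry)
  if (prop$kind == "addition") {
    if (np + 2 >= params$n_max) return(reject)
    wa <- site_index(prop$added, geometry)
    if (any(occ[wa + 1L] > 0) || wa[1] == wa[2]) return(reject)
  } else if (prop$kind == "kink") {
    wt <- site_index(prop$added, geometry)
    if (occ[wt + 1L] > 0) return(reject)
  }
  newc <- propose_apply(chain, prop)
  if (!is.null(chain$seg_id)) {
    cnt <- tabulate(newc$seg_id[seq_len(nrow(newc$coords) -
                                          as.integer(newc$shared_ends))] + 1L,
                    nbins = length(chain$seg_min))
    if (any(cnt < chain$seg_min) || any(cnt > chain$seg_max)) return(reject)
  }
  st_old <- lattice_state(geometry, chain = chain, gas = bulk$gas,
                          molecules = if (is.null(bulk$molecules)) list()
                                      else bulk$molecules)
  st_new <- lattice_state(geometry, chain = newc, gas = bulk$gas,
                          molecules = if (is.null(bulk$molecules)) list()
                                      else bulk$molecules)
  dE <- (energy_polymer(st_new, params) + energy_interaction(st_new, params)) -
        (energy_polymer(st_old, params) + energy_interaction(st_old, params))
  nb <- n - 1L
  H <- switch(prop$kind,
    addition = {
      pr2 <- proposal_probabilities(np + 2, params$p_kink)
      (pr2[["rem"]] * nb) / (probs[["add"]] * (nb + 2))
    },
    removal = {
      pr2 <- proposal_probabilities(np - 2, params$p_kink)
      (pr2[["add"]] * nb) / (probs[["rem"]] * (nb - 2))
    },
    kink = 1)
  if (runif(1) < min(1, H * exp(-dE)))
    list(accepted = TRUE, chain = newc, proposal = prop)
  else reject
}

# apply a proposal, carrying types/segments along
propose_apply <- function(chain, prop) {
  types <- chain$types
  seg <- chain$seg_id
  if (prop$kind == "addition") {
    s <- prop$bond + 1L
    types <- append(types, types[c(s, s + 1L)], after = s)
    if (!is.null(seg)) seg <- append(seg, seg[c(s, s + 1L)], after = s)
  } else if (prop$kind == "removal") {
    drop <- prop$removed + 1L
    types <- types[-drop]
    if (!is.null(seg)) seg <- seg[-drop]
  }
  out <- polymer_chain(prop$new_coords, chain$geometry, types = types,
                       type_labels = chain$type_labels, validate = FALSE)
  out$seg_id <- seg
  out$seg_min <- chain$seg_min
  out$seg_max <- chain$seg_max
  out
}

# per-site monomer count (length V, 1-based indexing into 0-based site index)
occupancy_vector <- function(chain, geometry) {
  v <- integer(prod(geometry$dims))
  w <- site_index(occupied_coords(chain), geometry)
  v[w + 1L] <- v[w + 1L] + 1L
  if (chain$shared_ends) {
    w1 <- site_index(chain$coords[1, ], geometry)
    v[w1 + 1L] <- 2L
  }
  v
}
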