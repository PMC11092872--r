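#' Periodic cubic lattice geometry
#'
#' Defines a periodic three-dimensional lattice with 0-based integer site
#' coordinates `(x, y, z)`, `0 <= x < L_x` etc.  All engines, observables and
#' oracles share this geometry and its conventions: neighbours are enumerated
#' in the fixed axis order `+x, -x, +y, -y, +z, -z`, and nearest-neighbour
#' pair sums count `(site, +axis)` pairs once, so that on a periodic
#' dimension of length 2 the doubled edge is counted twice.
#'
#' @param dims integer vector of length 3 (or a single integer for a cube),
#'   every dimension at least 2.
#' @return an object of class `lattice_geometry`.
#' @examples
#' g <- lattice_geometry(c(4, 4, 4))
#' neighbors(c(0, 0, 0), g)
#' @export
lattice_geometry <- function(dims) {
  if (length(dims) == 1) dims <- rep(dims, 3)
  if (length(dims) != 3) stop("dims must have length 3")
  dims <- as.integer(dims)
  if (anyNA(dims) || any(dims < 2)) stop("all lattice dimensions must be >= 2")
  structure(list(dims = dims), class = "lattice_geometry")
}

#' @export
print.lattice_geometry <- function(x, ...) {
  cat("periodic lattice ", paste(x$dims, collapse = " x "),
      " (", prod(x$dims), " sites)\n", sep = "")
  invisible(x)
}

#' Wrap coordinates into the periodic box
#'
#' @param site an integer vector of length 3 or an n x 3 matrix of
#'   (possibly unwrapped) coordinates.
#' @param geometry a [lattice_geometry()].
#' @return wrapped coordinates with the same shape as `site`.
#' @export
wrap_site <- function(site, geometry) {
  d <- geometry$dims
  if (is.matrix(site)) {
    cbind(site[, 1] %% d[1], site[, 2] %% d[2], site[, 3] %% d[3])
  } else {
    c(site[1] %% d[1], site[2] %% d[2], site[3] %% d[3])
  }
}

# 0-based linear index of (wrapped) coordinates; inverse below.  These are the
# indices understood by the compiled kernels.
site_index <- function(site, geometry) {
  d <- geometry$dims
  w <- wrap_site(site, geometry)
  if (is.matrix(w)) {
    as.integer(w[, 1] + d[1] * (w[, 2] + d[2] * w[, 3]))
  } else {
    as.integer(w[1] + d[1] * (w[2] + d[2] * w[3]))
  }
}

site_coords <- function(idx, geometry) {
  d <- geometry$dims
  idx <- as.integer(idx)
  x <- idx %% d[1]
  y <- (idx %/% d[1]) %% d[2]
  z <- idx %/% (d[1] * d[2])
  cbind(x = x, y = y, z = z)
}

#' Periodic nearest neighbours of a site
#'
#' Returns the six periodic nearest neighbours in the fixed axis order
#' `+x, -x, +y, -y, +z, -z`.  When every dimension is at least 3 the six
#' sites are distinct; on a dimension of length 2 the two neighbours along
#' that axis coincide (the doubled edge of the periodic graph).
#'
#' @param site integer vector of length 3, already inside the box.
#' @param geometry a [lattice_geometry()].
#' @return a 6 x 3 integer matrix, one neighbour per row.
#' @export
neighbors <- function(site, geometry) {
  d <- geometry$dims
  site <- as.integer(site)
  if (length(site) != 3 || anyNA(site) || any(site < 0) || any(site >= d))
    stop("site out of range for this geometry")
  steps <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                 c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  wrap_site(sweep(steps, 2, site, "+"), geometry)
}

#' Rebuild occupancy fields from chains and molecules
#'
#' Reconstructs the per-site spin fields from scratch: `s_p`, the polymer
#' occupancy (stored as the 1-based monomer type id, 0 when empty, so the sum
#' of per-type indicators is automatically 0/1 and self-avoidance is
#' explicit), and `s_1`, `s_2`, the two bulk-species indicators.  Molecules of
#' different species may share a site; a polymer monomer may share a site
#' with either bulk species.  Polymer-polymer or same-species bulk collisions
#' are invalid states and raise an error naming the offending site.
#'
#' @param chains a [polymer_chain()] or list of them.
#' @param molecules list of bulk molecules, each `list(species =, sites =)`
#'   with `sites` an N_b x 3 coordinate matrix.
#' @param geometry a [lattice_geometry()].
#' @param gas optional m x 3 matrix of occupied minimal-bulk sites, treated
#'   as species 1.
#' @return `list(s_p, s_1, s_2)` of 3-d arrays with dim = `geometry$dims`.
#' @export
rebuild_fields <- function(chains, molecules = list(), geometry, gas = NULL) {
  d <- geometry$dims
  s_p <- array(0L, dim = d)
  s_1 <- array(0L, dim = d)
  s_2 <- array(0L, dim = d)
  if (inherits(chains, "polymer_chain")) chains <- list(chains)
  fail <- function(what, coord) {
    stop(sprintf("%s collision at site (%d, %d, %d)", what,
                 coord[1], coord[2], coord[3]))
  }
  for (ch in chains) {
    w <- wrap_site(occupied_coords(ch), geometry)
    tp <- chain_types(ch)[seq_len(nrow(w))]
    for (i in seq_len(nrow(w))) {
      k <- w[i, , drop = TRUE] + 1L
      if (s_p[k[1], k[2], k[3]] != 0L) fail("polymer-polymer", w[i, ])
      s_p[k[1], k[2], k[3]] <- tp[i]
    }
  }
  place_bulk <- function(field, sites, what) {
    w <- wrap_site(sites, geometry)
    for (i in seq_len(nrow(w))) {
      k <- w[i, , drop = TRUE] + 1L
      if (field[k[1], k[2], k[3]] != 0L) fail(what, w[i, ])
      field[k[1], k[2], k[3]] <- 1L
    }
    field
  }
  for (m in molecules) {
    if (m$species == 1) s_1 <- place_bulk(s_1, m$sites, "same-species bulk")
    else s_2 <- place_bulk(s_2, m$sites, "same-species bulk")
  }
  if (!is.null(gas) && nrow(gas) > 0)
    s_1 <- place_bulk(s_1, gas, "same-species bulk")
  list(s_p = s_p, s_1 = s_1, s_2 = s_2)
}
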