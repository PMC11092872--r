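#' Unwrap a wrapped chain along its contour
#'
#' Rebuilds unwrapped coordinates monomer by monomer: the first monomer is
#' taken as-is and each bond contributes its minimal-image displacement.
#' Chains produced by this package are already unwrapped; this is needed when
#' coordinates have been reduced to the primary box (e.g. re-read from a
#' trajectory written with wrapped coordinates).
#'
#' @param coords n x 3 integer matrix of monomer coordinates.
#' @param geometry a [lattice_geometry()].
#' @return an n x 3 matrix of unwrapped coordinates.
#' @export
unwrap_chain <- function(coords, geometry) {
  d <- geometry$dims
  out <- coords
  for (i in seq_len(nrow(coords))[-1]) {
    step <- coords[i, ] - coords[i - 1L, ]
    step <- step - round(step / d) * d # minimal image, |step| = 1 per bond
    out[i, ] <- out[i - 1L, ] + step
  }
  out
}

#' Radius of gyration
#'
#' `R_g^2 = (1/N_p) sum_i |r_i - r_cm|^2` over the distinct monomers, using
#' unwrapped coordinates (a box-spanning chain would otherwise get a
#' corrupted centre of mass from wrapped positions).
#'
#' @param chain a [polymer_chain()] or an n x 3 unwrapped coordinate matrix.
#' @return `R_g` in lattice units.
#' @export
radius_of_gyration <- function(chain) {
  co <- if (inherits(chain, "polymer_chain")) occupied_coords(chain) else chain
  cm <- colMeans(co)
  sqrt(sum(sweep(co, 2, cm)^2) / nrow(co))
}

#' Bulk density difference between on-polymer and far-field sites
#'
#' The order parameter of the coupled transition: the bulk-monomer density
#' (site fraction of `s_1 + s_2`, or of the lattice-gas occupancy) within
#' Chebyshev distance `shell_radius` of any polymer monomer, minus the
#' density over all remaining sites.
#'
#' @param state a [lattice_state()] with a chain and a bulk.
#' @param shell_radius Chebyshev shell radius (default 0: the polymer's own
#'   sites).
#' @return `delta_rho_b`.
#' @export
bulk_density_difference <- function(state, shell_radius = 0) {
  geometry <- state$geometry
  V <- prod(geometry$dims)
  ind <- bulk_indicators(state)
  dens <- ind$s1 + ind$s2
  on <- logical(V)
  w <- site_index(occupied_coords(state$chain), geometry)
  if (shell_radius == 0) {
    on[w + 1L] <- TRUE
  } else {
    offs <- as.matrix(expand.grid(x = -shell_radius:shell_radius,
                                  y = -shell_radius:shell_radius,
                                  z = -shell_radius:shell_radius))
    co <- occupied_coords(state$chain)
    for (i in seq_len(nrow(offs))) {
      shifted <- sweep(co, 2, offs[i, ], "+")
      on[site_index(shifted, geometry) + 1L] <- TRUE
    }
  }
  if (all(on)) stop("far-field region is empty; delta_rho_b undefined")
  sum(dens[on]) / sum(on) - sum(dens[!on]) / sum(!on)
}

#' Bulk occupancy along the polymer contour
#'
#' For each relative contour position (binned, since `N_p` fluctuates), the
#' fraction of frames in which the monomer's site is co-occupied by bulk
#' species 1, and separately species 2.  Per-type averages are attached as
#' attribute `"by_type"`.
#'
#' @param frames trajectory frames of a `prewet_run` (collected with
#'   `collect_frames = TRUE`).
#' @param geometry the run's [lattice_geometry()].
#' @param nbins number of contour bins (default 50).
#' @return data.frame with `bin`, `position` (relative contour position at
#'   the bin centre), `occ1`, `occ2`.
#' @export
occupancy_profile <- function(frames, geometry, nbins = 50) {
  if (!length(frames)) stop("need at least one frame")
  acc1 <- numeric(nbins)
  acc2 <- numeric(nbins)
  cnt <- numeric(nbins)
  types_seen <- integer(0)
  t1 <- t2 <- tc <- NULL
  for (f in frames) {
    n <- nrow(f$chain)
    shared <- identical(site_index(f$chain[1, ], geometry),
                        site_index(f$chain[n, ], geometry)) &&
      !all(f$chain[1, ] == f$chain[n, ])
    np <- n - as.integer(shared)
    co <- f$chain[seq_len(np), , drop = FALSE]
    w <- site_index(co, geometry) + 1L
    V <- prod(geometry$dims)
    s1 <- integer(V)
    s2 <- integer(V)
    if (nrow(f$bulk1)) s1[site_index(f$bulk1, geometry) + 1L] <- 1L
    if (nrow(f$bulk2)) s2[site_index(f$bulk2, geometry) + 1L] <- 1L
    bin <- pmin(nbins, 1L + floor((seq_len(np) - 1L) / np * nbins))
    acc1 <- acc1 + tapply(s1[w], factor(bin, levels = seq_len(nbins)), sum,
                          default = 0)
    acc2 <- acc2 + tapply(s2[w], factor(bin, levels = seq_len(nbins)), sum,
                          default = 0)
    cnt <- cnt + tabulate(bin, nbins)
    tp <- f$types[seq_len(np)]
    k <- max(tp)
    if (is.null(t1)) { t1 <- numeric(k); t2 <- numeric(k); tc <- numeric(k) }
    t1 <- t1 + tapply(s1[w], factor(tp, levels = seq_len(k)), sum, default = 0)
    t2 <- t2 + tapply(s2[w], factor(tp, levels = seq_len(k)), sum, default = 0)
    tc <- tc + tabulate(tp, k)
  }
  out <- data.frame(bin = seq_len(nbins),
                    position = (seq_len(nbins) - 0.5) / nbins,
                    occ1 = ifelse(cnt > 0, acc1 / cnt, NA),
                    occ2 = ifelse(cnt > 0, acc2 / cnt, NA))
  attr(out, "by_type") <- data.frame(type = seq_along(tc),
                                     occ1 = ifelse(tc > 0, t1 / tc, NA),
                                     occ2 = ifelse(tc > 0, t2 / tc, NA))
  out
}

#' Monomer contact probability map
#'
#' Symmetric matrix over contour bins whose entry `(i, j)` is the
#' probability that a monomer in bin `i` and one in bin `j` occupy lattice
#' nearest-neighbour sites, averaged over frames (pairs in the same or
#' adjacent bins include the trivial bonded contacts).  Monomers are mapped
#' to bins by relative contour position so frames with fluctuating `N_p`
#' align.
#'
#' @param frames trajectory frames.
#' @param geometry the run's [lattice_geometry()].
#' @param nbins number of contour bins (default 50, at most 200).
#' @return an `nbins` x `nbins` matrix of probabilities in `[0, 1]`.
#' @export
contact_map <- function(frames, geometry, nbins = 50) {
  if (nbins < 1) stop("nbins must be at least 1")
  if (nbins > 200) stop("use at most 200 contour bins")
  if (!length(frames)) stop("need at least one frame")
  num <- matrix(0, nbins, nbins)
  den <- matrix(0, nbins, nbins)
  for (f in frames) {
    n <- nrow(f$chain)
    shared <- identical(site_index(f$chain[1, ], geometry),
                        site_index(f$chain[n, ], geometry)) &&
      !all(f$chain[1, ] == f$chain[n, ])
    np <- n - as.integer(shared)
    co <- f$chain[seq_len(np), , drop = FALSE]
    w <- site_index(co, geometry)
    idx_of <- integer(prod(geometry$dims))
    idx_of[w + 1L] <- seq_len(np)
    bin <- pmin(nbins, 1L + floor((seq_len(np) - 1L) / np * nbins))
    cnt <- tabulate(bin, nbins)
    # unordered contacts: each found once via the +axis neighbour of a site
    for (a in 1:3) {
      step <- c(0L, 0L, 0L)
      step[a] <- 1L
      wn <- site_index(sweep(co, 2, step, "+"), geometry)
      hit <- idx_of[wn + 1L]
      for (s in which(hit > 0)) {
        bi <- min(bin[s], bin[hit[s]])
        bj <- max(bin[s], bin[hit[s]])
        num[bi, bj] <- num[bi, bj] + 1
      }
    }
    # unordered monomer pairs per bin block
    blk <- outer(cnt, cnt)
    diag(blk) <- cnt * (cnt - 1) / 2
    blk[lower.tri(blk)] <- 0
    den <- den + blk
  }
  p <- ifelse(den > 0, num / den, 0)
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  p
}
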