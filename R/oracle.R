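#' Exact enumeration of pinned self-avoiding walks
#'
#' Depth-first enumeration of every self-avoiding nearest-neighbour walk
#' between two pinned endpoints with length `N_p < n_max`, Boltzmann-weighted
#' under the polymer Hamiltonian, giving the exact partition function and
#' averages against which the Monte-Carlo sampler is validated.  The walk is
#' enumerated in *unwrapped* coordinates with self-avoidance on wrapped
#' sites, so exactly the fixed-winding sector sampled by the engine is
#' counted (bond-translation moves conserve the winding of the chain around
#' the periodic box).  The endpoint may be given outside the primary box: a
#' target that is the periodic image of the start describes the spanning
#' chain, whose terminal monomers share one wrapped site (`N_p = monomers -
#' 1`), exactly as in the engine.
#'
#' @param geometry a [lattice_geometry()].
#' @param start integer site, inside the box.
#' @param end integer endpoint in unwrapped coordinates (may lie outside the
#'   box to select a winding sector).
#' @param n_max exclusive length bound.
#' @param params a [model_params()] (only `mu_p`, `v_p` enter).
#' @param cap abort if more than this many states are visited (default 1e7).
#' @return an `enumeration_result`: `n_states`, `Z`, `mean_energy`,
#'   `mean_contacts`, `mean_n_p`.
#' @export
enumerate_pinned_walks <- function(geometry, start, end, n_max, params,
                                   cap = 1e7) {
  res <- cpp_enumerate_walks(geometry$dims, as.integer(start),
                             as.integer(end), as.integer(n_max),
                             params$mu_p, params$v_p, cap)
  structure(res, class = "enumeration_result")
}

#' Exact enumeration of the minimal lattice gas
#'
#' Sums all `2^V` occupancy states of the lattice-gas Hamiltonian
#' `-mu_b sum s_i - j_bulk sum_<ij> s_i s_j`, plus the on-site polymer
#' coupling when a chain is supplied; limited to lattices of at most 24
#' sites.  Shares the engine's pair-counting convention, so Monte-Carlo
#' versus enumeration discrepancies isolate sampler bugs rather than energy
#' bugs.
#'
#' @param geometry a [lattice_geometry()] with at most 24 sites.
#' @param params a [model_params()].
#' @param chain optional [polymer_chain()] providing the coupling sites.
#' @return an `enumeration_result`: `n_states`, `Z`, `mean_n`,
#'   `mean_occupancy` (per site), `mean_energy`.
#' @export
enumerate_lattice_gas <- function(geometry, params, chain = NULL) {
  if (prod(geometry$dims) > 24)
    stop("lattice-gas enumeration limited to 24 sites")
  sites <- integer(0)
  jint <- numeric(0)
  if (!is.null(chain)) {
    sites <- site_index(occupied_coords(chain), geometry)
    tp <- chain_types(chain)[seq_along(sites)]
    j <- params$j_int
    jint <- ifelse(tp >= 1 & tp <= length(j), j[pmax(tp, 1)], 0)
  }
  res <- cpp_enumerate_gas(geometry$dims, params$mu_b, params$j_bulk,
                           as.integer(sites), as.numeric(jint))
  structure(res, class = "enumeration_result")
}

#' @export
print.enumeration_result <- function(x, ...) {
  cat("exact enumeration:", format(x$n_states, big.mark = ","), "states, Z =",
      signif(x$Z, 6), "\n")
  for (f in intersect(c("mean_energy", "mean_contacts", "mean_n_p", "mean_n",
                        "mean_occupancy"), names(x)))
    cat(sprintf("  %s = %.6g\n", f, x[[f]]))
  invisible(x)
}

#' Batch-means standard error of a Monte-Carlo series
#'
#' Autocorrelation-aware standard error of the mean: the series is cut into
#' `n_batch` contiguous batches and the standard error of the batch means is
#' returned.  Used for the "within 3 standard errors" sampler-vs-oracle
#' comparisons.
#'
#' @param x numeric series of measurements.
#' @param n_batch number of batches (default 50).
#' @export
batch_se <- function(x, n_batch = 50) {
  n <- length(x)
  if (n < 2 * n_batch) n_batch <- max(2, n %/% 2)
  size <- n %/% n_batch
  means <- vapply(seq_len(n_batch), function(b)
    mean(x[((b - 1) * size + 1):(b * size)]), numeric(1))
  stats::sd(means) / sqrt(n_batch)
}
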