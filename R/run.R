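# Drivers for the compiled Monte-Carlo engine.  One Monte-Carlo sweep is
# N_p attempted polymer moves, plus (minimal mode) one attempted spin flip
# per lattice site, or (full mode) one kink-or-reptation attempt per bulk
# monomer and one reservoir-exchange attempt.

params_for_engine <- function(params, chain) {
  ntypes <- max(chain$types)
  j <- params$j_int
  if (length(j) < ntypes) j <- c(j, rep(0, ntypes - length(j)))
  list(mu_p = params$mu_p, v_p = params$v_p, p_kink = params$p_kink,
       n_max = params$n_max, mu_b = params$mu_b, j_bulk = params$j_bulk,
       j_nn = params$j_nn, j_int = j, n_b = params$n_b)
}

seg_args <- function(chain) {
  if (is.null(chain$seg_id))
    list(id = integer(0), min = integer(0), max = integer(0))
  else
    list(id = as.integer(chain$seg_id), min = as.integer(chain$seg_min),
         max = as.integer(chain$seg_max))
}

run_engine <- function(mode, geometry, chain, params, sweeps, equil,
                       meas_every, seed, collect_frames, gas_init,
                       molecules_init, n_reservoir) {
  stopifnot(inherits(chain, "polymer_chain"), inherits(params, "model_params"))
  if (params$n_max <= geometry$dims[3] && chain$shared_ends)
    stop("n_max must exceed the spanned lattice dimension")
  gi <- if (is.null(gas_init) || nrow(gas_init) == 0) integer(0)
        else site_index(gas_init, geometry)
  mi <- lapply(molecules_init, function(m)
    list(species = as.integer(m$species),
         sites = site_index(m$sites, geometry)))
  sg <- seg_args(chain)
  res <- cpp_run(geometry$dims, chain$coords, as.integer(chain$types),
                 sg$id, sg$min, sg$max, params_for_engine(params, chain),
                 switch(mode, polymer = 0L, minimal = 1L, full = 2L),
                 as.integer(gi), mi, as.numeric(n_reservoir),
                 as.integer(sweeps), as.integer(equil),
                 as.integer(meas_every), collect_frames, as.numeric(seed))
  obs <- as.data.frame(res$obs)
  obs$delta_rho_b <- obs$dens_on - obs$dens_off
  obs$rho <- obs$n_p / obs$rg^3
  labels <- chain$type_labels
  occ1 <- res$occ1
  occ2 <- res$occ2
  colnames(occ1) <- paste0("occ1_", labels[seq_len(ncol(occ1))])
  colnames(occ2) <- paste0("occ2_", labels[seq_len(ncol(occ2))])
  obs <- cbind(obs, occ1, occ2)
  frames <- lapply(res$frames, function(f) {
    list(sweep = f$sweep, chain = f$chain, types = f$types,
         bulk1 = site_coords(f$bulk1, geometry),
         bulk2 = site_coords(f$bulk2, geometry))
  })
  final_chain <- polymer_chain(res$final$chain, geometry,
                               types = res$final$types,
                               type_labels = chain$type_labels,
                               validate = FALSE)
  if (!is.null(chain$seg_id)) {
    # segment ids follow the monomers through the run
    final_chain$seg_id <- res$final$seg
    final_chain$seg_min <- chain$seg_min
    final_chain$seg_max <- chain$seg_max
  }
  final <- list(chain = final_chain,
                gas = if (length(res$final$gas))
                        site_coords(res$final$gas, geometry) else NULL,
                molecules = lapply(res$final$molecules, function(m)
                  list(species = m$species,
                       sites = site_coords(m$sites, geometry))),
                n_reservoir = res$final$n_reservoir,
                seg_counts = res$final$seg_counts)
  acc <- res$accept
  acceptance <- data.frame(
    move = c("addition", "removal", "kink", "bulk_flip", "bulk_kink",
             "reptation", "exchange"),
    attempts = c(acc$poly_att, acc$flip_att, acc$bulk_att),
    accepted = c(acc$poly_acc, acc$flip_acc, acc$bulk_acc))
  acceptance$rate <- ifelse(acceptance$attempts > 0,
                            acceptance$accepted / acceptance$attempts, NA)
  structure(list(mode = mode, observables = obs, frames = frames,
                 final = final, acceptance = acceptance, geometry = geometry,
                 params = params, seed = seed,
                 schedule = list(sweeps = sweeps, equil = equil,
                                 meas_every = meas_every)),
            class = "prewet_run")
}

#' Simulate an isolated polymer
#'
#' Monte-Carlo run of the single pinned polymer with no bulk.
#'
#' @param geometry a [lattice_geometry()].
#' @param chain initial [polymer_chain()] (e.g.
#'   [straight_spanning_chain()]).
#' @param params a [model_params()].
#' @param sweeps measured sweeps after equilibration.
#' @param equil discarded equilibration sweeps.
#' @param meas_every measurement cadence in sweeps.
#' @param seed integer RNG seed (single seeded stream per run).
#' @param collect_frames store trajectory frames for later analysis.
#' @return a `prewet_run` with `$observables` (one row per measurement:
#'   sweep, N_p, R_g, rho, contacts, energies, acceptance summaries in
#'   `$acceptance`), `$frames` and `$final`.
#' @export
run_polymer <- function(geometry, chain, params, sweeps, equil = 0,
                        meas_every = 1, seed = 1, collect_frames = FALSE) {
  run_engine("polymer", geometry, chain, params, sweeps, equil, meas_every,
             seed, collect_frames, NULL, list(), 0)
}

#' Simulate the polymer coupled to a minimal lattice-gas bulk
#'
#' The bulk is a single species of monomeric particles with occupancy
#' `s_i`, energy `-mu_b sum s_i - j_bulk sum_<ij> s_i s_j`, updated by
#' Metropolis spin flips; it couples to the polymer through `j_int` at
#' shared sites.
#'
#' @inheritParams run_polymer
#' @param gas_init optional m x 3 matrix of initially occupied bulk sites
#'   (default empty); pass the `$final$gas` of a previous run to continue a
#'   scan.
#' @export
run_minimal <- function(geometry, chain, params, sweeps, equil = 0,
                        meas_every = 1, seed = 1, collect_frames = FALSE,
                        gas_init = NULL) {
  run_engine("minimal", geometry, chain, params, sweeps, equil, meas_every,
             seed, collect_frames, gas_init, list(), 0)
}

#' Simulate the polymer coupled to the two-species molecular bulk
#'
#' Bulk molecules are self-avoiding chains of length `n_b` (same-species
#' excluded volume; different species may share sites, gaining `-j_bulk`
#' per shared site), updated by kink and reptation moves and exchanged with
#' a reservoir of `n_reservoir` ideal molecules at rates
#' `lambda+ = N_r / (N_r + N_s + 1)`, `lambda- = (N_s + 1) / (N_r + N_s + 1)`.
#' Species 1 binds the polymer with `j_int` per monomer type.
#'
#' @inheritParams run_polymer
#' @param molecules_init list of initial molecules
#'   (`list(species =, sites =)`); default empty.
#' @param n_reservoir initial reservoir molecule count.
#' @export
run_full <- function(geometry, chain, params, sweeps, equil = 0,
                     meas_every = 1, seed = 1, collect_frames = FALSE,
                     molecules_init = list(), n_reservoir = 0) {
  run_engine("full", geometry, chain, params, sweeps, equil, meas_every,
             seed, collect_frames, NULL, molecules_init, n_reservoir)
}

#' @export
print.prewet_run <- function(x, ...) {
  o <- x$observables
  cat(sprintf("prewet_run (%s mode): %d measurements over %d sweeps\n",
              x$mode, nrow(o), x$schedule$sweeps))
  cat(sprintf("  <N_p> = %.1f  <R_g> = %.2f  <delta_rho_b> = %.3f\n",
              mean(o$n_p), mean(o$rg),
              mean(o$delta_rho_b, na.rm = TRUE)))
  invisible(x)
}

#' Scan a parameter with state carried between points
#'
#' Runs the requested engine at each parameter value in order, starting each
#' point from the final configuration of the previous one (a quasi-static
#' scan, the standard protocol for tracing hysteresis across a first-order
#' transition).
#'
#' @param mode `"minimal"` or `"full"`.
#' @param geometry,chain,params,sweeps,equil,meas_every,seed as in
#'   [run_minimal()].
#' @param axis name of the `model_params` field to scan (e.g. `"mu_b"`).
#' @param values numeric vector of parameter values, in scan order.
#' @param ... passed to the runner (e.g. `n_reservoir`).
#' @return list with `$summary` (one row per value: means of the key
#'   observables) and `$runs` (the individual `prewet_run`s).
#' @export
run_scan <- function(mode, geometry, chain, params, axis, values, sweeps,
                     equil = 0, meas_every = 1, seed = 1, ...) {
  runs <- vector("list", length(values))
  gas <- NULL
  mols <- list()
  nres <- list(...)$n_reservoir
  cur_chain <- chain
  for (i in seq_along(values)) {
    params[[axis]] <- values[i]
    if (mode == "minimal") {
      runs[[i]] <- run_minimal(geometry, cur_chain, params, sweeps, equil,
                               meas_every, seed = seed + i,
                               collect_frames = FALSE, gas_init = gas)
      gas <- runs[[i]]$final$gas
    } else {
      runs[[i]] <- run_full(geometry, cur_chain, params, sweeps, equil,
                            meas_every, seed = seed + i,
                            molecules_init = mols,
                            n_reservoir = if (i == 1) nres
                                          else runs[[i - 1]]$final$n_reservoir)
      mols <- runs[[i]]$final$molecules
    }
    cur_chain <- runs[[i]]$final$chain
  }
  summary <- do.call(rbind, lapply(seq_along(values), function(i) {
    o <- runs[[i]]$observables
    data.frame(value = values[i], n_p = mean(o$n_p), rg = mean(o$rg),
               delta_rho_b = mean(o$delta_rho_b, na.rm = TRUE),
               dens_on = mean(o$dens_on, na.rm = TRUE),
               dens_off = mean(o$dens_off, na.rm = TRUE),
               bulk_total = mean(o$bulk_total))
  }))
  names(summary)[1] <- axis
  list(summary = summary, runs = runs)
}
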