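#' Mean-field parameters for the coupled polymer/bulk free energy
#'
#' The variational theory works with two order parameters: the polymer's
#' radius of gyration `R_g` (equivalently the monomer density
#' `rho = N_p a^3 / R_g^3`) and the local bulk order parameter `phi` inside
#' the polymer volume.  Far from the polymer the bulk sits at `phi_inf`, the
#' global minimizer of the bulk free-energy density.
#'
#' @param n_p monomer count (the large-`N_p` limit is `1e6` in the scans).
#' @param a monomer length (default 1; all lengths in units of `a`).
#' @param v_p excluded-volume parameter (positive = repulsive).
#' @param t_b reduced temperature of the bulk; `t_b < 0` is subcritical
#'   (double-well bulk).
#' @param u quartic stabilizing coefficient, strictly positive.
#' @param mu_b bulk chemical potential (field conjugate to `phi`).
#' @param h per-monomer polymer-bulk binding; the mean-field analogue of the
#'   lattice `j_int`.
#' @return an object of class `mean_field_params`.
#' @export
mean_field_params <- function(n_p = 1e6, a = 1, v_p = 0, t_b = 1, u = 6,
                              mu_b = 0, h = 0) {
  if (u <= 0) stop("u must be > 0 (stability)")
  if (n_p < 1 || a <= 0) stop("need n_p >= 1 and a > 0")
  structure(list(n_p = n_p, a = a, v_p = v_p, t_b = t_b, u = u,
                 mu_b = mu_b, h = h), class = "mean_field_params")
}

#' Isolated-polymer free energy
#'
#' `F0_poly(R_g) = (3/2) x - log x + (v_p/2) N_p^2 a^3 / R_g^3 +
#'  (1/6) N_p^3 a^6 / R_g^6` with `x = R_g^2 / (N_p a^2)`: Gaussian
#' entropic elasticity plus two- and three-body mean-field interactions.
#'
#' @param rg radius of gyration (> 0), vectorized.
#' @param params a [mean_field_params()].
#' @export
f_poly0 <- function(rg, params) {
  x <- rg^2 / (params$n_p * params$a^2)
  rho <- params$n_p * params$a^3 / rg^3
  1.5 * x - log(x) +
    (params$v_p / 2) * params$n_p * rho + (1 / 6) * params$n_p * rho^2
}

# F0_poly as a function of density rho = N_p a^3 / R_g^3
f_poly0_rho <- function(rho, params) {
  rg <- (params$n_p * params$a^3 / rho)^(1 / 3)
  f_poly0(rg, params)
}

#' Minimize the isolated-polymer free energy
#'
#' One-dimensional minimization of [f_poly0()] over `log rho`, multi-start
#' across a wide density bracket so both the extended (`rho -> 0` as
#' `N_p -> inf`) and the collapsed (`rho` finite) minima are found.
#'
#' @param params a [mean_field_params()].
#' @param rho_range density search bracket.
#' @return `list(rho, rg, value)` at the global minimum.
#' @export
minimize_fpoly <- function(params, rho_range = c(1e-12, 3)) {
  lo <- log(rho_range[1])
  hi <- log(rho_range[2])
  cuts <- seq(lo, hi, length.out = 13)
  best <- NULL
  for (i in seq_len(length(cuts) - 1)) {
    op <- optimize(function(lr) f_poly0_rho(exp(lr), params),
                   lower = cuts[i], upper = cuts[i + 1], tol = 1e-10)
    if (is.null(best) || op$objective < best$objective) best <- op
  }
  rho <- exp(best$minimum)
  list(rho = rho, rg = (params$n_p * params$a^3 / rho)^(1 / 3),
       value = best$objective)
}

#' Landau free-energy density of the bulk
#'
#' `f_bulk(phi) = (t_b/2) phi^2 + (u/24) phi^4 - mu_b phi`.
#'
#' @param phi order parameter, vectorized.
#' @param params a [mean_field_params()].
#' @export
f_bulk <- function(phi, params) {
  params$t_b / 2 * phi^2 + params$u / 24 * phi^4 - params$mu_b * phi
}

# real critical points of f_bulk, sorted increasing
f_bulk_critical <- function(params) {
  r <- polyroot(c(-params$mu_b, params$t_b, 0, params$u / 6))
  re <- Re(r[abs(Im(r)) < 1e-8 * (1 + abs(r))])
  sort(unique(round(re, 12)))
}

#' Local minima of the bulk free energy
#'
#' @param params a [mean_field_params()].
#' @return data.frame with `phi`, `f`, `curvature` for each local minimum
#'   (one row in the supercritical single-well regime, two when the well is
#'   doubled), sorted by `phi`.
#' @export
f_bulk_minima <- function(params) {
  cp <- f_bulk_critical(params)
  curv <- params$t_b + params$u / 2 * cp^2
  keep <- curv > 0
  data.frame(phi = cp[keep], f = f_bulk(cp[keep], params),
             curvature = curv[keep])
}

#' Global minimizer of the bulk free energy
#'
#' Exact ties (e.g. the symmetric double well at `mu_b = 0`) are broken
#' toward the lower-`phi` branch for determinism; the tie is reported in
#' attribute `"tie"`.
#'
#' @param params a [mean_field_params()].
#' @return `phi_inf`, the minimizing order parameter.
#' @export
phi_inf <- function(params) {
  m <- f_bulk_minima(params)
  fmin <- min(m$f)
  cand <- m$phi[m$f <= fmin + 1e-12 * (1 + abs(fmin))]
  out <- min(cand)
  attr(out, "tie") <- length(cand) > 1
  out
}

#' Coupled free energy of polymer plus local bulk
#'
#' `F_sys(R_g, phi) = F0_poly(R_g) - h phi N_p + R_g^3 Delta_f_bulk(phi)`
#' with `Delta_f_bulk(phi) = f_bulk(phi) - f_bulk(phi_inf)`, so the
#' polymer-free bulk contribution is subtracted off and
#' `Delta_f_bulk(phi_inf) = 0` by construction.
#'
#' @param rg radius of gyration.
#' @param phi local bulk order parameter.
#' @param params a [mean_field_params()].
#' @export
f_sys <- function(rg, phi, params) {
  dfb <- f_bulk(phi, params) - f_bulk(as.numeric(phi_inf(params)), params)
  f_poly0(rg, params) - params$h * phi * params$n_p + rg^3 * dfb
}

# f_sys in (rho, phi); phi_ref = f_bulk(phi_inf) precomputed by callers
f_sys_rho <- function(rho, phi, params, f_ref) {
  rg3 <- params$n_p * params$a^3 / rho
  f_poly0_rho(rho, params) - params$h * phi * params$n_p +
    rg3 * (f_bulk(phi, params) - f_ref)
}

#' Minimize the coupled free energy over both order parameters
#'
#' Multi-start local descent (Nelder-Mead in `(log rho, phi)`, so
#' `R_g > 0` is implicit) from a grid of starting points: densities
#' log-spaced across `rho_range` and `phi` spanning the bulk minima
#' widened by one unit.  Converged minima are deduplicated and sorted by
#' free energy, global minimum first.
#'
#' @param params a [mean_field_params()].
#' @param rho_range density bracket for the start grid (default
#'   `c(1e-4, 3)`).
#' @param n_starts grid points per axis (default 12).
#' @return data.frame of local minima: `rho`, `phi`, `rg`, `f_sys`.
#' @export
minimize_fsys <- function(params, rho_range = c(1e-4, 3), n_starts = 12) {
  f_ref <- f_bulk(phi_inf(params), params)
  bm <- f_bulk_minima(params)
  phis <- seq(min(bm$phi) - 1, max(bm$phi) + 1, length.out = n_starts)
  lrhos <- seq(log(rho_range[1]), log(rho_range[2]), length.out = n_starts)
  obj <- function(p) f_sys_rho(exp(p[1]), p[2], params, f_ref)
  found <- list()
  for (lr in lrhos) for (ph in phis) {
    op <- optim(c(lr, ph), obj, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 2000))
    op2 <- optim(op$par, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 2000))
    found[[length(found) + 1]] <- c(op2$par, op2$value)
  }
  m <- do.call(rbind, found)
  res <- data.frame(rho = exp(m[, 1]), phi = m[, 2], f = m[, 3])
  res <- res[is.finite(res$f), ]
  res <- res[order(res$f), ]
  keep <- rep(TRUE, nrow(res))
  for (i in seq_len(nrow(res))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (abs(log(res$rho[i] / res$rho[j])) < 0.05 &&
          abs(res$phi[i] - res$phi[j]) < 0.02) {
        keep[i] <- FALSE
        break
      }
    }
  }
  res <- res[keep, , drop = FALSE]
  data.frame(rho = res$rho, phi = res$phi,
             rg = (params$n_p * params$a^3 / res$rho)^(1 / 3),
             f_sys = res$f, row.names = NULL)
}

#' Effective excluded volume from a weakly fluctuating supercritical bulk
#'
#' Integrating out a single-well (quadratic) bulk shifts the two-body
#' coefficient: `v_eff = v_p - h^2 / t_b`.  Only meaningful for `t_b > 0`.
#'
#' @param v_p bare excluded volume.
#' @param h polymer-bulk coupling.
#' @param t_b reduced temperature, must be positive.
#' @export
v_eff <- function(v_p, h, t_b) {
  if (any(t_b <= 0))
    stop("v_eff requires t_b > 0 (single-well quadratic bulk)")
  v_p - h^2 / t_b
}

#' Locate a collapse transition along a parameter scan
#'
#' Minimizes `F_sys` at each value of the scanned parameter and finds where
#' the polymer leaves the extended branch: either a *first-order* point,
#' where the identity of the global minimum switches between two coexisting
#' branches and `rho*` jumps discontinuously, or a *continuous* crossing,
#' where `rho*` passes a small threshold with no branch exchange.  The
#' reported location is the midpoint of the bracketing grid interval.
#'
#' @param params a [mean_field_params()].
#' @param axis one of `"v_p"`, `"mu_b"`, `"t_b"`, `"h"`.
#' @param values monotone grid of parameter values, in scan order (scan
#'   toward increasing density, e.g. decreasing `v_p`).
#' @param rho_threshold density threshold defining the continuous crossing
#'   (default 0.01).
#' @param jump_threshold minimum discontinuity in `rho*` to call the
#'   transition first order (default 0.2).
#' @param n_starts start-grid resolution passed to [minimize_fsys()].
#' @return list: `found`, `location`, `order` (`"continuous"` or
#'   `"first_order"`), and the scan `table` (one row per grid value with
#'   `rho`, `phi`, `f_sys`, `n_minima`).
#' @export
scan_transition <- function(params, axis, values, rho_threshold = 0.01,
                            jump_threshold = 0.2, n_starts = 12) {
  if (!axis %in% c("v_p", "mu_b", "t_b", "h")) stop("unknown scan axis")
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    params[[axis]] <- values[i]
    mm <- minimize_fsys(params, n_starts = n_starts)
    rows[[i]] <- data.frame(value = values[i], rho = mm$rho[1],
                            phi = mm$phi[1], f_sys = mm$f_sys[1],
                            n_minima = nrow(mm))
  }
  tab <- do.call(rbind, rows)
  names(tab)[1] <- axis
  for (i in seq_len(nrow(tab))[-1]) {
    jump <- abs(tab$rho[i] - tab$rho[i - 1])
    mid <- (values[i] + values[i - 1]) / 2
    if (jump > jump_threshold &&
        max(tab$n_minima[i - 1], tab$n_minima[i]) >= 2) {
      return(list(found = TRUE, location = mid, order = "first_order",
                  table = tab))
    }
    if ((tab$rho[i - 1] - rho_threshold) * (tab$rho[i] - rho_threshold) < 0) {
      return(list(found = TRUE, location = mid, order = "continuous",
                  table = tab))
    }
  }
  list(found = FALSE, location = NA_real_, order = NA_character_, table = tab)
}

#' Quadratic-branch approximation around the two bulk minima
#'
#' In the subcritical regime the bulk free energy is expanded to second
#' order around each of its minima `phi_m` (curvature
#' `t_m = t_b + u phi_m^2 / 2`); minimizing over `phi` analytically gives,
#' per branch, an effective isolated-polymer problem with
#' `v_eff = v_p - h^2 / t_m`, the constant `-h phi_m N_p`, and the volume
#' penalty `(N_p a^3 / rho) Delta_f_bulk(phi_m)`.  Each branch is then
#' minimized over `rho`.  A first-order transition is estimated where the
#' two branch free energies are equal (see [branch_transition()]).
#'
#' @param params a [mean_field_params()] with a double-well bulk.
#' @return data.frame, one row per branch: `phi_m`, `curvature`, `v_eff`,
#'   `rho`, `phi` (the branch minimizer `phi_m + h rho / (t_m a^3)`), and
#'   `f_branch`.
#' @export
quadratic_branches <- function(params) {
  bm <- f_bulk_minima(params)
  if (nrow(bm) < 2)
    stop("quadratic branches need a double-well bulk (two local minima)")
  f_ref <- f_bulk(phi_inf(params), params)
  out <- lapply(seq_len(nrow(bm)), function(k) {
    phi_m <- bm$phi[k]
    t_m <- bm$curvature[k]
    dfm <- bm$f[k] - f_ref
    branch_f <- function(rho) {
      f_poly0_rho(rho, params) -
        params$h^2 / (2 * t_m * params$a^3) * params$n_p * rho -
        params$h * phi_m * params$n_p +
        (params$n_p * params$a^3 / rho) * dfm
    }
    lo <- log(1e-12)
    hi <- log(3)
    cuts <- seq(lo, hi, length.out = 13)
    best <- NULL
    for (i in seq_len(length(cuts) - 1)) {
      op <- optimize(function(lr) branch_f(exp(lr)),
                     lower = cuts[i], upper = cuts[i + 1], tol = 1e-10)
      if (is.null(best) || op$objective < best$objective) best <- op
    }
    rho <- exp(best$minimum)
    data.frame(phi_m = phi_m, curvature = t_m,
               v_eff = params$v_p - params$h^2 / t_m, rho = rho,
               phi = phi_m + params$h * rho / (t_m * params$a^3),
               f_branch = best$objective)
  })
  do.call(rbind, out)
}

#' First-order transition estimate from branch crossing
#'
#' Scans a parameter and returns the midpoint of the grid interval where
#' the dilute and dense quadratic-branch free energies exchange order.
#'
#' @param params a [mean_field_params()].
#' @param axis scanned field name.
#' @param values monotone grid.
#' @return list `found`, `location`, `table` (branch free energies per
#'   value).
#' @export
branch_transition <- function(params, axis, values) {
  diffs <- numeric(length(values))
  rows <- vector("list", length(values))
  for (i in seq_along(values)) {
    params[[axis]] <- values[i]
    qb <- quadratic_branches(params)
    qb <- qb[order(qb$phi_m), ]
    diffs[i] <- qb$f_branch[1] - qb$f_branch[nrow(qb)]
    rows[[i]] <- data.frame(value = values[i], f_dilute = qb$f_branch[1],
                            f_dense = qb$f_branch[nrow(qb)])
  }
  tab <- do.call(rbind, rows)
  names(tab)[1] <- axis
  s <- which(diffs[-1] * diffs[-length(diffs)] < 0)
  if (!length(s))
    return(list(found = FALSE, location = NA_real_, table = tab))
  list(found = TRUE, location = (values[s[1]] + values[s[1] + 1]) / 2,
       table = tab)
}
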