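test_that("minimal-bulk occupancy matches the grand-canonical closed form", {
  # j_bulk = 0: independent sites, <s> = exp(mu_b) / (1 + exp(mu_b))
  g <- lattice_geometry(c(4, 4, 4))
  ch <- polymer_chain(rbind(c(0, 0, 0), c(0, 0, 1)), g) # inert dimer, j_int=0
  for (mu in c(-1, 0.5)) {
    p <- model_params(mu_b = mu, j_bulk = 0, n_max = 10)
    r <- run_minimal(g, ch, p, sweeps = 40000, equil = 2000, meas_every = 4,
                     seed = 17)
    occ <- r$observables$bulk_total / prod(g$dims)
    expected <- exp(mu) / (1 + exp(mu))
    expect_lt(abs(mean(occ) - expected), 3 * batch_se(occ) + 1e-4)
  }
})

test_that("interacting lattice gas matches exact enumeration on 2x2x2", {
  g <- lattice_geometry(c(2, 2, 2))
  p <- model_params(mu_b = 1, j_bulk = 1, n_max = 10)
  en <- enumerate_lattice_gas(g, p)
  ch <- polymer_chain(rbind(c(0, 0, 0), c(0, 0, 1)), g)
  r <- run_minimal(g, ch, p, sweeps = 60000, equil = 2000, meas_every = 4,
                   seed = 23)
  occ <- r$observables$bulk_total / 8
  expect_lt(abs(mean(occ) - en$mean_occupancy), 3 * batch_se(occ) + 1e-4)
})

test_that("reservoir exchange conserves N_r + N_s and empty reservoirs stay empty", {
  g <- lattice_geometry(c(8, 8, 8))
  ch <- straight_spanning_chain(g)
  p <- model_params(mu_b = 0.5, j_bulk = 0.8, j_nn = 0.1, j_int = 1,
                    n_b = 4, n_max = 20)
  r <- run_full(g, ch, p, sweeps = 2000, equil = 0, meas_every = 10,
                seed = 13, n_reservoir = 150)
  o <- r$observables
  expect_true(all(o$n_r + o$n_s1 + o$n_s2 == 150))
  expect_gt(mean(o$n_s1 + o$n_s2), 0)  # insertions do happen
  # lambda+ = 0 with an empty reservoir: no molecule can ever appear
  r0 <- run_full(g, ch, p, sweeps = 500, equil = 0, meas_every = 10,
                 seed = 13, n_reservoir = 0)
  expect_true(all(r0$observables$n_s1 + r0$observables$n_s2 == 0))
})

test_that("same-species excluded volume holds throughout a molecular-bulk run", {
  g <- lattice_geometry(c(8, 8, 8))
  ch <- straight_spanning_chain(g)
  p <- model_params(mu_b = 1, j_bulk = 1, j_nn = 0.1, j_int = 1.5,
                    n_b = 5, n_max = 20)
  r <- run_full(g, ch, p, sweeps = 3000, equil = 0, meas_every = 100,
                seed = 29, n_reservoir = 200, collect_frames = TRUE)
  # molecules stay intact chains; rebuild_fields errors on any same-species
  # collision, and cross-species sharing is fine
  fin <- r$final
  expect_silent(rebuild_fields(list(), fin$molecules, g))
  for (m in fin$molecules) {
    expect_equal(nrow(m$sites), 5)
    steps <- diff(m$sites)
    steps <- steps - round(steps / rep(g$dims, each = nrow(steps))) *
      rep(g$dims, each = nrow(steps))
    expect_true(all(rowSums(abs(steps)) == 1))
  }
  # frame occupancy agrees with the molecule lists (incremental == rebuild)
  f <- r$frames[[length(r$frames)]]
  fields <- rebuild_fields(list(), fin$molecules, g)
  expect_setequal(which(fields$s_1 == 1L) - 1L, site_index(f$bulk1, g))
  expect_setequal(which(fields$s_2 == 1L) - 1L, site_index(f$bulk2, g))
})

test_that("molecular bulk relaxes toward cross-species pairing when j_bulk is strong", {
  g <- lattice_geometry(c(8, 8, 8))
  ch <- polymer_chain(rbind(c(7, 7, 0), c(7, 7, 1)), g)
  p_on <- model_params(mu_b = -1, j_bulk = 2, j_nn = 0, j_int = 0, n_b = 3,
                       n_max = 10)
  p_off <- model_params(mu_b = -1, j_bulk = 0, j_nn = 0, j_int = 0, n_b = 3,
                        n_max = 10)
  r_on <- run_full(g, ch, p_on, sweeps = 6000, equil = 2000, meas_every = 10,
                   seed = 37, n_reservoir = 150)
  r_off <- run_full(g, ch, p_off, sweeps = 6000, equil = 2000,
                    meas_every = 10, seed = 37, n_reservoir = 150)
  # the on-site attraction pulls more molecules in from the reservoir
  expect_gt(mean(r_on$observables$n_s1 + r_on$observables$n_s2),
            mean(r_off$observables$n_s1 + r_off$observables$n_s2))
})
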