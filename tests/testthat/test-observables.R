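test_that("radius of gyration matches closed forms", {
  g <- geom8
  dimer <- polymer_chain(rbind(c(0, 0, 0), c(0, 0, 1)), g)
  expect_equal(radius_of_gyration(dimer)^2, 0.25)
  four <- polymer_chain(cbind(0, 0, 0:3), g)
  expect_equal(radius_of_gyration(four)^2, (16 - 1) / 12) # (N^2-1)/12, N=4
  # a chain stored across the boundary unwraps to its interior copy
  wrapped <- rbind(c(0, 0, 6), c(0, 0, 7), c(0, 0, 0), c(0, 0, 1))
  un <- unwrap_chain(wrapped, g)
  expect_equal(radius_of_gyration(un),
               radius_of_gyration(polymer_chain(cbind(0, 0, 0:3), g)))
})

test_that("bulk density difference behaves at the extremes", {
  g <- lattice_geometry(c(4, 4, 4))
  ch <- polymer_chain(cbind(0, 0, 0:2), g)
  # all bulk exactly on the polymer: delta = 1 - 0
  st <- lattice_state(g, chain = ch, gas = cbind(0, 0, 0:2))
  expect_equal(bulk_density_difference(st), 1)
  # uniform bulk: difference is zero
  all_sites <- as.matrix(expand.grid(x = 0:3, y = 0:3, z = 0:3))
  st2 <- lattice_state(g, chain = ch, gas = all_sites)
  expect_equal(bulk_density_difference(st2), 0)
  # antisymmetry under swapping the on/off labels
  set.seed(3)
  some <- all_sites[sample(64, 20), ]
  st3 <- lattice_state(g, chain = ch, gas = some)
  # direct recomputation from the definition
  on <- site_index(some, g) %in% site_index(ch$coords, g)
  dens_on <- sum(on) / 3
  dens_off <- (20 - sum(on)) / (64 - 3)
  expect_equal(bulk_density_difference(st3), dens_on - dens_off)
  # shell covering everything leaves no far field
  expect_error(bulk_density_difference(st2, shell_radius = 2), "far-field")
})

test_that("occupancy profile separates binding and non-binding segments", {
  g <- lattice_geometry(c(8, 8, 8))
  co <- cbind(0, 0, 0:5)
  types <- c(1, 1, 1, 2, 2, 2)
  frame <- list(sweep = 1, chain = co, types = types,
                bulk1 = co[1:3, , drop = FALSE],
                bulk2 = matrix(integer(0), ncol = 3))
  prof <- occupancy_profile(list(frame, frame), g, nbins = 6)
  expect_equal(prof$occ1, c(1, 1, 1, 0, 0, 0))
  expect_equal(prof$occ2, rep(0, 6))
  bt <- attr(prof, "by_type")
  expect_equal(bt$occ1, c(1, 0))
})

test_that("contact maps are symmetric with the expected geometry", {
  g <- geom8
  straight <- list(sweep = 1, chain = cbind(0, 0, 0:5),
                   types = rep(1L, 6), bulk1 = matrix(integer(0), ncol = 3),
                   bulk2 = matrix(integer(0), ncol = 3))
  cm <- contact_map(list(straight), g, nbins = 6)
  expect_equal(cm, t(cm))
  off <- abs(row(cm) - col(cm))
  expect_true(all(cm[off == 1] == 1))   # bonded neighbours always touch
  expect_true(all(cm[off > 1] == 0))    # no long-range contacts when straight
  sq <- list(sweep = 1, chain = square4()$coords, types = rep(1L, 4),
             bulk1 = matrix(integer(0), ncol = 3),
             bulk2 = matrix(integer(0), ncol = 3))
  cm2 <- contact_map(list(sq), g, nbins = 4)
  expect_equal(cm2[1, 4], 1)            # the closing corner contact
  expect_error(contact_map(list(sq), g, nbins = 0), "at least 1")
})

test_that("profiles and maps are invariant under global lattice translation", {
  set.seed(8)
  g <- lattice_geometry(c(6, 6, 6))
  ch <- random_saw(g, 10)
  gas <- cbind(sample(0:5, 6, TRUE), sample(0:5, 6, TRUE),
               sample(0:5, 6, TRUE))
  fr <- list(sweep = 1, chain = ch$coords, types = rep(1L, 10), bulk1 = gas,
             bulk2 = matrix(integer(0), ncol = 3))
  shift <- c(2, 5, 1)
  fr_s <- list(sweep = 1, chain = sweep(ch$coords, 2, shift, "+"),
               types = rep(1L, 10), bulk1 = sweep(gas, 2, shift, "+"),
               bulk2 = matrix(integer(0), ncol = 3))
  expect_equal(contact_map(list(fr), g, nbins = 10),
               contact_map(list(fr_s), g, nbins = 10))
  expect_equal(occupancy_profile(list(fr), g, nbins = 5)$occ1,
               occupancy_profile(list(fr_s), g, nbins = 5)$occ1)
})

test_that("collapsed chains are denser than extended ones as n_max grows", {
  g <- lattice_geometry(c(8, 8, 8))
  ch <- straight_spanning_chain(g)
  rho_at <- function(v_p, n_max) {
    p <- model_params(v_p = v_p, n_max = n_max)
    r <- run_polymer(g, ch, p, sweeps = 6000, equil = 3000, meas_every = 10,
                     seed = 19)
    mean(r$observables$rho)
  }
  # extended chains dilute with growing n_max; collapsed chains do not
  expect_lt(rho_at(1, 120) / rho_at(1, 40), 0.9)
  expect_gt(rho_at(-1.5, 120), 0.5 * rho_at(-1.5, 40))
})
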