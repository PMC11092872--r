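test_that("polymer energy counts sites and nearest-neighbour contacts", {
  p <- model_params(mu_p = 0, v_p = 1, n_max = 100)
  g <- geom8
  expect_equal(energy_polymer(lattice_state(g, chain = trimer_straight()), p),
               -3 + 2)   # 3 sites, 2 sequential contacts
  expect_equal(energy_polymer(lattice_state(g, chain = square4()), p),
               -4 + 4)   # closed square: 4 contacts
  p0 <- model_params(mu_p = 0, v_p = 0, n_max = 100)
  expect_equal(energy_polymer(lattice_state(g, chain = square4()), p0), 0)
  pmu <- model_params(mu_p = 2, v_p = 0, n_max = 100)
  expect_equal(energy_polymer(lattice_state(g, chain = trimer_straight()),
                              pmu), -6)
})

test_that("bulk energy: on-site cross-species attraction, per-molecule mu_b", {
  g <- geom8
  m1 <- straight_molecule(1, c(1, 1, 0), 5)
  m2 <- straight_molecule(2, c(1, 1, 0), 5)
  p <- model_params(mu_b = 0, j_bulk = 2, j_nn = 0, n_b = 5, n_max = 100)
  expect_equal(energy_bulk(lattice_state(g, molecules = list(m1, m2)), p),
               -2 * 5)   # N_b perfectly shared sites
  # empty bulk
  expect_equal(energy_bulk(lattice_state(g), p), 0)
  # two isolated same-species molecules: just the per-molecule potential
  p2 <- model_params(mu_b = 1.5, j_bulk = 1, j_nn = 0, n_b = 2, n_max = 100)
  mm <- list(straight_molecule(1, c(0, 0, 0), 2),
             straight_molecule(1, c(4, 4, 4), 2))
  expect_equal(energy_bulk(lattice_state(g, molecules = mm), p2), -3)
})

test_that("interaction energy couples species 1 to the polymer, by type", {
  g <- geom8
  ch <- polymer_chain(cbind(0, 0, 0:4), g, types = c(1, 1, 1, 2, 2),
                      type_labels = c("yellow", "green"))
  m1 <- straight_molecule(1, c(0, 0, 0), 5)
  m2 <- straight_molecule(2, c(0, 0, 0), 5)
  p <- model_params(j_int = c(1, 0), n_max = 100)
  st <- lattice_state(g, chain = ch, molecules = list(m1))
  expect_equal(energy_interaction(st, p), -3)  # only yellow sites count
  # species 2 never couples to the polymer
  st2 <- lattice_state(g, chain = ch, molecules = list(m2))
  expect_equal(energy_interaction(st2, p), 0)
  # uniform type, j_int = 1, 5 shared sites
  ch1 <- polymer_chain(cbind(0, 0, 0:4), g)
  st3 <- lattice_state(g, chain = ch1, molecules = list(m1))
  expect_equal(energy_interaction(st3, model_params(j_int = 1, n_max = 100)),
               -5)
})

test_that("minimal-bulk energy follows the lattice-gas Hamiltonian", {
  g <- lattice_geometry(c(4, 4, 4))
  gas <- rbind(c(0, 0, 0), c(0, 0, 1), c(2, 2, 2))
  p <- model_params(mu_b = 0.5, j_bulk = 2, n_max = 100)
  # one adjacent pair among the three occupied sites
  expect_equal(energy_bulk(lattice_state(g, gas = gas), p), -0.5 * 3 - 2)
})

test_that("energy_delta equals the full recomputation for random proposals", {
  set.seed(31)
  g <- lattice_geometry(c(5, 5, 6))
  p <- model_params(mu_p = 0.2, v_p = -0.7, n_max = 25, mu_b = -0.4,
                    j_bulk = 0.6, j_int = 1.2)
  ch <- straight_spanning_chain(g)
  gas <- unique(t(replicate(30, c(sample(0:4, 1), sample(0:4, 1),
                                  sample(0:5, 1)))))
  st <- lattice_state(g, chain = ch, gas = gas)
  expect_identical(energy_delta(st, list(kind = "none"), p), 0)
  checked <- 0
  for (i in 1:400) {
    bond <- sample(0:(nrow(ch$coords) - 2), 1)
    b <- ch$coords[bond + 2, ] - ch$coords[bond + 1, ]
    d <- prewetting:::orthogonal_directions(b)[sample.int(4, 1), ]
    prop <- classify_move(ch, bond, d)
    newc <- prewetting:::propose_apply(ch, prop)
    # only evaluate proposals that lead to a valid state
    valid <- tryCatch({
      polymer_chain(newc$coords, g)
      TRUE
    }, error = function(e) FALSE)
    if (!valid) next
    st_new <- lattice_state(g, chain = newc, gas = gas)
    full <- energy_total(st_new, p) - energy_total(st, p)
    local <- energy_delta(st, prop, p)
    expect_equal(local, full, tolerance = 1e-12)
    checked <- checked + 1
    if (prop$kind != "removal" && runif(1) < 0.5) {
      ch <- newc
      st <- lattice_state(g, chain = ch, gas = gas)
    }
  }
  expect_gt(checked, 100)
})

test_that("spin-flip delta matches the lattice-gas locals", {
  g <- lattice_geometry(c(4, 4, 4))
  p <- model_params(mu_b = 1, j_bulk = 0.5, n_max = 100)
  # isolated site turning on: dE = -mu_b
  st <- lattice_state(g, gas = matrix(integer(0), ncol = 3))
  expect_equal(energy_delta(st, list(kind = "flip", site = c(1, 1, 1)), p), -1)
  # site with k occupied neighbours: dE = -mu_b - j_bulk * k
  gas <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 2, 1))
  st2 <- lattice_state(g, gas = gas)
  expect_equal(energy_delta(st2, list(kind = "flip", site = c(1, 1, 1)), p),
               -1 - 0.5 * 3)
  # turning the same site off is minus the on-delta
  st3 <- lattice_state(g, gas = rbind(gas, c(1, 1, 1)))
  expect_equal(energy_delta(st3, list(kind = "flip", site = c(1, 1, 1)), p),
               1 + 0.5 * 3)
})

test_that("energies are translation invariant and match the compiled engine", {
  set.seed(41)
  g <- lattice_geometry(c(6, 6, 6))
  p <- model_params(mu_p = 0.3, v_p = -0.8, mu_b = 0.2, j_bulk = 0.7,
                    j_nn = 0.15, j_int = 0.9, n_b = 4, n_max = 50)
  for (rep in 1:10) {
    ch <- random_saw(g, 8)
    mols <- list(straight_molecule(1, c(3, 0, 0), 4),
                 straight_molecule(2, c(3, 0, 0), 4),
                 straight_molecule(1, c(0, 3, 2), 4))
    st <- lattice_state(g, chain = ch, molecules = mols)
    shift <- c(sample(0:5, 1), sample(0:5, 1), sample(0:5, 1))
    ch_s <- polymer_chain(sweep(ch$coords, 2, shift, "+"), g)
    mols_s <- lapply(mols, function(m)
      list(species = m$species, sites = sweep(m$sites, 2, shift, "+")))
    st_s <- lattice_state(g, chain = ch_s, molecules = mols_s)
    expect_equal(energy_total(st_s, p), energy_total(st, p),
                 tolerance = 1e-12)
    # reversing the chain direction leaves every energy unchanged
    st_r <- lattice_state(g, chain = polymer_chain(ch$coords[8:1, ], g),
                          molecules = mols)
    expect_equal(energy_total(st_r, p), energy_total(st, p),
                 tolerance = 1e-12)
    # independent compiled implementation agrees
    eC <- prewetting:::cpp_state_energies(
      g$dims, ch$coords, ch$types,
      prewetting:::params_for_engine(p, ch), 2L, integer(0),
      lapply(mols, function(m) list(species = m$species,
                                    sites = site_index(m$sites, g))))
    expect_equal(unname(eC[["e_poly"]]), energy_polymer(st, p))
    expect_equal(unname(eC[["e_bulk"]]), energy_bulk(st, p))
    expect_equal(unname(eC[["e_int"]]), energy_interaction(st, p))
  }
})
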