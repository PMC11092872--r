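test_that("bond translation is classified by flanking-monomer intersections", {
  # straight trimer: translated bond hits neither flank -> addition
  expect_equal(classify_move(trimer_straight(), 0, c(1, 0, 0))$kind,
               "addition")
  # L-shaped trimer: one flank intersected -> kink (interior monomer moves)
  kk <- classify_move(trimer_L(), 0, c(0, 1, 0))
  expect_equal(kk$kind, "kink")
  expect_equal(kk$mover, 1L)
  expect_equal(unname(kk$new_coords[2, ]), c(0, 1, 0))
  # closed square: both flanks intersected -> removal
  expect_equal(classify_move(square4(), 1, c(0, 0, -1))$kind, "removal")
  expect_error(classify_move(trimer_straight(), 0, c(0, 0, 1)), "orthogonal")
  expect_error(classify_move(trimer_straight(), 5, c(1, 0, 0)), "out of range")
})

test_that("R and compiled classifications agree on random chains", {
  g <- lattice_geometry(c(5, 5, 5))
  set.seed(21)
  for (rep in 1:40) {
    ch <- random_saw(g, sample(4:10, 1))
    bond <- sample(0:(nrow(ch$coords) - 2), 1)
    b <- ch$coords[bond + 2, ] - ch$coords[bond + 1, ]
    dirs <- prewetting:::orthogonal_directions(b)
    d <- dirs[sample.int(4, 1), ]
    rk <- classify_move(ch, bond, d)
    ck <- prewetting:::cpp_classify_move(g$dims, ch$coords, bond, as.integer(d))
    expect_equal(rk$kind, ck$kind)
    if (rk$kind == "kink") expect_equal(rk$mover, ck$mover)
  }
})

test_that("proposal probabilities follow the printed schedule and sum to one", {
  expect_equal(proposal_probabilities(2, 0), c(add = 2/3, rem = 1/3, kink = 0))
  p10 <- proposal_probabilities(10, 0.2)
  expect_equal(unname(p10[1]), 12 / 22 * 0.8, tolerance = 1e-12)
  expect_equal(unname(p10[2]), 10 / 22 * 0.8, tolerance = 1e-12)
  for (np in c(2, 5, 33, 1500)) for (pk in c(0, 0.2, 0.7))
    expect_equal(sum(proposal_probabilities(np, pk)), 1, tolerance = 1e-12)
  expect_error(proposal_probabilities(10, 1), "p_kink")
})

test_that("moves preserve chain invariants and respect the length window", {
  set.seed(5)
  g <- lattice_geometry(c(4, 4, 5))
  ch <- straight_spanning_chain(g)
  p <- model_params(v_p = -0.6, n_max = 11, p_kink = 0.2)
  ends <- ch$coords[c(1, nrow(ch$coords)), ]
  for (i in 1:2500) {
    out <- attempt_polymer_move(ch, p)
    ch <- out$chain
    np <- n_polymer(ch)
    expect_true(np >= g$dims[3] && np < 11)
  }
  # endpoints never displaced; chain still a valid self-avoiding walk
  expect_equal(ch$coords[c(1, nrow(ch$coords)), ], ends)
  expect_silent(polymer_chain(ch$coords, g))
  # the spanning chain grows in steps of two monomers (parity L_z + 2k) and
  # additions at the top of the window are rejected, so N_p caps at 9 < 11
  set.seed(6)
  seen <- integer(0)
  for (i in 1:2000) {
    seen <- c(seen, n_polymer(ch))
    out <- attempt_polymer_move(ch, p)
    ch <- out$chain
  }
  expect_setequal(unique(seen %% 2), 1) # L_z = 5, always odd
  expect_equal(max(seen), 9)
})

test_that("every applied move has a classified reverse move", {
  set.seed(9)
  g <- lattice_geometry(c(4, 4, 5))
  ch <- straight_spanning_chain(g)
  p <- model_params(v_p = 0, n_max = 14, p_kink = 0.3)
  nchecked <- 0
  for (i in 1:800) {
    out <- attempt_polymer_move(ch, p)
    if (out$accepted) {
      prop <- out$proposal
      rev_kind <- c(addition = "removal", removal = "addition",
                    kink = "kink")[[prop$kind]]
      rev_bond <- switch(prop$kind, addition = prop$bond + 1L,
                         removal = prop$bond - 1L, kink = prop$bond)
      b <- ch$coords[prop$bond + 2L, ] - ch$coords[prop$bond + 1L, ]
      rd <- if (prop$kind == "kink") {
        # the corner re-threads back along the original bond vector
        if (prop$mover == prop$bond) -b else b
      } else -prop$direction
      rev <- classify_move(out$chain, rev_bond, rd)
      expect_equal(rev$kind, rev_kind)
      expect_true(all(rev$new_coords == ch$coords) &&
                    nrow(rev$new_coords) == nrow(ch$coords))
      nchecked <- nchecked + 1
      ch <- out$chain
    }
  }
  expect_gt(nchecked, 50)
})

test_that("segment assignment satisfies the per-block windows", {
  g <- lattice_geometry(c(16, 16, 16))
  co <- cbind(0, 0, 0:99)
  ch <- polymer_chain(co, lattice_geometry(c(128, 128, 128)))
  sp <- segment_spec(c("yellow", "green"), c(50, 50), delta = 10)
  ch2 <- assign_segments(ch, sp)
  expect_equal(attr(ch2, "realized_counts"), c(50L, 50L))
  expect_equal(ch2$types, rep(1:2, each = 50))

  short <- polymer_chain(cbind(0, 0, 0:38), lattice_geometry(c(128, 128, 128)))
  expect_error(assign_segments(short, segment_spec("yellow", 50, 10)),
               "cannot satisfy")

  long <- polymer_chain(cbind(0, 0, 0:119), lattice_geometry(c(128, 128, 128)))
  ch3 <- assign_segments(long, segment_spec(c("yellow", "green"), c(50, 50),
                                            delta = 12))
  rc <- attr(ch3, "realized_counts")
  expect_equal(sum(rc), 120)
  expect_true(all(rc >= 38 & rc <= 62))
})

test_that("segment windows are never violated across a long segmented run", {
  g <- lattice_geometry(c(8, 8, 8))
  p0 <- model_params(v_p = 0, n_max = 60)
  r0 <- run_polymer(g, straight_spanning_chain(g), p0, sweeps = 2000,
                    equil = 0, meas_every = 500, seed = 2)
  ch <- assign_segments(r0$final$chain,
                        segment_spec(c("yellow", "green"), c(25, 25),
                                     delta = 8))
  lo <- ch$seg_min
  hi <- ch$seg_max
  # ~1e6 attempted moves
  r <- run_minimal(g, ch, model_params(v_p = -0.3, n_max = 60, mu_b = -1,
                                       j_bulk = 0.3, j_int = c(1, 0)),
                   sweeps = 20000, equil = 0, meas_every = 50, seed = 3,
                   collect_frames = TRUE)
  for (f in r$frames) {
    n <- nrow(f$chain)
    counts <- tabulate(f$types[seq_len(n - 1)], 2)
    expect_true(all(counts >= lo & counts <= hi))
  }
  expect_true(all(r$final$seg_counts >= lo & r$final$seg_counts <= hi))
})
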