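test_that("pair potentials match their closed forms at reference points", {
  p <- tiny_params()

  # WCA: unit depth shift at r = sigma, zero at and beyond the cutoff
  expect_equal(wca_pair_energy(1, p), 1.0)
  expect_equal(wca_pair_energy(2^(1 / 6), p), 0)
  expect_equal(wca_pair_energy(2, p), 0)
  expect_error(wca_pair_energy(0, p), "positive")

  # FENE: zero at rest, direct evaluation at d = sigma, divergence at R0
  expect_equal(fene_bond_energy(0, p), 0)
  expect_equal(fene_bond_energy(1, p), -0.5 * 30 * 1.5^2 * log(1 - (1 / 1.5)^2))
  expect_error(fene_bond_energy(1.5, p), "divergence")

  # sticky Gaussian: full depth at contact, one-sigma-of-the-well point,
  # zero outside its range
  expect_equal(sticky_pair_energy(2^(1 / 6), p), -100)
  expect_equal(sticky_pair_energy(2^(1 / 6) + 2.5, p), -100 * exp(-0.5))
  expect_equal(sticky_pair_energy(2^(1 / 6) + 5.1, p), 0)
  expect_equal(sticky_pair_energy(0.5, p), 0) # inside the inner boundary

  # bending: zero when straight, quadratic otherwise, off in the L regime
  pb <- tiny_params(kappa_bend = 10)
  expect_equal(bending_energy(pi, pb), 0)
  expect_equal(bending_energy(pi / 2, pb), 5 * (pi / 2)^2)
  expect_equal(bending_energy(0.3, p), 0) # kappa_bend = 0
})

test_that("total energy equals a naive O(N^2) sum on random states", {
  for (seed in 1:5) {
    p <- tiny_params(n = 10, kappa_bend = if (seed %% 2) 10 else 0,
                     internal = c(3L, 7L))
    st <- random_chain_state(p, seed)
    expect_equal(total_energy(st, p), naive_total_energy(st$positions, p),
                 tolerance = 1e-10)
    # with adhesion bonds present
    st$bonded_termini <- TRUE
    st$bonded_internal <- TRUE
    d_term <- sqrt(sum((st$positions[1, ] - st$positions[10, ])^2))
    if (d_term < p$r0_fene) {
      expect_equal(total_energy(st, p),
                   naive_total_energy(st$positions, p, TRUE, TRUE),
                   tolerance = 1e-10)
    }
  }
  # straight equispaced chain: all angles are pi, so no bending energy
  p <- tiny_params(n = 8, kappa_bend = 10, terminal = NULL)
  pos <- cbind(seq(0, by = 1.15, length.out = 8), 0, 0) # beyond WCA cutoff
  st <- chain_state(pos, matrix(0, 8, 3))
  br <- total_energy(st, p, breakdown = TRUE)
  expect_equal(br$bend, 0)
  expect_equal(br$wca, 0)
})

test_that("analytic forces match central finite differences", {
  for (seed in 1:4) {
    p <- tiny_params(n = 10, kappa_bend = if (seed %% 2) 10 else 0,
                     internal = c(3L, 7L))
    st <- random_chain_state(p, seed + 10)
    fa <- chain_forces(st, p)
    ff <- fd_forces(st, p)
    expect_lt(max(abs(fa - ff)) / max(abs(fa)), 1e-6)
  }
})

test_that("zero-force configurations give zero force", {
  p <- tiny_params(n = 4, kappa_bend = 10, terminal = NULL)
  # straight triplet at theta = pi: no bending force anywhere
  b0 <- equilibrium_bond_length(p)
  pos <- cbind(c(0, 1, 2, 3) * b0, 0, 0)
  st <- chain_state(pos, matrix(0, 4, 3))
  f <- chain_forces(st, p)
  # bending contributes nothing; the residual is the bond-force
  # imbalance within the optimizer's tolerance of the minimum
  expect_lt(max(abs(f)), 1e-2)
  # two non-bonded beads exactly at the WCA cutoff: no force
  r <- 2^(1 / 6)
  e_in <- wca_pair_energy(r - 1e-7, p)
  expect_lt(e_in, 1e-10) # potential flattens to zero at the cutoff
})

test_that("sticky attraction acts only between its two designated pairs", {
  p <- tiny_params(n = 10, internal = c(3L, 7L))
  st <- random_chain_state(p, 3)
  br0 <- total_energy(st, p, breakdown = TRUE)
  # move a bead that belongs to no sticky pair: U_stick is unchanged
  st2 <- st
  st2$positions[5, ] <- st2$positions[5, ] + c(0.05, -0.03, 0.02)
  br1 <- total_energy(st2, p, breakdown = TRUE)
  expect_equal(br1$stick, br0$stick)
  # move a sticky bead: U_stick changes (it sits inside the active range)
  st3 <- st
  st3$positions[3, ] <- st3$positions[3, ] + c(0.3, 0, 0)
  br2 <- total_energy(st3, p, breakdown = TRUE)
  expect_false(isTRUE(all.equal(br2$stick, br0$stick)))
})

test_that("energy breakdown composes into the total", {
  p <- tiny_params(n = 10, kappa_bend = 10, internal = c(4L, 8L))
  st <- random_chain_state(p, 12)
  br <- total_energy(st, p, breakdown = TRUE)
  expect_equal(br$wca + br$fene + br$stick + br$bend, br$total)
  expect_equal(total_energy(st, p), br$total)
})
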