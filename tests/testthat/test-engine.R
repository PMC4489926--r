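test_that("initial conformation is a jittered line at the bond minimum", {
  p <- model_params(n_beads = 200)
  pr <- run_protocol(seed = 4)
  st <- initial_conformation(p, pr)
  # end-to-end length: (N-1) times the numerically minimized bond length
  b0 <- optimize(function(d) fene_bond_energy(d, p) + wca_pair_energy(d, p),
                 c(0.5, 1.5 - 1e-9))$minimum
  ree <- sqrt(sum((st$positions[200, ] - st$positions[1, ])^2))
  expect_equal(ree, 199 * b0, tolerance = 0.01)
  # transverse jitter is bounded and angles stay near pi
  expect_lt(max(abs(st$positions[, 2:3])), 0.01)
  ang <- vapply(2:199, function(i) {
    a <- st$positions[i - 1, ] - st$positions[i, ]
    b <- st$positions[i + 1, ] - st$positions[i, ]
    acos(sum(a * b) / sqrt(sum(a^2) * sum(b^2)))
  }, 0)
  expect_lt(max(abs(ang - pi)), 1e-2)
  expect_false(st$bonded_termini)
  expect_false(st$bonded_internal)
  # determinism: same seed gives the identical state
  expect_identical(st, initial_conformation(p, pr))
})

test_that("velocities are Maxwell-Boltzmann at kbt", {
  p <- model_params(n_beads = 2000, sticky_terminal_pair = NULL)
  st <- initial_conformation(p, run_protocol(seed = 8))
  expect_equal(mean(st$velocities^2), p$kbt / p$mass, tolerance = 0.05)
})

test_that("gamma = 0 reduces the update to velocity Verlet", {
  p <- model_params(n_beads = 12, sticky_terminal_pair = NULL)
  pr0 <- run_protocol(seed = 2, gamma = 0)
  st <- initial_conformation(p, pr0)
  a <- langevin_step(st, p, pr0, 500, engine_seed = 7)
  b <- langevin_step(st, p, pr0, 500, thermostat = FALSE, engine_seed = 99)
  # no friction and no noise: the two trajectories are bitwise identical
  expect_identical(a$positions, b$positions)
  expect_identical(a$velocities, b$velocities)
})

test_that("trajectories are bitwise reproducible from their seed", {
  p <- model_params(n_beads = 30, sticky_internal_pair = c(10L, 20L))
  pr <- run_protocol(seed = 21, max_steps = 3e5)
  o1 <- run_until_circularization(p, pr)
  o2 <- run_until_circularization(p, pr)
  expect_identical(o1$final_positions, o2$final_positions)
  expect_identical(o1$steps_elapsed, o2$steps_elapsed)
  expect_identical(o1$circularized, o2$circularized)
})

test_that("adhesion events set permanent flags at the capture distance", {
  p <- model_params(n_beads = 10, sticky_internal_pair = c(3L, 7L))
  pr <- run_protocol(seed = 1)
  mk <- function(d37) {
    pos <- cbind(seq(0, by = 1.1, length.out = 10), 0, 0)
    pos[7, ] <- pos[3, ] + c(d37, 0, 0)
    # keep bonds legal by lifting intermediate beads
    pos[4:6, 2] <- c(0.9, 1.3, 0.9)
    chain_state(pos, matrix(0, 10, 3))
  }
  st <- adhesion_event(mk(1.29), "internal", p, pr)
  expect_true(st$bonded_internal)
  st2 <- adhesion_event(mk(3.0), "internal", p, pr)
  expect_false(st2$bonded_internal)
  # idempotent once set, whatever the distance
  st3 <- mk(3.0); st3$bonded_internal <- TRUE
  expect_true(adhesion_event(st3, "internal", p, pr)$bonded_internal)
})

test_that("adhesion flags are monotone along a trajectory", {
  p <- model_params(n_beads = 16, sticky_internal_pair = c(5L, 12L))
  pr <- run_protocol(seed = 31)
  st <- initial_conformation(p, pr)
  seen_int <- FALSE; seen_term <- FALSE
  for (k in 1:40) {
    st <- langevin_step(st, p, pr, 2500, engine_seed = 1000 + k)
    if (seen_int) expect_true(st$bonded_internal)
    if (seen_term) expect_true(st$bonded_termini)
    seen_int <- seen_int || st$bonded_internal
    seen_term <- seen_term || st$bonded_termini
  }
  expect_true(seen_term) # a 16-bead sticky chain closes quickly
})

test_that("runs end either circularized or censored, never both", {
  p <- model_params(n_beads = 40)
  # a tiny step cap censors the run
  oc <- run_until_circularization(p, run_protocol(seed = 5, max_steps = 10))
  expect_false(oc$circularized)
  expect_true(oc$censored)
  expect_error(close_chain(oc), "censored")
  # a generous cap on a short chain circularizes
  p2 <- model_params(n_beads = 20)
  o <- run_until_circularization(p2, run_protocol(seed = 6, max_steps = 2e6))
  expect_true(o$circularized)
  expect_false(o$censored)
  d <- sqrt(sum((o$final_positions[1, ] - o$final_positions[20, ])^2))
  expect_lte(d, run_protocol(seed = 6)$capture_distance)
  expect_lte(o$steps_elapsed, 2e6)
})

test_that("a FENE overstretch aborts the run with a diagnostic tag", {
  p <- model_params(n_beads = 12)
  # absurd time step: bonds blow through R0 almost immediately
  pr <- run_protocol(dt = 0.5, seed = 9, max_steps = 1e4)
  o <- run_until_circularization(p, pr)
  expect_true(o$censored)
  expect_match(o$error, "fene_overstretch")
  expect_error(langevin_step(initial_conformation(p, pr), p, pr, 1e4),
               "aborted")
})

test_that("the thermostat holds the kinetic temperature near kbt (quick)", {
  p <- model_params(n_beads = 4, sticky_terminal_pair = NULL)
  pr <- run_protocol(seed = 14)
  st <- initial_conformation(p, pr)
  ke_dof <- kinetic_temperature(st, p, pr, 4e5, sample_every = 40)
  expect_equal(ke_dof, 0.5 * p$kbt, tolerance = 0.05)
})
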