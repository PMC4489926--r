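test_that("the placement grid reproduces the canonical enumeration", {
  g <- enumerate_grid(500, 50)
  expect_equal(nrow(g), 20)
  expect_true(any(g$l_x == 50 & g$l_y == 300))
  # brute-force oracle at a coarser spacing
  g4 <- enumerate_grid(500, 100)
  expect_equal(g4[, c("l_x", "l_y")],
               data.frame(l_x = c(100, 100, 100, 200),
                          l_y = c(100, 200, 300, 200)))
  # canonical form: l_x <= l_y, loop at least one spacing, no coincident
  # sites; re-canonicalization is a no-op
  expect_true(all(g$l_x <= g$l_y))
  expect_true(all(g$loop_length >= 50))
  expect_true(all(g$l_x + g$l_y != 500))
  expect_true(all(g$site_x < g$site_y))
  g2 <- g[g$l_x <= g$l_y & g$l_x + g$l_y != 500 & g$loop_length >= 50, ]
  expect_equal(g, g2)
  expect_error(enumerate_grid(500, 0), "spacing")
  expect_error(enumerate_grid(500, 250), "spacing")
})

test_that("RKP arithmetic and failure modes follow the definition", {
  r <- rkp(4, 1000, 2, 1000)
  expect_equal(r$estimate, 2.0)
  expect_equal(r$p_k, 0.004)
  expect_equal(rkp(5, 700, 5, 700)$estimate, 1.0)
  expect_error(rkp(3, 100, 0, 100), "reference")
  # Katz interval brackets the estimate and is positive
  expect_true(r$ci[1] < 2 && r$ci[2] > 2 && r$ci[1] > 0)
  # zero numerator: degenerate interval starting at zero
  r0 <- rkp(0, 500, 3, 500)
  expect_equal(r0$estimate, 0)
  expect_equal(r0$ci[1], 0)
  expect_gt(r0$ci[2], 0)
})

test_that("loop fractions count knotted configurations correctly", {
  led <- data.frame(
    circularized = TRUE, censored = FALSE,
    knot_label = c(rep("3_1", 9), "4_1", rep("0_1", 5)),
    loop_closed = c(rep(TRUE, 8), FALSE, FALSE, rep(TRUE, 5)),
    relevant = c(rep(TRUE, 6), FALSE, FALSE, NA, NA, rep(NA, 5)))
  expect_equal(fcsl(led), 0.8)
  expect_equal(ftrsl(led), 0.6)
  # all loops open
  led$loop_closed <- FALSE
  led$relevant <- NA
  expect_equal(fcsl(led), 0)
  expect_equal(ftrsl(led), 0)
  # no knotted runs at all
  led0 <- led[led$knot_label == "0_1", ]
  expect_error(fcsl(led0), "no knotted")
  expect_error(ftrsl(led0), "no knotted")
})

test_that("FTRSL never exceeds FCSL on randomized ledgers", {
  for (s in 1:20) {
    led <- random_ledger(200, seed = s)
    if (!any(led$circularized & led$knot_label != "0_1", na.rm = TRUE)) next
    expect_lte(ftrsl(led), fcsl(led))
  }
})

test_that("the knot spectrum is a normalized distribution", {
  led <- data.frame(circularized = TRUE, censored = FALSE,
                    knot_label = c("3_1", "3_1", "3_1", "4_1"),
                    loop_closed = TRUE, relevant = FALSE)
  sp <- knot_spectrum(led)
  expect_equal(sp[["3_1"]], 0.75)
  expect_equal(sp[["4_1"]], 0.25)
  expect_error(knot_spectrum(led[led$knot_label == "5_2", ]), "empty")
  for (s in 1:10) {
    led <- random_ledger(150, seed = 100 + s)
    if (!any(led$circularized & led$knot_label != "0_1", na.rm = TRUE)) next
    expect_equal(sum(knot_spectrum(led)), 1)
  }
})

test_that("batches are reproducible, resumable and fully accounted", {
  p <- model_params(n_beads = 24)
  pr <- run_protocol(seed = 1, max_steps = 3e5)
  g <- enumerate_grid(24, 6)
  led1 <- run_batch(g[1, ], p, pr, n_runs = 4, seed_base = 50)
  led2 <- run_batch(g[1, ], p, pr, n_runs = 4, seed_base = 50)
  expect_equal(led1, led2)
  expect_equal(nrow(led1), 4)
  # ledger accounting: knotted + unknotted + censored = total
  knotted <- sum(knotted_mask_for_test(led1))
  unknotted <- sum(led1$circularized & led1$knot_label == "0_1", na.rm = TRUE)
  expect_equal(knotted + unknotted + sum(led1$censored), nrow(led1))
  # reference batches carry no internal-loop information
  ref <- run_batch(NULL, p, pr, n_runs = 2, seed_base = 70)
  expect_true(all(is.na(ref$loop_closed)))
  expect_true(all(is.na(ref$l_x)))
  # resuming from a ledger file skips completed seeds: a second call
  # appends nothing and returns the same rows
  path <- tempfile(fileext = ".csv")
  on.exit(unlink(path))
  led3 <- run_batch(g[1, ], p, pr, n_runs = 4, seed_base = 50,
                    ledger_path = path)
  n_lines <- length(readLines(path))
  led4 <- run_batch(g[1, ], p, pr, n_runs = 4, seed_base = 50,
                    ledger_path = path)
  expect_equal(nrow(led4), 4)
  expect_equal(length(readLines(path)), n_lines)
  expect_equal(led4$run_id, led3$run_id)
  # a partial ledger is topped up, not recomputed from scratch
  led5 <- run_batch(g[1, ], p, pr, n_runs = 6, seed_base = 50,
                    ledger_path = path)
  expect_equal(nrow(led5), 6)
  expect_equal(sort(led5$seed), 50:55)
})

test_that("experiment summaries aggregate a ledger consistently", {
  led <- random_ledger(400, seed = 3)
  ref <- random_ledger(400, seed = 4)
  s <- experiment_summary(list(l_x = 50, l_y = 100), led, ref)
  expect_equal(s$n_runs, 400)
  expect_equal(s$rkp, s$p_k / s$p_k0)
  expect_true(s$rkp_ci[1] <= s$rkp && s$rkp <= s$rkp_ci[2])
  expect_equal(sum(s$spectrum),
               sum(led$circularized & led$knot_label != "0_1", na.rm = TRUE))
  # a knot-free reference makes RKP undefined: reported as NA, not an error
  ref0 <- ref
  ref0$knot_label[ref0$circularized] <- "0_1"
  s0 <- experiment_summary(list(l_x = 50, l_y = 100), led, ref0)
  expect_true(is.na(s0$rkp))
  expect_equal(s0$p_k, s$p_k)
})

test_that("persistence length is recovered from synthetic correlations", {
  # exact discrete worm-like-chain decay, light multiplicative noise
  b <- 0.9609
  for (lp in c(5, 12)) {
    corr <- data.frame(s = 1:30,
                       c = exp(-(1:30) * b / lp))
    expect_equal(persistence_length(corr, bond_length = b), lp,
                 tolerance = 1e-6)
    noisy <- corr
    noisy$c <- noisy$c * exp(with_seed_local(9, rnorm(30, sd = 0.02)))
    expect_equal(persistence_length(noisy, bond_length = b), lp,
                 tolerance = 0.1)
  }
  # a frozen straight chain does not decay: unbounded estimate
  rigid <- data.frame(s = 1:30, c = rep(1, 30))
  expect_error(persistence_length(rigid), "decay")
})
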