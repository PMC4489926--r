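# shared fixtures: tiny parameter sets, a naive O(N^2) energy oracle,
# finite-difference forces, and spliced marked polygons for the
# loop-relevance tests

with_seed_local <- stickyknots:::with_seed_local

tiny_params <- function(n = 10, kappa_bend = 0, internal = NULL,
                        terminal = c(1L, as.integer(n))) {
  model_params(n_beads = n, kappa_bend = kappa_bend,
               sticky_terminal_pair = terminal,
               sticky_internal_pair = internal)
}

# independent energy oracle: plain R double loop over all interactions
naive_total_energy <- function(pos, p, bonded_term = FALSE,
                               bonded_int = FALSE) {
  n <- nrow(pos)
  d <- function(i, j) sqrt(sum((pos[i, ] - pos[j, ])^2))
  e <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) e <- e + wca_pair_energy(d(i, j), p)
  bonds <- cbind(1:(n - 1), 2:n)
  if (bonded_term && !is.null(p$sticky_terminal_pair))
    bonds <- rbind(bonds, p$sticky_terminal_pair)
  if (bonded_int && !is.null(p$sticky_internal_pair))
    bonds <- rbind(bonds, p$sticky_internal_pair)
  for (k in seq_len(nrow(bonds)))
    e <- e + fene_bond_energy(d(bonds[k, 1], bonds[k, 2]), p)
  for (q in list(p$sticky_terminal_pair, p$sticky_internal_pair))
    if (!is.null(q)) e <- e + sticky_pair_energy(d(q[1], q[2]), p)
  if (p$kappa_bend > 0) for (i in 2:(n - 1)) {
    a <- pos[i - 1, ] - pos[i, ]
    b <- pos[i + 1, ] - pos[i, ]
    cr <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
    th <- atan2(sqrt(sum(cr^2)), sum(a * b))
    e <- e + bending_energy(th, p)
  }
  e
}

# central finite differences of the total energy
fd_forces <- function(state, p, h = 1e-5) {
  n <- nrow(state$positions)
  f <- matrix(0, n, 3)
  for (i in seq_len(n)) for (k in 1:3) {
    s1 <- state; s1$positions[i, k] <- s1$positions[i, k] + h
    s2 <- state; s2$positions[i, k] <- s2$positions[i, k] - h
    f[i, k] <- -(total_energy(s1, p) - total_energy(s2, p)) / (2 * h)
  }
  f
}

# a mildly perturbed near-linear chain state that keeps bonds inside the
# FENE range
random_chain_state <- function(p, seed, jitter = 0.08) {
  with_seed_local(seed, {
    n <- p$n_beads
    pos <- cbind(0.97 * (0:(n - 1)), 0, 0) +
      matrix(rnorm(3 * n, sd = jitter), ncol = 3)
    chain_state(pos, matrix(rnorm(3 * n), ncol = 3))
  })
}

# marked polygon with a trefoil spliced into a chosen region: the curve
# runs through a compact trefoil and returns via a distant rectangular
# detour; marks select either the trefoil part or the detour part as the
# sticky loop
spliced_trefoil_polygon <- function(loop_over = c("knot", "detour")) {
  loop_over <- match.arg(loop_over)
  tre <- parametric_knot("3_1", 120)$vertices # extent about 3
  m <- nrow(tre)
  detour <- rbind(c(20, 0, 0), c(20, 20, 0), c(tre[1, 1], 20, 0))
  v <- rbind(tre, detour)
  marked <- if (loop_over == "knot") c(1L, m) else c(m + 1L, m + 3L)
  closed_polygon(v, marked = marked)
}

# random synthetic ledger for the statistics properties (not from runs)
random_ledger <- function(n, seed) {
  with_seed_local(seed, {
    circ <- runif(n) < 0.9
    lab <- ifelse(circ,
                  sample(c("0_1", "3_1", "4_1", "5_2"), n, TRUE,
                         prob = c(0.6, 0.3, 0.07, 0.03)),
                  NA_character_)
    knotted <- !is.na(lab) & lab != "0_1"
    closed <- ifelse(circ, runif(n) < 0.7, NA)
    rel <- ifelse(knotted & closed %in% TRUE, runif(n) < 0.8, NA)
    data.frame(run_id = sprintf("r%04d", seq_len(n)), config_hash = "t",
               seed = seq_len(n), l_x = 50, l_y = 100,
               circularized = circ, censored = !circ,
               steps = 1000, knot_label = lab,
               det_minus1 = NA_real_, det_minus2 = NA_real_,
               loop_closed = closed, relevant = rel, error = "",
               stringsAsFactors = FALSE)
  })
}

knotted_mask_for_test <- function(led) {
  led$circularized & !is.na(led$knot_label) & led$knot_label != "0_1"
}
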