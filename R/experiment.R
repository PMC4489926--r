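#' Enumerate the non-redundant sticky-site placements
#'
#' Arm lengths \code{l_x} (terminus to first internal sticky bead) and
#' \code{l_y} (other terminus to second sticky bead) run over multiples
#' of \code{spacing}; placements with coincident sticky beads
#' (\code{l_x + l_y = n_beads}) are excluded, the sticky loop must span
#' at least one grid spacing, and chain-reversal symmetry is removed by
#' canonicalizing to \code{l_x <= l_y}.  For a 500-bead chain on a
#' 50-bead grid this yields exactly 20 placements.
#'
#' @param n_beads chain length in beads.
#' @param spacing grid spacing in beads (0 < spacing < n_beads / 2).
#' @return data frame with columns \code{l_x}, \code{l_y},
#'   \code{loop_length}, \code{site_x}, \code{site_y} (1-based bead
#'   indices of the internal sticky pair).
#' @export
enumerate_grid <- function(n_beads, spacing) {
  if (spacing <= 0 || spacing >= n_beads / 2)
    stop("spacing must satisfy 0 < spacing < n_beads / 2")
  ls <- seq(spacing, n_beads - spacing, by = spacing)
  g <- expand.grid(l_x = ls, l_y = ls)
  g <- g[g$l_x <= g$l_y, , drop = FALSE]                  # reversal symmetry
  g <- g[g$l_x + g$l_y != n_beads, , drop = FALSE]        # coincident beads
  g$loop_length <- n_beads - g$l_x - g$l_y
  g <- g[g$loop_length >= spacing, , drop = FALSE]        # distinct, ordered
  g$site_x <- g$l_x + 1L
  g$site_y <- n_beads - g$l_y + 1L
  g <- g[order(g$l_x, g$l_y), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Internal sticky pair for a placement
#'
#' @param placement one row of \code{enumerate_grid} output, or a list
#'   with \code{l_x} and \code{l_y}.
#' @param n_beads chain length.
#' @return 1-based index pair \code{c(x, y)}.
#' @export
placement_sites <- function(placement, n_beads) {
  c(as.integer(placement$l_x + 1L),
    as.integer(n_beads - placement$l_y + 1L))
}

#' Run a batch of independent circularization simulations
#'
#' Runs \code{n_runs} independent trajectories with seeds
#' \code{seed_base + 0:(n_runs-1)}; \code{placement = NULL} simulates
#' the reference chain with adhesive termini only (the denominator of
#' the relative knotting probability).  Each outcome is classified
#' (knot type, loop closure, loop relevance) and appended to a ledger
#' data frame; when \code{ledger_path} is given, rows are appended to
#' the CSV as they complete and seeds already present are skipped, so
#' an interrupted campaign can resume.
#'
#' @param placement a row of \code{enumerate_grid}, or \code{NULL} for
#'   the reference chain.
#' @param params base \code{model_params} (its internal pair is
#'   overridden by the placement).
#' @param protocol a \code{run_protocol}; its seed field is ignored in
#'   favour of \code{seed_base + i}.
#' @param n_runs number of independent runs.
#' @param seed_base first seed.
#' @param ledger_path optional CSV path for incremental persistence.
#' @return the batch ledger as a data frame (one row per run).
#' @export
run_batch <- function(placement, params, protocol, n_runs, seed_base,
                      ledger_path = NULL) {
  stopifnot(n_runs >= 1)
  ip <- if (is.null(placement)) NULL
        else placement_sites(placement, params$n_beads)
  params <- model_params(
    n_beads = params$n_beads, sigma = params$sigma, epsilon = params$epsilon,
    mass = params$mass, kappa_fene = params$kappa_fene,
    r0_fene = params$r0_fene, u0_sticky = params$u0_sticky,
    lambda_sticky = params$lambda_sticky, kappa_bend = params$kappa_bend,
    kbt = params$kbt, sticky_internal_pair = ip)
  hash <- config_hash(params, protocol)
  done <- integer(0)
  if (!is.null(ledger_path) && file.exists(ledger_path)) {
    prev <- ledger_load(ledger_path)
    done <- prev$seed[prev$config_hash == hash]
  }
  rows <- vector("list", n_runs)
  for (i in seq_len(n_runs)) {
    seed <- as.integer(seed_base + i - 1)
    if (seed %in% done) next
    prot <- protocol
    prot$seed <- seed
    outcome <- run_until_circularization(params, prot)
    row <- classify_outcome(outcome, params, prot, hash = hash,
                            placement = placement)
    rows[[i]] <- row
    if (!is.null(ledger_path)) ledger_append(row, ledger_path)
  }
  new <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (!is.null(ledger_path)) {
    led <- ledger_load(ledger_path)
    led[led$config_hash == hash &
          led$seed %in% (seed_base + seq_len(n_runs) - 1), , drop = FALSE]
  } else new
}

# one ledger row from a run outcome (topology columns filled for
# circularized runs only)
classify_outcome <- function(outcome, params, protocol, hash = "",
                             placement = NULL) {
  row <- data.frame(
    run_id = sprintf("%s-%08d", hash, outcome$seed),
    config_hash = hash,
    seed = outcome$seed,
    l_x = if (is.null(placement)) NA_real_ else placement$l_x,
    l_y = if (is.null(placement)) NA_real_ else placement$l_y,
    circularized = outcome$circularized,
    censored = outcome$censored,
    steps = outcome$steps_elapsed,
    knot_label = NA_character_,
    det_minus1 = NA_real_, det_minus2 = NA_real_,
    loop_closed = NA, relevant = NA,
    error = outcome$error,
    stringsAsFactors = FALSE)
  if (!outcome$circularized) return(row)
  poly <- close_chain(outcome)
  cls <- classify_polygon(poly, seed = outcome$seed)
  row$knot_label <- cls$label
  row$det_minus1 <- cls$det_minus1
  row$det_minus2 <- cls$det_minus2
  lc <- if (is.null(params$sticky_internal_pair)) NA
        else loop_closed(outcome, params, protocol)
  row$loop_closed <- lc
  if (isTRUE(lc) && cls$label != "0_1") {
    rel <- loop_relevance(poly, cls$label, seed = outcome$seed)
    row$relevant <- identical(as.character(rel), "relevant")
  }
  row
}

#' Wilson score interval for a binomial fraction
#'
#' @param x successes, @param n trials, @param conf confidence level.
#' @return \code{c(lo, hi)}.
#' @export
wilson_interval <- function(x, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Relative knotting probability
#'
#' \deqn{RKP = P_K(l_x, l_y) / P_K^0} where each knotting probability is
#' the fraction of knotted final configurations over the non-censored
#' total.  The confidence interval uses the Katz log method for a ratio
#' of binomial proportions.
#'
#' @param n_knot,n_total knotted count and non-censored total for the
#'   chain with internal sticky beads.
#' @param n_knot_ref,n_total_ref same for the reference chain (sticky
#'   termini only).
#' @param conf confidence level.
#' @return list with \code{estimate}, \code{ci}, and the two knotting
#'   probabilities \code{p_k}, \code{p_k0}.
#' @export
rkp <- function(n_knot, n_total, n_knot_ref, n_total_ref, conf = 0.95) {
  if (n_total <= 0 || n_total_ref <= 0) stop("empty run set")
  if (n_knot_ref == 0)
    stop("undefined RKP: reference sample contains no knots")
  p1 <- n_knot / n_total
  p0 <- n_knot_ref / n_total_ref
  est <- p1 / p0
  ci <- c(NA_real_, NA_real_)
  if (n_knot > 0) {
    z <- qnorm(1 - (1 - conf) / 2)
    se <- sqrt((1 - p1) / n_knot + (1 - p0) / n_knot_ref)
    ci <- exp(log(est) + c(-1, 1) * z * se)
  } else {
    # zero numerator: one-sided upper bound from the Wilson interval
    up <- wilson_interval(0, n_total, conf)[2]
    ci <- c(0, up / p0)
  }
  list(estimate = est, ci = ci, p_k = p1, p_k0 = p0)
}

# knotted = circularized with a non-trivial label
knotted_mask <- function(ledger) {
  ledger$circularized & !is.na(ledger$knot_label) & ledger$knot_label != "0_1"
}

#' Fraction of knotted chains with a closed sticky loop
#'
#' @param ledger a batch ledger data frame.
#' @return FCSL in [0, 1]; errors when no knotted run is present.
#' @export
fcsl <- function(ledger) {
  k <- knotted_mask(ledger)
  if (!any(k)) stop("undefined fraction: no knotted outcomes")
  sum(k & ledger$loop_closed %in% TRUE) / sum(k)
}

#' Fraction of knotted chains with a topologically relevant sticky loop
#'
#' Relevance requires a closed loop, so FTRSL <= FCSL always.
#'
#' @inheritParams fcsl
#' @return FTRSL in [0, 1]; errors when no knotted run is present.
#' @export
ftrsl <- function(ledger) {
  k <- knotted_mask(ledger)
  if (!any(k)) stop("undefined fraction: no knotted outcomes")
  sum(k & ledger$loop_closed %in% TRUE & ledger$relevant %in% TRUE) / sum(k)
}

#' Knot spectrum of a ledger
#'
#' Fractions of each knot type among knotted runs; sums to one.
#'
#' @inheritParams fcsl
#' @param as_fraction return fractions (default) or raw counts.
#' @return named numeric vector.
#' @export
knot_spectrum <- function(ledger, as_fraction = TRUE) {
  k <- knotted_mask(ledger)
  if (!any(k)) stop("empty knot spectrum: no knotted outcomes")
  tab <- table(ledger$knot_label[k])
  out <- as.numeric(tab)
  names(out) <- names(tab)
  if (as_fraction) out / sum(out) else out
}

#' Per-placement experiment summary
#'
#' Aggregates one placement's ledger against the reference ledger:
#' knotting probability with Wilson interval, RKP with Katz interval,
#' FCSL, FTRSL and the knot spectrum.
#'
#' @param placement a row of \code{enumerate_grid}.
#' @param ledger placement batch ledger.
#' @param ref_ledger reference batch ledger.
#' @param conf confidence level.
#' @return list of class \code{experiment_summary}.
#' @export
experiment_summary <- function(placement, ledger, ref_ledger, conf = 0.95) {
  usable <- !ledger$censored
  usable_ref <- !ref_ledger$censored
  nk <- sum(knotted_mask(ledger))
  nk0 <- sum(knotted_mask(ref_ledger))
  # RKP is undefined when the reference shows no knots (the common case
  # for small campaigns); the summary then reports NA rather than failing
  r <- if (nk0 > 0) rkp(nk, sum(usable), nk0, sum(usable_ref), conf = conf)
       else list(estimate = NA_real_, ci = c(NA_real_, NA_real_),
                 p_k = nk / sum(usable), p_k0 = 0)
  structure(list(
    placement = placement,
    n_runs = nrow(ledger), n_censored = sum(ledger$censored),
    p_k = r$p_k, p_k_ci = wilson_interval(nk, sum(usable), conf),
    p_k0 = r$p_k0,
    rkp = r$estimate, rkp_ci = r$ci,
    fcsl = if (nk > 0) fcsl(ledger) else NA_real_,
    ftrsl = if (nk > 0) ftrsl(ledger) else NA_real_,
    spectrum = if (nk > 0) knot_spectrum(ledger, as_fraction = FALSE)
               else numeric(0)),
    class = "experiment_summary")
}

#' Equilibrated open-chain trajectory frames
#'
#' Simulates a plain chain (no sticky interactions at all) and returns
#' sampled frames after an equilibration stretch, as input for the
#' persistence-length estimator.
#'
#' @param params \code{model_params}; sticky pairs are stripped.
#' @param protocol \code{run_protocol}.
#' @param n_steps production steps.
#' @param equil_steps discarded equilibration steps.
#' @param sample_every sampling stride.
#' @return list of N x 3 position matrices.
#' @export
simulate_open_chain <- function(params, protocol, n_steps,
                                equil_steps = n_steps %/% 4,
                                sample_every = 500) {
  params <- model_params(
    n_beads = params$n_beads, sigma = params$sigma, epsilon = params$epsilon,
    mass = params$mass, kappa_fene = params$kappa_fene,
    r0_fene = params$r0_fene, u0_sticky = params$u0_sticky,
    lambda_sticky = params$lambda_sticky, kappa_bend = params$kappa_bend,
    kbt = params$kbt, sticky_terminal_pair = NULL,
    sticky_internal_pair = NULL)
  state <- initial_conformation(params, protocol)
  eq <- run_engine(state, params, protocol, equil_steps,
                   engine_seed = protocol$seed)
  if (nzchar(eq$error)) stop("integration aborted: ", eq$error)
  pr <- run_engine(eq$state, params, protocol, n_steps,
                   sample_every = sample_every, sample_frames = TRUE,
                   engine_seed = protocol$seed + 1)
  if (nzchar(pr$error)) stop("integration aborted: ", pr$error)
  pr$frames
}

#' Bond-vector correlation profile
#'
#' \eqn{\langle \cos\theta(s)\rangle}: the average inner product of unit
#' bond vectors a sequence separation s apart, over beads and frames.
#'
#' @param frames list of N x 3 position matrices.
#' @param s_max largest separation (defaults to half the bond count).
#' @return data frame with columns \code{s} and \code{c}.
#' @export
bond_correlation <- function(frames, s_max = NULL) {
  nb <- nrow(frames[[1]]) - 1
  if (is.null(s_max)) s_max <- nb %/% 2
  acc <- numeric(s_max)
  cnt <- numeric(s_max)
  for (fr in frames) {
    u <- diff(fr)
    u <- u / sqrt(rowSums(u^2))
    for (s in seq_len(s_max)) {
      d <- rowSums(u[1:(nb - s), , drop = FALSE] *
                   u[(1 + s):nb, , drop = FALSE])
      acc[s] <- acc[s] + sum(d)
      cnt[s] <- cnt[s] + length(d)
    }
  }
  data.frame(s = seq_len(s_max), c = acc / cnt)
}

#' Persistence length from bond correlations
#'
#' Fits the exponential decay
#' \eqn{\langle\cos\theta(s)\rangle \propto e^{-s b / l_p}} and returns
#' \eqn{l_p} in units of sigma.  The fit window covers the initial
#' decay only (separations where the correlation stays above
#' \eqn{c(1) e^{-1/2}} and above the noise floor): at larger
#' separations the excluded-volume swelling of a real chain makes the
#' decay slower than exponential, and the correlation estimates become
#' dominated by slowly relaxing chain-scale modes; both effects bias a
#' wide-window fit.  For the discrete worm-like chain,
#' \eqn{l_p / b \approx \kappa_{bend} / k_B T}.
#'
#' @param corr output of \code{bond_correlation} (or a list of frames,
#'   which is converted first).
#' @param bond_length mean bond length b (default the Kremer-Grest
#'   FENE+WCA minimum, about 0.961 sigma).
#' @param floor smallest usable correlation (noise floor).
#' @return persistence length (scalar).
#' @export
persistence_length <- function(corr, bond_length = 0.9609, floor = 0.02) {
  if (is.list(corr) && !is.data.frame(corr)) corr <- bond_correlation(corr)
  if (corr$c[nrow(corr)] > 0.99 || all(abs(diff(corr$c)) < 1e-12))
    stop("unbounded estimate: bond correlations do not decay (rigid rod?)")
  c1 <- corr$c[1]
  if (c1 <= floor) stop("correlation below the noise floor at s = 1")
  thr <- max(floor, c1 * exp(-0.5))
  use <- corr$c > thr
  first_bad <- which(!use)[1] # leading contiguous stretch only
  if (!is.na(first_bad)) use[first_bad:length(use)] <- FALSE
  if (sum(use) < 3) { # very flexible chain: take the first usable points
    use <- corr$c > floor
    first_bad <- which(!use)[1]
    if (!is.na(first_bad)) use[first_bad:length(use)] <- FALSE
    use[which(use)[-seq_len(min(3, sum(use)))]] <- FALSE
  }
  if (sum(use) < 2) stop("too few usable separations for the fit")
  fit <- lm(log(c) ~ s, data = corr[use, , drop = FALSE])
  slope <- coef(fit)[["s"]]
  if (slope >= 0)
    stop("unbounded estimate: bond correlations do not decay (rigid rod?)")
  -bond_length / slope
}
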