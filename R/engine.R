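#' Chain state constructor
#'
#' @param positions N x 3 matrix of bead coordinates.
#' @param velocities N x 3 matrix of bead velocities.
#' @param bonded_termini,bonded_internal permanent adhesion flags.
#' @param step_count MD steps elapsed.
#' @return an object of class \code{chain_state}.
#' @export
chain_state <- function(positions, velocities,
                        bonded_termini = FALSE, bonded_internal = FALSE,
                        step_count = 0) {
  stopifnot(is.matrix(positions), ncol(positions) == 3,
            is.matrix(velocities), all(dim(velocities) == dim(positions)))
  structure(list(positions = positions, velocities = velocities,
                 bonded_termini = bonded_termini,
                 bonded_internal = bonded_internal,
                 step_count = step_count),
            class = "chain_state")
}

#' Initial open, linear conformation
#'
#' Places the beads on a straight line at the mechanical bond-length
#' minimum of the FENE + WCA potential (about 0.97 sigma), adds a small
#' random transverse jitter (below 0.01 sigma) to break the collinear
#' degeneracy of the bending term, and draws Maxwell-Boltzmann
#' velocities at temperature \code{kbt}.  No adhesion flag is set.
#'
#' @param params a \code{model_params} object.
#' @param protocol a \code{run_protocol}; its seed fixes the random
#'   jitter and velocities.
#' @param seed overrides \code{protocol$seed} when given.
#' @return a \code{chain_state}.
#' @export
initial_conformation <- function(params, protocol, seed = NULL) {
  n <- params$n_beads
  if (is.null(seed)) seed <- protocol$seed
  b0 <- equilibrium_bond_length(params)
  with_seed_local(seed, {
    pos <- cbind(x = (seq_len(n) - 1) * b0,
                 y = runif(n, -0.0015, 0.0015) * params$sigma,
                 z = runif(n, -0.0015, 0.0015) * params$sigma)
    vel <- matrix(rnorm(3 * n, sd = sqrt(params$kbt / params$mass)),
                  ncol = 3)
    chain_state(pos, vel)
  })
}

# shared wrapper over the C++ integrator
run_engine <- function(state, params, protocol, n_steps,
                       thermostat = TRUE, sample_every = 0,
                       sample_frames = FALSE,
                       stop_on_circularization = FALSE,
                       engine_seed = NULL) {
  if (is.null(engine_seed)) engine_seed <- protocol$seed
  res <- cpp_run(state$positions, state$velocities, unclass(params),
                 isTRUE(state$bonded_termini), isTRUE(state$bonded_internal),
                 protocol$dt, protocol$gamma, protocol$capture_distance,
                 as.double(n_steps), as.double(engine_seed),
                 thermostat, as.double(sample_every), sample_frames,
                 stop_on_circularization)
  new_state <- chain_state(res$positions, res$velocities,
                           res$bonded_termini, res$bonded_internal,
                           state$step_count + res$steps)
  frames <- NULL
  if (sample_frames && length(res$frames)) {
    n <- params$n_beads
    nf <- length(res$frames) / (3 * n)
    frames <- lapply(seq_len(nf), function(k) {
      matrix(res$frames[((k - 1) * 3 * n + 1):(k * 3 * n)],
             ncol = 3, byrow = TRUE)
    })
  }
  list(state = new_state, steps = res$steps, error = res$error,
       circularized = res$circularized,
       capture_step_terminal = res$capture_step_terminal,
       capture_step_internal = res$capture_step_internal,
       ke_samples = res$ke_samples, frames = frames)
}

#' Advance the chain by Langevin dynamics
#'
#' BAOAB splitting of the Langevin equations at temperature \code{kbt};
#' with \code{gamma = 0} or \code{thermostat = FALSE} the update reduces
#' to velocity Verlet.  Permanent adhesion events are checked at every
#' step.  A fixed engine seed makes the trajectory bitwise reproducible.
#'
#' @param state a \code{chain_state}.
#' @inheritParams initial_conformation
#' @param n_steps number of time steps to integrate.
#' @param thermostat disable to run microcanonical (NVE) dynamics.
#' @param engine_seed seed of the noise stream (defaults to
#'   \code{protocol$seed}).
#' @return the updated \code{chain_state}.
#' @export
langevin_step <- function(state, params, protocol, n_steps = 1,
                          thermostat = TRUE, engine_seed = NULL) {
  out <- run_engine(state, params, protocol, n_steps,
                    thermostat = thermostat, engine_seed = engine_seed)
  if (nzchar(out$error))
    stop("integration aborted: ", out$error, " (time step too large?)")
  out$state
}

#' Apply a permanent adhesion event
#'
#' When the given sticky pair is within \code{capture_distance} and its
#' flag is not yet set, the flag is set and a permanent FENE bond (same
#' constants as the backbone) is considered added between the pair; the
#' Gaussian attraction remains active.  Once set, a flag never unsets,
#' so the call is idempotent.
#'
#' @param state a \code{chain_state}.
#' @param pair \code{"terminal"} or \code{"internal"}.
#' @inheritParams initial_conformation
#' @return the (possibly updated) \code{chain_state}.
#' @export
adhesion_event <- function(state, pair = c("terminal", "internal"),
                           params, protocol) {
  pair <- match.arg(pair)
  idx <- if (pair == "terminal") params$sticky_terminal_pair
         else params$sticky_internal_pair
  flag <- if (pair == "terminal") "bonded_termini" else "bonded_internal"
  if (is.null(idx)) stop("requested sticky pair is absent from the model")
  if (isTRUE(state[[flag]])) return(state)
  d <- sqrt(sum((state$positions[idx[1], ] - state$positions[idx[2], ])^2))
  if (d <= protocol$capture_distance) state[[flag]] <- TRUE
  state
}

#' Simulate until the chain circularizes
#'
#' Starts from a fresh open linear conformation (seeded by
#' \code{protocol$seed}), integrates Langevin dynamics with adhesion
#' checks at every step, and stops at the first terminal adhesion (the
#' circularization event, which freezes the topology) or at
#' \code{max_steps}, whichever comes first.  Internal adhesion never
#' stops a run; whether the sticky loop was closed at termination is
#' recorded.
#'
#' @inheritParams initial_conformation
#' @return an object of class \code{run_outcome} with fields
#'   \code{final_positions}, \code{circularized},
#'   \code{internal_loop_closed_at_end}, \code{censored},
#'   \code{steps_elapsed}, \code{seed} and \code{error} (\code{""} for a
#'   clean run, an error tag for an aborted one).
#' @export
run_until_circularization <- function(params, protocol) {
  state <- initial_conformation(params, protocol)
  out <- run_engine(state, params, protocol, protocol$max_steps,
                    thermostat = TRUE, stop_on_circularization = TRUE)
  circular <- isTRUE(out$circularized)
  structure(list(final_positions = out$state$positions,
                 final_velocities = out$state$velocities,
                 circularized = circular,
                 internal_loop_closed_at_end = isTRUE(out$state$bonded_internal),
                 censored = !circular,
                 steps_elapsed = out$steps,
                 capture_step_internal = out$capture_step_internal,
                 seed = protocol$seed,
                 error = out$error,
                 params = params),
            class = "run_outcome")
}

#' Mean kinetic energy per degree of freedom
#'
#' Diagnostic for the thermostat: at stationarity every degree of
#' freedom carries \code{kbt / 2}.
#'
#' @inheritParams initial_conformation
#' @param state starting \code{chain_state}.
#' @param n_steps total steps to integrate.
#' @param burn_in fraction of samples discarded as equilibration.
#' @param sample_every sampling stride in steps.
#' @return mean kinetic energy per degree of freedom.
#' @export
kinetic_temperature <- function(state, params, protocol, n_steps,
                                burn_in = 0.2, sample_every = 20) {
  out <- run_engine(state, params, protocol, n_steps,
                    sample_every = sample_every)
  if (nzchar(out$error)) stop("integration aborted: ", out$error)
  ke <- out$ke_samples
  nb <- floor(burn_in * length(ke))
  if (nb > 0) ke <- ke[-seq_len(nb)]
  mean(ke) / (3 * params$n_beads) # equals kbt / 2 at stationarity
}
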