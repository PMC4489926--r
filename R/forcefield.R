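#' Pairwise WCA (excluded-volume) energy
#'
#' Purely repulsive truncated-shifted Lennard-Jones potential
#' \deqn{V(r) = 4\epsilon[(\sigma/r)^{12} - (\sigma/r)^6 + 1/4]} for
#' \eqn{r \le 2^{1/6}\sigma} and 0 beyond; continuous at the cutoff.
#' Acts between every distinct bead pair, including bonded neighbours.
#'
#' @param r pair distance(s), must be positive.
#' @param params a \code{model_params} object.
#' @return energy in units of epsilon.
#' @export
wca_pair_energy <- function(r, params) {
  if (any(r <= 0)) stop("pair distance must be positive")
  rc <- 2^(1 / 6) * params$sigma
  sr6 <- (params$sigma / r)^6
  ifelse(r >= rc, 0, 4 * params$epsilon * (sr6^2 - sr6 + 0.25))
}

#' FENE bond energy
#'
#' \deqn{U(d) = -\frac{\kappa}{2}(R_0/\sigma)^2 \ln[1 - (d/R_0)^2]}
#' Monotone increasing in \eqn{d} and divergent as \eqn{d \to R_0};
#' a distance at or beyond \eqn{R_0} signals a broken bond (time step
#' too large) and raises an error.
#'
#' @param d bond length(s) in \code{[0, r0_fene)}.
#' @inheritParams wca_pair_energy
#' @return energy in units of epsilon.
#' @export
fene_bond_energy <- function(d, params) {
  if (any(d < 0)) stop("bond length must be non-negative")
  if (any(d >= params$r0_fene))
    stop("FENE divergence: bond length at or beyond r0_fene")
  -0.5 * params$kappa_fene * (params$r0_fene / params$sigma)^2 *
    log(1 - (d / params$r0_fene)^2)
}

#' Adhesive (sticky) pair energy
#'
#' Attractive Gaussian well between sticky beads of like type:
#' \deqn{G(r) = -U_0 \exp[-(r - 2^{1/6}\sigma)^2 / (2\lambda^2)]} for
#' \eqn{2^{1/6}\sigma \le r \le (2^{1/6}+5)\sigma}, 0 otherwise.  The
#' well is flat at its inner boundary; the small jump at the outer
#' boundary is kept as defined.  It acts only between the terminal pair
#' and between the internal pair, never across pairs.
#'
#' @inheritParams wca_pair_energy
#' @return energy in units of epsilon.
#' @export
sticky_pair_energy <- function(r, params) {
  if (any(r <= 0)) stop("pair distance must be positive")
  rmin <- 2^(1 / 6) * params$sigma
  rmax <- rmin + 5 * params$sigma
  ifelse(r < rmin | r > rmax, 0,
         -params$u0_sticky *
           exp(-(r - rmin)^2 / (2 * params$lambda_sticky^2)))
}

#' Bending energy of a bead triplet
#'
#' Harmonic in the interior angle about the straight configuration:
#' \eqn{(\kappa_{bend}/2)(\theta - \pi)^2}.  Identically zero in the
#' fully flexible regime (\code{kappa_bend = 0}).
#'
#' @param theta triplet angle(s) in \code{[0, pi]}.
#' @inheritParams wca_pair_energy
#' @return energy.
#' @export
bending_energy <- function(theta, params) {
  if (any(theta < -1e-12 | theta > pi + 1e-12))
    stop("theta must lie in [0, pi]")
  0.5 * params$kappa_bend * (theta - pi)^2
}

#' Total potential energy of a chain state
#'
#' Sum of WCA over all unordered bead pairs, FENE over backbone and
#' adhesion bonds, the (at most two) sticky Gaussian wells and the
#' bending term.
#'
#' @param state a \code{chain_state}.
#' @inheritParams wca_pair_energy
#' @param breakdown if \code{TRUE}, return the four terms as well.
#' @return total energy (scalar), or a list of terms.
#' @export
total_energy <- function(state, params, breakdown = FALSE) {
  e <- cpp_energy(state$positions, unclass(params),
                  isTRUE(state$bonded_termini), isTRUE(state$bonded_internal))
  if (!e$ok) stop("FENE divergence: bond length at or beyond r0_fene")
  if (breakdown) e[c("wca", "fene", "stick", "bend", "total")] else e$total
}

#' Forces on every bead
#'
#' Analytic negative gradient of the total potential energy; each term's
#' force is continuous at its cutoff.
#'
#' @inheritParams total_energy
#' @return an N x 3 matrix of forces.
#' @export
chain_forces <- function(state, params) {
  f <- cpp_forces(state$positions, unclass(params),
                  isTRUE(state$bonded_termini), isTRUE(state$bonded_internal))
  if (!f$ok) stop("FENE divergence: bond length at or beyond r0_fene")
  f$forces
}

#' Mechanical equilibrium bond length
#'
#' Numerically minimizes the combined FENE + WCA bond potential; with the
#' standard Kremer-Grest constants the minimum sits near 0.97 sigma.
#'
#' @inheritParams wca_pair_energy
#' @return bond length in units of sigma.
#' @export
equilibrium_bond_length <- function(params) {
  optimize(function(d) fene_bond_energy(d, params) + wca_pair_energy(d, params),
           interval = c(0.5 * params$sigma, params$r0_fene - 1e-9),
           tol = 1e-10)$minimum
}
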