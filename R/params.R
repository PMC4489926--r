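#' Model parameters of the adhesive bead-spring chain
#'
#' Collects every force-field constant of the coarse-grained DNA model in
#' reduced Lennard-Jones units: bead diameter \code{sigma}, energy scale
#' \code{epsilon} and bead mass \code{mass} all default to 1, so times are
#' measured in \code{tau = sigma * sqrt(mass / epsilon)}.  The chain is a
#' Kremer-Grest polymer (WCA excluded volume on all bead pairs, FENE
#' springs between consecutive beads) decorated with up to two pairs of
#' adhesive monomers that attract through a deep short-range Gaussian
#' well.  The terminal pair circularizes the chain; the optional internal
#' pair closes the sticky loop.
#'
#' @param n_beads number of beads (at least 4).
#' @param sigma bead diameter, the length unit.
#' @param epsilon energy unit.
#' @param mass bead mass.
#' @param kappa_fene FENE spring strength (default 30 epsilon).
#' @param r0_fene maximum FENE extension (default 1.5 sigma); must exceed
#'   the WCA minimum \code{2^(1/6) sigma}.
#' @param u0_sticky depth of the adhesive Gaussian well (default
#'   100 epsilon).
#' @param lambda_sticky width of the adhesive well (default 2.5 sigma).
#' @param kappa_bend bending stiffness of the harmonic angle term;
#'   0 selects the fully flexible chain regime ("L"), `10 * kbt` the
#'   semiflexible regime ("S").
#' @param kbt thermal energy (default epsilon).
#' @param sticky_terminal_pair 1-based indices of the circularizing pair,
#'   normally \code{c(1, n_beads)}; \code{NULL} disables it (plain chain).
#' @param sticky_internal_pair 1-based indices of the internal adhesive
#'   pair, strictly between the termini; \code{NULL} for the reference
#'   chain without a sticky loop.
#'
#' @return an object of class \code{model_params}.
#' @export
model_params <- function(n_beads = 500L,
                         sigma = 1, epsilon = 1, mass = 1,
                         kappa_fene = 30 * epsilon,
                         r0_fene = 1.5 * sigma,
                         u0_sticky = 100 * epsilon,
                         lambda_sticky = 2.5 * sigma,
                         kappa_bend = 0,
                         kbt = epsilon,
                         sticky_terminal_pair = c(1L, as.integer(n_beads)),
                         sticky_internal_pair = NULL) {
  p <- list(n_beads = as.integer(n_beads), sigma = sigma, epsilon = epsilon,
            mass = mass, kappa_fene = kappa_fene, r0_fene = r0_fene,
            u0_sticky = u0_sticky, lambda_sticky = lambda_sticky,
            kappa_bend = kappa_bend, kbt = kbt,
            sticky_terminal_pair = if (is.null(sticky_terminal_pair)) NULL
                                   else as.integer(sticky_terminal_pair),
            sticky_internal_pair = if (is.null(sticky_internal_pair)) NULL
                                   else as.integer(sticky_internal_pair))
  class(p) <- "model_params"
  validate_params(p)
  p
}

#' Validate model parameters
#'
#' Checks the structural invariants of the model: positive units, FENE
#' maximum extension beyond the WCA minimum, non-negative bending
#' stiffness, and sticky indices at / strictly inside the termini.
#'
#' @param p a \code{model_params} object.
#' @return \code{p}, invisibly; errors on violation.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "model_params"))
  if (p$n_beads < 4) stop("n_beads must be at least 4")
  for (f in c("sigma", "epsilon", "mass", "kbt"))
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) stop(sprintf("%s must be > 0", f))
  if (p$r0_fene <= 2^(1 / 6) * p$sigma)
    stop("r0_fene must exceed the WCA minimum 2^(1/6)*sigma")
  if (p$kappa_bend < 0) stop("kappa_bend must be >= 0")
  if (!is.null(p$sticky_terminal_pair)) {
    tp <- p$sticky_terminal_pair
    if (length(tp) != 2 || tp[1] != 1L || tp[2] != p$n_beads)
      stop("sticky_terminal_pair must be c(1, n_beads)")
  }
  if (!is.null(p$sticky_internal_pair)) {
    ip <- p$sticky_internal_pair
    if (length(ip) != 2 || ip[1] >= ip[2] || ip[1] <= 1L || ip[2] >= p$n_beads)
      stop("sticky_internal_pair must satisfy 1 < x < y < n_beads")
  }
  invisible(p)
}

#' Integration protocol for a circularization run
#'
#' @param dt integration time step in units of tau (default 0.005).
#' @param gamma Langevin friction rate in 1/tau (default 1).
#' @param capture_distance distance at which an adhesive pair bonds
#'   permanently; must be at least the WCA minimum \code{2^(1/6) sigma}
#'   and should stay clearly below the FENE maximum extension, since the
#'   permanent bond is a FENE spring: capturing at \code{r0_fene} itself
#'   would create a bond at its own divergence length.  The default
#'   1.3 sigma sits deep inside the adhesive well (well depth above
#'   99 epsilon there, far beyond thermal energy).
#' @param max_steps step cap after which a run is recorded as censored.
#' @param seed integer seed; a run is fully reproducible from
#'   (parameters, protocol, seed).
#' @param sample_every sampling stride for diagnostics (0 = no sampling).
#' @return an object of class \code{run_protocol}.
#' @export
run_protocol <- function(dt = 0.005, gamma = 1.0, capture_distance = 1.3,
                         max_steps = 1e9, seed = 1L, sample_every = 0) {
  stopifnot(dt > 0, gamma >= 0, capture_distance >= 2^(1 / 6),
            max_steps > 0, sample_every >= 0)
  structure(list(dt = dt, gamma = gamma,
                 capture_distance = capture_distance,
                 max_steps = max_steps, seed = as.integer(seed),
                 sample_every = sample_every),
            class = "run_protocol")
}

# flatten params + protocol to a named character vector with stable order
flat_config <- function(params, protocol = NULL) {
  enc <- function(x) {
    if (is.null(x)) "NULL" else paste(format(x, digits = 15), collapse = ",")
  }
  kv <- vapply(params[order(names(unclass(params)))], enc, "")
  if (!is.null(protocol)) {
    pv <- vapply(protocol[order(names(unclass(protocol)))], enc, "")
    names(pv) <- paste0("protocol.", names(pv))
    kv <- c(kv, pv)
  }
  kv
}

#' Write / read a run configuration
#'
#' Serializes \code{model_params} (and optionally a \code{run_protocol})
#' to a flat YAML key-value file in reduced units, and back.
#'
#' @param params a \code{model_params} object.
#' @param protocol optional \code{run_protocol}.
#' @param path file path.
#' @return \code{read_config} returns
#'   \code{list(params = ..., protocol = ...)}.
#' @export
write_config <- function(params, protocol = NULL, path) {
  obj <- list(params = unclass(params))
  if (!is.null(protocol)) obj$protocol <- unclass(protocol)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  p <- obj$params
  params <- model_params(
    n_beads = p$n_beads, sigma = p$sigma, epsilon = p$epsilon, mass = p$mass,
    kappa_fene = p$kappa_fene, r0_fene = p$r0_fene, u0_sticky = p$u0_sticky,
    lambda_sticky = p$lambda_sticky, kappa_bend = p$kappa_bend, kbt = p$kbt,
    sticky_terminal_pair = unlist(p$sticky_terminal_pair),
    sticky_internal_pair = unlist(p$sticky_internal_pair))
  protocol <- NULL
  if (!is.null(obj$protocol)) {
    q <- obj$protocol
    protocol <- run_protocol(dt = q$dt, gamma = q$gamma,
                             capture_distance = q$capture_distance,
                             max_steps = q$max_steps, seed = q$seed,
                             sample_every = q$sample_every)
  }
  list(params = params, protocol = protocol)
}

#' Short reproducibility hash of a configuration
#'
#' MD5 of the canonical flat key-value rendering of parameters and
#' protocol (seed excluded, so runs of one campaign share a hash).
#'
#' @inheritParams write_config
#' @return 8-character hash string.
#' @export
config_hash <- function(params, protocol = NULL) {
  kv <- flat_config(params, protocol)
  kv <- kv[names(kv) != "protocol.seed"]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(paste(names(kv), kv, sep = "="), tmp)
  # leading letter keeps the hash an unambiguous string in CSV ledgers
  paste0("h", substr(unname(tools::md5sum(tmp)), 1, 8))
}

# run R code under a fixed RNG seed without disturbing the caller's stream
with_seed_local <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
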