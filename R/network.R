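#' @useDynLib sigmux, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats optim rnorm runif setNames quantile ks.test sd approx
#' @importFrom utils write.csv read.csv
NULL

#' Construct a stochastic reaction network
#'
#' A `ReactionNetwork` couples a list of species, a stoichiometry matrix and
#' per-reaction propensity descriptors with a named parameter vector and a
#' system size `omega` (units L/nM) linking copy numbers `X` to
#' concentrations `x = X / omega`. Propensities are defined on the
#' concentration scale as `f_j(x, t) = k_j * prod(factors)`, where factors
#' are mass-action powers, Hill activation/repression terms, the time-gated
#' stimulus dose, or plain parameters; copy-number propensities are
#' `omega * f(X/omega, t)` (the density-dependent family underlying both the
#' SSA and the linear noise approximation).
#'
#' @param species character vector of unique species names.
#' @param reactions list of reaction descriptors; each a list with fields
#'   `name`, `rate` (parameter name), `reactants` / `products` (named integer
#'   counts; reactants also contribute mass-action factors), and optional
#'   `factors` (extra multiplicative terms, each a list with `type` one of
#'   `"power"`, `"hill_act"`, `"hill_rep"`, a `source` that is a species name,
#'   `"dose"`, or a parameter name, optional `source2` species added to the
#'   source, `K` parameter name and Hill coefficient `h` for Hill terms, and
#'   exponent `n` for powers).
#' @param params named numeric vector/list of positive rate constants
#'   (`theta~` on the natural scale).
#' @param omega system size (> 0).
#' @param variant tag describing the model.
#' @param dose_param name of the parameter gated by the stimulus protocol
#'   (`NA` if the model has no stimulus input).
#' @param init named list giving seed initial concentrations; values may be
#'   numbers or parameter names (resolved at evaluation time so that e.g. a
#'   total-abundance parameter flows into the initial condition).
#' @param provenance optional named character vector documenting the origin
#'   of each parameter value.
#' @return an object of class `ReactionNetwork`.
#' @export
reaction_network <- function(species, reactions, params, omega,
                             variant = "custom", dose_param = NA_character_,
                             init = list(), provenance = NULL) {
  params <- unlist(params)
  stopifnot(is.character(species), length(species) >= 1)
  if (anyDuplicated(species)) stop("species names must be unique")
  if (!all(is.finite(params)) || any(params < 0))
    stop("all parameters must be finite and >= 0")
  if (any(params == 0))
    stop("all parameters theta~ must be > 0 (got zero for: ",
         paste(names(params)[params == 0], collapse = ", "), ")")
  if (!is.numeric(omega) || omega <= 0) stop("omega must be > 0")
  net <- structure(list(
    species = species, reactions = reactions, params = params,
    omega = omega, variant = variant, dose_param = dose_param,
    init = init, provenance = provenance,
    windows = matrix(numeric(0), nrow = 2)
  ), class = "ReactionNetwork")
  enc <- encode_network(net) # validates reaction descriptors
  if (ncol(enc$stoich) != length(reactions))
    stop("stoichiometry must have one column per reaction")
  net
}

#' @export
print.ReactionNetwork <- function(x, ...) {
  cat(sprintf("ReactionNetwork '%s': %d species, %d reactions, omega = %g\n",
              x$variant, length(x$species), length(x$reactions), x$omega))
  cat("species:", paste(x$species, collapse = ", "), "\n")
  cat(sprintf("stimulus windows: %d (dose parameter: %s)\n",
              ncol(x$windows), x$dose_param))
  invisible(x)
}

# Flat numeric encoding consumed by the C++ core.
encode_network <- function(net) {
  sp <- net$species
  pn <- names(net$params)
  d <- length(sp); m <- length(net$reactions)
  stoich <- matrix(0, d, m, dimnames = list(sp, NULL))
  reac_k <- integer(m)
  fac <- list()
  src_code <- function(source) {
    if (identical(source, "dose")) return(0)
    i <- match(source, sp)
    if (!is.na(i)) return(i)
    j <- match(source, pn)
    if (!is.na(j)) return(-j)
    stop("unknown factor source: ", source)
  }
  for (j in seq_len(m)) {
    r <- net$reactions[[j]]
    reac_k[j] <- match(r$rate, pn)
    if (is.na(reac_k[j])) stop("unknown rate parameter: ", r$rate)
    for (s in names(r$reactants)) {
      i <- match(s, sp); if (is.na(i)) stop("unknown reactant species: ", s)
      stoich[i, j] <- stoich[i, j] - r$reactants[[s]]
      fac[[length(fac) + 1]] <- c(j, 1, i, 0, 0, r$reactants[[s]])
    }
    for (s in names(r$products)) {
      i <- match(s, sp); if (is.na(i)) stop("unknown product species: ", s)
      stoich[i, j] <- stoich[i, j] + r$products[[s]]
    }
    for (f in r$factors) {
      type <- match(f$type, c("power", "hill_act", "hill_rep"))
      if (is.na(type)) stop("unknown factor type: ", f$type)
      s1 <- src_code(f$source)
      s2 <- if (!is.null(f$source2)) src_code(f$source2) else 0
      if (s2 < 0) stop("source2 must be a species")
      kidx <- if (type > 1) match(f$K, pn) else 0
      if (type > 1 && is.na(kidx)) stop("unknown Hill constant parameter: ", f$K)
      h <- if (type > 1) f$h else if (!is.null(f$n)) f$n else 1
      fac[[length(fac) + 1]] <- c(j, type, s1, s2, kidx, h)
    }
  }
  factors <- if (length(fac)) do.call(rbind, fac) else matrix(numeric(0), 0, 6)
  dose_idx <- if (is.na(net$dose_param)) 0L else match(net$dose_param, pn)
  list(stoich = stoich, reac_k = reac_k, factors = factors,
       dose_idx = as.integer(dose_idx), windows = net$windows)
}

#' Stoichiometry matrix of a network
#' @param net a `ReactionNetwork`.
#' @return integer matrix, species by reactions.
#' @export
stoichiometry <- function(net) encode_network(net)$stoich

#' Evaluate reaction propensities
#'
#' Copy-number propensities `a_j(X, t) = omega * f_j(X/omega, t)`; a reaction
#' consuming an absent species has zero propensity.
#'
#' @param net a `ReactionNetwork` (stimulus windows as currently applied).
#' @param state nonnegative copy-number vector, one entry per species.
#' @param t time (minutes).
#' @return nonnegative per-reaction rate vector.
#' @export
propensities <- function(net, state, t = 0) {
  if (length(state) != length(net$species))
    stop("state must have one entry per species")
  if (any(state < 0)) stop("negative state entries are not allowed")
  enc <- encode_network(net)
  a <- net$omega * as.numeric(cpp_rates(enc, net$params, state / net$omega, t))
  setNames(a, vapply(net$reactions, function(r) r$name %||% "", ""))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Macroscopic drift and diffusion fields
#'
#' Returns the drift `F(x) = nu a(x)` and diffusion `D(x) = nu diag(a(x))
#' nu'` of the system-size expansion, on the concentration scale (`D` is the
#' coefficient of `omega^-1` in the LNA covariance equation).
#'
#' @param net a `ReactionNetwork`.
#' @param x nonnegative concentration vector.
#' @param t time (minutes).
#' @return list with `F` (drift vector), `D` (symmetric PSD diffusion
#'   matrix), and the Jacobian `J = dF/dx`.
#' @export
macroscopic_fields <- function(net, x, t = 0) {
  if (length(x) != length(net$species)) stop("dimension mismatch: x vs species")
  if (any(x < 0)) stop("x must be nonnegative")
  enc <- encode_network(net)
  out <- cpp_drift_jac(enc, net$params, x, t)
  list(F = setNames(as.numeric(out$F), net$species),
       D = 0.5 * (out$D + t(out$D)), J = out$J)
}

#' Describe a stimulus protocol
#'
#' @param kind one of `"continuous"`, `"single_pulse"`, `"pulse_train"`,
#'   `"unstimulated"`.
#' @param dose stimulus level while on (model dose-parameter units); `NULL`
#'   keeps the network's current dose parameter.
#' @param pulse_length pulse duration (min), for pulse kinds.
#' @param period pulse repeat period (min), for `pulse_train`.
#' @param horizon end of the experiment (min).
#' @return object of class `StimulusProtocol`.
#' @export
stimulus_protocol <- function(kind = c("continuous", "single_pulse",
                                       "pulse_train", "unstimulated"),
                              dose = NULL, pulse_length = 5, period = 100,
                              horizon = 500) {
  kind <- match.arg(kind)
  if (horizon < 0 || pulse_length < 0 || period < 0)
    stop("negative times are not allowed")
  if (!is.null(dose) && dose < 0) stop("dose must be >= 0")
  if (kind == "pulse_train" && pulse_length > period)
    stop("pulse_length must be <= period for a pulse train")
  structure(list(kind = kind, dose = dose, pulse_length = pulse_length,
                 period = period, horizon = horizon),
            class = "StimulusProtocol")
}

#' Stimulation windows of a protocol
#' @param protocol a `StimulusProtocol`.
#' @return 2 x n matrix of `[start; end)` windows.
#' @export
protocol_windows <- function(protocol) {
  with(protocol, switch(kind,
    unstimulated = matrix(numeric(0), nrow = 2),
    continuous = matrix(c(0, horizon), nrow = 2),
    single_pulse = matrix(c(0, min(pulse_length, horizon)), nrow = 2),
    pulse_train = {
      starts <- seq(0, horizon, by = period)
      starts <- starts[starts < horizon]
      rbind(starts, pmin(starts + pulse_length, horizon))
    }))
}

#' Dose level of a protocol-carrying network at a time point
#' @param net network with protocol applied.
#' @param t time (min), vectorised.
#' @return dose value(s), 0 outside stimulation windows.
#' @export
dose_at <- function(net, t) {
  if (any(t < 0)) stop("negative times are not allowed")
  dose <- if (is.na(net$dose_param)) 0 else net$params[[net$dose_param]]
  on <- vapply(t, function(tt)
    any(net$windows[1, ] <= tt & tt < net$windows[2, ]), logical(1))
  ifelse(on, dose, 0)
}

#' Apply a stimulus protocol to a network
#'
#' Sets the time-dependence of the dose parameter: `dose(t) = dose * 1[t in
#' stimulation windows]`, with instantaneous step edges.
#'
#' @param net a `ReactionNetwork`.
#' @param protocol a `StimulusProtocol`.
#' @return the network with stimulation windows (and, if the protocol states
#'   one, dose level) set.
#' @export
apply_protocol <- function(net, protocol) {
  stopifnot(inherits(protocol, "StimulusProtocol"))
  net$windows <- unname(protocol_windows(protocol))
  if (!is.null(protocol$dose)) {
    if (is.na(net$dose_param)) stop("network has no dose parameter")
    net$params[[net$dose_param]] <- protocol$dose
  }
  net$protocol <- protocol
  net
}

#' Scaled (log) parameter space
#'
#' Works in `theta_j = log theta~_j`, so that additive changes `delta theta`
#' correspond to relative changes of the natural-scale parameters.
#'
#' @param net a `ReactionNetwork`.
#' @param selection character vector of parameter names treated as signals.
#' @return object of class `ParameterSpace` with `names`, `theta0` (log
#'   scale) and `selection`.
#' @export
parameter_space <- function(net, selection = names(net$params)) {
  if (!all(selection %in% names(net$params)))
    stop("selection must be a subset of parameter names")
  structure(list(names = names(net$params),
                 theta0 = log(net$params), selection = selection),
            class = "ParameterSpace")
}

#' Construct a parameter/signal space directly
#'
#' Like [parameter_space()] but from an explicit base point; useful for
#' synthetic Gaussian signal models.
#'
#' @param theta0 named numeric vector of scaled (log) coordinates.
#' @param selection subset treated as signals (default all).
#' @return a `ParameterSpace`.
#' @export
signal_space <- function(theta0, selection = names(theta0)) {
  if (is.null(names(theta0))) stop("theta0 must be named")
  if (!all(selection %in% names(theta0)))
    stop("selection must be a subset of names(theta0)")
  structure(list(names = names(theta0), theta0 = theta0,
                 selection = selection), class = "ParameterSpace")
}

#' Replace network parameters from scaled coordinates
#' @param net a `ReactionNetwork`.
#' @param theta named (or `pspace`-ordered) vector of log-scale parameters;
#'   may cover a subset of parameters.
#' @return network with `params = exp(theta)` substituted.
#' @export
set_scaled_params <- function(net, theta) {
  if (is.null(names(theta))) stop("theta must be named")
  bad <- setdiff(names(theta), names(net$params))
  if (length(bad)) stop("unknown parameters: ", paste(bad, collapse = ", "))
  net$params[names(theta)] <- exp(theta)
  net
}

#' Initial (seed) state of a network
#' @param net a `ReactionNetwork`.
#' @return named concentration vector, `init` entries resolved against the
#'   current parameters, other species 0.
#' @export
initial_state <- function(net) {
  x0 <- setNames(numeric(length(net$species)), net$species)
  for (s in names(net$init)) {
    v <- net$init[[s]]
    x0[[s]] <- if (is.character(v)) net$params[[v]] else v
  }
  x0
}
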