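# Phase-corrected Linear Noise Approximation: joint Gaussian ensembles along
# the deterministic orbit, transversal-section projection, and fast
# stochastic simulation by section re-anchoring.

# symmetric PSD square root (eigenvalues clamped at zero)
msqrt <- function(M) {
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

new_gaussian_ensemble <- function(mean, cov, schedule = NULL, species = NULL,
                                  omega = NA_real_, params = NULL,
                                  internals = NULL, coords = "state") {
  cov <- (cov + t(cov)) / 2
  structure(list(mean = mean, cov = cov, schedule = schedule,
                 species = species, omega = omega, params = params,
                 internals = internals, coords = coords),
            class = "GaussianEnsemble")
}

#' Construct a Gaussian ensemble directly
#'
#' Mostly useful for tests and for wrapping externally computed moments in
#' the container used by the information-geometry operations.
#'
#' @param mean mean vector.
#' @param cov covariance matrix (symmetrised on input).
#' @param schedule optional `ObservationSchedule`.
#' @param species optional species names (coordinates are species x times).
#' @return a `GaussianEnsemble`.
#' @export
gaussian_ensemble <- function(mean, cov, schedule = NULL, species = NULL) {
  if (length(mean) != nrow(cov) || nrow(cov) != ncol(cov))
    stop("dimension mismatch between mean and cov")
  new_gaussian_ensemble(mean, cov, schedule, species)
}

#' @export
print.GaussianEnsemble <- function(x, ...) {
  cat(sprintf("GaussianEnsemble: dim %d (%s coordinates)", length(x$mean),
              x$coords))
  if (!is.null(x$schedule)) cat(sprintf(", q = %d times", x$schedule$q))
  cat("\n")
  invisible(x)
}

#' Propagate the (phase-corrected) LNA
#'
#' Computes the joint Gaussian `P_S(R)` of the state at all scheduled times:
#' the mean follows the macroscopic solution, the covariance solves
#' `dV/dt = J V + V J' + D/omega` and cross-time blocks are propagated
#' through the fundamental matrix of the variational equation. With
#' `phase_correct = TRUE` (the pcLNA), the Gaussian is re-anchored at every
#' scheduled time by projecting out the flow direction on the transversal
#' section, which removes accumulated phase variance before propagation
#' continues.
#'
#' @param net a `ReactionNetwork`.
#' @param protocol optional `StimulusProtocol`.
#' @param schedule an `ObservationSchedule`.
#' @param omega system size override (default `net$omega`).
#' @param x0 initial concentrations (default unstimulated steady state).
#' @param phase_correct apply the transversal-section correction.
#' @param rtol,atol solver tolerances.
#' @return a `GaussianEnsemble` over (species x scheduled times),
#'   concentration scale.
#' @export
propagate_lna <- function(net, protocol = NULL, schedule, omega = net$omega,
                          x0 = NULL, phase_correct = TRUE,
                          rtol = 1e-7, atol = 1e-10) {
  if (!inherits(schedule, "ObservationSchedule"))
    stop("schedule must be an ObservationSchedule")
  if (!is.null(protocol)) {
    net <- apply_protocol(net, protocol)
    if (max(schedule$times) > protocol$horizon)
      stop("schedule extends beyond the protocol horizon")
  }
  if (is.null(x0)) x0 <- steady_state(net)
  d <- length(net$species); q <- schedule$q
  enc <- encode_network(net)
  lna <- cpp_lna(enc, net$params, x0, 0, schedule$times, omega, rtol, atol)
  xs <- lna$xs; Fs <- lna$Fs
  proj <- vector("list", q)
  for (k in seq_len(q)) {
    f <- Fs[k, ]
    nf <- sqrt(sum(f^2))
    if (phase_correct) {
      if (nf < 1e-12 * (1 + sqrt(sum(xs[k, ]^2))))
        stop("zero flow vector at scheduled time ", schedule$times[k],
             ": no transversal direction")
      proj[[k]] <- diag(d) - tcrossprod(f) / nf^2
    } else proj[[k]] <- diag(d)
  }
  # marginal recursion with per-time correction
  Vp <- vector("list", q)
  Vm <- proj[[1]] %*% lna$Q[[1]] %*% proj[[1]]
  Vp[[1]] <- Vm
  if (q > 1) for (k in 2:q) {
    V <- lna$Phi[[k]] %*% Vp[[k - 1]] %*% t(lna$Phi[[k]]) + lna$Q[[k]]
    Vp[[k]] <- proj[[k]] %*% ((V + t(V)) / 2) %*% proj[[k]]
  }
  # joint covariance blocks
  Sigma <- matrix(0, d * q, d * q)
  idx <- function(k) ((k - 1) * d + 1):(k * d)
  for (k in seq_len(q)) {
    Sigma[idx(k), idx(k)] <- Vp[[k]]
    if (k < q) {
      C <- Vp[[k]]
      for (l in (k + 1):q) {
        C <- proj[[l]] %*% lna$Phi[[l]] %*% C
        Sigma[idx(l), idx(k)] <- C
        Sigma[idx(k), idx(l)] <- t(C)
      }
    }
  }
  mu <- as.numeric(t(xs))
  names(mu) <- paste(rep(net$species, q), rep(seq_len(q), each = d), sep = ".t")
  internals <- list(xs = xs, Fs = Fs, Phi = lna$Phi, Q = lna$Q, Vp = Vp,
                    proj = proj, phase_correct = phase_correct, d = d)
  new_gaussian_ensemble(mu, Sigma, schedule, net$species, omega,
                        log(net$params), internals)
}

#' Transversal section of the flow
#'
#' The hyperplane through `anchor` orthogonal to the flow vector there, with
#' an orthonormal basis of the section returned as columns.
#'
#' @param anchor point on the deterministic orbit.
#' @param flow drift vector `F(anchor)`.
#' @return object of class `TransversalSection` with `anchor`, unit `normal`
#'   and `basis` (d x (d-1), orthonormal, orthogonal to `normal`).
#' @export
transversal_section <- function(anchor, flow) {
  nf <- sqrt(sum(flow^2))
  if (nf < 1e-12 * (1 + sqrt(sum(anchor^2))))
    stop("zero flow vector at anchor: no transversal direction")
  d <- length(anchor)
  n <- flow / nf
  Qfull <- qr.Q(qr(cbind(n, diag(d))), complete = FALSE)[, 1:d, drop = FALSE]
  basis <- Qfull[, -1, drop = FALSE]
  # orient deterministically: first nonzero entry of each column positive
  for (j in seq_len(ncol(basis))) {
    i <- which(abs(basis[, j]) > 1e-12)[1]
    if (!is.na(i) && basis[i, j] < 0) basis[, j] <- -basis[, j]
  }
  structure(list(anchor = anchor, normal = n, basis = basis),
            class = "TransversalSection")
}

#' Sections at all scheduled times of a propagated ensemble
#' @param ens ensemble from [propagate_lna()].
#' @return list of `TransversalSection`, one per scheduled time.
#' @export
ensemble_sections <- function(ens) {
  if (is.null(ens$internals)) stop("ensemble has no propagation internals")
  lapply(seq_len(ens$schedule$q), function(k)
    transversal_section(ens$internals$xs[k, ], ens$internals$Fs[k, ]))
}

#' Project a Gaussian ensemble onto transversal-section coordinates
#'
#' Restricts the Gaussian to the hyperplane transversal to the flow,
#' expressed in the orthonormal section basis; the dimension drops by one
#' per time point because the phase (flow) direction is removed.
#'
#' @param ens a `GaussianEnsemble`. Either a single-time ensemble together
#'   with an explicit `section`, or a propagated ensemble (then the section
#'   at each scheduled time is used and `section` must be `NULL`).
#' @param section optional `TransversalSection` for the single-time case.
#' @return a `GaussianEnsemble` in section coordinates.
#' @export
section_project <- function(ens, section = NULL) {
  if (!is.null(section)) {
    d <- length(section$anchor)
    if (length(ens$mean) %% d != 0 || length(ens$mean) != d)
      stop("explicit-section projection expects a single-time ensemble")
    B <- section$basis
    new_gaussian_ensemble(drop(t(B) %*% (ens$mean - section$anchor)),
                          t(B) %*% ens$cov %*% B,
                          ens$schedule, NULL, ens$omega, ens$params,
                          coords = "section")
  } else {
    if (is.null(ens$internals)) stop("need either a section or internals")
    d <- ens$internals$d; q <- ens$schedule$q
    secs <- ensemble_sections(ens)
    B <- matrix(0, d * q, (d - 1) * q)
    mu <- numeric((d - 1) * q)
    for (k in seq_len(q)) {
      rows <- ((k - 1) * d + 1):(k * d)
      cols <- ((k - 1) * (d - 1) + 1):(k * (d - 1))
      B[rows, cols] <- secs[[k]]$basis
      mu[cols] <- t(secs[[k]]$basis) %*%
        (ens$mean[rows] - secs[[k]]$anchor)
    }
    new_gaussian_ensemble(mu, t(B) %*% ens$cov %*% B, ens$schedule,
                          NULL, ens$omega, ens$params,
                          internals = list(sections = secs, d = d),
                          coords = "section")
  }
}

#' Subset an ensemble to observed species / times
#' @param ens propagated `GaussianEnsemble` (state coordinates).
#' @param species species names to keep (default all).
#' @param times indices of scheduled times to keep (default all).
#' @return the restricted `GaussianEnsemble`.
#' @export
observe_ensemble <- function(ens, species = NULL, times = NULL) {
  if (is.null(ens$species)) stop("ensemble has no species coordinates")
  d <- length(ens$species); q <- length(ens$mean) / d
  if (is.null(species)) species <- ens$species
  if (is.null(times)) times <- seq_len(q)
  si <- match(species, ens$species)
  if (anyNA(si)) stop("unknown species")
  keep <- as.integer(outer(si, (times - 1) * d, `+`))
  new_gaussian_ensemble(ens$mean[keep], ens$cov[keep, keep, drop = FALSE],
                        ens$schedule, species, ens$omega, ens$params)
}

#' Simulate by phase-corrected LNA sampling
#'
#' Draws `n` trajectories of the scheduled states: at each scheduled phase
#' the deviation is sampled from the section-projected Gaussian, re-anchored
#' on the section, and propagated to the next phase through the fundamental
#' matrix plus fresh process noise. Copy numbers are returned; negative
#' samples (possible for low-copy coordinates) are truncated at zero and the
#' truncation count attached as attribute `"truncated"`.
#'
#' @param net a `ReactionNetwork`.
#' @param protocol optional `StimulusProtocol`.
#' @param schedule an `ObservationSchedule`.
#' @param n number of trajectories (>= 1).
#' @param seed optional RNG seed (reproducible runs).
#' @param omega system size override.
#' @param ens optionally a pre-computed ensemble from [propagate_lna()]
#'   (saves re-propagation).
#' @return array `n x species x q` of copy numbers.
#' @export
pclna_simulate <- function(net, protocol = NULL, schedule, n, seed = NULL,
                           omega = net$omega, ens = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ens))
    ens <- propagate_lna(net, protocol, schedule, omega = omega)
  int <- ens$internals
  d <- int$d; q <- ens$schedule$q
  out <- array(NA_real_, c(n, d, q),
               dimnames = list(NULL, ens$species, NULL))
  ntrunc <- 0L
  xi <- matrix(rnorm(n * d), n, d) %*% msqrt(int$Q[[1]])
  xi <- xi %*% int$proj[[1]] # projector symmetric
  for (k in seq_len(q)) {
    if (k > 1) {
      xi <- xi %*% t(int$Phi[[k]]) +
        matrix(rnorm(n * d), n, d) %*% msqrt(int$Q[[k]])
      xi <- xi %*% int$proj[[k]]
    }
    X <- ens$omega * sweep(xi, 2, int$xs[k, ], `+`)
    ntrunc <- ntrunc + sum(X < 0)
    X[X < 0] <- 0
    out[, , k] <- X
  }
  attr(out, "truncated") <- ntrunc
  out
}
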