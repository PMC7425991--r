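# Information geometry: Gaussian KL divergences, Neyman-Pearson likelihood
# ratio tests, the Fisher information matrix in log-parameter coordinates,
# and its factorisation I = s's into the sensitivity matrix.

ens_moments <- function(x) {
  if (inherits(x, "GaussianEnsemble")) list(mean = x$mean, cov = x$cov)
  else if (is.list(x) && !is.null(x$mean) && !is.null(x$cov)) x
  else stop("expected a GaussianEnsemble or a list(mean, cov)")
}

# eigenvalue-floored pseudo-inverse and log pseudo-determinant
floored_inverse <- function(S, floor_rel = 1e-10) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lmax <- max(e$values, 0)
  if (lmax <= 0) stop("covariance is identically zero")
  keep <- e$values > floor_rel * lmax
  inv <- e$vectors[, keep, drop = FALSE] %*%
    (t(e$vectors[, keep, drop = FALSE]) / e$values[keep])
  list(inv = inv, logdet = sum(log(e$values[keep])), rank = sum(keep),
       condition = lmax / min(e$values[keep]),
       values = e$values, vectors = e$vectors, keep = keep)
}

#' Kullback-Leibler divergence between Gaussian ensembles
#'
#' Exact closed-form `D_KL(P || Q)` for multivariate Gaussians. A singular
#' `Q` covariance is handled by an eigenvalue-floored pseudo-inverse (the
#' divergence is then computed on the common support); the condition number
#' used is attached as attribute `"condition"`.
#'
#' @param P,Q `GaussianEnsemble`s (or lists with `mean` and `cov`) of equal
#'   dimension.
#' @param bits return the divergence in bits instead of nats.
#' @param floor_rel relative eigenvalue floor for the pseudo-inverse.
#' @return divergence (nats by default).
#' @export
gaussian_kl <- function(P, Q, bits = FALSE, floor_rel = 1e-10) {
  P <- ens_moments(P); Q <- ens_moments(Q)
  if (length(P$mean) != length(Q$mean)) stop("dimension mismatch")
  k <- length(P$mean)
  fq <- floored_inverse(Q$cov, floor_rel)
  fp <- floored_inverse(P$cov, floor_rel)
  dm <- P$mean - Q$mean
  kl <- 0.5 * (sum(fq$inv * P$cov) +
               drop(t(dm) %*% fq$inv %*% dm) - fq$rank +
               fq$logdet - fp$logdet)
  kl <- max(kl, 0)
  if (bits) kl <- kl / log(2)
  attr(kl, "condition") <- fq$condition
  kl
}

log_dens_gauss <- function(x, mean, finv) {
  # x: matrix n x d; finv from floored_inverse
  dm <- sweep(x, 2, mean)
  -0.5 * (finv$rank * log(2 * pi) + finv$logdet +
            rowSums((dm %*% finv$inv) * dm))
}

#' Neyman-Pearson likelihood-ratio test specification
#'
#' @param null,alternative `GaussianEnsemble`s for the two simple
#'   hypotheses.
#' @param alpha false-positive rate in (0, 1).
#' @return object of class `DecisionTest`.
#' @export
decision_test <- function(null, alternative, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)")
  structure(list(null = ens_moments(null), alt = ens_moments(alternative),
                 alpha = alpha), class = "DecisionTest")
}

#' Power of the most powerful level-alpha test
#'
#' Thresholds the log-likelihood ratio `lambda(R) = log P_alt(R)/P_null(R)`
#' at the Monte-Carlo `(1 - alpha)` quantile of `lambda` under the null, and
#' estimates the power as `P_alt(lambda >= u_alpha)`.
#'
#' @param test a `DecisionTest`.
#' @param n_mc Monte-Carlo sample size per hypothesis.
#' @param seed optional RNG seed.
#' @return power estimate with attributes `u_alpha` and `alpha`.
#' @export
lr_test_power <- function(test, n_mc = 20000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(test$null$mean)
  f0 <- floored_inverse(test$null$cov)
  f1 <- floored_inverse(test$alt$cov)
  draw <- function(m, S, n)
    sweep(matrix(rnorm(n * d), n, d) %*% msqrt(S), 2, m, `+`)
  lam <- function(x) log_dens_gauss(x, test$alt$mean, f1) -
    log_dens_gauss(x, test$null$mean, f0)
  l0 <- lam(draw(test$null$mean, test$null$cov, n_mc))
  l1 <- lam(draw(test$alt$mean, test$alt$cov, n_mc))
  u <- quantile(l0, 1 - test$alpha, names = FALSE)
  # randomised Neyman-Pearson tie handling (exact size even when lambda has
  # atoms, e.g. identical hypotheses where lambda = 0 a.s.)
  p_gt <- mean(l0 > u); p_eq <- mean(l0 == u)
  gamma <- if (p_eq > 0) (test$alpha - p_gt) / p_eq else 0
  gamma <- min(max(gamma, 0), 1)
  p <- mean(l1 > u) + gamma * mean(l1 == u)
  attr(p, "u_alpha") <- u
  attr(p, "alpha") <- test$alpha
  p
}

#' Fisher information matrix in scaled (log) parameters
#'
#' Gaussian-family FIM at `theta0`:
#' `I_ij = dmu_i' Sinv dmu_j + tr(Sinv dS_i Sinv dS_j)/2`, with the mean and
#' covariance derivatives obtained by central finite differences in the
#' scaled coordinates `theta = log(theta~)` (steps are relative parameter
#' changes). Near-singular covariances (e.g. after section projection) use
#' an eigenvalue-floored pseudo-inverse.
#'
#' @param ensemble_fn function mapping a named log-parameter vector over
#'   `pspace$selection` to a `GaussianEnsemble` (or `list(mean, cov)`).
#' @param pspace a `ParameterSpace`.
#' @param fd_step central-difference step in log-parameters (relative
#'   change).
#' @param check_step if `TRUE`, recompute at `fd_step/2` and attach the
#'   maximum relative discrepancy as attribute `"step_check"` (Richardson
#'   self-check).
#' @param floor_rel eigenvalue floor for the covariance pseudo-inverse.
#' @return object of class `FisherInformation`: `I` (symmetric PSD matrix
#'   over the selection), `theta0`, `fd_step`, `names`.
#' @export
fim <- function(ensemble_fn, pspace, fd_step = 1e-3, check_step = FALSE,
                floor_rel = 1e-10) {
  sel <- pspace$selection
  s <- length(sel)
  th0 <- pspace$theta0[sel]
  base <- ens_moments(ensemble_fn(th0))
  finv <- floored_inverse(base$cov, floor_rel)
  one_fim <- function(h) {
    dmu <- matrix(0, length(base$mean), s)
    dSg <- vector("list", s)
    for (j in seq_len(s)) {
      tp <- th0; tp[sel[j]] <- tp[sel[j]] + h
      tm <- th0; tm[sel[j]] <- tm[sel[j]] - h
      ep <- ens_moments(ensemble_fn(tp)); em <- ens_moments(ensemble_fn(tm))
      if (!all(is.finite(ep$mean)) || !all(is.finite(em$mean)) ||
          !all(is.finite(ep$cov)) || !all(is.finite(em$cov)))
        stop("non-finite finite differences for parameter ", sel[j])
      dmu[, j] <- (ep$mean - em$mean) / (2 * h)
      dSg[[j]] <- (ep$cov - em$cov) / (2 * h)
    }
    I <- matrix(0, s, s, dimnames = list(sel, sel))
    A <- lapply(dSg, function(D) finv$inv %*% D)
    for (i in seq_len(s)) for (j in i:s) {
      v <- drop(t(dmu[, i]) %*% finv$inv %*% dmu[, j]) +
        0.5 * sum(t(A[[i]]) * A[[j]])
      I[i, j] <- v; I[j, i] <- v
    }
    I
  }
  I <- one_fim(fd_step)
  out <- structure(list(I = (I + t(I)) / 2, theta0 = th0, fd_step = fd_step,
                        names = sel), class = "FisherInformation")
  if (check_step) {
    I2 <- one_fim(fd_step / 2)
    attr(out, "step_check") <- max(abs(I2 - I)) / max(abs(I))
  }
  out
}

#' @export
print.FisherInformation <- function(x, ...) {
  cat(sprintf("FisherInformation over %d parameters (fd_step %g)\n",
              length(x$names), x$fd_step))
  cat("eigenvalues:", signif(eigen(x$I, symmetric = TRUE,
                                   only.values = TRUE)$values, 4), "\n")
  invisible(x)
}

#' Quadratic KL expansion
#'
#' The local divergence `D_KL(P_{S0+dS} || P_{S0}) = dS' I dS / 2`, exact up
#' to third-order terms in `dS`.
#'
#' @param I a `FisherInformation` (or plain matrix).
#' @param dS perturbation vector.
#' @return divergence (nats).
#' @export
quadratic_kl <- function(I, dS) {
  M <- if (inherits(I, "FisherInformation")) I$I else I
  if (length(dS) != nrow(M)) stop("dimension mismatch")
  0.5 * drop(t(dS) %*% M %*% dS)
}

#' Sensitivity matrix s with I = s's
#'
#' Factorises the FIM by a pivoted Cholesky decomposition; any factor with
#' `s's = I` yields identical multiplexing quantities (they depend only on
#' the Gram matrix), so the Cholesky factor is used and can be cross-checked
#' against the symmetric square root. Columns `s_j` are the principal
#' sensitivity coefficients of parameter `j`; singular values are attached.
#'
#' @param I a `FisherInformation` (or symmetric PSD matrix).
#' @param method `"cholesky"` (pivoted) or `"sqrt"` (symmetric square root).
#' @return object of class `SensitivityMatrix` with `s`, singular values
#'   `sv`, and parameter `names`.
#' @export
sensitivity_factor <- function(I, method = c("cholesky", "sqrt")) {
  method <- match.arg(method)
  M <- if (inherits(I, "FisherInformation")) I$I else I
  nm <- if (inherits(I, "FisherInformation")) I$names else colnames(M)
  M <- (M + t(M)) / 2
  ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev)))
    stop("FIM is indefinite beyond tolerance; cannot factor")
  if (method == "cholesky") {
    R <- suppressWarnings(chol(M, pivot = TRUE))
    piv <- attr(R, "pivot")
    s <- R[, order(piv), drop = FALSE]
  } else {
    s <- msqrt(M)
  }
  colnames(s) <- nm
  structure(list(s = s, sv = svd(s)$d, names = nm),
            class = "SensitivityMatrix")
}

#' @export
print.SensitivityMatrix <- function(x, ...) {
  cat(sprintf("SensitivityMatrix %d x %d; singular values: %s\n",
              nrow(x$s), ncol(x$s), paste(signif(x$sv, 4), collapse = ", ")))
  invisible(x)
}

#' Ensemble map for a model over scaled parameters
#'
#' Builds the `theta -> GaussianEnsemble` map used by [fim()]: for each
#' scaled parameter vector it recomputes the unstimulated steady state
#' (parameters entering the initial condition propagate), propagates the
#' pcLNA along the protocol, and expresses the ensemble in observation
#' coordinates fixed at `theta0` - by default transversal-section
#' coordinates (dimension `(d-1)` per scheduled time), which keep the
#' phase-corrected covariance nonsingular and make ensembles at different
#' parameters directly comparable.
#'
#' @param net a `ReactionNetwork`.
#' @param protocol a `StimulusProtocol`.
#' @param schedule an `ObservationSchedule`.
#' @param pspace a `ParameterSpace` for the model.
#' @param coords `"section"` (default) or `"state"` (raw species
#'   coordinates).
#' @param observed species kept when `coords = "state"`.
#' @param phase_correct apply the pcLNA phase correction.
#' @param x0 fixed initial concentrations; default recomputes the
#'   unstimulated steady state at every parameter value (use a fixed `x0`
#'   for autonomous oscillators, whose long-run state has no
#'   parameter-continuous limit).
#' @return function mapping a named log-parameter vector (over any subset of
#'   parameters) to a `list(mean, cov)`.
#' @export
model_ensemble_fn <- function(net, protocol, schedule, pspace,
                              coords = c("section", "state"),
                              observed = NULL, phase_correct = TRUE,
                              x0 = NULL) {
  coords <- match.arg(coords)
  net0 <- apply_protocol(net, protocol)
  ref <- propagate_lna(net0, NULL, schedule, phase_correct = phase_correct,
                       x0 = x0)
  d <- ref$internals$d; q <- schedule$q
  if (coords == "section") {
    secs <- ensemble_sections(ref)
    B <- matrix(0, d * q, (d - 1) * q)
    anchor <- numeric(d * q)
    for (k in seq_len(q)) {
      rows <- ((k - 1) * d + 1):(k * d)
      cols <- ((k - 1) * (d - 1) + 1):(k * (d - 1))
      B[rows, cols] <- secs[[k]]$basis
      anchor[rows] <- secs[[k]]$anchor
    }
    function(theta) {
      net2 <- set_scaled_params(net0, theta)
      ens <- propagate_lna(net2, NULL, schedule,
                           phase_correct = phase_correct, x0 = x0)
      list(mean = drop(t(B) %*% (ens$mean - anchor)),
           cov = t(B) %*% ens$cov %*% B)
    }
  } else {
    function(theta) {
      net2 <- set_scaled_params(net0, theta)
      ens <- propagate_lna(net2, NULL, schedule,
                           phase_correct = phase_correct, x0 = x0)
      if (!is.null(observed)) ens <- observe_ensemble(ens, observed)
      list(mean = ens$mean, cov = ens$cov)
    }
  }
}
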