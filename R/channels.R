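# Scalar channels dose -> P(R | dose): Gaussian-mixture response models with
# log-normal extrinsic cell-to-cell variability, Monte-Carlo mutual
# information, and Blahut-Arimoto channel capacity.

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Build a scalar dose channel
#'
#' For each dose level on the input grid, the response distribution is a
#' mixture of pcLNA Gaussians over extrinsic draws: the total NF-kB
#' abundance parameter and the system size Omega vary from cell to cell
#' with log-normal distributions of given coefficient of variation (mean
#' preserved). The response is the copy number of one species (nuclear
#' NF-kB by default) at the scheduled phases, or at a single fixed time.
#'
#' @param net a `ReactionNetwork` with a dose parameter.
#' @param doses positive, distinct input dose levels.
#' @param schedule an `ObservationSchedule` (e.g. first peaks and troughs),
#'   or a single fixed time via `fixed_schedule(30)`.
#' @param extrinsic list with `cv_total` (CV of the total-abundance
#'   parameter named in `total_param`) and `cv_omega`; zero CVs collapse the
#'   mixture to a single Gaussian.
#' @param total_param name of the total-abundance parameter.
#' @param n_mix extrinsic draws per dose (mixture components).
#' @param seed RNG seed for the extrinsic draws.
#' @param response species observed.
#' @param horizon protocol horizon (min).
#' @return object of class `ChannelSpec`: `doses`, `components` (per dose, a
#'   list of mixtures with equal weights, means and covariances on the
#'   copy-number scale), and metadata.
#' @export
build_channel <- function(net, doses, schedule,
                          extrinsic = list(cv_total = 0.3, cv_omega = 0.3),
                          total_param = "TNFKB", n_mix = 8, seed = 1,
                          response = "NFkB_n", horizon = NULL) {
  if (any(doses <= 0) || anyDuplicated(doses)) stop("doses must be positive and distinct")
  if (length(doses) < 2) stop("need at least 2 input doses")
  cvT <- extrinsic$cv_total %||% 0; cvO <- extrinsic$cv_omega %||% 0
  if (any(c(cvT, cvO) < 0) || any(!is.finite(c(cvT, cvO))))
    stop("degenerate extrinsic specification")
  set.seed(seed)
  if (is.null(horizon)) horizon <- max(schedule$times) + 1
  # log-normal with mean 1 and given CV
  ln_draw <- function(cv, n) {
    if (cv == 0) return(rep(1, n))
    s2 <- log(1 + cv^2)
    exp(rnorm(n, -s2 / 2, sqrt(s2)))
  }
  mT <- ln_draw(cvT, n_mix); mO <- ln_draw(cvO, n_mix)
  components <- lapply(doses, function(dz) {
    prot <- stimulus_protocol("continuous", dose = dz, horizon = horizon)
    lapply(seq_len(n_mix), function(m) {
      net2 <- net
      net2$params[[total_param]] <- net$params[[total_param]] * mT[m]
      om <- net$omega * mO[m]
      ens <- propagate_lna(net2, prot, schedule, omega = om)
      obs <- observe_ensemble(ens, response)
      list(w = 1 / n_mix, mean = om * obs$mean, cov = om^2 * obs$cov)
    })
  })
  structure(list(doses = doses, components = components,
                 response = response, schedule = schedule,
                 extrinsic = list(cv_total = cvT, cv_omega = cvO),
                 n_mix = n_mix, seed = seed),
            class = "ChannelSpec")
}

#' @export
print.ChannelSpec <- function(x, ...) {
  cat(sprintf("ChannelSpec: %d doses, %d mixture components, response %s at %d times\n",
              length(x$doses), x$n_mix, x$response, x$schedule$q))
  invisible(x)
}

# per-component inverses cached once
channel_density_fns <- function(channel) {
  lapply(channel$components, function(comps) {
    pre <- lapply(comps, function(cm)
      list(w = cm$w, mean = cm$mean, finv = floored_inverse(cm$cov)))
    function(x) { # x: matrix n x dim -> log density under the mixture
      ld <- sapply(pre, function(cm)
        log(cm$w) + log_dens_gauss(x, cm$mean, cm$finv))
      if (is.null(dim(ld))) ld <- matrix(ld, nrow = 1)
      apply(ld, 1, logsumexp)
    }
  })
}

channel_sampler <- function(channel) {
  function(k, n) { # n samples from dose k's mixture
    comps <- channel$components[[k]]
    pick <- sample.int(length(comps), n, replace = TRUE,
                       prob = vapply(comps, `[[`, numeric(1), "w"))
    dim_r <- length(comps[[1]]$mean)
    x <- matrix(NA_real_, n, dim_r)
    for (m in unique(pick)) {
      idx <- which(pick == m)
      cm <- comps[[m]]
      x[idx, ] <- sweep(matrix(rnorm(length(idx) * dim_r), length(idx)) %*%
                          msqrt(cm$cov), 2, cm$mean, `+`)
    }
    x
  }
}

#' Monte-Carlo mutual information of a channel
#'
#' `I(S; R) = E[log2 p(R|S) - log2 sum_s p(s) p(R|s)]` with mixture
#' densities evaluated exactly (log-sum-exp) and the expectation estimated
#' by sampling `(S, R)` pairs.
#'
#' @param channel a `ChannelSpec`.
#' @param input_dist input distribution on the dose grid (sums to 1);
#'   default uniform.
#' @param n_mc Monte-Carlo pairs.
#' @param seed optional RNG seed.
#' @return mutual information in bits, with attribute `"se"` (Monte-Carlo
#'   standard error).
#' @export
mutual_information <- function(channel, input_dist = NULL, n_mc = 2000,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- length(channel$doses)
  if (is.null(input_dist)) input_dist <- rep(1 / K, K)
  if (abs(sum(input_dist) - 1) > 1e-8 || any(input_dist < 0))
    stop("input_dist must be a distribution on the dose grid")
  dens <- channel_density_fns(channel)
  samp <- channel_sampler(channel)
  ks <- sample.int(K, n_mc, replace = TRUE, prob = input_dist)
  contrib <- numeric(n_mc)
  for (k in unique(ks)) {
    idx <- which(ks == k)
    x <- samp(k, length(idx))
    ld <- sapply(seq_len(K), function(kk) dens[[kk]](x))
    if (is.null(dim(ld))) ld <- matrix(ld, nrow = 1)
    lmix <- apply(sweep(ld, 2, log(input_dist), `+`), 1, logsumexp)
    contrib[idx] <- (ld[, k] - lmix) / log(2)
  }
  mi <- mean(contrib)
  attr(mi, "se") <- sd(contrib) / sqrt(n_mc)
  mi
}

#' Blahut-Arimoto capacity on a discrete transition matrix
#'
#' Exact alternating maximisation for a finite channel `P(y | x)` given as a
#' row-stochastic matrix; used as the algorithmic core reference and for
#' closed-form checks (e.g. the binary symmetric channel).
#'
#' @param P transition matrix (inputs x outputs), rows sum to 1.
#' @param tol convergence tolerance on the capacity bounds gap (bits).
#' @param max_iter iteration cap.
#' @return list with `capacity` (bits), `input_dist`, `trace`, `converged`.
#' @export
ba_discrete <- function(P, tol = 1e-9, max_iter = 10000) {
  K <- nrow(P)
  p <- rep(1 / K, K)
  trace <- numeric(0)
  converged <- FALSE
  lP <- ifelse(P > 0, log(P), -Inf)
  for (it in seq_len(max_iter)) {
    q <- colSums(p * P)
    D <- rowSums(ifelse(P > 0, P * (lP - rep(log(q), each = K)), 0))
    IL <- sum(p * D) / log(2); IU <- max(D) / log(2)
    trace <- c(trace, IL)
    if (IU - IL < tol) { converged <- TRUE; break }
    p <- p * exp(D); p <- p / sum(p)
  }
  list(capacity = IL, input_dist = p, trace = trace, converged = converged)
}

#' Blahut-Arimoto channel capacity of a Gaussian-mixture channel
#'
#' Monte-Carlo Blahut-Arimoto on the fixed dose grid: conditional densities
#' are evaluated exactly, the output expectation is estimated over a fixed
#' set of response samples per input, and the input distribution is
#' alternately re-weighted until the capacity lower/upper bounds meet.
#'
#' @param channel a `ChannelSpec`.
#' @param tol stopping gap between the Blahut-Arimoto bounds (bits).
#' @param max_iter iteration cap (result flagged unconverged beyond it).
#' @param n_mc response samples per input level.
#' @param seed RNG seed for the response samples.
#' @return object of class `ChannelCapacityResult`: `capacity` (bits),
#'   `input_dist`, `q` (number of observation phases), `trace`,
#'   `converged`, MC settings.
#' @export
blahut_arimoto <- function(channel, tol = 1e-4, max_iter = 500,
                           n_mc = 400, seed = 1) {
  set.seed(seed)
  K <- length(channel$doses)
  dens <- channel_density_fns(channel)
  samp <- channel_sampler(channel)
  # ld[[k]]: matrix n_mc x K of log densities of samples from input k
  ld <- vector("list", K)
  for (k in seq_len(K)) {
    x <- samp(k, n_mc)
    ld[[k]] <- sapply(seq_len(K), function(kk) dens[[kk]](x))
  }
  p <- rep(1 / K, K)
  trace <- numeric(0); converged <- FALSE
  for (it in seq_len(max_iter)) {
    D <- vapply(seq_len(K), function(k) {
      lmix <- apply(sweep(ld[[k]], 2, log(p), `+`), 1, logsumexp)
      mean(ld[[k]][, k] - lmix)
    }, numeric(1))
    IL <- sum(p * D) / log(2); IU <- max(D) / log(2)
    trace <- c(trace, IL)
    if (IU - IL < tol) { converged <- TRUE; break }
    p <- p * exp(D); p <- p / sum(p)
  }
  structure(list(capacity = IL, input_dist = setNames(p, channel$doses),
                 q = channel$schedule$q, trace = trace,
                 converged = converged, n_mc = n_mc, seed = seed),
            class = "ChannelCapacityResult")
}

#' @export
print.ChannelCapacityResult <- function(x, ...) {
  cat(sprintf("Channel capacity: %.3f bits (q = %d, %sconverged, %d iterations)\n",
              x$capacity, x$q, if (x$converged) "" else "NOT ", length(x$trace)))
  invisible(x)
}
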