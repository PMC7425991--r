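# The multiplexing-capacity calculus: normal components of sensitivity
# columns, the greedy (essentially unique) signal ordering with capacities
# MX_k = v_k^2 / 2, nested-subset selection, the signal chain rule, and a
# brute-force KL-minimisation oracle for the defining scaled-divergence.

sens_matrix <- function(s) {
  if (inherits(s, "SensitivityMatrix")) s$s
  else if (is.matrix(s)) s
  else stop("expected a SensitivityMatrix or a matrix")
}

#' Normal component of a sensitivity column
#'
#' The component of column `s_i` orthogonal to the span of the columns
#' indexed by `subset`, computed via the QR decomposition of the submatrix
#' (least-squares residual).
#'
#' @param s a `SensitivityMatrix` or matrix.
#' @param i column index probed.
#' @param subset column indices spanning the conditioning subspace (must not
#'   contain `i`; empty gives `s_i` itself).
#' @return the normal component vector `n(i | subset)`.
#' @export
normal_component <- function(s, i, subset = integer(0)) {
  S <- sens_matrix(s)
  p <- ncol(S)
  if (!(i %in% seq_len(p)) || !all(subset %in% seq_len(p)))
    stop("column indices out of range")
  if (i %in% subset) stop("i must not be in subset")
  if (!length(subset)) return(S[, i])
  qr.resid(qr(S[, subset, drop = FALSE]), S[, i])
}

#' Per-signal detectability D_KL(i, S0)
#'
#' The scaled minimum divergence for detecting a change in signal `i` while
#' all other signals may confound: `||n(i | j != i)||^2 / 2`. The larger the
#' value, the easier it is to detect the change in the `i`-th component.
#'
#' @param s a `SensitivityMatrix` or square matrix over the signals.
#' @param i signal index.
#' @return divergence (nats).
#' @export
dkl_capacity <- function(s, i) {
  S <- sens_matrix(s)
  n <- normal_component(S, i, setdiff(seq_len(ncol(S)), i))
  sum(n^2) / 2
}

#' Multiplexing-capacity ordering and report
#'
#' Greedy reordering of the signals: `i_1 = argmax ||s_i||`, then each next
#' index maximises the norm of the normal component with respect to the
#' already chosen columns. The residual lengths `v_k` are nonincreasing and
#' the multiplexing capacities of the nested subsets are `MX_k = v_k^2 / 2`;
#' `v_1...v_k <= sigma_1...sigma_k` with equality at `k = s`. Ties (|v
#' difference| < 1e-10) are broken by index and flagged.
#'
#' @param s a `SensitivityMatrix` or matrix (columns = signals).
#' @param bits report capacities in bits instead of nats.
#' @return object of class `MultiplexingReport`: `ordering` (signal names /
#'   indices), `v`, `MX`, per-signal `dkl`, normal components `n` (list),
#'   singular values `sv`, tie flags.
#' @export
mx_ordering <- function(s, bits = FALSE) {
  S <- sens_matrix(s)
  if (!all(is.finite(S))) stop("sensitivity matrix must be finite")
  p <- ncol(S)
  nm <- colnames(S) %||% as.character(seq_len(p))
  remaining <- seq_len(p)
  ordering <- integer(0)
  v <- numeric(p)
  ncomp <- vector("list", p)
  ties <- logical(p)
  for (k in seq_len(p)) {
    res <- vapply(remaining, function(i)
      sqrt(sum(normal_component(S, i, ordering)^2)), numeric(1))
    best <- max(res)
    cand <- remaining[res >= best - 1e-10]
    ties[k] <- length(cand) > 1
    pick <- min(cand) # deterministic tie-break by index
    v[k] <- res[match(pick, remaining)]
    ncomp[[k]] <- normal_component(S, pick, ordering)
    ordering <- c(ordering, pick)
    remaining <- setdiff(remaining, pick)
  }
  MX <- v^2 / 2
  dkl <- vapply(seq_len(p), function(i) dkl_capacity(S, i), numeric(1))
  if (bits) { MX <- MX / log(2); dkl <- dkl / log(2) }
  structure(list(ordering = ordering, signals = nm[ordering], v = v,
                 MX = MX, dkl = setNames(dkl, nm), n = ncomp,
                 sv = svd(S)$d, ties = ties, bits = bits),
            class = "MultiplexingReport")
}

#' @export
print.MultiplexingReport <- function(x, ...) {
  unit <- if (isTRUE(x$bits)) "bits" else "nats"
  cat(sprintf("MultiplexingReport (%s)\n", unit))
  print(data.frame(k = seq_along(x$v), signal = x$signals,
                   v = signif(x$v, 4), MX = signif(x$MX, 4),
                   tie = x$ties))
  invisible(x)
}

#' Largest nested signal subset above a capacity threshold
#'
#' Returns the nested subset `(i_1, ..., i_k)` of maximal size with
#' `MX_k >= m`.
#'
#' @param report a `MultiplexingReport`.
#' @param m positive capacity threshold (same units as the report).
#' @return integer vector of signal indices (possibly empty).
#' @export
mx_subset <- function(report, m) {
  if (m <= 0) stop("m must be > 0")
  k <- which(report$MX >= m)
  if (!length(k)) integer(0) else report$ordering[seq_len(max(k))]
}

#' Chain rule from parameter to signal sensitivities
#'
#' If the signals act through the parameters, `theta = theta(S)`, the signal
#' sensitivity matrix is the composition `s_signals = s_params d theta(S)`.
#' The conditioning of `d theta(S)` (condition number, and |det| when
#' square) is attached, since poorly conditioned signal maps destroy
#' multiplexing.
#'
#' @param s_params parameter-space `SensitivityMatrix` (or matrix).
#' @param dtheta Jacobian matrix `d theta / d S` (parameters x signals).
#' @param signal_names optional column names for the signals.
#' @return a `SensitivityMatrix` over the signals with attributes
#'   `"condition"` and (square case) `"det"`.
#' @export
signal_chain <- function(s_params, dtheta, signal_names = colnames(dtheta)) {
  S <- sens_matrix(s_params)
  if (ncol(S) != nrow(dtheta)) stop("dimension mismatch: params vs dtheta rows")
  s2 <- S %*% dtheta
  colnames(s2) <- signal_names %||% as.character(seq_len(ncol(s2)))
  sv <- svd(dtheta)$d
  out <- structure(list(s = s2, sv = svd(s2)$d, names = colnames(s2)),
                   class = "SensitivityMatrix")
  attr(out, "condition") <- if (min(sv) > 0) max(sv) / min(sv) else Inf
  if (nrow(dtheta) == ncol(dtheta)) attr(out, "det") <- abs(det(dtheta))
  out
}

#' Brute-force oracle for the scaled minimum KL divergence
#'
#' Numerically evaluates the defining quantity behind [dkl_capacity()]: for
#' a small change of size `l` in the `i`-th signal, minimises the exact
#' Gaussian KL divergence over all confounding signals `S'` with the `i`-th
#' component unchanged (grid search plus Nelder-Mead refinement on the
#' constraint hyperplane) and returns `l^-2` times the minimum. The outer
#' minimisation over the probed change is taken over the two axis directions
#' `S = S0 +/- l e_i`, which attain the local minimum up to third-order
#' terms. Intended as a test oracle for the QR-based local formulas.
#'
#' @param ensemble_fn map from a signal/parameter vector (named, log scale)
#'   to a `GaussianEnsemble` or `list(mean, cov)`.
#' @param pspace a `ParameterSpace` (signals = `selection`).
#' @param i index of the probed signal within the selection.
#' @param l probe radius (<= 0.05).
#' @param grid_density grid points per free dimension (>= 9 recommended).
#' @return scaled minimum divergence `l^-2 min_S' D_KL`.
#' @export
brute_force_oracle <- function(ensemble_fn, pspace, i, l = 0.01,
                               grid_density = 9) {
  if (l > 0.05) stop("l must be <= 0.05 (local oracle)")
  sel <- pspace$selection
  s <- length(sel)
  th0 <- pspace$theta0[sel]
  free <- setdiff(seq_len(s), i)
  ens_at <- function(dth) {
    th <- th0; th[] <- th0 + dth
    ens_moments(ensemble_fn(th))
  }
  best <- Inf
  for (sgn in c(1, -1)) {
    dS <- numeric(s); dS[i] <- sgn * l
    P <- ens_at(dS)
    obj <- function(cfree) {
      dSp <- numeric(s); dSp[free] <- cfree
      gaussian_kl(P, ens_at(dSp))
    }
    # coarse grid on the constraint hyperplane
    g <- seq(-2 * l, 2 * l, length.out = grid_density)
    grid <- as.matrix(do.call(expand.grid, rep(list(g), length(free))))
    vals <- apply(grid, 1, obj)
    start <- grid[which.min(vals), ]
    if (length(free) == 1) {
      opt <- stats::optimize(function(z) obj(z), c(-3 * l, 3 * l),
                             tol = 1e-12)
      opt <- list(value = opt$objective, convergence = 0)
    } else {
      opt <- optim(start, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-10, maxit = 2000))
    }
    if (!opt$convergence %in% c(0, 10) && opt$value > min(vals))
      stop("oracle optimisation failure; best found ", min(vals, opt$value))
    best <- min(best, opt$value, min(vals))
  }
  best / l^2
}
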