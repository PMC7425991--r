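# Exact stochastic simulation (direct-method Gillespie), the hybrid
# pcLNA-core / SSA-gene simulator, and envelope statistics.

#' Exact stochastic simulation (Gillespie direct method)
#'
#' Statistically exact sampling of the chemical master equation with
#' copy-number propensities `omega * f(X/omega, t)`. The piecewise-constant
#' dose signal is handled by restarting the exponential clock at protocol
#' window edges, which is exact for step-function propensities.
#'
#' @param net a `ReactionNetwork`.
#' @param protocol optional `StimulusProtocol`.
#' @param record_times times (min) at which the state is recorded (the state
#'   immediately before each time); a scalar `horizon` records on a 1-min
#'   grid.
#' @param seed optional RNG seed.
#' @param x0 initial copy numbers (default: rounded `omega` x unstimulated
#'   steady state).
#' @param omega system size override.
#' @return object of class `JumpTrajectory`: list with `times`, `states`
#'   (time x species copy-number matrix), `seed`, `protocol`.
#' @export
ssa_simulate <- function(net, protocol = NULL, record_times = NULL,
                         seed = NULL, x0 = NULL, omega = net$omega) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(protocol)) net <- apply_protocol(net, protocol)
  if (is.null(record_times)) {
    horizon <- if (!is.null(net$protocol)) net$protocol$horizon else 100
    record_times <- seq(0, horizon, by = 1)
  }
  if (length(record_times) == 1) record_times <- seq(0, record_times, by = 1)
  if (is.null(x0)) x0 <- round(omega * steady_state(net))
  if (any(x0 < 0) || any(x0 != round(x0)))
    stop("x0 must be nonnegative integers")
  enc <- encode_network(net)
  states <- cpp_ssa(enc, net$params, x0, 0, record_times, omega)
  colnames(states) <- net$species
  structure(list(times = record_times, states = states, seed = seed,
                 protocol = net$protocol), class = "JumpTrajectory")
}

#' @export
print.JumpTrajectory <- function(x, ...) {
  cat(sprintf("JumpTrajectory: %d recorded states, %d species\n",
              length(x$times), ncol(x$states)))
  invisible(x)
}

#' SSA ensemble at scheduled phases
#'
#' Runs `n` independent SSA trajectories and records the state at the
#' scheduled times; convenience wrapper returning the same array layout as
#' [pclna_simulate()].
#'
#' @inheritParams ssa_simulate
#' @param schedule an `ObservationSchedule`.
#' @param n number of trajectories.
#' @return array `n x species x q` of copy numbers.
#' @export
ssa_ensemble <- function(net, protocol = NULL, schedule, n, seed = NULL,
                         omega = net$omega, x0 = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(protocol)) net <- apply_protocol(net, protocol)
  if (is.null(x0)) x0 <- round(omega * steady_state(net))
  enc <- encode_network(net)
  d <- length(net$species)
  out <- array(NA_real_, c(n, d, schedule$q),
               dimnames = list(NULL, net$species, NULL))
  for (i in seq_len(n))
    out[i, , ] <- t(cpp_ssa(enc, net$params, x0, 0, schedule$times, omega))
  out
}

#' Section-projected SSA states at scheduled phases
#'
#' For each SSA trajectory, finds the crossing of the transversal section
#' anchored at each scheduled phase (sign change of the flow-direction
#' coordinate near the scheduled time, with linear interpolation at the
#' crossing) and returns the crossing states in section-basis coordinates;
#' used to compare SSA against the pcLNA on the sections. All phases are
#' extracted from a single run per trajectory.
#'
#' @param net a `ReactionNetwork` (protocol applied as for the runs).
#' @param protocol optional `StimulusProtocol`.
#' @param sections a `TransversalSection` or list of them (concentration
#'   scale).
#' @param t_phases scheduled times of the sections' phases (min).
#' @param n number of trajectories.
#' @param window half-width (min) of the search window around each phase.
#' @param dt recording resolution inside the windows.
#' @param seed optional RNG seed.
#' @param omega system size override.
#' @param x0 initial copy numbers (default rounded steady state).
#' @return list of matrices `n x (d-1)` of section coordinates
#'   (concentration scale), one per phase; a single matrix if one section
#'   was given.
#' @export
ssa_section_states <- function(net, protocol = NULL, sections, t_phases, n,
                               window = 10, dt = 0.25, seed = NULL,
                               omega = net$omega, x0 = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.null(protocol)) net <- apply_protocol(net, protocol)
  if (is.null(x0)) x0 <- round(omega * steady_state(net))
  single <- inherits(sections, "TransversalSection")
  if (single) sections <- list(sections)
  if (length(sections) != length(t_phases)) stop("sections/t_phases mismatch")
  enc <- encode_network(net)
  d <- length(net$species)
  grids <- lapply(t_phases, function(tp)
    seq(max(0, tp - window), tp + window, by = dt))
  grid <- sort(unique(unlist(grids)))
  out <- lapply(t_phases, function(tp) matrix(NA_real_, n, d - 1))
  for (i in seq_len(n)) {
    st <- cpp_ssa(enc, net$params, x0, 0, grid, omega) / omega
    for (a in seq_along(sections)) {
      sec <- sections[[a]]
      keep <- which(grid >= grids[[a]][1] &
                    grid <= grids[[a]][length(grids[[a]])])
      h <- as.numeric((st[keep, , drop = FALSE] -
                       matrix(sec$anchor, length(keep), d, byrow = TRUE)) %*%
                      sec$normal)
      cross <- which(h[-length(h)] < 0 & h[-1] >= 0)
      xk <- if (length(cross)) {
        k <- cross[which.min(abs(grid[keep][cross] - t_phases[a]))]
        w <- -h[k] / (h[k + 1] - h[k]) # linear interpolation at h = 0
        (1 - w) * st[keep[k], ] + w * st[keep[k + 1], ]
      } else st[keep[which.min(abs(h))], ]
      out[[a]][i, ] <- t(sec$basis) %*% (xk - sec$anchor)
    }
  }
  if (single) out[[1]] else out
}

#' Hybrid pcLNA / SSA simulation of a gene module driven by a core model
#'
#' The core network is simulated with the pcLNA (Gaussian sampling at the
#' scheduled phases); between phases, the core path imposed on the genes is
#' the deterministic solution plus a linear interpolation of the sampled
#' deviation, refreshed on a fine subgrid. The gene module (low copy number,
#' far from Gaussian) is simulated exactly by SSA driven by that path; the
#' coupling is strictly one-way (core to genes).
#'
#' @param core_net core `ReactionNetwork` (e.g. the m2NFkB variant).
#' @param gene_net gene `ReactionNetwork` whose driver species (shared names
#'   with the core) have zero stoichiometry rows.
#' @param protocol a `StimulusProtocol`.
#' @param schedule core `ObservationSchedule` (phase-correction times).
#' @param record_times gene-state recording times (min).
#' @param n number of hybrid trajectories.
#' @param seed optional RNG seed.
#' @param subgrid_dt driver refresh interval (min).
#' @param two_way must stay `FALSE`; gene-to-core feedback is unsupported.
#' @return list with `gene` (`n x gene-species x |record_times|` copy-number
#'   array) and `core` (the pcLNA samples at the scheduled phases).
#' @export
hybrid_simulate <- function(core_net, gene_net, protocol, schedule,
                            record_times, n, seed = NULL, subgrid_dt = 1,
                            two_way = FALSE) {
  if (isTRUE(two_way)) stop("two-way coupling is unsupported (one-way core -> genes)")
  if (!is.null(seed)) set.seed(seed)
  drivers <- intersect(gene_net$species, core_net$species)
  if (!length(drivers)) stop("gene module shares no driver species with core")
  gs <- stoichiometry(gene_net)
  if (any(gs[drivers, ] != 0))
    stop("driver species must have zero stoichiometry rows in the gene module")
  core_net <- apply_protocol(core_net, protocol)
  ens <- propagate_lna(core_net, NULL, schedule)
  core_samples <- pclna_simulate(core_net, NULL, schedule, n, ens = ens)
  # deterministic core path on the driver subgrid
  tmax <- max(record_times)
  grid <- sort(unique(c(seq(0, tmax, by = subgrid_dt), schedule$times, tmax)))
  traj <- solve_macroscopic(core_net, grid = grid)
  di_core <- match(drivers, core_net$species)
  gene_enc <- encode_network(gene_net)
  di_gene <- match(drivers, gene_net$species)
  d_g <- length(gene_net$species)
  out <- array(0, c(n, d_g, length(record_times)),
               dimnames = list(NULL, gene_net$species, NULL))
  sched_t <- c(0, schedule$times)
  for (i in seq_len(n)) {
    # deviation of this sample from the deterministic path at the phases
    cs <- matrix(core_samples[i, , ], dim(core_samples)[2])
    dev <- rbind(0, t(cs[di_core, , drop = FALSE]) / core_net$omega -
                   ens$internals$xs[, di_core, drop = FALSE])
    # piecewise-linear deviation on the subgrid (constant after last phase)
    dev_grid <- sapply(seq_along(drivers), function(a)
      approx(sched_t, dev[, a], xout = pmin(grid, max(sched_t)),
             rule = 2)$y)
    path <- pmax(traj$states[, di_core, drop = FALSE] + dev_grid, 0)
    out[i, , ] <- t(cpp_ssa_driven(gene_enc, gene_net$params,
                                   numeric(d_g), di_gene, grid, path,
                                   record_times, gene_net$omega))
  }
  list(gene = out, core = core_samples, record_times = record_times)
}

#' Empirical confidence envelopes
#'
#' Per-time empirical quantiles at `(1 - level)/2` and `(1 + level)/2`
#' together with the mean.
#'
#' @param samples matrix `n x times` (or `n x species x times` array with a
#'   `species` argument).
#' @param level envelope level in (0, 1), e.g. 0.95.
#' @param species species name when `samples` is a 3-d array.
#' @return object of class `EnvelopeSummary`: data frame with `time` index,
#'   `lower`, `mean`, `upper`, and attribute `n`.
#' @export
envelopes <- function(samples, level = 0.95, species = NULL) {
  if (length(dim(samples)) == 3) {
    if (is.null(species)) stop("species required for a 3-d sample array")
    samples <- samples[, species, ]
  }
  if (nrow(samples) < 20) stop("need at least 20 samples for envelopes")
  if (!(level > 0 && level < 1)) stop("level must be in (0,1)")
  lo <- apply(samples, 2, quantile, probs = (1 - level) / 2, names = FALSE)
  hi <- apply(samples, 2, quantile, probs = (1 + level) / 2, names = FALSE)
  mid <- colMeans(samples)
  out <- data.frame(index = seq_along(mid), lower = lo, mean = mid, upper = hi)
  attr(out, "n") <- nrow(samples)
  class(out) <- c("EnvelopeSummary", "data.frame")
  out
}
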