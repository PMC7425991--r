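# Shared fixtures: tiny closed-form networks, synthetic Gaussian signal
# models, and memoised expensive objects (schedules, ensembles).

rxn <- function(name, rate, reactants = c(), products = c(), factors = list())
  list(name = name, rate = rate, reactants = as.list(reactants),
       products = as.list(products), factors = factors)

# birth-death: 0 -> X (k), X -> 0 (g); stationary Poisson(k/g) at omega = 1
birth_death_net <- function(k = 5, g = 0.5, omega = 1)
  reaction_network("X", list(
    rxn("birth", "k", c(), c(X = 1)),
    rxn("death", "g", c(X = 1), c())),
    c(k = k, g = g), omega = omega, variant = "bd", init = list(X = k / g))

pure_death_net <- function(d = 0.1)
  reaction_network("X", list(rxn("death", "d", c(X = 1), c())),
                   c(d = d), omega = 1, variant = "pd", init = list(X = 100))

# linear relaxation dx/dt = -g x (deterministic check)
decay_net <- function(g = 1)
  reaction_network("X", list(rxn("decay", "g", c(X = 1), c())),
                   c(g = g), omega = 1, variant = "lin", init = list(X = 1))

# Hill-driven production for rate-law checks
hill_net <- function()
  reaction_network(c("X", "Y"), list(
    rxn("prod", "v", c(), c(Y = 1),
        list(list(type = "hill_act", source = "X", K = "K", h = 2))),
    rxn("rep", "w", c(), c(Y = 1),
        list(list(type = "hill_rep", source = "X", K = "K", h = 3))),
    rxn("deg", "g", c(Y = 1), c())),
    c(v = 2, w = 4, K = 3, g = 1), omega = 10, variant = "hill",
    init = list(X = 1))

# synthetic Gaussian signal model: mean = M theta + theta' Q_i theta terms,
# fixed SPD covariance. quad = 0 gives an exactly linear family.
lin_gauss_fn <- function(M, Sigma, quad = NULL) {
  force(M); force(Sigma); force(quad)
  function(theta) {
    th <- as.numeric(theta)
    mu <- drop(M %*% th)
    if (!is.null(quad))
      mu <- mu + vapply(quad, function(Q) drop(t(th) %*% Q %*% th), 0)
    list(mean = mu, cov = Sigma)
  }
}

rand_spd <- function(d, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(d * d), d)
  crossprod(A) + diag(d) * 0.5
}

# memoised toy-model objects shared across test files
toy_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- build_model("toy")
      x0 <- initial_state(net)
      traj <- solve_macroscopic(net, grid = seq(0, 40, by = 0.02), x0 = x0)
      sched <- observation_schedule(traj, "X", q = 8)
      ens <- propagate_lna(net, NULL, sched, x0 = x0)
      cache <<- list(net = net, x0 = x0, traj = traj, sched = sched,
                     ens = ens)
    }
    cache
  }
})

# memoised base-model protocol/schedule (continuous TNFa)
base_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      net <- build_model("base")
      prot <- stimulus_protocol("continuous", dose = 10, horizon = 600)
      traj <- solve_macroscopic(net, prot)
      sched <- observation_schedule(traj, "NFkB_n", q = 9)
      cache <<- list(net = net, prot = prot, traj = traj, sched = sched)
    }
    cache
  }
})
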