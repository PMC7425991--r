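test_that("SSA matches closed-form death process and Poisson stationarity", {
  # pure death: E X_t = 100 exp(-d t)
  net <- pure_death_net(d = 0.1)
  sched <- fixed_schedule(c(5, 10))
  sam <- ssa_ensemble(net, NULL, sched, n = 2000, seed = 1, x0 = c(X = 100))
  for (k in 1:2) {
    m <- 100 * exp(-0.1 * sched$times[k])
    se <- sd(sam[, 1, k]) / sqrt(2000)
    expect_lt(abs(mean(sam[, 1, k]) - m), 3.5 * se)
  }
  # birth-death occupancy: mean ~ var ~ k/g
  bd <- birth_death_net(k = 5, g = 0.5)
  tr <- ssa_simulate(bd, record_times = seq(50, 2050, by = 2), seed = 2,
                     x0 = c(X = 10))
  xs <- tr$states[, 1]
  expect_lt(abs(mean(xs) - 10), 0.5)
  expect_lt(abs(var(xs) - 10), 1.5)
})

test_that("zero propensities freeze the state; jumps follow stoichiometry", {
  net <- pure_death_net(d = 0.1)
  sam <- ssa_simulate(net, record_times = c(0, 10, 50), seed = 3,
                      x0 = c(X = 0))
  expect_true(all(sam$states == 0))
  # every recorded increment of the toy trajectory is an integer combination
  # of stoichiometry columns (here: integer states, conservation X + Y
  # changes only via birth/death which change it by 1)
  toy <- build_model("toy")
  tr <- ssa_simulate(toy, record_times = seq(0, 5, by = 0.5), seed = 4,
                     x0 = c(X = 500, Y = 500))
  expect_true(all(tr$states == round(tr$states)))
  expect_true(all(tr$states >= 0))
})

test_that("SSA is seed-reproducible and converges to the ODE with omega", {
  net <- build_model("toy")
  a <- ssa_simulate(net, record_times = c(1, 2, 3), seed = 9,
                    x0 = c(X = 1000, Y = 1000))
  b <- ssa_simulate(net, record_times = c(1, 2, 3), seed = 9,
                    x0 = c(X = 1000, Y = 1000))
  expect_identical(a$states, b$states)
  # relative deviation of SSA from ODE shrinks as omega grows
  x0c <- c(X = 1, Y = 1)
  traj <- solve_macroscopic(net, grid = c(0, 4), x0 = x0c)
  target <- traj$states[2, ]
  dev <- vapply(c(100, 1000, 10000), function(om) {
    nets <- build_model("toy", omega = om)
    sam <- ssa_ensemble(nets, NULL, fixed_schedule(4), n = 40, seed = om,
                        x0 = round(om * x0c))
    mean(abs(colMeans(sam[, , 1]) / om - target) / target)
  }, 0)
  expect_lt(dev[3], dev[1])
})

test_that("envelopes: quantile closed forms and degenerate input", {
  x <- matrix(rep(3, 40 * 4), 40)
  env <- envelopes(x, level = 0.9)
  expect_true(all(env$lower == 3 & env$upper == 3 & env$mean == 3))
  set.seed(8)
  g <- matrix(rnorm(40000), 4000)
  env <- envelopes(g, level = 0.95)
  expect_lt(max(abs(env$lower + 1.96)), 0.2)
  expect_lt(max(abs(env$upper - 1.96)), 0.2)
  expect_true(all(env$lower <= env$mean & env$mean <= env$upper))
  expect_error(envelopes(g[1:10, , drop = FALSE]), "20")
})

test_that("hybrid simulation: trivial and Poisson gene-module limits", {
  core <- build_model("m2NFkB")
  genes <- build_model("gene_module")
  prot <- stimulus_protocol("continuous", dose = 10, horizon = 200)
  traj <- solve_macroscopic(core, prot, grid = seq(0, 200, by = 1))
  sched <- observation_schedule(traj, "NFkB_n", q = 3)
  expect_error(hybrid_simulate(core, genes, prot, sched, c(10, 50), n = 2,
                               two_way = TRUE), "one-way")
  # zero transcription -> zero mRNA always
  g0 <- genes; g0$params[["k_egr"]] <- 1e-300; g0$params[["k_cox"]] <- 1e-300
  hs <- hybrid_simulate(core, g0, prot, sched, c(30, 130), n = 3, seed = 1)
  expect_true(all(hs$gene[, c("EGR1", "COX2"), ] == 0))
  # constitutive gene: stationary copy number Poisson(omega * k / g)
  const <- reaction_network(c("Z", "NFkB_n"), list(
    rxn("tx", "k", c(), c(Z = 1)),
    rxn("dg", "g", c(Z = 1), c())),
    c(k = 0.006, g = 0.03), omega = 100, variant = "constgene")
  hs <- hybrid_simulate(core, const, prot, sched,
                        record_times = seq(150, 200, by = 25), n = 60,
                        seed = 2)
  z <- as.vector(hs$gene[, "Z", ])
  lambda <- 100 * 0.006 / 0.03 # = 20
  expect_lt(abs(mean(z) - lambda), 4 * sqrt(lambda / length(z)) + 0.5)
  expect_lt(abs(var(z) / mean(z) - 1), 0.35)
})

test_that("hybrid gene readout separates stimulation protocols", {
  core <- build_model("m2NFkB")
  genes <- build_model("gene_module")
  res <- lapply(list(
    unstim = stimulus_protocol("unstimulated", horizon = 450),
    cont = stimulus_protocol("continuous", dose = 10, horizon = 450),
    pulse5 = stimulus_protocol("pulse_train", dose = 10, pulse_length = 5,
                               period = 100, horizon = 450)),
    function(prot) {
      traj <- solve_macroscopic(core, prot, grid = seq(0, 450, 1))
      sched <- tryCatch(observation_schedule(traj, "NFkB_n", q = 7),
                        error = function(e) fixed_schedule(seq(30, 430, 80)))
      hs <- hybrid_simulate(core, genes, prot, sched,
                            record_times = c(30, 430), n = 20, seed = 2)
      rbind(EGR1 = colMeans(hs$gene[, "EGR1", ]),
            COX2 = colMeans(hs$gene[, "COX2", ]))
    })
  # early EGR1 flags stimulation; late COX2 tracks cumulative modified
  # NF-kB (continuous > pulsed > unstimulated); EGR1 is repressed late
  # under continuous stimulation relative to sparse pulses
  expect_gt(res$cont["EGR1", 1], 3 * res$unstim["EGR1", 1])
  expect_gt(res$pulse5["EGR1", 1], 3 * res$unstim["EGR1", 1])
  expect_gt(res$cont["COX2", 2], res$pulse5["COX2", 2])
  expect_gt(res$pulse5["COX2", 2], res$unstim["COX2", 2] + 5)
  expect_gt(res$pulse5["EGR1", 2], res$cont["EGR1", 2])
})
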