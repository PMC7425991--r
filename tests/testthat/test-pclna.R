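test_that("LNA noiseless and linear-kinetics limits are exact", {
  # omega -> infinity proxy: covariance scales as 1/omega (exact), so the
  # noiseless limit is the trivial scaling; linear birth-death at
  # stationarity has Poisson variance = mean copy number
  net <- birth_death_net(k = 5, g = 0.5) # mean 10 at omega = 1
  sched <- fixed_schedule(c(25, 30))
  ens <- propagate_lna(net, NULL, sched, x0 = c(X = 10),
                       phase_correct = FALSE)
  expect_equal(unname(ens$mean), c(10, 10), tolerance = 1e-6)
  expect_equal(diag(ens$cov), c(10, 10), tolerance = 1e-4,
               ignore_attr = TRUE)
  # cross-time block: Cov(X_s, X_t) = var * exp(-g |t - s|) for OU
  expect_equal(ens$cov[1, 2], 10 * exp(-0.5 * 5), tolerance = 1e-3)
})

test_that("covariance scales exactly as 1/omega", {
  toy <- toy_cache()
  e1 <- propagate_lna(toy$net, NULL, toy$sched, omega = 1000, x0 = toy$x0)
  e2 <- propagate_lna(toy$net, NULL, toy$sched, omega = 2000, x0 = toy$x0)
  # exact in exact arithmetic; observed differences are solver tolerance
  expect_equal(e1$cov, 2 * e2$cov, tolerance = 1e-4)
  expect_equal(e1$mean, e2$mean, tolerance = 1e-7)
})

test_that("joint ensemble marginals equal single-time propagation", {
  toy <- toy_cache()
  ens <- propagate_lna(toy$net, NULL, toy$sched, x0 = toy$x0,
                       phase_correct = FALSE)
  k <- 3
  single <- propagate_lna(toy$net, NULL,
                          fixed_schedule(toy$sched$times[k]), x0 = toy$x0,
                          phase_correct = FALSE)
  idx <- (k - 1) * 2 + 1:2
  expect_equal(unname(ens$mean[idx]), unname(single$mean), tolerance = 1e-8)
  expect_equal(ens$cov[idx, idx], single$cov, tolerance = 1e-6,
               ignore_attr = TRUE)
})

test_that("section projection removes the flow direction", {
  # isotropic Gaussian: projected covariance is the identity on the section
  sec <- transversal_section(anchor = c(1, 2, 3), flow = c(1, 1, 0))
  ens <- gaussian_ensemble(mean = c(1, 2, 3), cov = diag(3))
  pr <- section_project(ens, sec)
  expect_equal(length(pr$mean), 2)
  expect_equal(pr$cov, diag(2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(pr$mean), c(0, 0))
  # basis orthonormal and orthogonal to the flow
  expect_equal(crossprod(sec$basis), diag(2), ignore_attr = TRUE)
  expect_equal(drop(t(sec$basis) %*% sec$normal), c(0, 0),
               tolerance = 1e-12)
  expect_error(transversal_section(c(1, 1), c(0, 0)), "zero flow")
  # propagated ensemble: projected dimension drops by one per time
  toy <- toy_cache()
  pe <- section_project(toy$ens)
  expect_equal(length(pe$mean), (2 - 1) * toy$sched$q)
  # the pc ensemble has (numerically) no variance along the flow at each time
  for (k in c(1, 4)) {
    f <- toy$ens$internals$Fs[k, ]; f <- f / sqrt(sum(f^2))
    idx <- (k - 1) * 2 + 1:2
    expect_lt(drop(t(f) %*% toy$ens$cov[idx, idx] %*% f),
              1e-10 * max(diag(toy$ens$cov[idx, idx])))
  }
})

test_that("pclna_simulate is seed-reproducible and matches the ODE mean", {
  toy <- toy_cache()
  s1 <- pclna_simulate(toy$net, NULL, toy$sched, n = 200, seed = 11,
                       ens = toy$ens)
  s2 <- pclna_simulate(toy$net, NULL, toy$sched, n = 200, seed = 11,
                       ens = toy$ens)
  expect_identical(s1, s2)
  s3 <- pclna_simulate(toy$net, NULL, toy$sched, n = 1000, seed = 12,
                       ens = toy$ens)
  for (k in c(2, 5)) {
    mu <- toy$net$omega * toy$ens$internals$xs[k, ]
    for (j in 1:2) {
      se <- sd(s3[, j, k]) / sqrt(1000)
      expect_lt(abs(mean(s3[, j, k]) - mu[j]), 3.5 * se + 1e-9)
    }
  }
})

test_that("section-projected pcLNA agrees with SSA section crossings (toy)", {
  toy <- toy_cache()
  secs <- ensemble_sections(toy$ens)
  k <- which(toy$sched$labels == "peak")[1]
  pc <- pclna_simulate(toy$net, NULL, toy$sched, n = 250, seed = 5,
                       ens = toy$ens)
  pc_sec <- sweep(pc[, , k] / toy$net$omega, 2, secs[[k]]$anchor) %*%
    secs[[k]]$basis
  ss_sec <- ssa_section_states(toy$net, NULL, secs[[k]],
                               t_phases = toy$sched$times[k], n = 250,
                               window = 2, dt = 0.05, seed = 6,
                               x0 = round(toy$net$omega * toy$x0))
  kt <- suppressWarnings(stats::ks.test(pc_sec[, 1], ss_sec[, 1]))
  expect_gt(kt$p.value, 0.01)
})
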