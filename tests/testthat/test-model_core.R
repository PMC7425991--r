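test_that("build_model returns structurally consistent networks", {
  for (v in c("base", "mNFkB", "m2NFkB", "gene_module", "toy")) {
    net <- build_model(v)
    expect_s3_class(net, "ReactionNetwork")
    expect_false(anyDuplicated(net$species) > 0)
    expect_true(all(net$params > 0))
    expect_gt(net$omega, 0)
    expect_identical(ncol(stoichiometry(net)), length(net$reactions))
  }
  expect_error(build_model("nope"), "valid tags")
  # base model carries the IkBa feedback loop and the IKK module species
  base <- build_model("base")
  expect_true(all(c("IkBa_c", "NFkB_n", "tIkBa", "IKKn", "IKKa", "IKKi")
                  %in% base$species))
})

test_that("m2NFkB modification requires both active IKK and S2 (AND logic)", {
  net <- build_model("m2NFkB")
  net <- apply_protocol(net, stimulus_protocol("continuous", horizon = 100))
  j <- which(vapply(net$reactions, `[[`, "", "name") == "nfkb_mod")
  st <- setNames(rep(10, length(net$species)), net$species)
  st_noikk <- st; st_noikk["IKKa"] <- 0
  expect_equal(unname(propensities(net, st_noikk, t = 1)[j]), 0)
  net0 <- net; net0$params[["S2"]] <- 1e-300 # S2 -> 0 limit
  expect_lt(propensities(net0, st, t = 1)[j], 1e-250)
  expect_gt(propensities(net, st, t = 1)[j], 0)
})

test_that("propensities: mass action, emptiness, Hill oracle", {
  net <- birth_death_net(k = 5, g = 0.5)
  a <- propensities(net, state = 10)
  expect_equal(unname(a), c(5, 0.5 * 10))
  expect_equal(unname(propensities(net, state = 0)), c(5, 0))
  expect_error(propensities(net, state = -1), "negative")
  expect_error(propensities(net, state = c(1, 2)), "one entry per species")
  # Hill rate laws against direct formula evaluation
  hn <- hill_net()
  x <- c(X = 4, Y = 7) # state in copies; omega = 10 -> conc X = 0.4
  a <- propensities(hn, x)
  cX <- 0.4
  expect_equal(unname(a[1]), 10 * 2 * cX^2 / (cX^2 + 3^2))
  expect_equal(unname(a[2]), 10 * 4 * 3^3 / (cX^3 + 3^3))
  expect_equal(unname(a[3]), 10 * 1 * 0.7)
})

test_that("macroscopic fields: birth-death closed form, PSD, F = nu a", {
  net <- birth_death_net(k = 2, g = 0.25)
  f <- macroscopic_fields(net, x = 8)
  expect_equal(unname(f$F), 2 - 0.25 * 8)
  expect_equal(unname(f$D), matrix(2 + 0.25 * 8), ignore_attr = TRUE)
  # PSD of D and F = nu a at omega = 1 for the base model at random states
  base <- build_model("base", omega = 1)
  base <- apply_protocol(base, stimulus_protocol("continuous", horizon = 10))
  set.seed(42)
  for (i in 1:5) {
    x <- runif(length(base$species), 0, 50)
    f <- macroscopic_fields(base, x, t = 1)
    expect_gte(min(eigen(f$D, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10 * max(abs(f$D)))
    a <- propensities(base, x, t = 1) # omega = 1: counts = conc
    expect_equal(unname(f$F), unname(drop(stoichiometry(base) %*% a)),
                 tolerance = 1e-12)
  }
})

test_that("stimulus protocols gate the dose as stated", {
  net <- build_model("base")
  pt <- stimulus_protocol("pulse_train", dose = 7, pulse_length = 5,
                          period = 100, horizon = 500)
  net2 <- apply_protocol(net, pt)
  expect_equal(dose_at(net2, c(0, 4.9, 5, 50, 100, 104.9, 105, 200, 204)),
               c(7, 7, 0, 0, 7, 7, 0, 7, 7))
  cont <- apply_protocol(net, stimulus_protocol("continuous", dose = 3,
                                                horizon = 100))
  expect_true(all(dose_at(cont, seq(0, 99)) == 3))
  uns <- apply_protocol(net, stimulus_protocol("unstimulated"))
  expect_true(all(dose_at(uns, seq(0, 400, 50)) == 0))
  expect_error(dose_at(cont, -1), "negative")
  expect_error(stimulus_protocol("pulse_train", pulse_length = 200,
                                 period = 100), "pulse_length")
})

test_that("scaled parameters round-trip exactly and selection is validated", {
  for (v in c("base", "mNFkB", "toy")) {
    net <- build_model(v)
    ps <- parameter_space(net)
    expect_equal(exp(ps$theta0), net$params, tolerance = 1e-14)
    net2 <- set_scaled_params(net, ps$theta0)
    expect_equal(net2$params, net$params, tolerance = 1e-14)
  }
  expect_error(parameter_space(build_model("toy"), "nope"), "subset")
})

test_that("base and mNFkB drifts agree when the modification is off", {
  base <- build_model("base")
  mn <- build_model("mNFkB")
  mn$params[["p_m1"]] <- 1e-300
  prot <- stimulus_protocol("continuous", dose = 10, horizon = 50)
  base <- apply_protocol(base, prot); mn <- apply_protocol(mn, prot)
  set.seed(7)
  x <- setNames(runif(length(base$species), 0, 40), base$species)
  xm <- setNames(numeric(length(mn$species)), mn$species)
  xm[base$species] <- x # modified pools at 0
  Fb <- macroscopic_fields(base, x, t = 1)$F
  Fm <- macroscopic_fields(mn, xm, t = 1)$F
  expect_equal(Fm[base$species], Fb, tolerance = 1e-12)
})
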