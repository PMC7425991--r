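test_that("Gaussian KL: closed forms, nonnegativity, MC oracle", {
  p <- gaussian_ensemble(0, matrix(1))
  q <- gaussian_ensemble(1, matrix(1))
  expect_equal(as.numeric(gaussian_kl(p, p)), 0)
  expect_equal(as.numeric(gaussian_kl(q, p)), 0.5)
  expect_equal(as.numeric(gaussian_kl(q, p, bits = TRUE)), 0.5 / log(2))
  expect_error(gaussian_kl(p, gaussian_ensemble(c(0, 0), diag(2))),
               "dimension")
  # random 3-d pairs: closed form vs Monte-Carlo E_P[log P/Q], and KL >= 0
  # with equality iff P = Q
  set.seed(21)
  for (rep in 1:3) {
    SP <- rand_spd(3); SQ <- rand_spd(3)
    mp <- rnorm(3); mq <- rnorm(3)
    P <- gaussian_ensemble(mp, SP); Q <- gaussian_ensemble(mq, SQ)
    kl <- as.numeric(gaussian_kl(P, Q))
    expect_gte(kl, 0)
    n <- 40000
    X <- sweep(matrix(rnorm(3 * n), n) %*% chol(SP), 2, mp, `+`)
    ld <- function(x, m, S) {
      ch <- chol(S)
      z <- forwardsolve(t(ch), t(sweep(x, 2, m)))
      -0.5 * (3 * log(2 * pi) + 2 * sum(log(diag(ch))) / 1 + colSums(z^2))
    }
    l <- ld(X, mp, SP) - ld(X, mq, SQ)
    expect_lt(abs(mean(l) - kl), 3 * sd(l) / sqrt(n))
  }
})

test_that("likelihood-ratio test: size, closed-form power, monotonicity", {
  # size: alternative = null gives power ~ alpha
  P <- gaussian_ensemble(c(0, 0), diag(2))
  t0 <- decision_test(P, P, alpha = 0.1)
  p0 <- lr_test_power(t0, n_mc = 40000, seed = 1)
  expect_lt(abs(as.numeric(p0) - 0.1), 0.01)
  # 1-d mean shift delta, unit variance: power = Phi(delta - z_{1-alpha})
  pw <- function(delta) as.numeric(lr_test_power(
    decision_test(gaussian_ensemble(0, matrix(1)),
                  gaussian_ensemble(delta, matrix(1)), alpha = 0.05),
    n_mc = 40000, seed = 2))
  for (delta in c(1, 2)) {
    expect_lt(abs(pw(delta) - pnorm(delta - qnorm(0.95))), 0.02)
  }
  expect_gt(pw(5), 0.99)
  expect_true(pw(0.5) < pw(1) && pw(1) < pw(2))
})

test_that("FIM: location family, scale, analytic-derivative oracle", {
  ps1 <- signal_space(c(th = 0))
  I1 <- fim(function(th) list(mean = as.numeric(th), cov = matrix(1)), ps1)
  expect_equal(unname(I1$I), matrix(1), tolerance = 1e-8)
  sig2 <- 4
  I2 <- fim(function(th) list(mean = as.numeric(th), cov = matrix(sig2)), ps1)
  expect_equal(I2$I[1, 1], 1 / sig2, tolerance = 1e-8)
  # synthetic mu(theta), Sigma(theta) with known analytic FIM
  # mu = M theta, Sigma = S0 + sum_j theta_j A_j (at theta0 = 0)
  set.seed(31)
  M <- matrix(rnorm(12), 4, 3)
  S0 <- rand_spd(4)
  A <- lapply(1:3, function(j) { B <- matrix(rnorm(16), 4); 0.1 * (B + t(B)) })
  fn <- function(th) {
    th <- as.numeric(th)
    S <- S0; for (j in 1:3) S <- S + th[j] * A[[j]]
    list(mean = drop(M %*% th), cov = S)
  }
  ps <- signal_space(c(a = 0, b = 0, c = 0))
  Ifd <- fim(fn, ps, fd_step = 1e-3, check_step = TRUE)
  S0i <- solve(S0)
  Ian <- t(M) %*% S0i %*% M
  for (i in 1:3) for (j in 1:3)
    Ian[i, j] <- Ian[i, j] + 0.5 * sum(diag(S0i %*% A[[i]] %*% S0i %*% A[[j]]))
  expect_lt(max(abs(Ifd$I - Ian)) / max(abs(Ian)), 1e-4)
  expect_lt(attr(Ifd, "step_check"), 1e-4)
})

test_that("quadratic KL expansion and its symmetry", {
  I <- rand_spd(4, seed = 41)
  expect_equal(quadratic_kl(I, rep(0, 4)), 0)
  dS <- rnorm(4)
  perm <- sample(4)
  expect_equal(quadratic_kl(I, dS),
               quadratic_kl(I[perm, perm], dS[perm]), tolerance = 1e-12)
  # exact KL vs quadratic form on a linear-Gaussian family: the quadratic
  # form is exact for linear mean and fixed covariance
  M <- matrix(rnorm(9), 3); S <- rand_spd(3)
  fn <- lin_gauss_fn(M, S)
  ps <- signal_space(setNames(rep(0, 3), c("x", "y", "z")))
  Ifd <- fim(fn, ps)
  d <- c(0.01, -0.005, 0.02)
  kl_exact <- as.numeric(gaussian_kl(fn(d), fn(rep(0, 3))))
  expect_equal(quadratic_kl(Ifd, d), kl_exact, tolerance = 1e-5)
})

test_that("sensitivity factor: reconstruction, spectra, factor invariance", {
  I <- rand_spd(5, seed = 51)
  colnames(I) <- rownames(I) <- letters[1:5]
  s1 <- sensitivity_factor(I)
  s2 <- sensitivity_factor(I, method = "sqrt")
  expect_lt(norm(crossprod(s1$s) - I, "F") / norm(I, "F"), 1e-10)
  expect_lt(norm(crossprod(s2$s) - I, "F") / norm(I, "F"), 1e-10)
  # eigenvalues of I are squared singular values of s
  expect_equal(sort(s1$sv^2), sort(eigen(I, symmetric = TRUE)$values),
               tolerance = 1e-8)
  expect_true(all(diff(s1$sv) <= 1e-12))
  # identity FIM: any factor gives the same MX outputs as the identity
  rid <- mx_ordering(diag(4))
  rch <- mx_ordering(sensitivity_factor(diag(4)))
  expect_equal(rid$v, rch$v, tolerance = 1e-10)
  # cross-factor: identical multiplexing reports
  r1 <- mx_ordering(s1); r2 <- mx_ordering(s2)
  expect_identical(r1$ordering, r2$ordering)
  expect_equal(r1$v, r2$v, tolerance = 1e-8)
  expect_equal(r1$dkl, r2$dkl, tolerance = 1e-8)
  expect_error(sensitivity_factor(diag(c(1, -1))), "indefinite")
})
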