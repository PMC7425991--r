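test_that("normal components: orthogonal, collinear, QR vs least squares", {
  s <- cbind(c(2, 0), c(0, 1))
  expect_equal(normal_component(s, 1, 2), c(2, 0))
  s2 <- cbind(c(1, 2), 3 * c(1, 2))
  expect_equal(normal_component(s2, 2, 1), c(0, 0), tolerance = 1e-12)
  expect_error(normal_component(s, 1, 1), "must not")
  expect_error(normal_component(s, 7), "out of range")
  set.seed(61)
  S <- matrix(rnorm(25), 5)
  for (i in c(1, 4)) {
    sub <- setdiff(1:5, i)[1:3]
    n_qr <- normal_component(S, i, sub)
    beta <- solve(crossprod(S[, sub]), crossprod(S[, sub], S[, i]))
    n_ls <- S[, i] - S[, sub] %*% beta
    expect_lt(max(abs(n_qr - n_ls)), 1e-10)
  }
})

test_that("per-signal detectability and the greedy MX ordering", {
  s <- diag(c(2, 1))
  expect_equal(dkl_capacity(s, 1), 2)
  expect_equal(dkl_capacity(s, 2), 0.5)
  dup <- cbind(c(1, 1), c(1, 1))
  expect_equal(dkl_capacity(dup, 1), 0, tolerance = 1e-12)
  expect_equal(dkl_capacity(dup, 2), 0, tolerance = 1e-12)
  rep3 <- mx_ordering(diag(c(3, 2, 1)))
  expect_identical(rep3$ordering, 1:3)
  expect_equal(rep3$v, c(3, 2, 1))
  expect_equal(rep3$MX, c(4.5, 2, 0.5))
  # two identical columns among three: full-set capacity collapses to 0
  s3 <- cbind(c(1, 0, 0), c(0, 1, 0), c(0, 1, 0))
  r3 <- mx_ordering(s3)
  expect_equal(r3$v[3], 0, tolerance = 1e-12)
  expect_equal(r3$MX[3], 0, tolerance = 1e-12)
  expect_true(any(r3$ties))
})

test_that("v monotonicity and the singular-value product identity", {
  set.seed(62)
  for (rep in 1:100) {
    p <- sample(2:6, 1)
    S <- matrix(rnorm(p * p), p)
    r <- mx_ordering(S)
    expect_true(all(diff(r$v) <= 1e-10))
    sv <- svd(S)$d
    for (k in seq_len(p))
      expect_lte(prod(r$v[1:k]), prod(sv[1:k]) * (1 + 1e-8))
    expect_equal(prod(r$v), prod(sv), tolerance = 1e-6)
  }
})

test_that("MX quantities are invariant under orthogonal rotations", {
  set.seed(63)
  S <- matrix(rnorm(25), 5)
  r0 <- mx_ordering(S)
  for (rep in 1:5) {
    Q <- qr.Q(qr(matrix(rnorm(25), 5)))
    r1 <- mx_ordering(Q %*% S)
    expect_identical(r1$ordering, r0$ordering)
    expect_equal(r1$v, r0$v, tolerance = 1e-9)
    expect_equal(r1$dkl, r0$dkl, tolerance = 1e-9)
  }
})

test_that("threshold subsets", {
  r <- mx_ordering(diag(c(3, 2, 1)))
  expect_identical(mx_subset(r, 1), 1:2)
  expect_identical(mx_subset(r, 10), integer(0))
  expect_identical(mx_subset(r, 0.5), 1:3)
  expect_error(mx_subset(r, 0), "m must be")
})

test_that("signal chain rule: identity, singularity, recomputation oracle", {
  set.seed(64)
  S <- matrix(rnorm(16), 4)
  r0 <- mx_ordering(S)
  rid <- mx_ordering(signal_chain(S, diag(4)))
  expect_equal(rid$v, r0$v, tolerance = 1e-12)
  dsing <- diag(4); dsing[4, 4] <- 0
  rs <- mx_ordering(signal_chain(S, dsing))
  expect_equal(rs$MX[4], 0, tolerance = 1e-12)
  expect_error(signal_chain(S, diag(3)), "dimension")
  # chained MX equals MX of the composed map computed by finite differences:
  # linear-Gaussian model over params theta, signals act via theta = D s
  M <- matrix(rnorm(16), 4); S0 <- rand_spd(4)
  D <- diag(4) + 0.2 * matrix(rnorm(16), 4) # well conditioned
  ps_th <- signal_space(setNames(rep(0, 4), paste0("t", 1:4)))
  I_th <- fim(lin_gauss_fn(M, S0), ps_th)
  s_th <- sensitivity_factor(I_th)
  chained <- mx_ordering(signal_chain(s_th, D))
  fn_sig <- function(sg) lin_gauss_fn(M, S0)(drop(D %*% as.numeric(sg)))
  ps_sg <- signal_space(setNames(rep(0, 4), paste0("s", 1:4)))
  direct <- mx_ordering(sensitivity_factor(fim(fn_sig, ps_sg)))
  expect_equal(chained$v, direct$v, tolerance = 1e-4)
  expect_true(is.finite(attr(signal_chain(s_th, D), "condition")))
  expect_gt(attr(signal_chain(s_th, D), "det"), 0)
})

test_that("brute-force oracle agrees with the normal-component formula", {
  set.seed(65)
  M <- matrix(rnorm(9), 3); S0 <- rand_spd(3)
  fn <- lin_gauss_fn(M, S0)
  ps <- signal_space(setNames(rep(0, 3), c("s1", "s2", "s3")))
  s <- sensitivity_factor(fim(fn, ps))
  # orthogonalised probe: for the linear family the oracle equals
  # ||n(i | j != i)||^2 / 2 up to optimiser tolerance
  for (i in 1:3) {
    o <- brute_force_oracle(fn, ps, i, l = 0.01, grid_density = 9)
    expect_equal(o, dkl_capacity(s, i), tolerance = 1e-3)
  }
  # column inside the span of the others: oracle -> 0
  M2 <- M; M2[, 3] <- M[, 1] + M[, 2]
  fn2 <- lin_gauss_fn(M2, S0)
  expect_lt(brute_force_oracle(fn2, ps, 3, l = 0.01), 1e-6)
  # third-order convergence on a quadratically perturbed family; the linear
  # part is kept well conditioned so the normal component stays O(1) and
  # relative gaps are meaningful
  Mw <- diag(3) + 0.3 * matrix(rnorm(9), 3)
  quad <- lapply(1:3, function(j) {
    B <- matrix(rnorm(9), 3); 0.3 * (B + t(B)) })
  fnq <- lin_gauss_fn(Mw, S0, quad = quad)
  sq <- sensitivity_factor(fim(fnq, ps))
  ref <- dkl_capacity(sq, 2)
  gaps <- vapply(c(0.04, 0.02, 0.01), function(l)
    abs(brute_force_oracle(fnq, ps, 2, l = l) - ref) / ref, 0)
  expect_lt(gaps[3], gaps[1])
  expect_lt(gaps[3], 0.05)
  expect_error(brute_force_oracle(fn, ps, 1, l = 0.2), "l must be")
})
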