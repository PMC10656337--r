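sparse10_gamma <- c(rep(0, 8), 1, 1)
sparse10_a <- rep(1, 10)

test_that("L1 profile evaluates the shifted-DIF L1 norm", {
  expect_equal(l1_profile(sparse10_gamma, sparse10_a, c = 0), 2)
  expect_equal(l1_profile(rep(0, 6), runif(6, 0.5, 2), c = 0), 0)
  set.seed(2)
  g <- rnorm(8); a <- rnorm(8); cc <- rnorm(1)
  expect_identical(l1_profile(g, a, cc), sum(abs(g - a * cc)))
  expect_error(l1_profile(1:3, 1:2, 0), "same length")
})

test_that("L1 profile is convex in the shift", {
  set.seed(3)
  for (k in 1:20) {
    g <- rnorm(7); a <- runif(7, 0.3, 2)
    c1 <- rnorm(1, sd = 2); c2 <- rnorm(1, sd = 2); lam <- runif(1)
    expect_lte(l1_profile(g, a, lam * c1 + (1 - lam) * c2),
               lam * l1_profile(g, a, c1) +
                 (1 - lam) * l1_profile(g, a, c2) + 1e-12)
  }
})

test_that("weighted-median shift solves the LAD problem", {
  # sparse configuration with a strict minimum at zero
  expect_identical(ml1_shift(sparse10_gamma, sparse10_a), 0)
  # single item: exact fit
  expect_equal(ml1_shift(3, 2), 1.5)
  expect_equal(l1_profile(3, 2, ml1_shift(3, 2)), 0)
  # grid-search oracle over random instances
  set.seed(10)
  for (k in 1:1000) {
    J <- sample(2:12, 1)
    g <- rnorm(J); a <- runif(J, 0.2, 3) * sample(c(-1, 1), J, TRUE)
    cstar <- ml1_shift(g, a)
    cgrid <- grid_argmin_h(g, a)
    expect_lte(l1_profile(g, a, cstar), l1_profile(g, a, cgrid) + 1e-10)
    expect_lt(abs(ml1_shift(g, a) - cgrid), 2e-4)
  }
})

test_that("the shift is a local (hence global) minimizer of the profile", {
  set.seed(11)
  for (k in 1:50) {
    J <- sample(3:10, 1)
    g <- rnorm(J); a <- runif(J, 0.2, 2)
    cstar <- ml1_shift(g, a)
    h0 <- l1_profile(g, a, cstar)
    for (eps in c(1e-3, 1e-2, 1e-1)) {
      expect_lte(h0, l1_profile(g, a, cstar + eps) + 1e-12)
      expect_lte(h0, l1_profile(g, a, cstar - eps) + 1e-12)
    }
  }
})

test_that("zero-slope items are dropped with a warning; all-zero slopes error", {
  expect_warning(s <- ml1_shift(c(1, 0.5), c(2, 0)), "dropped")
  expect_equal(s, 0.5)
  expect_error(suppressWarnings(ml1_shift(c(1, 1), c(0, 0))), "unidentified")
})

test_that("necessary-and-sufficient condition check matches the profile geometry", {
  v <- check_prop1(sparse10_gamma, sparse10_a)
  expect_true(v$holds)
  # indicator counts for the sparse example
  expect_equal(sum(sparse10_gamma >= 0), 10)
  expect_equal(sum(sparse10_gamma < 0), 0)
  expect_equal(sum(sparse10_gamma <= 0), 8)
  expect_equal(sum(sparse10_gamma > 0), 2)
  expect_equal(v$ineq7_lhs, -10)
  expect_equal(v$ineq8_lhs, 6)

  expect_true(check_prop1(rep(0, 5), rep(1, 5))$holds)

  # one-directional DIF with too few nulls: minimum is away from zero
  g <- c(1, 1, 1, 0); a <- rep(1, 4)
  expect_false(check_prop1(g, a)$holds)
  expect_gt(abs(grid_argmin_h(g, a)), 0.5)

  expect_error(check_prop1(c(0, 1), c(1, 0)), "a_j != 0")
})

test_that("condition check agrees with the minimizer on random instances", {
  set.seed(12)
  for (k in 1:200) {
    J <- sample(3:10, 1)
    g <- round(rnorm(J), 1); a <- runif(J, 0.3, 2)
    v <- check_prop1(g, a)
    cstar <- ml1_shift(g, a)
    if (v$holds) {
      expect_identical(cstar, 0)
      # strictness: profile rises on both sides
      expect_gt(l1_profile(g, a, 1e-6), l1_profile(g, a, 0))
      expect_gt(l1_profile(g, a, -1e-6), l1_profile(g, a, 0))
    } else {
      flat_right <- l1_profile(g, a, 1e-6) <= l1_profile(g, a, 0) + 1e-12
      flat_left <- l1_profile(g, a, -1e-6) <= l1_profile(g, a, 0) + 1e-12
      expect_true(cstar != 0 || flat_right || flat_left)
    }
  }
})

test_that("count-based sufficient condition behaves as a sufficient condition only", {
  # zero DIF: holds whatever the slope spread
  expect_true(check_cor1(rep(0, 6), c(1, 2, 1, 2, 1, 2))$holds)
  # rho* = 2, 7 nulls, one positive- and one negative-ratio item (J = 9)
  a <- c(rep(1, 4), rep(2, 5)); g <- c(rep(0, 7), 0.5, -0.5)
  r <- g / a; rho <- max(abs(a)) / min(abs(a))
  direct <- (sum(r <= 0) > rho * sum(r > 0)) &&
    (sum(r >= 0) > rho * sum(r < 0))
  expect_identical(check_cor1(g, a)$holds, direct)
  expect_equal(check_cor1(g, a)$rho_star, 2)
  # balanced DIF with a large slope spread: sufficient check fails but the
  # exact condition holds
  g2 <- c(0, 0, 1, -1); a2 <- c(1, 1, 4, 4)
  expect_false(check_cor1(g2, a2)$holds)
  expect_true(check_prop1(g2, a2)$holds)
  expect_identical(grid_argmin_h(g2, a2), 0)
})

test_that("minimal-L1 transform re-identifies without changing the model", {
  # already identified: fixed point
  p0 <- mimic_params(0, 1, sparse10_a, rep(0, 10), sparse10_gamma)
  tr0 <- ml1_transform(p0)
  expect_identical(tr0$shift, 0)
  expect_equal(tr0$params$gamma, p0$gamma)
  expect_equal(tr0$params$beta, p0$beta)

  set.seed(13)
  for (k in 1:25) {
    p <- random_params(8)
    cc <- rnorm(1, sd = 2)
    t1 <- ml1_transform(p)
    t2 <- ml1_transform(shift_params(p, cc))
    # invariance over the equivalence class
    expect_equal(t2$params$gamma, t1$params$gamma, tolerance = 1e-10)
    expect_equal(t2$params$beta, t1$params$beta, tolerance = 1e-10)
    # L1 norm never increases; idempotence
    expect_lte(sum(abs(t1$params$gamma)), sum(abs(p$gamma)) + 1e-12)
    t11 <- ml1_transform(t1$params)
    expect_identical(t11$shift, 0)
    expect_equal(t11$params$gamma, t1$params$gamma)
  }
})

test_that("minimal-L1 transform preserves the marginal likelihood", {
  set.seed(14)
  p <- random_params(6)
  dat <- sim_responses(p, 60, seed = 15)
  tr <- ml1_transform(p)
  expect_lt(abs(marginal_loglik(p, dat, quad = gh_quadrature(41)) -
                marginal_loglik(tr$params, dat, quad = gh_quadrature(41))),
            1e-6)
})
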