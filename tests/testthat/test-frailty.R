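test_that("gamma frailty density has mean 1, variance theta, and integrates to 1", {
  expect_equal(gamma_frailty_logdensity(1, 1), -1)   # Exp(1) at u = 1
  dens <- function(u, th) exp(gamma_frailty_logdensity(u, th))
  I <- integrate(function(u) dens(u, 0.5), 0, Inf, rel.tol = 1e-10)$value
  m <- integrate(function(u) u * dens(u, 0.5), 0, Inf, rel.tol = 1e-10)$value
  v <- integrate(function(u) (u - 1)^2 * dens(u, 0.5), 0, Inf,
                 rel.tol = 1e-10)$value
  expect_equal(I, 1, tolerance = 1e-8)
  expect_equal(m, 1, tolerance = 1e-8)
  expect_equal(v, 0.5, tolerance = 1e-8)
  expect_error(gamma_frailty_logdensity(1, 0), "point mass")
  expect_error(gamma_frailty_logdensity(-1, 0.5), "positive")
})

test_that("Laplace transform matches (1+theta*s)^(-1/theta) with a smooth theta -> 0 limit", {
  expect_equal(laplace_transform(0, 0.7), 1)
  expect_equal(laplace_transform(1, 1), 0.5)
  expect_equal(laplace_transform(2, 1e-10), exp(-2))
  # continuity across the independence branch point
  s <- c(0.5, 2, 10)
  expect_equal(laplace_transform(s, 1.0001e-8), laplace_transform(s, 0.9999e-8),
               tolerance = 1e-7)
})

test_that("Kendall's tau is theta/(theta+2), zero at independence, strictly increasing", {
  expect_equal(kendalls_tau(0), 0)
  expect_equal(kendalls_tau(2), 0.5)
  expect_equal(round(100 * kendalls_tau(0.088), 1), 4.2)
  th <- sort(c(0, 10^seq(-4, 2, length.out = 40)))
  tau <- kendalls_tau(th)
  expect_true(all(diff(tau) > 0))
  expect_true(all(tau >= 0 & tau < 1))
})

test_that("cluster marginal log-likelihood matches frozen closed-form values", {
  p <- loglogistic_params(1, 2)
  # single event at t=1, theta=1: log h(1) - 2*log(1 + log 2); h(1) = 1
  expect_equal(cluster_loglik(cluster_data(1, 1), p, 1), -1.053178068,
               tolerance = 1e-8)
  # single censored at t=1, theta=1: log LP(log 2)
  expect_equal(cluster_loglik(cluster_data(1, 0), p, 1), -0.5265890341,
               tolerance = 1e-8)
})

test_that("cluster marginal log-likelihood agrees with the quadrature oracle", {
  set.seed(21)
  for (r in 1:40) {
    theta <- runif(1, 0.05, 2)
    k <- runif(1, 0.8, 8)
    p <- loglogistic_params(runif(1, 5, 25)^-k, k)  # median 5-25 years
    cd <- random_cluster(p, theta)
    ref <- quad_cluster_loglik(cd, p, theta)
    expect_equal(cluster_loglik(cd, p, theta), ref,
                 tolerance = 1e-6 * max(1, abs(ref)))
  }
})

test_that("theta -> 0 recovers the independence log-likelihood", {
  set.seed(22)
  p <- loglogistic_params(0.02, 4)
  for (r in 1:10) {
    cd <- random_cluster(p, 0.5)
    indep <- sum(cd$events * log(conditional_hazard(cd$times, p, cd$etas, "AFT"))) -
      sum(conditional_cumhaz(cd$times, p, cd$etas, "AFT"))
    expect_equal(cluster_loglik(cd, p, 1e-12), indep, tolerance = 1e-6)
    expect_lt(abs(cluster_loglik(cd, p, 1e-8) - indep), 1e-5)
  }
})

test_that("cluster likelihood equals derivatives of the Laplace transform (d <= 2)", {
  set.seed(23)
  p <- loglogistic_params(0.1, 3)
  theta <- 0.6
  LP1 <- function(s) -(1 + theta * s)^(-1 / theta - 1)              # LP'
  LP2 <- function(s) (1 / theta + 1) * theta * (1 + theta * s)^(-1 / theta - 2)
  for (r in 1:10) {
    t2 <- runif(2, 1, 20); e2 <- rnorm(2, 0, 0.3)
    h <- conditional_hazard(t2, p, e2, "AFT")
    A <- sum(conditional_cumhaz(t2, p, e2, "AFT"))
    # all censored: L = LP(A)
    expect_equal(cluster_loglik(cluster_data(t2, c(0, 0), e2), p, theta),
                 log(laplace_transform(A, theta)), tolerance = 1e-10)
    # one event: L = h1 * (-LP'(A))
    expect_equal(cluster_loglik(cluster_data(t2, c(1, 0), e2), p, theta),
                 log(h[1] * (-LP1(A))), tolerance = 1e-10)
    # two events: L = h1*h2*LP''(A)
    expect_equal(cluster_loglik(cluster_data(t2, c(1, 1), e2), p, theta),
                 log(h[1] * h[2] * LP2(A)), tolerance = 1e-10)
  }
})

test_that("total log-likelihood is additive and permutation invariant", {
  set.seed(24)
  p <- loglogistic_params(0.05, 3)
  cd <- cluster_data(2, 1)
  expect_equal(total_loglik(list(cd, cd), p, 0.5),
               2 * cluster_loglik(cd, p, 0.5))
  cls <- replicate(6, random_cluster(p, 0.5), simplify = FALSE)
  expect_equal(total_loglik(cls, p, 0.8), total_loglik(rev(cls), p, 0.8))
  # at theta = 0 splitting a cluster into singletons changes nothing
  big <- random_cluster(p, 0.5, n_max = 6)
  singles <- lapply(seq_along(big$times), function(j)
    cluster_data(big$times[j], big$events[j], big$etas[j]))
  expect_equal(total_loglik(singles, p, 0), cluster_loglik(big, p, 0),
               tolerance = 1e-10)
})

test_that("frailty posterior mean follows gamma conjugacy", {
  p11 <- loglogistic_params(1, 1)
  # theta = 0: degenerate frailty
  expect_equal(frailty_posterior_mean(cluster_data(3, 1), p11, 0), 1)
  # three events with total cumulative hazard A = 1: (2+3)/(2+1)
  t3 <- rep(exp(1 / 3) - 1, 3)
  cd <- cluster_data(t3, c(1, 1, 1))
  expect_equal(sum(conditional_cumhaz(cd$times, p11, cd$etas, "AFT")), 1)
  expect_equal(frailty_posterior_mean(cd, p11, 0.5), 5 / 3, tolerance = 1e-12)
  # d = A = 2 gives exactly 1
  t2 <- rep(exp(1) - 1, 2)
  expect_equal(frailty_posterior_mean(cluster_data(t2, c(1, 1)), p11, 0.5), 1,
               tolerance = 1e-12)
})

test_that("boundary LR test halves the chi-square(1) tail and handles the null mass", {
  expect_equal(lr_test_theta(-10, -10)$p.value, 1)
  expect_equal(lr_test_theta(-10, -10 - 2.706 / 2)$p.value, 0.05,
               tolerance = 1e-3)
  expect_equal(lr_test_theta(-10, -10 - 3.841 / 2)$p.value, 0.025,
               tolerance = 1e-3)
  expect_equal(lr_test_theta(-9, -10)$statistic, 2)
  expect_error(lr_test_theta(-11, -10), "nested")
})
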