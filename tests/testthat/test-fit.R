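test_that("time ratio and Wald p-value behave as documented", {
  expect_equal(time_ratio(0), 1)
  expect_equal(time_ratio(c(1, -1)), exp(c(1, -1)))
  expect_error(time_ratio(NA), "finite")

  expect_equal(wald_pvalue(0, 3), 1)
  expect_equal(wald_pvalue(1.96, 1), 0.05, tolerance = 1e-3)
  # middle wealth-quintile row of a published table prints 0.056
  expect_equal(round(wald_pvalue(-0.014243, 0.0074423), 3), 0.056)
  expect_error(wald_pvalue(1, 0), "positive")
})

test_that("numeric Hessian is exact on a quadratic with known curvature", {
  A <- matrix(c(4, 1, 0.5, 1, 3, 0.2, 0.5, 0.2, 2), 3, 3)
  f <- function(x) 0.5 * drop(t(x) %*% A %*% x) + sum(x)
  H <- frailtyLL:::num_hessian(f, c(0.3, -1, 2))
  expect_equal(H, A, tolerance = 1e-6)
})

test_that("frailty-off AFT fit agrees with an independent log-logistic AFT fitter", {
  skip_if_not_installed("survival")
  cfg <- toy_config(G = 20, n_i = 100, theta = 0, k = 4, beta = c(0.3, -0.2))
  pop <- generate_population(cfg, seed = 31)
  spec <- model_spec_from_schema(toy_schema(), frailty = FALSE)
  fit <- fit_model(pop$data, spec)
  sr <- survival::survreg(survival::Surv(time, event) ~ x1 + x2,
                          data = pop$data, dist = "loglogistic")
  expect_equal(unname(fit$coefficients), unname(coef(sr)), tolerance = 1e-3)
  expect_equal(fit$gamma_reported, sr$scale, tolerance = 1e-3)
  expect_equal(fit$loglik, sr$loglik[2], tolerance = 1e-5)
  # and our SEs match the information-based SEs of the reference fit
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(sr))[1:3])),
               tolerance = 0.02)
})

test_that("fit recovers generating parameters within 3 SE on one simulated dataset", {
  cfg <- toy_config(G = 60, n_i = 200, theta = 0.5, k = 6)
  pop <- generate_population(cfg, seed = 32)
  fit <- fit_model(pop$data, model_spec_from_schema(toy_schema()))
  expect_true(fit$converged)
  truth <- c(log(17), 0.3, -0.2)
  z <- abs(fit$coefficients - truth) / fit$se
  expect_true(all(z < 3))
  expect_equal(fit$shape_k, 6, tolerance = 0.15)
  expect_lt(abs(fit$theta - 0.5) / fit$se_theta, 3)
  expect_equal(fit$tau, fit$theta / (fit$theta + 2))
  # optimum dominates the truth
  ll_truth <- total_loglik_at(pop$data, cfg)
  expect_gte(fit$loglik, ll_truth)
  # small LR p: heterogeneity clearly present
  expect_lt(fit$lr_theta$p.value, 1e-6)
})

test_that("fit is invariant to row order", {
  cfg <- toy_config(G = 15, n_i = 40, theta = 0.3)
  pop <- generate_population(cfg, seed = 33)
  spec <- model_spec_from_schema(toy_schema())
  f1 <- fit_model(pop$data, spec)
  set.seed(1)
  f2 <- fit_model(pop$data[sample(nrow(pop$data)), ], spec)
  expect_equal(f1$loglik, f2$loglik, tolerance = 1e-7)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-5)
})

test_that("rescaling time shifts the intercept by log(c) and nothing else (AFT)", {
  cfg <- toy_config(G = 15, n_i = 40, theta = 0.3)
  pop <- generate_population(cfg, seed = 34)
  spec <- model_spec_from_schema(toy_schema())
  f1 <- fit_model(pop$data, spec)
  d2 <- pop$data
  d2$time <- d2$time * 10
  f2 <- fit_model(d2, spec)
  expect_equal(f2$coefficients[1], f1$coefficients[1] + log(10),
               tolerance = 1e-3, ignore_attr = TRUE)
  expect_equal(f2$coefficients[-1], f1$coefficients[-1], tolerance = 1e-3)
  expect_equal(f2$shape_k, f1$shape_k, tolerance = 1e-2)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-2)
})

test_that("standard errors shrink like 1/sqrt(n)", {
  spec <- model_spec_from_schema(toy_schema(), frailty = FALSE)
  ses <- sapply(c(500, 2000, 8000), function(n) {
    cfg <- toy_config(G = 10, n_i = n / 10, theta = 0, k = 4)
    pop <- generate_population(cfg, seed = 35)
    unname(fit_model(pop$data, spec)$se[2])
  })
  expect_equal(ses[1] / ses[2], 2, tolerance = 0.25)
  expect_equal(ses[2] / ses[3], 2, tolerance = 0.25)
})

test_that("degenerate designs are caught, empty categories dropped with a warning", {
  cfg <- toy_config(G = 8, n_i = 30, theta = 0.2)
  pop <- generate_population(cfg, seed = 36)
  spec <- model_spec_from_schema(toy_schema())
  # single cluster with frailty on
  one <- pop$data[pop$data$cluster == "c001", ]
  expect_error(fit_model(one, spec), "single cluster")
  # collinear dummies
  d <- pop$data
  d$x2 <- d$x1
  expect_error(fit_model(d, model_spec_from_schema(toy_schema())), "singular")
  # empty category is dropped, fit proceeds
  sp3 <- model_spec(list(x1 = c("a", "b", "ghost"), x2 = c("a", "b")))
  expect_warning(f <- fit_model(pop$data, sp3), "ghost")
  expect_true(f$converged)
  # zero-covariate fit has a constant row only
  f0 <- fit_model(pop$data, model_spec())
  tab <- summary_table(f0)
  expect_equal(tab$term, "Constant")
})

test_that("summary table mirrors the fit and its phi column is exp(coef)", {
  cfg <- toy_config(G = 10, n_i = 50, theta = 0.3)
  pop <- generate_population(cfg, seed = 37)
  fit <- fit_model(pop$data, model_spec_from_schema(toy_schema()))
  tab <- summary_table(fit)
  expect_equal(tab$phi, exp(tab$coef))
  expect_equal(nrow(tab), 3)  # constant + 2 dummies
  re <- attr(tab, "random_effects")
  expect_equal(re$tau, re$theta / (re$theta + 2))
  ses <- standard_errors(fit)
  expect_true(all(ses > 0))
  expect_equal(unname(ses["gamma"]), fit$se_gamma)
})
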