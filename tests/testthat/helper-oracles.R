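# Independent oracles and small builders shared across tests.

# Brute-force marginal likelihood of one cluster: numerically integrate
# the frailty-conditional likelihood against the gamma frailty density,
# via the probability transform u = qgamma(x) for a bounded smooth
# integrand. Independent of the closed form in cluster_loglik().
quad_cluster_loglik <- function(cd, p, theta, mode = "AFT") {
  h <- conditional_hazard(cd$times, p, cd$etas, mode)
  H <- conditional_cumhaz(cd$times, p, cd$etas, mode)
  g <- function(x) {
    u <- qgamma(x, shape = 1 / theta, scale = theta)
    vapply(u, function(ui)
      exp(sum(cd$events * log(ui * h)) - ui * sum(H)), numeric(1))
  }
  log(integrate(g, 0, 1, rel.tol = 1e-10, subdivisions = 500L)$value)
}

# random small cluster drawn FROM the model at the given baseline, with
# frailty and random censoring, so cumulative hazards have model scale
random_cluster <- function(p = loglogistic_params(0.02, 4), theta = 0.5,
                           n_max = 6) {
  n <- sample.int(n_max, 1)
  u <- if (theta > 0) rgamma(1, shape = 1 / theta, scale = theta) else 1
  etas <- rnorm(n, 0, 0.5)
  t_lat <- sample_event_time(rep(u, n), etas, p, "AFT")
  C <- runif(n, 5, 60)   # interview-age style right censoring
  cluster_data(times = pmin(t_lat, C), events = as.numeric(t_lat <= C),
               etas = etas)
}

# marginal log-likelihood of a dataset evaluated at the generating truth
total_loglik_at <- function(data, cfg) {
  eta <- rep(0, nrow(data))
  for (nm in names(cfg$covariate_schema))
    eta <- eta + cfg$true_beta[[nm]][as.character(data[[nm]])]
  frailtyLL:::marginal_loglik_vec(data$time, data$event, data$cluster,
                                  unname(eta), cfg$true_baseline,
                                  cfg$true_theta, cfg$mode)
}

# two binary covariates, balanced
toy_schema <- function() list(
  x1 = list(categories = c("a", "b"), probs = c(0.5, 0.5), reference = "a"),
  x2 = list(categories = c("a", "b"), probs = c(0.5, 0.5), reference = "a"))

toy_config <- function(G = 60, n_i = 200, theta = 0.5, k = 6,
                       beta = c(0.3, -0.2), median_t = 17) {
  synthetic_config(
    cluster_sizes = setNames(rep(n_i, G), sprintf("c%03d", seq_len(G))),
    covariate_schema = toy_schema(),
    true_beta = list(x1 = c(a = 0, b = beta[1]), x2 = c(a = 0, b = beta[2])),
    true_intercept = log(median_t), true_shape_k = k, true_theta = theta)
}
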