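# Gamma shared frailty: density, Laplace transform, and the closed-form
# marginal likelihood per cluster.
#
# With u_i ~ Gamma(shape 1/theta, scale theta) (mean 1, variance theta)
# shared by all subjects of cluster i, integrating u_i out of
# prod_j [u h_j]^{d_j} exp(-u H_j) gives, with A = sum_j H_j and
# d = sum_j d_j,
#   log L_i = sum_{d_j=1} log h_j
#           + sum_{m=0}^{d-1} log(1 + m*theta)
#           - (1/theta + d) * log(1 + theta*A),
# the (-1)^d d-th derivative of the Laplace transform LP(s) =
# (1+theta*s)^(-1/theta) evaluated at A, times the hazard product.

# below this, theta is treated as exactly 0 (independence branch)
THETA_EPS <- 1e-8

check_theta <- function(theta, positive = FALSE) {
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta))
    stop("'theta' must be a single finite number")
  if (theta < 0) stop("'theta' must be non-negative")
  if (positive && theta == 0)
    stop("theta = 0 is a point mass at u = 1; it has no density on (0, Inf)")
  invisible(TRUE)
}

#' Gamma frailty density, Laplace transform and Kendall's tau
#'
#' The shared frailty is one-parameter gamma with mean 1 and variance
#' `theta` (shape `1/theta`, scale `theta`). Its Laplace transform is
#' \eqn{LP(s) = (1+\theta s)^{-1/\theta}}, which tends to \eqn{e^{-s}} as
#' \eqn{\theta \to 0} (independence); the within-cluster dependence it
#' induces between two event times is Kendall's
#' \eqn{\tau = \theta/(\theta+2)}.
#'
#' @param u positive frailty value(s).
#' @param theta frailty variance, `>= 0` (`> 0` for the density).
#' @return `gamma_frailty_logdensity`: log-density at `u`;
#'   `laplace_transform`: value in (0, 1]; `kendalls_tau`: value in
#'   \[0, 1).
#' @examples
#' kendalls_tau(0.088)          # ~ 0.042
#' laplace_transform(1, 1)      # 0.5
#' @export
gamma_frailty_logdensity <- function(u, theta) {
  check_theta(theta, positive = TRUE)
  if (any(u <= 0)) stop("'u' must be positive")
  dgamma(u, shape = 1 / theta, scale = theta, log = TRUE)
}

#' @rdname gamma_frailty_logdensity
#' @param s non-negative argument of the Laplace transform.
#' @export
laplace_transform <- function(s, theta) {
  check_theta(theta)
  if (any(s < 0)) stop("'s' must be non-negative")
  if (theta < THETA_EPS) exp(-s) else exp(-log1p(theta * s) / theta)
}

#' @rdname gamma_frailty_logdensity
#' @export
kendalls_tau <- function(theta) {
  if (any(theta < 0)) stop("'theta' must be non-negative")
  theta / (theta + 2)
}

#' Per-cluster survival data
#'
#' Bundles the observed times, event indicators and linear-predictor
#' values of one cluster for use with [cluster_loglik()] and
#' [frailty_posterior_mean()].
#'
#' @param times positive observed times.
#' @param events 0/1 event indicators.
#' @param etas linear predictor values (default all 0).
#' @param cluster_id optional label.
#' @return An object of class `"cluster_data"`.
#' @export
cluster_data <- function(times, events, etas = rep(0, length(times)),
                         cluster_id = NA) {
  if (length(times) != length(events) || length(times) != length(etas))
    stop("'times', 'events' and 'etas' must have equal length")
  check_times(times, positive = TRUE)
  if (!all(events %in% c(0, 1))) stop("'events' must be 0/1")
  if (any(!is.finite(etas))) stop("'etas' must be finite")
  structure(list(cluster_id = cluster_id, times = as.numeric(times),
                 events = as.numeric(events), etas = as.numeric(etas)),
            class = "cluster_data")
}

# Vectorized marginal log-likelihood over all clusters at once.
# cluster must be an integer/factor index; returns a scalar.
marginal_loglik_vec <- function(time, event, cluster, eta, p, theta, mode) {
  H <- conditional_cumhaz(time, p, eta, mode)
  idx <- as.integer(factor(cluster))
  ev <- event == 1
  sumlogh <- if (any(ev))
    sum(log(conditional_hazard(time[ev], p, eta[ev], mode))) else 0
  if (theta < THETA_EPS) {
    ll <- sumlogh - sum(H)
  } else {
    A <- rowsum(H, idx)[, 1]
    d <- rowsum(as.numeric(event), idx)[, 1]
    maxd <- max(d)
    # sum_{m=0}^{d-1} log(1+m*theta) via a cumulative-sum lookup
    cs <- c(0, cumsum(log1p(theta * seq_len(max(maxd, 1)) - theta)))
    ll <- sumlogh + sum(cs[d + 1]) - sum((1 / theta + d) * log1p(theta * A))
  }
  if (!is.finite(ll)) stop("non-finite log-likelihood; parameters out of range")
  ll
}

#' Marginal log-likelihood of clustered survival data
#'
#' `cluster_loglik` evaluates the closed-form contribution of one cluster
#' to the marginal (frailty-integrated) log-likelihood; `total_loglik`
#' sums contributions over clusters. At `theta` below `1e-8` the
#' independence log-likelihood \eqn{\sum \delta_j \log h_j - \sum H_j}
#' is returned (the continuous \eqn{\theta \to 0} limit).
#'
#' @param cd a [cluster_data()] object (`clusters`: a list of them).
#' @param p a [loglogistic_params()] object.
#' @param theta frailty variance, `>= 0`.
#' @param mode covariate metric, `"AFT"` or `"PH"`.
#' @return A finite scalar log-likelihood.
#' @export
cluster_loglik <- function(cd, p, theta, mode = c("AFT", "PH")) {
  stopifnot(inherits(cd, "cluster_data"))
  check_theta(theta)
  mode <- match.arg(mode)
  marginal_loglik_vec(cd$times, cd$events, rep(1L, length(cd$times)),
                      cd$etas, p, theta, mode)
}

#' @rdname cluster_loglik
#' @param clusters list of [cluster_data()] objects.
#' @export
total_loglik <- function(clusters, p, theta, mode = c("AFT", "PH")) {
  if (!length(clusters)) stop("need at least one cluster")
  mode <- match.arg(mode)
  sum(vapply(clusters, cluster_loglik, numeric(1), p = p, theta = theta,
             mode = mode))
}

#' Posterior mean of a cluster's frailty
#'
#' By gamma conjugacy the frailty given a cluster's data is gamma with
#' shape `1/theta + d` and rate `1/theta + A` (`d` events, `A` summed
#' conditional cumulative hazard), so the posterior mean is
#' `(1/theta + d) / (1/theta + A)`. Clusters with more events than their
#' cumulative hazard predicts are frailer (mean > 1). At `theta = 0` the
#' frailty is degenerate at 1.
#'
#' @inheritParams cluster_loglik
#' @return Positive scalar.
#' @export
frailty_posterior_mean <- function(cd, p, theta, mode = c("AFT", "PH")) {
  stopifnot(inherits(cd, "cluster_data"))
  check_theta(theta)
  mode <- match.arg(mode)
  if (theta < THETA_EPS) return(1)
  A <- sum(conditional_cumhaz(cd$times, p, cd$etas, mode))
  d <- sum(cd$events)
  (1 / theta + d) / (1 / theta + A)
}

#' Boundary likelihood-ratio test of zero frailty variance
#'
#' Tests `theta = 0` against `theta > 0`. Because the null value lies on
#' the boundary of the parameter space, the null reference distribution
#' of the LR statistic is the 50:50 mixture of a point mass at 0
#' (chi-square with 0 df) and a chi-square with 1 df:
#' \eqn{p = \tfrac12 P(\chi^2_1 \ge X)} for \eqn{X > 0} and \eqn{p = 1}
#' at \eqn{X = 0}.
#'
#' @param loglik_frailty maximized log-likelihood with frailty.
#' @param loglik_nofrailty maximized log-likelihood without frailty;
#'   must not exceed `loglik_frailty` by more than `1e-6` (nesting).
#' @return A list with elements `statistic` and `p.value`.
#' @examples
#' lr_test_theta(-100, -101.9)  # X = 3.8, p ~ 0.026
#' @export
lr_test_theta <- function(loglik_frailty, loglik_nofrailty) {
  stopifnot(is.finite(loglik_frailty), is.finite(loglik_nofrailty))
  x <- 2 * (loglik_frailty - loglik_nofrailty)
  if (x < -1e-6)
    stop("frailty log-likelihood below no-frailty log-likelihood: ",
         "models are not nested or fits did not converge")
  x <- max(x, 0)
  p <- if (x == 0) 1 else 0.5 * pchisq(x, df = 1, lower.tail = FALSE)
  list(statistic = x, p.value = p)
}
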