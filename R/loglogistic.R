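#' Log-logistic baseline parameters
#'
#' Constructs and validates the parameter pair of the log-logistic
#' survival distribution \eqn{S(t) = 1/(1+\lambda t^k)}. `lam` is a
#' rate-like scale parameter (units time^-k) and `k` a dimensionless
#' shape; the hazard rises then falls iff `k > 1`. The scale metric
#' usually printed by AFT software is `gamma = 1/k` (the log-time scale),
#' available via [reported_gamma()].
#'
#' @param lam positive scale parameter \eqn{\lambda}.
#' @param k positive shape parameter.
#' @return An object of class `"loglogistic_params"`: a list with
#'   elements `lam` and `k`.
#' @examples
#' p <- loglogistic_params(lam = 1, k = 2)
#' loglogistic_survival(1, p)  # 0.5
#' @export
loglogistic_params <- function(lam, k) {
  stopifnot(is.numeric(lam), is.numeric(k), length(lam) == 1L, length(k) == 1L)
  if (!is.finite(lam) || lam <= 0) stop("'lam' must be a finite positive number")
  if (!is.finite(k) || k <= 0) stop("'k' must be a finite positive number")
  structure(list(lam = lam, k = k), class = "loglogistic_params")
}

#' @rdname loglogistic_params
#' @param p a `loglogistic_params` object.
#' @export
reported_gamma <- function(p) {
  stopifnot(inherits(p, "loglogistic_params"))
  1 / p$k
}

#' @export
print.loglogistic_params <- function(x, ...) {
  cat(sprintf("Log-logistic baseline: lambda = %g, k = %g (gamma = 1/k = %g)\n",
              x$lam, x$k, 1 / x$k))
  invisible(x)
}

check_times <- function(t, positive = FALSE) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("times must be finite numbers")
  if (positive) {
    if (any(t <= 0)) stop("times must be strictly positive")
  } else if (any(t < 0)) stop("times must be non-negative")
  invisible(TRUE)
}

#' Log-logistic distribution functions
#'
#' Baseline survival, hazard, density, cumulative hazard and quantile
#' (inverse survival) functions of the log-logistic distribution with
#' \eqn{S(t) = 1/(1+\lambda t^k)}. The cumulative hazard is
#' \eqn{H(t) = -\log S(t) = \log(1+\lambda t^k)}, so `exp(-H)` and `S`
#' agree identically and `pdf = hazard * survival`.
#'
#' @param t vector of non-negative times (strictly positive for the
#'   hazard and density).
#' @param p a [loglogistic_params()] object.
#' @return Numeric vector of the same length as `t` (or `s`).
#' @examples
#' p <- loglogistic_params(1, 2)
#' loglogistic_hazard(1, p)             # 1
#' loglogistic_cumhaz(1, p)             # log(2)
#' loglogistic_quantile(0.5, p)         # median = 1
#' @export
loglogistic_survival <- function(t, p) {
  stopifnot(inherits(p, "loglogistic_params"))
  check_times(t)
  1 / (1 + p$lam * t^p$k)
}

#' @rdname loglogistic_survival
#' @export
loglogistic_hazard <- function(t, p) {
  stopifnot(inherits(p, "loglogistic_params"))
  check_times(t)
  if (any(t == 0) && p$k < 1)
    stop("hazard diverges at t = 0 when k < 1")
  p$lam * p$k * t^(p$k - 1) / (1 + p$lam * t^p$k)
}

#' @rdname loglogistic_survival
#' @export
loglogistic_pdf <- function(t, p) {
  loglogistic_hazard(t, p) * loglogistic_survival(t, p)
}

#' @rdname loglogistic_survival
#' @export
loglogistic_cumhaz <- function(t, p) {
  stopifnot(inherits(p, "loglogistic_params"))
  check_times(t)
  log1p(p$lam * t^p$k)
}

#' @rdname loglogistic_survival
#' @param s survival probability in (0, 1); the quantile returns the time
#'   at which the survival function equals `s`.
#' @export
loglogistic_quantile <- function(s, p) {
  stopifnot(inherits(p, "loglogistic_params"))
  if (!is.numeric(s) || any(!is.finite(s)) || any(s <= 0) || any(s >= 1))
    stop("'s' must lie strictly inside (0, 1)")
  ((1 - s) / (s * p$lam))^(1 / p$k)
}

check_mode <- function(mode) {
  mode <- match.arg(toupper(mode), c("AFT", "PH"))
  mode
}

#' Covariate-adjusted conditional hazard and cumulative hazard
#'
#' Conditional (frailty u = 1) forms of the log-logistic hazard given a
#' linear predictor `eta` = \eqn{\beta'Z}. In `"PH"` mode the hazard is
#' multiplied, \eqn{h(t) = e^{\eta} h_0(t)}; in `"AFT"` mode time is
#' rescaled, \eqn{h(t) = e^{-\eta} h_0(t e^{-\eta})}, so `exp(eta)`
#' multiplies event time (`exp(eta) > 1` delays the event). Both reduce
#' to the baseline at `eta = 0`.
#'
#' @inheritParams loglogistic_survival
#' @param eta linear predictor value(s), finite; recycled against `t`.
#' @param mode `"AFT"` (default) or `"PH"`.
#' @return Numeric vector.
#' @export
conditional_cumhaz <- function(t, p, eta, mode = c("AFT", "PH")) {
  mode <- check_mode(match.arg(mode))
  if (!is.numeric(eta) || any(!is.finite(eta))) stop("'eta' must be finite")
  if (mode == "PH") exp(eta) * loglogistic_cumhaz(t, p)
  else loglogistic_cumhaz(t * exp(-eta), p)
}

#' @rdname conditional_cumhaz
#' @export
conditional_hazard <- function(t, p, eta, mode = c("AFT", "PH")) {
  mode <- check_mode(match.arg(mode))
  if (!is.numeric(eta) || any(!is.finite(eta))) stop("'eta' must be finite")
  if (mode == "PH") exp(eta) * loglogistic_hazard(t, p)
  else exp(-eta) * loglogistic_hazard(t * exp(-eta), p)
}
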