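#' Weibull distribution functions with domain guards
#'
#' The two-parameter Weibull distribution with shape \eqn{k > 0} and scale
#' \eqn{\lambda > 0} (hours) is the parametric family the recurrent model
#' emits for every observation window: its density is
#' \deqn{f(x) = (k/\lambda) (x/\lambda)^{k-1} e^{-(x/\lambda)^k}.}
#' A shape below 1 encodes a failure rate that decreases over time, a shape
#' above 1 one that increases; the scale locates the distribution's width on
#' the time axis.
#'
#' These wrappers enforce the non-negative time domain, handle the density's
#' boundary at `x = 0` explicitly (`k/lambda` for `k = 1`, `0` for `k > 1`,
#' and a large finite sentinel with a warning for `k < 1`, where the density
#' diverges), and otherwise defer to the standard distribution routines.
#'
#' @param x Non-negative time in hours. Vectorised.
#' @param shape Weibull shape \eqn{k}, strictly positive.
#' @param scale Weibull scale \eqn{\lambda} in hours, strictly positive.
#' @param p Probability in (0, 1) for [weib_quantile()].
#' @return Numeric vector: density per hour ([weib_pdf()]), probability
#'   ([weib_cdf()], [weib_survival()]), or hours ([weib_quantile()],
#'   [weib_median()]).
#' @examples
#' weib_pdf(1, shape = 1, scale = 1)      # exp(-1)
#' weib_cdf(3, shape = 2, scale = 3)      # 1 - exp(-1) at x = scale, any shape
#' weib_median(shape = 2, scale = 10)     # 10 * log(2)^(1/2)
#' @name weibull_funs
NULL

check_weibull_params <- function(shape, scale) {
  if (any(!is.finite(shape)) || any(shape <= 0)) {
    stop_domain("Weibull shape must be finite and > 0")
  }
  if (any(!is.finite(scale)) || any(scale <= 0)) {
    stop_domain("Weibull scale must be finite and > 0")
  }
  invisible(NULL)
}

check_time_domain <- function(x) {
  if (any(is.na(x)) || any(x < 0)) {
    stop_domain("time must be >= 0")
  }
  invisible(NULL)
}

#' @rdname weibull_funs
#' @export
weib_pdf <- function(x, shape, scale) {
  check_weibull_params(shape, scale)
  check_time_domain(x)
  out <- stats::dweibull(x, shape = shape, scale = scale)
  at0 <- x == 0
  if (any(at0)) {
    k0 <- rep_len(shape, length(x))[at0]
    l0 <- rep_len(scale, length(x))[at0]
    val0 <- ifelse(k0 > 1, 0, ifelse(k0 == 1, 1 / l0, .Machine$double.xmax))
    if (any(k0 < 1)) {
      warning("density diverges at x = 0 for shape < 1; returning a large finite sentinel")
    }
    out[at0] <- val0
  }
  out
}

#' @rdname weibull_funs
#' @export
weib_cdf <- function(x, shape, scale) {
  check_weibull_params(shape, scale)
  check_time_domain(x)
  stats::pweibull(x, shape = shape, scale = scale)
}

#' @rdname weibull_funs
#' @export
weib_survival <- function(x, shape, scale) {
  check_weibull_params(shape, scale)
  check_time_domain(x)
  stats::pweibull(x, shape = shape, scale = scale, lower.tail = FALSE)
}

#' @rdname weibull_funs
#' @export
weib_quantile <- function(p, shape, scale) {
  check_weibull_params(shape, scale)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop_domain("p must lie strictly inside (0, 1)")
  }
  stats::qweibull(p, shape = shape, scale = scale)
}

#' @rdname weibull_funs
#' @export
weib_median <- function(shape, scale) {
  weib_quantile(0.5, shape, scale)
}

#' Censoring-aware Weibull negative log-likelihood
#'
#' The training objective of the recurrent time-to-event model. For an
#' observation with remaining time \eqn{t > 0} and event indicator \eqn{u}:
#' an observed event (\eqn{u = 1}) contributes \eqn{-\log f(t)}, a censored
#' observation (\eqn{u = 0}) contributes \eqn{-\log S(t) = (t/\lambda)^k}
#' (its event is only known to lie beyond \eqn{t}). Everything is computed in
#' log space so the result is finite for all admissible inputs.
#'
#' @param t Remaining time in hours, strictly positive. Censored times are
#'   expected to already be capped at the safety threshold \eqn{\tau}.
#' @param u Event indicator: 1 = event observed, 0 = censored.
#' @param shape,scale Weibull parameters, strictly positive.
#' @return Numeric vector of per-observation negative log-likelihood
#'   contributions.
#' @examples
#' weib_nll(2, u = 0, shape = 1, scale = 1)  # (2/1)^1 = 2
#' weib_nll(1, u = 1, shape = 1, scale = 1)  # -log(exp(-1)) = 1
#' @export
weib_nll <- function(t, u, shape, scale) {
  check_weibull_params(shape, scale)
  if (any(!is.finite(t)) || any(t <= 0)) {
    stop_domain("remaining time must be finite and > 0")
  }
  if (!all(u %in% c(0, 1))) {
    stop_domain("event indicator u must be 0 or 1")
  }
  lt <- log(t) - log(scale)              # log(t / lambda)
  cumhaz <- exp(pmin(shape * lt, 700))   # (t/lambda)^k, overflow-guarded
  cumhaz - u * (log(shape) + (shape - 1) * lt - log(scale))
}

#' Output-layer link functions and the loss gradient in raw coordinates
#'
#' The network's two output heads produce unconstrained reals which are mapped
#' to valid Weibull parameters by a softplus link for the shape
#' (\eqn{k = \log(1 + e^{a})}) and an exponential link for the scale
#' (\eqn{\lambda = e^{b}}); both are strictly positive and monotone.
#' [wtte_nll_grad_raw()] returns the analytic gradient of [weib_nll()] with
#' respect to the raw (pre-link) outputs, the quantity backpropagated during
#' training.
#'
#' @param raw Unconstrained real input(s).
#' @return [link_shape()], [link_scale()]: strictly positive parameter values.
#'   [wtte_nll_grad_raw()]: a two-column matrix `(d_raw_shape, d_raw_scale)`.
#' @examples
#' link_shape(0)   # log(2)
#' link_scale(0)   # 1
#' @export
link_shape <- function(raw) {
  # log(1 + exp(raw)) computed stably on both tails
  ifelse(raw > 0, raw + log1p(exp(-raw)), log1p(exp(raw)))
}

#' @rdname link_shape
#' @export
link_scale <- function(raw) {
  exp(raw)
}

#' @rdname link_shape
#' @param t,u Remaining time and event indicator as in [weib_nll()].
#' @param raw_shape,raw_scale Raw head outputs (pre-link).
#' @export
wtte_nll_grad_raw <- function(t, u, raw_shape, raw_scale) {
  k <- link_shape(raw_shape)
  lam <- link_scale(raw_scale)
  lt <- log(t) - log(lam)
  e <- exp(pmin(k * lt, 700))
  dk <- e * lt - u * (1 / k + lt)
  dlam <- (k / lam) * (u - e)
  # chain through the links: dk/da = sigmoid(a), dlam/db = lam
  cbind(
    d_raw_shape = dk * stats::plogis(raw_shape),
    d_raw_scale = dlam * lam
  )
}
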