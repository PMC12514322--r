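#' Ex-Gaussian distribution helpers
#'
#' Density, distribution function, quantile function and random generation
#' for the ex-Gaussian distribution, the convolution of a normal
#' (`mu`, `sigma`) and an exponential with mean `tau`.  This is the
#' canonical right-skewed law for simple reaction times: `mu` and `sigma`
#' describe the Gaussian core, `tau` the slow exponential tail, and the
#' population mean is `mu + tau` (all in milliseconds here).
#'
#' @param x,q vector of quantiles (ms).
#' @param p vector of probabilities in (0, 1).
#' @param n number of draws.
#' @param mu Gaussian mean (ms).
#' @param sigma Gaussian standard deviation (ms), `> 0`.
#' @param tau exponential mean (ms), `> 0`.
#' @return `dexgauss` the density, `pexgauss` the CDF, `qexgauss` the
#'   quantile function (numeric inversion of `pexgauss`), `rexgauss`
#'   random draws.
#' @examples
#' pexgauss(500, mu = 400, sigma = 40, tau = 100)
#' qexgauss(0.5, mu = 400, sigma = 40, tau = 100)
#' @name exgauss
NULL

check_exg <- function(mu, sigma, tau) {
  if (!is.finite(mu) || !is.finite(sigma) || !is.finite(tau))
    stop("ex-Gaussian parameters must be finite", call. = FALSE)
  if (sigma <= 0) stop("ex-Gaussian 'sigma' must be > 0", call. = FALSE)
  if (tau <= 0) stop("ex-Gaussian 'tau' must be > 0", call. = FALSE)
  invisible(TRUE)
}

#' @rdname exgauss
#' @export
dexgauss <- function(x, mu, sigma, tau) {
  check_exg(mu, sigma, tau)
  # log-scale to keep the exp factor from overflowing far in the left tail
  lg <- -log(tau) + sigma^2 / (2 * tau^2) - (x - mu) / tau +
    stats::pnorm((x - mu) / sigma - sigma / tau, log.p = TRUE)
  exp(lg)
}

#' @rdname exgauss
#' @export
pexgauss <- function(q, mu, sigma, tau) {
  check_exg(mu, sigma, tau)
  u <- (q - mu) / sigma
  p <- stats::pnorm(u) -
    exp(sigma^2 / (2 * tau^2) - (q - mu) / tau +
          stats::pnorm(u - sigma / tau, log.p = TRUE))
  pmin(pmax(p, 0), 1)
}

#' @rdname exgauss
#' @export
qexgauss <- function(p, mu, sigma, tau) {
  check_exg(mu, sigma, tau)
  if (any(p <= 0 | p >= 1)) stop("'p' must lie strictly in (0, 1)", call. = FALSE)
  # bracket generously: normal quantile shifted by the exponential tail
  lo <- mu - sigma * 10
  hi <- mu + sigma * 10 + tau * 50
  vapply(p, function(pp) {
    stats::uniroot(function(x) pexgauss(x, mu, sigma, tau) - pp,
                   lower = lo, upper = hi, tol = 1e-8, extendInt = "upX")$root
  }, numeric(1))
}

#' @rdname exgauss
#' @export
rexgauss <- function(n, mu, sigma, tau) {
  check_exg(mu, sigma, tau)
  stats::rnorm(n, mu, sigma) + stats::rexp(n, rate = 1 / tau)
}
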