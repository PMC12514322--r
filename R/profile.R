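#' Percentile-indexed congruency-shift profile
#'
#' A delta profile encodes the ground-truth congruency effect of a
#' simulated target type as a quadratic function of the percentile,
#' \eqn{\delta(p) = a + b p + c p^2}, in milliseconds.  Incongruent
#' reaction times are generated from a congruent (baseline) draw `x` by
#' the transform \eqn{g(x) = x + \delta(F(x))}, where `F` is the
#' baseline ex-Gaussian CDF.  When `g` is strictly increasing, the
#' population `q`-quantile of the incongruent distribution equals
#' `Q_cong(q) + delta(q)` exactly, which makes the vincentized delta
#' function recoverable in closed form.  Construction refuses profiles
#' for which `g` is not strictly increasing on a dense grid spanning the
#' baseline quantiles `1e-4` to `1 - 1e-4`.
#'
#' @param a intercept of the shift (ms).
#' @param b linear coefficient (ms per unit percentile).
#' @param c quadratic coefficient (ms per unit percentile squared).
#' @param baseline list with elements `mu`, `sigma`, `tau`: the
#'   ex-Gaussian baseline parameters (ms) against which monotonicity of
#'   the induced transform is checked.
#' @param grid_n number of grid points for the monotonicity check.
#' @return an object of class `delta_profile` with fields `a`, `b`, `c`
#'   and the `baseline` used for validation.
#' @seealso [theoretical_delta()], [simulate_cohort()]
#' @examples
#' pr <- delta_profile(40, -80, 0, baseline = list(mu = 450, sigma = 50, tau = 120))
#' theoretical_delta(pr, c(.1, .3, .5, .7, .9))
#' @export
delta_profile <- function(a, b, c = 0,
                          baseline = list(mu = 450, sigma = 50, tau = 120),
                          grid_n = 1e4) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c),
            length(a) == 1L, length(b) == 1L, length(c) == 1L)
  if (!all(is.finite(c(a, b, c))))
    stop("profile coefficients must be finite", call. = FALSE)
  baseline <- as.list(baseline)
  check_exg(baseline$mu, baseline$sigma, baseline$tau)

  prof <- structure(list(a = a, b = b, c = c, baseline = baseline),
                    class = "delta_profile")

  # strict monotonicity of g(x) = x + delta(F(x)) on a dense quantile grid
  lohi <- qexgauss(c(1e-4, 1 - 1e-4),
                   baseline$mu, baseline$sigma, baseline$tau)
  x <- seq(lohi[1], lohi[2], length.out = grid_n)
  g <- x + delta_fun(prof)(pexgauss(x, baseline$mu, baseline$sigma, baseline$tau))
  bad <- which(diff(g) <= 0)
  if (length(bad)) {
    stop(sprintf(paste0("delta profile (a=%g, b=%g, c=%g) induces a ",
                        "non-increasing incongruent transform: first violation ",
                        "at grid point %d (x = %.2f ms)"),
                 a, b, c, bad[1], x[bad[1]]), call. = FALSE)
  }
  prof
}

# closure evaluating delta(p) for a profile
delta_fun <- function(profile) {
  force(profile)
  function(p) profile$a + profile$b * p + profile$c * p^2
}

#' Evaluate a profile's ground-truth delta function
#'
#' Returns the closed-form congruency-effect shift \eqn{\delta(p)} of a
#' [delta_profile()] at the requested percentiles.  This is the recovery
#' oracle for the simulation pipeline: the vincentized delta estimated
#' from a large simulated cohort converges to these values.
#'
#' @param profile a `delta_profile`.
#' @param probs percentiles in (0, 1).
#' @return numeric vector of shifts (ms), one per probability.
#' @export
theoretical_delta <- function(profile, probs) {
  stopifnot(inherits(profile, "delta_profile"))
  if (any(probs <= 0 | probs >= 1))
    stop("'probs' must lie strictly in (0, 1)", call. = FALSE)
  delta_fun(profile)(probs)
}

#' @export
#' @method print delta_profile
print.delta_profile <- function(x, ...) {
  cat(sprintf("delta profile: delta(p) = %g %+g p %+g p^2  (ms)\n",
              x$a, x$b, x$c))
  cat(sprintf("validated against ex-Gaussian baseline (mu=%g, sigma=%g, tau=%g)\n",
              x$baseline$mu, x$baseline$sigma, x$baseline$tau))
  invisible(x)
}
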