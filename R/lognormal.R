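#' Lognormal parameter container
#'
#' Holds the mean and standard deviation of a lognormal distribution at log
#' scale, together with the unit of the natural-scale variable.  This is the
#' working representation for menstrual iron loss per cycle, skewed intake
#' distributions, and the fitted summary of the simulated requirement
#' distribution.
#'
#' @param mu Mean at log scale.
#' @param sigma Standard deviation at log scale; must be strictly positive.
#' @param unit Unit of the natural-scale quantity, e.g. `"mg/cycle"`.
#' @return An object of class `lognormal_params`.
#' @examples
#' lognormal_params(2.13, 1.04, unit = "mg/cycle")
#' @export
lognormal_params <- function(mu, sigma, unit = "mg/d") {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) {
    stop("'sigma' must be strictly positive (degenerate lognormal not allowed)")
  }
  structure(list(mu = mu, sigma = sigma, unit = unit),
            class = "lognormal_params")
}

#' @export
print.lognormal_params <- function(x, ...) {
  cat(sprintf("Lognormal(mu = %.4g, sigma = %.4g) [%s]; median %.4g, mean %.4g\n",
              x$mu, x$sigma, x$unit, exp(x$mu),
              exp(x$mu + x$sigma^2 / 2)))
  invisible(x)
}

#' Lognormal parameters from a reported range
#'
#' Solves for the unique lognormal whose `p`-th and `q`-th percentiles equal
#' the reported lower and upper bounds.  Published menstrual-loss studies
#' usually report a minimum and maximum; interpreting these as the 2.5th and
#' 97.5th percentiles gives two equations
#' `pnorm((log(lower) - mu)/sigma) = p` and
#' `pnorm((log(upper) - mu)/sigma) = q`, which have the closed-form solution
#' `sigma = (log(upper) - log(lower)) / (z_q - z_p)` and
#' `mu = (z_q log(lower) - z_p log(upper)) / (z_q - z_p)`.
#'
#' @param lower Reported lower bound (> 0), interpreted as the `p`-th
#'   percentile.
#' @param upper Reported upper bound (>= lower), interpreted as the `q`-th
#'   percentile.
#' @param p,q Percentile ranks assigned to `lower` and `upper`; defaults
#'   0.025 and 0.975.  Must satisfy `0 < p < q < 1`.
#' @param unit Unit label carried on the result.
#' @return A [lognormal_params] object.
#' @examples
#' lognormal_from_range(2, 50)                  # a typical blood-loss range
#' lognormal_from_range(5, 40, p = 0.1, q = 0.9) # sensitivity to rank choice
#' @export
lognormal_from_range <- function(lower, upper, p = 0.025, q = 0.975,
                                 unit = "mg/cycle") {
  stopifnot(is.numeric(lower), is.numeric(upper),
            is.numeric(p), is.numeric(q))
  if (lower <= 0 || upper <= 0) stop("range bounds must be strictly positive")
  if (upper < lower) stop("'upper' must be >= 'lower'")
  if (!(p > 0 && p < q && q < 1)) stop("need 0 < p < q < 1")
  if (upper == lower) {
    stop("degenerate range (lower == upper): sigma would be 0; ",
         "a point mass is not a valid lognormal")
  }
  zp <- stats::qnorm(p)
  zq <- stats::qnorm(q)
  sigma <- (log(upper) - log(lower)) / (zq - zp)
  mu <- (zq * log(lower) - zp * log(upper)) / (zq - zp)
  lognormal_params(mu, sigma, unit = unit)
}

#' Pool lognormal estimates across studies
#'
#' Combines per-study lognormal parameters by a sample-size-weighted mean of
#' the log-scale means and, by default, of the log-scale standard deviations.
#' Weighting the SDs themselves (rather than the variances) is the literal
#' reading of "weighted mean of the estimates"; weighting the variances is
#' available via `sigma_method = "variance"`.
#'
#' @param params A list of [lognormal_params], one per study.
#' @param n Integer vector of per-study sample sizes (weights).
#' @param sigma_method `"sd"` (default) pools sigma by weighted mean of the
#'   per-study sigmas; `"variance"` pools the variances and returns the square
#'   root.
#' @return A [lognormal_params] object with the pooled parameters.
#' @examples
#' pool_lognormal(list(lognormal_params(1, 0.5), lognormal_params(3, 1.5)),
#'                n = c(10, 30))
#' @export
pool_lognormal <- function(params, n, sigma_method = c("sd", "variance")) {
  sigma_method <- match.arg(sigma_method)
  if (length(params) == 0L) stop("no studies to pool")
  if (!all(vapply(params, inherits, logical(1), "lognormal_params"))) {
    stop("'params' must be a list of lognormal_params objects")
  }
  if (length(n) != length(params) || any(n < 1)) {
    stop("'n' must give a sample size >= 1 for every study")
  }
  units <- vapply(params, `[[`, character(1), "unit")
  if (length(unique(units)) != 1L) {
    stop("cannot pool studies with mixed units: ",
         paste(unique(units), collapse = ", "))
  }
  w <- n / sum(n)
  mus <- vapply(params, `[[`, numeric(1), "mu")
  sigmas <- vapply(params, `[[`, numeric(1), "sigma")
  mu_pooled <- sum(w * mus)
  sigma_pooled <- switch(sigma_method,
    sd = sum(w * sigmas),
    variance = sqrt(sum(w * sigmas^2))
  )
  lognormal_params(mu_pooled, sigma_pooled, unit = units[[1L]])
}
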