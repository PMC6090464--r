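# Maximum-likelihood fits of the two weight-distribution models on the
# surviving |w| values, scored by Kolmogorov-Smirnov distance. The
# boundary-power model has a closed-form MLE; the truncated power law is
# fitted numerically with the normalization constant evaluated on the
# bounded domain.

validateFitValues <- function(values, wt) {
  if (length(values) < 10)
    stop(sprintf("insufficient data: %d values (need at least 10)",
                 length(values)))
  if (any(values <= wt) || any(values > 1))
    stop("all values must lie in (w_t, 1]")
  if (any(values == 1)) {
    warning("values exactly equal to 1 perturbed to 1 - 1e-12")
    values[values == 1] <- 1 - 1e-12
  }
  values
}

boundaryPowerLogLik <- function(gamma, values, lo) {
  length(values) * log(gamma + 1) + gamma * sum(log(1 - values)) -
    length(values) * (gamma + 1) * log(1 - lo)
}

#' Fit the boundary-power distribution model
#'
#' Fits p(|w|) = (gamma + 1) (1 - |w|)^gamma, renormalized to the
#' post-threshold domain (w_t, 1\] (conditional density
#' (gamma + 1) (1 - |w|)^gamma / (1 - w_t)^(gamma + 1)). The MLE is closed
#' form: gamma_hat = -n / sum(ln((1 - |w_k|) / (1 - w_t))) - 1. A negative
#' threshold (reachable on the sweep grid) clamps the domain lower bound to
#' 0, where the model is defined.
#'
#' @param values surviving |w| values, each in (w_t, 1\].
#' @param wt fit-domain lower bound (the threshold).
#' @return a [DistributionFit-class] with parameter `gamma`.
#' @examples
#' x <- sampleBoundaryPower(10, 2000, seed = 1)
#' fitParams(fitBoundaryPower(x, 0))
#' @export
fitBoundaryPower <- function(values, wt = 0) {
  lo <- max(wt, 0)
  values <- validateFitValues(values, wt)
  n <- length(values)
  s <- sum(log((1 - values) / (1 - lo)))
  gammaHat <- -n / s - 1
  cdf <- function(x) 1 - ((1 - x) / (1 - lo))^(gammaHat + 1)
  new("DistributionFit", modelName = "boundary_power",
      params = c(gamma = gammaHat),
      logLik = boundaryPowerLogLik(gammaHat, values, lo),
      ksDistance = ksDistance(values, cdf),
      nValues = n, wt = wt)
}

# log of the normalization integral of x^(alpha-1) exp(-x/xc) on (lo, hi].
# Routed through pgamma (with the Gamma prefactor restored) when alpha > 0;
# direct quadrature otherwise.
tplLogNorm <- function(alpha, xc, lo, hi) {
  if (alpha > 0) {
    d <- stats::pgamma(hi, shape = alpha, scale = xc) -
      stats::pgamma(lo, shape = alpha, scale = xc)
    if (!is.finite(d) || d <= 0) return(NA_real_)
    lgamma(alpha) + alpha * log(xc) + log(d)
  } else {
    v <- tryCatch(
      stats::integrate(function(t) t^(alpha - 1) * exp(-t / xc), lo, hi,
                       rel.tol = 1e-10)$value,
      error = function(e) NA_real_)
    if (!is.finite(v) || v <= 0) return(NA_real_)
    log(v)
  }
}

tplCdf <- function(alpha, xc, lo, hi) {
  if (alpha > 0) {
    plo <- stats::pgamma(lo, shape = alpha, scale = xc)
    phi <- stats::pgamma(hi, shape = alpha, scale = xc)
    function(x) (stats::pgamma(x, shape = alpha, scale = xc) - plo) /
      (phi - plo)
  } else {
    # trapezoid CDF on a fine grid; alpha <= 0 only arises with lo > 0
    grid <- seq(lo, hi, length.out = 4001)
    f <- grid^(alpha - 1) * exp(-grid / xc)
    cum <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * diff(grid)))
    cum <- cum / cum[length(cum)]
    function(x) stats::approx(grid, cum, xout = x, rule = 2)$y
  }
}

#' Fit the exponentially truncated power law
#'
#' Fits the density proportional to x^(alpha - 1) exp(-x / x_c),
#' normalized on (w_t, 1\], by numerical maximum likelihood over
#' alpha in (-10, 10\] and x_c in (1e-3, 1e3). When the domain extends to
#' 0 the exponent is bounded below at 0.05 so the density stays
#' normalizable. The exponential is decaying: that is the truncation the
#' comparator literature defines.
#'
#' @param values surviving |w| values, each in (w_t, 1\].
#' @param wt fit-domain lower bound (the threshold).
#' @param variable "w" (default) fits |w| directly; "wtilde" fits the
#'   complement 1 - |w| instead.
#' @return a [DistributionFit-class] with parameters `alpha` and `x_c`.
#' @export
fitTruncatedPowerLaw <- function(values, wt = 0,
                                 variable = c("w", "wtilde")) {
  variable <- match.arg(variable)
  lo <- max(wt, 0)
  values <- validateFitValues(values, wt)
  if (variable == "wtilde") {
    x <- 1 - values
    dlo <- 0
    dhi <- 1 - lo
  } else {
    x <- values
    dlo <- lo
    dhi <- 1
  }
  x[x < 1e-12] <- 1e-12
  n <- length(x)
  aLow <- if (dlo < 1e-3) 0.05 else -10
  sumLog <- sum(log(x))
  sumX <- sum(x)
  nll <- function(par) {
    a <- par[1]
    xc <- exp(par[2])
    lz <- tplLogNorm(a, xc, dlo, dhi)
    if (!is.finite(lz)) return(1e10)
    -((a - 1) * sumLog - sumX / xc - n * lz)
  }
  opt <- stats::optim(c(1, log(0.3)), nll, method = "L-BFGS-B",
                      lower = c(aLow, log(1e-3)),
                      upper = c(10, log(1e3)),
                      control = list(maxit = 500))
  if (opt$convergence != 0)
    stop(sprintf("truncated power law fit failed to converge (code %d: %s)",
                 opt$convergence, opt$message))
  alpha <- opt$par[1]
  xc <- exp(opt$par[2])
  cdf <- tplCdf(alpha, xc, dlo, dhi)
  new("DistributionFit", modelName = "truncated_power_law",
      params = c(alpha = alpha, x_c = xc),
      logLik = -opt$value,
      ksDistance = ksDistance(x, cdf),
      nValues = n, wt = wt)
}

#' Kolmogorov-Smirnov distance between a sample and a model CDF
#'
#' D = sup over the sample points of |F_e - P|, evaluating both sides of
#' each empirical step (the supremum of the difference with a continuous
#' model CDF occurs at a step edge). Invariant to duplicating sample
#' points.
#'
#' @param values sample inside the model's domain.
#' @param modelCdf vectorized cumulative distribution function,
#'   nondecreasing from 0 to 1 on that domain.
#' @return distance in \[0, 1\].
#' @examples
#' ksDistance(c(0.25, 0.75), function(x) x) # 0.25 against uniform
#' @export
ksDistance <- function(values, modelCdf) {
  if (length(values) == 0) stop("'values' must be non-empty")
  x <- sort(values)
  u <- unique(x)
  cu <- cumsum(tabulate(match(x, u), nbins = length(u))) / length(x)
  fu <- modelCdf(u)
  if (any(!is.finite(fu)) || any(fu < -1e-9) || any(fu > 1 + 1e-9))
    stop("model CDF returned values outside [0, 1] on the sample")
  max(abs(cu - fu), abs(c(0, cu[-length(cu)]) - fu))
}
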