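# The Rician (Rice) distance model. When two points at true separation mu
# are each localized with isotropic Gaussian noise, the measured 2D
# Euclidean distance d follows the Rice law
#
#   p(d | mu, sigma) = (d / sigma^2) exp(-(mu^2 + d^2) / (2 sigma^2))
#                      I0(d mu / sigma^2)
#
# with I0 the modified Bessel function of order 0. mu = 0 reduces to the
# Rayleigh distribution; mu >> sigma approaches Normal(mu, sigma). The
# density above is the normalized form (it integrates to one); a commonly
# reprinted variant carries an extra 1/(2 pi) factor which leaves MLE
# locations untouched but breaks normalization, and is deliberately not
# used here.

# log I0(z), finite for arbitrarily large z. R's besselI underflows for
# z beyond ~5e5 even when exponentially scaled, so the uniform asymptotic
# series takes over above z = 500 (relative error < 1e-9 there).
log_i0 <- function(z) {
  out <- numeric(length(z))
  lo <- z < 500
  if (any(lo)) {
    out[lo] <- log(besselI(z[lo], 0, expon.scaled = TRUE)) + z[lo]
  }
  if (any(!lo)) {
    zh <- z[!lo]
    out[!lo] <- zh - 0.5 * log(2 * pi * zh) +
      log1p(1 / (8 * zh) + 9 / (128 * zh^2) + 225 / (3072 * zh^3))
  }
  out
}

# I1(z)/I0(z), same large-argument strategy; used by the analytic gradient.
i1_over_i0 <- function(z) {
  out <- numeric(length(z))
  lo <- z < 500
  if (any(lo)) {
    out[lo] <- besselI(z[lo], 1, expon.scaled = TRUE) /
      besselI(z[lo], 0, expon.scaled = TRUE)
  }
  if (any(!lo)) {
    zh <- z[!lo]
    out[!lo] <- 1 - 1 / (2 * zh) - 1 / (8 * zh^2)
  }
  out
}

#' Rice distance distribution
#'
#' Normalized density, log-density, distribution function and random
#' generation for the Rice law of 2D distances between two noisily
#' localized points. `mu` is the true separation, `sigma` the per-axis
#' localization scale; both in the same units as `d` (nm throughout the
#' pipeline).
#'
#' `rice_cdf` evaluates via the noncentral chi-squared representation
#' (d^2/sigma^2 is noncentral chi-squared with 2 df and ncp mu^2/sigma^2).
#' `sample_rician` draws distances as the modulus of a 2D Gaussian
#' displacement with mean length `mu`, which is the defining construction.
#'
#' @param d distances, nonnegative.
#' @param mu true separation, >= 0.
#' @param sigma distribution scale, > 0.
#' @param n number of draws.
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return `rice_logpdf` and `rice_pdf` return densities evaluated at `d`;
#'   `rice_cdf` probabilities; `sample_rician` a numeric vector of `n`
#'   distances.
#' @examples
#' integrate(rice_pdf, 0, 60, mu = 20, sigma = 5)   # == 1
#' mean(sample_rician(1e4, 0, 1, seed = 1))          # ~ sqrt(pi/2)
#' @export
rice_logpdf <- function(d, mu, sigma) {
  check_rice_par(mu, sigma)
  if (any(d < 0)) stop("distances must be nonnegative", call. = FALSE)
  s2 <- sigma^2
  ifelse(d == 0, -Inf,
         log(d) - log(s2) - (mu^2 + d^2) / (2 * s2) + log_i0(d * mu / s2))
}

#' @rdname rice_logpdf
#' @export
rice_pdf <- function(d, mu, sigma) exp(rice_logpdf(d, mu, sigma))

#' @rdname rice_logpdf
#' @export
rice_cdf <- function(d, mu, sigma) {
  check_rice_par(mu, sigma)
  stats::pchisq(d^2 / sigma^2, df = 2, ncp = mu^2 / sigma^2)
}

#' @rdname rice_logpdf
#' @export
sample_rician <- function(n, mu, sigma, seed = NULL) {
  check_rice_par(mu, sigma)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a positive count", call. = FALSE)
  }
  with_seed(seed, {
    x <- mu + stats::rnorm(n, 0, sigma)
    y <- stats::rnorm(n, 0, sigma)
    sqrt(x^2 + y^2)
  })
}

check_rice_par <- function(mu, sigma) {
  if (!is.numeric(mu) || length(mu) != 1L || !is.finite(mu) || mu < 0) {
    stop("'mu' must be a single finite number >= 0", call. = FALSE)
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single finite number > 0", call. = FALSE)
  }
  invisible(NULL)
}

# Negative log-likelihood and analytic gradient on (mu, log sigma).
rice_nll <- function(par, d) {
  -sum(rice_logpdf(d, par[1], exp(par[2])))
}
rice_nll_grad <- function(par, d) {
  mu <- par[1]; s2 <- exp(2 * par[2])
  z <- d * mu / s2
  r <- i1_over_i0(z)
  dmu <- sum(-mu / s2 + (d / s2) * r)
  dlogsigma <- sum(-2 + (mu^2 + d^2) / s2 - 2 * z * r)
  -c(dmu, dlogsigma)
}

#' Maximum-likelihood fit of the Rice distance distribution
#'
#' Estimates (mu, sigma) by bounded quasi-Newton maximization of the Rice
#' log-likelihood with an analytic gradient, parameterized on
#' (mu, log sigma) with mu >= 0. Initialization is moment-based: sigma0
#' from the Rayleigh-corrected variance, mu0 from E\[d^2\] = mu^2 + 2 sigma^2
#' (clamped at zero when the moment estimate would be imaginary). A mu-hat
#' on the boundary is reported as 0 and flagged, not treated as an error.
#'
#' @param d numeric vector of distances (nm); n >= 3, all >= 0, not all
#'   identical.
#' @return a list with elements `mu`, `sigma`, `loglik`, `n`, `boundary`
#'   (TRUE when mu-hat sits at 0) and `convergence` (0 for success).
#' @examples
#' d <- sample_rician(2000, 20, 10, seed = 1)
#' fit_rice(d)[c("mu", "sigma")]
#' @export
fit_rice <- function(d) {
  d <- as.numeric(d)
  if (length(d) < 3L) stop("need at least 3 distances", call. = FALSE)
  if (any(!is.finite(d)) || any(d < 0)) {
    stop("distances must be finite and nonnegative", call. = FALSE)
  }
  if (stats::sd(d) < .Machine$double.eps * max(1, mean(d))) {
    stop("degenerate sample: all distances identical (sigma -> 0)",
         call. = FALSE)
  }
  m2 <- mean(d^2); v <- stats::var(d)
  sigma0 <- sqrt(max(v / (2 - pi / 2), 1e-12))
  mu0 <- sqrt(max(m2 - 2 * sigma0^2, 0))
  # The Rice likelihood can hold a local maximum on the mu = 0 (Rayleigh)
  # boundary next to an interior optimum, so the moment start is backed
  # up by two further starts and the best converged solution wins.
  starts <- list(c(mu0, log(sigma0)),
                 c(stats::median(d), log(max(stats::sd(d), 1e-12))),
                 c(mean(d), log(max(sqrt(v / 2), 1e-12))))
  opt <- NULL
  for (s0 in starts) {
    o <- tryCatch(
      stats::optim(s0, rice_nll, rice_nll_grad, d = d,
                   method = "L-BFGS-B",
                   lower = c(0, s0[2] - 20), upper = c(Inf, s0[2] + 20),
                   control = list(factr = 10, pgtol = 1e-10, maxit = 500)),
      error = function(e) NULL)
    if (is.null(o) || (o$convergence != 0 && o$convergence != 52)) next
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  if (is.null(opt)) {
    stop(sprintf(paste0("Rice MLE did not converge from any start; ",
                        "moment init mu0=%.4g sigma0=%.4g"),
                 mu0, sigma0), call. = FALSE)
  }
  mu <- opt$par[1]; sigma <- exp(opt$par[2])
  list(mu = mu, sigma = sigma, loglik = -opt$value, n = length(d),
       boundary = mu < 1e-8 * sigma, convergence = opt$convergence)
}
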