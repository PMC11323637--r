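#' Inverse-gamma draws
#'
#' `rinvgamma(n, shape, scale)` draws from the inverse-gamma distribution
#' with density \eqn{\propto x^{-shape-1} e^{-scale/x}} (so `1/X` is
#' `Gamma(shape, rate = scale)`). This is the parameterization used by every
#' conditional in the shrinkage sampler.
#'
#' @param n Number of draws.
#' @param shape,scale Positive parameters (vectorized).
#' @return Numeric vector of length `n`.
#' @export
rinvgamma <- function(n, shape, scale) {
  1 / stats::rgamma(n, shape = shape, rate = scale)
}

#' @rdname rinvgamma
#' @param x Quantiles.
#' @export
pinvgamma <- function(x, shape, scale) {
  stats::pgamma(scale / pmax(x, .Machine$double.xmin), shape = shape, lower.tail = FALSE)
}

#' Half-Cauchy scale-mixture draws
#'
#' Composes the inverse-gamma mixture
#' \eqn{x^2 | a \sim IG(1/2, 1/a)}, \eqn{a \sim IG(1/2, 1)} whose marginal is
#' the standard half-Cauchy \eqn{C^+(0,1)} on \eqn{x}. This identity is what
#' lets the sampler update half-Cauchy-distributed shrinkage scales through
#' conjugate inverse-gamma steps.
#'
#' @param n Number of draws.
#' @return Positive numeric vector distributed as \eqn{C^+(0,1)}.
#' @export
rhalfcauchy_mixture <- function(n) {
  a <- rinvgamma(n, 1 / 2, 1)
  sqrt(rinvgamma(n, 1 / 2, 1 / a))
}

#' Generalized inverse-Gaussian draws
#'
#' Samples from the three-parameter GIG distribution with density
#' \eqn{f(x) \propto x^{p-1} \exp\{-(a x + b/x)/2\}}, \eqn{x > 0}, via
#' Devroye's log-concave rejection algorithm. Degenerate boundary cases are
#' the conjugate limits the sampler actually hits: `b = 0` reduces to
#' `Gamma(p, rate = a/2)` (requires `p > 0`), `a = 0` to
#' `InvGamma(-p, b/2)` (requires `p < 0`).
#'
#' @param n Number of draws.
#' @param p Real order parameter.
#' @param a,b Non-negative rate parameters (not both 0 unless the
#'   corresponding gamma limit exists).
#' @return Positive numeric vector of length `n`.
#' @export
rgig <- function(n, p, a, b) {
  if (length(p) != 1L || length(a) != 1L || length(b) != 1L)
    return(mapply(function(pp, aa, bb) rgig(1L, pp, aa, bb),
                  rep_len(p, n), rep_len(a, n), rep_len(b, n)))
  if (b <= 0) {
    if (p <= 0) stop("rgig: b = 0 requires p > 0")
    return(stats::rgamma(n, shape = p, rate = a / 2))
  }
  if (a <= 0) {
    if (p >= 0) stop("rgig: a = 0 requires p < 0")
    return(rinvgamma(n, shape = -p, scale = b / 2))
  }
  vapply(seq_len(n), function(i) gig_one(p, a, b), numeric(1))
}

# single GIG(p, a, b) draw; Devroye (2014) rejection from a log-concave hat
gig_one <- function(p, a, b) {
  lam <- p
  swap <- FALSE
  if (lam < 0) { lam <- -lam; swap <- TRUE }
  omega <- sqrt(a * b)
  alpha <- sqrt(omega^2 + lam^2) - lam
  psi <- function(x) -alpha * (cosh(x) - 1) - lam * (exp(x) - x - 1)
  dpsi <- function(x) -alpha * sinh(x) - lam * (exp(x) - 1)

  x <- -psi(1)
  t <- if (x >= 0.5 && x <= 2) 1
       else if (x > 2) sqrt(2 / (alpha + lam))
       else log(4 / (alpha + 2 * lam))
  x <- -psi(-1)
  s <- if (x >= 0.5 && x <= 2) 1
       else if (x > 2) sqrt(4 / (alpha * cosh(1) + lam))
       else min(1 / lam, log(1 + 1 / alpha + sqrt(1 / alpha^2 + 2 / alpha)))

  eta <- -psi(t); zeta <- -dpsi(t); theta <- -psi(-s); xi <- dpsi(-s)
  pp <- 1 / xi; r <- 1 / zeta
  td <- t - r * eta; sd_ <- s - pp * theta
  q <- td + sd_

  repeat {
    u <- stats::runif(1); v <- stats::runif(1); w <- stats::runif(1)
    if (u < q / (pp + q + r)) {
      rnd <- -sd_ + q * v
    } else if (u < (q + r) / (pp + q + r)) {
      rnd <- td - r * log(v)
    } else {
      rnd <- -sd_ + pp * log(v)
    }
    f1 <- if (rnd > td) exp(-eta - zeta * (rnd - t)) else 1
    f2 <- if (rnd < -sd_) exp(-theta + xi * (rnd + s)) else 1
    if (w * f1 * f2 <= exp(psi(rnd))) break
  }
  rnd <- exp(rnd) * (lam / omega + sqrt(1 + lam^2 / omega^2))
  if (swap) rnd <- 1 / rnd
  rnd / sqrt(a / b)
}
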